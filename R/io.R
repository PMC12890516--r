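#' Read a long-format trace file
#'
#' Reads a TSV/CSV of chase traces: columns `time_s`, `intensity`, optional
#' `background`, and the label columns `fiber_id`, `subject_id`, `group`,
#' `treatment` as available. One file may hold many fibers.
#'
#' @param path File path; the delimiter is taken from the extension (`.csv`
#'   is comma, anything else tab).
#' @return A tibble.
#' @export
read_traces <- function(path) {
  data <- read_delim_auto(path)
  check_columns(data, c("time_s", "intensity", "fiber_id"), path)
  data
}

#' Read a protein x sample abundance file
#'
#' First column `protein_id`, one numeric column per sample; blank cells are
#' missing values.
#'
#' @inheritParams read_traces
#' @return A tibble (see [abundance-tables]).
#' @export
read_abundance <- function(path) {
  data <- read_delim_auto(path)
  check_columns(data, "protein_id", path)
  data
}

#' Read a sample-to-group map file
#'
#' Two columns: `sample_id`, `group`.
#'
#' @inheritParams read_traces
#' @return A tibble.
#' @export
read_group_map <- function(path) {
  data <- read_delim_auto(path)
  check_columns(data, c("sample_id", "group"), path)
  data
}

#' Read a term annotation (two-column TSV or GMT)
#'
#' Two-column files must have `term_id` and `protein_id` columns. `.gmt`
#' files use the usual layout: term, description, then member ids.
#'
#' @inheritParams read_traces
#' @return A tibble (`term_id`, `protein_id`).
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    return(list_rbind(map(lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L) {
        stop_invalid(sprintf("malformed GMT line: %s", substr(l, 1, 40)))
      }
      tibble(term_id = parts[1], protein_id = parts[-(1:2)])
    })))
  }
  data <- read_delim_auto(path)
  check_columns(data, c("term_id", "protein_id"), path)
  data[, c("term_id", "protein_id")]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("input file not found: %s", path))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

write_table <- function(data, path) {
  data <- data[, !vapply(data, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}
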