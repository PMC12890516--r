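#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 pmap list_rbind
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "myorelax_invalid_input")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stop_invalid <- function(msg) abort(msg, class = "myorelax_invalid_input")

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_invalid(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
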