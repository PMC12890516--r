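#' Classify fiber type from myosin heavy-chain abundances
#'
#' Implements the percentage rule used for proteomic fiber typing: the
#' abundances of the four adult MYH isoforms are summed per sample and each
#' isoform expressed as a percentage. A sample with >= 80 % of one isoform is
#' a pure fiber, named by the isoform-to-type map (MYH7 -> I, MYH2 -> 2A,
#' MYH1 -> 2X, MYH4 -> 2B); otherwise it is a mixed fiber named by the
#' highest and second-highest contributions, highest first (e.g. dominant
#' MYH7 with MYH2 second gives "mixed I/2A"). Percentage ties are broken by
#' the fixed isoform order MYH7 > MYH2 > MYH1 > MYH4.
#'
#' @param data A data frame with one row per sample/fiber holding the four
#'   isoform abundance columns (arbitrary, non-negative units).
#' @param isoform_cols Named character vector mapping isoform column names in
#'   `data`; names must be `MYH7`, `MYH2`, `MYH1`, `MYH4`. Defaults to
#'   lower-case column names `myh7` etc.
#' @param threshold Pure-fiber threshold in percent; the comparison is
#'   inclusive (default 80).
#' @return `data` with percentage columns (`pct_MYH7`, ...) and a
#'   `fiber_type` label appended.
#' @examples
#' classify_fiber_types(data.frame(myh7 = 80, myh2 = 20, myh1 = 0, myh4 = 0))
#' @export
classify_fiber_types <- function(data,
                                 isoform_cols = c(MYH7 = "myh7", MYH2 = "myh2",
                                                  MYH1 = "myh1", MYH4 = "myh4"),
                                 threshold = 80) {
  required <- c("MYH7", "MYH2", "MYH1", "MYH4")
  if (!setequal(names(isoform_cols), required)) {
    stop_invalid("`isoform_cols` must be named MYH7, MYH2, MYH1, MYH4.")
  }
  check_columns(data, unname(isoform_cols), "abundance data")
  data <- as_tibble(data)

  ab <- as.matrix(data[, isoform_cols[required]])
  colnames(ab) <- required
  if (any(!is.finite(ab)) || any(ab < 0)) {
    stop_invalid("isoform abundances must be finite and non-negative.")
  }
  totals <- rowSums(ab)
  if (any(totals == 0)) {
    abort("sample(s) with all-zero isoform abundances cannot be classified.",
          class = "myorelax_unclassifiable")
  }
  pct <- 100 * ab / totals
  type_of <- c(MYH7 = "I", MYH2 = "2A", MYH1 = "2X", MYH4 = "2B")

  # tie-break by fixed isoform priority: order() is stable, and columns are
  # already in priority order MYH7 > MYH2 > MYH1 > MYH4
  labels <- vapply(seq_len(nrow(pct)), function(i) {
    ord <- order(pct[i, ], decreasing = TRUE)
    top <- required[ord[1L]]
    if (pct[i, ord[1L]] >= threshold) {
      paste0("pure ", type_of[[top]])
    } else {
      second <- required[ord[2L]]
      paste0("mixed ", type_of[[top]], "/", type_of[[second]])
    }
  }, character(1))

  for (iso in required) data[[paste0("pct_", iso)]] <- unname(pct[, iso])
  data$fiber_type <- labels
  data
}
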