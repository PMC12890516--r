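#' Background-subtract and normalize Mant-ATP chase traces
#'
#' For each fiber, subtracts the mean background fluorescence from the fiber
#' intensity frame by frame and normalizes every time point by the
#' background-corrected intensity of the final Mant-ATP image before washout
#' (T = 0), so the normalized trace is exactly 1 at T = 0. No correction for
#' rapid wash-out of nonspecifically bound Mant-ATP is applied.
#'
#' @param data A data frame with one row per frame: `time_s` (seconds,
#'   strictly increasing per fiber, starting at 0), `intensity` (fiber
#'   fluorescence, arbitrary units) and optionally `background` (same-length
#'   series or a constant). A `fiber_id` column separates fibers; any other
#'   columns (`subject_id`, `group`, `treatment`, ...) are carried through.
#' @param background Scalar background used when `data` has no `background`
#'   column (default 0).
#' @return A tibble shaped like `data` with `intensity` replaced by the
#'   normalized values and a `state` column set to `"normalized"`.
#' @examples
#' tr <- gen_decay_trace(P1 = 25, T1 = 20, P2 = 45, T2 = 230,
#'                       noise_sd = 0, seed = 1)
#' raw <- dplyr::mutate(tr, intensity = intensity * 800 + 120,
#'                      background = 120)
#' preprocess_traces(raw)
#' @export
preprocess_traces <- function(data, background = 0) {
  check_columns(data, c("time_s", "intensity"), "trace data")
  data <- as_tibble(data)
  if (!"background" %in% names(data)) data$background <- background
  if (!"fiber_id" %in% names(data)) data$fiber_id <- "fiber_1"

  out <- data |>
    group_by(.data$fiber_id) |>
    group_modify(~ normalize_one_trace(.x, .y$fiber_id)) |>
    ungroup()
  out$state <- "normalized"
  out[union(names(data), "state")]
}

normalize_one_trace <- function(df, fiber_id) {
  t <- df$time_s
  if (any(diff(t) <= 0)) {
    stop_invalid(sprintf(
      "fiber '%s': times must be strictly increasing.", fiber_id
    ))
  }
  if (t[1] != 0) {
    stop_invalid(sprintf(
      "fiber '%s': the first frame must be the T = 0 washout image (time_s = 0).",
      fiber_id
    ))
  }
  corrected <- df$intensity - df$background
  denom <- corrected[1]
  if (!is.finite(denom) || denom <= 0) {
    abort(
      sprintf(
        "fiber '%s': background-corrected T = 0 intensity is not positive; trace is degenerate.",
        fiber_id
      ),
      class = "myorelax_degenerate_trace"
    )
  }
  df$intensity <- corrected / denom
  if (any(!is.finite(df$intensity))) {
    abort(
      sprintf("fiber '%s': normalized intensities are not all finite.", fiber_id),
      class = "myorelax_degenerate_trace"
    )
  }
  df
}
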