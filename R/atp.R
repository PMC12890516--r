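#' Theoretical myosin ATP consumption
#'
#' Combines the fitted DRX/SRX amplitudes and time constants with an assumed
#' intrafiber myosin concentration (220 uM by default) into a theoretical
#' ATP consumption per cell, in uM ATP per minute:
#'
#' \deqn{ATP = \frac{P_1}{100} \cdot C \cdot \frac{60}{T_1}
#'           + \frac{P_2}{100} \cdot C \cdot \frac{60}{T_2}}
#'
#' The `"corrected"` variant above divides each amplitude by its own phase's
#' turnover lifetime. The `"verbatim"` variant divides both terms by `T1`
#' (the form printed in the source protocol); it is kept selectable because
#' the two differ materially whenever `P2 > 0`.
#'
#' @param P1,P2 Amplitudes in percent.
#' @param T1,T2 Time constants in seconds.
#' @param myosin_conc Myosin concentration in uM (default 220).
#' @param variant `"corrected"` (default) or `"verbatim"`.
#' @return Numeric vector, uM ATP min^-1 per cell.
#' @examples
#' atp_score(P1 = 20, T1 = 30, P2 = 40, T2 = 250)                      # 109.12
#' atp_score(P1 = 20, T1 = 30, P2 = 40, T2 = 250, variant = "verbatim") # 264
#' @export
atp_score <- function(P1, P2, T1, T2, myosin_conc = 220,
                      variant = c("corrected", "verbatim")) {
  variant <- match.arg(variant)
  if (any(P1 < 0 | P2 < 0, na.rm = TRUE)) {
    stop_invalid("amplitudes must be non-negative.")
  }
  if (any(T1 <= 0 | T2 <= 0, na.rm = TRUE)) {
    stop_invalid("time constants must be positive.")
  }
  slow_tau <- if (variant == "corrected") T2 else T1
  P1 / 100 * myosin_conc * 60 / T1 + P2 / 100 * myosin_conc * 60 / slow_tau
}

#' Add ATP-consumption scores to a fit table
#'
#' Appends `atp_corrected` and `atp_verbatim` columns (uM ATP min^-1 per
#' cell; see [atp_score()]) to a per-fiber fit table. Rows whose fit did not
#' converge get `NA` with a warning; a single non-converged `relax_fit`
#' object is refused outright.
#'
#' @param x A fit table from [fit_relaxation()] (columns `P1`, `P2`, `T1`,
#'   `T2`, optionally `converged`), or a single `relax_fit` object.
#' @param myosin_conc Myosin concentration in uM (default 220).
#' @param ... Unused.
#' @return For a data frame: the table with the two score columns appended.
#'   For a `relax_fit`: a one-row tibble of both scores.
#' @export
atp_consumption <- function(x, myosin_conc = 220, ...) {
  UseMethod("atp_consumption")
}

#' @rdname atp_consumption
#' @export
atp_consumption.relax_fit <- function(x, myosin_conc = 220, ...) {
  if (!isTRUE(x$converged)) {
    abort("fit did not converge; refusing to score it.",
          class = "myorelax_not_fitted")
  }
  tibble(
    atp_corrected = atp_score(x$P1, x$P2, x$T1, x$T2, myosin_conc, "corrected"),
    atp_verbatim = atp_score(x$P1, x$P2, x$T1, x$T2, myosin_conc, "verbatim")
  )
}

#' @rdname atp_consumption
#' @export
atp_consumption.data.frame <- function(x, myosin_conc = 220, ...) {
  check_columns(x, c("P1", "P2", "T1", "T2"), "fit table")
  ok <- if ("converged" %in% names(x)) x$converged else rep(TRUE, nrow(x))
  ok <- ok & is.finite(x$T1) & is.finite(x$T2) & x$T1 > 0 & x$T2 > 0
  if (any(!ok)) {
    warn(sprintf("%d non-converged fit(s) scored as NA.", sum(!ok)))
  }
  out <- as_tibble(x)
  out$atp_corrected <- ifelse(
    ok, atp_score(pmax(x$P1, 0), pmax(x$P2, 0),
                  ifelse(ok, x$T1, 1), ifelse(ok, x$T2, 1),
                  myosin_conc, "corrected"), NA_real_)
  out$atp_verbatim <- ifelse(
    ok, atp_score(pmax(x$P1, 0), pmax(x$P2, 0),
                  ifelse(ok, x$T1, 1), ifelse(ok, x$T2, 1),
                  myosin_conc, "verbatim"), NA_real_)
  out
}

#' Relative change versus a baseline treatment
#'
#' Expresses each fiber's fitted parameters as a fold of the mean of the
#' baseline (e.g. vehicle) treatment group within its stratum (e.g.
#' genotype), as used for phosphorylation-challenge designs. The baseline
#' group mean maps to 1 by construction.
#'
#' @param data Per-fiber fit table with a treatment column and the columns in
#'   `vars`.
#' @param baseline Label of the baseline treatment (e.g. `"vehicle"`).
#' @param treatment Name of the treatment column (default `"treatment"`).
#' @param strata Optional name(s) of stratification column(s) (e.g.
#'   `"group"`); baselines are computed within each stratum. `NULL` for a
#'   single stratum.
#' @param vars Columns to normalize (default `P1`, `P2`, `T1`, `T2`).
#' @return The input tibble with `<var>_rel` columns appended
#'   (dimensionless folds).
#' @export
relative_change <- function(data, baseline, treatment = "treatment",
                            strata = "group",
                            vars = c("P1", "P2", "T1", "T2")) {
  check_columns(data, c(treatment, vars), "fit table")
  data <- as_tibble(data)
  strata <- intersect(strata %||% character(), names(data))

  grouped <- if (length(strata)) group_by(data, across(all_of(strata))) else
    group_by(data, .dummy = 1L)
  out <- grouped |>
    group_modify(function(df, key) {
      base <- df[df[[treatment]] == baseline, , drop = FALSE]
      if (nrow(base) == 0L) {
        abort(
          sprintf("no '%s' baseline rows in stratum %s.", baseline,
                  paste(unlist(key), collapse = "/")),
          class = "myorelax_missing_baseline"
        )
      }
      for (v in vars) {
        df[[paste0(v, "_rel")]] <- df[[v]] / mean(base[[v]])
      }
      df
    }) |>
    ungroup()
  out$.dummy <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
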