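#' Welch two-sample t test on a tidy table
#'
#' Unpaired two-sided t test with Welch's correction for unequal variances,
#' the fiber-level and subject-level two-group comparison used throughout the
#' relaxed-state analyses.
#'
#' @param data A data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the two-level grouping column.
#' @return A one-row tibble: `statistic` (t), `df` (Welch-Satterthwaite),
#'   `p_value`, `estimate` (difference of means, first level minus second),
#'   `group1`, `group2`, `n1`, `n2`.
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
#' welch_t_test(df, "y", "g")
#' @export
welch_t_test <- function(data, value = "value", group = "group") {
  check_columns(data, c(value, group), "data")
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) {
    stop_invalid("`group` must have exactly two levels.")
  }
  y <- data[[value]]
  a <- y[g == levels(g)[1]]
  b <- y[g == levels(g)[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs at least 2 observations.")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, estimate = mean(a) - mean(b),
    group1 = levels(g)[1], group2 = levels(g)[2],
    n1 = length(a), n2 = length(b)
  )
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Omnibus F test across groups followed by all pairwise Tukey honest
#' significant difference comparisons, as used for multi-arm cohorts
#' (e.g. control / disease / low-dose / high-dose).
#'
#' @inheritParams welch_t_test
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`, and a
#'   `pairwise` list-column holding a tibble of Tukey-adjusted pairwise
#'   comparisons (`contrast`, `estimate`, `p_adj`).
#' @export
anova_tukey <- function(data, value = "value", group = "group") {
  check_columns(data, c(value, group), "data")
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  if (nlevels(df$g) < 2L) stop_invalid("need at least 2 groups.")
  if (any(table(df$g) < 2L)) {
    stop_invalid("every group needs at least 2 observations.")
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  f <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- tibble(
    contrast = rownames(tk),
    estimate = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
  tibble(
    statistic = f, df1 = an$Df[1L], df2 = an$Df[2L], p_value = p,
    pairwise = list(pairwise)
  )
}

#' Two-way ANOVA with Tukey HSD on cell means
#'
#' Main effects and interaction for a two-factor layout (e.g. genotype x
#' treatment), with type-II sums of squares (identical to type I/III for the
#' balanced designs these experiments use), plus Tukey-adjusted pairwise
#' comparisons of the factor-combination cell means.
#'
#' @inheritParams welch_t_test
#' @param factor_a,factor_b Names of the two factor columns.
#' @return A tibble with one row per term (`term`, `statistic`, `df1`, `df2`,
#'   `p_value`) and a `pairwise` list-column (populated on the first row)
#'   with Tukey comparisons of the cell means.
#' @export
two_way_anova_tukey <- function(data, value = "value",
                                factor_a = "factor_a", factor_b = "factor_b") {
  check_columns(data, c(value, factor_a, factor_b), "data")
  df <- data.frame(
    y = data[[value]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  cells <- table(df$a, df$b)
  if (any(cells < 2L)) {
    stop_invalid("every factor-combination cell needs at least 2 observations.")
  }
  fit <- stats::aov(y ~ a * b, data = df)
  a2 <- car::Anova(fit, type = 2)
  terms <- c("a", "b", "a:b")
  labels <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  df_res <- a2["Residuals", "Df"]

  cell_fit <- stats::aov(y ~ cell, data = transform(df, cell = interaction(a, b, sep = ":")))
  tk <- stats::TukeyHSD(cell_fit)$cell
  pairwise <- tibble(
    contrast = rownames(tk),
    estimate = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )

  tibble(
    term = labels,
    statistic = a2[terms, "F value"],
    df1 = a2[terms, "Df"],
    df2 = df_res,
    p_value = a2[terms, "Pr(>F)"],
    pairwise = c(list(pairwise), vector("list", 2L))
  )
}

#' Average fiber-level values per subject
#'
#' Collapses a per-fiber table to one mean per subject and variable, the
#' "one circle per patient/animal" reporting level that complements the
#' per-fiber view.
#'
#' @param data Per-fiber table with a `subject_id` column.
#' @param vars Columns to average; defaults to all numeric columns.
#' @param keep Extra grouping columns carried through if present (default
#'   `"group"`).
#' @return A tibble with one row per subject: `subject_id`, carried columns,
#'   `n_fibers`, and the per-subject means of `vars`.
#' @export
aggregate_by_subject <- function(data, vars = NULL, keep = "group") {
  check_columns(data, "subject_id", "fit table")
  data <- as_tibble(data)
  keep <- intersect(keep, names(data))
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("n_points"))
  }
  data |>
    group_by(across(all_of(c("subject_id", keep)))) |>
    summarise(
      n_fibers = n(),
      across(all_of(vars), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}
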