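#' @title Proteome abundance tables
#' @description
#' The proteomics functions all share one tabular convention: a tibble with a
#' `protein_id` column and one numeric column per sample (missing values as
#' `NA`), plus a separate group map — a data frame with `sample_id` and
#' `group` columns (or a named character vector of groups). This mirrors how
#' reporter-intensity (TMT) and DIA log-intensity matrices are exported.
#' @name abundance-tables
NULL

sample_cols <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], "protein_id")
}

as_group_map <- function(groups, samples) {
  if (is.data.frame(groups)) {
    check_columns(groups, c("sample_id", "group"), "group map")
    gm <- stats::setNames(as.character(groups$group), groups$sample_id)
  } else if (!is.null(names(groups))) {
    gm <- stats::setNames(as.character(groups), names(groups))
  } else {
    stop_invalid("`groups` must be a sample_id/group data frame or a named vector.")
  }
  missing <- setdiff(samples, names(gm))
  if (length(missing) > 0L) {
    stop_invalid(sprintf("group map lacks sample(s): %s",
                         paste(missing, collapse = ", ")))
  }
  gm[samples]
}

abundance_to_matrix <- function(data) {
  check_columns(data, "protein_id", "abundance table")
  sc <- sample_cols(data)
  if (length(sc) == 0L) stop_invalid("no numeric sample columns found.")
  m <- as.matrix(data[, sc])
  rownames(m) <- data$protein_id
  m
}

matrix_to_abundance <- function(m) {
  bind_cols(tibble(protein_id = rownames(m)), as_tibble(m))
}

#' Equalize total abundance across sample channels
#'
#' Rescales every sample column of a raw-intensity matrix so that all
#' channels have the same total abundance, preserving within-channel ratios.
#' This is the correction applied to TMT reporter intensities before
#' between-group comparison.
#'
#' @param data Abundance table (see [abundance-tables]) on the raw intensity
#'   scale with strictly positive observed values.
#' @param reference Which total every channel is scaled to: `"max"` (default,
#'   the highest channel total), `"median"` or `"mean"` of the channel
#'   totals.
#' @return The table with each sample column rescaled; column totals (over
#'   observed values) all equal the reference total.
#' @export
normalize_total_abundance <- function(data,
                                      reference = c("max", "median", "mean")) {
  reference <- match.arg(reference)
  m <- abundance_to_matrix(data)
  if (any(m[!is.na(m)] <= 0)) {
    stop_invalid("raw intensities must be strictly positive.")
  }
  totals <- colSums(m, na.rm = TRUE)
  if (any(totals == 0)) {
    stop_invalid("sample column(s) with zero total abundance.")
  }
  target <- switch(reference,
    max = max(totals), median = stats::median(totals), mean = mean(totals)
  )
  m <- sweep(m, 2, target / totals, `*`)
  matrix_to_abundance(m)
}

#' Drop proteins with excessive within-group missingness
#'
#' Removes any protein whose fraction of missing values exceeds
#' `max_missing_frac` within at least one group (strict inequality, so a
#' protein missing exactly half of one group is retained at the default).
#'
#' @param data Log2 abundance table (see [abundance-tables]).
#' @param groups Sample-to-group map.
#' @param max_missing_frac Highest tolerated within-group missing fraction
#'   (default 0.5).
#' @return The filtered table; the number of dropped proteins is attached as
#'   attribute `n_dropped` and reported via a message.
#' @export
filter_by_missingness <- function(data, groups, max_missing_frac = 0.5) {
  m <- abundance_to_matrix(data)
  gm <- as_group_map(groups, colnames(m))
  keep <- rep(TRUE, nrow(m))
  for (g in unique(gm)) {
    sub <- m[, gm == g, drop = FALSE]
    frac <- rowMeans(is.na(sub))
    keep <- keep & (frac <= max_missing_frac)
  }
  out <- as_tibble(data)[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  message(sprintf("filter_by_missingness: dropped %d of %d proteins.",
                  n_dropped, nrow(m)))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Mixed KNN / MinProb imputation of missing log2 intensities
#'
#' Per protein and per group: if the group has at least `knn_valid_frac`
#' valid values for that protein, its missing entries are imputed by
#' k-nearest-neighbour averaging over proteins (Euclidean distance on the
#' group's jointly observed samples); all remaining missing entries are drawn
#' from a down-shifted Gaussian (the MinProb model of left-censored,
#' low-abundance missingness) with mean `sample mean - shift * sample sd` and
#' standard deviation `width * sample sd`, computed from the observed values
#' of each sample (or of the whole matrix with `minprob_scope = "matrix"`).
#' Observed values are never modified.
#'
#' @param data Filtered log2 abundance table (see [abundance-tables]).
#' @param groups Sample-to-group map.
#' @param knn_valid_frac Minimum valid fraction within a group for the KNN
#'   route (default 0.6).
#' @param k Number of neighbours (default 3). If fewer neighbours are
#'   available the pool that exists is used, with a warning.
#' @param width,shift MinProb width and down-shift, as multiples of the
#'   observed standard deviation (defaults 0.3 and 1.8).
#' @param seed Integer seed making the MinProb draws reproducible.
#' @param minprob_scope `"sample"` (default) computes MinProb moments per
#'   sample; `"matrix"` from all observed values.
#' @return The completed table; imputed coordinates are attached as the
#'   logical-matrix attribute `imputed_mask`.
#' @export
mixed_impute <- function(data, groups, knn_valid_frac = 0.6, k = 3,
                         width = 0.3, shift = 1.8, seed = NULL,
                         minprob_scope = c("sample", "matrix")) {
  minprob_scope <- match.arg(minprob_scope)
  m <- abundance_to_matrix(data)
  gm <- as_group_map(groups, colnames(m))
  miss <- is.na(m)
  if (!any(miss)) {
    out <- as_tibble(data)
    attr(out, "imputed_mask") <- miss
    return(out)
  }

  warned_pool <- FALSE
  # KNN route, group by group
  for (g in unique(gm)) {
    cols <- which(gm == g)
    sub <- m[, cols, drop = FALSE]
    valid_frac <- rowMeans(!is.na(sub))
    knn_rows <- which(valid_frac >= knn_valid_frac & rowSums(is.na(sub)) > 0)
    for (i in knn_rows) {
      for (j_local in which(is.na(sub[i, ]))) {
        donors <- which(!is.na(sub[, j_local]))
        donors <- setdiff(donors, i)
        if (length(donors) == 0L) next # falls through to MinProb
        shared <- !is.na(sub[i, ])
        d <- vapply(donors, function(r) {
          both <- shared & !is.na(sub[r, ])
          if (!any(both)) return(Inf)
          sqrt(mean((sub[i, both] - sub[r, both])^2))
        }, numeric(1))
        donors <- donors[is.finite(d)]
        d <- d[is.finite(d)]
        if (length(donors) == 0L) next
        if (length(donors) < k && !warned_pool) {
          warn(sprintf(
            "mixed_impute: fewer than k = %d neighbours available; using all %d.",
            k, length(donors)))
          warned_pool <- TRUE
        }
        nn <- donors[order(d)][seq_len(min(k, length(donors)))]
        m[i, cols[j_local]] <- mean(sub[nn, j_local])
      }
    }
  }

  # MinProb route for everything still missing
  still <- is.na(m)
  if (any(still)) {
    if (minprob_scope == "matrix") {
      mu_all <- mean(m[!miss], na.rm = TRUE)
      sd_all <- stats::sd(m[!miss], na.rm = TRUE)
    }
    m <- with_seed(seed, {
      for (j in seq_len(ncol(m))) {
        rows <- which(still[, j])
        if (length(rows) == 0L) next
        if (minprob_scope == "sample") {
          obs <- m[!miss[, j], j] # original observed values only
          if (length(obs) < 2L) {
            stop_invalid(sprintf(
              "sample '%s' has too few observed values for MinProb moments.",
              colnames(m)[j]))
          }
          mu <- mean(obs); s <- stats::sd(obs)
        } else {
          mu <- mu_all; s <- sd_all
        }
        m[rows, j] <- stats::rnorm(length(rows), mu - shift * s, width * s)
      }
      m
    })
  }

  out <- matrix_to_abundance(m)
  attr(out, "imputed_mask") <- miss
  out
}

#' Per-protein differential abundance between two groups
#'
#' Unpaired two-tailed t test per protein between the two groups of
#' `contrast`, Benjamini-Hochberg adjustment across all tested proteins, and
#' a joint significance gate: adjusted p at most `alpha` AND absolute fold
#' change at least `fc`. Set `p_adjust = "none"` for the raw-p gate used
#' with the reporter-intensity (TMT) arm, and `fc = 1` to disable the
#' fold-change gate.
#'
#' @param data Complete (imputed) log2 abundance table.
#' @param groups Sample-to-group map.
#' @param contrast Character vector `c(case, control)`; the log2 fold change
#'   is `mean(case) - mean(control)`, so "up" means higher in the case group.
#' @param alpha FDR (or raw-p) significance level (default 0.05).
#' @param fc Fold-change gate on the linear scale (default 2, i.e.
#'   |log2FC| >= 1).
#' @param p_adjust `"BH"` (default) or `"none"`.
#' @param var_equal Use the pooled-variance Student t instead of Welch
#'   (default `FALSE`).
#' @return A tibble with one row per protein: `protein_id`, `log2_fc`,
#'   `statistic`, `df`, `p`, `q`, `significant`, `direction`. Contrast and
#'   gate settings are attached as attributes.
#' @export
differential_abundance <- function(data, groups, contrast, alpha = 0.05,
                                   fc = 2, p_adjust = c("BH", "none"),
                                   var_equal = FALSE) {
  p_adjust <- match.arg(p_adjust)
  if (length(contrast) != 2L) stop_invalid("`contrast` must be c(case, control).")
  m <- abundance_to_matrix(data)
  if (any(is.na(m))) {
    stop_invalid("matrix still has missing values; impute first.")
  }
  gm <- as_group_map(groups, colnames(m))
  if (!all(contrast %in% gm)) {
    stop_invalid("contrast group(s) absent from the group map.")
  }
  x <- m[, gm == contrast[1], drop = FALSE]
  y <- m[, gm == contrast[2], drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop_invalid("each contrast group needs n >= 2 samples.")

  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- lfc / se
  p <- 2 * stats::pt(-abs(stat), df)
  # constant-in-both-groups proteins: no evidence either way
  flat <- !is.finite(stat)
  stat[flat & lfc == 0] <- 0
  p[flat & lfc == 0] <- 1
  p[flat & lfc != 0] <- 0
  df[flat] <- NA_real_

  q <- if (p_adjust == "BH") bh_adjust(p) else p
  significant <- q <= alpha & abs(lfc) >= log2(fc)
  out <- tibble(
    protein_id = rownames(m),
    log2_fc = unname(lfc),
    statistic = unname(stat),
    df = unname(df),
    p = unname(p),
    q = unname(q),
    significant = unname(significant),
    direction = dplyr::case_when(lfc > 0 ~ "up", lfc < 0 ~ "down",
                                 TRUE ~ NA_character_)
  )
  attr(out, "contrast") <- contrast
  attr(out, "alpha") <- alpha
  attr(out, "fc") <- fc
  attr(out, "p_adjust") <- p_adjust
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1) controlling the false
#'   discovery rate.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_invalid("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' Partition differential proteins into restoration sets
#'
#' Compares two differential-abundance results computed against the same
#' reference group — disease vs control without treatment, and disease vs
#' control under treatment — and partitions the untreated significant
#' proteins into: `maintained` (significant in both contrasts with the same
#' direction), `restored` (significant only without treatment: the rescue
#' set), `discordant` (significant in both, opposite directions), plus the
#' `emergent` set (significant only under treatment).
#'
#' @param diff_untreated,diff_treated Results from
#'   [differential_abundance()] over compatible protein universes.
#' @param direction `"both"` (default), `"down"` or `"up"`: restrict the
#'   analysis to hits of one direction (the published rescue analysis uses
#'   the downregulated hits).
#' @return An object of class `restoration_sets`: a list of the four
#'   protein-id sets plus `counts`. `tidy()` turns it into a long tibble.
#' @export
restoration_sets <- function(diff_untreated, diff_treated,
                             direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  for (d in list(diff_untreated, diff_treated)) {
    check_columns(d, c("protein_id", "significant", "direction"), "diff result")
  }
  if (length(intersect(diff_untreated$protein_id, diff_treated$protein_id)) == 0L) {
    stop_invalid("the two results share no proteins; universes are disjoint.")
  }
  dirs <- if (direction == "both") c("down", "up") else direction
  sig_u <- diff_untreated[diff_untreated$significant %in% TRUE, ]
  sig_t <- diff_treated[diff_treated$significant %in% TRUE, ]
  u_dir <- stats::setNames(sig_u$direction, sig_u$protein_id)
  t_dir <- stats::setNames(sig_t$direction, sig_t$protein_id)

  u_set <- names(u_dir)[u_dir %in% dirs]
  t_set <- names(t_dir)[t_dir %in% dirs]

  both <- intersect(u_set, names(t_dir))
  maintained <- both[u_dir[both] == t_dir[both]]
  discordant <- both[u_dir[both] != t_dir[both]]
  restored <- setdiff(u_set, both)
  emergent <- setdiff(t_set, names(u_dir))

  out <- list(
    maintained = maintained, restored = restored,
    emergent = emergent, discordant = discordant,
    direction = direction,
    counts = c(maintained = length(maintained), restored = length(restored),
               emergent = length(emergent), discordant = length(discordant))
  )
  class(out) <- "restoration_sets"
  out
}

#' @export
print.restoration_sets <- function(x, ...) {
  cat("Restoration-set partition (direction:", x$direction, ")\n")
  print(x$counts)
  invisible(x)
}

#' @rdname restoration_sets
#' @param x A `restoration_sets` object.
#' @param ... Unused.
#' @export
tidy.restoration_sets <- function(x, ...) {
  sets <- c("maintained", "restored", "emergent", "discordant")
  list_rbind(map(sets, function(s) {
    if (length(x[[s]]) == 0L) return(tibble(protein_id = character(), set = character()))
    tibble(protein_id = x[[s]], set = s)
  }))
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of each annotation term against a hit
#' list, with the background set as all proteins identified. Terms are
#' intersected with the background before testing; only terms with at least
#' `min_targets` hits in the term are tested, and the tested terms are
#' Benjamini-Hochberg adjusted.
#'
#' @param hits Character vector of significant protein ids (must be a subset
#'   of `background`).
#' @param annotation A two-column data frame (`term_id`, `protein_id`) or a
#'   named list of protein-id vectors (GMT-style).
#' @param background Character vector: all identified proteins.
#' @param min_targets Minimum number of hits inside a term for it to be
#'   tested (default 5).
#' @return A tibble with one row per tested term: `term_id`, `term_size`
#'   (within background), `overlap`, `p` (upper tail, `P[X >= overlap]`),
#'   `q` (BH), sorted by `p`. The number of terms excluded by the size rule
#'   is attached as attribute `n_excluded`.
#' @export
hypergeometric_enrichment <- function(hits, annotation, background,
                                      min_targets = 5) {
  if (is.data.frame(annotation)) {
    check_columns(annotation, c("term_id", "protein_id"), "annotation")
    terms <- split(annotation$protein_id, annotation$term_id)
  } else if (is.list(annotation)) {
    terms <- annotation
  } else {
    stop_invalid("`annotation` must be a term_id/protein_id table or a named list.")
  }
  background <- unique(background)
  hits <- unique(hits)
  if (!all(hits %in% background)) {
    stop_invalid("`hits` must be a subset of `background`.")
  }
  N <- length(background)
  n <- length(hits)

  rows <- list_rbind(map(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), background)
    K <- length(members)
    k <- length(intersect(members, hits))
    tibble(term_id = tm, term_size = K, overlap = k,
           p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }))
  tested <- rows[rows$overlap >= min_targets, , drop = FALSE]
  n_excluded <- nrow(rows) - nrow(tested)
  if (nrow(tested) > 0L) {
    tested$q <- bh_adjust(tested$p)
    tested <- tested[order(tested$p), , drop = FALSE]
  } else {
    tested$q <- numeric(0)
  }
  attr(tested, "n_excluded") <- n_excluded
  tested
}

#' Principal-component scores of the sample space
#'
#' Centered (optionally unit-scaled) PCA of samples over proteins, used to
#' summarize proteome heterogeneity between groups and its reduction under
#' treatment.
#'
#' @param data Complete log2 abundance table.
#' @param groups Optional sample-to-group map carried into the output.
#' @param scale Unit-scale each protein (default `FALSE`).
#' @param n_components Number of leading components to return (default up to
#'   5).
#' @return A tibble of class `pca_scores`: `sample_id`, optional `group`,
#'   `PC1..PCk`; the explained-variance fractions are in attribute
#'   `var_explained`.
#' @export
pca_scores <- function(data, groups = NULL, scale = FALSE, n_components = 5) {
  m <- abundance_to_matrix(data)
  if (ncol(m) < 2L) stop_invalid("PCA needs at least 2 samples.")
  if (any(is.na(m))) stop_invalid("matrix must be complete for PCA.")
  x <- t(m)
  keep <- apply(x, 2, stats::sd) > 0 | !scale
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale)
  kmax <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(kmax), drop = FALSE])
  out <- bind_cols(tibble(sample_id = colnames(m)), scores)
  if (!is.null(groups)) {
    gm <- as_group_map(groups, colnames(m))
    out <- out |> mutate(group = unname(gm), .after = "sample_id")
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(kmax)]
  class(out) <- c("pca_scores", class(out))
  out
}
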