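#' Run the relaxed-state kinetics pipeline end to end
#'
#' Reads (or accepts) a long-format trace table, preprocesses and fits every
#' fiber, scores theoretical ATP consumption, aggregates to subject means,
#' runs the group comparison appropriate for the number of groups (Welch t
#' for two, one-way ANOVA with Tukey HSD for more) at both fiber and subject
#' level, and writes the result tables plus a manifest that records every
#' parameter needed to reproduce the run. Nothing is written if any input
#' fails validation.
#'
#' @param traces Path to a trace TSV/CSV (see [read_traces()]) or an
#'   in-memory trace table.
#' @param output_dir Directory for the output tables; created if needed.
#' @param preprocess Run [preprocess_traces()] first (default `TRUE`; set
#'   `FALSE` for already-normalized traces).
#' @param myosin_conc Myosin concentration for ATP scoring, uM (default 220).
#' @param baseline Optional baseline treatment label; when given and a
#'   `treatment` column exists, [relative_change()] columns are added.
#' @param alpha Significance level recorded in the manifest (default 0.05).
#' @return Invisibly, a list with `fits`, `subject_means`, `comparisons` and
#'   the output paths.
#' @export
run_relax_pipeline <- function(traces, output_dir, preprocess = TRUE,
                               myosin_conc = 220, baseline = NULL,
                               alpha = 0.05) {
  data <- if (is.character(traces)) read_traces(traces) else as_tibble(traces)
  check_columns(data, c("fiber_id", "time_s", "intensity"), "trace data")

  if (preprocess && !("state" %in% names(data) &&
                      all(data$state == "normalized"))) {
    data <- preprocess_traces(data)
  }
  fits <- fit_relaxation(data)
  fits <- atp_consumption(fits, myosin_conc = myosin_conc)
  if (!is.null(baseline) && "treatment" %in% names(fits)) {
    fits <- relative_change(fits, baseline = baseline)
  }

  subject_means <- if ("subject_id" %in% names(fits)) {
    aggregate_by_subject(fits)
  } else {
    tibble()
  }

  comparisons <- list()
  if ("group" %in% names(fits) && length(unique(fits$group)) >= 2L) {
    vars <- intersect(c("P1", "P2", "T1", "T2", "atp_corrected"), names(fits))
    for (level in c("fiber", "subject")) {
      tab <- if (level == "fiber") fits else subject_means
      if (nrow(tab) == 0L) next
      for (v in vars) {
        ok <- stats::complete.cases(tab[[v]])
        sub <- tab[ok, ]
        res <- if (length(unique(sub$group)) == 2L) {
          w <- welch_t_test(sub, v, "group")
          tibble(contrast = paste(w$group1, "vs", w$group2), test = "welch_t",
                 statistic = w$statistic, df = w$df, p_value = w$p_value)
        } else {
          a <- anova_tukey(sub, v, "group")
          bind_rows(
            tibble(contrast = "omnibus", test = "anova_F",
                   statistic = a$statistic, df = a$df1, p_value = a$p_value),
            tibble(contrast = a$pairwise[[1]]$contrast, test = "tukey_hsd",
                   statistic = NA_real_, df = NA_real_,
                   p_value = a$pairwise[[1]]$p_adj)
          )
        }
        comparisons[[length(comparisons) + 1L]] <-
          bind_cols(tibble(variable = v, level = level), res)
      }
    }
  }
  comparisons <- if (length(comparisons)) bind_rows(comparisons) else tibble()

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fits = file.path(output_dir, "fiber_fits.tsv"),
    subject_means = file.path(output_dir, "subject_means.tsv"),
    comparisons = file.path(output_dir, "comparisons.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_table(fits, paths$fits)
  if (nrow(subject_means)) write_table(subject_means, paths$subject_means)
  if (nrow(comparisons)) write_table(comparisons, paths$comparisons)
  write_manifest(paths$manifest, list(
    pipeline = "relax",
    input = if (is.character(traces)) traces else "<in-memory>",
    parameters = list(preprocess = preprocess, myosin_conc = myosin_conc,
                      baseline = baseline, alpha = alpha),
    n_fibers = nrow(fits)
  ))
  invisible(list(fits = fits, subject_means = subject_means,
                 comparisons = comparisons, paths = paths))
}

#' Run the proteomics pipeline end to end
#'
#' Chains the abundance workflow: optional total-abundance normalization and
#' log2 transform (for raw-intensity input), within-group missingness
#' filtering, mixed KNN/MinProb imputation, differential abundance for each
#' requested contrast, restoration sets when exactly two contrasts share a
#' reference, hypergeometric enrichment when an annotation is supplied, and
#' PCA scores. Writes all tables plus a manifest recording parameters and the
#' imputation seed. Nothing is written if any input fails validation.
#'
#' @param abundance Path to an abundance TSV/CSV or an in-memory table (see
#'   [abundance-tables]).
#' @param groups Path to a group-map file or an in-memory map.
#' @param output_dir Directory for outputs.
#' @param contrasts A list of `c(case, control)` pairs.
#' @param scale `"log2"` (default) if the input is already log2; `"raw"`
#'   applies [normalize_total_abundance()] then log2.
#' @param annotation Optional annotation path or table for enrichment.
#' @param alpha,fc,p_adjust Differential-abundance gate settings (defaults
#'   0.05, 2, `"BH"`).
#' @param max_missing_frac,knn_valid_frac,k,width,shift Filtering and
#'   imputation settings (see [filter_by_missingness()], [mixed_impute()]).
#' @param restoration_direction Direction for [restoration_sets()] (default
#'   `"both"`).
#' @param min_targets Enrichment term-size rule (default 5).
#' @param seed Imputation seed, recorded in the manifest.
#' @return Invisibly, a list with the computed tables and output paths.
#' @export
run_proteome_pipeline <- function(abundance, groups, output_dir,
                                  contrasts, scale = c("log2", "raw"),
                                  annotation = NULL,
                                  alpha = 0.05, fc = 2,
                                  p_adjust = c("BH", "none"),
                                  max_missing_frac = 0.5,
                                  knn_valid_frac = 0.6, k = 3,
                                  width = 0.3, shift = 1.8,
                                  restoration_direction = "both",
                                  min_targets = 5, seed = 1L) {
  scale <- match.arg(scale)
  p_adjust <- match.arg(p_adjust)
  data <- if (is.character(abundance)) read_abundance(abundance) else
    as_tibble(abundance)
  gmap <- if (is.character(groups)) read_group_map(groups) else
    as_tibble(groups)
  anno <- if (is.null(annotation)) NULL else if (is.character(annotation))
    read_annotation(annotation) else as_tibble(annotation)
  if (!is.list(contrasts) || !all(lengths(contrasts) == 2L)) {
    stop_invalid("`contrasts` must be a list of c(case, control) pairs.")
  }
  # validate sample/group congruence up front: fail before writing anything
  as_group_map(gmap, sample_cols(data))

  if (scale == "raw") {
    data <- normalize_total_abundance(data)
    m <- abundance_to_matrix(data)
    data <- matrix_to_abundance(log2(m))
  }
  data <- filter_by_missingness(data, gmap, max_missing_frac = max_missing_frac)
  data <- mixed_impute(data, gmap, knn_valid_frac = knn_valid_frac, k = k,
                       width = width, shift = shift, seed = seed)

  diffs <- map(contrasts, function(ct) {
    differential_abundance(data, gmap, contrast = ct, alpha = alpha, fc = fc,
                           p_adjust = p_adjust)
  })
  names(diffs) <- vapply(contrasts, function(ct) paste(ct, collapse = "_vs_"),
                         character(1))
  diff_table <- list_rbind(map(names(diffs), function(nm) {
    mutate(diffs[[nm]], contrast = nm, .before = 1L)
  }))

  restoration <- NULL
  if (length(diffs) == 2L &&
      contrasts[[1]][2] == contrasts[[2]][2]) {
    restoration <- restoration_sets(diffs[[1]], diffs[[2]],
                                    direction = restoration_direction)
  }

  enrichment <- NULL
  if (!is.null(anno)) {
    hits <- diffs[[1]]$protein_id[diffs[[1]]$significant]
    if (length(hits) > 0L) {
      enrichment <- hypergeometric_enrichment(
        hits, anno, background = diffs[[1]]$protein_id,
        min_targets = min_targets
      )
    }
  }

  pca <- pca_scores(data, gmap)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    differential = file.path(output_dir, "differential.tsv"),
    restoration = file.path(output_dir, "restoration_sets.tsv"),
    enrichment = file.path(output_dir, "enrichment.tsv"),
    pca = file.path(output_dir, "pca_scores.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_table(diff_table, paths$differential)
  if (!is.null(restoration)) write_table(tidy(restoration), paths$restoration)
  if (!is.null(enrichment)) write_table(enrichment, paths$enrichment)
  write_table(as_tibble(pca), paths$pca)
  write_manifest(paths$manifest, list(
    pipeline = "proteome",
    input = if (is.character(abundance)) abundance else "<in-memory>",
    parameters = list(
      scale = scale, alpha = alpha, fc = fc, p_adjust = p_adjust,
      max_missing_frac = max_missing_frac, knn_valid_frac = knn_valid_frac,
      k = k, width = width, shift = shift,
      restoration_direction = restoration_direction,
      min_targets = min_targets, seed = seed
    ),
    contrasts = names(diffs),
    n_proteins = nrow(data)
  ))
  invisible(list(data = data, differential = diff_table, diffs = diffs,
                 restoration = restoration, enrichment = enrichment,
                 pca = pca, paths = paths))
}

write_manifest <- function(path, manifest) {
  manifest$package_version <- as.character(utils::packageVersion("myorelax"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
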