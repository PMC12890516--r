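#' Simulate one normalized Mant-ATP chase trace
#'
#' Evaluates the two-state decay model on an acquisition grid and adds i.i.d.
#' Gaussian noise to the normalized fluorescence; the T = 0 frame is forced
#' to exactly 1, matching the normalization convention.
#'
#' @inheritParams decay_model
#' @param grid Frame times in seconds, strictly increasing and starting at 0
#'   (default: the standard chase protocol, [mant_atp_grid()]).
#' @param noise_sd Standard deviation of the Gaussian noise on normalized
#'   fluorescence (default 0.01).
#' @param seed Integer seed; the same seed always yields the same trace.
#' @param fiber_id,subject_id,group,treatment Optional labels attached to the
#'   trace.
#' @return A tibble: `fiber_id`, label columns, `time_s`, `intensity`,
#'   `state = "normalized"`.
#' @examples
#' gen_decay_trace(P1 = 25, T1 = 20, P2 = 45, T2 = 230, seed = 1)
#' @export
gen_decay_trace <- function(P1, P2, T1, T2, grid = mant_atp_grid(),
                            noise_sd = 0.01, seed = NULL,
                            fiber_id = "fiber_1", subject_id = "subject_1",
                            group = "group_1", treatment = NA_character_) {
  if (noise_sd < 0) stop_invalid("`noise_sd` must be non-negative.")
  if (grid[1] != 0 || any(diff(grid) <= 0)) {
    stop_invalid("`grid` must be strictly increasing and start at 0.")
  }
  y <- decay_model(grid, P1 = P1, T1 = T1, P2 = P2, T2 = T2)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(grid), 0, noise_sd))
  }
  y[1] <- 1
  tibble(
    fiber_id = fiber_id, subject_id = subject_id, group = group,
    treatment = treatment, time_s = grid, intensity = y, state = "normalized"
  )
}

#' Specification for a synthetic decay cohort
#'
#' Bundles the study-design knobs for [gen_cohort()]: per-group parameter
#' means, between-subject and within-subject (fiber) standard deviations, the
#' hierarchy sizes and the trace noise. The default two-group design mirrors
#' a disease-vs-control chase study: the disease group carries more myosin
#' heads in the ATP-demanding DRX state (P1 20 % vs 28 %), correspondingly
#' fewer in SRX, and faster turnover time constants.
#'
#' @param n_subjects Subjects per group (default 7).
#' @param n_fibers Fibers per subject (default 10).
#' @param group_means A data frame with columns `group`, `P1`, `P2`
#'   (percent), `T1`, `T2` (seconds), one row per group.
#' @param between_sd,within_sd Named numeric vectors (`P1`, `P2`, `T1`, `T2`)
#'   of between-subject and within-subject standard deviations.
#' @param noise_sd Gaussian noise sd on normalized fluorescence (default
#'   0.01).
#' @param grid Acquisition grid (default [mant_atp_grid()]).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 7, n_fibers = 10,
                        group_means = tibble(
                          group = c("control", "disease"),
                          P1 = c(20, 28), P2 = c(45, 37),
                          T1 = c(25, 20), T2 = c(230, 210)
                        ),
                        between_sd = c(P1 = 3, P2 = 3, T1 = 3, T2 = 20),
                        within_sd = c(P1 = 4, P2 = 4, T1 = 4, T2 = 25),
                        noise_sd = 0.01, grid = mant_atp_grid()) {
  if (n_subjects < 1 || n_fibers < 1) {
    stop_invalid("subject and fiber counts must be positive.")
  }
  check_columns(group_means, c("group", "P1", "P2", "T1", "T2"), "group_means")
  if (any(between_sd < 0) || any(within_sd < 0) || noise_sd < 0) {
    stop_invalid("standard deviations must be non-negative.")
  }
  if (any(group_means$P1 + group_means$P2 > 100)) {
    stop_invalid("mean P1 + P2 must not exceed 100 %.")
  }
  structure(
    list(n_subjects = n_subjects, n_fibers = n_fibers,
         group_means = as_tibble(group_means),
         between_sd = between_sd, within_sd = within_sd,
         noise_sd = noise_sd, grid = grid),
    class = "cohort_spec"
  )
}

#' Simulate a hierarchical decay cohort with known ground truth
#'
#' Draws subject-level parameter means around each group's means, then
#' fiber-level parameters around each subject's means, and renders one
#' noisy normalized trace per fiber via [gen_decay_trace()]. Parameters are
#' clamped to the physical domain (non-negative amplitudes summing to at most
#' 98 %, time constants at least 1 s).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the full cohort is reproducible.
#' @return A list with `traces` (long tibble of all fibers) and `truth` (one
#'   row per fiber with the generating parameters).
#' @export
gen_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- c("P1", "P2", "T1", "T2")
  with_seed(seed, {
    truth <- list()
    for (gi in seq_len(nrow(spec$group_means))) {
      grp <- spec$group_means$group[gi]
      gmean <- unlist(spec$group_means[gi, pars])
      for (s in seq_len(spec$n_subjects)) {
        smean <- stats::rnorm(4, gmean, spec$between_sd[pars])
        sid <- sprintf("%s_s%02d", grp, s)
        for (f in seq_len(spec$n_fibers)) {
          fp <- stats::rnorm(4, smean, spec$within_sd[pars])
          names(fp) <- pars
          fp[c("P1", "P2")] <- pmax(fp[c("P1", "P2")], 0)
          tot <- fp[["P1"]] + fp[["P2"]]
          if (tot > 98) fp[c("P1", "P2")] <- fp[c("P1", "P2")] * 98 / tot
          fp[c("T1", "T2")] <- pmax(fp[c("T1", "T2")], 1)
          if (fp[["T2"]] <= fp[["T1"]]) fp[["T2"]] <- fp[["T1"]] * 5
          truth[[length(truth) + 1L]] <- tibble(
            fiber_id = sprintf("%s_f%02d", sid, f), subject_id = sid,
            group = grp, P1 = fp[["P1"]], P2 = fp[["P2"]],
            T1 = fp[["T1"]], T2 = fp[["T2"]]
          )
        }
      }
    }
    truth <- list_rbind(truth)
    traces <- list_rbind(map(seq_len(nrow(truth)), function(i) {
      gen_decay_trace(
        P1 = truth$P1[i], P2 = truth$P2[i],
        T1 = truth$T1[i], T2 = truth$T2[i],
        grid = spec$grid, noise_sd = spec$noise_sd, seed = NULL,
        fiber_id = truth$fiber_id[i], subject_id = truth$subject_id[i],
        group = truth$group[i]
      )
    }))
    list(traces = traces, truth = truth)
  })
}

#' Specification for a synthetic abundance matrix
#'
#' Design knobs for [gen_abundance_matrix()]: a log-normal baseline proteome,
#' additive log2 effects in designated case groups, optional restoration of a
#' fraction of those effects in treated case groups, and abundance-dependent
#' (MNAR, left-censored) missingness driven by a logistic function of the
#' underlying log2 abundance. The default four-group design mirrors a
#' genotype x treatment proteome study (n = 6 per group, 1000 proteins, 50
#' effect proteins of 2 log2 units).
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param n_per_group Named integer vector: samples per group.
#' @param effect_groups Groups carrying the disease effect.
#' @param restored_groups Subset of `effect_groups` in which a fraction
#'   `restored_frac` of effect proteins is attenuated to zero (treatment
#'   rescue).
#' @param baseline_mean,baseline_sd Mean and sd of the per-protein baseline
#'   log2 abundance (defaults 25 and 2).
#' @param within_sd Within-group sample sd in log2 units (default 0.3).
#' @param n_effects Number of effect proteins (default 50).
#' @param effect_size Absolute effect in log2 units (default 2); the sign is
#'   random per protein.
#' @param restored_frac Fraction of effect proteins restored under treatment
#'   (default 0).
#' @param mnar_slope,mnar_intercept Missingness model
#'   `P(missing) = plogis(mnar_intercept - mnar_slope * value)`; the defaults
#'   (0, -Inf) produce a complete matrix.
#' @return A list of class `matrix_spec`.
#' @export
matrix_spec <- function(n_proteins = 1000,
                        n_per_group = c(control = 6, disease = 6),
                        effect_groups = "disease",
                        restored_groups = character(),
                        baseline_mean = 25, baseline_sd = 2,
                        within_sd = 0.3,
                        n_effects = 50, effect_size = 2,
                        restored_frac = 0,
                        mnar_slope = 0, mnar_intercept = -Inf) {
  if (n_effects > n_proteins) stop_invalid("`n_effects` exceeds `n_proteins`.")
  if (is.null(names(n_per_group))) stop_invalid("`n_per_group` must be named.")
  if (restored_frac < 0 || restored_frac > 1) {
    stop_invalid("`restored_frac` must lie in [0, 1].")
  }
  if (mnar_slope < 0) stop_invalid("`mnar_slope` must be non-negative.")
  if (!all(restored_groups %in% effect_groups)) {
    stop_invalid("`restored_groups` must be a subset of `effect_groups`.")
  }
  structure(
    list(n_proteins = n_proteins, n_per_group = n_per_group,
         effect_groups = effect_groups, restored_groups = restored_groups,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         within_sd = within_sd, n_effects = n_effects,
         effect_size = effect_size, restored_frac = restored_frac,
         mnar_slope = mnar_slope, mnar_intercept = mnar_intercept),
    class = "matrix_spec"
  )
}

#' Simulate a log2 abundance matrix with known effect and restoration truth
#'
#' @param spec A [matrix_spec()].
#' @param seed Integer seed.
#' @return A list with `data` (abundance table, `NA` where censored),
#'   `groups` (sample-to-group tibble) and `truth` (per protein:
#'   `is_effect`, `direction`, `is_restored`).
#' @export
gen_abundance_matrix <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "matrix_spec"))
  with_seed(seed, {
    prot <- sprintf("prot_%04d", seq_len(spec$n_proteins))
    groups_vec <- rep(names(spec$n_per_group), spec$n_per_group)
    samples <- unlist(lapply(names(spec$n_per_group), function(g) {
      sprintf("%s_r%d", g, seq_len(spec$n_per_group[[g]]))
    }))

    baseline <- stats::rnorm(spec$n_proteins, spec$baseline_mean, spec$baseline_sd)
    effect_idx <- if (spec$n_effects > 0) {
      sample.int(spec$n_proteins, spec$n_effects)
    } else integer()
    signs <- sample(c(-1, 1), length(effect_idx), replace = TRUE)
    n_restored <- round(spec$restored_frac * length(effect_idx))
    restored_idx <- if (n_restored > 0) effect_idx[seq_len(n_restored)] else integer()

    effect_of <- numeric(spec$n_proteins)
    effect_of[effect_idx] <- signs * spec$effect_size

    m <- matrix(NA_real_, spec$n_proteins, length(samples),
                dimnames = list(prot, samples))
    for (j in seq_along(samples)) {
      g <- groups_vec[j]
      mu <- baseline
      if (g %in% spec$effect_groups) {
        eff <- effect_of
        if (g %in% spec$restored_groups) eff[restored_idx] <- 0
        mu <- mu + eff
      }
      m[, j] <- stats::rnorm(spec$n_proteins, mu, spec$within_sd)
    }

    if (spec$mnar_slope > 0 || is.finite(spec$mnar_intercept)) {
      p_miss <- stats::plogis(spec$mnar_intercept - spec$mnar_slope * m)
      m[stats::runif(length(m)) < p_miss] <- NA_real_
    }

    truth <- tibble(
      protein_id = prot,
      is_effect = seq_len(spec$n_proteins) %in% effect_idx,
      direction = dplyr::case_when(
        effect_of > 0 ~ "up", effect_of < 0 ~ "down", TRUE ~ NA_character_
      ),
      is_restored = seq_len(spec$n_proteins) %in% restored_idx
    )
    list(
      data = matrix_to_abundance(m),
      groups = tibble(sample_id = samples, group = groups_vec),
      truth = truth
    )
  })
}

#' Simulate a term-annotation map with one enriched term
#'
#' Random term memberships over a background, plus one deliberately enriched
#' term assembled mostly from a designated hit list, for exercising
#' [hypergeometric_enrichment()] end to end.
#'
#' @param background Character vector of protein ids.
#' @param n_terms Number of random terms (default 50).
#' @param term_size Integer range `c(min, max)` of term sizes (default
#'   `c(10, 40)`).
#' @param enriched_hits Optional character vector of hit proteins; when
#'   given, a term `"term_enriched"` is added containing
#'   `round(enriched_frac * length(enriched_hits))` of the hits plus random
#'   background fill to the mean term size.
#' @param enriched_frac Fraction of the hits placed inside the enriched term
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A tibble (`term_id`, `protein_id`).
#' @export
gen_annotation <- function(background, n_terms = 50, term_size = c(10, 40),
                           enriched_hits = NULL, enriched_frac = 0.8,
                           seed = NULL) {
  if (length(background) == 0L) stop_invalid("`background` must be non-empty.")
  if (max(term_size) > length(background)) {
    stop_invalid("term sizes cannot exceed the background size.")
  }
  with_seed(seed, {
    out <- list_rbind(map(seq_len(n_terms), function(i) {
      size <- sample(seq(term_size[1], term_size[2]), 1L)
      tibble(term_id = sprintf("term_%03d", i),
             protein_id = sample(background, size))
    }))
    if (!is.null(enriched_hits)) {
      if (!all(enriched_hits %in% background)) {
        stop_invalid("`enriched_hits` must be drawn from `background`.")
      }
      inside <- sample(enriched_hits,
                       max(1L, round(enriched_frac * length(enriched_hits))))
      fill_n <- max(0L, round(mean(term_size)) - length(inside))
      fill <- sample(setdiff(background, inside), fill_n)
      out <- bind_rows(out, tibble(term_id = "term_enriched",
                                   protein_id = c(inside, fill)))
    }
    out
  })
}
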