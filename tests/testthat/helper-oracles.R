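# Independent oracle implementations used to cross-check the package.
# These deliberately use different routes (exhaustive search, literal
# textbook formulas, lm()/eigen()) than the implementation under test.

# Brute-force grid-search fitter for the double-exponential decay: exhaustive
# search over a coarse (T1, T2) grid with amplitudes from an ordinary linear
# model fit at each grid point.
oracle_grid_fit <- function(time_s, intensity,
                            t1_grid = seq(8, 40, by = 1),
                            t2_grid = seq(120, 350, by = 10)) {
  y0 <- 1 - intensity
  best <- list(rss = Inf)
  for (T1 in t1_grid) {
    b1 <- 1 - exp(-time_s / T1)
    for (T2 in t2_grid) {
      if (T2 <= T1) next
      b2 <- 1 - exp(-time_s / T2)
      fit <- stats::lm(y0 ~ 0 + b1 + b2)
      a <- pmax(stats::coef(fit), 0)
      rss <- sum((y0 - a[1] * b1 - a[2] * b2)^2)
      if (rss < best$rss) {
        best <- list(P1 = 100 * a[[1]], P2 = 100 * a[[2]],
                     T1 = T1, T2 = T2, rss = rss)
      }
    }
  }
  best
}

# Literal Benjamini-Hochberg step-up: sort, compute p * m / rank, enforce
# monotonicity from the largest rank down, cap at 1, restore input order.
oracle_bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj[i] <- min(adj[i], adj[i + 1])
  }
  pmin(adj, 1)[order(ord)]
}

# Exact upper-tail hypergeometric probability from binomial coefficients.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# One-way ANOVA decomposition by literal sums of squares.
oracle_anova_f <- function(values, group) {
  group <- factor(group)
  grand <- mean(values)
  ss_between <- sum(tapply(values, group, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(unlist(tapply(values, group, function(v) (v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  list(F = (ss_between / df1) / (ss_within / df2),
       ss_between = ss_between, ss_within = ss_within,
       df1 = df1, df2 = df2)
}

# Balanced two-way ANOVA sums of squares from the cell-means decomposition.
oracle_two_way_ss <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(values)
  n_a <- table(a); n_b <- table(b)
  ss_a <- sum(n_a * (tapply(values, a, mean) - grand)^2)
  ss_b <- sum(n_b * (tapply(values, b, mean) - grand)^2)
  cell_means <- tapply(values, list(a, b), mean)
  n_cell <- table(a, b)
  ss_cells <- sum(n_cell * (cell_means - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_cells - ss_a - ss_b)
}

# tiny helper: abundance tibble straight from a matrix
abundance_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)),
    tibble::as_tibble(m)
  )
}
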