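make_matrix <- function(n = 20, samples = c(a1 = "g1", a2 = "g1", b1 = "g2",
                                            b2 = "g2"),
                        seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n * length(samples), 20, 1), nrow = n,
              dimnames = list(sprintf("p%02d", seq_len(n)), names(samples)))
  list(data = abundance_tbl(m),
       groups = tibble::tibble(sample_id = names(samples),
                               group = unname(samples)))
}

test_that("total-abundance normalization equalizes channel totals", {
  mm <- make_matrix()
  norm <- normalize_total_abundance(mm$data)
  m <- as.matrix(norm[, -1])
  totals <- colSums(m)
  expect_lt(max(abs(totals - max(totals))) / max(totals), 1e-12)

  # already equal-total input is a fixed point
  again <- normalize_total_abundance(norm)
  expect_equal(as.matrix(again[, -1]), m, tolerance = 1e-12)

  # within-column ratios preserved
  raw <- as.matrix(mm$data[, -1])
  expect_equal(m[, 1] / m[2, 1], raw[, 1] / raw[2, 1], tolerance = 1e-12)

  # independent summation oracle on a seeded random matrix
  set.seed(99)
  r <- matrix(runif(60, 1, 100), 12, 5,
              dimnames = list(sprintf("q%02d", 1:12), sprintf("s%d", 1:5)))
  rn <- as.matrix(normalize_total_abundance(abundance_tbl(r))[, -1])
  target <- max(vapply(seq_len(5), function(j) sum(r[, j]), numeric(1)))
  for (j in 1:5) expect_equal(sum(rn[, j]), target, tolerance = 1e-9)

  zero <- abundance_tbl(matrix(c(1, 1, 0, 0), 2,
                               dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  expect_error(normalize_total_abundance(zero),
               class = "myorelax_invalid_input")
})

test_that("missingness filter drops by the strict within-group rule", {
  samples <- c(a1 = "g1", a2 = "g1", a3 = "g1", a4 = "g1", a5 = "g1",
               b1 = "g2", b2 = "g2", b3 = "g2", b4 = "g2", b5 = "g2")
  m <- matrix(20, nrow = 3, ncol = 10,
              dimnames = list(c("drop_me", "keep_complete", "keep_boundary"),
                              names(samples)))
  m["drop_me", 1:3] <- NA           # 3/5 = 0.6 missing in g1: dropped
  m["keep_boundary", c(1, 2)] <- NA # worst group at 2/5 = 0.4: retained
  groups <- tibble::tibble(sample_id = names(samples), group = unname(samples))

  suppressMessages(kept <- filter_by_missingness(abundance_tbl(m), groups))
  expect_setequal(kept$protein_id, c("keep_complete", "keep_boundary"))
  expect_equal(attr(kept, "n_dropped"), 1)

  # exactly 50 % missing in the worst group is retained ("more than" rule)
  m2 <- matrix(20, nrow = 1, ncol = 10,
               dimnames = list("half", names(samples)))
  m2["half", c(1, 2)] <- NA
  m2["half", c(6, 7)] <- NA
  suppressMessages(k2 <- filter_by_missingness(abundance_tbl(m2), groups))
  expect_equal(k2$protein_id, "half")
  # exactly half missing when groups have even size
  m3 <- matrix(20, 1, 4, dimnames = list("even", c("a1", "a2", "b1", "b2")))
  m3[1, 1] <- NA # 1/2 in g1
  g4 <- tibble::tibble(sample_id = colnames(m3),
                       group = c("g1", "g1", "g2", "g2"))
  suppressMessages(k3 <- filter_by_missingness(abundance_tbl(m3), g4))
  expect_equal(nrow(k3), 1)

  expect_error(
    filter_by_missingness(abundance_tbl(m2),
                          tibble::tibble(sample_id = "a1", group = "g1")),
    class = "myorelax_invalid_input"
  )
})

test_that("mixed imputation routes by the 60 % rule and never touches observed values", {
  # 5-sample group: 3 valid (60 %) routes to KNN, 2 valid (40 %) to MinProb
  samples <- stats::setNames(rep("g1", 5), sprintf("s%d", 1:5))
  set.seed(4)
  m <- matrix(rnorm(40 * 5, 25, 2), 40, 5,
              dimnames = list(sprintf("p%02d", 1:40), names(samples)))
  m["p01", 4:5] <- NA # 3/5 valid -> KNN
  m["p02", 3:5] <- NA # 2/5 valid -> MinProb
  groups <- tibble::tibble(sample_id = names(samples), group = "g1")
  obs_mask <- !is.na(m)

  imp <- mixed_impute(abundance_tbl(m), groups, seed = 11)
  im <- as.matrix(imp[, -1])
  rownames(im) <- imp$protein_id
  expect_false(any(is.na(im)))
  expect_equal(im[obs_mask], m[obs_mask]) # observed untouched
  expect_equal(attr(imp, "imputed_mask"), !obs_mask)

  # KNN-imputed entry equals the mean of its k = 3 nearest donors at that
  # sample, with neighbours found on jointly observed columns
  donors <- rownames(m)[-(1:2)]
  d <- apply(m[donors, 1:3], 1, function(r) sqrt(mean((m["p01", 1:3] - r)^2)))
  nn <- names(sort(d))[1:3]
  expect_equal(im["p01", 4], mean(m[nn, 4]))

  # MinProb-imputed entry is a down-shifted draw, not a neighbour average:
  # far below the sample's observed mean
  expect_lt(im["p02", 5], mean(m[obs_mask[, 5], 5]) - 1.8 * sd(m[obs_mask[, 5], 5]) +
              4 * 0.3 * sd(m[obs_mask[, 5], 5]))

  # seeded determinism
  imp2 <- mixed_impute(abundance_tbl(m), groups, seed = 11)
  expect_equal(as.matrix(imp2[, -1]), im, ignore_attr = TRUE)

  # complete matrix passes through unchanged, any seed
  complete <- make_matrix(n = 8)
  expect_equal(mixed_impute(complete$data, complete$groups, seed = 1),
               mixed_impute(complete$data, complete$groups, seed = 2),
               ignore_attr = TRUE)
})

test_that("MinProb draws recover the down-shifted Gaussian moments", {
  # one sample fully observed with known moments, one mostly missing
  n <- 6000
  set.seed(21)
  obs <- rnorm(n, 25, 2)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25 # exact moments
  m <- matrix(NA_real_, n, 2, dimnames = list(sprintf("p%05d", 1:n),
                                              c("s1", "s2")))
  m[, 1] <- obs
  m[1:1000, 2] <- obs[1:1000] # s2: 1000 observed, 5000 missing
  groups <- tibble::tibble(sample_id = c("s1", "s2"), group = "g1")

  imp <- mixed_impute(abundance_tbl(m), groups, seed = 31)
  drawn <- as.matrix(imp[, -1])[1001:n, 2]
  mu2 <- mean(obs[1:1000]); sd2 <- sd(obs[1:1000])
  se_mean <- 0.3 * sd2 / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - (mu2 - 1.8 * sd2)), 3 * se_mean)
  expect_lt(abs(sd(drawn) - 0.3 * sd2), 3 * 0.3 * sd2 / sqrt(2 * length(drawn)))
})

test_that("differential abundance applies the joint FDR and fold-change gate", {
  mm <- make_matrix(n = 30, seed = 8)
  # identical groups: log2FC all 0, nothing significant
  m <- as.matrix(mm$data[, -1])
  rownames(m) <- mm$data$protein_id
  m[, 3:4] <- m[, 1:2]
  same <- differential_abundance(abundance_tbl(log2(m)), mm$groups,
                                 contrast = c("g2", "g1"))
  expect_true(all(same$log2_fc == 0))
  expect_true(all(!same$significant))
  expect_true(all(same$p == 1))

  # a strong small-fold protein fails the fold-change gate
  set.seed(12)
  base <- matrix(rnorm(50 * 8, 20, 0.05), 50, 8,
                 dimnames = list(sprintf("p%02d", 1:50),
                                 c(paste0("a", 1:4), paste0("b", 1:4))))
  base["p01", 5:8] <- base["p01", 5:8] + 0.9 # tiny q, |lfc| = 0.9 < 1
  base["p02", 5:8] <- base["p02", 5:8] + 2.0 # passes both gates
  groups <- tibble::tibble(sample_id = colnames(base),
                           group = rep(c("g1", "g2"), each = 4))
  res <- differential_abundance(abundance_tbl(base), groups,
                                contrast = c("g2", "g1"))
  expect_lt(res$q[res$protein_id == "p01"], 0.01)
  expect_false(res$significant[res$protein_id == "p01"])
  expect_true(res$significant[res$protein_id == "p02"])
  expect_equal(res$direction[res$protein_id == "p02"], "up")
  expect_equal(res$log2_fc[res$protein_id == "p02"],
               mean(base["p02", 5:8]) - mean(base["p02", 1:4]))

  # q >= p after BH, and fc = 1 reduces to the pure FDR gate
  expect_true(all(res$q >= res$p - 1e-15))
  res_fc1 <- differential_abundance(abundance_tbl(base), groups,
                                    contrast = c("g2", "g1"), fc = 1)
  expect_setequal(res_fc1$protein_id[res_fc1$significant],
                  res$protein_id[res$q <= 0.05])

  # per-protein Welch statistics agree with stats::t.test
  for (pid in c("p01", "p05")) {
    ht <- t.test(base[pid, 5:8], base[pid, 1:4])
    expect_equal(res$statistic[res$protein_id == pid],
                 unname(ht$statistic), tolerance = 1e-10)
    expect_equal(res$p[res$protein_id == pid], ht$p.value, tolerance = 1e-10)
  }

  expect_error(
    differential_abundance(abundance_tbl(base), groups, c("g2", "absent")),
    class = "myorelax_invalid_input"
  )
})

test_that("BH adjustment equals the literal step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh_stepup(p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "myorelax_invalid_input")
})

test_that("restoration sets partition the untreated hits by the direction rules", {
  mk_diff <- function(ids, sig, dir) {
    tibble::tibble(protein_id = ids, significant = sig, direction = dir)
  }
  ids <- sprintf("p%02d", 1:12)
  untreated <- mk_diff(ids, ids %in% sprintf("p%02d", 1:10), "down")
  treated <- mk_diff(ids, ids %in% sprintf("p%02d", 6:12), "down")
  rs <- restoration_sets(untreated, treated)
  expect_setequal(rs$maintained, sprintf("p%02d", 6:10))
  expect_setequal(rs$restored, sprintf("p%02d", 1:5))
  expect_setequal(rs$emergent, sprintf("p%02d", 11:12))
  expect_length(rs$discordant, 0)
  expect_equal(unname(rs$counts), c(5, 5, 2, 0))

  # identical significant sets: everything maintained
  rs_same <- restoration_sets(untreated, untreated)
  expect_length(rs_same$restored, 0)
  expect_length(rs_same$emergent, 0)
  expect_setequal(rs_same$maintained, sprintf("p%02d", 1:10))

  # direction flip lands in discordant, never maintained
  flip <- treated
  flip$direction[flip$protein_id == "p06"] <- "up"
  rs_flip <- restoration_sets(untreated, flip)
  expect_true("p06" %in% rs_flip$discordant)
  expect_false("p06" %in% rs_flip$maintained)

  # tidy() emits the long membership table; partition invariant holds
  td <- tidy(rs_flip)
  expect_setequal(
    td$protein_id[td$set %in% c("maintained", "restored", "discordant")],
    untreated$protein_id[untreated$significant]
  )

  expect_error(
    restoration_sets(untreated, mk_diff("zz", TRUE, "down")),
    class = "myorelax_invalid_input"
  )
})

test_that("hypergeometric enrichment matches exact tail sums and the size rule", {
  bg <- sprintf("b%02d", 1:20)
  hits <- bg[1:10]
  term <- c(bg[1:4], bg[11]) # K = 5, overlap 4
  res <- hypergeometric_enrichment(hits, list(t1 = term), bg, min_targets = 4)
  expect_equal(res$p, 28028 / 184756, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_tail(4, 5, 20, 10), tolerance = 1e-12)

  # overlap below min_targets excludes the term from the tested results
  res5 <- hypergeometric_enrichment(hits, list(t1 = term), bg, min_targets = 5)
  expect_equal(nrow(res5), 0)
  expect_equal(attr(res5, "n_excluded"), 1)

  # saturated term: overlap = |hits| and p = 1
  sat <- hypergeometric_enrichment(hits, list(all = bg), bg)
  expect_equal(sat$overlap, 10)
  expect_equal(sat$p, 1)

  # p decreases monotonically in the overlap, all else fixed
  ps <- vapply(5:10, function(k) {
    oracle_hyper_tail(k, 10, 30, 12)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  impl <- vapply(5:10, function(k) {
    term_k <- c(hits[seq_len(k)], setdiff(bg, hits)[seq_len(10 - k)])
    hypergeometric_enrichment(hits, list(t = term_k), bg)$p
  }, numeric(1))
  expect_true(all(diff(impl) < 0))

  expect_error(
    hypergeometric_enrichment(c(hits, "outsider"), list(t1 = term), bg),
    class = "myorelax_invalid_input"
  )
})

test_that("PCA scores reproduce an independent eigen-decomposition", {
  mm <- make_matrix(n = 15, samples = c(a1 = "g1", a2 = "g1", a3 = "g1",
                                        b1 = "g2", b2 = "g2", b3 = "g2"),
                    seed = 23)
  lgm <- log2(as.matrix(mm$data[, -1]))
  rownames(lgm) <- mm$data$protein_id
  lg <- abundance_tbl(lgm)
  sc <- pca_scores(lg, mm$groups)
  x <- scale(t(as.matrix(lg[, -1])), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  scores_oracle <- x %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(sc[[paste0("PC", j)]]), abs(scores_oracle[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  ve <- attr(sc, "var_explained")
  expect_equal(ve[1:2], (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)

  # rank-1 structure: first component explains ~100 % of the variance
  r1 <- outer(rnorm(10), c(1, 2, 3, 4)) + 20
  rownames(r1) <- sprintf("p%02d", 1:10); colnames(r1) <- sprintf("s%d", 1:4)
  sc1 <- pca_scores(abundance_tbl(r1))
  expect_gt(attr(sc1, "var_explained")[1], 0.999)

  # identical samples: no variance anywhere
  dup <- abundance_tbl(matrix(rep(rnorm(10), 2), 10, 2,
                              dimnames = list(sprintf("p%02d", 1:10),
                                              c("s1", "s2"))))
  sc_dup <- pca_scores(dup)
  expect_lt(max(abs(sc_dup$PC1)), 1e-10)

  expect_error(pca_scores(abundance_tbl(r1[, 1, drop = FALSE])),
               class = "myorelax_invalid_input")
})
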