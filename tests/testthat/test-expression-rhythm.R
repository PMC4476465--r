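make_records <- function(n, n_genes = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    gene_id = sample(sprintf("g%02d", seq_len(n_genes)), n, replace = TRUE),
    start = sample.int(500, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mismatches = sample(0:4, n, replace = TRUE),
    uniquely_aligned = sample(c(TRUE, FALSE), n, replace = TRUE,
                              prob = c(0.8, 0.2)))
}

test_that("read filtering enforces the mismatch rule and start dedup", {
  rec <- data.frame(gene_id = c("a", "a", "a"), start = c(100, 100, 101),
                    strand = c("+", "+", "+"), mismatches = c(0, 1, 3),
                    uniquely_aligned = TRUE)
  out <- filter_and_dedup(rec)
  expect_equal(nrow(out), 1)          # same (gene,+,100) collapsed; mm=3 gone
  expect_equal(out$start, 100)
  expect_equal(out$mismatches, 0)     # first occurrence kept
  multi <- data.frame(gene_id = "a", start = 5, strand = "+",
                      mismatches = 0, uniquely_aligned = FALSE)
  expect_equal(nrow(filter_and_dedup(multi)), 0)
})

test_that("filtering matches a brute-force set oracle and is idempotent", {
  rec <- make_records(1000)
  out <- filter_and_dedup(rec)
  surv <- rec[rec$uniquely_aligned & rec$mismatches <= 2, ]
  oracle_n <- length(unique(paste(surv$gene_id, surv$strand, surv$start)))
  expect_equal(nrow(out), oracle_n)
  expect_identical(filter_and_dedup(out), out)
})

test_that("tallying counts matches a group-by oracle", {
  genes <- sprintf("g%02d", 1:20)
  expect_equal(unname(tally_counts(make_records(0), genes)), rep(0L, 20))
  rec <- filter_and_dedup(make_records(800))
  counts <- tally_counts(rec, genes)
  oracle <- vapply(genes, function(g) sum(rec$gene_id == g), integer(1))
  expect_equal(counts, oracle)
  expect_warning(tally_counts(data.frame(gene_id = "zz", start = 1,
                                         strand = "+", mismatches = 0,
                                         uniquely_aligned = TRUE),
                              genes), "unknown gene")
})

test_that("TMM normalization satisfies its defining identities", {
  set.seed(8)
  x <- stats::rpois(1000, 60) + 1L
  # identical samples give equal factors
  ident <- poisson_tmm_normalize(
    matrix(x, ncol = 2, nrow = 1000,
           dimnames = list(sprintf("g%04d", 1:1000), c("s1", "s2"))))
  expect_equal(unname(ident$size_factors[1] / ident$size_factors[2]), 1,
               tolerance = 1e-9)
  # exact doubling forces a factor ratio of 2
  dbl <- matrix(c(x, 2L * x), ncol = 2,
                dimnames = list(sprintf("g%04d", 1:1000), c("s1", "s2")))
  nm <- poisson_tmm_normalize(dbl)
  expect_equal(unname(nm$size_factors[2] / nm$size_factors[1]), 2,
               tolerance = 1e-9)
  # trimmed weighted mean of adjusted log-folds vanishes, every sample
  resid <- vapply(seq_along(nm$detail), function(s) {
    d <- nm$detail[[s]]
    k <- !d$trimmed
    sum(d$weight[k] * (d$M[k] - nm$log2_size_factors[s])) / sum(d$weight[k])
  }, numeric(1))
  expect_true(all(abs(resid) < 1e-9))
  # trimmed set is the outer quartiles of M
  d1 <- nm$detail[[1]]
  q <- stats::quantile(d1$M, c(0.25, 0.75), names = FALSE)
  expect_identical(d1$trimmed, d1$M < q[1] | d1$M > q[2])
  expect_error(poisson_tmm_normalize(matrix(0L, 10, 3)),
               class = "normalization_failed")
})

test_that("TMM normalization recovers planted size factors within 5%", {
  spec <- expression_sim_spec(5000, frac_rhythmic = 0,
                              size_factors = rep(c(0.5, 1, 2), 4), seed = 42)
  sim <- simulate_expression_timecourse(spec)
  nm <- poisson_tmm_normalize(sim$counts)
  ratio <- nm$size_factors / sim$truth$true_size_factors
  ratio <- ratio / exp(mean(log(ratio)))   # up to one global constant
  expect_true(all(abs(ratio - 1) < 0.05))
  # equal factors at large means recover ~1 everywhere
  eq <- expression_sim_spec(2000, frac_rhythmic = 0,
                            mean_log_expr = c(meanlog = log(500), sdlog = 0.3),
                            seed = 43)
  nm_eq <- poisson_tmm_normalize(simulate_expression_timecourse(eq)$counts)
  f <- nm_eq$size_factors / exp(mean(log(nm_eq$size_factors)))
  expect_true(all(abs(f - 1) < 0.02))
})

test_that("replicate concordance grades identical, null and distorted pairs", {
  lib <- stats::rpois(2000, 50)
  expect_equal(replicate_concordance(lib, lib), 1.0)
  rp <- simulate_replicate_pair(stats::rlnorm(5000, log(100), 1), c(1, 1),
                                seed = 17)
  expect_equal(replicate_concordance(rp$lib1, rp$lib2), 0.99,
               tolerance = 0.015)
  distorted <- rp$lib2
  hit <- seq_len(1000)                      # 20% of genes inflated 10x
  distorted[hit] <- distorted[hit] * 10L
  expect_lte(replicate_concordance(rp$lib1, distorted), 0.85)
  expect_error(replicate_concordance(c(0, 0), c(0, 0)), "all-zero")
})

test_that("the g-factor has exact analytic limits and invariances", {
  pure <- diel_cosine(peak_zt = 16)
  expect_equal(g_factor(pure), 1.0, tolerance = 1e-9)
  expect_equal(as.numeric(g_factor(rep(3, 12))), 0)
  expect_true(attr(g_factor(rep(3, 12)), "degenerate"))
  set.seed(12)
  x <- stats::rnorm(12)
  expect_equal(g_factor(x), g_factor(5 + 2 * x), tolerance = 1e-12)
  # harmonics variant credits a 12-h harmonic to the numerator
  sq <- diel_cosine(16) + 0.5 * cos(2 * pi * ((1 + 4 * (0:11)) - 16) / 12)
  expect_lt(g_factor(sq), 1)
  expect_equal(g_factor(sq, include_harmonics = TRUE), 1.0,
               tolerance = 1e-9)
  expect_error(g_factor(stats::rnorm(10), interval_h = 4,
                        target_period_h = 24), "natural FFT grid")
})

test_that("white-noise g-factors agree exactly with a brute-force oracle", {
  set.seed(33)
  X <- matrix(stats::rnorm(12 * 1e4), ncol = 12)
  g_pkg <- apply(X, 1, g_factor)
  g_orc <- apply(X, 1, oracle_g)
  expect_equal(g_pkg, g_orc, tolerance = 1e-12)
  expect_equal(mean(g_pkg), mean(g_orc))
  gh_pkg <- apply(X[1:500, ], 1, g_factor, include_harmonics = TRUE)
  gh_orc <- apply(X[1:500, ], 1, oracle_g, include_harmonics = TRUE)
  expect_equal(gh_pkg, gh_orc, tolerance = 1e-12)
})

test_that("DCG selection is strict at the cutoff", {
  tab <- data.frame(gene_id = c("a", "b", "c"), g = c(0.6, 0.5, 0.49))
  expect_equal(as.character(select_dcgs(tab)), "a")
  empty <- data.frame(gene_id = character(0), g = numeric(0))
  expect_length(select_dcgs(empty), 0)
})

test_that("the g ranking separates planted rhythmic genes (AUROC)", {
  spec <- expression_sim_spec(5000, frac_rhythmic = 180 / 5000,
                              phases_zt = c(1, 5, 9, 13, 17), seed = 11)
  sim <- simulate_expression_timecourse(spec)
  nm <- poisson_tmm_normalize(sim$counts)
  gt <- g_factor_table(nm$normalized)
  expect_gte(rank_auroc(gt$g, sim$truth$rhythmic_flag), 0.95)
})

test_that("phase clustering recovers planted groups and is deterministic", {
  spec <- expression_sim_spec(600, frac_rhythmic = 0.5,
                              phases_zt = c(1, 5, 9, 13, 17),
                              amplitude_logfc = 3,
                              mean_log_expr = c(meanlog = log(500), sdlog = 0.5),
                              seed = 14)
  sim <- simulate_expression_timecourse(spec)
  nm <- poisson_tmm_normalize(sim$counts)
  rhy <- names(which(sim$truth$rhythmic_flag))
  cl <- kmeans_phase_clusters(nm$normalized[rhy, ], K = 5, seed = 3)
  expect_identical(
    cl$assignment,
    kmeans_phase_clusters(nm$normalized[rhy, ], K = 5, seed = 3)$assignment)
  ari <- mclust::adjustedRandIndex(cl$assignment,
                                   sim$truth$true_phase_zt[rhy])
  expect_gte(ari, 0.9)
  # labels ordered by ascending circular-mean peak ZT
  expect_false(is.unsorted(cl$cluster_peak_zt, na.rm = TRUE))
})

test_that("identical profiles collapse into one cluster with empties flagged", {
  prof <- matrix(rep(diel_cosine(9), each = 10), nrow = 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  cl <- kmeans_phase_clusters(prof, K = 5, seed = 2)
  expect_true(all(cl$assignment == 1))
  expect_equal(sum(cl$empty), 4)
})

test_that("peak-ZT estimation is exact, shift-equivariant and noise-robust", {
  expect_equal(estimate_peak_zt(diel_cosine(16))$peak_zt, 16,
               tolerance = 1e-6)
  set.seed(18)
  x <- stats::rnorm(12)
  p1 <- estimate_peak_zt(x)$peak_zt
  p2 <- estimate_peak_zt(x[c(12, 1:11)])$peak_zt   # delay by one sample
  expect_equal(circ_dist_h(p2, p1 + 4), 0, tolerance = 1e-6)
  flat <- estimate_peak_zt(rep(1, 12))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$peak_zt))
  # noisy planted phases recovered within +-2 h for >= 90% of genes
  set.seed(19)
  phases <- rep_len(c(1, 5, 9, 13, 17), 500)
  ok <- vapply(seq_along(phases), function(i) {
    y <- diel_cosine(phases[i]) + stats::rnorm(12, 0, 0.3)
    circ_dist_h(estimate_peak_zt(y)$peak_zt, phases[i]) <= 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("noiseless planted phases are recovered exactly", {
  spec <- expression_sim_spec(100, frac_rhythmic = 1,
                              phases_zt = c(1, 7, 13, 19), seed = 25)
  sim <- simulate_expression_timecourse(spec)
  lam <- vapply(seq_len(100), function(g)
    sim$truth$mu[g] * 2^(1 * cos(2 * pi *
      ((1 + 4 * (0:11)) - sim$truth$true_phase_zt[g]) / 24)), numeric(12))
  est <- apply(t(lam), 1, function(x) estimate_peak_zt(log2(x))$peak_zt)
  expect_equal(unname(circ_dist_h(est, sim$truth$true_phase_zt)),
               rep(0, 100), tolerance = 1e-6)
})

test_that("replicate columns collapse by label averaging", {
  m <- matrix(1:12, 3, 4,
              dimnames = list(paste0("g", 1:3),
                              c("ZT1_day1", "ZT1_day1", "ZT5_day1",
                                "ZT9_day1")))
  out <- collapse_replicates(m)
  expect_equal(colnames(out), c("ZT1_day1", "ZT5_day1", "ZT9_day1"))
  expect_equal(unname(out[, "ZT1_day1"]), c(2.5, 3.5, 4.5))
})
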