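test_that("min-coverage factors scale every total to the minimum", {
  m <- matrix(c(50, 50, 120, 80), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(unname(size_factors_min_coverage(m)), c(1, 0.5))
  expect_equal(unname(size_factors_min_coverage(c(100, 100))), c(1, 1))
  expect_equal(unname(size_factors_min_coverage(c(100, 200))), c(1, 0.5))

  set.seed(21)
  r <- matrix(rpois(200, 30), 20, 10)
  f <- size_factors_min_coverage(r)
  expect_equal(unname(colSums(r) * f), rep(min(colSums(r)), 10))
  # invariant to row permutation
  expect_equal(size_factors_min_coverage(r[sample.int(20), ]), f)
  expect_error(size_factors_min_coverage(cbind(r, 0)), "zero total")
})

test_that("library_size column takes precedence over in-peak totals", {
  counts <- matrix(c(10L, 10L, 80L, 80L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("a", "b")))
  sheet <- data.frame(sample_id = c("a", "b"), assay = "H3K4me3",
                      timepoint_h = c(0, 24), replicate = 1,
                      treated = c(FALSE, TRUE),
                      library_size = c(2e6, 1e6))
  cm <- count_matrix(counts, sheet)
  expect_equal(unname(size_factors_min_coverage(cm)), c(0.5, 1))
})

test_that("spike-in size factors recover global scaling", {
  mk_cm <- function(sp, genes = NULL) {
    counts <- rbind(genes, sp)
    rownames(counts) <- c(
      if (!is.null(genes)) sprintf("g%03d", seq_len(nrow(genes))),
      sprintf("ERCC-%03d", seq_len(nrow(sp)))
    )
    sheet <- data.frame(sample_id = paste0("s", seq_len(ncol(counts))),
                        assay = "RNA",
                        timepoint_h = seq_len(ncol(counts)), replicate = 1,
                        treated = TRUE)
    colnames(counts) <- sheet$sample_id
    count_matrix(counts, sheet)
  }
  sp <- matrix(rep(c(100L, 200L, 400L), 3), 3, 3, byrow = FALSE)
  expect_equal(unname(size_factors_spike_in(mk_cm(sp), min_rows = 3)),
               rep(1, 3))

  # doubling one column's spike-ins doubles its factor relative to others
  sp2 <- sp; sp2[, 2] <- sp2[, 2] * 2L
  f <- size_factors_spike_in(mk_cm(sp2), min_rows = 3)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)

  # spike-in factors ignore the endogenous rows entirely
  genes <- matrix(rpois(30, 50), 10, 3,
                  dimnames = list(NULL, colnames(sp2)))
  f2 <- size_factors_spike_in(mk_cm(sp2, genes), min_rows = 3)
  expect_equal(f2, f)

  # simulated truth: log-uniform factors in [0.5, 2], 92 rows, mean 500
  set.seed(22)
  true_f <- exp(runif(6, log(0.5), log(2)))
  sp3 <- sapply(true_f, function(s) rpois(92, 500 * s))
  colnames(sp3) <- paste0("s", 1:6)
  f3 <- size_factors_spike_in(mk_cm(sp3), min_rows = 10)
  rel <- f3 / (true_f / exp(mean(log(true_f))))
  expect_lt(max(abs(rel - 1)), 0.02)

  cm_nospike <- mk_cm(sp)
  cm_nospike$spike_in[] <- FALSE
  expect_error(size_factors_spike_in(cm_nospike), "min_coverage")
})

test_that("method-of-moments dispersion matches its closed form", {
  # var 1100 at mean 100: alpha = (1100 - 100) / 100^2 = 0.1
  y <- c(100 - sqrt(550), 100 + sqrt(550))
  expect_equal(estimate_dispersion(y), 0.1)
  # under-dispersed rows floor out
  expect_equal(estimate_dispersion(c(5, 5, 5, 5)), 1e-8)
  expect_equal(estimate_dispersion(c(0, 0, 0)), 1e-8)
  expect_error(estimate_dispersion(7), ">= 2 samples")

  # NB rows at alpha = 0.05, 50 samples: median estimate within 30%
  set.seed(23)
  est <- replicate(300, estimate_dispersion(rnbinom(50, mu = 200, size = 20)))
  expect_lt(abs(median(est) / 0.05 - 1), 0.3)
})

test_that("nb_wald_test recovers effects and is null-calibrated", {
  # identical groups of equal counts: log2fc exactly 0
  dt <- nb_wald_test(matrix(100, 2, 3), matrix(100, 2, 3), alpha = 0.05)
  expect_equal(dt$log2fc, c(0, 0))
  expect_true(all(dt$p > 0.9))

  # all-zero site is untestable
  dt0 <- nb_wald_test(matrix(0, 1, 3), matrix(0, 1, 3), alpha = 0.05)
  expect_true(dt0$untestable)
  expect_equal(dt0$p, 1)
  expect_equal(dt0$log2fc, 0)

  # 4-fold depletion at mean 500, 3 vs 3: median log2fc within 0.15 of -2
  set.seed(24)
  y1 <- matrix(rnbinom(500 * 3, mu = 125, size = 20), 500, 3)
  y0 <- matrix(rnbinom(500 * 3, mu = 500, size = 20), 500, 3)
  dt4 <- nb_wald_test(y1, y0, alpha = 0.05)
  expect_lt(abs(median(dt4$log2fc) + 2), 0.15)

  # null calibration at both dispersions (smaller n than the full check)
  set.seed(25)
  for (alpha in c(0.01, 0.1)) {
    y <- matrix(rnbinom(4000 * 6, mu = 500, size = 1 / alpha), 4000, 6)
    dtn <- nb_wald_test(y[, 1:3], y[, 4:6], alpha = alpha)
    expect_gt(mean(dtn$p < 0.05), 0.03)
    expect_lt(mean(dtn$p < 0.05), 0.07)
  }
})

test_that("nb_wald_test agrees with an independent GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(26)
  alpha <- 0.08
  sf <- c(1.2, 0.8, 1, 1.1, 0.9, 1)
  x <- c(1, 1, 1, 0, 0, 0)
  for (k in 1:5) {
    y <- rnbinom(6, mu = sf * ifelse(x == 1, 80, 200), size = 1 / alpha)
    ours <- chromkinetics:::nb_wald_fit(matrix(y, 1), x, sf, alpha)
    fit <- suppressWarnings(stats::glm(
      y ~ x + offset(log(sf)),
      family = MASS::negative.binomial(theta = 1 / alpha)
    ))
    expect_equal(ours$coef, unname(coef(fit)["x"]), tolerance = 1e-4)
    # fixed-alpha Wald: compare against the unscaled covariance
    cov1 <- summary(fit, dispersion = 1)$cov.scaled
    expect_equal(ours$se, unname(sqrt(diag(cov1))["x"]), tolerance = 0.02)
  }
})

test_that("power rises with effect size and replicate count", {
  set.seed(27)
  rej <- function(fold, reps) {
    y1 <- matrix(rnbinom(800 * reps, mu = 200 * fold, size = 20), 800)
    y0 <- matrix(rnbinom(800 * reps, mu = 200, size = 20), 800)
    mean(nb_wald_test(y1, y0, alpha = 0.05)$p < 0.05)
  }
  expect_gt(rej(0.25, 3), rej(0.5, 3))
  expect_gt(rej(0.5, 6), rej(0.5, 2))
})

test_that("bh_adjust equals the hand-coded step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))

  base_p <- c(0.001, 0.02, 0.04, 0.4, 0.9, 0.02)
  perms <- list(1:6, 6:1, c(3, 1, 4, 2, 6, 5), c(2, 6, 1, 5, 3, 4))
  for (pm in perms) {
    p <- base_p[pm]
    expect_equal(bh_adjust(p), oracle_bh(p))
  }

  q <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls follow the q and fold-change thresholds", {
  dt <- data.frame(
    log2fc = c(-0.60, -0.50, 0.70, 0.58, -0.59, 0.60),
    q = c(0.01, 0.001, 0.20, 0.01, 0.05, 0.049)
  )
  out <- call_significant(dt)
  expect_equal(as.character(out$call),
               c("loss",   # passes both bounds
                 "none",   # |lfc| below 0.58
                 "none",   # q too large
                 "none",   # lfc exactly 0.58: strict
                 "none",   # q exactly 0.05: strict
                 "gain"))
})

test_that("differential_timecourse calls the expected direction", {
  cfg <- tiny_config(seed = 31)
  sim <- simulate_experiment(cfg)
  dt <- differential_timecourse(sim$marks$H3K4me3, timepoints = c(2, 16))
  expect_setequal(unique(dt$timepoint_h), c(2, 16))
  truth <- sim$annotation$truth
  fast16 <- dt[dt$timepoint_h == 16 &
                 dt$site_id %in% truth$promoter_id[truth$speed_class_true == "fast"], ]
  # at 16 h fast promoters sit at the residual plateau: strong loss
  expect_gt(mean(fast16$call == "loss"), 0.8)
  expect_lt(mean(fast16$call == "gain"), 0.01)
})
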