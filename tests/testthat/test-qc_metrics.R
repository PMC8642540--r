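# Five quality metrics: limits, constructed fixtures, and independent
# brute-force oracles for the linear-algebra pieces.

test_that("drift_spearman hits its limits on constructed data", {
  n <- 20
  # every feature equals the injection order -> all significant -> 0
  m <- matrix(rep(1:n, each = 4), 4, n,
              dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:n)))
  d <- make_dataset(m, rep("sample", n))
  res <- drift_spearman(d)
  expect_equal(res$score, 0)
  expect_equal(res$detail$p_correlated, res$detail$p_total)

  # a single uncorrelated feature -> score 100
  set.seed(1)
  m1 <- matrix(rnorm(n), 1, n,
               dimnames = list("f1", sprintf("s%d", 1:n)))
  d1 <- make_dataset(m1, rep("sample", n), log_transformed = TRUE)
  expect_equal(drift_spearman(d1)$score, 100)
})

test_that("drift_spearman is invariant under monotone transformation", {
  sim <- simulate_ms_dataset(n_features = 40, n_bio_samples = 20,
                             n_redundant_groups = 3, seed = 7)
  d <- sim$dataset
  d3 <- d
  d3$intensities <- d$intensities^3
  expect_equal(drift_spearman(d3)$score, drift_spearman(d)$score)
})

test_that("drift_pca scores 0 when PC1 is the injection order", {
  # two blocks of features moving exactly with the order dominate PC1
  n <- 12
  o <- 1:n
  m <- rbind(f1 = o, f2 = 2 * o, f3 = -o + 20, f4 = o * 0.5,
             f5 = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8))
  colnames(m) <- sprintf("s%d", 1:n)
  d <- make_dataset(m, rep("sample", n), log_transformed = TRUE)
  res <- drift_pca(d)
  expect_lt(res$score, 1e-6)
  expect_equal(res$detail$cos2_alpha, 1, tolerance = 1e-9)
})

test_that("cos2_alpha equals the brute-force least-squares R2", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    m <- matrix(rlnorm(4 * n, 5, 1), 4, n,
                dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:n)))
    d <- make_dataset(m, rep("sample", n))
    res <- drift_pca(d, n_components = 3)
    oracle <- cos2_oracle(res$detail$scores,
                          res$detail$injection_order -
                            mean(res$detail$injection_order))
    expect_equal(res$detail$cos2_alpha, oracle, tolerance = 1e-10)
  }
})

test_that("qc_spread distances match a brute-force Mahalanobis oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n_f <- 5; n_s <- 8
    m <- matrix(rlnorm(n_f * n_s, 6, 0.5), n_f, n_s,
                dimnames = list(sprintf("f%d", 1:n_f), sprintf("s%d", 1:n_s)))
    d <- make_dataset(m, rep(c("pool", "sample"), c(3, 5)))
    res <- qc_spread(d)
    det <- res$detail$distances
    # recompute from the same 3D scores with explicit inversion
    sc <- metaboqc:::pca_scores(d, det$sample_id, 3)
    oracle <- mahalanobis_oracle(sc)
    expect_equal(det$mahalanobis, unname(oracle), tolerance = 1e-10)
    expect_equal(res$score,
                 max(0, (1 - max(oracle[1:3]) / max(oracle[4:8])) * 100),
                 tolerance = 1e-10)
  }
})

test_that("qc_spread scores 100 for centroidal QCs and clamps at 0", {
  # pools identical and biological samples symmetric about them
  base <- c(100, 200, 50, 80)
  delta <- rbind(c(10, -4, 2, 1), c(-3, 8, -5, 2))
  m <- cbind(p1 = base, p2 = base,
             s1 = base + delta[1, ], s2 = base - delta[1, ],
             s3 = base + delta[2, ], s4 = base - delta[2, ])
  rownames(m) <- sprintf("f%d", 1:4)
  d <- make_dataset(m, c("pool", "pool", rep("sample", 4)))
  expect_equal(qc_spread(d)$score, 100, tolerance = 1e-6)

  # a pooled QC far outside the biological cloud -> clamped to 0
  m2 <- m
  m2[, "p2"] <- base * 6
  d2 <- make_dataset(m2, c("pool", "pool", rep("sample", 4)))
  expect_equal(qc_spread(d2)$score, 0)
})

test_that("qc_cv counts the 30% boundary as passing", {
  cvs <- seq(0.05, 0.5, by = 0.05)
  pools <- 20
  # deterministic deviation pattern rescaled to hit each CV exactly
  dev <- seq(-1, 1, length.out = pools)
  dev <- dev - mean(dev)
  m <- t(vapply(cvs, function(cv) {
    1000 + dev * (cv * 1000 / sd(dev))
  }, numeric(pools)))
  rownames(m) <- sprintf("f%d", seq_along(cvs))
  colnames(m) <- sprintf("p%d", 1:pools)
  d <- make_dataset(m, rep("pool", pools))
  res <- qc_cv(d)
  expect_equal(res$score, 60)   # six of ten CVs are <= 0.30, inclusive
  expect_equal(res$detail$p_total, 10)
  # constant pool rows -> CV 0 -> 100
  m0 <- matrix(5, 3, 4, dimnames = list(sprintf("f%d", 1:3),
                                        sprintf("p%d", 1:4)))
  expect_equal(qc_cv(make_dataset(m0, rep("pool", 4)))$score, 100)
})

test_that("ICC(A,1) matches the aov-based oracle on random matrices", {
  for (seed in 1:30) {
    set.seed(seed)
    y <- matrix(rnorm(8 * 3, 10, 2), 8, 3)
    expect_equal(metaboqc:::icc_a1(y), icc_a1_oracle(y), tolerance = 1e-10)
  }
})

test_that("qc_icc is 100 for perfect agreement and errors without variance", {
  pools <- 4
  set.seed(5)
  vals <- rlnorm(30, 8, 2)
  m <- matrix(rep(vals, pools), 30, pools,
              dimnames = list(sprintf("f%d", 1:30), sprintf("p%d", 1:pools)))
  d <- make_dataset(m, rep("pool", pools))
  expect_equal(qc_icc(d)$score, 100)

  m0 <- matrix(7, 30, pools, dimnames = dimnames(m))
  expect_error(qc_icc(make_dataset(m0, rep("pool", pools))), "variance|bin")
})

test_that("quality_report assembles five scores in [0, 100]", {
  sim <- simulate_ms_dataset(drift_amplitude = 0, seed = 17)
  d <- run_pipeline(sim$dataset, steps = c("blank", "dilution", "drift"))$dataset
  qr <- quality_report(d)
  s <- tidy(qr)
  expect_equal(nrow(s), 5)
  expect_true(all(s$score >= 0 & s$score <= 100))
  # no drift, 5% noise: per-metric floors derived by simulation; Drift PCA
  # is bounded by its own null expectation 100*(1 - 3/(n-1)) ~ 93.75 at
  # this 49-injection sequence and fluctuates well below it
  sc <- stats::setNames(s$score, s$metric)
  expect_gte(sc["drift_spearman"], 95)
  expect_gte(sc["drift_pca"], 70)
  expect_gte(sc["qc_spread"], 85)
  expect_gte(sc["qc_cv"], 95)
  expect_gte(sc["qc_icc"], 90)
  g <- glance(qr)
  expect_equal(g$mean_score, mean(s$score))

  no_pool <- sim$dataset
  no_pool$samples$sample_type[no_pool$samples$sample_type == "pool"] <- "sample"
  expect_error(quality_report(no_pool), "pool")
})

test_that("standard screening flags exactly the planted outlier", {
  n <- 30
  set.seed(9)
  m <- rbind(std1 = rnorm(n, 1000, 10),
             std2 = rnorm(n, 500, 5))
  colnames(m) <- sprintf("s%d", 1:n)
  m["std1", 7] <- 1000 + 5 * 10 * sqrt((n - 1) / n)  # ~5 sd out
  d <- make_dataset(m, rep("sample", n))
  res <- flag_standard_outliers(d, c("std1", "std2"))
  expect_equal(res$flagged$sample_id, "s7")
  expect_equal(res$flagged$standard, "std1")
  expect_equal(nrow(res$summary), 2)

  m_const <- rbind(std1 = rep(100, n))
  colnames(m_const) <- sprintf("s%d", 1:n)
  d2 <- make_dataset(m_const, rep("sample", n))
  expect_equal(nrow(flag_standard_outliers(d2, "std1")$flagged), 0)
})

test_that("standard flag rate matches the normal tail probability", {
  set.seed(23)
  n <- 50; reps <- 100
  hits <- 0
  for (i in seq_len(reps)) {
    m <- rbind(std1 = rnorm(n, 100, 3), std2 = rnorm(n, 100, 3))
    colnames(m) <- sprintf("s%d", 1:n)
    d <- make_dataset(m, rep("sample", n))
    hits <- hits + nrow(flag_standard_outliers(d, c("std1", "std2"))$flagged)
  }
  rate <- hits / (reps * 2 * n)
  # P(|Z| > 3) ~ 0.0027; estimated mean/sd shrink it somewhat at n = 50
  expect_lt(rate, 0.008)
  expect_gt(rate, 0.0002)
})

test_that("PCA metrics are rotation-invariant when scaling is off", {
  set.seed(13)
  n_f <- 10; n_s <- 14
  m <- matrix(rnorm(n_f * n_s), n_f, n_s,
              dimnames = list(sprintf("f%d", 1:n_f), sprintf("s%d", 1:n_s)))
  types <- rep(c("pool", "sample"), c(4, 10))
  d <- make_dataset(m, types, log_transformed = TRUE)
  q <- qr.Q(qr(matrix(rnorm(n_f^2), n_f)))
  m_rot <- q %*% m
  dimnames(m_rot) <- dimnames(m)
  d_rot <- make_dataset(m_rot, types, log_transformed = TRUE)
  expect_equal(drift_pca(d_rot, scale = FALSE)$score,
               drift_pca(d, scale = FALSE)$score, tolerance = 1e-8)
  expect_equal(qc_spread(d_rot, scale = FALSE)$score,
               qc_spread(d, scale = FALSE)$score, tolerance = 1e-8)
})

test_that("increasing drift amplitude never raises the drift scores", {
  amps <- c(0, 0.15, 0.3)
  scores <- sapply(amps, function(a) {
    sim <- simulate_ms_dataset(n_features = 60, n_bio_samples = 30,
                               n_redundant_groups = 4, drift_amplitude = a,
                               seed = 19)
    c(drift_spearman(sim$dataset)$score, drift_pca(sim$dataset)$score)
  })
  expect_true(all(diff(scores[1, ]) <= 1e-8))
  expect_true(all(diff(scores[2, ]) <= 1e-8))
})
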