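# The five-step post-processing chain, tested step by step on hand-built
# fixtures where the expected outcome follows from the stated rules.

test_that("blank filter applies the 3x rule with equality passing", {
  # feature rows: bio mean 8 vs blank 3 (discard, 8 < 9); 12 vs 4 (keep,
  # boundary equality); bio signal with all-zero blanks (keep)
  m <- rbind(f1 = c(3, 3, 8, 8),
             f2 = c(4, 4, 12, 12),
             f3 = c(0, 0, 100, 50))
  d <- make_dataset(m, c("blank", "blank", "sample", "sample"))
  res <- blank_filter(d)
  expect_equal(rownames(res$dataset$intensities), c("f2", "f3"))
  expect_equal(res$report$n_features_in, 3)
  expect_equal(res$report$n_features_out, 2)
  expect_equal(res$report$discarded$feature_id, "f1")
})

test_that("blank filter ignores missing values and skips without blanks", {
  m <- rbind(f1 = c(NA, 3, 8, 10))
  d <- make_dataset(m, c("blank", "blank", "sample", "sample"))
  # blank mean over observed = 3; bio mean 9 >= 9 -> kept
  expect_equal(nrow(blank_filter(d)$dataset$intensities), 1)

  d2 <- make_dataset(rbind(f1 = c(5, 6)), c("sample", "sample"))
  expect_warning(res <- blank_filter(d2), "skipped")
  expect_true(res$report$skipped)
  expect_equal(nrow(res$dataset$intensities), 1)
})

test_that("dilution filter thresholds Pearson r against 1/dilution", {
  m <- rbind(prop = c(10, 5, 2.5, 7, 7),     # r = 1 -> kept
             flat = c(7, 7, 7, 7, 7),        # undefined r -> discarded
             weak = c(2.5, 5, 10, 7, 7))     # r = -1 -> discarded
  d <- make_dataset(m, c("pool_dilution", "pool_dilution", "pool_dilution",
                         "sample", "sample"),
                    dilution = c(1, 2, 4))
  res <- dilution_filter(d)
  expect_equal(rownames(res$dataset$intensities), "prop")
  expect_setequal(res$report$discarded$feature_id, c("flat", "weak"))
})

test_that("a four-point dilution series is judged by the textbook r", {
  v <- c(10, 6, 2, 1)
  inv <- 1 / c(1, 2, 4, 8)
  # textbook product-moment formula, independent of stats::cor
  r_oracle <- sum((v - mean(v)) * (inv - mean(inv))) /
    sqrt(sum((v - mean(v))^2) * sum((inv - mean(inv))^2))
  expect_gt(r_oracle, 0.7)   # ~0.986, so the feature must be kept
  m <- rbind(f1 = c(v, 50, 50))
  d <- make_dataset(m, c(rep("pool_dilution", 4), "sample", "sample"),
                    dilution = c(1, 2, 4, 8))
  expect_equal(nrow(dilution_filter(d)$dataset$intensities), 1)
})

test_that("dilution filter is skipped with fewer than 3 distinct factors", {
  m <- rbind(f1 = c(10, 5, 3, 3))
  d <- make_dataset(m, c("pool_dilution", "pool_dilution", "sample", "sample"),
                    dilution = c(1, 2))
  expect_warning(res <- dilution_filter(d), "skipped")
  expect_true(res$report$skipped)
})

test_that("drift correction is the identity on flat signal", {
  m <- matrix(100, 1, 12,
              dimnames = list("f1", sprintf("s%d", 1:12)))
  d <- make_dataset(m, rep(c("pool", "sample"), 6))
  res <- drift_correct(d, reference = "pool")
  expect_equal(res$dataset$intensities, d$intensities, tolerance = 1e-9)
  expect_true("drift_corrected" %in% res$dataset$features$flags[[1]])
})

test_that("noiseless linear drift is removed to numerical precision", {
  orders <- 1:20
  raw <- 1000 * (1 + 0.03 * orders)          # strictly linear drift
  m <- matrix(raw, 1, 20, dimnames = list("f1", sprintf("s%d", orders)))
  types <- rep(c("pool", "sample"), 10)
  d <- make_dataset(m, types)
  res <- drift_correct(d, reference = "pool")
  pools <- colnames(m)[types == "pool"]
  v <- res$dataset$intensities[1, pools]
  expect_lt(sd(v) / mean(v), 1e-6)
  # biological samples inside the reference injection range flatten too
  bio <- res$dataset$intensities[1, types == "sample"]
  expect_lt(sd(bio[1:9]) / mean(bio[1:9]), 1e-9)
})

test_that("features with too few reference observations stay uncorrected", {
  m <- rbind(f1 = c(10, NA, NA, 12, 11, 14, 15, 16),
             f2 = c(10, 11, 12, 12, 11, 14, 15, 16))
  types <- c("pool", "pool", "pool", "pool", "pool", "sample", "sample",
             "sample")
  d <- make_dataset(m, types)
  res <- drift_correct(d, reference = "pool")
  expect_true("drift_uncorrected" %in% res$dataset$features$flags[[1]])
  expect_equal(res$dataset$intensities["f1", ], d$intensities["f1", ])
  expect_true("drift_corrected" %in% res$dataset$features$flags[[2]])
})

test_that("invalid loess span is rejected", {
  sim <- simulate_ms_dataset(n_features = 5, n_bio_samples = 6,
                             n_redundant_groups = 0, n_standards = 0, seed = 2)
  expect_error(drift_correct(sim$dataset, span = 0), "span")
  expect_error(drift_correct(sim$dataset, span = 1.5), "span")
})

test_that("drift correction preserves the reference median per feature", {
  sim <- simulate_ms_dataset(n_features = 15, n_bio_samples = 20,
                             n_redundant_groups = 2, n_standards = 1, seed = 21)
  res <- drift_correct(sim$dataset, reference = "pool")
  pools <- sim$dataset$samples$sample_id[
    sim$dataset$samples$sample_type == "pool"]
  m_before <- apply(sim$dataset$intensities[, pools], 1, median)
  m_after <- apply(res$dataset$intensities[, pools], 1, median)
  expect_equal(m_after, m_before, tolerance = 1e-6)
})

test_that("CV filter discards on threshold or sample-CV comparison", {
  pools <- c("p1", "p2", "p3")
  m <- rbind(flat = c(100, 100, 100, 80, 120, 100),
             noisy = c(100, 160, 40, 100, 100, 100),     # pool CV ~ 0.6
             overbio = c(100, 120, 80, 100, 101, 99))    # pool CV > bio CV
  d <- make_dataset(m, c("pool", "pool", "pool", "sample", "sample", "sample"))
  res <- cv_filter(d)
  expect_equal(rownames(res$dataset$intensities), "flat")
  expect_setequal(res$report$discarded$feature_id, c("noisy", "overbio"))
  expect_true(all(c("qc_cv", "sample_cv") %in%
                    names(res$dataset$features)))
})

test_that("redundancy filter needs all three criteria and collapses chains", {
  bios <- 10
  base <- sin(seq_len(bios)) * 20 + 100
  # A-B linked (isotope offset), B-C linked (water loss from B), no A-C row;
  # D co-elutes and correlates but its mz offset matches nothing
  m <- rbind(A = base * 3,
             B = base * 2,
             C = base * 1,
             D = base * 1.5)
  mz <- c(200, 201.00336, 219.01392 - 0.005 + 0.0049, 201.5)
  # C chosen so that |mz_B - mz_C| ~ 18.01056 within tolerance
  mz[3] <- mz[2] + 18.01056
  rt <- c(300, 301, 302, 300.5)
  d <- make_dataset(cbind(m, m[, 1:2]),
                    c(rep("sample", bios), "pool", "pool"),
                    mz = mz, rt = rt)
  res <- redundancy_filter(d)
  expect_setequal(res$report$discarded$feature_id, c("B", "C"))
  expect_true("A" %in% rownames(res$dataset$intensities))
  expect_true("D" %in% rownames(res$dataset$intensities))
  grp <- res$groups
  expect_equal(unique(grp$representative), "A")
  expect_setequal(grp$member, c("A", "B", "C"))
})

test_that("redundancy criteria are individually necessary", {
  bios <- 8
  base <- cos(seq_len(bios)) * 10 + 50
  mk <- function(mz, rt, profiles) {
    make_dataset(profiles, rep("sample", bios), mz = mz, rt = rt)
  }
  # far apart in rt: not grouped despite mz match and correlation
  d_rt <- mk(c(100, 101.00336), c(100, 150),
             rbind(a = base, b = base * 2))
  expect_equal(nrow(redundancy_filter(d_rt)$report$discarded), 0)
  # mz difference of 1.5 Da matches no reference row: not grouped
  d_mz <- mk(c(100, 101.5), c(100, 101),
             rbind(a = base, b = base * 2))
  expect_equal(nrow(redundancy_filter(d_mz)$report$discarded), 0)
  # uncorrelated profiles: not grouped
  d_r <- mk(c(100, 101.00336), c(100, 101),
            rbind(a = base, b = rev(base)))
  expect_equal(nrow(redundancy_filter(d_r)$report$discarded), 0)
})

test_that("log2 transform maps 8 to 3, zeros to missing, and guards reapplication", {
  m <- rbind(f1 = c(8, 0, 1024))
  d <- make_dataset(m, rep("sample", 3))
  d2 <- log2_transform(d)
  expect_equal(unname(d2$intensities[1, ]), c(3, NA, 10))
  expect_true(d2$log_transformed)
  expect_error(log2_transform(d2), "already")

  d_neg <- d
  d_neg$intensities[1, 2] <- -1   # malformed on purpose, bypassing ms_dataset()
  expect_error(log2_transform(d_neg), "negative")
})

test_that("filters are idempotent and scale-invariant", {
  sim <- simulate_ms_dataset(n_features = 60, n_bio_samples = 12,
                             n_redundant_groups = 4, seed = 31)
  d <- sim$dataset
  for (f in list(blank_filter, dilution_filter, cv_filter,
                 function(x) redundancy_filter(x))) {
    once <- f(d)$dataset
    twice <- f(once)$dataset
    expect_identical(rownames(twice$intensities), rownames(once$intensities))
  }
  # global positive rescaling leaves the kept sets unchanged
  d_scaled <- d
  d_scaled$intensities <- d$intensities * 7.3
  for (f in list(blank_filter, dilution_filter, cv_filter)) {
    expect_identical(rownames(f(d_scaled)$dataset$intensities),
                     rownames(f(d)$dataset$intensities))
  }
})

test_that("the pipeline runs the fixed order and reports a cascade", {
  sim <- simulate_ms_dataset(seed = 1)
  res <- run_pipeline(sim$dataset)
  expect_equal(res$cascade$step,
               c("blank_filter", "dilution_filter", "drift_correct",
                 "cv_filter", "redundancy_filter"))
  # counts chain: out of one step = into the next
  expect_equal(res$cascade$n_features_in[-1],
               res$cascade$n_features_out[-nrow(res$cascade)])
  expect_true(res$dataset$log_transformed)
  expect_error(run_pipeline(sim$dataset, steps = c("cv", "bogus")), "bogus")
  # all steps disabled -> identity
  ident <- run_pipeline(sim$dataset, steps = character(0))
  expect_identical(ident$dataset$intensities, sim$dataset$intensities)
})
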