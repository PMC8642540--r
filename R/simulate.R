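#' @importFrom stats rnorm runif rlnorm setNames
NULL

# multiplicative lognormal noise with mean 1 and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Smooth multiplicative drift g(order) = exp(a * s(order)) with s a random
# cubic rescaled so that max|g - 1| equals `amplitude` over the sequence.
make_drift <- function(orders, amplitude) {
  coef <- rnorm(3)   # always drawn, so the RNG stream does not depend on amplitude
  if (amplitude <= 0) return(rep(1, length(orders)))
  x <- (orders - min(orders)) / max(1, diff(range(orders))) * 2 - 1
  s <- coef[1] * x + coef[2] * x^2 + coef[3] * x^3
  if (max(abs(s)) == 0) return(rep(1, length(orders)))
  s <- s / max(abs(s))
  if (max(s) < abs(min(s))) s <- -s   # so the peak sits on the high side
  s <- s / max(s)
  exp(log(1 + amplitude) * s)
}

#' Simulate an LC-MS run with pooled QCs, blanks and a dilution series
#'
#' Generates a feature table with the statistical structure the
#' post-processing pipeline assumes, together with the planted ground
#' truth: an injection sequence opening with solvent blanks and a
#' pooled-QC dilution series, then biological samples with a pooled QC
#' every `qc_every` injections; per-feature lognormal baseline abundances
#' spread over four decades; smooth multiplicative injection-order drift;
#' features dominated by blank background; chemically redundant feature
#' groups (fixed m/z offsets, near-identical retention times, correlated
#' profiles); and designated spiked-standard features.
#'
#' Pooled-QC intensities equal the mean of the biological-sample levels
#' times the drift and measurement noise; dilution-series intensities
#' scale with the inverse dilution factor. Planted blank features have
#' biological means twice their blank means (failing the 3x rule with
#' margin), all others fifteen times (passing with margin). Blank
#' injections carry no drift.
#'
#' @param n_features Total number of features, planted structure included.
#' @param n_bio_samples Number of biological samples.
#' @param qc_every A pooled QC every this many biological injections.
#' @param n_blanks Solvent blanks at the head of the sequence.
#' @param dilution_factors Dilution series of the pooled QC (1 = undiluted).
#' @param noise_cv Measurement (injection-to-injection) CV.
#' @param bio_cv Biological between-sample CV.
#' @param drift_amplitude Maximum relative intensity change over the
#'   sequence caused by drift.
#' @param frac_blank_features Fraction of features dominated by blank
#'   background.
#' @param n_redundant_groups Number of planted redundancy groups.
#' @param redundant_group_size Features per group including the
#'   representative.
#' @param mz_offsets Da offsets used for planted redundancy.
#' @param n_standards Number of features designated as spiked standards.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list with `dataset` (an [ms_dataset()]) and `truth` (class
#'   `synthetic_truth`: `blank_features`, `redundancy` tibble, `standards`,
#'   `baseline`, `drift` matrix, `expected_final_features`, `config`).
#' @export
simulate_ms_dataset <- function(n_features = 200,
                                n_bio_samples = 40,
                                qc_every = 5,
                                n_blanks = 3,
                                dilution_factors = c(1, 2, 4, 8),
                                noise_cv = 0.05,
                                bio_cv = 0.20,
                                drift_amplitude = 0.30,
                                frac_blank_features = 0.10,
                                n_redundant_groups = 10,
                                redundant_group_size = 3,
                                mz_offsets = default_mzdiff_table()$delta_mz,
                                n_standards = 4,
                                seed = NULL) {
  stopifnot(n_features >= 1, n_bio_samples >= 1, qc_every >= 2,
            n_blanks >= 0, noise_cv >= 0, bio_cv >= 0,
            drift_amplitude >= 0, frac_blank_features >= 0,
            frac_blank_features <= 1, n_redundant_groups >= 0,
            redundant_group_size >= 2, n_standards >= 0)
  if (!is.null(seed)) set.seed(seed)

  n_blank_feat <- round(frac_blank_features * n_features)
  n_members <- n_redundant_groups * (redundant_group_size - 1)
  if (n_blank_feat + n_members + n_redundant_groups + n_standards > n_features) {
    stop("config infeasible: planted structure needs more features than ",
         "n_features provides", call. = FALSE)
  }

  ## ---- injection sequence ----
  rows <- list()
  push <- function(id, type, dil = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_id = id, sample_type = type, dilution_factor = dil)
  }
  for (b in seq_len(n_blanks)) push(sprintf("blank%d", b), "blank")
  for (d in seq_along(dilution_factors)) {
    push(sprintf("dil%d_f%g", d, dilution_factors[d]), "pool_dilution",
         dilution_factors[d])
  }
  n_pool <- 0L
  n_pool <- n_pool + 1L; push(sprintf("pool%02d", n_pool), "pool")
  for (j in seq_len(n_bio_samples)) {
    push(sprintf("samp%03d", j), "sample")
    if (j %% qc_every == 0) {
      n_pool <- n_pool + 1L; push(sprintf("pool%02d", n_pool), "pool")
    }
  }
  if (n_bio_samples %% qc_every != 0) {
    n_pool <- n_pool + 1L; push(sprintf("pool%02d", n_pool), "pool")
  }
  samples <- dplyr::bind_rows(rows)
  samples$injection_order <- seq_len(nrow(samples))
  samples$genotype <- NA_character_
  samples$sex <- NA_character_
  samples$batch <- "batch1"
  bio_idx <- samples$sample_type == "sample"
  samples$genotype[bio_idx] <- rep_len(c("WT", "LAT", "MX2"),
                                       sum(bio_idx))
  samples$sex[bio_idx] <- rep_len(c("M", "F"), sum(bio_idx))

  n_samp <- nrow(samples)
  fid <- sprintf("M%04d", seq_len(n_features))

  ## ---- planted roles (disjoint) ----
  idx_all <- seq_len(n_features)
  rep_idx <- if (n_redundant_groups > 0) idx_all[seq_len(n_redundant_groups)] else integer(0)
  member_idx <- if (n_members > 0) idx_all[n_redundant_groups + seq_len(n_members)] else integer(0)
  rest <- setdiff(idx_all, c(rep_idx, member_idx))
  blank_idx <- if (n_blank_feat > 0) rest[seq_len(n_blank_feat)] else integer(0)
  rest <- setdiff(rest, blank_idx)
  std_idx <- if (n_standards > 0) rest[seq_len(n_standards)] else integer(0)

  ## ---- per-feature parameters ----
  baseline <- 10^runif(n_features, 4, 8)
  mz <- runif(n_features, 80, 1000)
  rt <- runif(n_features, 30, 900)

  drift <- matrix(1, n_features, n_samp,
                  dimnames = list(fid, samples$sample_id))
  non_blank_inj <- samples$sample_type != "blank"
  for (i in seq_len(n_features)) {
    drift[i, non_blank_inj] <- make_drift(
      samples$injection_order[non_blank_inj], drift_amplitude)
  }

  ## ---- true levels ----
  bio_ids <- samples$sample_id[bio_idx]
  level <- matrix(0, n_features, n_samp,
                  dimnames = list(fid, samples$sample_id))
  bio_level <- baseline * matrix(lnorm_noise(n_features * length(bio_ids), bio_cv),
                                 n_features, length(bio_ids))
  level[, bio_ids] <- bio_level
  pool_level <- rowMeans(bio_level)
  pool_ids <- samples$sample_id[samples$sample_type == "pool"]
  level[, pool_ids] <- pool_level
  dil_rows <- samples$sample_type == "pool_dilution"
  for (k in which(dil_rows)) {
    level[, k] <- pool_level / samples$dilution_factor[k]
  }
  mean_bio <- rowMeans(bio_level)
  blank_level <- mean_bio / 15
  blank_level[blank_idx] <- mean_bio[blank_idx] / 2
  blank_ids <- samples$sample_id[samples$sample_type == "blank"]
  level[, blank_ids] <- blank_level

  ## ---- redundant members copy their representative's profile ----
  group <- integer(0); rep_of <- character(0); mem_of <- character(0)
  offsets_used <- numeric(0)
  if (n_redundant_groups > 0) {
    gsz <- redundant_group_size - 1
    for (g in seq_len(n_redundant_groups)) {
      r <- rep_idx[g]
      mem <- member_idx[(g - 1) * gsz + seq_len(gsz)]
      for (m in mem) {
        sc <- runif(1, 0.3, 0.8)
        off <- sample(mz_offsets, 1)
        level[m, ] <- level[r, ] * sc
        drift[m, ] <- drift[r, ]
        mz[m] <- mz[r] + off + runif(1, -5e-4, 5e-4)
        rt[m] <- rt[r] + runif(1, -1.5, 1.5)
        group <- c(group, g)
        rep_of <- c(rep_of, fid[r])
        mem_of <- c(mem_of, fid[m])
        offsets_used <- c(offsets_used, off)
      }
    }
  }

  ## ---- measurement noise, drift applied ----
  noise <- matrix(lnorm_noise(n_features * n_samp, noise_cv),
                  n_features, n_samp)
  # member noise is nearly shared with the representative so that the
  # profile correlation stays > 0.95 even at high noise_cv
  for (k in seq_along(mem_of)) {
    i <- match(mem_of[k], fid); r <- match(rep_of[k], fid)
    noise[i, ] <- noise[r, ] * lnorm_noise(n_samp, min(0.01, noise_cv))
  }
  intensities <- level * drift * noise

  features <- tibble::tibble(
    feature_id = fid, mz = mz, rt = rt,
    annotation = ifelse(seq_len(n_features) %in% std_idx, "standard",
                        NA_character_))
  dataset <- ms_dataset(intensities, samples, features)

  truth <- structure(list(
    blank_features = fid[blank_idx],
    redundancy = tibble::tibble(group = group, representative = rep_of,
                                member = mem_of, offset = offsets_used),
    standards = fid[std_idx],
    baseline = setNames(baseline, fid),
    drift = drift,
    expected_final_features = n_features - n_blank_feat - n_members,
    config = list(n_features = n_features, n_bio_samples = n_bio_samples,
                  qc_every = qc_every, n_blanks = n_blanks,
                  dilution_factors = dilution_factors, noise_cv = noise_cv,
                  bio_cv = bio_cv, drift_amplitude = drift_amplitude,
                  frac_blank_features = frac_blank_features,
                  n_redundant_groups = n_redundant_groups,
                  redundant_group_size = redundant_group_size,
                  n_standards = n_standards, seed = seed)
  ), class = "synthetic_truth")

  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d blank features, %d redundancy ",
                     "groups, %d standards\n"),
              length(x$blank_features),
              length(unique(x$redundancy$group)), length(x$standards)))
  invisible(x)
}

#' Simulate a preclinical phenotyping table with historical controls
#'
#' Emulates a control database of wild-type animals plus a small project
#' control cohort measured on the same quantitative variables. Each
#' variable is, per sex, either normally distributed or lognormal
#' (right-skewed); the generating family is recorded so that
#' transformation selection can be scored against the truth. Both cohorts
#' are drawn from the same distributions (the project animals are genuine
#' controls).
#'
#' @param n_historical Historical-control animals (males get the 573/1112
#'   share of the reference database design).
#' @param n_project Project control animals.
#' @param n_variables Number of quantitative variables.
#' @param skewed_fraction Fraction of variables drawn lognormal.
#' @param seed Integer seed.
#' @return A list with `table` (tibble: `animal_id`, `sex`, `cohort`,
#'   variable columns) and `truth` (tibble: `variable`, `family`).
#' @export
simulate_preclinical <- function(n_historical = 1112, n_project = 15,
                                 n_variables = 200, skewed_fraction = 1 / 3,
                                 seed = NULL) {
  stopifnot(n_historical >= 3, n_project >= 0, n_variables >= 1,
            skewed_fraction >= 0, skewed_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)

  n_skew <- round(skewed_fraction * n_variables)
  family <- rep("normal", n_variables)
  if (n_skew > 0) family[sample.int(n_variables, n_skew)] <- "lognormal"
  vars <- sprintf("var%03d", seq_len(n_variables))

  n_hist_m <- round(n_historical * 573 / 1112)
  sex_hist <- rep(c("M", "F"), c(n_hist_m, n_historical - n_hist_m))
  sex_proj <- rep_len(c("M", "F"), n_project)
  sex <- c(sex_hist, sex_proj)
  cohort <- rep(c("historical", "project"), c(n_historical, n_project))
  n_tot <- n_historical + n_project

  tab <- tibble::tibble(
    animal_id = sprintf("animal%04d", seq_len(n_tot)),
    sex = sex, cohort = cohort)
  mu <- runif(n_variables, 10, 100)
  sex_shift <- runif(n_variables, 0, 0.15)
  cv <- runif(n_variables, 0.05, 0.20)
  sdlog <- runif(n_variables, 0.4, 0.8)
  for (v in seq_len(n_variables)) {
    mu_sex <- ifelse(sex == "M", mu[v] * (1 + sex_shift[v]),
                     mu[v] * (1 - sex_shift[v]))
    if (family[v] == "normal") {
      tab[[vars[v]]] <- rnorm(n_tot, mu_sex, cv[v] * mu_sex)
    } else {
      tab[[vars[v]]] <- rlnorm(n_tot, meanlog = log(mu_sex), sdlog = sdlog[v])
    }
  }
  list(table = tab,
       truth = tibble::tibble(variable = vars, family = family,
                              mu = mu, sex_shift = sex_shift,
                              cv = cv, sdlog = sdlog))
}
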