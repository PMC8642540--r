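# Small hand-built datasets used across test files.

# A dataset built directly from a features x samples matrix plus minimal
# metadata. `types` follows the matrix column order; injection order is
# 1..n unless given.
make_dataset <- function(mat, types, dilution = NULL, order = NULL,
                         mz = NULL, rt = NULL, log_transformed = FALSE) {
  n_s <- ncol(mat)
  n_f <- nrow(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%d", seq_len(n_s))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%d", seq_len(n_f))
  dil <- rep(NA_real_, n_s)
  if (!is.null(dilution)) dil[types == "pool_dilution"] <- dilution
  samples <- tibble::tibble(
    sample_id = colnames(mat),
    sample_type = types,
    injection_order = if (is.null(order)) seq_len(n_s) else order,
    dilution_factor = dil)
  features <- tibble::tibble(
    feature_id = rownames(mat),
    mz = if (is.null(mz)) seq(100, by = 10, length.out = n_f) else mz,
    rt = if (is.null(rt)) seq(60, by = 30, length.out = n_f) else rt)
  ms_dataset(mat, samples, features, log_transformed = log_transformed)
}

# Brute-force ICC(A,1) via stats::aov two-way decomposition: independent
# of the package's own mean-squares implementation.
icc_a1_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y)
  df <- data.frame(value = as.vector(y),
                   row = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ row + col, data = df))[[1]]
  msr <- tab["row", "Mean Sq"]
  msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force Mahalanobis distances via explicit covariance inversion.
mahalanobis_oracle <- function(x) {
  ctr <- colMeans(x)
  S_inv <- solve(stats::cov(x))
  apply(x, 1, function(p) sqrt(drop(t(p - ctr) %*% S_inv %*% (p - ctr))))
}

# Brute-force squared-cosine of the angle between v and its least-squares
# projection on the column span of T, via explicit normal equations.
cos2_oracle <- function(T_mat, v) {
  beta <- solve(t(T_mat) %*% T_mat) %*% t(T_mat) %*% v
  proj <- T_mat %*% beta
  sum(proj^2) / sum(v^2)
}
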