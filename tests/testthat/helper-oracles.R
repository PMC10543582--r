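# Independent oracles used by the combat and pipeline tests.  These are
# deliberately coded from the definitions (not by calling the package
# internals) so that implementation and check stay on separate routes.

# Brute-force conditional posterior-mean fixed point for one batch,
# computed from the raw standardized rows (not from the moment identity
# the implementation uses).  Run far past any practical tolerance.
eb_fixed_point_oracle <- function(z_batch, gamma_bar, tau2, shape, scale,
                                  iters = 10000, tol = 1e-12) {
  z_batch <- as.matrix(z_batch)
  n <- nrow(z_batch)
  g <- colMeans(z_batch)
  d2 <- colMeans(sweep(z_batch, 2, g)^2)
  for (k in seq_len(iters)) {
    g_new <- (n * tau2 * colMeans(z_batch) + d2 * gamma_bar) /
      (n * tau2 + d2)
    sum2 <- colSums(sweep(z_batch, 2, g_new)^2)
    d2_new <- (scale + 0.5 * sum2) / (n / 2 + shape - 1)
    if (max(abs(g_new - g), abs(d2_new - d2)) < tol) {
      g <- g_new; d2 <- d2_new
      break
    }
    g <- g_new; d2 <- d2_new
  }
  list(gamma_star = g, delta_star = sqrt(d2))
}

# Direct per-batch location/scale re-standardization: the closed form the
# no-shrinkage harmonization must reproduce.  Works on the raw data with
# the covariate part removed independently via lm().
restandardize_oracle <- function(y, batch, covariates = NULL) {
  y <- as.matrix(y)
  batch <- factor(batch)
  n <- nrow(y)
  if (is.null(covariates)) {
    D <- stats::model.matrix(~ 0 + batch)
  } else {
    D <- stats::model.matrix(~ 0 + batch + .,
                             data = as.data.frame(covariates))
  }
  out <- y
  for (v in seq_len(ncol(y))) {
    fit <- stats::lm.fit(D, y[, v])
    coefs <- fit$coefficients
    bc <- coefs[seq_len(nlevels(batch))]
    alpha <- sum(table(batch) / n * bc)
    cov_part <- drop(D[, -seq_len(nlevels(batch)), drop = FALSE] %*%
                       coefs[-seq_len(nlevels(batch))])
    if (is.null(covariates)) cov_part <- rep(0, n)
    sigma <- sqrt(mean(fit$residuals^2))
    r <- y[, v] - alpha - cov_part
    for (b in levels(batch)) {
      i <- batch == b
      mu_b <- mean(r[i])
      sd_b <- sqrt(mean((r[i] - mu_b)^2))
      out[i, v] <- alpha + cov_part[i] + sigma * (r[i] - mu_b) / sd_b
    }
  }
  out
}

# Small deterministic 2-batch x 3-feature standardized fixture used by the
# EB limit and fixed-point tests.
make_eb_fixture <- function() {
  set.seed(424242)
  n <- c(12, 15)
  batch <- rep(c("A", "B"), n)
  z <- rbind(
    matrix(rnorm(n[1] * 3, mean = rep(c(-0.4, -0.3, -0.5), each = n[1]),
                 sd = rep(c(0.8, 1.0, 1.2), each = n[1])), ncol = 3),
    matrix(rnorm(n[2] * 3, mean = rep(c(0.3, 0.4, 0.2), each = n[2]),
                 sd = rep(c(1.1, 0.9, 1.3), each = n[2])), ncol = 3))
  colnames(z) <- paste0("f", 1:3)
  list(z = z, batch = batch)
}
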