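#' Covariate-adjusted standardization for scanner harmonization
#'
#' First stage of the location-scale harmonization model
#'
#' \deqn{y_{ijv} = \alpha_v + X_{ij}^T\beta_v + \gamma_{iv} +
#'       \delta_{iv}\,\epsilon_{ijv},\qquad \epsilon \sim N(0, \sigma_v^2),}
#'
#' where \eqn{i} indexes the batch (scanner/site/protocol), \eqn{j} the
#' subject and \eqn{v} the feature.  Per feature, a least-squares fit of
#' intercept + covariates + batch indicators is computed under the
#' identifiability constraint \eqn{\sum_i n_i \hat\gamma_i = 0}, so
#' \eqn{\hat\alpha_v} is the sample-size-weighted grand intercept.
#' \eqn{\hat\sigma_v} is the root-mean-square residual over all subjects
#' (1/n convention).  The standardized data
#' \eqn{z = (y - \hat\alpha - X\hat\beta)/\hat\sigma} retain the batch
#' effects, which the empirical-Bayes stage then estimates and removes.
#'
#' @param y Numeric matrix, subjects x features (a data frame of numeric
#'   columns is accepted).  No missing values.
#' @param batch Batch label per subject (factor or character); every batch
#'   needs at least 2 subjects.
#' @param covariates Optional data frame of biological covariates (e.g. age
#'   and group); expanded with `model.matrix`, so factors are allowed.
#' @return A list with elements `fit` (partial fit: `alpha_hat`,
#'   `beta_hat`, `sigma_hat`, raw- and standardized-scale `gamma_hat`,
#'   batch bookkeeping, the covariate model matrix) and `z` (the
#'   standardized matrix).
#' @export
fit_standardize <- function(y, batch, covariates = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (is.null(colnames(y)))
    colnames(y) <- paste0("feature_", seq_len(ncol(y)))
  if (anyNA(y) || !all(is.finite(y)))
    stop("feature matrix contains missing or non-finite values; ",
         "impute or drop those subjects first")
  batch <- droplevels(factor(batch))
  n <- nrow(y)
  if (length(batch) != n)
    stop("batch must have one label per subject")
  nb <- table(batch)
  if (any(nb < 2))
    stop("every batch needs at least 2 subjects; offending batch(es): ",
         paste(names(nb)[nb < 2], collapse = ", "))

  X <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  B <- diag(nlevels(batch))[as.integer(batch), , drop = FALSE]
  colnames(B) <- levels(batch)
  D <- cbind(B, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrD, y)
  nlev <- nlevels(batch)
  bcoef <- coef[seq_len(nlev), , drop = FALSE]
  beta_hat <- if (is.null(X)) NULL else coef[-seq_len(nlev), , drop = FALSE]

  w <- as.numeric(nb) / n
  alpha_hat <- drop(crossprod(w, bcoef))          # weighted grand intercept
  gamma_hat_raw <- sweep(bcoef, 2, alpha_hat)     # sum_i n_i gamma_i = 0

  fitted <- D %*% coef
  sigma_hat <- sqrt(colMeans((y - fitted)^2))
  scale_y <- pmax(sqrt(colMeans(y^2)), 1)
  sigma_hat[sigma_hat < 1e-8 * scale_y] <- 0  # numerically exact fit
  if (any(sigma_hat <= 0))
    stop("zero residual variance for feature(s): ",
         paste(colnames(y)[sigma_hat <= 0], collapse = ", "),
         "; the standardization is undefined")

  cov_part <- if (is.null(X)) matrix(0, n, ncol(y)) else X %*% beta_hat
  z <- sweep(sweep(y - cov_part, 2, alpha_hat), 2, sigma_hat, "/")
  dimnames(z) <- dimnames(y)

  fit <- list(alpha_hat = alpha_hat, beta_hat = beta_hat,
              sigma_hat = sigma_hat,
              gamma_hat_raw = gamma_hat_raw,
              gamma_hat = sweep(gamma_hat_raw, 2, sigma_hat, "/"),
              batch = batch, batch_levels = levels(batch),
              n_batch = as.numeric(nb), X = X,
              features = colnames(y))
  list(fit = fit, z = z)
}

# per-batch location (mean) and scale^2 (1/n_i convention) of the
# standardized data; rows = batches, cols = features
batch_moments <- function(z, batch) {
  batch <- droplevels(factor(batch))
  n_i <- as.numeric(table(batch))
  g <- rowsum(z, batch) / n_i
  resid2 <- (z - g[as.integer(batch), , drop = FALSE])^2
  d2 <- rowsum(resid2, batch) / n_i
  list(gamma_hat = g, delta2_hat = d2, n_batch = n_i,
       batch_levels = levels(batch))
}

# inverse-gamma shape/scale whose mean and variance match (m, s2)
ig_moment_match <- function(m, s2) {
  list(shape = (2 * s2 + m^2) / s2, scale = (m * s2 + m^3) / s2)
}

#' Empirical-Bayes hyperpriors for the batch effects
#'
#' Across features, the per-batch location effects \eqn{\hat\gamma_{iv}}
#' are modeled as draws from \eqn{N(\bar\gamma_i, \tau_i^2)} and the scale
#' effects \eqn{\hat\delta^2_{iv}} as draws from an inverse-gamma
#' \eqn{(\lambda_i, \theta_i)}.  Hyperparameters are estimated by the
#' method of moments: \eqn{\bar\gamma_i, \tau_i^2} are the across-feature
#' mean and variance of \eqn{\hat\gamma_{iv}}, and \eqn{\lambda_i,
#' \theta_i} solve the inverse-gamma mean/variance equations for the
#' across-feature moments of \eqn{\hat\delta^2_{iv}}.
#'
#' With a single feature (or zero across-feature variance) the moments are
#' degenerate; the prior is then flagged so that the adjustment falls back
#' to complete pooling for that component, with a warning.
#'
#' @param z Standardized matrix from [fit_standardize()].
#' @param batch Batch label per subject.
#' @return Data frame with one row per batch: `batch`, `n`, `gamma_bar`,
#'   `tau2`, `lambda` (shape), `theta` (scale), plus attributes
#'   `gamma_hat` and `delta2_hat` (batch x feature matrices of the
#'   standardized-data batch moments).
#' @export
estimate_hyperpriors <- function(z, batch) {
  z <- as.matrix(z)
  mom <- batch_moments(z, batch)
  V <- ncol(z)
  nb <- length(mom$batch_levels)
  pri <- data.frame(batch = mom$batch_levels, n = mom$n_batch,
                    gamma_bar = rowMeans(mom$gamma_hat),
                    tau2 = NA_real_, lambda = NA_real_, theta = NA_real_)
  for (i in seq_len(nb)) {
    if (V < 2) {
      pri$tau2[i] <- 0
      pri$lambda[i] <- Inf
      pri$theta[i] <- Inf
    } else {
      # across-feature moments with the 1/V convention, matching the
      # 1/n convention used for the within-batch moments
      g <- mom$gamma_hat[i, ]
      pri$tau2[i] <- mean((g - mean(g))^2)
      d2 <- mom$delta2_hat[i, ]
      m <- mean(d2)
      s2 <- mean((d2 - m)^2)
      if (s2 <= 0) {
        pri$lambda[i] <- Inf
        pri$theta[i] <- Inf
      } else {
        ig <- ig_moment_match(m, s2)
        pri$lambda[i] <- ig$shape
        pri$theta[i] <- ig$scale
      }
    }
  }
  if (V < 2)
    warning("only one feature: across-feature hyperpriors are degenerate; ",
            "EB adjustment falls back to complete pooling")
  attr(pri, "gamma_hat") <- mom$gamma_hat
  attr(pri, "delta2_hat") <- mom$delta2_hat
  attr(pri, "delta2_mean") <- rowMeans(mom$delta2_hat)
  pri
}

#' Iterative empirical-Bayes batch-effect estimates
#'
#' Conditional posterior-mean updates for the per-(batch, feature) location
#' and scale effects on the standardized data: given the current
#' \eqn{\delta^{*2}}, the posterior mean of \eqn{\gamma} under its normal
#' prior is
#' \deqn{\gamma^* = \frac{n_i\tau_i^2\,\hat\gamma +
#'       \delta^{*2}\bar\gamma_i}{n_i\tau_i^2 + \delta^{*2}},}
#' and given \eqn{\gamma^*}, the posterior mean of \eqn{\delta^2} under its
#' inverse-gamma prior is
#' \deqn{\delta^{*2} = \frac{\theta_i + \tfrac12\sum_j (z_{ijv} -
#'       \gamma^*)^2}{n_i/2 + \lambda_i - 1}.}
#' Iteration stops when the largest absolute change falls below `tol` or
#' after `max_iter` sweeps (non-convergence returns the last iterate with a
#' warning and `converged = FALSE`).
#'
#' Limits: \eqn{\tau^2 \to \infty} gives \eqn{\gamma^* = \hat\gamma}
#' (no pooling); \eqn{\tau^2 = 0} gives \eqn{\gamma^* = \bar\gamma_i}
#' (complete pooling).  A degenerate scale prior (infinite `lambda`,
#' `theta`, from zero across-feature variance) pins \eqn{\delta^{*2}} at
#' the across-feature mean of \eqn{\hat\delta^2}.
#'
#' @param z Standardized matrix from [fit_standardize()].
#' @param batch Batch label per subject.
#' @param priors Hyperprior table from [estimate_hyperpriors()] (rows in
#'   batch-level order; columns `gamma_bar`, `tau2`, `lambda`, `theta`).
#' @param tol Convergence tolerance on the max absolute change.
#' @param max_iter Iteration cap.
#' @return List with batch x feature matrices `gamma_star` and
#'   `delta_star` (> 0), `iterations` per batch, and `converged`.
#' @export
eb_adjust <- function(z, batch, priors, tol = 1e-6, max_iter = 100L) {
  z <- as.matrix(z)
  mom <- batch_moments(z, batch)
  nb <- length(mom$batch_levels)
  stopifnot(nrow(priors) == nb)
  gamma_star <- mom$gamma_hat
  delta2_star <- mom$delta2_hat
  iterations <- integer(nb)
  converged <- logical(nb)
  for (i in seq_len(nb)) {
    n_i <- mom$n_batch[i]
    g_hat <- mom$gamma_hat[i, ]
    d2_hat <- mom$delta2_hat[i, ]
    g_bar <- priors$gamma_bar[i]
    tau2 <- priors$tau2[i]
    lam <- priors$lambda[i]
    th <- priors$theta[i]
    d2_mean <- mean(d2_hat)
    fixed_scale <- !is.finite(lam) || !is.finite(th)
    if (fixed_scale && tau2 == 0) {
      # both priors degenerate: complete pooling, closed form
      gamma_star[i, ] <- g_bar
      delta2_star[i, ] <- d2_mean
      converged[i] <- TRUE
      next
    }
    g_old <- g_hat
    d2_old <- d2_hat
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- if (!is.finite(tau2)) g_hat
               else if (tau2 == 0) rep(g_bar, length(g_hat))
               else (n_i * tau2 * g_hat + d2_old * g_bar) /
                    (n_i * tau2 + d2_old)
      # sum_j (z - g_new)^2 = n_i * (d2_hat + (g_hat - g_new)^2)
      sum2 <- n_i * (d2_hat + (g_hat - g_new)^2)
      d2_new <- if (fixed_scale) rep(d2_mean, length(d2_hat))
                else (th + 0.5 * sum2) / (n_i / 2 + lam - 1)
      delta_max <- max(abs(g_new - g_old), abs(d2_new - d2_old))
      g_old <- g_new
      d2_old <- d2_new
      if (delta_max < tol) { converged[i] <- TRUE; break }
      if (it >= max_iter) break
    }
    iterations[i] <- it
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d2_old
  }
  if (!all(converged))
    warning("EB iteration did not converge within ", max_iter,
            " sweeps for batch(es): ",
            paste(mom$batch_levels[!converged], collapse = ", "),
            "; last iterate returned")
  list(gamma_star = gamma_star, delta_star = sqrt(delta2_star),
       iterations = iterations, converged = all(converged))
}

#' Fit the harmonization model
#'
#' Runs covariate-adjusted standardization ([fit_standardize()]),
#' hyperprior estimation ([estimate_hyperpriors()]) and the iterative
#' empirical-Bayes adjustment ([eb_adjust()]), returning every fitted
#' quantity needed to harmonize the data or audit the fit.
#'
#' @inheritParams fit_standardize
#' @param eb Use empirical-Bayes shrinkage?  `FALSE` uses the unshrunk
#'   per-batch estimates \eqn{\hat\gamma, \hat\delta} directly (a plain
#'   per-batch location/scale re-standardization).
#' @param tol,max_iter Passed to [eb_adjust()].
#' @return An object of class `combat_fit`.
#' @seealso [apply_harmonization()], [combat_harmonize()]
#' @export
combat_fit <- function(y, batch, covariates = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 100L) {
  fs <- fit_standardize(y, batch, covariates)
  fit <- fs$fit
  priors <- estimate_hyperpriors(fs$z, fit$batch)
  mom <- batch_moments(fs$z, fit$batch)
  fit$delta_hat <- sqrt(mom$delta2_hat)
  fit$priors <- priors
  fit$eb <- isTRUE(eb)
  if (fit$eb) {
    adj <- eb_adjust(fs$z, fit$batch, priors, tol = tol,
                     max_iter = max_iter)
    fit$gamma_star <- adj$gamma_star
    fit$delta_star <- adj$delta_star
    fit$iterations <- adj$iterations
    fit$converged <- adj$converged
  } else {
    fit$gamma_star <- mom$gamma_hat
    fit$delta_star <- fit$delta_hat
    fit$iterations <- 0L
    fit$converged <- TRUE
  }
  class(fit) <- "combat_fit"
  fit
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("Location-scale harmonization fit (",
      if (x$eb) "empirical Bayes" else "no shrinkage", ")\n", sep = "")
  cat("  features: ", paste(x$features, collapse = ", "), "\n")
  cat("  batches:  ", paste0(x$batch_levels, " (n=", x$n_batch, ")",
                             collapse = ", "), "\n")
  cat("  gamma* (standardized scale):\n")
  print(round(x$gamma_star, 4))
  cat("  delta*:\n")
  print(round(x$delta_star, 4))
  invisible(x)
}

#' Apply a harmonization fit
#'
#' Reconstructs harmonized values from a [combat_fit()]: on the
#' standardized scale the estimated batch location is subtracted and the
#' batch scale divided out, then the residual is returned to the original
#' scale and the covariate part restored,
#'
#' \deqn{y^{harm}_{ijv} = \hat\sigma_v\,
#'   \frac{z_{ijv} - \gamma^*_{iv}}{\delta^*_{iv}}
#'   + \hat\alpha_v + X_{ij}^T\hat\beta_v.}
#'
#' Covariate associations are preserved by construction.  With a single
#' batch the transformation is the identity up to floating-point error.
#'
#' @param y The feature matrix the fit was produced on (same subjects, same
#'   order).
#' @param fit A [combat_fit()].
#' @return Numeric matrix of harmonized values, same shape as `y`.
#' @export
apply_harmonization <- function(y, fit) {
  stopifnot(inherits(fit, "combat_fit"))
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(y) != length(fit$batch) || ncol(y) != length(fit$features))
    stop("shape mismatch: fit was produced on ", length(fit$batch),
         " subjects x ", length(fit$features), " features")
  if (!is.null(colnames(y)) && !identical(colnames(y), fit$features))
    stop("feature names do not match the fit: ",
         paste(colnames(y), collapse = ", "))
  cov_part <- if (is.null(fit$X)) matrix(0, nrow(y), ncol(y))
              else fit$X %*% fit$beta_hat
  z <- sweep(sweep(y - cov_part, 2, fit$alpha_hat), 2, fit$sigma_hat, "/")
  bi <- as.integer(fit$batch)
  z_adj <- (z - fit$gamma_star[bi, , drop = FALSE]) /
    fit$delta_star[bi, , drop = FALSE]
  out <- sweep(sweep(z_adj, 2, fit$sigma_hat, "*"), 2, fit$alpha_hat, "+") +
    cov_part
  dimnames(out) <- dimnames(y)
  out
}

#' Fit and apply harmonization in one call
#'
#' @inheritParams combat_fit
#' @return List with `harmonized` (matrix) and `fit` (the [combat_fit()]).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_per_cell = 50, seed = 7))
#' h <- combat_harmonize(cohort[, c("alps_left", "alps_right")],
#'                       batch = cohort$scanner,
#'                       covariates = cohort[, c("age", "group")])
#' round(h$fit$gamma_star, 3)
combat_harmonize <- function(y, batch, covariates = NULL, eb = TRUE,
                             tol = 1e-6, max_iter = 100L) {
  fit <- combat_fit(y, batch, covariates, eb = eb, tol = tol,
                    max_iter = max_iter)
  list(harmonized = apply_harmonization(as.matrix(y), fit), fit = fit)
}

#' Serialize a harmonization fit for audit
#'
#' Converts the fitted quantities (intercepts, covariate coefficients,
#' residual scales, batch effects, hyperpriors, EB estimates, convergence
#' info) to a plain list of named numeric vectors/matrices suitable for
#' `yaml::write_yaml()` or `jsonlite::write_json()`.
#'
#' @param fit A [combat_fit()].
#' @return A list of plain R objects (no factors, no matrices without
#'   dimnames).
#' @export
combat_fit_to_list <- function(fit) {
  stopifnot(inherits(fit, "combat_fit"))
  mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    rn <- rownames(m)
    lapply(stats::setNames(seq_len(nrow(m)),
                           if (is.null(rn)) paste0("row_", seq_len(nrow(m)))
                           else rn),
           function(i) stats::setNames(as.numeric(m[i, ]), colnames(m)))
  }
  list(features = fit$features,
       batch_levels = fit$batch_levels,
       n_batch = fit$n_batch,
       eb = fit$eb,
       alpha_hat = as.list(stats::setNames(as.numeric(fit$alpha_hat),
                                           fit$features)),
       beta_hat = mat(fit$beta_hat),
       sigma_hat = as.list(stats::setNames(as.numeric(fit$sigma_hat),
                                           fit$features)),
       gamma_hat = mat(fit$gamma_hat),
       delta_hat = mat(fit$delta_hat),
       gamma_star = mat(fit$gamma_star),
       delta_star = mat(fit$delta_star),
       priors = as.list(fit$priors[
         c("batch", "n", "gamma_bar", "tau2", "lambda", "theta")]),
       iterations = fit$iterations,
       converged = fit$converged)
}
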