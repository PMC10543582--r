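test_that("standardization reproduces closed-form least squares", {
  # one batch, no covariates: alpha is the sample mean, z has mean 0, RMS 1
  set.seed(1)
  y <- cbind(f1 = rnorm(40, 2, 0.5), f2 = rnorm(40, -1, 2))
  fs <- fit_standardize(y, batch = rep("A", 40))
  expect_equal(fs$fit$alpha_hat, colMeans(y))
  expect_equal(colMeans(fs$z), c(f1 = 0, f2 = 0), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(fs$z^2)), c(f1 = 1, f2 = 1), tolerance = 1e-12)

  # two equal-size batches shifted by +c: raw-scale gamma = (-c/2, +c/2)
  shift <- 0.6
  set.seed(2)
  base <- rnorm(30, 1.5, 0.001)  # near-noiseless
  y2 <- cbind(f = c(base, base + shift))
  b2 <- rep(c("A", "B"), each = 30)
  fs2 <- fit_standardize(y2, b2)
  expect_equal(unname(fs2$fit$gamma_hat_raw[, 1]), c(-shift / 2, shift / 2),
               tolerance = 1e-3)
  # standardized-scale gamma is the raw one over sigma_hat
  expect_equal(fs2$fit$gamma_hat, fs2$fit$gamma_hat_raw /
                 rep(fs2$fit$sigma_hat, each = 2))
  # a truly noiseless instance makes sigma zero: informative error
  y0 <- cbind(f = c(rep(1.5, 30), rep(1.5 + shift, 30)))
  expect_error(fit_standardize(y0, b2), "zero residual variance")

  # full fit agrees with lm() on the same design
  cfg <- simulation_config(n_per_cell = 60, seed = 31L)
  ch <- generate_cohort(cfg)
  y3 <- as.matrix(ch[, c("alps_left", "alps_right")])
  fs3 <- fit_standardize(y3, ch$scanner, ch[, c("age", "group")])
  ref <- lm(y3 ~ 0 + factor(ch$scanner) + ch$age + (ch$group == "AD"))
  expect_equal(unname(fs3$fit$beta_hat),
               unname(coef(ref)[4:5, ]), tolerance = 1e-10)
  expect_equal(unname(colSums(fs3$fit$gamma_hat_raw *
                                fs3$fit$n_batch)),
               c(0, 0), tolerance = 1e-10)
})

test_that("covariate coefficients are recovered from a large synthetic cohort", {
  cfg <- simulation_config(n_per_cell = 500, seed = 77L)
  ch <- generate_cohort(cfg)
  y <- as.matrix(ch[, c("alps_left", "alps_right")])
  fs <- fit_standardize(y, ch$scanner, ch[, c("age", "group")])
  # 3 standard errors from lm() on the same design
  for (v in 1:2) {
    ref <- summary(lm(y[, v] ~ 0 + factor(ch$scanner) + ch$age +
                        I(ch$group == "AD")))
    se <- ref$coefficients[4:5, "Std. Error"]
    expect_lt(abs(fs$fit$beta_hat[1, v] - cfg$beta_age), 3 * se[1])
    expect_lt(abs(fs$fit$beta_hat[2, v] - cfg$beta_group), 3 * se[2])
  }
})

test_that("standardization rejects bad designs with the offender named", {
  y <- cbind(f = rnorm(20))
  b <- rep(c("A", "B"), each = 10)
  covs <- data.frame(age = rnorm(20))
  covs$age2 <- covs$age * 2  # collinear
  expect_error(fit_standardize(y, b, covs), "age2")
  expect_error(fit_standardize(y, c(rep("A", 19), "B")), "B")
  y[3] <- NA
  expect_error(fit_standardize(y, b), "missing")
})

test_that("hyperprior moments match their definitions", {
  # construct standardized data with exact per-batch moments:
  # feature sds chosen so delta2_hat = (0.5, 1.5) in batch A
  n <- 8
  spread <- function(s2) rep(c(1, -1), n / 2) * sqrt(s2)
  z <- cbind(f1 = c(spread(0.5), spread(0.5)),
             f2 = c(spread(1.5), spread(1.5)))
  batch <- rep(c("A", "B"), each = n)
  pri <- estimate_hyperpriors(z, batch)
  # gamma_hat identical (zero) across features -> tau2 = 0
  expect_equal(pri$tau2, c(0, 0))
  # inverse-gamma moment match for mean 1.0, variance 0.25:
  # shape 6 and scale 5 solve the two moment equations
  expect_equal(pri$lambda, c(6, 6))
  expect_equal(pri$theta, c(5, 5))
  # round trip: the matched IG really has those moments
  m <- pri$theta[1] / (pri$lambda[1] - 1)
  v <- pri$theta[1]^2 / ((pri$lambda[1] - 1)^2 * (pri$lambda[1] - 2))
  expect_equal(m, 1.0)
  expect_equal(v, 0.25)
  expect_equal(unname(attr(pri, "delta2_hat")["A", ]), c(0.5, 1.5))
})

test_that("EB adjustment reproduces its no-pooling and complete-pooling limits", {
  fx <- make_eb_fixture()
  pri <- estimate_hyperpriors(fx$z, fx$batch)
  g_hat <- attr(pri, "gamma_hat")

  no_pool <- pri; no_pool$tau2 <- c(Inf, Inf)
  adj <- eb_adjust(fx$z, fx$batch, no_pool)
  expect_equal(adj$gamma_star, g_hat, tolerance = 1e-15)

  full_pool <- pri; full_pool$tau2 <- c(0, 0)
  adj0 <- eb_adjust(fx$z, fx$batch, full_pool)
  for (i in 1:2)
    expect_equal(unname(adj0$gamma_star[i, ]),
                 rep(pri$gamma_bar[i], 3), tolerance = 1e-15)
})

test_that("EB estimates match an independent fixed-point solver", {
  fx <- make_eb_fixture()
  pri <- estimate_hyperpriors(fx$z, fx$batch)
  adj <- eb_adjust(fx$z, fx$batch, pri, tol = 1e-12, max_iter = 1000L)
  for (i in 1:2) {
    b <- c("A", "B")[i]
    oracle <- eb_fixed_point_oracle(fx$z[fx$batch == b, ],
                                    pri$gamma_bar[i], pri$tau2[i],
                                    pri$lambda[i], pri$theta[i])
    expect_equal(unname(adj$gamma_star[i, ]), unname(oracle$gamma_star),
                 tolerance = 1e-10)
    expect_equal(unname(adj$delta_star[i, ]), unname(oracle$delta_star),
                 tolerance = 1e-10)
  }
  expect_true(adj$converged)
})

test_that("single-batch harmonization is the identity", {
  cfg <- simulation_config(
    n_per_cell = 80, seed = 13L,
    scanners = data.frame(scanner = "only", gamma = 0, delta = 1))
  ch <- generate_cohort(cfg)
  y <- as.matrix(ch[, c("alps_left", "alps_right")])
  h <- combat_harmonize(y, ch$scanner, ch[, c("age", "group")])
  expect_lt(max(abs(h$harmonized - y) / pmax(abs(y), 1e-12)), 1e-8)
})

test_that("disabling shrinkage equals a direct per-batch re-standardization", {
  cfg <- simulation_config(n_per_cell = 40, seed = 23L)
  ch <- generate_cohort(cfg)
  y <- as.matrix(ch[, c("alps_left", "alps_right")])
  covs <- ch[, c("age", "group")]
  h <- combat_harmonize(y, ch$scanner, covs, eb = FALSE)
  oracle <- restandardize_oracle(y, ch$scanner, covs)
  expect_lt(max(abs(h$harmonized - oracle)), 1e-10)
})

test_that("harmonization removes scanner effects and preserves the group effect", {
  cfg <- simulation_config(seed = 41L)  # spec'd default study conditions
  ch <- generate_cohort(cfg)
  y <- as.matrix(ch[, c("alps_left", "alps_right")])
  h <- combat_harmonize(y, ch$scanner, ch[, c("age", "group")])
  scanners <- unique(ch$scanner)
  prs <- combn(scanners, 2)
  for (v in 1:2) for (k in seq_len(ncol(prs))) {
    d <- cohens_d(h$harmonized[ch$scanner == prs[1, k], v],
                  h$harmonized[ch$scanner == prs[2, k], v])
    expect_lt(d, 0.1)
  }
  # configured group effect recovered from the harmonized data
  for (v in 1:2) {
    ref <- summary(lm(h$harmonized[, v] ~ ch$age + I(ch$group == "AD")))
    est <- ref$coefficients[3, ]
    expect_lt(abs(est["Estimate"] - cfg$beta_group),
              3 * est["Std. Error"])
  }
})

test_that("harmonizing twice changes almost nothing", {
  cfg <- simulation_config(seed = 51L)
  ch <- generate_cohort(cfg)
  y <- as.matrix(ch[, c("alps_left", "alps_right")])
  covs <- ch[, c("age", "group")]
  h1 <- combat_harmonize(y, ch$scanner, covs)$harmonized
  h2 <- combat_harmonize(h1, ch$scanner, covs)$harmonized
  rms_change <- sqrt(mean((h2 - h1)^2)) / sqrt(mean(h1^2))
  expect_lt(rms_change, 0.01)
})

test_that("residual batch effects shrink as the per-cell sample size grows", {
  gap_after <- function(n, seed) {
    cfg <- simulation_config(n_per_cell = n, seed = seed)
    ch <- generate_cohort(cfg)
    y <- as.matrix(ch[, c("alps_left", "alps_right")])
    h <- combat_harmonize(y, ch$scanner, ch[, c("age", "group")])$harmonized
    # remove the stored ground-truth covariate part of feature 1
    m <- tapply(h[, 1] - ch$alps_left_cov, ch$scanner, mean)
    s <- tapply(h[, 1] - ch$alps_left_cov, ch$scanner, sd)
    c(loc = max(m) - min(m), scale = max(s) / min(s))
  }
  seeds <- 101:110
  gaps <- sapply(c(25, 100, 400), function(n)
    rowMeans(sapply(seeds, function(s) gap_after(n, s))))
  # mean residual location gap and scale ratio move toward 0 and 1 with n
  expect_gt(gaps["loc", 1], gaps["loc", 3])
  expect_gt(gaps["scale", 1], gaps["scale", 3])
  expect_lt(gaps["loc", 3], 0.05)
  expect_lt(gaps["scale", 3], 1.1)
})

test_that("the full pipeline agrees with the reference genomics implementation", {
  skip_if_not_installed("sva")
  set.seed(3)
  n <- 150
  batch <- rep(c("A", "B", "C"), each = 50)
  age <- runif(n, 60, 85)
  grp <- rep_len(c(0, 1), n)
  y <- sapply(1:10, function(v) 1.5 - 0.01 * age - 0.1 * grp +
                c(A = -0.3, B = 0, C = 0.3)[batch] +
                c(A = 0.7, B = 1, C = 1.5)[batch] * rnorm(n, 0, 0.2))
  colnames(y) <- paste0("f", 1:10)
  mine <- combat_harmonize(y, batch,
                           covariates = data.frame(age = age,
                                                   group = grp))$harmonized
  ref <- suppressMessages(
    t(sva::ComBat(dat = t(y), batch = batch,
                  mod = model.matrix(~ age + grp))))
  # small gap expected: the reference uses the 1/(n-1) convention for the
  # per-batch scale estimate and a looser EB stopping rule
  expect_lt(max(abs(mine - ref)), 0.02)
})
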