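test_that("Cohen's d matches hand evaluation and its affine behavior", {
  x <- rnorm(20)
  expect_equal(cohens_d(x, x), 0)

  # hand arithmetic on the eight-number jitter fixture
  x1 <- c(0, 0.1, -0.1, 0)
  x2 <- c(1, 1.1, 0.9, 1)
  s_c <- sqrt((4 * var(x1) + 4 * var(x2)) / 8)
  expect_equal(cohens_d(x1, x2), abs(mean(x1) - mean(x2)) / s_c)
  expect_equal(cohens_d(x1, x2), sqrt(150))  # 1 / sqrt(0.02/3)

  # translation invariance and 1/k scaling about the midpoint
  for (c0 in c(-3, 0.5, 10))
    expect_equal(cohens_d(x1 + c0, x2 + c0), cohens_d(x1, x2))
  mid <- mean(c(x1, x2))
  for (k in c(0.5, 2, 10))
    expect_equal(cohens_d(mid + k * (x1 - mid), mid + k * (x2 - mid)),
                 cohens_d(x1, x2))

  expect_error(cohens_d(c(1, 1), c(2, 2)), "constant")
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("Welch's t matches the textbook formulas on a printed fixture", {
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- c(2, 3, 4, 5, 6)
  cmp <- welch_t(x1, x2)
  se2 <- var(x1) / 5 + var(x2) / 5
  t_hand <- (mean(x1) - mean(x2)) / sqrt(se2)
  dof_hand <- se2^2 / ((var(x1) / 5)^2 / 4 + (var(x2) / 5)^2 / 4)
  expect_equal(attr(cmp, "welch_t"), t_hand)      # -1
  expect_equal(attr(cmp, "welch_dof"), dof_hand)  # 8
  expect_equal(attr(cmp, "p_value"), 2 * pt(t_hand, dof_hand))

  # swapping the samples flips t, leaves p (and d) unchanged
  rev <- welch_t(x2, x1)
  expect_equal(attr(rev, "welch_t"), -attr(cmp, "welch_t"))
  expect_equal(attr(rev, "p_value"), attr(cmp, "p_value"))
  expect_equal(attr(rev, "cohen_d"), attr(cmp, "cohen_d"))

  # identical samples and the constant-equal degenerate case
  same <- welch_t(x1, x1)
  expect_equal(attr(same, "welch_t"), 0)
  expect_equal(attr(same, "p_value"), 1)
  flat <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(attr(flat, "welch_t"), 0)
  expect_equal(attr(flat, "p_value"), 1)
})

test_that("Pearson r matches the product-moment formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_hand)  # 0.6
  expect_equal(res$r, 0.6)
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 2))

  expect_error(pearson_r(c(1, 1, 1), y[1:3]), "zero variance")
  expect_error(pearson_r(x[1:2], y[1:2]), "at least 3")
})

test_that("Type II ANOVA isolates the truly active factor", {
  set.seed(9)
  n <- 240
  scanner <- factor(rep(c("A", "B", "C"), each = n / 3))
  group <- factor(rep_len(c("CN", "AD"), n))
  age <- runif(n, 60, 85)

  # outcome a linear function of age only (tiny jitter keeps the
  # residual SS positive so the F statistics are defined)
  an <- glm_anova(2 + 0.05 * age + rnorm(n, 0, 1e-3),
                  data.frame(scanner, age, group))
  eta <- setNames(an$partial_eta2, an$term)
  expect_gt(an$f_value[an$term == "age"], 1e6)
  expect_lt(eta[["scanner"]], 0.05)
  expect_lt(eta[["group"]], 0.05)

  # no true scanner effect: partial eta^2 stays near zero at large n
  cfg <- simulation_config(
    n_per_cell = 400, seed = 61L,
    scanners = data.frame(scanner = c("A", "B", "C"), gamma = c(0, 0, 0),
                          delta = c(1, 1, 1)))
  ch <- generate_cohort(cfg)
  an2 <- glm_anova(ch$alps_left,
                   ch[, c("scanner", "age", "group")])
  expect_lt(an2$partial_eta2[an2$term == "scanner"], 0.02)

  # balanced one-factor two-level design: F equals the pooled t squared
  y <- rnorm(60, mean = rep(c(0, 0.8), each = 30))
  g <- factor(rep(c("a", "b"), each = 30))
  an3 <- glm_anova(y, data.frame(g))
  t_pooled <- t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(an3$f_value, unname(t_pooled^2))

  expect_error(glm_anova(y, data.frame(g = c("a", rep("b", 59)))),
               "fewer than 2")
})

test_that("noncentral-t power behaves as the null and monotonicity demand", {
  expect_equal(power_two_sample(0, 30, 30)$power, 0.05)
  expect_equal(power_two_sample(0, 45, 82, alpha = 0.10)$power, 0.10)

  # strictly increasing in d, n1, n2, alpha
  p_d <- sapply(c(0.2, 0.3, 0.5, 0.8), function(d)
    power_two_sample(d, 40, 40)$power)
  expect_true(all(diff(p_d) > 0))
  p_n <- sapply(c(20, 40, 80, 160), function(n)
    power_two_sample(0.4, n, 50)$power)
  expect_true(all(diff(p_n) > 0))
  p_a <- sapply(c(0.01, 0.05, 0.1), function(a)
    power_two_sample(0.4, 40, 40, a)$power)
  expect_true(all(diff(p_a) > 0))
  expect_true(all(c(p_d, p_n, p_a) > 0 & c(p_d, p_n, p_a) < 1))
})

test_that("required sample sizes are minimal and shrink with effect size", {
  res <- sample_size_for_power(0.5, 0.80, 0.05, allocation_ratio = 1)
  # brute-force minimality: the returned n reaches the target, n-1 does not
  expect_gte(power_two_sample(0.5, res$n1, res$n2)$power, 0.80)
  expect_lt(power_two_sample(0.5, res$n1 - 1, res$n1 - 1)$power, 0.80)
  # exhaustive search over n agrees
  ns <- 2:200
  pw <- sapply(ns, function(n) power_two_sample(0.5, n, n)$power)
  expect_equal(res$n1, ns[min(which(pw >= 0.80))])

  # monotone: larger d needs fewer subjects
  need <- sapply(c(0.2, 0.3, 0.5), function(d)
    sample_size_for_power(d, 0.80)$total_n)
  expect_true(all(diff(need) < 0))

  # unequal allocation keeps the ratio
  res2 <- sample_size_for_power(0.45, 0.80, allocation_ratio = 2)
  expect_equal(res2$n2, as.integer(ceiling(2 * res2$n1)))
  expect_gte(res2$power, 0.80)
})
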