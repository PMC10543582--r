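#' Cohen's d with an n-weighted pooled standard deviation
#'
#' Standardized mean difference between two samples,
#' \deqn{d = \frac{|\bar x_1 - \bar x_2|}{S_c},\qquad
#'       S_c = \sqrt{\frac{n_1 s_1^2 + n_2 s_2^2}{n_1 + n_2}},}
#' where \eqn{s_1, s_2} are the usual \eqn{1/(n-1)} sample standard
#' deviations and the pooling weights are the group sizes themselves (not
#' \eqn{n_k - 1}).  This is the convention used for scanner- and
#' group-effect sizes throughout the package; it differs slightly from the
#' textbook \eqn{n_1 + n_2 - 2} denominator.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @return Non-negative effect size (dimensionless).
#' @export
#' @examples
#' cohens_d(rnorm(50), rnorm(50, 0.5))
cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  stopifnot(all(is.finite(x1)), all(is.finite(x2)))
  s_c <- sqrt((n1 * stats::var(x1) + n2 * stats::var(x2)) / (n1 + n2))
  diff <- abs(mean(x1) - mean(x2))
  if (s_c == 0) {
    if (diff == 0) return(0)
    stop("both samples are constant with unequal means; d is infinite")
  }
  diff / s_c
}

#' Welch's two-sample comparison with effect size
#'
#' Unequal-variance t test (Welch-Satterthwaite degrees of freedom,
#' two-sided p) together with per-group summaries and [cohens_d()].
#' Degenerate input (both samples constant and equal) returns t = 0,
#' p = 1 rather than an error.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param labels Length-2 character group labels, for the output table.
#' @return Data frame of class `group_comparison` with one row per group
#'   (`group`, `n`, `mean`, `sd`) and attributes `cohen_d`, `welch_t`,
#'   `welch_dof`, `p_value` (also exposed as columns `t`, `dof`, `p_value`,
#'   `cohen_d` repeated on the first row for table export).
#' @export
welch_t <- function(x1, x2, labels = c("group1", "group2")) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    if (mean(x1) == mean(x2)) {
      t_stat <- 0; dof <- n1 + n2 - 2; p <- 1
    } else {
      stop("both samples are constant with unequal means; t is undefined")
    }
  } else {
    tt <- stats::t.test(x1, x2, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    dof <- unname(tt$parameter)
    p <- tt$p.value
  }
  out <- data.frame(group = labels, n = c(n1, n2),
                    mean = c(mean(x1), mean(x2)),
                    sd = c(stats::sd(x1), stats::sd(x2)))
  out$t <- c(t_stat, NA)
  out$dof <- c(dof, NA)
  out$p_value <- c(p, NA)
  out$cohen_d <- c(cohens_d(x1, x2), NA)
  attr(out, "welch_t") <- t_stat
  attr(out, "welch_dof") <- dof
  attr(out, "p_value") <- p
  attr(out, "cohen_d") <- out$cohen_d[1]
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Pearson correlation with a t-transform p value
#'
#' Product-moment correlation and its two-sided p value from the exact t
#' transform (`stats::cor.test`).
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, each with
#'   positive variance.
#' @param pair Optional length-2 character naming the variable pair.
#' @return Data frame with `var_x`, `var_y`, `n`, `r`, `p_value`.
#' @export
pearson_r <- function(x, y, pair = c("x", "y")) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in '", pair[if (stats::sd(x) == 0) 1 else 2],
         "'; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(var_x = pair[1], var_y = pair[2], n = length(x),
             r = unname(ct$estimate), p_value = ct$p.value)
}

#' Type II ANOVA with partial eta squared
#'
#' Fits `outcome ~ .` over the supplied predictors with `stats::lm`
#' (character/factor columns as categorical factors, numeric columns as
#' continuous) and computes per-term F tests from Type II sums of squares
#' (`car::Anova`), robust to mild imbalance, together with
#' \deqn{\textrm{partial } \eta^2 = \frac{SS_{term}}{SS_{term} + SS_{resid}}.}
#'
#' @param outcome Numeric response.
#' @param predictors Data frame of predictors (e.g. scanner, age, group).
#' @return Data frame with one row per term: `term`, `df`, `sum_sq`,
#'   `f_value`, `p_value`, `partial_eta2`; residual df and SS as
#'   attributes `residual_df`, `residual_ss`.
#' @export
glm_anova <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  stopifnot(length(outcome) == nrow(predictors))
  for (nm in names(predictors)) {
    v <- predictors[[nm]]
    if (is.character(v) || is.logical(v)) predictors[[nm]] <- factor(v)
    if (is.factor(predictors[[nm]])) {
      predictors[[nm]] <- droplevels(predictors[[nm]])
      cnt <- table(predictors[[nm]])
      if (any(cnt < 2))
        stop("factor '", nm, "' has level(s) with fewer than 2 ",
             "observations: ", paste(names(cnt)[cnt < 2], collapse = ", "))
    }
  }
  dat <- cbind(.outcome = outcome, predictors)
  fit <- stats::lm(.outcome ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("model is rank deficient; aliased coefficient(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  an <- car::Anova(fit, type = 2)
  terms <- rownames(an)
  resid_row <- terms == "Residuals"
  ss_res <- an[resid_row, "Sum Sq"]
  out <- data.frame(term = terms[!resid_row],
                    df = an[!resid_row, "Df"],
                    sum_sq = an[!resid_row, "Sum Sq"],
                    f_value = an[!resid_row, "F value"],
                    p_value = an[!resid_row, "Pr(>F)"])
  out$partial_eta2 <- out$sum_sq / (out$sum_sq + ss_res)
  attr(out, "residual_df") <- an[resid_row, "Df"]
  attr(out, "residual_ss") <- ss_res
  out
}

#' Two-sample power from the noncentral t distribution
#'
#' Power of the two-sided two-sample t test at significance level `alpha`
#' for standardized effect size `d`, using degrees of freedom
#' \eqn{n_1 + n_2 - 2} and noncentrality
#' \eqn{d\sqrt{n_1 n_2/(n_1 + n_2)}}.  At d = 0 the power equals
#' `alpha` (the two-sided rejection rate under the null).
#'
#' @param d Non-negative standardized effect size.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Data frame of class `power_result`: `d`, `n1`, `n2`, `alpha`,
#'   `power`.
#' @export
#' @examples
#' power_two_sample(0.438, 45, 82)  # about 0.65
power_two_sample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  t_crit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(-t_crit, df, ncp) + 1 - stats::pt(t_crit, df, ncp)
  structure(data.frame(d = d, n1 = n1, n2 = n2, alpha = alpha,
                       power = power),
            class = c("power_result", "data.frame"))
}

#' Smallest group sizes reaching a target power
#'
#' Increments the size of group 1 (group 2 follows the allocation ratio
#' \eqn{n_2 = \lceil r\, n_1\rceil}, floored at 2) until
#' [power_two_sample()] reaches `target_power`.
#'
#' @param d Positive standardized effect size.
#' @param target_power Desired power, in (`alpha`, 1).
#' @param alpha Two-sided significance level.
#' @param allocation_ratio Ratio \eqn{n_2 / n_1}.
#' @param n_max Search cap on \eqn{n_1} (error if exceeded).
#' @return Data frame of class `power_result`: `d`, `n1`, `n2`, `alpha`,
#'   `power` (achieved), `target_power`, `total_n`.
#' @export
sample_size_for_power <- function(d, target_power = 0.80, alpha = 0.05,
                                  allocation_ratio = 1, n_max = 1e6) {
  stopifnot(d > 0, target_power > alpha, target_power < 1,
            allocation_ratio > 0)
  n1 <- 2L
  repeat {
    n2 <- max(2L, as.integer(ceiling(allocation_ratio * n1)))
    pw <- power_two_sample(d, n1, n2, alpha)$power
    if (pw >= target_power) break
    n1 <- n1 + 1L
    if (n1 > n_max) stop("no group size up to ", n_max,
                         " reaches the target power")
  }
  structure(data.frame(d = d, n1 = n1, n2 = n2, alpha = alpha, power = pw,
                       target_power = target_power, total_n = n1 + n2),
            class = c("power_result", "data.frame"))
}
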