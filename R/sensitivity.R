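# Heterogeneity and pleiotropy diagnostics: Cochran's Q (naive and
# LD-aware generalized forms), the Egger intercept test, and Bonferroni
# multiple-testing control.

#' Cochran's Q heterogeneity test
#'
#' Without LD: \eqn{Q = \sum_j w_j (\theta_j - \hat\theta_{FE})^2} with the
#' IVW weights and the fixed-effects pooled estimate — always about the
#' fixed-effects estimate, the standard definition, even when the reported
#' estimate uses random effects. With an LD matrix supplied the
#' generalized residual form is used instead:
#' \eqn{Q = (\beta_Y - \hat\theta \beta_X)' \Omega^{-1} (\beta_Y -
#' \hat\theta \beta_X)} about the GLS estimate, the appropriate statistic
#' when instruments are correlated. Either way the reference distribution
#' is chi-square with J - 1 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least two variants.
#' @param ld optional signed LD correlation matrix; triggers the
#'   generalized form.
#' @return list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(h, ld = NULL) {
  J <- n_snp(h)
  if (J < 2) stop("Cochran's Q needs at least two instruments",
                  call. = FALSE)
  if (is.null(ld)) {
    w <- h$beta_x^2 / h$se_y^2
    theta <- h$beta_y / h$beta_x
    est <- sum(w * theta) / sum(w)
    q <- sum(w * (theta - est)^2)
  } else {
    fit <- mr_ivw_correlated(h, ld, variance_model = "fixed")
    omega <- .omega(h, ld)
    resid <- h$beta_y - fit$log_or * h$beta_x
    q <- sum(resid * solve(omega, resid))
  }
  df <- J - 1
  list(q_stat = q, q_df = df, q_p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Egger intercept test for directional horizontal pleiotropy
#'
#' The intercept of the Egger regression estimates the average pleiotropic
#' effect; a nonzero value indicates directional pleiotropy. Uses
#' [mr_egger()] over independent instruments, or [mr_egger_correlated()]
#' when an LD matrix is supplied. The p-value is t-based with J - 2
#' degrees of freedom.
#'
#' @param h a `harmonized_set` with at least three variants.
#' @param ld optional signed LD correlation matrix.
#' @param variance_model passed through to the Egger fit.
#' @return list with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(h, ld = NULL,
                                 variance_model = c("multiplicative_random",
                                                    "fixed")) {
  variance_model <- match.arg(variance_model)
  fit <- if (is.null(ld)) {
    mr_egger(h, variance_model)
  } else {
    mr_egger_correlated(h, ld, variance_model)
  }
  list(intercept = fit$intercept, se = fit$intercept_se,
       pvalue = fit$intercept_p)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param n_tests number of tests in the family (>= 1).
#' @return the per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}

#' Significance flag against a threshold
#'
#' The comparison is non-strict (`p <= threshold`): a p-value exactly at
#' the adjusted threshold counts as significant.
#'
#' @param p p-value(s).
#' @param threshold adjusted threshold.
#' @return logical vector.
#' @export
is_significant <- function(p, threshold) p <= threshold

#' Sensitivity report for one outcome and instrument set
#'
#' Bundles the heterogeneity and pleiotropy diagnostics for one
#' (outcome, instrument set) pair: Cochran's Q and the Egger intercept,
#' using the generalized LD-aware forms when an LD matrix is supplied.
#'
#' @param h a `harmonized_set`.
#' @param ld optional signed LD correlation matrix.
#' @param outcome outcome label.
#' @param instrument_set `"canonical"` or `"all_snps"`.
#' @param variance_model passed to the Egger fit.
#' @return one-row data.frame with columns `outcome, instrument_set,
#'   n_snp, egger_intercept, egger_intercept_se, egger_intercept_p,
#'   q_stat, q_df, q_p` (intercept columns NA when fewer than three
#'   instruments are available).
#' @export
sensitivity_report <- function(h, ld = NULL, outcome = "outcome",
                               instrument_set = c("canonical", "all_snps"),
                               variance_model = c("multiplicative_random",
                                                  "fixed")) {
  instrument_set <- match.arg(instrument_set)
  variance_model <- match.arg(variance_model)
  q <- cochran_q(h, ld)
  if (n_snp(h) >= 3) {
    eg <- egger_intercept_test(h, ld, variance_model)
  } else {
    warning("fewer than 3 instruments: Egger intercept not computed for ",
            outcome, " (", instrument_set, ")")
    eg <- list(intercept = NA_real_, se = NA_real_, pvalue = NA_real_)
  }
  data.frame(outcome = outcome, instrument_set = instrument_set,
             n_snp = n_snp(h), egger_intercept = eg$intercept,
             egger_intercept_se = eg$se, egger_intercept_p = eg$pvalue,
             q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
             stringsAsFactors = FALSE)
}
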