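# The five causal-effect estimators: inverse-variance weighting and
# MR-Egger regression, each in canonical (independent-instrument) and
# correlated (LD-aware generalized least squares) form, plus the weighted
# median. All effects are on the log-odds scale; odds ratios and their
# 95% intervals are derived by exponentiation.

#' Construct an MR estimate record
#'
#' @param method one of `ivw_canonical`, `ivw_correlated`,
#'   `egger_canonical`, `egger_correlated`, `weighted_median`.
#' @param n_snp number of instruments used.
#' @param log_or causal log-odds estimate.
#' @param se its standard error (> 0).
#' @param pvalue two-sided p-value.
#' @param ci_mult multiplier for the 95% interval half-width on the log
#'   scale (1.96 for normal-based methods, a t quantile for Egger).
#' @param intercept,intercept_se,intercept_p Egger intercept triple
#'   (NA for non-Egger methods).
#' @return an object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, n_snp, log_or, se, pvalue,
                        ci_mult = 1.96,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_p = NA_real_) {
  stopifnot(se > 0)
  structure(
    list(method = method, n_snp = as.integer(n_snp),
         log_or = log_or, se = se,
         or_value = exp(log_or),
         ci_low = exp(log_or - ci_mult * se),
         ci_high = exp(log_or + ci_mult * se),
         pvalue = pvalue,
         intercept = intercept, intercept_se = intercept_se,
         intercept_p = intercept_p),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d instruments): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$n_snp, x$or_value, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, logOR = x$log_or,
             SE = x$se, OR = x$or_value, CI_low = x$ci_low,
             CI_high = x$ci_high, p = x$pvalue, stringsAsFactors = FALSE)
}

#' Per-variant Wald ratio estimates
#'
#' The building block of every estimator: \eqn{\theta_j = \beta_{Yj} /
#' \beta_{Xj}} with first-order standard error \eqn{SE_j = SE_{Yj} /
#' |\beta_{Xj}|}. Variants with a zero exposure effect must be excluded
#' before this call.
#'
#' @param h a `harmonized_set`.
#' @return data.frame with columns `rsid, theta, se`.
#' @export
ratio_estimates <- function(h) {
  if (any(h$beta_x == 0)) {
    stop("zero exposure effect: exclude such variants before computing ",
         "Wald ratios", call. = FALSE)
  }
  data.frame(rsid = h$rsids, theta = h$beta_y / h$beta_x,
             se = h$se_y / abs(h$beta_x), stringsAsFactors = FALSE)
}

# IVW weights: exposure effect squared over outcome variance. Identical to
# the inverse first-order variance of the Wald ratio.
.ivw_weights <- function(h) h$beta_x^2 / h$se_y^2

#' Inverse-variance-weighted estimate over independent instruments
#'
#' Combines Wald ratios with weights \eqn{w_j = \beta_{Xj}^2 / SE_{Yj}^2};
#' algebraically identical to weighted through-origin regression of
#' outcome effects on exposure effects with weights \eqn{1/SE_{Yj}^2}.
#' Under the fixed model the SE is \eqn{(\sum w_j)^{-1/2}}; under the
#' multiplicative random-effects model it is inflated by
#' \eqn{\max(1, \sqrt{Q/(J-1)})} with Q Cochran's heterogeneity statistic
#' about the pooled estimate (no inflation with a single instrument).
#'
#' @param h a `harmonized_set` with at least one variant.
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with method `ivw_canonical`.
#' @export
mr_ivw <- function(h, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  J <- n_snp(h)
  if (J == 0) stop("no instruments", call. = FALSE)
  w <- .ivw_weights(h)
  theta <- h$beta_y / h$beta_x
  est <- sum(w * theta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (variance_model == "multiplicative_random" && J > 1) {
    q <- sum(w * (theta - est)^2)
    se <- se * max(1, sqrt(q / (J - 1)))
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("ivw_canonical", J, est, se, p)
}

# Build the outcome covariance Omega_jk = se_y_j se_y_k rho_jk for the
# variants of h, in h's order, with optional ridge regularization
# Omega + eps * diag(Omega). Errors when the condition number stays above
# 1e10 after regularization (near-collinear instruments).
.omega <- function(h, ld, ridge = 0) {
  missing <- setdiff(h$rsids, rownames(ld))
  if (length(missing) > 0) {
    stop("LD matrix does not cover variant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rho <- ld[h$rsids, h$rsids, drop = FALSE]
  omega <- outer(h$se_y, h$se_y) * rho
  if (ridge > 0) omega <- omega + ridge * diag(diag(omega), nrow(omega))
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    stop("instrument covariance is singular or ill-conditioned ",
         "(condition number > 1e10); increase the ridge or drop ",
         "near-collinear instruments", call. = FALSE)
  }
  omega
}

#' Inverse-variance-weighted estimate over correlated instruments
#'
#' Generalized least squares through the origin under the outcome
#' covariance \eqn{\Omega_{jk} = SE_{Yj} SE_{Yk} \rho_{jk}} built from the
#' signed LD correlations: \eqn{\hat\theta = (\beta_X' \Omega^{-1}
#' \beta_X)^{-1} \beta_X' \Omega^{-1} \beta_Y}. Lets all variants of a
#' gene region contribute while correcting for their correlation. Reduces
#' exactly to [mr_ivw()] under an identity LD matrix.
#'
#' @param h a `harmonized_set`.
#' @param ld signed LD correlation matrix covering `h`'s variants.
#' @param variance_model as in [mr_ivw()]; the random-effects inflation
#'   uses the generalized residual sum of squares.
#' @param ridge optional ridge fraction added to the diagonal of
#'   \eqn{\Omega} (default 0).
#' @return an `mr_estimate` with method `ivw_correlated`.
#' @export
mr_ivw_correlated <- function(h, ld,
                              variance_model = c("multiplicative_random",
                                                 "fixed"),
                              ridge = 0) {
  variance_model <- match.arg(variance_model)
  J <- n_snp(h)
  if (J == 0) stop("no instruments", call. = FALSE)
  omega <- .omega(h, ld, ridge)
  oi_bx <- solve(omega, h$beta_x)
  prec <- sum(h$beta_x * oi_bx)
  est <- sum(oi_bx * h$beta_y) / prec
  se <- sqrt(1 / prec)
  resid <- h$beta_y - est * h$beta_x
  q_gls <- sum(resid * solve(omega, resid))
  if (variance_model == "multiplicative_random" && J > 1) {
    se <- se * max(1, sqrt(q_gls / (J - 1)))
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("ivw_correlated", J, est, se, p)
}

# Orient every variant so the exposure effect is positive (negate both
# betas where needed). Wald ratios, and hence all estimators, are
# invariant; Egger's intercept is only meaningful in this orientation.
.orient_positive <- function(h) {
  flip <- h$beta_x < 0
  h$beta_x[flip] <- -h$beta_x[flip]
  h$beta_y[flip] <- -h$beta_y[flip]
  h
}

#' MR-Egger regression over independent instruments
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept (weights \eqn{1/SE_{Yj}^2}), after orienting every
#' variant to a positive exposure effect. The slope is a causal estimate
#' robust to directional pleiotropy under the InSIDE assumption; a nonzero
#' intercept indicates directional horizontal pleiotropy. Inference is
#' t-based with J - 2 degrees of freedom; the multiplicative
#' random-effects model inflates both standard errors by
#' \eqn{\max(1, \sqrt{RSS_w/(J-2)})}.
#'
#' @param h a `harmonized_set` with at least three variants.
#' @param variance_model as in [mr_ivw()].
#' @return an `mr_estimate` with method `egger_canonical` and the
#'   intercept triple filled in.
#' @export
mr_egger <- function(h, variance_model = c("multiplicative_random",
                                           "fixed")) {
  variance_model <- match.arg(variance_model)
  J <- n_snp(h)
  if (J < 3) stop("insufficient instruments for Egger (need >= 3)",
                  call. = FALSE)
  h <- .orient_positive(h)
  w <- 1 / h$se_y^2
  X <- cbind(1, h$beta_x)
  xtwx <- crossprod(X, X * w)
  coefs <- drop(solve(xtwx, crossprod(X, w * h$beta_y)))
  cov_u <- solve(xtwx)
  resid <- h$beta_y - drop(X %*% coefs)
  rss_w <- sum(w * resid^2)
  scale2 <- if (variance_model == "multiplicative_random") {
    max(1, rss_w / (J - 2))
  } else 1
  ses <- unname(sqrt(diag(cov_u) * scale2))
  tstat <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tstat), df = J - 2)
  mr_estimate("egger_canonical", J, coefs[2], ses[2], pvals[2],
              ci_mult = stats::qt(0.975, df = J - 2),
              intercept = coefs[1], intercept_se = ses[1],
              intercept_p = pvals[1])
}

#' MR-Egger regression over correlated instruments
#'
#' Generalized least squares with intercept under the same outcome
#' covariance \eqn{\Omega} as [mr_ivw_correlated()], after the positive
#' exposure orientation. Reduces exactly to [mr_egger()] under identity
#' LD. Inference is t-based with J - 2 degrees of freedom.
#'
#' @inheritParams mr_ivw_correlated
#' @return an `mr_estimate` with method `egger_correlated`.
#' @export
mr_egger_correlated <- function(h, ld,
                                variance_model = c("multiplicative_random",
                                                   "fixed"),
                                ridge = 0) {
  variance_model <- match.arg(variance_model)
  J <- n_snp(h)
  if (J < 3) stop("insufficient instruments for Egger (need >= 3)",
                  call. = FALSE)
  # orienting a variant negates its estimation-error correlations with
  # the others: Omega -> S Omega S with S the sign matrix
  s <- ifelse(h$beta_x < 0, -1, 1)
  omega <- outer(s, s) * .omega(h, ld, ridge)
  h <- .orient_positive(h)
  X <- cbind(1, h$beta_x)
  oi_X <- solve(omega, X)
  xtox <- crossprod(X, oi_X)
  coefs <- drop(solve(xtox, crossprod(oi_X, h$beta_y)))
  cov_u <- solve(xtox)
  resid <- h$beta_y - drop(X %*% coefs)
  rss_gls <- sum(resid * solve(omega, resid))
  scale2 <- if (variance_model == "multiplicative_random") {
    max(1, rss_gls / (J - 2))
  } else 1
  ses <- unname(sqrt(diag(cov_u) * scale2))
  tstat <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tstat), df = J - 2)
  mr_estimate("egger_correlated", J, coefs[2], ses[2], pvals[2],
              ci_mult = stats::qt(0.975, df = J - 2),
              intercept = coefs[1], intercept_se = ses[1],
              intercept_p = pvals[1])
}

# Weighted median of ratio estimates: order ratios ascending, form the
# cumulative weight mass s_k = sum_{i<=k} w'_(i) - w'_(k)/2 and linearly
# interpolate where s crosses one half.
.weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wp <- w[ord] / sum(w)
  s <- cumsum(wp) - wp / 2
  if (s[1] >= 0.5) return(th[1])
  if (s[length(s)] <= 0.5) return(th[length(th)])
  k <- max(which(s < 0.5))
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median estimate
#'
#' The 0.5-quantile of the weighted distribution of Wald ratios, using the
#' IVW weights \eqn{w_j = \beta_{Xj}^2/SE_{Yj}^2}; consistent when
#' instruments carrying at least half the weight are valid. The standard
#' error comes from a parametric bootstrap: both effect vectors are
#' resampled from normals centered on the observed effects with their
#' reported SEs, the estimate recomputed, and the SD over replicates
#' taken. The p-value and 95% CI use the normal approximation.
#'
#' @param h a `harmonized_set` with at least three variants.
#' @param n_boot bootstrap replicate count (default 1000).
#' @param seed RNG seed, required: the bootstrap never touches the global
#'   RNG state silently.
#' @return an `mr_estimate` with method `weighted_median`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  J <- n_snp(h)
  if (J < 3) stop("insufficient instruments for the weighted median ",
                  "(need >= 3)", call. = FALSE)
  if (missing(seed)) stop("seed is required for the bootstrap", call. = FALSE)
  theta <- h$beta_y / h$beta_x
  est <- .weighted_median_point(theta, .ivw_weights(h))
  boot <- local({
    set.seed(seed)
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, h$beta_x, h$se_x)
      by <- stats::rnorm(J, h$beta_y, h$se_y)
      bx[bx == 0] <- .Machine$double.eps
      .weighted_median_point(by / bx, bx^2 / h$se_y^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("weighted_median", J, est, se, p)
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' @param log_or causal log-odds estimate.
#' @param se its standard error (> 0).
#' @return list with `or_value`, `ci_low`, `ci_high` (95% normal interval
#'   exponentiated).
#' @export
to_odds_ratio <- function(log_or, se) {
  stopifnot(se > 0)
  z <- 1.96
  list(or_value = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se))
}
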