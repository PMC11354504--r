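# The five estimators against brute-force oracles, their reduction and
# invariance properties, and the odds-ratio arithmetic.

test_that("Wald ratios follow the elementwise definition", {
  h <- harmonized_set(c("a", "b"), beta_x = c(0.5, -0.4),
                      se_x = c(0.02, 0.02), beta_y = c(0.5, 0),
                      se_y = c(0.05, 0.06))
  r <- ratio_estimates(h)
  expect_equal(r$theta, c(1, 0))
  expect_equal(r$se, c(0.05 / 0.5, 0.06 / 0.4))
  h0 <- harmonized_set("a", 0, 0.02, 0.1, 0.05)
  expect_error(ratio_estimates(h0), "zero exposure effect")
  # joint negation leaves ratios unchanged
  h2 <- h
  h2$beta_x <- -h$beta_x
  h2$beta_y <- -h$beta_y
  expect_equal(ratio_estimates(h2)$theta, r$theta)
})

test_that("IVW handles the single-variant and equal-weight cases exactly", {
  h1 <- harmonized_set("a", 0.5, 0.02, 0.1, 0.05)
  fit <- mr_ivw(h1)
  expect_equal(fit$log_or, 0.2)
  expect_equal(fit$se, 0.1)
  h2 <- harmonized_set(c("a", "b"), c(0.5, 0.5), c(0.02, 0.02),
                       c(0.1, 0.2), c(0.05, 0.05))
  expect_equal(mr_ivw(h2, "fixed")$log_or, 0.3)
  expect_error(mr_ivw(harmonized_set(character(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0))),
               "no instruments")
})

test_that("IVW matches the through-origin WLS oracle to 1e-10", {
  for (seed in 1:50) {
    h <- random_harmonized(10, seed)
    o <- oracle_ivw(h$beta_x, h$beta_y, h$se_y)
    fit <- mr_ivw(h, "fixed")
    expect_equal(fit$log_or, o$theta, tolerance = 1e-10)
    expect_equal(fit$se, o$se, tolerance = 1e-10)
  }
})

test_that("Egger matches the normal-equations oracle to 1e-10", {
  for (seed in 1:50) {
    h <- random_harmonized(10, seed + 100)
    o <- oracle_egger(h$beta_x, h$beta_y, h$se_y)
    fit <- mr_egger(h, "fixed")
    expect_equal(fit$log_or, o$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(fit$se, o$se_slope, tolerance = 1e-10)
    expect_equal(fit$intercept_se, o$se_intercept, tolerance = 1e-10)
  }
})

test_that("correlated forms match the Cholesky-whitening GLS oracle", {
  for (seed in 1:50) {
    set.seed(seed + 200)
    J <- 6
    h <- random_harmonized(J, seed + 200)
    rho <- 0.5
    ld <- matrix(rho, J, J); diag(ld) <- 1
    dimnames(ld) <- list(h$rsids, h$rsids)
    omega <- outer(h$se_y, h$se_y) * ld

    o1 <- oracle_gls(matrix(h$beta_x, ncol = 1), h$beta_y, omega)
    fit1 <- mr_ivw_correlated(h, ld, "fixed")
    expect_equal(fit1$log_or, unname(o1$coefs[1]), tolerance = 1e-10)
    expect_equal(fit1$se, o1$se[1], tolerance = 1e-10)

    s <- sign(h$beta_x)
    o2 <- oracle_gls(cbind(1, h$beta_x * s), h$beta_y * s,
                     diag(s) %*% omega %*% diag(s))
    fit2 <- mr_egger_correlated(h, ld, "fixed")
    expect_equal(fit2$log_or, unname(o2$coefs[2]), tolerance = 1e-10)
    expect_equal(fit2$intercept, unname(o2$coefs[1]), tolerance = 1e-10)
    expect_equal(fit2$se, o2$se[2], tolerance = 1e-10)
  }
})

test_that("correlated estimators reduce exactly to canonical under identity LD", {
  for (seed in 1:10) {
    h <- random_harmonized(8, seed + 300)
    ld <- identity_ld(h$rsids)
    ivw_c <- mr_ivw_correlated(h, ld, "fixed")
    ivw <- mr_ivw(h, "fixed")
    expect_equal(ivw_c$log_or, ivw$log_or, tolerance = 1e-12)
    expect_equal(ivw_c$se, ivw$se, tolerance = 1e-12)
    eg_c <- mr_egger_correlated(h, ld, "fixed")
    eg <- mr_egger(h, "fixed")
    expect_equal(eg_c$log_or, eg$log_or, tolerance = 1e-12)
    expect_equal(eg_c$intercept, eg$intercept, tolerance = 1e-12)
    expect_equal(eg_c$se, eg$se, tolerance = 1e-12)
  }
})

test_that("a singular covariance without regularization raises the guard", {
  h <- random_harmonized(4, 1)
  ld <- matrix(1, 4, 4)
  dimnames(ld) <- list(h$rsids, h$rsids)
  expect_error(mr_ivw_correlated(h, ld), "condition|singular")
  expect_error(mr_egger_correlated(h, ld), "condition|singular")
})

test_that("Egger is invariant to joint negation and exact on collinear data", {
  h <- random_harmonized(8, 5)
  fit <- mr_egger(h, "fixed")
  h2 <- h
  flip <- c(1, 4, 6)
  h2$beta_x[flip] <- -h2$beta_x[flip]
  h2$beta_y[flip] <- -h2$beta_y[flip]
  fit2 <- mr_egger(h2, "fixed")
  expect_equal(fit2$log_or, fit$log_or, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-12)
  # points exactly through the origin: zero intercept, slope = ratio
  h3 <- harmonized_set(letters[1:4], c(0.2, 0.3, 0.5, 0.7), 0.01,
                       0.4 * c(0.2, 0.3, 0.5, 0.7),
                       c(0.03, 0.04, 0.05, 0.06))
  fit3 <- mr_egger(h3)
  expect_equal(fit3$intercept, 0, tolerance = 1e-14)
  expect_equal(fit3$log_or, 0.4, tolerance = 1e-14)
  expect_error(mr_egger(harmonized_set(c("a", "b"), c(1, 1), c(1, 1),
                                       c(1, 1), c(1, 1))),
               "insufficient")
})

test_that("weighted median reproduces order-statistic and dominant-weight cases", {
  h <- harmonized_set(letters[1:3], c(1, 1, 1), 0.01, c(1, 2, 3),
                      c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$log_or, 2)
  # middle variant carrying half the weight: estimate equals its ratio
  w_target <- c(0.25, 0.5, 0.25)
  se_y <- 1 / sqrt(w_target)     # beta_x = 1 so w = 1/se_y^2
  h2 <- harmonized_set(letters[1:3], c(1, 1, 1), 0.01, c(1, 5, 9), se_y)
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$log_or, 5)
  expect_error(mr_weighted_median(h, n_boot = 10),
               "seed")
})

test_that("weighted median matches the exhaustive crossing-scan oracle", {
  for (seed in 1:50) {
    h <- random_harmonized(5, seed + 400)
    fit <- mr_weighted_median(h, n_boot = 20, seed = seed)
    o <- oracle_weighted_median(h$beta_y / h$beta_x,
                                h$beta_x^2 / h$se_y^2)
    expect_equal(fit$log_or, o, tolerance = 1e-12)
  }
})

test_that("the bootstrap SE is seed-deterministic", {
  h <- random_harmonized(6, 9)
  a <- mr_weighted_median(h, n_boot = 200, seed = 77)
  b <- mr_weighted_median(h, n_boot = 200, seed = 77)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 78)
  expect_false(identical(a$se, c_$se))
  expect_lt(abs(a$se - c_$se) / a$se, 0.5)
})

test_that("all estimators return c exactly when every ratio equals c", {
  cc <- 0.37
  bx <- c(0.2, 0.35, 0.5, 0.65)
  h <- harmonized_set(letters[1:4], bx, 0.01, cc * bx,
                      c(0.03, 0.05, 0.04, 0.06))
  ld <- identity_ld(h$rsids)
  expect_equal(mr_ivw(h)$log_or, cc, tolerance = 1e-13)
  expect_equal(mr_ivw_correlated(h, ld)$log_or, cc, tolerance = 1e-13)
  expect_equal(mr_egger(h)$log_or, cc, tolerance = 1e-12)
  expect_equal(mr_egger_correlated(h, ld)$log_or, cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h, n_boot = 20, seed = 1)$log_or, cc,
               tolerance = 1e-13)
  expect_equal(cochran_q(h)$q_stat, 0, tolerance = 1e-18)
})

test_that("the through-origin WLS identity holds on random inputs", {
  for (seed in 1:20) {
    h <- random_harmonized(12, seed + 500)
    w <- h$beta_x^2 / h$se_y^2
    theta <- h$beta_y / h$beta_x
    ratio_form <- sum(w * theta) / sum(w)
    wls_form <- sum(h$beta_x * h$beta_y / h$se_y^2) /
      sum(h$beta_x^2 / h$se_y^2)
    expect_equal(mr_ivw(h, "fixed")$log_or, ratio_form, tolerance = 1e-12)
    expect_equal(ratio_form, wls_form, tolerance = 1e-12)
  }
})

test_that("odds-ratio conversion matches the published-interval arithmetic", {
  o <- to_odds_ratio(0, 0.05)
  expect_equal(o$or_value, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
  # back-solved from the printed 95% interval 0.786-0.967
  o2 <- to_odds_ratio(-0.13699, 0.05287)
  expect_equal(round(o2$or_value, 3), 0.872)
  expect_equal(round(o2$ci_low, 3), 0.786)
  expect_equal(round(o2$ci_high, 3), 0.967)
  ors <- vapply(seq(-1, 1, 0.2),
                function(b) to_odds_ratio(b, 0.1)$or_value, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("estimates keep the OR/CI consistency invariant", {
  for (seed in 1:10) {
    h <- random_harmonized(6, seed + 600)
    for (fit in list(mr_ivw(h), mr_egger(h),
                     mr_weighted_median(h, n_boot = 30, seed = seed))) {
      expect_equal(fit$or_value, exp(fit$log_or))
      expect_lte(fit$ci_low, fit$or_value)
      expect_gte(fit$ci_high, fit$or_value)
    }
  }
})
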