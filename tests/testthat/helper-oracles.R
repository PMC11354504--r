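# Independent brute-force oracles and fixture builders. The oracles share
# no code with the implementation: they solve the defining linear systems
# directly (normal equations written out, Cholesky whitening, exhaustive
# interval scans) so that agreement is evidence, not tautology.

# Random aligned exposure/outcome effects with strong instruments.
random_harmonized <- function(J, seed, theta = 0.2) {
  set.seed(seed)
  bx <- runif(J, 0.1, 0.7) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.02, 0.06)
  sy <- runif(J, 0.02, 0.08)
  by <- theta * bx + rnorm(J, 0, sy)
  harmonized_set(sprintf("rs%d", seq_len(J)), bx, sx, by, sy)
}

# Through-origin weighted least squares by the explicit normal equation:
# theta = sum(w x y) / sum(w x^2), var = 1 / sum(w x^2), w = 1/se_y^2.
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  list(theta = theta, se = sqrt(1 / sum(w * bx^2)))
}

# Weighted regression with intercept via the written-out 2x2 normal
# equations, after orienting exposure effects positive.
oracle_egger <- function(bx, by, sy) {
  s <- sign(bx)
  x <- bx * s
  y <- by * s
  w <- 1 / sy^2
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  a <- (swxx * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  # unscaled covariance of (a, b): inverse of the 2x2 information matrix
  var_a <- swxx / det
  var_b <- sw / det
  list(intercept = a, slope = b, se_intercept = sqrt(var_a),
       se_slope = sqrt(var_b))
}

# GLS by Cholesky whitening: premultiply by inv(t(chol)) and run plain
# (unweighted) least squares on the whitened system.
oracle_gls <- function(X, y, omega) {
  L <- t(chol(omega))
  Xw <- forwardsolve(L, X)
  yw <- forwardsolve(L, y)
  fit <- qr(Xw)
  coefs <- qr.coef(fit, yw)
  cov_u <- chol2inv(qr.R(fit))
  list(coefs = coefs, se = sqrt(diag(cov_u)))
}

# Exhaustive weighted-median: evaluate the cumulative-midpoint curve at
# every order statistic and scan all adjacent intervals for the 0.5
# crossing.
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]
  wp <- w[ord] / sum(w)
  s <- cumsum(wp) - wp / 2
  if (s[1] >= 0.5) return(th[1])
  n <- length(th)
  if (s[n] <= 0.5) return(th[n])
  for (k in seq_len(n - 1)) {
    if (s[k] < 0.5 && s[k + 1] >= 0.5) {
      return(th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k]))
    }
  }
  stop("no crossing found")
}

# Independent greedy clumping: a direct transcription of the rule working
# on index vectors, used to cross-check ld_clump.
oracle_clump <- function(d, ld, r2_thr, window_kb) {
  ord <- order(d$pvalue, d$chrom, d$pos)
  alive <- ord
  kept <- integer(0)
  while (length(alive) > 0) {
    i <- alive[1]
    kept <- c(kept, i)
    alive <- alive[-1]
    if (length(alive) == 0) break
    drop <- vapply(alive, function(j) {
      if (d$chrom[j] != d$chrom[i]) return(FALSE)
      if (abs(d$pos[j] - d$pos[i]) >= window_kb * 1000) return(FALSE)
      r <- if (d$rsid[i] %in% rownames(ld) && d$rsid[j] %in% rownames(ld)) {
        ld[d$rsid[i], d$rsid[j]]
      } else 0
      r^2 >= r2_thr
    }, logical(1))
    alive <- alive[!drop]
  }
  sort(d$rsid[kept])
}

# Identity LD matrix over given rsids.
identity_ld <- function(rsids) {
  m <- diag(length(rsids))
  dimnames(m) <- list(rsids, rsids)
  m
}
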