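# Independent oracles used across the test files.

# Posterior first/second moments at a fitted prior by adaptive quadrature of
# the exact posterior integrals (atom at zero handled analytically).
quad_posterior <- function(g, x, s) {
  lik <- function(th) stats::dnorm(x, th, s)
  if (g$family == "point_normal") {
    atom <- g$pi0
    cont <- function(th) (1 - g$pi0) * stats::dnorm(th, 0, sqrt(g$a))
  } else if (g$family == "scale_mix_normal") {
    atom <- g$weights[1]
    pos <- which(g$grid > 0)
    cont <- function(th) {
      rowSums(vapply(pos, function(m) {
        g$weights[m] * stats::dnorm(th, 0, g$grid[m])
      }, numeric(length(th))))
    }
  } else if (g$family == "normal") {
    atom <- 0
    cont <- function(th) stats::dnorm(th, 0, sqrt(g$a))
  } else {
    return(list(mean = 0, mean2 = 0))
  }
  intg <- function(f) {
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  }
  den <- atom * lik(0) + intg(function(t) cont(t) * lik(t))
  m1 <- intg(function(t) t * cont(t) * lik(t)) / den
  m2 <- intg(function(t) t^2 * cont(t) * lik(t)) / den
  list(mean = m1, mean2 = m2)
}

# Grid-search oracle for the point-normal marginal likelihood.
pn_grid_loglik <- function(x, s, n_pi = 200, n_a = 200) {
  l0 <- stats::dnorm(x, 0, s, log = TRUE)
  a0 <- max(mean(x^2 - s^2), min(s)^2)
  la_grid <- seq(log(a0) - 8, log(a0) + 4, length.out = n_a)
  pi_grid <- seq(1e-4, 1 - 1e-4, length.out = n_pi)
  best <- -Inf
  for (la in la_grid) {
    l1 <- stats::dnorm(x, 0, sqrt(s^2 + exp(la)), log = TRUE)
    for (p0 in pi_grid) {
      aa <- log(p0) + l0
      bb <- log1p(-p0) + l1
      m <- pmax(aa, bb)
      ll <- sum(m + log(exp(aa - m) + exp(bb - m)))
      if (ll > best) best <- ll
    }
  }
  best
}

# Explicit-loop weighted regression oracle for one side of the rank-1 update.
loop_regression <- function(Yv, mask, tau, v, w, side) {
  n <- nrow(Yv); p <- ncol(Yv)
  if (side == "loading") {
    est <- se <- numeric(n)
    for (i in seq_len(n)) {
      num <- den <- 0
      for (j in seq_len(p)) {
        if (mask[i, j]) {
          num <- num + tau[i, j] * Yv[i, j] * v[j]
          den <- den + tau[i, j] * w[j]
        }
      }
      est[i] <- if (den > 0) num / den else 0
      se[i] <- if (den > 0) den^-0.5 else Inf
    }
  } else {
    est <- se <- numeric(p)
    for (j in seq_len(p)) {
      num <- den <- 0
      for (i in seq_len(n)) {
        if (mask[i, j]) {
          num <- num + tau[i, j] * Yv[i, j] * v[i]
          den <- den + tau[i, j] * w[i]
        }
      }
      est[j] <- if (den > 0) num / den else 0
      se[j] <- if (den > 0) den^-0.5 else Inf
    }
  }
  list(est = est, se = se)
}

# random normal-means dataset with a sparse mean vector and mixed noise
random_nm <- function(seed, m = 50, with_inf = FALSE) {
  set.seed(seed)
  s <- stats::runif(m, 0.5, 2)
  if (with_inf) s[sample.int(m, max(1, m %/% 10))] <- Inf
  theta <- ifelse(stats::runif(m) < 0.5, 0, stats::rnorm(m, 0, 2))
  x <- theta + ifelse(is.finite(s), stats::rnorm(m, 0, pmin(s, 1e3)), 0)
  x[!is.finite(s)] <- stats::rnorm(sum(!is.finite(s)))
  nm_data(x, s)
}

# checks that a trace is non-decreasing within relative tolerance
expect_monotone_trace <- function(trace, rel_tol = 1e-8) {
  if (length(trace) < 2) return(invisible(TRUE))
  prev <- trace[-length(trace)]
  expect_true(all(diff(trace) >= -rel_tol * abs(prev)))
}
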