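# Empirical Bayes normal means (EBNM) solvers.
#
# Model: x_j | theta_j ~ N(theta_j, s_j^2), theta_1..theta_m ~iid g, with g
# restricted to a prior family. Each solver estimates g by maximizing the
# marginal likelihood and returns the posterior first and second moments of
# theta under the fitted prior. Coordinates with s_j = +Inf carry no
# information: they contribute 0 to the log likelihood and receive the prior
# moments. All supported families are symmetric and unimodal at zero, so
# posterior means are shrunk towards zero and never change sign.

# ---- small numeric utilities -------------------------------------------------

# log(exp(a) + exp(b)), elementwise, safe for -Inf entries
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

# row-wise log-sum-exp of a matrix, safe for -Inf rows
row_logsumexp <- function(lm) {
  m <- lm[cbind(seq_len(nrow(lm)), max.col(lm, ties.method = "first"))]
  out <- m + log(rowSums(exp(lm - m)))
  out[!is.finite(m)] <- -Inf
  out
}

# ---- domain types ------------------------------------------------------------

#' Normal-means data
#'
#' Bundle of observations and their standard errors for the normal-means
#' model `x_j ~ N(theta_j, s_j^2)`.
#'
#' @param x numeric vector of observations; must be finite.
#' @param s numeric vector of standard errors, same length as `x`; entries
#'   must be strictly positive and may be `+Inf` to flag coordinates that
#'   carry no information (their posterior equals the prior).
#' @return An object of class `"nm_data"`.
#' @export
nm_data <- function(x, s) {
  x <- as.numeric(x)
  s <- as.numeric(s)
  if (length(x) != length(s)) {
    stop("`x` and `s` must have the same length (", length(x), " vs ",
         length(s), ")")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite")
  if (anyNA(s) || any(s <= 0)) stop("`s` must be positive (Inf is allowed)")
  structure(list(x = x, s = s), class = "nm_data")
}

as_nm_data <- function(data) {
  if (inherits(data, "nm_data")) data else stop("expected an `nm_data` object")
}

#' Prior specifications
#'
#' Constructors for the prior families supported by the normal-means solvers:
#' a point mass at zero, a zero-mean normal, a point-normal ("spike and
#' slab") mixture, and a scale mixture of zero-centered normals on a fixed
#' grid of standard deviations.
#'
#' @param a slab variance (nonnegative).
#' @param pi0 mixture weight on the point mass at zero, in `[0, 1]`.
#' @param grid vector of component standard deviations, strictly increasing
#'   with first element 0.
#' @param weights simplex vector of mixture weights, same length as `grid`.
#' @return An object of class `"prior_spec"`.
#' @export
prior_point_mass <- function() {
  structure(list(family = "point_mass_zero"), class = "prior_spec")
}

#' @rdname prior_point_mass
#' @export
prior_normal <- function(a) {
  if (length(a) != 1 || !is.finite(a) || a < 0) stop("`a` must be a nonnegative scalar")
  structure(list(family = "normal", a = a), class = "prior_spec")
}

#' @rdname prior_point_mass
#' @export
prior_point_normal <- function(pi0, a) {
  if (length(pi0) != 1 || is.na(pi0) || pi0 < 0 || pi0 > 1) {
    stop("`pi0` must be in [0, 1]")
  }
  if (length(a) != 1 || !is.finite(a) || a < 0) stop("`a` must be a nonnegative scalar")
  structure(list(family = "point_normal", pi0 = pi0, a = a),
            class = "prior_spec")
}

#' @rdname prior_point_mass
#' @export
prior_scale_mix_normal <- function(grid, weights) {
  grid <- as.numeric(grid)
  weights <- as.numeric(weights)
  if (length(grid) == 0) stop("`grid` must be non-empty")
  if (grid[1] != 0) stop("`grid` must include sigma = 0 as its first element")
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  if (length(weights) != length(grid)) stop("`weights` must match `grid` in length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10) {
    stop("`weights` must be nonnegative and sum to 1")
  }
  structure(list(family = "scale_mix_normal", grid = grid, weights = weights),
            class = "prior_spec")
}

# prior mean is 0 for every supported family; second moment varies
prior_second_moment <- function(g) {
  switch(g$family,
    point_mass_zero  = 0,
    normal           = g$a,
    point_normal     = (1 - g$pi0) * g$a,
    scale_mix_normal = sum(g$weights * g$grid^2),
    stop("unknown prior family: ", g$family)
  )
}

# is the prior (numerically) a point mass at zero?
prior_is_delta0 <- function(g) {
  switch(g$family,
    point_mass_zero  = TRUE,
    normal           = g$a == 0,
    point_normal     = g$pi0 >= 1 || g$a == 0,
    scale_mix_normal = sum(g$weights[g$grid > 0]) < 1e-12,
    FALSE
  )
}

new_nm_fit <- function(g_hat, loglik, post_mean, post_mean2) {
  structure(list(g_hat = g_hat, loglik = loglik,
                 post_mean = as.numeric(post_mean),
                 post_mean2 = as.numeric(post_mean2)),
            class = "nm_fit")
}

# ---- marginal likelihood -----------------------------------------------------

# per-coordinate log marginal density log integral N(x; theta, s^2) g(dtheta);
# for all supported families this is a finite mixture of zero-mean normals
# with variances s^2 + sigma^2. Only called with finite s.
nm_log_density <- function(g, x, s) {
  switch(g$family,
    point_mass_zero = stats::dnorm(x, 0, s, log = TRUE),
    normal = stats::dnorm(x, 0, sqrt(s^2 + g$a), log = TRUE),
    point_normal = {
      la <- log(g$pi0) + stats::dnorm(x, 0, s, log = TRUE)
      lb <- log1p(-g$pi0) + stats::dnorm(x, 0, sqrt(s^2 + g$a), log = TRUE)
      logaddexp(la, lb)
    },
    scale_mix_normal = {
      lm <- vapply(seq_along(g$grid), function(m) {
        log(g$weights[m]) + stats::dnorm(x, 0, sqrt(s^2 + g$grid[m]^2), log = TRUE)
      }, numeric(length(x)))
      lm <- matrix(lm, nrow = length(x))
      row_logsumexp(lm)
    },
    stop("unknown prior family: ", g$family)
  )
}

#' Marginal log-likelihood of normal-means data under a prior
#'
#' Computes `sum_j log integral N(x_j; theta, s_j^2) g(dtheta)`. Coordinates
#' with infinite standard error contribute 0.
#'
#' @param g a [prior_spec][prior_point_mass] object.
#' @param data an [nm_data] object.
#' @return scalar log-likelihood.
#' @export
nm_marginal_loglik <- function(g, data) {
  data <- as_nm_data(data)
  fin <- is.finite(data$s)
  if (!any(fin)) return(0)
  sum(nm_log_density(g, data$x[fin], data$s[fin]))
}

# ---- family-specific solvers -------------------------------------------------

#' Solve the normal-means problem with a point mass at zero
#'
#' The degenerate prior `delta_0`: posterior moments are identically zero and
#' the log-likelihood is that of pure noise.
#'
#' @param data an [nm_data] object.
#' @return An object of class `"nm_fit"` with elements `g_hat`, `loglik`,
#'   `post_mean`, `post_mean2`.
#' @export
fit_point_mass <- function(data) {
  data <- as_nm_data(data)
  m <- length(data$x)
  g <- prior_point_mass()
  new_nm_fit(g, nm_marginal_loglik(g, data), rep(0, m), rep(0, m))
}

#' Solve the normal-means problem with a zero-mean normal prior
#'
#' Estimates the prior variance `a >= 0` by marginal maximum likelihood
#' (one-dimensional optimization over `log a`, with the boundary `a = 0`
#' checked explicitly), then computes the conjugate posterior moments.
#'
#' @inheritParams fit_point_mass
#' @return An `"nm_fit"` object.
#' @export
fit_normal <- function(data) {
  data <- as_nm_data(data)
  fin <- is.finite(data$s)
  if (!any(fin)) stop("no informative observations: all standard errors are infinite")
  xf <- data$x[fin]
  sf <- data$s[fin]
  smin2 <- min(sf)^2

  obj <- function(loga) sum(stats::dnorm(xf, 0, sqrt(sf^2 + exp(loga)), log = TRUE))
  hi <- log(4 * max(max(xf^2), smin2))
  lo <- log(smin2) - 30
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)
  a_hat <- exp(opt$maximum)
  ll_a <- opt$objective
  ll_0 <- sum(stats::dnorm(xf, 0, sf, log = TRUE))
  if (ll_0 >= ll_a) {
    g <- prior_normal(0)
    return(new_nm_fit(g, ll_0, rep(0, length(data$x)), rep(0, length(data$x))))
  }
  g <- prior_normal(a_hat)
  r <- a_hat / (a_hat + data$s^2)      # 0 where s = Inf
  pm <- data$x * r
  pv <- a_hat * (1 - r)                # prior variance a where s = Inf
  new_nm_fit(g, ll_a, pm, pm^2 + pv)
}

# posterior moments under a point-normal prior; handles s = Inf and the
# delta_0 boundary (a = 0 or pi0 = 1) where Bayes weights would be 0/0
pn_posterior <- function(g, data) {
  x <- data$x
  s <- data$s
  m <- length(x)
  if (g$pi0 >= 1 || g$a == 0) {
    return(list(mean = rep(0, m), mean2 = rep(0, m)))
  }
  r <- g$a / (g$a + s^2)
  mu <- x * r
  v <- g$a * (1 - r)
  la <- log(g$pi0) + stats::dnorm(x, 0, s, log = TRUE)
  lb <- log1p(-g$pi0) + stats::dnorm(x, 0, sqrt(s^2 + g$a), log = TRUE)
  w <- exp(lb - logaddexp(la, lb))     # posterior slab weight
  inf <- !is.finite(s)
  if (any(inf)) {                      # no data: posterior equals prior
    w[inf] <- 1 - g$pi0
    mu[inf] <- 0
    v[inf] <- g$a
  }
  list(mean = w * mu, mean2 = w * (mu^2 + v))
}

#' Solve the normal-means problem with a point-normal prior
#'
#' Fits the "spike and slab" prior `pi0 delta_0 + (1 - pi0) N(0, a)` by
#' marginal maximum likelihood. The likelihood is non-convex in `(pi0, a)`,
#' so a quasi-Newton search on `(logit pi0, log a)` is run from four
#' deterministic starts (`pi0` in 0.1, 0.5, 0.9, 0.99; `a` at a
#' method-of-moments value) and the best optimum is kept; the boundary
#' `pi0 = 1` (a point mass) is checked explicitly.
#'
#' @inheritParams fit_point_mass
#' @return An `"nm_fit"` object.
#' @export
fit_point_normal <- function(data) {
  data <- as_nm_data(data)
  fin <- is.finite(data$s)
  m <- length(data$x)
  if (!any(fin)) {
    g <- prior_point_normal(1, 0)
    return(new_nm_fit(g, 0, rep(0, m), rep(0, m)))
  }
  xf <- data$x[fin]
  sf <- data$s[fin]
  l0 <- stats::dnorm(xf, 0, sf, log = TRUE)

  nll <- function(par) {
    pi0 <- stats::plogis(par[1])
    a <- exp(par[2])
    la <- log(pi0) + l0
    lb <- log1p(-pi0) + stats::dnorm(xf, 0, sqrt(sf^2 + a), log = TRUE)
    -sum(logaddexp(la, lb))
  }
  # analytic gradient in (logit pi0, log a); w below is the per-coordinate
  # posterior slab weight
  ngr <- function(par) {
    pi0 <- stats::plogis(par[1])
    a <- exp(par[2])
    v <- sf^2 + a
    l1 <- stats::dnorm(xf, 0, sqrt(v), log = TRUE)
    la <- log(pi0) + l0
    lb <- log1p(-pi0) + l1
    lden <- logaddexp(la, lb)
    w <- exp(lb - lden)
    d_pi0 <- sum(exp(l0 - lden) - exp(l1 - lden))        # d loglik / d pi0
    d_a <- sum(w * (xf^2 / v - 1) / (2 * v))             # d loglik / d a
    -c(d_pi0 * pi0 * (1 - pi0), d_a * a)
  }

  a0 <- max(mean(xf^2 - sf^2), min(sf)^2)
  best <- NULL
  for (p0 in c(0.1, 0.5, 0.9, 0.99)) {
    res <- tryCatch(
      stats::optim(c(stats::qlogis(p0), log(a0)), nll, gr = ngr,
                   method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("point-normal optimization failed from all starts")

  pi0 <- stats::plogis(best$par[1])
  a <- exp(best$par[2])
  ll <- -best$value
  ll_pm <- sum(l0)
  if (ll_pm > ll) {                    # boundary: point mass beats the interior
    pi0 <- 1
    a <- 0
    ll <- ll_pm
  }
  g <- prior_point_normal(pi0, a)
  post <- pn_posterior(g, data)
  new_nm_fit(g, ll, post$mean, post$mean2)
}

#' Default grid of component standard deviations for the scale mixture
#'
#' Geometric grid with ratio `sqrt(2)` from `min(s)/10` up to
#' `2 * sqrt(max(x^2 - s^2, min(s)^2))`, preceded by `sigma = 0`; the
#' adaptive-shrinkage convention, dense enough that the grid is not a tuning
#' burden.
#'
#' @param x,s observations and standard errors (finite entries only).
#' @return numeric vector of standard deviations starting at 0.
#' @export
default_smn_grid <- function(x, s) {
  smin <- min(s)
  lo <- smin / 10
  hi <- 2 * sqrt(max(max(x^2 - s^2), smin^2))
  if (!is.finite(hi) || hi <= lo) return(c(0, lo))
  nstep <- ceiling(log(hi / lo) / log(sqrt(2)))
  c(0, lo * sqrt(2)^(0:nstep))
}

#' Solve the normal-means problem with a scale mixture of normals
#'
#' The prior is `sum_m pi_m N(0, sigma_m^2)` on a fixed grid of standard
#' deviations including `sigma = 0`; only the weights are estimated. The
#' marginal log-likelihood is concave in the weights, so EM converges to the
#' global optimum; all single-component (vertex) solutions are also checked
#' so the returned fit always dominates each component alone.
#'
#' @inheritParams fit_point_mass
#' @param grid optional vector of component standard deviations (first
#'   element must be 0, strictly increasing). Defaults to [default_smn_grid].
#' @param maxiter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance (defaults to `1e-9` per observation).
#' @return An `"nm_fit"` object.
#' @export
fit_scale_mix_normal <- function(data, grid = NULL, maxiter = 1000, tol = NULL) {
  data <- as_nm_data(data)
  fin <- is.finite(data$s)
  m <- length(data$x)
  if (is.null(grid)) {
    if (!any(fin)) grid <- c(0, 1) else grid <- default_smn_grid(data$x[fin], data$s[fin])
  }
  grid <- as.numeric(grid)
  if (length(grid) == 0) stop("`grid` must be non-empty")
  if (grid[1] != 0) stop("`grid` must include sigma = 0 as its first element")
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing")
  M <- length(grid)

  if (!any(fin)) {
    g <- prior_scale_mix_normal(grid, c(1, rep(0, M - 1)))
    return(new_nm_fit(g, 0, rep(0, m), rep(0, m)))
  }

  xf <- data$x[fin]
  sf <- data$s[fin]
  mf <- length(xf)
  if (is.null(tol)) tol <- 1e-9 * mf

  # mf x M matrix of component log densities (fixed across EM iterations);
  # shifted per row so the loop below runs entirely in density space with a
  # single matrix-vector product per iteration
  llmat <- vapply(seq_len(M), function(k) {
    stats::dnorm(xf, 0, sqrt(sf^2 + grid[k]^2), log = TRUE)
  }, numeric(mf))
  llmat <- matrix(llmat, nrow = mf)
  shift <- llmat[cbind(seq_len(mf), max.col(llmat, ties.method = "first"))]
  D <- exp(llmat - shift)              # in (0, 1], row maxima equal 1
  shift_sum <- sum(shift)

  w <- rep(1 / M, M)
  ll_old <- -Inf
  for (it in seq_len(maxiter)) {
    num <- pmax(as.numeric(D %*% w), 1e-300)
    ll <- sum(log(num)) + shift_sum
    w <- w * colMeans(D / num)         # combined E and M step
    if (it > 1 && ll - ll_old < tol) break
    ll_old <- ll
  }
  # evaluate at the final weights
  num <- pmax(as.numeric(D %*% w), 1e-300)
  ll <- sum(log(num)) + shift_sum
  # vertex safeguard: a single component can (marginally) beat a nearly
  # converged EM iterate when the optimum sits on the simplex boundary
  comp_ll <- colSums(llmat)
  if (max(comp_ll) > ll) {
    w <- as.numeric(seq_len(M) == which.max(comp_ll))
    num <- pmax(as.numeric(D %*% w), 1e-300)
    ll <- sum(log(num)) + shift_sum
  }
  r <- sweep(D, 2L, w, "*") / num      # posterior responsibilities

  # posterior moments: responsibility-weighted conjugate-normal moments
  shrink <- outer(sf^2, grid^2, function(s2, v) v / (v + s2))  # mf x M
  mu <- xf * shrink
  vv <- sweep(shrink, 2L, grid^2, function(r_, v) v * (1 - r_))
  pm_f <- rowSums(r * mu)
  pm2_f <- rowSums(r * (mu^2 + vv))

  pm <- rep(0, m)
  pm2 <- rep(sum(w * grid^2), m)       # prior moments where s = Inf
  pm[fin] <- pm_f
  pm2[fin] <- pm2_f
  g <- prior_scale_mix_normal(grid, w / sum(w))
  new_nm_fit(g, ll, pm, pm2)
}

#' Solve an empirical-Bayes normal-means problem
#'
#' Dispatches to the family-specific solver and returns the fitted prior, its
#' marginal log-likelihood, and the posterior first and second moments.
#'
#' @inheritParams fit_point_mass
#' @param family one of `"point_normal"`, `"point_mass_zero"`, `"normal"`,
#'   `"scale_mix_normal"`.
#' @param grid optional grid for the scale-mixture family.
#' @return An `"nm_fit"` object.
#' @export
solve_ebnm <- function(data,
                       family = c("point_normal", "point_mass_zero",
                                  "normal", "scale_mix_normal"),
                       grid = NULL) {
  family <- match.arg(family)
  switch(family,
    point_mass_zero  = fit_point_mass(data),
    normal           = fit_normal(data),
    point_normal     = fit_point_normal(data),
    scale_mix_normal = fit_scale_mix_normal(data, grid = grid)
  )
}
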