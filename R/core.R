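# Variational core of the rank-1 coordinate ascent: regression-style
# statistics that reduce each loading/factor update to a normal-means
# problem, expected squared residuals, the precision update, KL terms, and
# the variational objective F (a lower bound on the marginal log-likelihood).

#' Observed data matrix with a missingness mask
#'
#' Wraps an `n x p` numeric matrix together with a logical mask of observed
#' cells. Unobserved cells (`NA` in `values`, or `FALSE` in `mask`) are stored
#' as an arbitrary finite placeholder (zero) and never influence any
#' computation: all downstream sums run over observed cells only, implemented
#' by setting the corresponding precisions to zero.
#'
#' @param values numeric matrix; `NA` entries are treated as missing when
#'   `mask` is not supplied.
#' @param mask optional logical matrix, `TRUE` for observed cells.
#' @return An object of class `"observed_matrix"` with elements `values`
#'   (placeholder 0 at missing cells) and `mask`.
#' @export
observed_matrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("matrix must be at least 1 x 1")
  if (is.null(mask)) {
    mask <- !is.na(values)
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
    if (!identical(dim(mask), dim(values))) stop("`mask` must match `values` in shape")
    if (anyNA(mask)) stop("`mask` must not contain NA")
  }
  values[!mask] <- 0
  if (any(!is.finite(values[mask]))) stop("observed cells must be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, mask = mask), class = "observed_matrix")
}

as_observed <- function(Y) {
  if (inherits(Y, "observed_matrix")) Y else observed_matrix(Y)
}

n_observed <- function(Y) sum(Y$mask)

#' Precision model
#'
#' An `n x p` matrix of residual precisions tau together with a structure
#' label. The precision is exactly zero where the data are missing;
#' within-structure equality (e.g. a single shared value for
#' `"constant"`) is maintained by [update_tau].
#'
#' @param structure one of `"constant"`, `"by_column"`, `"by_row"`,
#'   `"by_entry_fixed"`.
#' @param tau nonnegative `n x p` precision matrix (expanded view).
#' @return An object of class `"precision_model"`.
#' @export
precision_model <- function(structure = c("constant", "by_column", "by_row",
                                          "by_entry_fixed"),
                            tau) {
  structure <- match.arg(structure)
  tau <- as.matrix(tau)
  if (any(tau < 0) || anyNA(tau)) stop("`tau` must be nonnegative")
  base::structure(list(structure = structure, tau = tau),
                  class = "precision_model")
}

tau_matrix <- function(tau) {
  if (inherits(tau, "precision_model")) tau$tau else as.matrix(tau)
}

#' Maximum-likelihood precision update
#'
#' Given expected squared residuals, returns the precision that maximizes the
#' Gaussian likelihood under the requested structure: the reciprocal mean
#' expected squared residual, shared across the whole matrix
#' (`"constant"`), per column, or per row. Blocks with no observed cells get
#' precision 0; blocks with a perfect fit (zero residual) are clamped at
#' `clamp` to keep the objective finite.
#'
#' @param R2 matrix of expected squared residuals (nonnegative on observed
#'   cells).
#' @param mask logical matrix of observed cells.
#' @param structure precision structure; `"by_entry_fixed"` returns `tau`
#'   unchanged.
#' @param tau current precision (required for `"by_entry_fixed"`).
#' @param clamp upper bound on the precision (default `1e8`).
#' @return A [precision_model].
#' @export
update_tau <- function(R2, mask,
                       structure = c("constant", "by_column", "by_row",
                                     "by_entry_fixed"),
                       tau = NULL, clamp = 1e8) {
  structure <- match.arg(structure)
  R2 <- as.matrix(R2)
  mask <- as.matrix(mask)
  if (any(R2[mask] < 0)) stop("expected squared residuals must be nonnegative")

  block_tau <- function(ssum, nobs) {
    ifelse(nobs == 0, 0, ifelse(ssum <= 0, clamp, pmin(nobs / ssum, clamp)))
  }

  taum <- switch(structure,
    constant = {
      t1 <- block_tau(sum(R2[mask]), sum(mask))
      ifelse(mask, t1, 0)
    },
    by_column = {
      ssum <- colSums(R2 * mask)
      nobs <- colSums(mask)
      tj <- block_tau(ssum, nobs)
      ifelse(mask, matrix(tj, nrow(R2), ncol(R2), byrow = TRUE), 0)
    },
    by_row = {
      ssum <- rowSums(R2 * mask)
      nobs <- rowSums(mask)
      ti <- block_tau(ssum, nobs)
      ifelse(mask, matrix(ti, nrow(R2), ncol(R2)), 0)
    },
    by_entry_fixed = {
      if (is.null(tau)) stop("`tau` is required for structure \"by_entry_fixed\"")
      tau_matrix(tau)
    }
  )
  precision_model(structure, taum)
}

#' Regression statistics for one side of a rank-1 update
#'
#' The loading update of the variational coordinate ascent reduces to a
#' normal-means problem whose observations and standard errors are weighted
#' regression statistics of the data on the current factor moments:
#' `est_i = sum_j tau_ij Y_ij v_j / sum_j tau_ij w_j` and
#' `se_i = (sum_j tau_ij w_j)^(-1/2)`, with sums over observed cells only
#' (`v`, `w` are the first and second moments of the fixed side).
#' `side = "factor"` swaps the roles of rows and columns. Rows (or columns)
#' with no information get `est = 0`, `se = +Inf`.
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param tau a [precision_model] or nonnegative matrix.
#' @param v,w first and second moments of the fixed side (length `p` for a
#'   loading update, `n` for a factor update); requires `w >= v^2`.
#' @param side `"loading"` or `"factor"`.
#' @return list with numeric vectors `est` and `se`.
#' @export
regression_stats <- function(Y, tau, v, w, side = c("loading", "factor")) {
  side <- match.arg(side)
  Y <- as_observed(Y)
  tm <- tau_matrix(tau)
  if (any(tm < 0)) stop("`tau` must be nonnegative")
  if (!identical(dim(tm), dim(Y$values))) stop("`tau` must match the data in shape")
  fixed_len <- if (side == "loading") ncol(Y$values) else nrow(Y$values)
  if (length(v) != fixed_len || length(w) != fixed_len) {
    stop("`v` and `w` must have length ", fixed_len, " for side \"", side, "\"")
  }
  if (any(w < v^2 - 1e-8)) stop("`w` must dominate `v^2` elementwise")

  tY <- tm * Y$values
  if (side == "loading") {
    num <- as.numeric(tY %*% v)
    den <- as.numeric(tm %*% w)
  } else {
    num <- as.numeric(crossprod(tY, v))
    den <- as.numeric(crossprod(tm, w))
  }
  est <- ifelse(den > 0, num / den, 0)
  se <- ifelse(den > 0, den^(-0.5), Inf)
  list(est = est, se = se)
}

#' One coordinate-ascent update of a loading or a factor
#'
#' Forms the regression statistics against the fixed side's moments and
#' solves the corresponding normal-means problem. The caller installs the
#' returned posterior moments; because the normal-means solution maximizes
#' the variational objective over this block (for families that include the
#' point mass at zero), the objective cannot decrease.
#'
#' @inheritParams regression_stats
#' @param other list with elements `mean` and `mean2`: the fixed side's first
#'   and second moments.
#' @param family prior family passed to [solve_ebnm].
#' @param grid optional grid for the scale-mixture family.
#' @return An `"nm_fit"` object with two extra fields: `nm` (the normal-means
#'   data the fit was computed from) and `kl` (the block's KL term, see
#'   [kl_term]).
#' @export
update_side <- function(Y, tau, other, side = c("loading", "factor"),
                        family = "point_normal", grid = NULL) {
  side <- match.arg(side)
  rs <- regression_stats(Y, tau, other$mean, other$mean2, side)
  d <- nm_data(rs$est, rs$se)
  if (!any(is.finite(rs$se))) {
    # degenerate block (e.g. the fixed side is identically zero): no
    # information anywhere, collapse to the point mass
    fit <- fit_point_mass(d)
  } else {
    fit <- solve_ebnm(d, family, grid = grid)
  }
  fit$nm <- d
  fit$kl <- kl_term(fit, d)
  fit
}

#' Expected squared residuals under the variational posterior
#'
#' For factor moments `(lbar, l2bar, fbar, f2bar)` per component,
#' `E (Y_ij - sum_k l_ki f_kj)^2 = (Y_ij - sum_k lbar_ki fbar_kj)^2
#'  - sum_k lbar_ki^2 fbar_kj^2 + sum_k l2bar_ki f2bar_kj`,
#' using the full factorization of the variational family (independence
#' across components). With degenerate moments (`l2bar = lbar^2`,
#' `f2bar = fbar^2`) this collapses exactly to the squared residuals. Values
#' at unobserved cells are set to 0.
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param factors list of factor-moment sets, each a list with elements
#'   `l_mean`, `l_mean2` (length `n`) and `f_mean`, `f_mean2` (length `p`).
#' @return `n x p` matrix of expected squared residuals.
#' @export
expected_residual2 <- function(Y, factors = list()) {
  Y <- as_observed(Y)
  n <- nrow(Y$values)
  p <- ncol(Y$values)
  K <- length(factors)
  if (K == 0) {
    R2 <- Y$values^2
  } else {
    L  <- vapply(factors, function(f) as.numeric(f$l_mean),  numeric(n))
    L2 <- vapply(factors, function(f) as.numeric(f$l_mean2), numeric(n))
    FF <- vapply(factors, function(f) as.numeric(f$f_mean),  numeric(p))
    F2 <- vapply(factors, function(f) as.numeric(f$f_mean2), numeric(p))
    L  <- matrix(L, nrow = n);  L2 <- matrix(L2, nrow = n)
    FF <- matrix(FF, nrow = p); F2 <- matrix(F2, nrow = p)
    R2 <- (Y$values - L %*% t(FF))^2 - (L^2) %*% t(FF^2) + L2 %*% t(F2)
  }
  R2[!Y$mask] <- 0
  pmax(R2, 0)
}

#' KL term of a normal-means fit
#'
#' Kullback-Leibler divergence from the variational posterior implied by the
#' fit to the fitted prior, computed through the normal-means identity: at
#' the exact posterior, `loglik = E_q log p(x | theta) - KL(q || g)`, so
#' `KL = sum_j [-log(2 pi s_j^2)/2 - (x_j^2 - 2 x_j mean_j + mean2_j) /
#' (2 s_j^2)] - loglik`. Always nonnegative; coordinates with infinite
#' standard error contribute 0.
#'
#' @param fit an `"nm_fit"` object.
#' @param data the [nm_data] it was fitted to.
#' @return scalar KL divergence.
#' @export
kl_term <- function(fit, data) {
  data <- as_nm_data(data)
  fin <- is.finite(data$s)
  if (!any(fin)) return(0)
  x <- data$x[fin]
  s <- data$s[fin]
  pm <- fit$post_mean[fin]
  pm2 <- fit$post_mean2[fin]
  elp <- sum(-0.5 * log(2 * pi * s^2) - (x^2 - 2 * x * pm + pm2) / (2 * s^2))
  elp - fit$loglik
}

#' Variational objective F
#'
#' The evidence lower bound of the factorization model:
#' `F = sum_obs [log(tau_ij / 2 pi) / 2 - tau_ij R2_ij / 2]
#'  - sum_k KL_l[k] - sum_k KL_f[k]`,
#' with `R2` the expected squared residuals. With `K = 0` this is the
#' Gaussian log-likelihood of the data under a noise-only model.
#'
#' @inheritParams expected_residual2
#' @param tau a [precision_model]; must be strictly positive on observed
#'   cells.
#' @param kl_l,kl_f numeric vectors of per-component KL terms.
#' @return scalar objective value.
#' @export
compute_objective <- function(Y, tau, factors = list(),
                              kl_l = numeric(0), kl_f = numeric(0)) {
  Y <- as_observed(Y)
  tm <- tau_matrix(tau)
  obs <- Y$mask
  if (any(tm[obs] <= 0)) stop("`tau` must be strictly positive on observed cells")
  R2 <- expected_residual2(Y, factors)
  sum(0.5 * log(tm[obs] / (2 * pi)) - 0.5 * tm[obs] * R2[obs]) -
    sum(kl_l) - sum(kl_f)
}
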