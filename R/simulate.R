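# Simulation designs and evaluation metrics: a rank-1 sparse-loading design,
# a rank-3 sparse bi-cluster design, relative RMSE of a low-rank
# reconstruction, held-out RMSE, orthogonal cross-validation masking, and a
# truncated-SVD baseline.

new_sim_truth <- function(Y, L_true, F_true, tau_true, seed, design) {
  structure(list(Y = Y, L_true = L_true, F_true = F_true,
                 tau_true = tau_true, seed = seed, design = design),
            class = "sim_truth")
}

#' True signal matrix of a simulation
#'
#' @param sim a `"sim_truth"` object.
#' @return the `n x p` matrix `L_true' F_true`.
#' @export
sim_signal <- function(sim) {
  t(sim$L_true) %*% sim$F_true
}

#' Single-factor simulation with sparse loadings
#'
#' Simulates an `n x p` matrix under a rank-1 model with a sparse loading and
#' a dense factor: `l_i ~ pi0 delta_0 + (1 - pi0) * equal mixture of
#' N(0, sigma_m^2)` over `sigma^2 = (0.25, 0.5, 1, 2, 4)`, `f_j ~ N(0, 1)`,
#' noise `N(0, 1/tau)`. Default dimensions 200 x 300. Sparsity/noise pairs
#' studied with this design: `(pi0, tau)` = (0.9, 1), (0.3, 1/16),
#' (0, 1/25). Draw order is loadings, factors, noise, so runs are exactly
#' reproducible from `(parameters, seed)`.
#'
#' @param pi0 probability that a loading element is exactly zero, in
#'   `[0, 1]`.
#' @param tau noise precision (positive).
#' @param seed integer seed.
#' @param n,p matrix dimensions.
#' @return A `"sim_truth"` object: `Y` (an [observed_matrix]), `L_true`
#'   (`1 x n`), `F_true` (`1 x p`), `tau_true`, `seed`.
#' @export
sim_rank1 <- function(pi0, tau, seed, n = 200, p = 300) {
  if (length(pi0) != 1 || is.na(pi0) || pi0 < 0 || pi0 > 1) {
    stop("`pi0` must be in [0, 1]")
  }
  if (length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be positive")
  }
  sigma2 <- c(0.25, 0.5, 1, 2, 4)
  set.seed(seed)
  nonzero <- stats::runif(n) >= pi0
  l <- numeric(n)
  m <- sum(nonzero)
  if (m > 0) {
    comp <- sample.int(length(sigma2), m, replace = TRUE)
    l[nonzero] <- stats::rnorm(m, 0, sqrt(sigma2[comp]))
  }
  f <- stats::rnorm(p)
  E <- matrix(stats::rnorm(n * p, 0, 1 / sqrt(tau)), n, p)
  Y <- outer(l, f) + E
  new_sim_truth(observed_matrix(Y), matrix(l, 1, n), matrix(f, 1, p),
                tau, seed, "rank1")
}

#' Sparse bi-cluster simulation (rank 3)
#'
#' Simulates a 150 x 240 matrix with three loading/factor pairs on disjoint
#' index blocks: loadings nonzero on rows 1-10 (sd 2), 11-60 (sd 1) and
#' 61-150 (sd 1/2); factors nonzero on columns 1-80 (sd 1/2), 81-160 (sd 1)
#' and 161-240 (sd 2); noise precision 1/4 (variance 4). Distinct groups of
#' samples are each loaded on only one factor, with group sizes and signal
#' strengths varying across components.
#'
#' @param seed integer seed.
#' @param tau noise precision (default 1/4).
#' @return A `"sim_truth"` object with `L_true` 3 x 150 and `F_true`
#'   3 x 240.
#' @export
sim_bicluster <- function(seed, tau = 1 / 4) {
  n <- 150
  p <- 240
  set.seed(seed)
  L <- matrix(0, 3, n)
  L[1, 1:10]   <- stats::rnorm(10, 0, 2)
  L[2, 11:60]  <- stats::rnorm(50, 0, 1)
  L[3, 61:150] <- stats::rnorm(90, 0, 1 / 2)
  FF <- matrix(0, 3, p)
  FF[1, 1:80]    <- stats::rnorm(80, 0, 1 / 2)
  FF[2, 81:160]  <- stats::rnorm(80, 0, 1)
  FF[3, 161:240] <- stats::rnorm(80, 0, 2)
  E <- matrix(stats::rnorm(n * p, 0, 1 / sqrt(tau)), n, p)
  Y <- t(L) %*% FF + E
  new_sim_truth(observed_matrix(Y), L, FF, tau, seed, "bicluster")
}

#' Relative root mean squared error
#'
#' `sqrt(sum((Bhat - B)^2) / sum(B^2))`: the reconstruction error of an
#' estimated signal matrix relative to the size of the true signal. Equals 0
#' for a perfect reconstruction and 1 for the all-zero estimate.
#'
#' @param B_hat,B matrices of the same shape; `B` must not be identically
#'   zero.
#' @return scalar.
#' @export
rrmse <- function(B_hat, B) {
  B_hat <- as.matrix(B_hat)
  B <- as.matrix(B)
  if (!identical(dim(B_hat), dim(B))) stop("matrices must have the same shape")
  den <- sum(B^2)
  if (den == 0) stop("`B` must not be identically zero")
  sqrt(sum((B_hat - B)^2) / den)
}

#' Root mean squared error on held-out cells
#'
#' `sqrt(mean((Y - Y_hat)^2))` over the cells selected by `mask`.
#'
#' @param Y_hat,Y matrices of the same shape.
#' @param mask logical matrix selecting at least one cell.
#' @return scalar.
#' @export
rmse_heldout <- function(Y_hat, Y, mask) {
  Y_hat <- as.matrix(Y_hat)
  Y <- as.matrix(Y)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(Y_hat), dim(Y)) || !identical(dim(mask), dim(Y))) {
    stop("matrices must have the same shape")
  }
  if (!any(mask)) stop("`mask` must select at least one cell")
  sqrt(mean((Y[mask] - Y_hat[mask])^2))
}

#' Orthogonal cross-validation folds
#'
#' Rows are randomly partitioned into `k` groups and columns into `k` groups;
#' fold `t` holds out the observed cells whose row group plus column group is
#' `t` modulo `k`. The folds are disjoint, each fold masks only
#' originally-observed cells, and their union is exactly the set of observed
#' cells, so every cell is held out exactly once. The diagonal-block pattern
#' leaves every row and every column with training cells in every fold
#' (when `n, p >> k`), which plain random masking does not guarantee.
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param k number of folds, at least 2 and at most `min(n, p)`.
#' @param seed integer seed.
#' @return list of class `"holdout_mask"`: element `folds` is a list of `k`
#'   logical matrices.
#' @export
ocv_folds <- function(Y, k, seed) {
  Y <- as_observed(Y)
  n <- nrow(Y$values)
  p <- ncol(Y$values)
  if (k < 2) stop("`k` must be at least 2")
  if (k > min(n, p)) stop("`k` must not exceed min(n, p)")
  set.seed(seed)
  rg <- sample(rep_len(0:(k - 1), n))
  cg <- sample(rep_len(0:(k - 1), p))
  grp <- outer(rg, cg, "+") %% k
  folds <- lapply(0:(k - 1), function(t) Y$mask & (grp == t))
  structure(list(folds = folds, k = k, seed = seed), class = "holdout_mask")
}

#' Truncated-SVD baseline
#'
#' Best rank-`K` approximation of a fully observed matrix by singular value
#' decomposition; the reference point the factorization methods are compared
#' against.
#'
#' @param Y an [observed_matrix] (fully observed) or plain matrix without
#'   `NA`s.
#' @param K target rank.
#' @return `n x p` matrix of rank at most `K`.
#' @export
svd_baseline <- function(Y, K) {
  Y <- as_observed(Y)
  if (!all(Y$mask)) stop("the SVD baseline requires a fully observed matrix")
  K <- min(K, dim(Y$values))
  sv <- svd(Y$values, nu = K, nv = K)
  sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
}
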