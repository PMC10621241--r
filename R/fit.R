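# Multi-factor model fitting: initialization, rank-1 coordinate ascent,
# greedy factor addition, backfitting, the rank-selection null check,
# imputation, percentage of variance explained, and normalization.
#
# The fit object keeps the loading/factor posterior moments as n x K and
# p x K matrices (columns are components), plus the fitted priors, per-block
# KL terms, the precision model, and the objective trace. The recorded trace
# is monotone by construction: it holds the rank-0 objective, then one value
# per accepted factor during the greedy pass (the null check keeps whichever
# of "keep" and "drop" has the larger objective, and the "drop" value equals
# the previous accepted objective with re-estimated precision), then one
# value per backfitting sweep (plain block coordinate ascent). Per-iteration
# traces of single-factor optimizations are monotone too and are exposed by
# fit_rank1.

#' Fitting configuration
#'
#' @param prior_family_l,prior_family_f prior family for the loadings and the
#'   factors; one of `"point_normal"` (default: fast, sparsity-inducing),
#'   `"scale_mix_normal"`, `"normal"`, `"point_mass_zero"`.
#' @param Kmax maximum number of components for the greedy pass.
#' @param tau_structure residual precision structure (see [precision_model]).
#' @param tol convergence tolerance: iteration stops when the objective gain
#'   drops below `tol` per observed cell. Expressed per cell so that the
#'   criterion is invariant under rescaling of the data.
#' @param maxiter iteration cap for a single factor's optimization.
#' @param backfit_maxiter sweep cap for backfitting.
#' @param seed optional integer seed, used only by operations that draw
#'   random numbers (none of the fitting routines do).
#' @param nullcheck if `TRUE` (default), each factor is tested against its
#'   point-mass replacement after convergence and dropped when the objective
#'   prefers the replacement.
#' @param backfit if `TRUE`, [ebmf()] follows the greedy pass with
#'   backfitting.
#' @param tau_clamp upper bound on the precision for perfect-fit blocks.
#' @param grid_l,grid_f optional scale-mixture grids.
#' @param fixed_tau precision matrix for `tau_structure = "by_entry_fixed"`.
#' @param verbose print per-factor progress.
#' @return list of class `"ebmf_config"`.
#' @export
ebmf_config <- function(prior_family_l = "point_normal",
                        prior_family_f = "point_normal",
                        Kmax = 20,
                        tau_structure = "constant",
                        tol = 1e-8,
                        maxiter = 500,
                        backfit_maxiter = 100,
                        seed = NULL,
                        nullcheck = TRUE,
                        backfit = FALSE,
                        tau_clamp = 1e8,
                        grid_l = NULL,
                        grid_f = NULL,
                        fixed_tau = NULL,
                        verbose = FALSE) {
  if (tol <= 0) stop("`tol` must be positive")
  if (Kmax < 1) stop("`Kmax` must be at least 1")
  structure(list(prior_family_l = prior_family_l,
                 prior_family_f = prior_family_f,
                 Kmax = Kmax, tau_structure = tau_structure, tol = tol,
                 maxiter = maxiter, backfit_maxiter = backfit_maxiter,
                 seed = seed, nullcheck = nullcheck, backfit = backfit,
                 tau_clamp = tau_clamp, grid_l = grid_l, grid_f = grid_f,
                 fixed_tau = fixed_tau, verbose = verbose),
            class = "ebmf_config")
}

# ---- internal state helpers --------------------------------------------------

empty_state <- function(Y, config) {
  Y <- as_observed(Y)
  if (!any(Y$mask)) stop("matrix has no observed cells")
  n <- nrow(Y$values)
  p <- ncol(Y$values)
  structure(list(Y = Y,
                 L = matrix(0, n, 0), L2 = matrix(0, n, 0),
                 FF = matrix(0, p, 0), F2 = matrix(0, p, 0),
                 priors_l = list(), priors_f = list(),
                 kl_l = numeric(0), kl_f = numeric(0),
                 tau = NULL, objective_trace = numeric(0),
                 config = config),
            class = "ebmf_fit")
}

state_k <- function(state) ncol(state$L)

state_factors <- function(state) {
  lapply(seq_len(state_k(state)), function(k) {
    list(l_mean = state$L[, k], l_mean2 = state$L2[, k],
         f_mean = state$FF[, k], f_mean2 = state$F2[, k])
  })
}

#' Extract the moment set of one component
#'
#' @param fit an `"ebmf_fit"` object.
#' @param k component index.
#' @return list with `l_mean`, `l_mean2`, `f_mean`, `f_mean2`.
#' @export
factor_moments <- function(fit, k) {
  if (k < 1 || k > state_k(fit)) stop("component index out of range")
  state_factors(fit)[[k]]
}

refresh_tau <- function(state) {
  R2 <- expected_residual2(state$Y, state_factors(state))
  state$tau <- update_tau(R2, state$Y$mask, state$config$tau_structure,
                          tau = if (is.null(state$tau)) state$config$fixed_tau else state$tau,
                          clamp = state$config$tau_clamp)
  state
}

state_objective <- function(state) {
  compute_objective(state$Y, state$tau, state_factors(state),
                    state$kl_l, state$kl_f)
}

# residual matrix excluding component k (Eq-style deflation); the values at
# unobserved cells are irrelevant (precision zero there)
residual_excluding <- function(state, k) {
  v <- state$Y$values
  K <- state_k(state)
  keep <- setdiff(seq_len(K), k)
  if (length(keep) > 0) {
    v <- v - state$L[, keep, drop = FALSE] %*% t(state$FF[, keep, drop = FALSE])
  }
  structure(list(values = v, mask = state$Y$mask), class = "observed_matrix")
}

add_factor <- function(state, l, f) {
  state$L <- cbind(state$L, l)
  state$L2 <- cbind(state$L2, l^2)
  state$FF <- cbind(state$FF, f)
  state$F2 <- cbind(state$F2, f^2)
  state$priors_l <- c(state$priors_l, list(prior_point_mass()))
  state$priors_f <- c(state$priors_f, list(prior_point_mass()))
  state$kl_l <- c(state$kl_l, 0)
  state$kl_f <- c(state$kl_f, 0)
  state
}

remove_factor <- function(state, k) {
  state$L <- state$L[, -k, drop = FALSE]
  state$L2 <- state$L2[, -k, drop = FALSE]
  state$FF <- state$FF[, -k, drop = FALSE]
  state$F2 <- state$F2[, -k, drop = FALSE]
  state$priors_l <- state$priors_l[-k]
  state$priors_f <- state$priors_f[-k]
  state$kl_l <- state$kl_l[-k]
  state$kl_f <- state$kl_f[-k]
  state
}

# one block update of component k's loading then factor, against the
# deflated residuals, keeping tau fixed
update_factor_blocks <- function(state, k) {
  Rk <- residual_excluding(state, k)
  cfg <- state$config
  lf <- update_side(Rk, state$tau,
                    other = list(mean = state$FF[, k], mean2 = state$F2[, k]),
                    side = "loading", family = cfg$prior_family_l,
                    grid = cfg$grid_l)
  state$L[, k] <- lf$post_mean
  state$L2[, k] <- lf$post_mean2
  state$priors_l[[k]] <- lf$g_hat
  state$kl_l[k] <- lf$kl
  ff <- update_side(Rk, state$tau,
                    other = list(mean = state$L[, k], mean2 = state$L2[, k]),
                    side = "factor", family = cfg$prior_family_f,
                    grid = cfg$grid_f)
  state$FF[, k] <- ff$post_mean
  state$F2[, k] <- ff$post_mean2
  state$priors_f[[k]] <- ff$g_hat
  state$kl_f[k] <- ff$kl
  state
}

# run component k's coordinate ascent (tau, loading, factor) to convergence;
# returns the state and the per-iteration objective values
optimize_factor <- function(state, k) {
  cfg <- state$config
  nobs <- n_observed(state$Y)
  trace <- numeric(0)
  f_prev <- -Inf
  for (it in seq_len(cfg$maxiter)) {
    state <- refresh_tau(state)
    state <- update_factor_blocks(state, k)
    f_val <- state_objective(state)
    trace <- c(trace, f_val)
    if (it > 1 && f_val - f_prev < cfg$tol * nobs) break
    f_prev <- f_val
  }
  list(state = state, trace = trace)
}

# is component k numerically zero?
is_zero_factor <- function(state, k) {
  (max(abs(state$L[, k])) * max(abs(state$FF[, k])) < 1e-12) ||
    (prior_is_delta0(state$priors_l[[k]]) && prior_is_delta0(state$priors_f[[k]]))
}

finalize_fit <- function(state) {
  state$pve <- compute_pve(state)
  state
}

# ---- initialization ----------------------------------------------------------

#' Rank-1 initialization by alternating least squares
#'
#' Computes the leading rank-1 approximation of the observed cells by
#' unpenalized alternating least squares started from a normalized column of
#' ones. With a fully observed matrix this converges to the leading singular
#' pair; with missing cells it performs zero-penalty matrix completion.
#' Deterministic given the data.
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param maxiter,tol iteration cap and squared-change tolerance on the
#'   normalized loading.
#' @return list with numeric vectors `l` (unit norm) and `f` (carries the
#'   scale), such that `l %o% f` approximates `Y`.
#' @export
init_rank1 <- function(Y, maxiter = 200, tol = 1e-12) {
  Y <- as_observed(Y)
  if (!any(Y$mask)) stop("matrix has no observed cells")
  n <- nrow(Y$values)
  p <- ncol(Y$values)
  Yv <- Y$values                       # zero at missing cells
  M <- 1 * Y$mask
  l <- rep(1 / sqrt(n), n)
  f <- rep(0, p)
  # zero-penalty ALS is unstable when a column (row) is observed only where
  # the current loading (factor) is near zero; such entries are floored to 0
  # rather than allowed to blow up
  safe_ratio <- function(num, den) {
    out <- ifelse(den > 1e-12 * max(den, 0), num / den, 0)
    out[!is.finite(out)] <- 0
    out
  }
  for (it in seq_len(maxiter)) {
    f <- safe_ratio(as.numeric(crossprod(Yv, l)), as.numeric(crossprod(M, l^2)))
    if (all(f == 0)) return(list(l = rep(0, n), f = rep(0, p)))
    l_new <- safe_ratio(as.numeric(Yv %*% f), as.numeric(M %*% (f^2)))
    mx <- max(abs(l_new))
    if (mx == 0) return(list(l = rep(0, n), f = rep(0, p)))
    l_new <- l_new / mx
    l_new <- l_new / sqrt(sum(l_new^2))
    if (sum((l_new - l)^2) < tol) {
      l <- l_new
      break
    }
    l <- l_new
  }
  f <- safe_ratio(as.numeric(crossprod(Yv, l)), as.numeric(crossprod(M, l^2)))
  list(l = l, f = f)
}

# ---- single-factor and multi-factor fitting ----------------------------------

#' Fit a single-component model
#'
#' Initializes from [init_rank1] and iterates the coordinate ascent
#' (precision, loading, factor) until the objective gain per observed cell
#' drops below `config$tol`. The objective trace holds one value per
#' iteration and is non-decreasing. No null check is applied; see
#' [greedy_fit] or [nullcheck] for rank selection.
#'
#' @param Y an [observed_matrix] (or plain matrix with `NA`s).
#' @param family_l,family_f prior families (override the config).
#' @param config an [ebmf_config].
#' @return An `"ebmf_fit"` object with `K = 1`.
#' @export
fit_rank1 <- function(Y, family_l = NULL, family_f = NULL,
                      config = ebmf_config()) {
  if (!is.null(family_l)) config$prior_family_l <- family_l
  if (!is.null(family_f)) config$prior_family_f <- family_f
  state <- empty_state(Y, config)
  init <- init_rank1(state$Y)
  state <- add_factor(state, init$l, init$f)
  res <- optimize_factor(state, 1)
  state <- res$state
  state$objective_trace <- res$trace
  finalize_fit(state)
}

#' Greedy multi-factor fit
#'
#' Adds components one at a time: each new component is initialized by
#' [init_rank1] on the residuals of the current fit, optimized to
#' convergence, then tested by [nullcheck]; the pass stops at `Kmax` or as
#' soon as a new component is zeroed. The returned rank `K` can be anywhere
#' from 0 to `Kmax`. The objective trace starts at the rank-0 objective and
#' appends one value per accepted component; it is strictly increasing, so a
#' returned `K >= 1` certifies that the variational bound (and hence the
#' marginal likelihood) prefers the fit to the rank-0 model.
#'
#' @inheritParams fit_rank1
#' @param Kmax maximum number of components (overrides the config).
#' @return An `"ebmf_fit"` object.
#' @export
greedy_fit <- function(Y, Kmax = NULL, family_l = NULL, family_f = NULL,
                       config = ebmf_config()) {
  if (!is.null(Kmax)) config$Kmax <- Kmax
  if (!is.null(family_l)) config$prior_family_l <- family_l
  if (!is.null(family_f)) config$prior_family_f <- family_f
  state <- empty_state(Y, config)
  state <- refresh_tau(state)
  trace <- state_objective(state)      # rank-0 baseline

  for (k in seq_len(config$Kmax)) {
    init <- init_rank1(residual_excluding(state, k = state_k(state) + 1))
    cand <- add_factor(state, init$l, init$f)
    kk <- state_k(cand)
    opt <- optimize_factor(cand, kk)
    cand <- opt$state
    if (config$nullcheck) {
      nc <- nullcheck(cand, kk)
      if (nc$zeroed) {
        trace <- c(trace, nc$objective)
        state <- remove_factor(nc$fit, kk)
        break
      }
      cand <- nc$fit
      trace <- c(trace, nc$objective)
    } else {
      if (is_zero_factor(cand, kk)) {
        state <- remove_factor(cand, kk)
        break
      }
      trace <- c(trace, utils::tail(opt$trace, 1))
    }
    state <- cand
    if (config$verbose) {
      message(sprintf("component %d accepted: F = %.6g", kk, utils::tail(trace, 1)))
    }
  }
  state <- refresh_tau(state)
  state$objective_trace <- trace
  finalize_fit(state)
}

#' Backfitting refinement
#'
#' Cyclically re-optimizes every component against the residuals of the
#' others until the overall objective converges, then applies the null check
#' to each component and drops those that collapse to zero. Because every
#' sweep is block coordinate ascent started from a valid variational state,
#' the objective never falls below that of the input fit.
#'
#' @param fit an `"ebmf_fit"` (typically from [greedy_fit]).
#' @param config optional [ebmf_config] overriding the fit's own.
#' @return An `"ebmf_fit"` object.
#' @export
backfit <- function(fit, config = NULL) {
  state <- fit
  if (!is.null(config)) state$config <- config
  cfg <- state$config
  if (state_k(state) == 0) return(finalize_fit(state))
  nobs <- n_observed(state$Y)
  trace <- state$objective_trace
  f_prev <- if (length(trace) > 0) utils::tail(trace, 1) else -Inf

  for (sweep in seq_len(cfg$backfit_maxiter)) {
    for (k in seq_len(state_k(state))) {
      state <- refresh_tau(state)
      state <- update_factor_blocks(state, k)
    }
    f_val <- state_objective(state)
    trace <- c(trace, f_val)
    if (f_val - f_prev < cfg$tol * nobs) break
    f_prev <- f_val
  }

  if (cfg$nullcheck) {
    k <- 1
    while (k <= state_k(state)) {
      nc <- nullcheck(state, k)
      if (nc$zeroed) {
        state <- remove_factor(nc$fit, k)
        trace <- c(trace, nc$objective)
      } else {
        state <- nc$fit
        k <- k + 1
      }
    }
  }
  state <- refresh_tau(state)
  state$objective_trace <- trace
  finalize_fit(state)
}

#' Full fit: greedy pass plus optional backfitting
#'
#' Convenience wrapper running [greedy_fit] and, when `config$backfit` is
#' `TRUE`, [backfit].
#'
#' @inheritParams greedy_fit
#' @return An `"ebmf_fit"` object.
#' @export
ebmf <- function(Y, Kmax = NULL, family_l = NULL, family_f = NULL,
                 config = ebmf_config()) {
  fit <- greedy_fit(Y, Kmax = Kmax, family_l = family_l, family_f = family_f,
                    config = config)
  if (fit$config$backfit) fit <- backfit(fit)
  fit
}

#' Null check: compare a component against its point-mass replacement
#'
#' Computes the objective with component `k` as fitted (precision
#' re-estimated) and with component `k` replaced by point masses at zero
#' (moments zero, precision re-estimated), and keeps whichever state has the
#' larger objective. This guards against local optima that are worse than
#' the lower-rank model and implements conservative rank selection: whenever
#' the kept state has the component, the variational bound — and therefore
#' the marginal likelihood — strictly prefers it to the reduced model.
#'
#' @param fit an `"ebmf_fit"` object.
#' @param k component index.
#' @return list with elements `fit` (the kept state), `zeroed` (logical) and
#'   `objective` (the kept state's objective). A `K = 0` fit is returned
#'   unchanged.
#' @export
nullcheck <- function(fit, k) {
  if (state_k(fit) == 0) {
    return(list(fit = fit, zeroed = FALSE,
                objective = if (length(fit$objective_trace) > 0)
                  utils::tail(fit$objective_trace, 1) else NA_real_))
  }
  keep <- refresh_tau(fit)
  f_keep <- state_objective(keep)

  drop <- fit
  drop$L[, k] <- 0
  drop$L2[, k] <- 0
  drop$FF[, k] <- 0
  drop$F2[, k] <- 0
  drop$priors_l[[k]] <- prior_point_mass()
  drop$priors_f[[k]] <- prior_point_mass()
  drop$kl_l[k] <- 0
  drop$kl_f[k] <- 0
  drop <- refresh_tau(drop)
  f_drop <- state_objective(drop)

  if (f_drop >= f_keep) {
    list(fit = drop, zeroed = TRUE, objective = f_drop)
  } else {
    list(fit = keep, zeroed = FALSE, objective = f_keep)
  }
}

# ---- derived quantities ------------------------------------------------------

#' Posterior-mean reconstruction / imputation
#'
#' Plug-in reconstruction `sum_k lbar_k fbar_k'`, defined at every cell
#' including missing ones; a `K = 0` fit imputes zero everywhere.
#'
#' @param fit an `"ebmf_fit"` object.
#' @return `n x p` numeric matrix.
#' @export
impute <- function(fit) {
  n <- nrow(fit$Y$values)
  p <- ncol(fit$Y$values)
  if (state_k(fit) == 0) return(matrix(0, n, p))
  fit$L %*% t(fit$FF)
}

#' Percentage of variance explained per component
#'
#' `pve_k = s_k / (sum_k' s_k' + sum_ij 1 / tau_ij)` with
#' `s_k = sum_ij (lbar_ki fbar_kj)^2`, all sums over observed cells. A loose
#' but useful measure of the signal captured by each component (the
#' components are not orthogonal).
#'
#' @param fit an `"ebmf_fit"` object with positive precision on observed
#'   cells.
#' @return numeric vector of length `K` with entries in `[0, 1]`.
#' @export
compute_pve <- function(fit) {
  K <- state_k(fit)
  if (K == 0) return(numeric(0))
  if (is.null(fit$tau)) fit <- refresh_tau(fit)
  obs <- fit$Y$mask
  s <- vapply(seq_len(K), function(k) {
    sum((outer(fit$L[, k], fit$FF[, k])^2)[obs])
  }, numeric(1))
  denom <- sum(s) + sum(1 / fit$tau$tau[obs])
  s / denom
}

#' Rescale components to unit-norm loadings
#'
#' Each loading is scaled to unit Euclidean norm and the factor absorbs the
#' scale; second moments are rescaled consistently so that all moment
#' invariants and the reconstruction `lbar_k fbar_k'` are preserved. Zero
#' components are left untouched. Fitted priors are reported on the original
#' scale. Idempotent.
#'
#' @param fit an `"ebmf_fit"` object.
#' @return An `"ebmf_fit"` object.
#' @export
normalize_fit <- function(fit) {
  for (k in seq_len(state_k(fit))) {
    cn <- sqrt(sum(fit$L[, k]^2))
    if (cn > 0) {
      fit$L[, k] <- fit$L[, k] / cn
      fit$L2[, k] <- fit$L2[, k] / cn^2
      fit$FF[, k] <- fit$FF[, k] * cn
      fit$F2[, k] <- fit$F2[, k] * cn^2
    }
  }
  fit
}

#' @export
print.ebmf_fit <- function(x, ...) {
  K <- state_k(x)
  cat("Empirical Bayes matrix factorization fit\n")
  cat(sprintf("  data: %d x %d (%d observed cells)\n",
              nrow(x$Y$values), ncol(x$Y$values), n_observed(x$Y)))
  cat(sprintf("  components: %d\n", K))
  if (length(x$objective_trace) > 0) {
    cat(sprintf("  objective: %.6g\n", utils::tail(x$objective_trace, 1)))
  }
  if (K > 0 && !is.null(x$pve)) {
    cat("  pve:", paste(sprintf("%.3f", x$pve), collapse = " "), "\n")
  }
  invisible(x)
}
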