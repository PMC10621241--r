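# Variational core: regression statistics, expected squared residuals,
# precision updates, KL terms, the objective, and the master monotonicity
# property of the block coordinate ascent.

test_that("regression statistics reproduce hand arithmetic and exact rank-1 identities", {
  Y <- matrix(c(2, 1, 4, 2), 2, 2)    # [[2,4],[1,2]]
  tau <- matrix(1, 2, 2)
  rs <- regression_stats(Y, tau, v = c(1, 2), w = c(1, 4), side = "loading")
  expect_equal(rs$est, c(2, 1))
  expect_equal(rs$se, rep(5^-0.5, 2))

  # noiseless rank-1 with degenerate moments recovers the loading exactly
  set.seed(1)
  l <- rnorm(7); f <- rnorm(5)
  rs2 <- regression_stats(outer(l, f), matrix(1, 7, 5), v = f, w = f^2,
                          side = "loading")
  expect_equal(rs2$est, l)
  # and symmetrically for the factor side
  rs3 <- regression_stats(outer(l, f), matrix(1, 7, 5), v = l, w = l^2,
                          side = "factor")
  expect_equal(rs3$est, f)

  # fully unobserved row: no data contract
  Ym <- matrix(rnorm(12), 3, 4)
  Ym[2, ] <- NA
  tm <- matrix(1, 3, 4); tm[2, ] <- 0
  v4 <- rnorm(4)
  rs4 <- regression_stats(observed_matrix(Ym), tm, v = v4,
                          w = v4^2 + runif(4), side = "loading")
  expect_equal(rs4$est[2], 0)
  expect_equal(rs4$se[2], Inf)

  expect_error(regression_stats(Y, -tau, c(1, 2), c(1, 4), "loading"),
               "nonnegative")
  expect_error(regression_stats(Y, tau, c(1, 2, 3), c(1, 4, 9), "loading"),
               "length")
})

test_that("regression statistics match weighted least squares for degenerate moments", {
  # with known tau and degenerate factor moments the update reduces to n
  # independent weighted regressions of the rows of Y on f
  set.seed(2)
  Y <- matrix(rnorm(60), 6, 10)
  tau <- matrix(runif(60, 0.5, 2), 6, 10)
  f <- rnorm(10)
  rs <- regression_stats(Y, tau, v = f, w = f^2, side = "loading")
  for (i in 1:6) {
    expect_equal(rs$est[i], sum(tau[i, ] * Y[i, ] * f) / sum(tau[i, ] * f^2))
    expect_equal(rs$se[i], sum(tau[i, ] * f^2)^-0.5)
  }
})

test_that("masked cells behave exactly like dropped cells in all sums", {
  set.seed(3)
  for (rep in 1:5) {
    Yv <- matrix(rnorm(80), 10, 8)
    mask <- matrix(runif(80) > 0.3, 10, 8)
    mask[1, ] <- FALSE                 # one fully missing row
    Y <- observed_matrix(ifelse(mask, Yv, NA))
    tauv <- matrix(runif(80, 0.5, 2), 10, 8) * mask
    v <- rnorm(8); w <- v^2 + runif(8)
    rs <- regression_stats(Y, tauv, v, w, "loading")
    oracle <- loop_regression(Yv, mask, tauv, v, w, "loading")
    expect_equal(rs$est, oracle$est)
    expect_equal(rs$se, oracle$se)

    u <- rnorm(10); w2 <- u^2 + runif(10)
    rs2 <- regression_stats(Y, tauv, u, w2, "factor")
    oracle2 <- loop_regression(Yv, mask, tauv, u, w2, "factor")
    expect_equal(rs2$est, oracle2$est)
    expect_equal(rs2$se, oracle2$se)

    # constant-precision update over observed cells only
    R2 <- matrix(runif(80), 10, 8)
    tt <- update_tau(R2, mask, "constant")
    expect_equal(unique(tt$tau[mask]), sum(mask) / sum(R2[mask]))
    expect_true(all(tt$tau[!mask] == 0))
  }
})

test_that("expected squared residuals implement the moment expansion", {
  # direct substitution: (1 - 1)^2 - 1*1 + 2*3 = 5
  Y <- matrix(1, 1, 1)
  fac <- list(list(l_mean = 1, l_mean2 = 2, f_mean = 1, f_mean2 = 3))
  expect_equal(expected_residual2(Y, fac)[1, 1], 5)

  # degenerate moments collapse to plain squared residuals
  set.seed(4)
  l <- rnorm(6); f <- rnorm(4); Yv <- matrix(rnorm(24), 6, 4)
  fac2 <- list(list(l_mean = l, l_mean2 = l^2, f_mean = f, f_mean2 = f^2))
  expect_equal(expected_residual2(Yv, fac2), (Yv - outer(l, f))^2)

  # zero moments give back the squared data; masked cells are zeroed
  Ym <- Yv; Ym[2, 3] <- NA
  z <- list(list(l_mean = rep(0, 6), l_mean2 = rep(0, 6),
                 f_mean = rep(0, 4), f_mean2 = rep(0, 4)))
  r2 <- expected_residual2(observed_matrix(Ym), z)
  expect_equal(r2[2, 3], 0)
  expect_equal(r2[-2, ], Yv[-2, ]^2)
})

test_that("precision updates are structure-wise maximum likelihood with clamping", {
  mask <- matrix(TRUE, 3, 4)
  tt <- update_tau(matrix(4, 3, 4), mask, "constant")
  expect_equal(unique(as.numeric(tt$tau)), 0.25)

  # perfect-fit column clamps rather than diverging
  R2 <- matrix(1, 3, 4); R2[, 2] <- 0
  tc <- update_tau(R2, mask, "by_column")
  expect_equal(tc$tau[1, 2], 1e8)
  expect_equal(tc$tau[1, 1], 1)

  # missing cell drops out of the sums: observed residuals 1,2,3 -> 3/6
  m2 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  R2b <- matrix(c(1, 2, 3, 99), 2, 2)
  expect_equal(unique(update_tau(R2b, m2, "constant")$tau[m2]), 0.5)

  # by_row and fixed structures
  tr <- update_tau(matrix(c(1, 2), 2, 3), matrix(TRUE, 2, 3), "by_row")
  expect_equal(tr$tau[, 1], c(1, 0.5))
  tf <- update_tau(matrix(1, 2, 2), matrix(TRUE, 2, 2), "by_entry_fixed",
                   tau = matrix(7, 2, 2))
  expect_equal(tf$tau, matrix(7, 2, 2))

  expect_error(update_tau(matrix(-1, 2, 2), matrix(TRUE, 2, 2)), "nonnegative")

  # block with no observed cells gets precision zero
  m3 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  t3 <- update_tau(matrix(1, 2, 2), m3, "by_column")
  expect_equal(t3$tau[, 2], c(0, 0))
})

test_that("KL terms are zero for the point mass, nonnegative otherwise", {
  d <- nm_data(c(1.4, -0.3, 2.2), c(1, 0.5, 2))
  expect_equal(kl_term(fit_point_mass(d), d), 0)
  for (seed in 1:5) {
    dd <- random_nm(seed, m = 30, with_inf = TRUE)
    for (fam in c("normal", "point_normal", "scale_mix_normal")) {
      fit <- solve_ebnm(dd, fam)
      kl <- kl_term(fit, dd)
      expect_gte(kl, -1e-8)
      expect_true(is.finite(kl))
    }
  }
})

test_that("point-normal KL matches direct quadrature of KL(q || g)", {
  set.seed(6)
  m <- 25
  s <- runif(m, 0.6, 1.5)
  x <- ifelse(runif(m) < 0.5, 0, rnorm(m, 0, 2)) + rnorm(m) * s
  d <- nm_data(x, s)
  fit <- fit_point_normal(d)
  g <- fit$g_hat
  kl_direct <- sum(vapply(seq_len(m), function(j) {
    la <- log(g$pi0) + dnorm(x[j], 0, s[j], log = TRUE)
    lb <- log1p(-g$pi0) + dnorm(x[j], 0, sqrt(g$a + s[j]^2), log = TRUE)
    mx <- max(la, lb)
    lse <- mx + log(exp(la - mx) + exp(lb - mx))
    w0 <- exp(la - lse)
    r <- g$a / (g$a + s[j]^2)
    mu <- x[j] * r
    v <- g$a * s[j]^2 / (g$a + s[j]^2)
    cont <- stats::integrate(function(t) {
      qc <- (1 - w0) * dnorm(t, mu, sqrt(v))
      qc * (log(qc) - log((1 - g$pi0) * dnorm(t, 0, sqrt(g$a))))
    }, mu - 12 * sqrt(v), mu + 12 * sqrt(v), rel.tol = 1e-10)$value
    w0 * log(w0 / g$pi0) + cont
  }, numeric(1)))
  expect_equal(kl_term(fit, d), kl_direct, tolerance = 1e-6)
})

test_that("the objective reduces to closed Gaussian forms at K = 0", {
  Y <- matrix(0, 1, 1)
  expect_equal(compute_objective(Y, precision_model("constant", matrix(1, 1, 1))),
               -0.5 * log(2 * pi))

  # profile likelihood identity at the ML precision
  set.seed(7)
  Yv <- matrix(rnorm(35, 0, 2), 5, 7)
  tt <- update_tau(Yv^2, matrix(TRUE, 5, 7), "constant")
  f0 <- compute_objective(Yv, tt)
  nobs <- 35
  expect_equal(f0, -nobs / 2 * (log(2 * pi * mean(Yv^2)) + 1))

  expect_error(
    compute_objective(Yv, precision_model("constant", matrix(0, 5, 7))),
    "strictly positive")
})

test_that("each block update never decreases the objective", {
  # master correctness property of the coordinate ascent: from any valid
  # variational state, each of the tau / loading / factor updates is a
  # block maximization of F
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12; p <- 9
    Yv <- outer(rnorm(n), rnorm(p)) + matrix(rnorm(n * p), n, p)
    if (seed %% 2 == 0) Yv[matrix(runif(n * p) < 0.2, n, p)] <- NA
    Y <- observed_matrix(Yv)
    fam <- if (seed %% 3 == 0) "scale_mix_normal" else "point_normal"
    cfg <- ebmf_config(prior_family_l = fam, prior_family_f = fam, maxiter = 2)
    st <- ebmf:::empty_state(Y, cfg)
    st <- ebmf:::add_factor(st, init_rank1(Y)$l, init_rank1(Y)$f)
    st <- ebmf:::refresh_tau(st)
    st <- ebmf:::update_factor_blocks(st, 1)  # now a valid variational state
    f0 <- ebmf:::state_objective(st)

    st <- ebmf:::refresh_tau(st)
    f1 <- ebmf:::state_objective(st)
    expect_gte(f1, f0 - 1e-8 * abs(f0))

    st <- ebmf:::update_factor_blocks(st, 1)
    f2 <- ebmf:::state_objective(st)
    expect_gte(f2, f1 - 1e-8 * abs(f1))
  }
})

test_that("update_side returns prior moments when the fixed side is zero", {
  Y <- matrix(rnorm(20), 4, 5)
  tau <- precision_model("constant", matrix(1, 4, 5))
  fit <- update_side(Y, tau, other = list(mean = rep(0, 5), mean2 = rep(0, 5)),
                     side = "loading", family = "point_normal")
  expect_equal(fit$post_mean, rep(0, 4))
  expect_equal(fit$nm$s, rep(Inf, 4))
  expect_equal(fit$kl, 0)
})

test_that("rescaling the data and precision together rescales the update", {
  set.seed(8)
  Yv <- matrix(rnorm(24), 4, 6)
  tau <- matrix(runif(24, 0.5, 2), 4, 6)
  v <- rnorm(6); w <- v^2 + runif(6)
  a <- regression_stats(Yv, tau, v, w, "loading")
  b <- regression_stats(10 * Yv, tau / 100, v, w, "loading")
  expect_equal(b$est, 10 * a$est)
  expect_equal(b$se, 10 * a$se)
})
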