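test_that("payoff matches direct arithmetic", {
  par1 <- minimal_model_params(beta = 1, lam = 1)
  expect_equal(saddle_payoff(c(0.5, 0, 0), par1), -log(2))
  par2 <- minimal_model_params(beta = 0.5, lam = 0.5)
  expect_equal(saddle_payoff(c(0.2, 0.25, 0.25), par2),
               0.25 - 0.5 * shannon_entropy(c(0.2, 0.8)) - 0.5 * 2 * 0.25^2)
  expect_equal(round(saddle_payoff(c(0.2, 0.25, 0.25), par2), 4), -0.0627)
  # beta = lam = 0 limit is approached as both shrink: payoff -> E_q[c]
  par3 <- minimal_model_params(beta = 1e-12, lam = 1e-12)
  expect_equal(saddle_payoff(c(1 - 1e-12, 1, 0), par3), 1, tolerance = 1e-9)
})

test_that("drift matches its closed form and the saddle gradient of payoff", {
  par <- minimal_model_params(beta = 0.5, lam = 0.5)
  d <- saddle_drift(c(0.2, 0, 0), par)
  expect_equal(unname(d[1]), -0.2 * 0.8 * 0.5 * log(0.25))
  expect_equal(round(unname(d[1]), 4), 0.1109)
  expect_equal(unname(d[2]), 0.2)
  expect_equal(unname(d[3]), 0.8)
  # descent in p through the replicator preconditioner, ascent in c:
  # dp = -p(1-p) dL/dp, dc = +dL/dc, against a finite-difference oracle
  set.seed(41)
  for (i in 1:50) {
    par_i <- minimal_model_params(beta = stats::runif(1, 0.1, 1),
                                  lam = stats::runif(1, 0.1, 1),
                                  bias = stats::rnorm(2, sd = 0.3))
    s <- c(stats::runif(1, 0.05, 0.95), stats::rnorm(2))
    g <- fd_gradient(function(x) saddle_payoff(x, par_i), s)
    expected <- c(-s[1] * (1 - s[1]) * g[1], g[2], g[3])
    expect_equal(unname(as.numeric(saddle_drift(s, par_i))), expected,
                 tolerance = 1e-6)
  }
})

test_that("the interior stationary point satisfies the fixed-point equations", {
  for (lam in c(0.1, 0.25, 0.5, 1)) {
    par <- minimal_model_params(lam = lam)
    st <- stationary_point(par)
    expect_equal(unname(as.numeric(st)), c(0.5, 1 / (4 * lam), 1 / (4 * lam)))
    expect_lt(max(abs(saddle_drift(st, par))), 1e-12)
  }
  expect_error(stationary_point(minimal_model_params(bias = c(0.5, 0))),
               class = "cfgeom_unsupported_case")
})

test_that("linearization exposes the rotational saddle structure", {
  par <- minimal_model_params(beta = 0.5, lam = 0.5)
  rep <- linearize_saddle(stationary_point(par), par)
  # analytic reduced (p, c1 - c2) block [[-beta, -1/4], [2, -2 lam]] plus the
  # decoupled sum mode at -2 lam
  ev_block <- eigen(matrix(c(-0.5, 2, -0.25, -1), 2, 2), only.values = TRUE)$values
  got <- rep$eigenvalues
  expect_true(rep$rotational)
  complex_pair <- got[abs(Im(got)) > 1e-6]
  expect_equal(sort(Re(complex_pair)), sort(Re(ev_block)), tolerance = 1e-5)
  expect_equal(sort(abs(Im(complex_pair))), sort(abs(Im(ev_block))),
               tolerance = 1e-5)
  expect_equal(Re(complex_pair)[1], -0.75, tolerance = 1e-5)
  expect_equal(abs(Im(complex_pair))[1], 0.6614, tolerance = 1e-3)
  real_mode <- got[abs(Im(got)) <= 1e-6]
  expect_equal(Re(real_mode), -2 * par$lam, tolerance = 1e-5)
  # Jacobian eigendecomposition is internally consistent
  ed <- eigen(rep$jacobian)
  expect_lt(max(Mod(rep$jacobian %*% ed$vectors - ed$vectors %*% diag(ed$values))),
            1e-8)
})

test_that("complex eigenvalues appear exactly when the discriminant is negative", {
  # reduced-block discriminant (beta - 2 lam)^2 - 2
  for (beta in c(0.1, 0.5, 1, 2, 3)) {
    for (lam in c(0.1, 0.5, 1)) {
      par <- minimal_model_params(beta = beta, lam = lam)
      rep <- linearize_saddle(stationary_point(par), par)
      expect_identical(rep$rotational, (beta - 2 * lam)^2 < 2,
                       label = sprintf("beta=%g lam=%g", beta, lam))
    }
  }
})

test_that("integration preserves the simplex and fixed points", {
  par <- minimal_model_params(lam = 0.5, steps = 500L,
                              p0 = 0.5, c0 = c(0.5, 0.5))
  traj <- integrate_saddle(par)
  expect_equal(length(traj$times), 501L)
  expect_lt(max(abs(traj$p - 0.5)), 1e-12)
  expect_lt(max(abs(traj$c1 - 0.5)), 1e-12)
  expect_false(any(traj$clipped))
})

test_that("the constraint sum mode relaxes on its exact exponential", {
  # c1 + c2 obeys ds/dt = 1 - 2 lam s independently of p
  for (rg in c("collapse", "bounded", "runaway")) {
    par <- minimal_preset(rg, steps = 2000L)
    traj <- integrate_saddle(par)
    lam <- par$lam
    s0 <- sum(par$c0)
    s_exact <- 1 / (2 * lam) + (s0 - 1 / (2 * lam)) * exp(-2 * lam * traj$times)
    expect_equal(traj$c1 + traj$c2, s_exact, tolerance = 1e-7)
  }
})

test_that("the three presets realize their regimes", {
  bounded <- integrate_saddle(minimal_preset("bounded"))
  expect_true(all(bounded$p >= 0.15 & bounded$p <= 0.85))
  expect_false(any(bounded$clipped))

  collapse <- integrate_saddle(minimal_preset("collapse"))
  h_term <- shannon_entropy(future_law(c(collapse$p[length(collapse$p)],
                                         1 - collapse$p[length(collapse$p)])))
  expect_lt(h_term, 0.01)
  # boundary attraction is monotone after the start
  expect_true(all(diff(collapse$p) < 1e-8))

  runaway <- integrate_saddle(minimal_preset("runaway"))
  ser <- regime_series(runaway)
  expect_gt(max(ser$fisher), 1e3)
  near <- pmin(runaway$p, 1 - runaway$p) < 0.05
  reentries <- sum(near[-length(near)] & !near[-1L])
  expect_gte(reentries, 1L)
})

test_that("stochastic forcing is reproducible and seed-sensitive", {
  p1 <- minimal_preset("bounded", steps = 300L, noise_sd = 0.01, seed = 5L)
  t1 <- integrate_saddle(p1)
  t2 <- integrate_saddle(p1)
  expect_identical(t1$p, t2$p)
  p3 <- minimal_preset("bounded", steps = 300L, noise_sd = 0.01, seed = 6L)
  expect_false(identical(integrate_saddle(p3)$p, t1$p))
})

test_that("gradient-flow baseline has the Lyapunov property the saddle lacks", {
  # monotone nonincreasing potential on random quadratic bowls
  set.seed(51)
  for (i in 1:100) {
    d <- sample(1:4, 1)
    a <- matrix(stats::rnorm(d * d), d)
    A <- crossprod(a) + diag(d) * 0.1
    V <- function(th) 0.5 * sum(th * (A %*% th))
    tr <- gradient_flow_baseline(V, stats::rnorm(d), step = 0.2 / max(eigen(A)$values),
                                 iters = 50L)
    expect_true(all(diff(tr$potential) <= 1e-12))
  }
  # zero-gradient start stays put
  V <- function(th) sum(th^2)
  tr0 <- gradient_flow_baseline(V, c(0, 0), iters = 10L)
  expect_equal(tr0$theta[11L, ], c(0, 0))
  # descent on the squared drift norm converges to the saddle's fixed point,
  # yet the saddle flow itself rotates there: the contrast with gradient flow
  par <- minimal_model_params(beta = 0.5, lam = 0.5)
  V_crit <- function(th) sum(saddle_drift(th, par)^2)
  tr <- gradient_flow_baseline(V_crit, c(0.4, 0.4, 0.6), step = 0.05,
                               iters = 2000L)
  expect_lt(tr$potential[2001L], 1e-10)
  expect_equal(tr$theta[2001L, ], c(0.5, 0.5, 0.5), tolerance = 1e-4)
  expect_true(linearize_saddle(tr$theta[2001L, ], par)$rotational)
  # a gradient system's Jacobian (negated Hessian) is symmetric: all-real spectrum
  hess <- matrix(0, 3, 3)
  for (j in 1:3) {
    hj <- function(x) fd_gradient(function(y) saddle_payoff(y, par), x)[j]
    hess[j, ] <- fd_gradient(hj, c(0.4, 0.4, 0.6), h = 1e-4)
  }
  expect_lt(max(abs(hess - t(hess))), 1e-4)
  expect_true(all(abs(Im(eigen(-(hess + t(hess)) / 2)$values)) == 0))
})

test_that("integration reports blow-ups with the offending step", {
  par <- minimal_model_params(beta = 0.5, lam = 0.5, dt = 1e6, steps = 50L,
                              c0 = c(1e4, -1e4))
  err <- tryCatch(suppressWarnings(integrate_saddle(par)), error = function(e) e)
  expect_s3_class(err, "cfgeom_blowup_error")
  expect_true(!is.null(err$step))
})
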