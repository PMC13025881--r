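test_that("future_law validates and normalizes simplex vectors", {
  q <- future_law(c(0.2, 0.8), labels = c("a", "b"))
  expect_s3_class(q, "future_law")
  expect_equal(sum(q$probs), 1)
  expect_error(future_law(c(0.2, 0.9)), class = "cfgeom_invalid_law")
  expect_error(future_law(c(-0.1, 1.1)), class = "cfgeom_invalid_law")
  expect_error(future_law(1), class = "cfgeom_invalid_law")
  expect_error(future_law(c(0.5, NA)), class = "cfgeom_invalid_law")
})

test_that("entropy matches closed forms and respects its bounds", {
  expect_equal(shannon_entropy(future_law(c(0.5, 0.5))), log(2))
  expect_equal(round(shannon_entropy(future_law(c(0.2, 0.8))), 2), 0.50)
  expect_equal(shannon_entropy(future_law(c(1, 0))), 0)
  # bounds on random laws, equality cases at the extremes
  set.seed(11)
  for (k in c(2, 3, 5, 7)) {
    for (i in 1:20) {
      h <- shannon_entropy(future_law(random_law(k)))
      expect_gte(h, 0)
      expect_lte(h, log(k) + 1e-12)
    }
    expect_equal(shannon_entropy(future_law(rep(1 / k, k))), log(k))
  }
})

test_that("KL divergence is a divergence and matches the regime table cells", {
  u <- future_law(c(0.5, 0.5))
  expect_equal(kl_divergence(u, u), 0)
  expect_equal(round(kl_divergence(future_law(c(0.2, 0.8)), u), 2), 0.19)
  expect_equal(round(kl_divergence(future_law(c(1e-9, 1 - 1e-9)), u), 2), 0.69)
  # Gibbs inequality on random pairs: >= 0 with equality iff equal
  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    a <- random_law(k); b <- random_law(k)
    expect_gte(kl_divergence(future_law(a), future_law(b)), 0)
    expect_gt(kl_divergence(future_law(a), future_law(b)) +
                as.numeric(all(abs(a - b) < 1e-14)), 0)
    expect_equal(kl_divergence(future_law(a), future_law(a)), 0)
  }
})

test_that("KL enforces absolute continuity unless asked for Inf", {
  law <- future_law(c(0.5, 0.3, 0.2))
  base <- future_law(c(0.5, 0.5, 0))
  expect_error(kl_divergence(law, base), class = "cfgeom_support_error")
  expect_identical(kl_divergence(law, base, infinite = TRUE), Inf)
  # zero mass in the law where the baseline has none is fine
  expect_lt(kl_divergence(base, future_law(c(0.4, 0.4, 0.2))), Inf)
})

test_that("binary Fisher information matches 1/[p(1-p)] and the KL expansion", {
  expect_equal(fisher_binary(0.5), 4)
  expect_equal(fisher_binary(0.2), 6.25)
  expect_equal(fisher_binary(0.3), 1 / 0.21)
  expect_error(fisher_binary(0), class = "cfgeom_boundary_error")
  expect_error(fisher_binary(1), class = "cfgeom_boundary_error")
  # local quadratic expansion of KL: error shrinks with eps and is below
  # 1e-3 relative at eps = 1e-4
  for (p in seq(0.1, 0.9, by = 0.1)) {
    i_exact <- fisher_binary(p)
    err3 <- abs(fisher_from_kl(p, 1e-3) - i_exact)
    err4 <- abs(fisher_from_kl(p, 1e-4) - i_exact)
    expect_lt(err4, err3)
    expect_lt(err4 / i_exact, 1e-3)
  }
})

test_that("clip_probability clips and flags only boundary values", {
  out <- clip_probability(c(0, 0.5, 1, 1e-13))
  expect_equal(out$clipped, c(TRUE, FALSE, TRUE, TRUE))
  expect_true(all(out$p >= 1e-12 & out$p <= 1 - 1e-12))
})

test_that("Monte-Carlo Fisher matrix agrees with closed forms", {
  # binary outcome family in its mean parameter: closed form 1/[p(1-p)]
  bern <- list(
    sampler = function(theta, n) stats::rbinom(n, 1, theta[1]),
    logdensity = function(x, theta) x * log(theta[1]) + (1 - x) * log(1 - theta[1]))
  fit <- fisher_matrix_mc(bern$sampler, bern$logdensity, 0.2, n = 1e5, seed = 42)
  # 3 standard errors of the score-squared average at p = 0.2, n = 1e5
  se <- sqrt((0.2 * 25^2 + 0.8 * 1.5625^2 - 6.25^2) / 1e5)
  expect_lt(abs(fit$fisher[1, 1] - 6.25), 3 * se + 1e-3)
  expect_equal(fit$trace_value, fit$fisher[1, 1])
  expect_equal(fit$lambda_max, fit$fisher[1, 1])

  # K = 3 categorical in mean parameters (q1, q2):
  # g = diag(1/q1, 1/q2) + (1/q3) * ones
  q <- c(0.2, 0.3)
  cat3 <- list(
    sampler = function(theta, n)
      sample(1:3, n, replace = TRUE,
             prob = c(theta, 1 - sum(theta))),
    logdensity = function(x, theta) {
      p <- c(theta, 1 - sum(theta))
      log(p[x])
    })
  fit3 <- fisher_matrix_mc(cat3$sampler, cat3$logdensity, q, n = 2e5, seed = 7)
  g_true <- diag(1 / q) + 1 / (1 - sum(q))
  expect_lt(max(abs(fit3$fisher - g_true)), 0.05 * max(g_true))
  expect_gte(fit3$trace_value, fit3$lambda_max)
  expect_gte(fit3$lambda_max, 0)

  # unit-variance Gaussian location family: unit Fisher information
  gauss <- list(
    sampler = function(theta, n) stats::rnorm(n, mean = theta[1]),
    logdensity = function(x, theta) stats::dnorm(x, mean = theta[1], log = TRUE))
  fitg <- fisher_matrix_mc(gauss$sampler, gauss$logdensity, 0.3, n = 1e5, seed = 3)
  expect_lt(abs(fitg$fisher[1, 1] - 1), 0.03)
})

test_that("credible sets are canonical and minimal", {
  cs <- credible_set(future_law(c(0.7, 0.2, 0.1)), delta = 0.1)
  expect_equal(cs$member_indices, c(1L, 2L))
  expect_equal(cs$mass, 0.9)
  cs2 <- credible_set(future_law(c(0.7, 0.2, 0.1)), delta = 0.5)
  expect_equal(cs2$member_indices, 1L)
  expect_equal(cs2$mass, 0.7)
  cs3 <- credible_set(future_law(rep(0.25, 4)), delta = 1e-9)
  expect_equal(cs3$member_indices, 1:4)
  # ties broken by ascending index
  cs4 <- credible_set(future_law(c(0.3, 0.4, 0.3)), delta = 0.35)
  expect_equal(cs4$member_indices, c(1L, 2L))
  # exhaustive enumeration battery for all K <= 6
  set.seed(21)
  for (i in 1:60) {
    k <- sample(2:6, 1)
    q <- random_law(k)
    delta <- stats::runif(1, 0.02, 0.6)
    got <- credible_set(future_law(q), delta)
    oracle <- credible_set_oracle(q, delta)
    expect_equal(length(got$member_indices), oracle$cardinality)
    expect_gte(got$mass, 1 - delta - 1e-12)
  }
})

test_that("projection removes outcomes and renormalizes", {
  q <- future_law(c(0.5, 0.3, 0.2))
  expect_equal(op_project(q, c(1, 2))$probs, c(0.625, 0.375, 0))
  expect_equal(op_project(q, 1:3)$probs, q$probs)
  expect_equal(op_project(q, 2)$probs, c(0, 1, 0))
  expect_error(op_project(future_law(c(0.5, 0.5, 0)), 3),
               class = "cfgeom_degenerate_projection")
})

test_that("exponential tilting reweights by cost", {
  u <- future_law(c(0.5, 0.5))
  expect_equal(op_tilt(u, c(3, -1), gain = 0)$probs, u$probs)
  expect_equal(op_tilt(u, c(0, log(2)), gain = 1)$probs, c(2 / 3, 1 / 3))
  # gain -> Inf concentrates on the minimum-cost outcome
  lim <- op_tilt(future_law(c(0.2, 0.3, 0.5)), c(1, 0.2, 0.7), gain = 1e4)
  expect_equal(lim$probs, c(0, 1, 0), tolerance = 1e-10)
  # outputs remain valid laws on random inputs
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    out <- op_tilt(future_law(random_law(k)), stats::rnorm(k),
                   gain = stats::runif(1, 0, 5))
    expect_s3_class(out, "future_law")
    expect_equal(sum(out$probs), 1)
  }
})

test_that("intervention operators fail to commute except in nested cases", {
  q <- future_law(c(0.5, 0.3, 0.2))
  proj12 <- function(l) op_project(l, c(1, 2))
  proj1 <- function(l) op_project(l, 1)
  tilt3 <- function(l) op_tilt(l, c(0, 0, 2), gain = 1)
  expect_equal(ops_commutator(q, tilt3, tilt3), 0)
  # projecting away the costly outcome before vs after tilting differs
  expect_gt(ops_commutator(q, proj12, tilt3), 0)
  # nested projections commute
  expect_equal(ops_commutator(q, proj12, proj1), 0)
})

test_that("future laws round-trip through CSV and JSON", {
  q <- future_law(c(0.25, 0.5, 0.25), labels = c("x", "y", "z"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_future_law(q, csv)
  write_future_law(q, js)
  expect_equal(read_future_law(csv)$probs, q$probs)
  expect_equal(read_future_law(js)$probs, q$probs)
  expect_equal(read_future_law(js)$labels, c("x", "y", "z"))
})
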