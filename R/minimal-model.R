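#' Parameters of the minimal adversarial saddle-flow model
#'
#' The minimal model couples an Explorer, which adapts the binary future law
#' `q = (p, 1 - p)` to preserve diversity, and a Verifier, which adapts a
#' feasibility cost pair `c = (c1, c2)` to enforce constraints. Both act on the
#' shared payoff `L(q, c) = E_q[c + bias] - beta * H(q) - lam * (c1^2 + c2^2)`
#' by simultaneous descent (Explorer, via a replicator/mirror-descent flow on
#' the simplex) and ascent (Verifier).
#'
#' @param beta exploratory pressure, `> 0`: weight on the entropy bonus.
#' @param lam constraint regularization, `> 0`: quadratic penalty on `|c|`.
#' @param bias length-2 per-outcome cost offsets added to the constraint
#'   channel (biased constraints; default `c(0, 0)`).
#' @param dt integrator step in model time (default 0.01).
#' @param steps number of integration steps (default 20000).
#' @param p0 initial probability of future 1, strictly in (0, 1).
#' @param c0 initial feasibility cost pair.
#' @param noise_sd optional perturbation scale for stochastic forcing
#'   (default 0, deterministic). See [integrate_saddle()] for how noise enters.
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return object of class `minimal_model_params`.
#' @export
minimal_model_params <- function(beta = 0.5, lam = 0.5, bias = c(0, 0),
                                 dt = 0.01, steps = 20000L, p0 = 0.2,
                                 c0 = c(0, 0), noise_sd = 0, seed = 1L) {
  if (!is.numeric(beta) || beta <= 0) cf_stop("beta must be > 0", "cfgeom_invalid_argument")
  if (!is.numeric(lam) || lam <= 0) cf_stop("lam must be > 0", "cfgeom_invalid_argument")
  if (length(bias) != 2L || any(!is.finite(bias)))
    cf_stop("bias must be a finite length-2 vector", "cfgeom_invalid_argument")
  if (dt <= 0) cf_stop("dt must be > 0", "cfgeom_invalid_argument")
  if (p0 <= 0 || p0 >= 1) cf_stop("p0 must lie strictly in (0, 1)", "cfgeom_invalid_argument")
  if (length(c0) != 2L || any(!is.finite(c0)))
    cf_stop("c0 must be a finite length-2 vector", "cfgeom_invalid_argument")
  if (noise_sd < 0) cf_stop("noise_sd must be >= 0", "cfgeom_invalid_argument")
  structure(list(beta = beta, lam = lam, bias = as.numeric(bias), dt = dt,
                 steps = as.integer(steps), p0 = p0, c0 = as.numeric(c0),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "minimal_model_params")
}

#' Saddle state of the minimal model
#'
#' @param p probability of future 1, strictly in (0, 1) (after clipping).
#' @param c1,c2 feasibility costs of the two futures.
#' @return object of class `saddle_state` (named numeric vector).
#' @export
saddle_state <- function(p, c1, c2) {
  if (p <= 0 || p >= 1) cf_stop("p must lie strictly in (0, 1)", "cfgeom_boundary_error")
  structure(c(p = p, c1 = c1, c2 = c2), class = "saddle_state")
}

#' Adversarial payoff of the minimal model
#'
#' `L(q, c) = E_q[c + bias] - beta * H(q) - lam * (c1^2 + c2^2)` with
#' `q = (p, 1 - p)`. The Explorer descends L in `q` (entropy bonus), the
#' Verifier ascends it in `c` (cost enforcement, quadratically regularized).
#'
#' @param state a [saddle_state()] or numeric `(p, c1, c2)`.
#' @param params a [minimal_model_params()].
#' @return scalar payoff.
#' @export
saddle_payoff <- function(state, params) {
  s <- as.numeric(state)
  p <- s[1]; c1 <- s[2]; c2 <- s[3]
  q <- c(p, 1 - p)
  sum(q * (c(c1, c2) + params$bias)) - params$beta * shannon_entropy(future_law(q)) -
    params$lam * (c1^2 + c2^2)
}

# Core drift arithmetic, shared by the exported wrapper and the integrator.
# Explorer: replicator flow dp = -p(1-p) dL/dp; Verifier: plain ascent in c.
drift_core <- function(p, c1, c2, beta, lam, b1, b2) {
  c(-p * (1 - p) * ((c1 + b1) - (c2 + b2) + beta * log(p / (1 - p))),
    p - 2 * lam * c1,
    (1 - p) - 2 * lam * c2)
}

#' Saddle-flow drift of the minimal model
#'
#' The coupled descent-ascent vector field:
#' `dp/dt = -p(1-p) * [(c1 + b1) - (c2 + b2) + beta * log(p/(1-p))]`
#' (mirror-descent/replicator flow of the Explorer, so that the simplex is
#' invariant), `dc1/dt = p - 2 lam c1`, `dc2/dt = (1 - p) - 2 lam c2`
#' (gradient ascent of the Verifier). The entropy term is restoring: it pulls
#' `p` toward 1/2 with strength `beta`.
#'
#' @param state a [saddle_state()] or numeric `(p, c1, c2)`; `p` outside (0, 1)
#'   is clipped to the interior before evaluation.
#' @param params a [minimal_model_params()].
#' @return named numeric `(dp, dc1, dc2)`.
#' @export
saddle_drift <- function(state, params) {
  s <- as.numeric(state)
  p <- clip_probability(s[1])$p
  d <- drift_core(p, s[2], s[3], params$beta, params$lam,
                  params$bias[1], params$bias[2])
  stats::setNames(d, c("dp", "dc1", "dc2"))
}

#' Integrate the minimal adversarial model
#'
#' Fixed-step fourth-order Runge-Kutta over `steps * dt` model time.
#' After each step `p` is clipped to `[1e-12, 1 - 1e-12]` and the clip is
#' flagged. With `noise_sd > 0` an Euler-Maruyama perturbation is added each
#' step: on the `p`-channel the noise enters through the replicator
#' preconditioner `p (1 - p)` (i.e. additively in the payoff/logit channel, so
#' the simplex remains invariant in distribution); on the `c`-channels it is
#' additive. Deterministic given `params` (and `seed` when `noise_sd > 0`).
#'
#' @param params a [minimal_model_params()].
#' @return object of class `saddle_trajectory`: list with `times`, `p`, `c1`,
#'   `c2`, `clipped` (all length `steps + 1`) and the generating `params`.
#' @export
integrate_saddle <- function(params) {
  stopifnot(inherits(params, "minimal_model_params"))
  n <- params$steps
  dt <- params$dt
  beta <- params$beta; lam <- params$lam
  b1 <- params$bias[1]; b2 <- params$bias[2]
  p <- numeric(n + 1L); c1 <- numeric(n + 1L); c2 <- numeric(n + 1L)
  clipped <- logical(n + 1L)
  p[1L] <- params$p0; c1[1L] <- params$c0[1]; c2[1L] <- params$c0[2]
  eps <- 1e-12
  noisy <- params$noise_sd > 0
  sq <- params$noise_sd * sqrt(dt)
  run <- function() {
    s <- c(p[1L], c1[1L], c2[1L])
    for (i in seq_len(n)) {
      k1 <- drift_core(s[1], s[2], s[3], beta, lam, b1, b2)
      s2 <- s + dt / 2 * k1
      k2 <- drift_core(s2[1], s2[2], s2[3], beta, lam, b1, b2)
      s3 <- s + dt / 2 * k2
      k3 <- drift_core(s3[1], s3[2], s3[3], beta, lam, b1, b2)
      s4 <- s + dt * k3
      k4 <- drift_core(s4[1], s4[2], s4[3], beta, lam, b1, b2)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (noisy) {
        w <- stats::rnorm(3L)
        s[1] <- s[1] + sq * s[1] * (1 - s[1]) * w[1]
        s[2] <- s[2] + sq * w[2]
        s[3] <- s[3] + sq * w[3]
      }
      if (any(!is.finite(s)))
        cf_stop(sprintf("integration blew up at step %d", i), "cfgeom_blowup_error",
                step = i)
      if (s[1] < eps || s[1] > 1 - eps) {
        s[1] <- min(max(s[1], eps), 1 - eps)
        clipped[i + 1L] <<- TRUE
      }
      p[i + 1L] <<- s[1]; c1[i + 1L] <<- s[2]; c2[i + 1L] <<- s[3]
    }
  }
  if (noisy) with_seed(params$seed, run()) else run()
  structure(list(times = seq(0, by = dt, length.out = n + 1L),
                 p = p, c1 = c1, c2 = c2, clipped = clipped, params = params),
            class = "saddle_trajectory")
}

#' @export
print.saddle_trajectory <- function(x, ...) {
  cat(sprintf("<saddle_trajectory> %d steps, dt = %g, p in [%.4g, %.4g], %d clipped\n",
              length(x$times) - 1L, x$params$dt, min(x$p), max(x$p), sum(x$clipped)))
  invisible(x)
}

#' @export
as.data.frame.saddle_trajectory <- function(x, ...) {
  data.frame(time = x$times, p = x$p, c1 = x$c1, c2 = x$c2,
             clipped = as.integer(x$clipped))
}

#' Interior stationary point of the minimal model
#'
#' With unbiased constraints the flow has the interior stationary point
#' `p* = 1/2`, `c1* = c2* = 1 / (4 lam)`. An analytic solution is only
#' available for `bias = c(0, 0)`; nonzero bias errors.
#'
#' @param params a [minimal_model_params()] with zero bias.
#' @return a [saddle_state()].
#' @export
stationary_point <- function(params) {
  if (any(params$bias != 0))
    cf_stop("analytic stationary point requires zero bias",
            "cfgeom_unsupported_case")
  saddle_state(0.5, 1 / (4 * params$lam), 1 / (4 * params$lam))
}

#' Linearize the saddle flow at a state
#'
#' Numeric Jacobian of [saddle_drift()] by central differences (step `1e-6`),
#' with its eigenvalues and a flag for rotational (complex-eigenvalue)
#' structure. The saddle flow generically has rotational components -- there is
#' no Lyapunov potential -- in contrast to the symmetric Jacobian of a
#' single-objective gradient flow.
#'
#' @param state a [saddle_state()] or numeric `(p, c1, c2)` in the interior.
#' @param params a [minimal_model_params()].
#' @param h finite-difference step.
#' @return object of class `linearization_report`: list with `jacobian` (3x3),
#'   `eigenvalues` (complex triple, sorted by decreasing real part) and
#'   `rotational` (TRUE iff any eigenvalue has nonzero imaginary part).
#' @export
linearize_saddle <- function(state, params, h = 1e-6) {
  s <- as.numeric(state)
  J <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    up <- s; up[j] <- up[j] + h
    dn <- s; dn[j] <- dn[j] - h
    J[, j] <- (as.numeric(saddle_drift(up, params)) -
               as.numeric(saddle_drift(dn, params))) / (2 * h)
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(jacobian = J, eigenvalues = ev,
                 rotational = any(abs(Im(ev)) > 1e-9)),
            class = "linearization_report")
}

#' @export
print.linearization_report <- function(x, ...) {
  cat("<linearization_report> eigenvalues:",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "),
      if (x$rotational) "(rotational)" else "(non-rotational)", "\n")
  invisible(x)
}

#' Regime presets of the minimal model
#'
#' Documented parameter sets realizing the three generic regimes, all started
#' from `p0 = 0.2`:
#' \describe{
#'   \item{collapse}{weak exploratory pressure with biased constraints
#'     (`beta = 0.05`, `lam = 4`, `bias = c(0.5, 0)`): the future law is
#'     attracted to the simplex boundary, entropy is lost and Fisher
#'     sensitivity diverges.}
#'   \item{bounded}{intermediate symmetric parameters (`beta = 0.5`,
#'     `lam = 0.5`, zero bias): the future law stays interior with bounded
#'     diversity and sensitivity.}
#'   \item{runaway}{weak constraint regularization with large initial costs
#'     (`beta = 0.1`, `lam = 0.02`, `c0 = c(5, -5)`): transient near-boundary
#'     excursions generate extreme sensitivity spikes with repeated interior
#'     re-entry, without permanent collapse.}
#' }
#'
#' @param regime one of `"collapse"`, `"bounded"`, `"runaway"`.
#' @param ... overrides passed to [minimal_model_params()] (e.g. `noise_sd`,
#'   `seed`, `steps`).
#' @return a [minimal_model_params()].
#' @export
minimal_preset <- function(regime = c("collapse", "bounded", "runaway"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    collapse = list(beta = 0.05, lam = 4,    bias = c(0.5, 0), c0 = c(0, 0)),
    bounded  = list(beta = 0.5,  lam = 0.5,  bias = c(0, 0),   c0 = c(0, 0)),
    runaway  = list(beta = 0.1,  lam = 0.02, bias = c(0, 0),   c0 = c(5, -5)))
  args <- utils::modifyList(c(base, list(p0 = 0.2)), list(...))
  do.call(minimal_model_params, args)
}

#' Single-objective gradient-flow baseline
#'
#' Explicit-Euler gradient descent `theta <- theta - step * grad V(theta)` on a
#' scalar potential. Its potential trace is monotone nonincreasing (V is a
#' Lyapunov function) and its Jacobian, a negated Hessian, is symmetric with
#' all-real eigenvalues: the contrast with the rotational, non-convergent
#' saddle flow is the point of the baseline.
#'
#' @param potential function `theta -> scalar`.
#' @param theta0 numeric start.
#' @param step Euler step size.
#' @param iters iteration count.
#' @param grad optional analytic gradient `theta -> vector`; central finite
#'   differences (step `1e-6`) otherwise.
#' @return list with `theta` (iters+1 x d matrix of iterates) and `potential`
#'   (numeric trace).
#' @export
gradient_flow_baseline <- function(potential, theta0, step = 0.01, iters = 1000L,
                                   grad = NULL) {
  d <- length(theta0)
  if (is.null(grad)) {
    h <- 1e-6
    grad <- function(th) {
      g <- numeric(d)
      for (j in seq_len(d)) {
        up <- th; up[j] <- up[j] + h
        dn <- th; dn[j] <- dn[j] - h
        g[j] <- (potential(up) - potential(dn)) / (2 * h)
      }
      g
    }
  }
  th <- matrix(NA_real_, iters + 1L, d)
  v <- numeric(iters + 1L)
  th[1L, ] <- theta0
  v[1L] <- potential(theta0)
  if (!is.finite(v[1L]))
    cf_stop("potential not finite at the start", "cfgeom_invalid_argument")
  cur <- as.numeric(theta0)
  for (i in seq_len(iters)) {
    cur <- cur - step * grad(cur)
    vi <- potential(cur)
    if (any(!is.finite(cur)) || !is.finite(vi))
      cf_stop(sprintf("gradient descent diverged at iteration %d", i),
              "cfgeom_blowup_error", step = i)
    th[i + 1L, ] <- cur
    v[i + 1L] <- vi
  }
  list(theta = th, potential = v)
}
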