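#' Configuration of the resource-selection adversarial simulator
#'
#' A one-dimensional adversarial game over future endpoints: an affine-Gaussian
#' generator proposes endpoints `x = mu + sigma * xi`, `xi ~ N(0, 1)`, while a
#' logistic discriminator with features `(1, x, x^2)` learns to distinguish
#' them from an environment-selected reference distribution with density
#' proportional to `exp(-cost(x) / r)`, where `cost` is the feasibility cost
#' and `r` a bounded resource gating the selection temperature. The generator
#' is rewarded for diverse futures that evade selection; the discriminator
#' sharpens feasibility constraints. No single scalar objective governs the
#' joint dynamics.
#'
#' @param feasibility_pressure weight on the generator's mean feasibility cost.
#' @param diversity_pressure weight on the generator's batch-entropy bonus
#'   (implemented as `log sigma`, the Gaussian entropy up to a constant).
#' @param resource_max resource cap `r_max`; the resource lives in
#'   `(0, r_max]`.
#' @param resource_recovery relaxation rate of the resource toward `r_max`.
#' @param resource_drain drain rate proportional to feasibility cost plus
#'   gradient activity.
#' @param feasible_halfwidth `a`: endpoints with `|x| <= a` are feasible.
#' @param batch samples per optimization step (`>= 16`).
#' @param steps optimization steps.
#' @param learn_rate_gen,learn_rate_disc step sizes of the two players.
#' @param checkpoint_every record diagnostics every this many steps.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return object of class `gan_config`.
#' @export
gan_config <- function(feasibility_pressure = 1, diversity_pressure = 0.5,
                       resource_max = 1, resource_recovery = 0.05,
                       resource_drain = 0.01, feasible_halfwidth = 2,
                       batch = 64L, steps = 600L, learn_rate_gen = 0.05,
                       learn_rate_disc = 0.1, checkpoint_every = 50L,
                       seed = 1L) {
  vals <- c(feasibility_pressure, resource_max,
            resource_recovery, resource_drain, feasible_halfwidth,
            learn_rate_gen, learn_rate_disc)
  if (any(!is.finite(vals)) || any(vals <= 0))
    cf_stop("all pressures, rates and bounds must be positive",
            "cfgeom_invalid_argument")
  if (!is.finite(diversity_pressure) || diversity_pressure < 0)
    cf_stop("diversity_pressure must be >= 0", "cfgeom_invalid_argument")
  if (batch < 16L) cf_stop("batch must be >= 16", "cfgeom_invalid_argument")
  structure(list(feasibility_pressure = feasibility_pressure,
                 diversity_pressure = diversity_pressure,
                 resource_max = resource_max,
                 resource_recovery = resource_recovery,
                 resource_drain = resource_drain,
                 feasible_halfwidth = feasible_halfwidth,
                 batch = as.integer(batch), steps = as.integer(steps),
                 learn_rate_gen = learn_rate_gen,
                 learn_rate_disc = learn_rate_disc,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Regime presets of the resource-selection simulator
#'
#' \describe{
#'   \item{collapse}{strong feasibility pressure, weak diversity pressure:
#'     generated futures concentrate narrowly well inside the feasible region
#'     (mode collapse).}
#'   \item{bounded}{balanced pressures: endpoint distributions stay broad yet
#'     feasible.}
#'   \item{runaway}{weak feasibility pressure, strong diversity pressure:
#'     diversity overwhelms constraint and probability mass is driven beyond
#'     the feasibility boundary.}
#' }
#'
#' @param regime one of `"collapse"`, `"bounded"`, `"runaway"`.
#' @param ... overrides passed to [gan_config()] (e.g. `seed`, `steps`).
#' @return a [gan_config()].
#' @export
gan_preset <- function(regime = c("collapse", "bounded", "runaway"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    collapse = list(feasibility_pressure = 5, diversity_pressure = 0.01,
                    resource_recovery = 0.002, resource_drain = 0.2),
    bounded  = list(feasibility_pressure = 1, diversity_pressure = 0.2,
                    resource_recovery = 0.05, resource_drain = 0.05),
    runaway  = list(feasibility_pressure = 0.005, diversity_pressure = 4,
                    resource_recovery = 0.05, resource_drain = 0.005))
  do.call(gan_config, utils::modifyList(base, list(...)))
}

#' Generator/discriminator/resource state
#'
#' @param mu,log_sigma affine generator parameters (`x = mu + sigma * xi`).
#' @param disc logistic discriminator weights on features `(1, x, x^2)`.
#' @param resource current resource level in `(0, r_max]`.
#' @return object of class `gan_state`.
#' @export
gan_state <- function(mu = 0, log_sigma = 0, disc = c(0, 0, 0), resource = 1) {
  if (length(disc) != 3L) cf_stop("disc needs 3 weights", "cfgeom_invalid_argument")
  if (resource <= 0) cf_stop("resource must be positive", "cfgeom_invalid_argument")
  structure(list(mu = mu, log_sigma = log_sigma, disc = as.numeric(disc),
                 resource = resource), class = "gan_state")
}

#' @export
print.gan_state <- function(x, ...) {
  cat(sprintf("<gan_state> mu = %.4g, sigma = %.4g, resource = %.4g\n",
              x$mu, exp(x$log_sigma), x$resource))
  invisible(x)
}

#' Feasibility cost of a future endpoint
#'
#' Zero inside the feasible interval, quadratic outside:
#' `max(0, |x| - a)^2` with `a = feasible_halfwidth`.
#'
#' @param x numeric endpoints.
#' @param feasible_halfwidth the feasibility bound `a`.
#' @return non-negative costs, same length as `x`.
#' @export
feasibility_cost <- function(x, feasible_halfwidth = 2) {
  if (any(!is.finite(x))) cf_stop("endpoints must be finite", "cfgeom_invalid_argument")
  pmax(0, abs(x) - feasible_halfwidth)^2
}

#' Sample future endpoints from the generator
#'
#' `x = mu + sigma * xi` with `xi ~ N(0, 1)`; reproducible given `seed`.
#'
#' @param state a [gan_state()].
#' @param n number of endpoints.
#' @param seed optional RNG seed.
#' @return numeric vector of endpoints.
#' @export
sample_futures <- function(state, n, seed = NULL) {
  stopifnot(inherits(state, "gan_state"))
  with_seed(seed, state$mu + exp(state$log_sigma) * stats::rnorm(n))
}

# Exact sampler for the resource-gated reference density ~ exp(-cost(x)/r):
# uniform on [-a, a] (mass 2a) plus half-normal tails of scale sqrt(r/2)
# (mass sqrt(pi r) / 2 each).
sample_reference <- function(n, a, r) {
  tail_mass <- sqrt(pi * r) / 2
  p_in <- 2 * a / (2 * a + 2 * tail_mass)
  inside <- stats::runif(n) < p_in
  x <- numeric(n)
  x[inside] <- stats::runif(sum(inside), -a, a)
  k <- sum(!inside)
  if (k > 0) {
    y <- abs(stats::rnorm(k, sd = sqrt(r / 2)))
    x[!inside] <- (a + y) * sample(c(-1, 1), k, replace = TRUE)
  }
  x
}

#' Train the resource-selection adversarial simulator
#'
#' Alternating stochastic gradient steps. Each step:
#' \enumerate{
#'   \item the discriminator ascends the logistic real-vs-generated objective,
#'     "real" samples drawn from the resource-gated reference density
#'     proportional to `exp(-cost(x) / r)` (depleted resource = colder, more
#'     selective environment);
#'   \item the generator descends the saturating evasion loss
#'     `mean(log(1 - D(x)))` plus `feasibility_pressure` times the mean
#'     resource-gated cost, minus `diversity_pressure * log sigma` (the
#'     Gaussian batch-entropy bonus up to a constant). The generator's cost
#'     term uses the gated halfwidth `a * r / r_max`: a depleted resource
#'     narrows the region within which feasibility can be maintained. The
#'     saturating evasion loss means selection exerts vanishing force on
#'     endpoints the discriminator already confidently rejects -- which is
#'     precisely how runaway mass escapes selection;
#'   \item the resource drains with activity (mean gated cost plus gradient
#'     magnitudes) and recovers toward `resource_max`, clipped to
#'     `[1e-3, resource_max]`.
#' }
#' `log sigma` is kept in `[-8, 8]` and per-parameter generator gradients are
#' clipped to `[-50, 50]` to bound the parameter space.
#'
#' @param config a [gan_config()].
#' @param init optional initial [gan_state()].
#' @return object of class `gan_trace`: list with `state` (final
#'   [gan_state()]), `checkpoints` (data.frame of per-checkpoint parameters,
#'   resource and diagnostics), `resource` (per-step series) and `config`.
#' @export
train_gan <- function(config, init = gan_state(resource = config$resource_max)) {
  stopifnot(inherits(config, "gan_config"))
  with_seed(config$seed, train_gan_loop(config, init))
}

train_gan_loop <- function(config, init, steps = config$steps,
                           record = TRUE) {
  a <- config$feasible_halfwidth
  fp <- config$feasibility_pressure
  dp <- config$diversity_pressure
  mu <- init$mu; ls <- init$log_sigma; w <- init$disc; r <- init$resource
  resource <- numeric(steps)
  cks <- list()
  for (step in seq_len(steps)) {
    sig <- exp(ls)
    xi <- stats::rnorm(config$batch)
    x <- mu + sig * xi
    xr <- sample_reference(config$batch, a, r)
    # discriminator ascent on logistic real-vs-generated log-likelihood
    phi_r <- cbind(1, xr, xr^2)
    phi_f <- cbind(1, x, x^2)
    d_r <- stats::plogis(phi_r %*% w)
    d_f <- stats::plogis(phi_f %*% w)
    gw <- colMeans(phi_r * as.numeric(1 - d_r)) - colMeans(phi_f * as.numeric(d_f))
    w <- w + config$learn_rate_disc * gw
    # generator descent: saturating evasion + resource-gated feasibility
    # - diversity bonus
    a_gated <- a * r / config$resource_max
    d_f2 <- as.numeric(stats::plogis(cbind(1, x, x^2) %*% w))
    dldx <- -d_f2 * (w[2] + 2 * w[3] * x) +
      fp * 2 * pmax(0, abs(x) - a_gated) * sign(x)
    g_mu <- min(max(mean(dldx), -50), 50)
    g_ls <- min(max(mean(dldx * sig * xi) - dp, -50), 50)
    mu <- mu - config$learn_rate_gen * g_mu
    ls <- min(max(ls - config$learn_rate_gen * g_ls, -8), 8)
    # resource: recovery toward the cap, drain with activity
    activity <- mean(feasibility_cost(x, a_gated)) + abs(g_mu) + abs(g_ls) +
      sum(abs(gw))
    r <- r + config$resource_recovery * (config$resource_max - r) -
      config$resource_drain * activity
    r <- min(max(r, 1e-3), config$resource_max)
    if (any(!is.finite(c(mu, ls, w, r))))
      cf_stop(sprintf("adversarial training diverged at step %d", step),
              "cfgeom_blowup_error", step = step)
    resource[step] <- r
    if (record && (step %% config$checkpoint_every == 0L || step == steps)) {
      st <- gan_state(mu, ls, w, r)
      diag <- finite_sample_diagnostics(st, n = 1000L,
                                        feasible_halfwidth = a,
                                        measure_recovery = FALSE)
      cks[[length(cks) + 1L]] <- data.frame(
        checkpoint = step, mu = mu, sigma = exp(ls), resource = r,
        diversity = diag$diversity, entropy_proxy = diag$entropy_proxy,
        sensitivity_amplification = diag$sensitivity_amplification,
        boundary_residence = diag$boundary_residence,
        mean_feasibility_cost = diag$mean_feasibility_cost)
    }
  }
  structure(list(state = gan_state(mu, ls, w, r),
                 checkpoints = if (record) do.call(rbind, cks) else NULL,
                 resource = resource, config = config),
            class = "gan_trace")
}

#' @export
print.gan_trace <- function(x, ...) {
  cat(sprintf("<gan_trace> %d steps; final mu = %.4g, sigma = %.4g, resource = %.4g\n",
              x$config$steps, x$state$mu, exp(x$state$log_sigma),
              x$state$resource))
  invisible(x)
}

# Histogram plug-in differential entropy with Freedman-Diaconis bins.
# Returns list(value, degenerate): on a degenerate histogram (zero IQR) falls
# back to the Gaussian entropy implied by the sample variance, flagged.
histogram_entropy <- function(x) {
  iqr <- stats::IQR(x)
  v <- stats::var(x)
  if (iqr <= 0 || v <= 0) {
    val <- if (v > 0) 0.5 * log(2 * pi * exp(1) * v) else -Inf
    return(list(value = val, degenerate = TRUE))
  }
  width <- 2 * iqr * length(x)^(-1 / 3)
  breaks <- seq(min(x) - width / 2, max(x) + width, by = width)
  counts <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L)
  p <- counts[counts > 0] / length(x)
  list(value = -sum(p * log(p)) + log(width), degenerate = FALSE)
}

#' Finite-sample diagnostics of a generator state
#'
#' Table-style diagnostics computed purely from generated samples:
#' \itemize{
#'   \item `diversity`: unbiased variance of the endpoints;
#'   \item `entropy_proxy`: histogram plug-in differential entropy
#'     (Freedman-Diaconis bins; Gaussian fallback with a flag when the
#'     histogram degenerates);
#'   \item `sensitivity_amplification`: RMS endpoint change per unit latent
#'     perturbation, `RMS[G(xi + delta_z) - G(xi)] / delta_z` (equals `sigma`
#'     exactly for the affine generator);
#'   \item `boundary_residence`: fraction of endpoints outside the feasible
#'     interval;
#'   \item `mean_feasibility_cost`: average [feasibility_cost()];
#'   \item `recovery_time`: optimizer steps after a documented impulse
#'     (`mu <- mu + 5 a`) until the mean endpoint, diversity, boundary
#'     residence and mean feasibility cost simultaneously re-enter 20% bands
#'     around their pre-impulse values. The bands are evaluated on the exact
#'     moments of the affine-Gaussian generator (so the check is free of
#'     sampling noise); zero references use absolute floors (0.1 a for the
#'     mean, 0.05 for residence, 0.1 for cost). Requires `config` and further
#'     (unrecorded) training, capped at `recovery_max_steps`.
#' }
#'
#' @param state a [gan_state()].
#' @param n sample count (`>= 100`).
#' @param seed optional RNG seed.
#' @param delta_z latent perturbation magnitude (default 0.1).
#' @param feasible_halfwidth feasibility bound `a`.
#' @param measure_recovery also measure `recovery_time` (needs `config`).
#' @param config the [gan_config()] used for recovery training.
#' @param recovery_max_steps cap on the recovery measurement.
#' @return object of class `sample_diagnostics` (list of the fields above,
#'   plus `entropy_degenerate`).
#' @export
finite_sample_diagnostics <- function(state, n = 1000L, seed = NULL,
                                      delta_z = 0.1, feasible_halfwidth = 2,
                                      measure_recovery = FALSE, config = NULL,
                                      recovery_max_steps = 500L) {
  stopifnot(inherits(state, "gan_state"))
  if (n < 100L) cf_stop("diagnostics need n >= 100 samples", "cfgeom_invalid_argument")
  res <- with_seed(seed, {
    xi <- stats::rnorm(n)
    sig <- exp(state$log_sigma)
    x <- state$mu + sig * xi
    x_shift <- state$mu + sig * (xi + delta_z)
    ent <- histogram_entropy(x)
    costs <- feasibility_cost(x, feasible_halfwidth)
    list(
      diversity = stats::var(x),
      entropy_proxy = ent$value,
      entropy_degenerate = ent$degenerate,
      sensitivity_amplification = sqrt(mean((x_shift - x)^2)) / delta_z,
      boundary_residence = mean(abs(x) > feasible_halfwidth),
      mean_feasibility_cost = mean(costs),
      recovery_time = NA_real_)
  })
  if (measure_recovery) {
    if (is.null(config))
      cf_stop("recovery_time needs the training config", "cfgeom_invalid_argument")
    res$recovery_time <- with_seed(seed, measure_recovery_time(
      state, config, recovery_max_steps))
  }
  structure(res, class = "sample_diagnostics")
}

#' @export
print.sample_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("<sample_diagnostics> Var = %.4g, H = %.4g, RMS/dz = %.4g, ",
                     "residence = %.3f, cost = %.4g, recovery = %s\n"),
              x$diversity, x$entropy_proxy, x$sensitivity_amplification,
              x$boundary_residence, x$mean_feasibility_cost,
              format(x$recovery_time)))
  invisible(x)
}

# Exact endpoint moments of the affine-Gaussian generator: mean, variance,
# P(|x| > a) and E[(|x| - a)+^2] in closed form.
gaussian_endpoint_moments <- function(mu, sigma, a) {
  z1 <- (a - mu) / sigma
  z2 <- (a + mu) / sigma
  tail2 <- function(z) (1 + z^2) * stats::pnorm(-z) - z * stats::dnorm(z)
  list(mean = mu, diversity = sigma^2,
       residence = stats::pnorm(-z1) + stats::pnorm(-z2),
       cost = sigma^2 * (tail2(z1) + tail2(z2)))
}

# Impulse-recovery protocol: displace mu by 5a, keep training (unrecorded),
# and count steps until the mean endpoint, diversity, residence and mean cost
# are all back inside 20% bands of their pre-impulse values. Bands are checked
# on the exact generator moments so the stopping rule carries no sampling
# noise; zero references use absolute floors (0.1 a mean, 0.05 residence,
# 0.1 cost).
measure_recovery_time <- function(state, config, max_steps) {
  a <- config$feasible_halfwidth
  ref <- gaussian_endpoint_moments(state$mu, exp(state$log_sigma), a)
  st <- gan_state(state$mu + 5 * a, state$log_sigma, state$disc, state$resource)
  mean_band <- max(0.2 * abs(ref$mean), 0.1 * a)
  res_band <- max(0.2 * ref$residence, 0.05)
  cost_band <- max(0.2 * ref$cost, 0.1)
  for (step in seq_len(max_steps)) {
    tr <- train_gan_loop(config, st, steps = 1L, record = FALSE)
    st <- tr$state
    cur <- gaussian_endpoint_moments(st$mu, exp(st$log_sigma), a)
    if (abs(cur$mean - ref$mean) <= mean_band &&
        cur$diversity >= 0.8 * ref$diversity &&
        cur$diversity <= 1.2 * ref$diversity &&
        abs(cur$residence - ref$residence) <= res_band &&
        abs(cur$cost - ref$cost) <= cost_band)
      return(step)
  }
  max_steps
}
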