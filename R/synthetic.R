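#' Specification of a synthetic perturbation-response fixture
#'
#' Describes an ensemble of perturbation-response trials emulating the three
#' dynamical regimes. Trials follow `z(t) = g_i * u_i * h(t) + e_i(t)` where
#' `u_i ~ N(0, u_sd^2)` is the trial's perturbation, `g_i` a per-trial gain,
#' `h(t)` a regime-dependent response kernel and `e_i(t)` AR(1) noise:
#' \describe{
#'   \item{collapse}{fast monotone kernel `exp(-3 t)`, low gain (`0.3 * gain`)
#'     with shrinking trial-to-trial gain dispersion and weak noise.}
#'   \item{bounded}{damped-oscillatory kernel `exp(-t) cos(2 pi t / 1.5)`,
#'     unit gain with moderate dispersion and noise.}
#'   \item{runaway}{prolonged erratic kernel -- a slowly growing envelope
#'     `exp(0.4 t)` modulating a trial-randomized phase oscillation -- with
#'     amplifying gain (`3 * gain`), large dispersion and strong noise.}
#' }
#'
#' @param regime `"collapse"`, `"bounded"`, `"runaway"`, or `"linear"` for a
#'   pure linear-gain design `z = g * u * h(t)` with `h == 1` at the peak
#'   (used for gain-recovery checks).
#' @param n_trials number of trials (`>= 2`).
#' @param noise_sd AR(1) innovation scale (`>= 0`).
#' @param gain baseline gain `g`.
#' @param u_sd perturbation scale.
#' @param n_time time points on `[0, t_max]`.
#' @param t_max length of the observation window (model time).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(regime = c("bounded", "collapse", "runaway", "linear"),
                         n_trials = 200L, noise_sd = 0.05, gain = 1,
                         u_sd = 1, n_time = 81L, t_max = 4) {
  regime <- match.arg(regime)
  if (n_trials < 2L) cf_stop("n_trials must be >= 2", "cfgeom_invalid_argument")
  if (noise_sd < 0) cf_stop("noise_sd must be >= 0", "cfgeom_invalid_argument")
  structure(list(regime = regime, n_trials = as.integer(n_trials),
                 noise_sd = noise_sd, gain = gain, u_sd = u_sd,
                 n_time = as.integer(n_time), t_max = t_max),
            class = "fixture_spec")
}

#' Generate a synthetic perturbation-response ensemble
#'
#' Draws an ensemble from a [fixture_spec()]; deterministic given `seed`.
#'
#' @param spec a [fixture_spec()].
#' @param seed RNG seed.
#' @return a [pr_ensemble()].
#' @export
make_ensemble <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(seed, {
    n <- spec$n_trials
    times <- seq(0, spec$t_max, length.out = spec$n_time)
    u <- stats::rnorm(n, sd = spec$u_sd)
    ar1 <- function(m, sd, rho = 0.8) {
      e <- matrix(stats::rnorm(m * length(times), sd = sd), m)
      if (length(times) > 1L)
        for (j in 2:length(times)) e[, j] <- rho * e[, j - 1L] + e[, j]
      e
    }
    z <- switch(spec$regime,
      linear = {
        h <- rep(1, length(times))
        g <- rep(spec$gain, n)
        g * u %o% h + ar1(n, spec$noise_sd)
      },
      collapse = {
        h <- exp(-3 * times)
        # dispersion shrinks over the trial sequence: late trials are nearly
        # identical copies of the mean response
        g <- spec$gain * 0.3 * (1 + 0.2 * exp(-seq_len(n) / (n / 4)) * stats::rnorm(n))
        g * u %o% h + ar1(n, 0.2 * spec$noise_sd, rho = 0.5)
      },
      bounded = {
        h <- exp(-times) * cos(2 * pi * times / 1.5)
        g <- spec$gain * (1 + 0.15 * stats::rnorm(n))
        g * u %o% h + ar1(n, spec$noise_sd)
      },
      runaway = {
        g <- spec$gain * 3 * (1 + 0.5 * stats::rnorm(n))
        phase <- stats::runif(n, 0, 2 * pi)
        env <- exp(0.4 * times)
        z <- matrix(0, n, length(times))
        for (i in seq_len(n))
          z[i, ] <- g[i] * u[i] * env * cos(2 * pi * times / 2 + phase[i])
        z + ar1(n, 4 * spec$noise_sd)
      })
    pr_ensemble(u, z, times = times, condition_id = rep(spec$regime, n))
  })
}

#' Perturbation-response ensembles from the minimal-model presets
#'
#' Builds an observable ensemble for each minimal-model regime by applying a
#' small impulse perturbation `u_i ~ N(0, impulse_sd^2)` to the initial
#' constraint `c1(0)` of the preset, integrating, and recording as the
#' response the deviation `z_i(t) = p_i(t) - p_ref(t)` of the perturbed
#' probability series from the unperturbed preset trajectory. Proxies computed
#' on these ensembles discriminate the regimes from observations alone.
#'
#' @param regime `"collapse"`, `"bounded"` or `"runaway"`.
#' @param n_trials number of perturbed integrations.
#' @param impulse_sd perturbation scale on `c1(0)` (default 0.05).
#' @param steps integration steps per trial (default 4000; shorter than the
#'   preset default to keep ensemble generation fast).
#' @param seed RNG seed.
#' @return a [pr_ensemble()] with one row per trial.
#' @export
make_preset_ensemble <- function(regime, n_trials = 20L, impulse_sd = 0.05,
                                 steps = 4000L, seed = 1L) {
  with_seed(seed, {
    base <- minimal_preset(regime, steps = steps)
    ref <- integrate_saddle(base)
    u <- stats::rnorm(n_trials, sd = impulse_sd)
    z <- matrix(0, n_trials, steps + 1L)
    for (i in seq_len(n_trials)) {
      pert <- minimal_preset(regime, steps = steps,
                             c0 = base$c0 + c(u[i], 0))
      z[i, ] <- integrate_saddle(pert)$p - ref$p
    }
    pr_ensemble(u, z, times = ref$times, condition_id = rep(regime, n_trials))
  })
}
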