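#' Per-time geometric series of a trajectory
#'
#' Evaluates the three geometric observables along a trajectory's binary future
#' law `q(t) = (p(t), 1 - p(t))`: Shannon entropy `H(q)`, divergence
#' `KL(q || q0)` from the uniform baseline `q0 = (1/2, 1/2)`, and Fisher
#' sensitivity `I(p) = 1/[p(1-p)]`. `p` is clipped to `[1e-12, 1 - 1e-12]`
#' before the boundary-divergent Fisher evaluation; integrator clip flags are
#' propagated.
#'
#' @param traj a `saddle_trajectory` from [integrate_saddle()], or a numeric
#'   probability series.
#' @return data.frame with columns `time`, `p`, `entropy`, `kl`, `fisher`,
#'   `clipped`.
#' @export
regime_series <- function(traj) {
  if (inherits(traj, "saddle_trajectory")) {
    p <- traj$p; times <- traj$times; clipped <- traj$clipped
  } else {
    p <- as.numeric(traj)
    times <- seq_along(p) - 1
    clipped <- rep(FALSE, length(p))
  }
  if (length(p) == 0L) cf_stop("empty trajectory", "cfgeom_invalid_argument")
  cl <- clip_probability(p)
  data.frame(time = times, p = p,
             entropy = binary_entropy(cl$p),
             kl = binary_kl_uniform(cl$p),
             fisher = fisher_binary(cl$p),
             clipped = clipped | cl$clipped)
}

#' Summarize a trajectory into regime diagnostics
#'
#' Computes the extrema of the trajectory's probability, entropy, KL-from-
#' uniform and (clipped) Fisher series, the boundary time fraction -- the
#' fraction of steps with `min(p, 1-p) < band` -- and auxiliary evidence used
#' by [classify_regime()]: the mean entropy over the terminal window, the split
#' of boundary residence between the two simplex faces, and the number of
#' interior re-entries (boundary-band exits).
#'
#' @param traj a `saddle_trajectory` or numeric probability series.
#' @param band boundary band half-width (default 0.05).
#' @param terminal_window fraction of the series treated as terminal
#'   (default 0.1).
#' @return object of class `regime_diagnostics`: list with `min_p`, `max_p`,
#'   `min_H`, `max_H`, `max_KL`, `max_I`, `boundary_fraction`, `band`,
#'   `terminal_H`, `lower_fraction`, `upper_fraction`, `reentries`, `n_steps`.
#' @export
summarize_trajectory <- function(traj, band = 0.05, terminal_window = 0.1) {
  if (band <= 0 || band >= 0.5)
    cf_stop("band must lie in (0, 0.5)", "cfgeom_invalid_argument")
  ser <- regime_series(traj)
  p <- ser$p
  n <- length(p)
  near <- pmin(p, 1 - p) < band
  tail_idx <- seq.int(max(1L, n - ceiling(terminal_window * n) + 1L), n)
  exits <- if (n > 1L) sum(near[-n] & !near[-1L]) else 0L
  structure(list(
    min_p = min(p), max_p = max(p),
    min_H = min(ser$entropy), max_H = max(ser$entropy),
    max_KL = max(ser$kl), max_I = max(ser$fisher),
    boundary_fraction = mean(near), band = band,
    terminal_H = mean(ser$entropy[tail_idx]),
    lower_fraction = mean(near & p < 0.5),
    upper_fraction = mean(near & p >= 0.5),
    reentries = exits,
    n_steps = n
  ), class = "regime_diagnostics")
}

#' @export
print.regime_diagnostics <- function(x, ...) {
  # report rounded to 2 decimals, mirroring the package's summary tables;
  # raw values stay in the object / JSON
  cat("<regime_diagnostics>\n")
  cat(sprintf("  p in [%.2f, %.2f], H in [%.2f, %.2f] nats\n",
              x$min_p, x$max_p, x$min_H, x$max_H))
  cat(sprintf("  max KL = %.2f nats, max I = %.4g, boundary fraction = %.2f (band %.2f)\n",
              x$max_KL, x$max_I, x$boundary_fraction, x$band))
  invisible(x)
}

#' Rule-based regime classification
#'
#' Maps [summarize_trajectory()] diagnostics to one of the three generic
#' regimes, with an explicit `"ambiguous"` output when evidence straddles the
#' thresholds (never a silent misclassification):
#' \itemize{
#'   \item \strong{collapse}: terminal-window entropy below `eps_H`, boundary
#'     fraction above 0.5, residence one-sided (mass pinned to a single face).
#'   \item \strong{runaway}: peak Fisher sensitivity above `I_big` with at
#'     least one interior re-entry (excursions, not permanent collapse).
#'   \item \strong{bounded}: otherwise, provided the boundary fraction is
#'     below `eps_b` and the terminal entropy is not collapsed.
#' }
#'
#' @param diag a `regime_diagnostics` object.
#' @param eps_H terminal-entropy collapse threshold in nats (default 0.05).
#' @param I_big Fisher-amplification threshold (default `1e3`).
#' @param eps_b boundary-fraction threshold for the bounded call (default 0.05).
#' @return object of class `regime_call`: list with `label` in
#'   `{"collapse", "bounded", "runaway", "ambiguous"}` and `evidence`, the
#'   per-rule scores behind the call.
#' @export
classify_regime <- function(diag, eps_H = 0.05, I_big = 1e3, eps_b = 0.05) {
  stopifnot(inherits(diag, "regime_diagnostics"))
  side <- max(diag$lower_fraction, diag$upper_fraction)
  one_sided <- diag$boundary_fraction == 0 ||
    side / diag$boundary_fraction > 0.9
  evidence <- list(
    terminal_H = diag$terminal_H,
    boundary_fraction = diag$boundary_fraction,
    one_sided = one_sided,
    max_I = diag$max_I,
    reentries = diag$reentries,
    thresholds = list(eps_H = eps_H, I_big = I_big, eps_b = eps_b)
  )
  label <-
    if (diag$terminal_H < eps_H && diag$boundary_fraction > 0.5 && one_sided) {
      "collapse"
    } else if (diag$max_I > I_big && diag$reentries >= 1L) {
      "runaway"
    } else if (diag$boundary_fraction < eps_b && diag$terminal_H >= eps_H) {
      "bounded"
    } else {
      "ambiguous"
    }
  structure(list(label = label, evidence = evidence), class = "regime_call")
}

#' @export
print.regime_call <- function(x, ...) {
  cat(sprintf("<regime_call> %s (terminal H = %.3g, boundary fraction = %.2f, max I = %.3g, reentries = %d)\n",
              x$label, x$evidence$terminal_H, x$evidence$boundary_fraction,
              x$evidence$max_I, x$evidence$reentries))
  invisible(x)
}
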