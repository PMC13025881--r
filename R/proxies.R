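#' Perturbation-response ensemble
#'
#' Repeated trials of a perturbation `u` applied to a system and an observed
#' response time series `z(t)` on a shared grid. This is the observable object
#' from which the operational regime proxies are estimated: no access to the
#' underlying future distribution is required.
#'
#' @param perturbations numeric vector, one perturbation magnitude per trial.
#' @param responses numeric matrix, one row per trial, columns on the shared
#'   time grid.
#' @param times numeric time grid (defaults to `0, 1, ...`).
#' @param condition_id per-trial grouping key for "matched conditions"
#'   (defaults to a single condition).
#' @return object of class `pr_ensemble`.
#' @export
pr_ensemble <- function(perturbations, responses, times = NULL,
                        condition_id = NULL) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n < 2L) cf_stop("an ensemble needs >= 2 trials", "cfgeom_invalid_argument")
  if (length(perturbations) != n)
    cf_stop("one perturbation per trial required", "cfgeom_invalid_argument")
  if (is.null(times)) times <- seq_len(ncol(responses)) - 1
  if (length(times) != ncol(responses))
    cf_stop("times must match the response grid", "cfgeom_invalid_argument")
  if (anyNA(responses) || any(!is.finite(responses)) || anyNA(perturbations))
    cf_stop("ensemble values must be finite", "cfgeom_invalid_argument")
  if (is.null(condition_id)) condition_id <- rep("c1", n)
  if (length(condition_id) != n)
    cf_stop("one condition_id per trial required", "cfgeom_invalid_argument")
  structure(list(perturbations = as.numeric(perturbations),
                 responses = responses, times = as.numeric(times),
                 condition_id = as.character(condition_id)),
            class = "pr_ensemble")
}

#' @export
print.pr_ensemble <- function(x, ...) {
  cat(sprintf("<pr_ensemble> %d trials x %d time points, %d condition(s)\n",
              nrow(x$responses), ncol(x$responses),
              length(unique(x$condition_id))))
  invisible(x)
}

#' Per-trial response summary functionals
#'
#' Named summary functionals `F` applied to each trial's response series:
#' `"peak"` (the signed response value at its maximum magnitude; the default
#' throughout), `"latency"` (time of the absolute peak), `"l2"` (Euclidean
#' norm of the series, a simple trajectory embedding) and `"identity"` (the
#' scalar response itself; only valid for single-point series).
#'
#' @param summary a name above, or a function `(z, times) -> scalar`.
#' @return a function `(z, times) -> scalar`.
#' @export
response_summary <- function(summary = c("peak", "latency", "l2", "identity")) {
  if (is.function(summary)) return(summary)
  summary <- match.arg(summary)
  switch(summary,
    peak = function(z, times) z[which.max(abs(z))],
    latency = function(z, times) times[which.max(abs(z))],
    l2 = function(z, times) sqrt(sum(z^2)),
    identity = function(z, times) {
      if (length(z) != 1L)
        cf_stop("identity summary requires scalar responses", "cfgeom_invalid_argument")
      z
    })
}

summarize_trials <- function(ens, summary) {
  f <- response_summary(summary)
  apply(ens$responses, 1L, function(z) f(z, ens$times))
}

#' Effective counterfactual sensitivity
#'
#' The finite-sample proxy `Var(F(z)) / Var(u)`: how strongly per-trial
#' response summaries vary relative to the variance of the applied
#' perturbations. Low values indicate insensitivity (collapse-dominated
#' dynamics), bounded intermediate values regulated geometry, and large values
#' amplification of small perturbations (explosive sensitivity). Unbiased
#' (n-1) sample variances throughout.
#'
#' @param ens a [pr_ensemble()].
#' @param summary per-trial summary functional (see [response_summary()]).
#' @return the unitless variance ratio.
#' @export
effective_sensitivity <- function(ens, summary = "peak") {
  stopifnot(inherits(ens, "pr_ensemble"))
  vu <- stats::var(ens$perturbations)
  if (vu <= 0)
    cf_stop("perturbation variance is zero; sensitivity ratio undefined",
            "cfgeom_undefined_ratio")
  stats::var(summarize_trials(ens, summary)) / vu
}

#' Response diversity under matched conditions
#'
#' Unbiased sample variance of per-trial response summaries across nominally
#' identical trials: the diversity of realized futures, not the noise
#' magnitude. If the ensemble mixes conditions, `condition` must pick one.
#'
#' @param ens a [pr_ensemble()].
#' @param summary per-trial summary functional (see [response_summary()]).
#' @param condition condition to select when the ensemble has several.
#' @return variance of the summary across trials (functional units squared).
#' @export
response_diversity <- function(ens, summary = "peak", condition = NULL) {
  stopifnot(inherits(ens, "pr_ensemble"))
  conds <- unique(ens$condition_id)
  if (is.null(condition)) {
    if (length(conds) > 1L)
      cf_stop("ensemble mixes conditions; pass `condition` to select one",
              "cfgeom_mixed_conditions")
    keep <- rep(TRUE, nrow(ens$responses))
  } else {
    keep <- ens$condition_id == condition
    if (sum(keep) < 2L)
      cf_stop("need >= 2 trials under the selected condition",
              "cfgeom_invalid_argument")
  }
  sub <- pr_ensemble(ens$perturbations[keep],
                     ens$responses[keep, , drop = FALSE],
                     times = ens$times,
                     condition_id = ens$condition_id[keep])
  stats::var(summarize_trials(sub, summary))
}

#' Recovery curve after a perturbation
#'
#' Distance `R(tau) = d(z(t0 + tau), baseline)` of an observed trajectory from
#' a reference as a function of lag after a perturbation at `t0`. The shape of
#' the curve is a time-resolved regime signature: monotone decay
#' (collapse-dominated stabilization), bounded oscillatory recovery
#' (adversarially stabilized dynamics) or divergence (explosive regimes).
#'
#' @param z numeric response series (or matrix, rows = time, for the
#'   `"euclidean"` metric over multivariate observations).
#' @param times time grid matching `z`.
#' @param t0 perturbation time; lags are measured from here.
#' @param baseline reference: a constant, a series on the same grid, or a
#'   vector/matrix matching the post-`t0` window.
#' @param metric `"absolute"` (default, scalar series) or `"euclidean"`.
#' @return object of class `recovery_curve`: list with `taus`, `distances` and
#'   `shape_label` in `{"monotone", "oscillatory", "divergent"}`. The label
#'   derives from the sign changes of the differenced curve (0 changes:
#'   monotone; >= 2: oscillatory) and a terminal comparison (final distance
#'   above the initial one: divergent).
#' @export
recovery_curve <- function(z, times = NULL, t0 = 0, baseline = 0,
                           metric = c("absolute", "euclidean")) {
  metric <- match.arg(metric)
  zm <- if (is.null(dim(z))) matrix(z, ncol = 1L) else as.matrix(z)
  if (is.null(times)) times <- seq_len(nrow(zm)) - 1
  if (length(times) != nrow(zm))
    cf_stop("times must match the series", "cfgeom_invalid_argument")
  post <- which(times >= t0)
  if (length(post) == 0L)
    cf_stop("no observations at or after t0", "cfgeom_invalid_argument")
  zw <- zm[post, , drop = FALSE]
  bm <- if (is.null(dim(baseline)) && length(baseline) == 1L) {
    matrix(baseline, nrow = nrow(zw), ncol = ncol(zw))
  } else if (is.null(dim(baseline)) && length(baseline) == length(times)) {
    matrix(baseline[post], ncol = 1L)
  } else {
    as.matrix(baseline)
  }
  if (!all(dim(bm) == dim(zw)))
    cf_stop("baseline does not match the post-perturbation window",
            "cfgeom_invalid_argument")
  diffs <- zw - bm
  distances <- switch(metric,
    absolute = as.numeric(abs(diffs)),
    euclidean = sqrt(rowSums(diffs^2)))
  taus <- times[post] - t0
  dr <- diff(distances)
  s <- sign(dr[dr != 0])
  changes <- if (length(s) > 1L) sum(s[-1L] != s[-length(s)]) else 0L
  last <- distances[length(distances)]
  label <- if (length(distances) > 1L && last > distances[1L]) {
    "divergent"
  } else if (changes >= 2L) {
    "oscillatory"
  } else {
    "monotone"
  }
  structure(list(taus = taus, distances = distances, shape_label = label),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %d lags, R(0) = %.4g, R(end) = %.4g, shape: %s\n",
              length(x$taus), x$distances[1L],
              x$distances[length(x$distances)], x$shape_label))
  invisible(x)
}

#' Boundary residence of a probability series
#'
#' Fraction of samples with `min(x, 1 - x) < band`: the time a binary future
#' law spends within a small band of the simplex boundary.
#'
#' @param series numeric values in `[0, 1]`.
#' @param band boundary band half-width (default 0.05).
#' @return fraction in `[0, 1]`.
#' @export
boundary_residence <- function(series, band = 0.05) {
  x <- as.numeric(series)
  if (anyNA(x) || any(x < 0 | x > 1))
    cf_stop("series values must lie in [0, 1]", "cfgeom_invalid_argument")
  mean(pmin(x, 1 - x) < band)
}

#' Early-warning flags from windowed proxy series
#'
#' Nonparametric trend detection over a sequence of analysis windows: each
#' proxy column is tested for a monotone trend against window order with
#' Kendall's tau, flagged rising/falling when `|tau| > tau_threshold` and flat
#' otherwise. Combinations of trends raise the early-warning flags:
#' \itemize{
#'   \item `approaching-explosive`: rising `sensitivity` with flat (or
#'     falling) `diversity` -- amplification without new futures;
#'   \item `impending-collapse`: falling `diversity` with flat
#'     `mean_response` -- the repertoire narrows while the mean is preserved;
#'   \item `weakening-coupling`: rising `recovery_time` with flat
#'     `amplitude` -- slower recovery without loss of response.
#' }
#'
#' @param windows data.frame with one row per window, in time order, with any
#'   of the columns `sensitivity`, `diversity`, `mean_response`,
#'   `recovery_time`, `amplitude`. At least 3 windows are required.
#' @param tau_threshold Kendall-tau magnitude declaring a trend (default 0.5).
#' @return character vector of raised flags (possibly empty), with attribute
#'   `"trends"` giving each column's tau and trend call.
#' @export
early_warning_flags <- function(windows, tau_threshold = 0.5) {
  windows <- as.data.frame(windows)
  if (nrow(windows) < 3L)
    cf_stop("early-warning detection needs >= 3 windows", "cfgeom_invalid_argument")
  known <- c("sensitivity", "diversity", "mean_response", "recovery_time",
             "amplitude")
  idx <- seq_len(nrow(windows))
  trend_of <- function(x) {
    if (stats::sd(x) == 0) return(list(tau = 0, call = "flat"))
    tau <- suppressWarnings(stats::cor(idx, x, method = "kendall"))
    call <- if (!is.na(tau) && tau > tau_threshold) "rising"
            else if (!is.na(tau) && tau < -tau_threshold) "falling"
            else "flat"
    list(tau = if (is.na(tau)) 0 else tau, call = call)
  }
  trends <- lapply(windows[intersect(known, names(windows))], trend_of)
  call_of <- function(name) if (name %in% names(trends)) trends[[name]]$call else NA
  flags <- character(0)
  if (identical(call_of("sensitivity"), "rising") &&
      call_of("diversity") %in% c("flat", "falling"))
    flags <- c(flags, "approaching-explosive")
  if (identical(call_of("diversity"), "falling") &&
      identical(call_of("mean_response"), "flat"))
    flags <- c(flags, "impending-collapse")
  if (identical(call_of("recovery_time"), "rising") &&
      identical(call_of("amplitude"), "flat"))
    flags <- c(flags, "weakening-coupling")
  structure(flags,
            trends = lapply(trends, function(t) list(tau = t$tau, call = t$call)))
}
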