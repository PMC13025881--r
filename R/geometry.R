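#' Discrete future law
#'
#' A probability vector over a finite set of K >= 2 future outcomes. This is the
#' basic object of counterfactual geometry: it encodes the relative accessibility
#' of alternative futures rather than a distribution over observed states.
#'
#' @param probs numeric vector of outcome probabilities; entries must be
#'   non-negative and sum to 1 within `tol`. The stored vector is renormalized
#'   to sum to 1 exactly in floating point.
#' @param labels optional character vector of outcome identifiers.
#' @param tol tolerance on `abs(sum(probs) - 1)` (default `1e-12`).
#' @return an object of class `future_law`: a list with elements `probs` and
#'   `labels`.
#' @examples
#' q <- future_law(c(0.2, 0.8))
#' shannon_entropy(q)
#' @export
future_law <- function(probs, labels = NULL, tol = 1e-12) {
  if (!is.numeric(probs) || length(probs) < 2L)
    cf_stop("a future law needs a numeric vector over K >= 2 outcomes",
            "cfgeom_invalid_law")
  if (anyNA(probs) || any(!is.finite(probs)))
    cf_stop("future-law probabilities must be finite", "cfgeom_invalid_law")
  if (any(probs < 0))
    cf_stop("future-law probabilities must be non-negative", "cfgeom_invalid_law")
  s <- sum(probs)
  if (abs(s - 1) > tol)
    cf_stop(sprintf("future-law probabilities sum to %.15g, not 1 (tol %g)", s, tol),
            "cfgeom_invalid_law")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(probs))
      cf_stop("labels must match the number of outcomes", "cfgeom_invalid_law")
  }
  structure(list(probs = probs / s, labels = labels), class = "future_law")
}

#' @export
print.future_law <- function(x, ...) {
  cat("<future_law> K =", length(x$probs), "\n")
  nm <- if (is.null(x$labels)) seq_along(x$probs) - 1L else x$labels
  print(stats::setNames(x$probs, nm))
  invisible(x)
}

as_future_law <- function(x) {
  if (inherits(x, "future_law")) x else future_law(x)
}

#' Shannon entropy of a future law (nats)
#'
#' Counterfactual diversity: `H(q) = -sum_i q_i log q_i`, natural logarithm,
#' with the convention `0 * log 0 = 0`. Lies in `[0, log K]`, attaining 0 at a
#' degenerate law and `log K` at the uniform law.
#'
#' @param law a [future_law()] or a probability vector.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(law) {
  q <- as_future_law(law)$probs
  pos <- q > 0
  -sum(q[pos] * log(q[pos]))
}

#' Kullback-Leibler divergence between future laws (nats)
#'
#' Relative counterfactual diversity `KL(q || q0) = sum_i q_i log(q_i / q0_i)`,
#' measuring how selectively structured `law` is relative to a baseline.
#' Requires absolute continuity: a support violation (`q_i > 0` where
#' `q0_i = 0`) is an error unless `infinite = TRUE`, in which case `Inf` is
#' returned.
#'
#' @param law,baseline [future_law()] objects (or probability vectors) on the
#'   same outcome set.
#' @param infinite return `Inf` on support violation instead of erroring.
#' @return divergence in nats, `>= 0`, zero iff the laws coincide.
#' @export
kl_divergence <- function(law, baseline, infinite = FALSE) {
  q <- as_future_law(law)$probs
  q0 <- as_future_law(baseline)$probs
  if (length(q) != length(q0))
    cf_stop("laws live on different outcome sets", "cfgeom_invalid_law")
  viol <- q > 0 & q0 == 0
  if (any(viol)) {
    if (infinite) return(Inf)
    cf_stop("absolute continuity violated: law has mass where baseline has none",
            "cfgeom_support_error")
  }
  pos <- q > 0
  sum(q[pos] * log(q[pos] / q0[pos]))
}

#' Fisher information of a binary future law
#'
#' For a two-outcome law `q = (p, 1-p)` parameterized by its mean, the Fisher
#' information is `I(p) = 1 / [p (1 - p)]`: minimal (4) at `p = 1/2` and
#' divergent toward the simplex boundary, where nearby future laws become
#' arbitrarily distinguishable.
#'
#' @param p probability (or vector of probabilities), strictly inside (0, 1).
#'   Boundary values error; trajectory-level code clips first (see
#'   [clip_probability()]).
#' @return `1 / (p * (1 - p))`.
#' @export
fisher_binary <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    cf_stop("fisher_binary requires 0 < p < 1; clip boundary values first",
            "cfgeom_boundary_error")
  1 / (p * (1 - p))
}

#' Clip a probability away from the simplex boundary
#'
#' Clips to `[eps, 1 - eps]` and reports whether clipping occurred. Used before
#' boundary-divergent quantities such as [fisher_binary()] are evaluated along
#' trajectories.
#'
#' @param p numeric vector in `[0, 1]`.
#' @param eps half-width of the excluded boundary strip (default `1e-12`).
#' @return list with `p` (clipped values) and `clipped` (logical vector).
#' @export
clip_probability <- function(p, eps = 1e-12) {
  clipped <- p < eps | p > 1 - eps
  list(p = pmin(pmax(p, eps), 1 - eps), clipped = clipped)
}

#' Monte-Carlo Fisher information matrix of a parametric family
#'
#' Estimates `g_ij(theta) = E[ s_i(x) s_j(x) ]`, the expected outer product of
#' the score `s(x) = d log q_theta(x) / d theta`, by averaging over `n` draws
#' from the family at `theta`. Scores are computed from `logdensity` by forward
#' finite differences (step `fd_step`) unless an analytic `score` function is
#' supplied. Also returns the two scalar sensitivity summaries used throughout
#' the package: the trace and the largest eigenvalue.
#'
#' @param sampler function `(theta, n)` returning `n` draws (vector, or matrix
#'   with one row per draw).
#' @param logdensity function `(x, theta)` returning the log density/mass,
#'   vectorized over draws.
#' @param theta numeric parameter vector.
#' @param n number of Monte-Carlo draws (`>= 100`).
#' @param seed optional RNG seed for reproducibility.
#' @param score optional function `(x, theta)` returning the `n x d` score
#'   matrix; overrides finite differences.
#' @param fd_step forward-difference step (default `1e-6`).
#' @return list with `fisher` (d x d symmetric PSD matrix up to sampling
#'   error), `trace_value`, `lambda_max`, `n`, and class
#'   `sensitivity_summary`.
#' @export
fisher_matrix_mc <- function(sampler, logdensity, theta, n = 10000L,
                             seed = NULL, score = NULL, fd_step = 1e-6) {
  if (n < 100L)
    cf_stop("fisher_matrix_mc needs n >= 100 draws", "cfgeom_estimation_error")
  d <- length(theta)
  x <- with_seed(seed, sampler(theta, n))
  if (is.null(score)) {
    base <- logdensity(x, theta)
    S <- matrix(0, nrow = length(base), ncol = d)
    for (j in seq_len(d)) {
      th <- theta
      th[j] <- th[j] + fd_step
      S[, j] <- (logdensity(x, th) - base) / fd_step
    }
  } else {
    S <- score(x, theta)
    if (is.null(dim(S))) S <- matrix(S, ncol = d)
  }
  if (anyNA(S) || any(!is.finite(S)))
    cf_stop("non-finite scores encountered in Fisher estimation",
            "cfgeom_estimation_error")
  G <- crossprod(S) / nrow(S)
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  structure(list(fisher = G,
                 trace_value = sum(diag(G)),
                 lambda_max = max(ev),
                 n = nrow(S)),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("<sensitivity_summary> d = %d, n = %d, tr(g) = %.6g, lambda_max = %.6g\n",
              nrow(x$fisher), x$n, x$trace_value, x$lambda_max))
  invisible(x)
}

#' Minimal credible set of a future law
#'
#' The smallest set of outcomes carrying at least `1 - delta` probability mass:
#' the finite analogue of the counterfactual manifold. Outcomes are added by
#' descending probability, ties broken by ascending index, yielding a canonical
#' minimal-cardinality set (credible sets are generally non-unique).
#'
#' @param law a [future_law()] or probability vector.
#' @param delta credibility slack in (0, 1); the set carries mass `>= 1 - delta`.
#' @return object of class `credible_set`: list with `member_indices` (1-based),
#'   `mass` and `delta`.
#' @export
credible_set <- function(law, delta) {
  q <- as_future_law(law)$probs
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    cf_stop("delta must lie strictly in (0, 1)", "cfgeom_invalid_argument")
  ord <- order(-q)                       # stable: ties keep ascending index
  cum <- cumsum(q[ord])
  k <- which(cum >= 1 - delta - 1e-12)[1L]
  idx <- sort(ord[seq_len(k)])
  structure(list(member_indices = idx, mass = sum(q[idx]), delta = delta),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set> delta = %g, |M| = %d, mass = %.6g\n",
              x$delta, length(x$member_indices), x$mass))
  invisible(x)
}

#' Projection intervention: remove future outcomes
#'
#' Zeroes the probability of excluded outcomes and renormalizes the retained
#' mass, modelling an intervention that removes regions of trajectory space.
#'
#' @param law a [future_law()] or probability vector.
#' @param keep 1-based indices of outcomes to retain (non-empty, with positive
#'   total mass).
#' @return the projected [future_law()].
#' @export
op_project <- function(law, keep) {
  law <- as_future_law(law)
  q <- law$probs
  keep <- unique(as.integer(keep))
  if (length(keep) == 0L || any(keep < 1L) || any(keep > length(q)))
    cf_stop("keep must be a non-empty subset of outcome indices",
            "cfgeom_invalid_argument")
  mass <- sum(q[keep])
  if (mass <= 0)
    cf_stop("projection retains zero probability mass", "cfgeom_degenerate_projection")
  out <- numeric(length(q))
  out[keep] <- q[keep] / mass
  future_law(out, labels = law$labels)
}

#' Exponential tilting intervention: reweight futures by cost
#'
#' Returns `q_i exp(-gain * cost_i) / Z`, an intervention that reshapes the
#' feasibility of futures without removing any. `gain = 0` is the identity; as
#' `gain -> Inf` mass concentrates on the minimum-cost supported outcome. Costs
#' are shifted by their supported minimum before exponentiation so large gains
#' do not underflow.
#'
#' @param law a [future_law()] or probability vector.
#' @param cost finite per-outcome cost vector.
#' @param gain tilt strength (default 1).
#' @return the tilted [future_law()].
#' @export
op_tilt <- function(law, cost, gain = 1) {
  law <- as_future_law(law)
  q <- law$probs
  if (!is.numeric(cost) || length(cost) != length(q) || any(!is.finite(cost)))
    cf_stop("cost must be a finite vector matching the outcome set",
            "cfgeom_invalid_argument")
  if (!is.finite(gain))
    cf_stop("gain must be finite", "cfgeom_invalid_argument")
  supp <- q > 0
  shift <- min(cost[supp])
  w <- q * exp(-gain * (cost - shift))
  z <- sum(w)
  if (!is.finite(z) || z <= 0)
    cf_stop("tilt normalizer degenerate", "cfgeom_degenerate_tilt")
  future_law(w / z, labels = law$labels)
}

#' Total-variation distance between future laws
#'
#' `TV(q, q') = sup_A |q(A) - q'(A)| = 0.5 * sum_i |q_i - q'_i|`.
#'
#' @param law_a,law_b [future_law()] objects or probability vectors on the same
#'   outcome set.
#' @return TV distance in `[0, 1]`.
#' @export
total_variation <- function(law_a, law_b) {
  a <- as_future_law(law_a)$probs
  b <- as_future_law(law_b)$probs
  if (length(a) != length(b))
    cf_stop("laws live on different outcome sets", "cfgeom_invalid_law")
  0.5 * sum(abs(a - b))
}

#' Commutator defect of two intervention operators
#'
#' Interventions on future laws need not commute. Returns the total-variation
#' distance between `op_b(op_a(law))` and `op_a(op_b(law))`; zero iff the two
#' orderings coincide on this law.
#'
#' @param law a [future_law()] or probability vector.
#' @param op_a,op_b functions mapping a `future_law` to a `future_law`, e.g.
#'   partially applied [op_project()] / [op_tilt()].
#' @return non-negative TV distance.
#' @export
ops_commutator <- function(law, op_a, op_b) {
  law <- as_future_law(law)
  total_variation(op_b(op_a(law)), op_a(op_b(law)))
}

# Vectorized binary-law observables used by trajectory diagnostics; identical
# to shannon_entropy / kl_divergence / fisher_binary on (p, 1-p).
binary_entropy <- function(p) {
  h <- numeric(length(p))
  i <- p > 0 & p < 1
  h[i] <- -(p[i] * log(p[i]) + (1 - p[i]) * log(1 - p[i]))
  h
}

binary_kl_uniform <- function(p) {
  k <- numeric(length(p))
  k <- ifelse(p > 0, p * log(2 * p), 0) + ifelse(p < 1, (1 - p) * log(2 * (1 - p)), 0)
  k
}

#' Read or write a future law as CSV or JSON
#'
#' CSV files have columns `label, prob`; JSON files an object with fields
#' `labels` and `probs`. The format is inferred from the file extension.
#'
#' @param law a [future_law()].
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_future_law` returns a [future_law()]; `write_future_law`
#'   returns `path` invisibly.
#' @export
write_future_law <- function(law, path) {
  law <- as_future_law(law)
  labels <- if (is.null(law$labels)) as.character(seq_along(law$probs) - 1L) else law$labels
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(labels = labels, probs = law$probs), path,
                         auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(data.frame(label = labels, prob = law$probs),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_future_law
#' @export
read_future_law <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$probs))
      cf_stop("future-law JSON lacks a 'probs' field", "cfgeom_io_error")
    future_law(as.numeric(x$probs), labels = x$labels)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("label", "prob") %in% names(df)))
      cf_stop("future-law CSV must have columns label, prob", "cfgeom_io_error")
    future_law(as.numeric(df$prob), labels = df$label)
  }
}
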