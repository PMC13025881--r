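# Independent oracles used across test files.

# Random point on the K-simplex (all entries strictly positive).
random_law <- function(k) {
  x <- stats::rexp(k) + 1e-6
  x / sum(x)
}

# Exhaustive-enumeration credible-set oracle: smallest cardinality among all
# subsets whose mass reaches 1 - delta.
credible_set_oracle <- function(probs, delta) {
  k <- length(probs)
  for (size in 1:k) {
    sets <- utils::combn(k, size, simplify = FALSE)
    masses <- vapply(sets, function(s) sum(probs[s]), numeric(1))
    ok <- masses >= 1 - delta - 1e-12
    if (any(ok)) {
      return(list(cardinality = size, best_mass = max(masses[ok])))
    }
  }
  stop("unreachable: the full set always qualifies")
}

# Fisher information of a binary law via the local quadratic expansion of KL.
fisher_from_kl <- function(p, eps) {
  2 * kl_divergence(future_law(c(p, 1 - p)),
                    future_law(c(p + eps, 1 - p - eps))) / eps^2
}

# Central finite-difference gradient of a scalar function.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}
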