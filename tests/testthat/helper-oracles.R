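# Independent oracles used to cross-check the package's optimizers.
# They deliberately re-derive everything from first principles: direct
# probability products, explicit maximization over assignments, and raw
# least-squares scans, with no shared code with the implementation.

# Brute-force pulse likelihood: scan every k-subset of the distinct LAD beds
# and, per taxon, maximize the log-probability over every pulse at or above
# its LAD by direct product over intervening beds.
oracle_pulse_scan <- function(lads, p, k) {
  eps <- 1 / (2 * length(lads))
  pobs <- pmax(p, eps)
  miss <- pmax(1 - p, eps)
  cand <- sort(unique(lads))
  combos <- utils::combn(cand, k)
  best <- list(ll = -Inf, pulses = NULL)
  for (i in seq_len(ncol(combos))) {
    pulses <- combos[, i]
    ll <- 0
    for (L in lads) {
      opts <- pulses[pulses >= L]
      if (!length(opts)) { ll <- -Inf; break }
      contrib <- vapply(opts, function(P) {
        v <- log(pobs[L])
        if (P > L) for (b in (L + 1):P) v <- v + log(miss[b])
        v
      }, numeric(1))
      ll <- ll + max(contrib)
    }
    if (ll > best$ll + 1e-12) best <- list(ll = ll, pulses = pulses)
  }
  best
}

# Brute-force interval likelihood over all (lo < hi) bed pairs.
oracle_interval_scan <- function(lads, p) {
  eps <- 1 / (2 * length(lads))
  pobs <- pmax(p, eps)
  miss <- pmax(1 - p, eps)
  B <- length(p)
  best <- list(ll = -Inf, bounds = NULL)
  for (lo in 1:(B - 1)) for (hi in (lo + 1):B) {
    if (hi < max(lads)) next
    ll <- 0
    for (L in lads) {
      tot <- 0
      for (e in max(lo, L):hi) {
        v <- pobs[L]
        if (e > L) for (b in (L + 1):e) v <- v * miss[b]
        tot <- tot + v / (hi - lo + 1)
      }
      ll <- ll + log(tot)
    }
    if (ll > best$ll + 1e-12) best <- list(ll = ll, bounds = c(lo, hi))
  }
  best
}

# Exhaustive SSE scan for segmented regression over observed x placements.
oracle_grid_sse <- function(x, y, k, min_seg = 3) {
  n <- length(x)
  cand <- unique(x[min_seg:(n - min_seg + 1)])
  combos <- utils::combn(cand, k)
  best <- Inf
  best_psi <- NULL
  for (i in seq_len(ncol(combos))) {
    psi <- combos[, i]
    if (k > 1) {
      occ <- vapply(seq_len(k - 1), function(j)
        sum(x > psi[j] & x <= psi[j + 1]), numeric(1))
      if (any(occ < min_seg)) next
    }
    X <- cbind(1, x)
    for (ps in psi) X <- cbind(X, pmax(x - ps, 0))
    sse <- sum(stats::lm.fit(X, y)$residuals^2)
    if (sse < best) { best <- sse; best_psi <- psi }
  }
  list(sse = best, psi = best_psi)
}

# Independent Poisson IRLS (Newton) to cross-check glm coefficients.
oracle_poisson_newton <- function(y, X, iters = 50) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    mu <- exp(drop(X %*% beta))
    W <- mu
    z <- drop(X %*% beta) + (y - mu) / mu
    beta <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
  }
  drop(beta)
}
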