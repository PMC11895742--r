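#' Per-bed fossil recovery probabilities
#'
#' Estimates the probability that a taxon alive in a bed is actually sampled
#' there, the quantity that controls the Signor-Lipps smearing of last
#' appearances below true extinction horizons. The estimator is occupancy
#' among range-through taxa: `p_b = (# taxa with an occurrence in bed b) /
#' (# taxa whose FAD-LAD range spans bed b)`. Probabilities are floored at
#' `eps = 1/(2 * n_taxa)` (beds spanned by no taxon get the floor) so that
#' downstream log-likelihoods stay finite.
#'
#' @param ranges a `taxon_ranges` data frame (see [compute_ranges()]).
#' @param window a [strat_column()] (typically a [column_window()]).
#' @return A data frame of class `recovery_profile` with columns
#'   `bed_id, order_index, p`.
#' @export
estimate_recovery <- function(ranges, window) {
  if (nrow(window) == 0) stop("empty window")
  if (nrow(ranges) == 0) stop("no taxa to estimate recovery from")
  eps <- 1 / (2 * nrow(ranges))
  occ <- integer(nrow(window))
  rt <- integer(nrow(window))
  for (i in seq_len(nrow(ranges))) {
    span <- window$order_index >= ranges$fad_index[i] &
      window$order_index <= ranges$lad_index[i]
    rt[span] <- rt[span] + 1L
    hit <- window$order_index %in% ranges$horizons[[i]]
    occ[hit] <- occ[hit] + 1L
  }
  p <- ifelse(rt > 0, occ / rt, eps)
  p <- pmin(pmax(p, eps), 1)
  out <- data.frame(bed_id = window$bed_id, order_index = window$order_index,
                    p = p, stringsAsFactors = FALSE)
  class(out) <- c("recovery_profile", "data.frame")
  out
}

#' Constant recovery profile
#'
#' Convenience constructor for a [recovery profile][estimate_recovery] with
#' the same sampling probability in every bed of a window.
#'
#' @param window a [strat_column()].
#' @param p recovery probability in (0, 1].
#' @export
constant_recovery <- function(window, p) {
  stopifnot(length(p) == 1 || length(p) == nrow(window), all(p > 0), all(p <= 1))
  out <- data.frame(bed_id = window$bed_id, order_index = window$order_index,
                    p = rep_len(p, nrow(window)), stringsAsFactors = FALSE)
  class(out) <- c("recovery_profile", "data.frame")
  out
}

#' Last-appearance data for pulse fitting
#'
#' Extracts LAD bed order indices for the non-singleton taxa of a range table,
#' restricted to a window. Singletons carry no information on extinction
#' timing and are excluded from pulse detection.
#'
#' @param ranges a `taxon_ranges` data frame.
#' @param window a [strat_column()].
#' @param drop_singletons drop taxa known from a single horizon (default TRUE).
#' @return Named integer vector: taxon -> LAD bed order index.
#' @export
lads_from_ranges <- function(ranges, window, drop_singletons = TRUE) {
  keep <- ranges$lad_index %in% window$order_index
  if (drop_singletons) keep <- keep & !ranges$is_singleton
  stats::setNames(ranges$lad_index[keep], ranges$taxon[keep])
}

# --- internal machinery -----------------------------------------------------

# Map global order indices to positions 1..B within the window.
window_pos <- function(window, order_index) {
  pos <- match(order_index, window$order_index)
  if (anyNA(pos)) stop("LAD bed outside the analysis window")
  pos
}

# cumulative log miss-probabilities; the per-bed miss probability (1 - p) is
# floored at eps = 1/(2 * n_taxa) so a missed bed under complete sampling gets
# a large finite penalty instead of -Inf (the same floor applied to p itself)
miss_cumlog <- function(p, eps) cumsum(log(pmax(1 - p, eps)))

# log-likelihood of one pulse placement (positions, sorted) given distinct
# LAD positions dl with counts nl; clog from miss_cumlog; base term added by
# caller. Assignment: each LAD maps to the nearest pulse at-or-above it.
placement_loglik <- function(pulses, dl, nl, clog) {
  j <- findInterval(dl - 0.5, pulses) + 1L
  sum(nl * (clog[pulses[j]] - clog[dl]))
}

new_pulse_model <- function(k, pulse_pos, window, assignment, loglik, n_taxa,
                            n_params, interval_pos = NULL) {
  mids <- (window$base_m + window$top_m) / 2
  structure(list(
    k = k,
    pulse_pos = pulse_pos,
    pulse_beds = if (k >= 1) window$bed_id[pulse_pos] else character(0),
    pulse_heights = if (k >= 1) mids[pulse_pos] else numeric(0),
    interval_pos = interval_pos,
    interval_beds = if (!is.null(interval_pos)) window$bed_id[interval_pos],
    interval_bounds = if (!is.null(interval_pos)) mids[interval_pos],
    assignment = assignment,
    loglik = loglik,
    n_taxa = n_taxa,
    n_params = n_params,
    bic = -2 * loglik + n_params * log(n_taxa),
    pulse_cis = NULL,
    window = window
  ), class = "pulse_model")
}

#' Maximum-likelihood positions of k extinction pulses
#'
#' First step of the two-step pulse analysis: given the number of pulses `k`,
#' find the pulse horizons and taxon-to-pulse assignment maximizing the
#' missed-sampling likelihood. A taxon assigned to a pulse at bed `P` but last
#' seen at bed `L <= P` was sampled at `L` and missed in every bed of
#' `(L, P]`, giving the per-taxon likelihood
#' `p_L * prod_{L < b <= P} (1 - p_b)`.
#'
#' Candidate pulse horizons are the observed LAD beds; the search is an
#' exhaustive scan over placements (the topmost pulse must sit at the topmost
#' LAD bed), with the optimal assignment mapping each taxon to the nearest
#' pulse at or above its LAD. Ties prefer stratigraphically lower placements.
#'
#' @param lads named integer vector of LAD bed order indices (see
#'   [lads_from_ranges()]).
#' @param recovery a [recovery profile][estimate_recovery] aligned to `window`.
#' @param k number of pulses, `>= 1`.
#' @param window a [strat_column()].
#' @return A `pulse_model` (list with `k`, `pulse_beds`, `pulse_heights`,
#'   `assignment`, `loglik`, `bic`).
#' @export
fit_k_pulses <- function(lads, recovery, k, window) {
  stopifnot(k >= 1)
  p <- recovery$p[window_pos(window, recovery$order_index)]
  pos <- window_pos(window, lads)
  cand <- sort(unique(pos))
  if (length(cand) < k)
    stop("fewer distinct LAD beds (", length(cand), ") than pulses k = ", k)
  clog <- miss_cumlog(p, 1 / (2 * length(lads)))
  tab <- table(pos)
  dl <- as.integer(names(tab)); nl <- as.integer(tab)
  base <- sum(nl * log(p[dl]))
  top <- max(cand)
  lower <- setdiff(cand, top)
  combos <- if (k == 1) matrix(integer(0), nrow = 0, ncol = 1)
            else t(utils::combn(lower, k - 1))
  best_ll <- -Inf; best_pulses <- NULL
  iter <- if (k == 1) 1L else nrow(combos)
  for (i in seq_len(iter)) {
    pulses <- if (k == 1) top else c(combos[i, ], top)
    ll <- base + placement_loglik(pulses, dl, nl, clog)
    if (ll > best_ll + 1e-12) { best_ll <- ll; best_pulses <- pulses }
  }
  j <- findInterval(pos - 0.5, best_pulses) + 1L
  assignment <- stats::setNames(j, names(lads))
  new_pulse_model(k, best_pulses, window, assignment, best_ll,
                  n_taxa = length(lads), n_params = k)
}

#' Maximum-likelihood extinction interval (continuous-loss model)
#'
#' Alternative to discrete pulses: true extinction horizons are uniform over
#' a contiguous run of beds `[low, high]` and last appearances arise from the
#' same per-bed missed-sampling model. The likelihood is maximized by grid
#' scan over all bed pairs in the window (the upper bound cannot lie below the
#' topmost LAD). Encoded as a `pulse_model` with `k = 0`.
#'
#' @inheritParams fit_k_pulses
#' @return A `pulse_model` with `k = 0` and `interval_beds`/`interval_bounds`.
#' @export
fit_interval <- function(lads, recovery, window) {
  p <- recovery$p[window_pos(window, recovery$order_index)]
  pos <- window_pos(window, lads)
  cand <- sort(unique(pos))
  if (length(cand) < 2)
    stop("interval model degenerate with a single distinct LAD bed; compare k = 1 instead")
  B <- length(p)
  clog <- miss_cumlog(p, 1 / (2 * length(lads)))
  tab <- table(pos)
  dl <- as.integer(names(tab)); nl <- as.integer(tab)
  base <- sum(nl * log(p[dl]) - nl * clog[dl])
  top_lad <- max(cand)
  best_ll <- -Inf; best <- NULL
  for (lo in seq_len(B - 1L)) {
    hi_min <- max(lo + 1L, top_lad)
    if (hi_min > B) next
    for (hi in seq.int(hi_min, B)) {
      seg <- clog[lo:hi]
      m <- max(seg)
      tailsum <- rev(cumsum(rev(exp(seg - m))))  # tailsum[a-lo+1] = sum_{e=a}^{hi}
      a <- pmax(lo, dl)
      ll <- base + sum(nl * (m + log(tailsum[a - lo + 1L]))) -
        sum(nl) * log(hi - lo + 1)
      if (ll > best_ll + 1e-12) { best_ll <- ll; best <- c(lo, hi) }
    }
  }
  new_pulse_model(0L, integer(0), window,
                  assignment = stats::setNames(rep(NA_integer_, length(lads)),
                                               names(lads)),
                  loglik = best_ll, n_taxa = length(lads), n_params = 2,
                  interval_pos = best)
}

# sample bootstrap LADs for taxa dying at pulse position P (conditional on
# being observed at least once): P(lad = b) ∝ p_b * prod_{b<b'<=P}(1-p_b')
sample_lads_given_pulse <- function(pulse_pos_per_taxon, p, clog, n_rep) {
  n <- length(pulse_pos_per_taxon)
  out <- matrix(0L, nrow = n, ncol = n_rep)
  for (P in unique(pulse_pos_per_taxon)) {
    rows <- which(pulse_pos_per_taxon == P)
    w <- p[1:P] * exp(clog[P] - clog[1:P])
    draws <- sample.int(P, length(rows) * n_rep, replace = TRUE, prob = w)
    out[rows, ] <- draws
  }
  out
}

#' Select the number of extinction pulses
#'
#' Second step of the two-step analysis: fits the continuous-interval model
#' and pulse models `k = 1..K_max`, selects by BIC, and confirms each
#' adjacent-pulse-count decision (`k` vs `k - 1`, for `k >= 2`) with a
#' parametric-bootstrap likelihood-ratio test at level `alpha`: datasets are
#' simulated from the smaller model (taxa die at their assigned pulse, last
#' appearances re-thinned through the recovery profile), both models are
#' refitted, and the observed LR is compared to the bootstrap distribution.
#' If the larger model is not supported the count is decremented and testing
#' continues downward. Deterministic given `seed`.
#'
#' @inheritParams fit_k_pulses
#' @param K_max largest pulse count to consider.
#' @param n_boot bootstrap replicates for the LR confirmation (>= 99).
#' @param alpha level of the bootstrap LR test.
#' @param seed integer seed (the caller's RNG state is untouched).
#' @return The selected `pulse_model`, with attributes `bic_trace` (named BIC
#'   per candidate model) and `lrt_pvalues` (any bootstrap confirmations run).
#' @export
select_pulse_count <- function(lads, recovery, window, K_max = 3,
                               n_boot = 199, alpha = 0.05, seed = NULL) {
  stopifnot(K_max >= 1, n_boot >= 99)
  pos <- window_pos(window, lads)
  m <- length(unique(pos))
  fits <- list()
  if (m >= 2) fits[["interval"]] <- fit_interval(lads, recovery, window)
  for (k in seq_len(min(K_max, m)))
    fits[[paste0("k", k)]] <- fit_k_pulses(lads, recovery, k, window)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  # ties prefer fewer parameters, then fewer pulses
  np <- vapply(fits, function(f) f$n_params, numeric(1))
  ord <- order(bics, np)
  best <- fits[[ord[1]]]

  pvals <- numeric(0)
  if (best$k >= 2) {
    p <- recovery$p[window_pos(window, recovery$order_index)]
    clog <- miss_cumlog(p, 1 / (2 * length(lads)))
    with_seed(seed, {
      while (best$k >= 2) {
        small <- fits[[paste0("k", best$k - 1)]]
        lr_obs <- 2 * (best$loglik - small$loglik)
        pulse_of_taxon <- small$pulse_pos[small$assignment]
        sim <- sample_lads_given_pulse(pulse_of_taxon, p, clog, n_boot)
        lr_boot <- numeric(n_boot)
        for (b in seq_len(n_boot)) {
          lb <- stats::setNames(window$order_index[sim[, b]], names(lads))
          nd <- length(unique(lb))
          if (nd < best$k) { lr_boot[b] <- 0; next }  # larger model unidentifiable: no evidence for it
          f_small <- fit_k_pulses(lb, recovery, best$k - 1, window)
          f_big <- fit_k_pulses(lb, recovery, best$k, window)
          lr_boot[b] <- 2 * (f_big$loglik - f_small$loglik)
        }
        pv <- (1 + sum(lr_boot >= lr_obs)) / (1 + n_boot)
        pvals[paste0("k", best$k, "_vs_k", best$k - 1)] <- pv
        if (pv > alpha) best <- small else break
      }
    })
  }
  attr(best, "bic_trace") <- bics
  attr(best, "lrt_pvalues") <- pvals
  best
}

#' Bootstrap confidence intervals on pulse positions
#'
#' Resamples taxa with replacement, refits pulse positions at the model's
#' fixed `k` (or interval bounds for `k = 0`), and reports percentile
#' intervals of the pulse heights at confidence `C`. Deterministic given
#' `seed`.
#'
#' @param model a fitted `pulse_model`.
#' @inheritParams select_pulse_count
#' @param C confidence level of the percentile intervals.
#' @return `model` with `pulse_cis`: a matrix with one row per pulse (or the
#'   two interval bounds for `k = 0`) and columns `low`, `high` (meters).
#' @export
pulse_confidence <- function(model, lads, recovery, window,
                             n_boot = 199, C = 0.95, seed = NULL) {
  k <- model$k
  n <- length(lads)
  need_distinct <- if (k >= 1) k else 2L
  heights <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = if (k >= 1) k else 2L)
    for (b in seq_len(n_boot)) {
      lb <- lads
      for (try in 1:1000) {
        idx <- sample.int(n, n, replace = TRUE)
        lb <- lads[idx]
        if (length(unique(lb)) >= need_distinct) break
      }
      fit <- if (k >= 1) fit_k_pulses(lb, recovery, k, window)
             else fit_interval(lb, recovery, window)
      out[b, ] <- if (k >= 1) fit$pulse_heights else fit$interval_bounds
    }
    out
  })
  a <- (1 - C) / 2
  cis <- t(apply(heights, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(cis) <- c("low", "high")
  rownames(cis) <- if (k >= 1) paste0("pulse", seq_len(k)) else c("low_bound", "high_bound")
  model$pulse_cis <- cis
  model$ci_confidence <- C
  model
}

#' Pulse models per clade
#'
#' Runs pulse-count selection separately within each clade. Clades with fewer
#' than `min_richness` non-singleton species are reported as `"insufficient"`
#' rather than fitted, mirroring the practice of not inferring extinction
#' timing from depauperate groups.
#'
#' @param ranges a `taxon_ranges` data frame.
#' @param window a [strat_column()].
#' @param min_richness minimum number of non-singleton species per clade.
#' @param recovery optional shared [recovery profile][estimate_recovery]; by
#'   default each clade's profile is estimated from its own ranges.
#' @inheritParams select_pulse_count
#' @return Named list: per clade either a `pulse_model` or the string
#'   `"insufficient"`.
#' @export
per_clade_pulses <- function(ranges, window, min_richness = 10,
                             recovery = NULL, K_max = 3, n_boot = 199,
                             seed = NULL) {
  out <- list()
  for (cl in sort(unique(ranges$clade))) {
    sub <- ranges[ranges$clade == cl, , drop = FALSE]
    lads <- lads_from_ranges(sub, window)
    if (length(lads) < min_richness) {
      out[[cl]] <- "insufficient"
      next
    }
    rec <- recovery %||% estimate_recovery(sub, window)
    out[[cl]] <- select_pulse_count(lads, rec, window, K_max = K_max,
                                    n_boot = n_boot, seed = seed)
  }
  out
}

#' @export
print.pulse_model <- function(x, ...) {
  if (x$k >= 1) {
    cat("Extinction pulse model: k =", x$k, "pulse(s) at bed(s)",
        paste(x$pulse_beds, collapse = ", "),
        sprintf("(%s m)\n", paste(sprintf("%.3f", x$pulse_heights),
                                  collapse = ", ")))
  } else {
    cat("Extinction interval model: beds",
        paste(x$interval_beds, collapse = " to "),
        sprintf("(%.3f to %.3f m)\n", x$interval_bounds[1], x$interval_bounds[2]))
  }
  cat(sprintf("  taxa: %d   logLik: %.3f   BIC: %.3f\n",
              x$n_taxa, x$loglik, x$bic))
  if (!is.null(x$pulse_cis)) {
    cat(sprintf("  %.0f%% bootstrap CIs (m):\n", 100 * x$ci_confidence))
    print(round(x$pulse_cis, 3))
  }
  invisible(x)
}
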