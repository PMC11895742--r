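#' Continuous piecewise-linear (segmented) regression
#'
#' Fits `y = b0 + b1*x + sum_j d_j * (x - psi_j)_+` by least squares, jointly
#' estimating the breakpoints `psi_j`. Estimation uses iterative
#' linearization: at the current breakpoints the model is augmented with the
#' gap covariates `V_j = -1(x > psi_j)` and each breakpoint is updated by
#' `psi_j <- psi_j + gamma_j / d_j` (the ratio of the gap coefficient to the
#' slope change) until the updates fall below `tol` times the x-range. The
#' procedure is restarted from several quantile-spaced initial breakpoint
#' configurations and the best sum of squared errors is kept. Breakpoints are
#' constrained strictly inside the data span with at least `min_seg` points
#' per segment.
#'
#' With `k = 0` this is ordinary least squares.
#'
#' @param x,y numeric vectors (heights and proxy values).
#' @param k number of breakpoints, `>= 0`. Requires `n >= 2k + 4`.
#' @param starts optional numeric vector (length `k`) of initial breakpoints;
#'   by default 10 quantile-spaced configurations are tried.
#' @param tol convergence tolerance as a fraction of the x-range.
#' @param max_iter maximum linearization iterations per start.
#' @param min_seg minimum data points per segment (identifiability guard).
#' @param n_starts number of multi-start configurations.
#' @return An object of class `segmented_fit`: list with `n_breakpoints`,
#'   `breakpoints`, `coefficients` (`intercept`, `slope`, slope changes
#'   `delta1..deltak`), `fitted`, `residuals`, `sse`, `sigma2`, `bic`,
#'   `converged`, and the data `x`, `y`.
#' @export
fit_segmented <- function(x, y, k, starts = NULL, tol = 1e-8, max_iter = 50,
                          min_seg = 3, n_starts = 10) {
  stopifnot(length(x) == length(y), k >= 0)
  n <- length(x)
  if (n < 2 * k + 4) stop("need n >= 2k + 4 points (n = ", n, ", k = ", k, ")")
  if (diff(range(x)) <= 0) stop("degenerate x: all values equal")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  if (k == 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    return(finish_segfit(x, y, numeric(0), fit$coefficients, TRUE))
  }

  start_list <- if (!is.null(starts)) list(sort(starts)) else
    quantile_starts(x, k, n_starts)
  cands <- lapply(start_list, function(psi0)
    segmented_one_start(x, y, psi0, tol, max_iter, min_seg))
  # a breakpoint scan restricted to observed x-values guards against local
  # optima of the linearization; its best placement is kept both as-is and
  # polished by one more linearization pass
  g <- grid_scan(x, y, k, min_seg)
  if (!is.null(g)) {
    cands <- c(cands, list(g),
               list(segmented_one_start(x, y, g$psi, tol, max_iter, min_seg)))
  }
  best <- cands[[which.min(vapply(cands, function(z) z$sse, numeric(1)))]]
  finish_segfit(x, y, best$psi, best$coef, best$converged)
}

# quantile-spaced initial breakpoint configurations, deterministically
# shifted across starts to cover the span
quantile_starts <- function(x, k, n_starts) {
  shifts <- seq(-0.25, 0.25, length.out = n_starts) / (k + 1)
  lapply(shifts, function(s) {
    probs <- pmin(pmax(seq_len(k) / (k + 1) + s, 0.05), 0.95)
    as.numeric(stats::quantile(x, probs, names = FALSE))
  })
}

# exhaustive least-squares scan over breakpoint placements at observed
# x-values (thinned to quantiles when the combinatorial grid gets large)
grid_scan <- function(x, y, k, min_seg, max_eval = 2000) {
  n <- length(x)
  cand <- unique(x[seq(min_seg, n - min_seg + 1)])
  while (choose(length(cand), k) > max_eval && length(cand) > k + 1)
    cand <- unique(as.numeric(stats::quantile(
      cand, seq(0.01, 0.99, length.out = ceiling(length(cand) / 2)),
      names = FALSE, type = 1)))
  if (length(cand) < k) return(NULL)
  combos <- utils::combn(cand, k)
  best <- NULL
  for (i in seq_len(ncol(combos))) {
    psi <- combos[, i]
    if (k > 1 && any(vapply(seq_len(k - 1), function(j)
      sum(x > psi[j] & x <= psi[j + 1]), numeric(1)) < min_seg)) next
    U <- outer(x, psi, function(xx, p) pmax(xx - p, 0))
    fit <- stats::lm.fit(cbind(1, x, U), y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      co <- fit$coefficients; co[is.na(co)] <- 0
      best <- list(psi = psi, coef = co, sse = sse, converged = TRUE)
    }
  }
  best
}

segmented_one_start <- function(x, y, psi, tol, max_iter, min_seg) {
  n <- length(x)
  k <- length(psi)
  span <- range(x)
  clamp <- function(psi) {
    # keep strictly inside the span, ordered, with min_seg points per segment
    psi <- sort(psi)
    lo <- x[min_seg]; hi <- x[n - min_seg + 1]
    psi <- pmin(pmax(psi, lo + 1e-9), hi - 1e-9)
    # enforce min_seg points between consecutive breakpoints
    if (k > 1) for (j in 2:k) {
      m <- sum(x > psi[j - 1] & x <= psi[j])
      if (m < min_seg) {
        i <- which(x > psi[j - 1])[min_seg]
        psi[j] <- if (!is.na(i) && i <= n) min(x[i] + 1e-9, hi - 1e-9) else hi - 1e-9
      }
    }
    sort(psi)
  }
  psi <- clamp(psi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- outer(x, psi, function(xx, p) pmax(xx - p, 0))
    V <- outer(x, psi, function(xx, p) -as.numeric(xx > p))
    X <- cbind(1, x, U, V)
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    d <- beta[2 + seq_len(k)]
    g <- beta[2 + k + seq_len(k)]
    g[is.na(g)] <- 0; d[is.na(d)] <- 0
    step <- ifelse(abs(d) > 1e-12, g / d, 0)
    # damp overshoots beyond the span
    step <- pmin(pmax(step, -diff(span)), diff(span))
    psi_new <- clamp(psi + step)
    if (max(abs(psi_new - psi)) < tol * diff(span)) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
  }
  U <- outer(x, psi, function(xx, p) pmax(xx - p, 0))
  fit <- stats::lm.fit(cbind(1, x, U), y)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  list(psi = psi, coef = coef, sse = sum(fit$residuals^2), converged = converged)
}

finish_segfit <- function(x, y, psi, coef, converged) {
  n <- length(x)
  psi <- unname(as.numeric(psi))
  k <- length(psi)
  coef <- as.numeric(coef)
  names(coef) <- c("intercept", "slope", if (k) paste0("delta", seq_len(k)))
  fitted <- eval_segmented(coef, psi, x)
  res <- y - fitted
  sse <- sum(res^2)
  p_eff <- 2 + 2 * k  # intercept, slope, and (delta, psi) per breakpoint
  bic <- n * log(max(sse, 1e-300) / n) + p_eff * log(n)
  structure(list(
    n_breakpoints = k, breakpoints = psi, coefficients = coef,
    fitted = fitted, residuals = res, sse = sse,
    sigma2 = sse / max(n - p_eff, 1), bic = bic, converged = converged,
    x = x, y = y
  ), class = "segmented_fit")
}

eval_segmented <- function(coef, psi, x) {
  coef <- unname(coef)
  out <- coef[1] + coef[2] * x
  for (j in seq_along(psi)) out <- out + coef[2 + j] * pmax(x - psi[j], 0)
  out
}

#' Predict from a segmented fit
#'
#' Evaluates the continuous piecewise-linear curve; values outside the fitted
#' span are linearly extrapolated from the terminal segments with a warning.
#'
#' @param fit a `segmented_fit`.
#' @param xnew numeric heights at which to predict.
#' @return Numeric predictions.
#' @export
predict_segmented <- function(fit, xnew) {
  span <- range(fit$x)
  if (any(xnew < span[1] - 1e-9 | xnew > span[2] + 1e-9))
    warning("predicting outside the fitted span; extrapolating terminal segment")
  eval_segmented(fit$coefficients, fit$breakpoints, xnew)
}

#' Select the number of breakpoints by BIC
#'
#' Fits `k = 0..K_max` breakpoints and returns the fit minimizing BIC, used
#' both for proxy state-shift detection and to provide the imputation curve.
#' Each breakpoint contributes two effective parameters (its position and its
#' slope change). Values of `k` for which the data are too short are skipped.
#'
#' @inheritParams fit_segmented
#' @param K_max largest breakpoint count to consider (>= 1).
#' @return The selected `segmented_fit` with attribute `bic_trace`.
#' @export
select_segmented <- function(x, y, K_max = 3, ...) {
  stopifnot(K_max >= 1)
  fits <- list()
  for (k in 0:K_max) {
    if (length(x) < 2 * k + 4 || length(x) < (k + 1) * 3) next
    fits[[paste0("k", k)]] <- fit_segmented(x, y, k, ...)
  }
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[order(bics, seq_along(bics))[1]]]
  attr(best, "bic_trace") <- bics
  best
}

#' Flag transient anomalies (spikes) against a segmented trend
#'
#' Volcanism-type tracers are expected to register as transient spikes rather
#' than persistent state shifts. A sample is flagged when its absolute
#' residual from the segmented trend exceeds `threshold` times the MAD-based
#' robust scale of all residuals. If the robust scale is zero nothing is
#' flagged.
#'
#' @param x,y the data the fit was computed from.
#' @param fit a `segmented_fit` of the same data.
#' @param threshold multiple of the robust scale (default 3).
#' @return Data frame `x, y, residual, flag` (class `anomaly_flags`) with
#'   attribute `scale`.
#' @export
flag_anomalies <- function(x, y, fit, threshold = 3) {
  ord <- order(x)
  res <- y[ord] - predict_segmented(fit, x[ord])
  sc <- stats::mad(res)
  flag <- if (sc > 0) abs(res) > threshold * sc else rep(FALSE, length(res))
  out <- data.frame(x = x[ord], y = y[ord], residual = res, flag = flag)
  attr(out, "scale") <- sc
  attr(out, "threshold") <- threshold
  class(out) <- c("anomaly_flags", "data.frame")
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented regression:", x$n_breakpoints, "breakpoint(s)")
  if (x$n_breakpoints)
    cat(" at", paste(sprintf("%.4f", x$breakpoints), collapse = ", "))
  cat(sprintf("\n  SSE: %.5g   BIC: %.3f   converged: %s\n",
              x$sse, x$bic, x$converged))
  print(round(x$coefficients, 5))
  invisible(x)
}
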