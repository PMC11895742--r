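#' Pairwise correlation screen
#'
#' Pearson and Spearman correlations with two-sided p-values for every pair
#' of columns of a bed-by-proxy matrix, optionally including a response
#' (e.g. richness) as an extra column. Zero-variance columns yield `NA`
#' correlations for their pairs.
#'
#' @param mat numeric matrix or data frame, rows = beds, columns = proxies.
#' @param response optional numeric vector appended as column `"response"`.
#' @return Data frame `var1, var2, pearson_r, pearson_p, spearman_r,
#'   spearman_p`, one row per unordered pair.
#' @export
correlation_screen <- function(mat, response = NULL) {
  mat <- as.data.frame(mat)
  if (!is.null(response)) mat$response <- response
  if (nrow(mat) < 3) stop("need at least 3 complete rows")
  nm <- names(mat)
  pairs <- utils::combn(length(nm), 2)
  out <- data.frame(var1 = nm[pairs[1, ]], var2 = nm[pairs[2, ]],
                    pearson_r = NA_real_, pearson_p = NA_real_,
                    spearman_r = NA_real_, spearman_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- mat[[pairs[1, i]]]; b <- mat[[pairs[2, i]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    pe <- stats::cor.test(a, b, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    out$pearson_r[i] <- unname(pe$estimate); out$pearson_p[i] <- pe$p.value
    out$spearman_r[i] <- unname(sp$estimate); out$spearman_p[i] <- sp$p.value
  }
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the OLS regression of
#' column `j` on all other columns. Perfect collinearity is reported as
#' `Inf`.
#'
#' @param mat numeric matrix or data frame with >= 2 columns and more rows
#'   than columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(mat) {
  mat <- as.data.frame(mat)
  if (ncol(mat) < 2) stop("VIF needs at least 2 columns")
  if (nrow(mat) <= ncol(mat)) stop("VIF needs more rows than columns")
  vapply(seq_along(mat), function(j) {
    fit <- stats::lm.fit(cbind(1, as.matrix(mat[, -j, drop = FALSE])), mat[[j]])
    ssr <- sum(fit$residuals^2)
    sst <- sum((mat[[j]] - mean(mat[[j]]))^2)
    if (sst == 0) return(NA_real_)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(names(mat))
}

#' Iteratively drop collinear predictors
#'
#' Removes `forced_drops` first (e.g. a proxy measured at too coarse a
#' resolution), then repeatedly drops the highest-VIF column above
#' `vif_threshold` until all remaining VIFs are below it. Every drop is
#' recorded with the VIF that triggered it.
#'
#' @param mat bed-by-proxy data frame.
#' @param vif_threshold drop columns whose VIF exceeds this (default 10).
#' @param forced_drops character vector of columns to remove unconditionally.
#' @return The reduced data frame, with attribute `audit`: a data frame
#'   `dropped, vif, reason` in drop order.
#' @export
drop_collinear <- function(mat, vif_threshold = 10, forced_drops = character()) {
  mat <- as.data.frame(mat)
  audit <- data.frame(dropped = character(0), vif = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
  for (f in intersect(forced_drops, names(mat))) {
    audit <- rbind(audit, data.frame(dropped = f, vif = NA_real_,
                                     reason = "forced", stringsAsFactors = FALSE))
    mat[[f]] <- NULL
  }
  while (ncol(mat) >= 2) {
    v <- vif(mat)
    v[is.na(v)] <- 0
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    audit <- rbind(audit, data.frame(dropped = worst, vif = max(v),
                                     reason = "vif", stringsAsFactors = FALSE))
    mat[[worst]] <- NULL
  }
  attr(mat, "audit") <- audit
  mat
}

#' Poisson GLM of richness on proxies
#'
#' Log-link Poisson regression of per-bed species richness on bed-level proxy
#' values, fitted by iteratively reweighted least squares via [stats::glm()].
#'
#' @param response non-negative integer counts (per-bed richness).
#' @param mat bed-by-proxy data frame aligned to `response`.
#' @return A `glm_result`: list with `coefficients` (a table with estimate,
#'   SE, z, p), `null_deviance`, `deviance`, `aic`, `converged`, and the
#'   underlying `glm` object as `fit`.
#' @export
fit_poisson_glm <- function(response, mat = NULL) {
  if (any(response < 0) || any(response != round(response)))
    stop("response must be non-negative integer counts")
  dat <- if (is.null(mat) || ncol(as.data.frame(mat)) == 0)
    data.frame(.y = response)
  else cbind(data.frame(.y = response), as.data.frame(mat))
  fit <- stats::glm(.y ~ ., data = dat, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  s <- summary(fit)
  co <- s$coefficients
  colnames(co) <- c("estimate", "se", "z", "p")
  structure(list(
    coefficients = co,
    null_deviance = fit$null.deviance,
    deviance = fit$deviance,
    aic = fit$aic,
    converged = fit$converged,
    fit = fit
  ), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("Poisson GLM (log link)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("null deviance %.3f, residual deviance %.3f, AIC %.3f\n",
              x$null_deviance, x$deviance, x$aic))
  invisible(x)
}

#' Paired Poisson GLMs for two collinear focal proxies
#'
#' When two proxies are too correlated to enter one model (at Meishan,
#' the Cd-isotope productivity proxy against apatite oxygen isotopes), two
#' models are fitted on the otherwise identical post-VIF predictor set: model
#' A excludes `focal[1]`, model B excludes `focal[2]`. Their AICs are
#' compared.
#'
#' @param response per-bed richness counts.
#' @param mat bed-by-proxy data frame containing both focal columns.
#' @param focal character vector of the two mutually exclusive proxies;
#'   defaults to `c("d114_110Cd", "d18O_apatite")`.
#' @return List with `model_a` (without `focal[1]`), `model_b` (without
#'   `focal[2]`), and `aic` (named vector).
#' @export
run_glm_pair <- function(response, mat,
                         focal = c("d114_110Cd", "d18O_apatite")) {
  mat <- as.data.frame(mat)
  if (!all(focal %in% names(mat)))
    stop("focal proxy missing from matrix: ",
         paste(setdiff(focal, names(mat)), collapse = ", "))
  a <- fit_poisson_glm(response, mat[, setdiff(names(mat), focal[1]), drop = FALSE])
  b <- fit_poisson_glm(response, mat[, setdiff(names(mat), focal[2]), drop = FALSE])
  list(model_a = a, model_b = b,
       aic = c(without_first_focal = a$aic, without_second_focal = b$aic))
}

#' Jaccard distances between bed assemblages
#'
#' Binary Jaccard dissimilarity `1 - |A ∩ B| / |A ∪ B|` between the taxon
#' sets of each pair of beds. Beds with no taxa at all are at distance 1 from
#' non-empty beds and, by convention, distance 0 from each other (with a
#' warning).
#'
#' @param incidence 0/1 matrix, rows = taxa, columns = beds.
#' @return A `dist` object over beds.
#' @export
jaccard_distances <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (ncol(incidence) < 2) stop("need at least 2 beds")
  m <- t(incidence) > 0
  empty <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  if (any(empty)) {
    warning("bed(s) with empty assemblages: ",
            paste(colnames(incidence)[empty], collapse = ", "))
    dm <- as.matrix(d)
    dm[empty, ] <- 1; dm[, empty] <- 1
    dm[empty, empty] <- 0
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  d
}

#' Partial distance-based redundancy analysis
#'
#' Constrained ordination of a dissimilarity matrix on explanatory proxy
#' columns, after partialling out conditioning variables; the distance matrix
#' is embedded by principal coordinates and the real axes regressed on the
#' constraints (capscale approach). Negative eigenvalues are reported, not
#' corrected, unless `sqrt_correction = TRUE` takes the square root of the
#' dissimilarities first.
#'
#' @param d a `dist` over beds (e.g. from [jaccard_distances()]).
#' @param constraints data frame of explanatory columns, rows aligned to `d`.
#' @param condition optional data frame of conditioning columns.
#' @param sqrt_correction take `sqrt(d)` before analysis (makes Jaccard
#'   distances Euclidean-embeddable).
#' @return A `dbrda_result`: list with `constrained_eig`, `unconstrained_eig`,
#'   `imaginary_inertia`, `proportion_constrained`, `site_scores`,
#'   `biplot_scores`, `conditioned`, and the underlying vegan object `fit`.
#' @export
partial_dbrda <- function(d, constraints = NULL, condition = NULL,
                          sqrt_correction = FALSE) {
  if (sqrt_correction) d <- sqrt(d)
  n <- attr(d, "Size")
  dat <- data.frame(row.names = seq_len(n))
  rhs <- "1"
  if (!is.null(constraints) && ncol(as.data.frame(constraints))) {
    constraints <- as.data.frame(constraints)
    if (nrow(constraints) != n) stop("constraints rows must match distance size")
    if (ncol(constraints) >= n - 1) stop("model saturated: too many constraints")
    dat <- cbind(dat, constraints)
    rhs <- paste(colnames(constraints), collapse = " + ")
  }
  if (!is.null(condition) && ncol(as.data.frame(condition))) {
    condition <- as.data.frame(condition)
    dat <- cbind(dat, condition)
    rhs <- paste0(rhs, " + Condition(",
                  paste(colnames(condition), collapse = " + "), ")")
  }
  fm <- stats::as.formula(paste("d ~", rhs))
  environment(fm) <- environment()
  fit <- vegan::capscale(fm, data = dat)
  has_cca <- !is.null(fit$CCA)
  # capscale reports inertia on a variance scale; rescale by (n - 1) so the
  # unconstrained eigenvalues coincide with classical PCoA of the same d
  sc <- n - 1
  ceig <- if (has_cca) fit$CCA$eig * sc else numeric(0)
  ueig <- fit$CA$eig * sc
  total <- sum(ceig) + sum(ueig) + sum(abs(fit$pCCA$tot.chi %||% 0)) * sc
  structure(list(
    constrained_eig = ceig,
    unconstrained_eig = ueig,
    imaginary_inertia = if (!is.null(fit$CA$imaginary.chi)) abs(fit$CA$imaginary.chi) * sc else 0,
    proportion_constrained = if (total > 0) sum(ceig) / total else 0,
    site_scores = if (has_cca || length(ueig))
      vegan::scores(fit, display = "sites",
                    choices = seq_len(min(2, has_cca * length(ceig) + length(ueig)))),
    biplot_scores = if (has_cca) fit$CCA$biplot,
    conditioned = if (!is.null(condition)) colnames(condition) else character(0),
    data = dat,
    fit = fit
  ), class = "dbrda_result")
}

#' Permutation tests for a partial dbRDA
#'
#' Overall and marginal (per-term) permutation tests of the constrained
#' inertia pseudo-F, permuting residuals of the conditioning model when
#' conditions are present; `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#' Deterministic given `seed`.
#'
#' @param result a `dbrda_result`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return List with `overall` (statistic + p) and `terms` (data frame of
#'   per-term marginal tests).
#' @export
permutation_test_dbrda <- function(result, n_perm = 199, seed = NULL) {
  stopifnot(n_perm >= 99)
  fit <- result$fit
  with_seed(seed, {
    ov <- stats::anova(fit, permutations = n_perm)
    terms <- if (!is.null(fit$CCA))
      stats::anova(fit, by = "margin", permutations = n_perm)
    else NULL
    list(
      overall = list(F = ov$F[1], p = ov$`Pr(>F)`[1]),
      terms = if (!is.null(terms))
        data.frame(term = rownames(terms)[seq_len(nrow(terms) - 1)],
                   F = terms$F[seq_len(nrow(terms) - 1)],
                   p = terms$`Pr(>F)`[seq_len(nrow(terms) - 1)],
                   stringsAsFactors = FALSE)
    )
  })
}

#' Within-bed proxy variance versus extinction rate
#'
#' For each proxy, correlates its within-bed sample variance with the per-bed
#' extinction rate (Spearman, pairwise-complete). Beds with fewer than two
#' samples contribute no variance. A proxy whose variance series is constant
#' or all-missing is reported with `NA`.
#'
#' @param bed_variances data frame `proxy, bed_id, var` (e.g. stacked `var`
#'   columns of [aggregate_to_beds()]).
#' @param rates data frame `bed_id, rate` from [extinction_rate_per_bed()].
#' @return Data frame `proxy, n, spearman_r, p`.
#' @export
variance_vs_extinction_rate <- function(bed_variances, rates) {
  stopifnot_cols(bed_variances, c("proxy", "bed_id", "var"), "bed_variances")
  stopifnot_cols(rates, c("bed_id", "rate"), "rates")
  proxies <- unique(bed_variances$proxy)
  out <- data.frame(proxy = proxies, n = 0L, spearman_r = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(proxies)) {
    sub <- bed_variances[bed_variances$proxy == proxies[i], , drop = FALSE]
    v <- sub$var[match(rates$bed_id, sub$bed_id)]
    ok <- !is.na(v) & !is.na(rates$rate)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 4 && stats::sd(v[ok]) > 0 && stats::sd(rates$rate[ok]) > 0) {
      ct <- suppressWarnings(stats::cor.test(v[ok], rates$rate[ok],
                                             method = "spearman"))
      out$spearman_r[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out
}

#' Polynomial trend fit
#'
#' Least-squares polynomial of a response on a proxy (default order 2), as
#' used for overlaying a trend line on scatter plots of body size against an
#' environmental proxy.
#'
#' @param x,y numeric vectors.
#' @param degree polynomial order (default 2). Requires `n >= degree + 2`.
#' @return List with `coefficients` (ascending powers), `r_squared`,
#'   `fitted`, and the `lm` object as `fit`.
#' @export
fit_polynomial_trend <- function(x, y, degree = 2) {
  if (length(x) < degree + 2) stop("need n >= degree + 2 points")
  if (stats::sd(x) == 0) stop("degenerate x: all values equal")
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  list(coefficients = stats::setNames(co, paste0("b", 0:degree)),
       r_squared = summary(fit)$r.squared,
       fitted = unname(stats::fitted(fit)),
       fit = fit)
}
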