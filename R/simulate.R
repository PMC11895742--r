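#' Simulation configuration
#'
#' Bundles everything the synthetic generators need: a stratigraphic column,
#' the true extinction model (discrete pulses or a continuous interval),
#' per-bed recovery probabilities, proxy specifications, optional Poisson
#' link coefficients for richness, and a mandatory seed.
#'
#' @param n_taxa number of taxa to simulate.
#' @param column a [strat_column()].
#' @param pulse_beds character vector of bed ids at which extinction pulses
#'   sit (`true_k = length(pulse_beds)`); taxa are split evenly across pulses
#'   unless `pulse_weights` is given. Mutually exclusive with `interval_beds`.
#' @param interval_beds length-2 character vector: taxa die uniformly over
#'   the beds between these ids (inclusive). Encodes the `k = 0` model.
#' @param pulse_weights optional assignment probabilities over pulses.
#' @param recovery scalar or per-bed vector of sampling probabilities in
#'   (0, 1].
#' @param proxies optional named list of proxy specs, each a list with
#'   `breakpoints` (heights), `slopes` (length = breakpoints + 1),
#'   `intercept`, `sigma` (noise SD), `heights` (sample heights; default 5
#'   per bed at regular spacing).
#' @param glm_coef optional named numeric vector `(intercept, <proxy names>)`
#'   for [simulate_linked_richness()].
#' @param seed integer seed; mandatory so every generator is a pure function
#'   of its configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa, column, pulse_beds = NULL, interval_beds = NULL,
                       pulse_weights = NULL, recovery = 0.7, proxies = NULL,
                       glm_coef = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(pulse_beds) == is.null(interval_beds))
    stop("give exactly one of pulse_beds or interval_beds")
  if (any(recovery <= 0) || any(recovery > 1))
    stop("recovery probabilities must be in (0, 1]")
  if (!is.null(pulse_beds)) bed_index(column, pulse_beds)
  if (!is.null(interval_beds)) bed_index(column, interval_beds)
  structure(list(
    n_taxa = n_taxa, column = column, pulse_beds = pulse_beds,
    interval_beds = interval_beds, pulse_weights = pulse_weights,
    recovery = rep_len(recovery, nrow(column)),
    proxies = proxies, glm_coef = glm_coef, seed = seed
  ), class = "sim_config")
}

#' Simulate a fossil occurrence table under Signor-Lipps thinning
#'
#' Each taxon receives a true extinction bed (its assigned pulse, or uniform
#' over the configured interval) and an origination bed uniform at or below
#' it; in every bed it lived through it is sampled independently with that
#' bed's recovery probability. Taxa with zero sampled occurrences are dropped
#' (and counted), exactly the censoring a real occurrence database suffers.
#'
#' @param cfg a [sim_config()].
#' @return List: `occurrences` (an `occurrence_df`), and `truth` with the
#'   true `k`, pulse/interval beds, per-taxon extinction beds and
#'   assignments, and `n_dropped`.
#' @export
simulate_occurrences <- function(cfg) {
  col <- cfg$column
  B <- nrow(col)
  with_seed(cfg$seed, {
    if (!is.null(cfg$pulse_beds)) {
      k <- length(cfg$pulse_beds)
      pulse_pos <- match(cfg$pulse_beds, col$bed_id)
      w <- cfg$pulse_weights %||% rep(1 / k, k)
      assignment <- sample.int(k, cfg$n_taxa, replace = TRUE, prob = w)
      ext <- pulse_pos[assignment]
    } else {
      k <- 0L
      iv <- match(cfg$interval_beds, col$bed_id)
      assignment <- rep(NA_integer_, cfg$n_taxa)
      ext <- sample(seq.int(iv[1], iv[2]), cfg$n_taxa, replace = TRUE)
    }
    orig <- vapply(ext, function(e) sample.int(e, 1), integer(1))
    rows <- vector("list", cfg$n_taxa)
    for (t in seq_len(cfg$n_taxa)) {
      beds <- seq.int(orig[t], ext[t])
      hit <- beds[stats::runif(length(beds)) < cfg$recovery[beds]]
      if (length(hit))
        rows[[t]] <- data.frame(taxon = sprintf("sp%03d", t),
                                bed_id = col$bed_id[hit],
                                stringsAsFactors = FALSE)
    }
    kept <- !vapply(rows, is.null, logical(1))
    occ <- do.call(rbind, rows[kept])
    if (is.null(occ))
      occ <- data.frame(taxon = character(0), bed_id = character(0))
    occ$clade <- "Simulata"
    occ$qualifier <- "none"
    occ$habitat <- "marine"
    occ$palynomorph <- FALSE
    occ$source <- "simulation"
    occ$resolved <- TRUE
    occ <- occ[, c("taxon", "clade", "bed_id", "qualifier", "habitat",
                   "palynomorph", "source", "resolved")]
    list(
      occurrences = as_occurrences(occ, col),
      truth = list(k = k, pulse_beds = cfg$pulse_beds,
                   interval_beds = cfg$interval_beds,
                   extinction_pos = ext, origination_pos = orig,
                   assignment = assignment,
                   kept = kept, n_dropped = sum(!kept))
    )
  })
}

#' Simulate a proxy series with a piecewise-linear trend
#'
#' Values are a continuous piecewise-linear function of height plus additive
#' Gaussian noise, sampled at the configured heights (default: 5 evenly spaced
#' samples per bed).
#'
#' @param cfg a [sim_config()] whose `proxies` entry names `proxy`.
#' @param proxy name of the proxy spec to draw.
#' @return List: `series` (a `proxy_series`) and `truth` (breakpoints,
#'   slopes, intercept, sigma).
#' @export
simulate_proxy <- function(cfg, proxy) {
  spec <- cfg$proxies[[proxy]]
  if (is.null(spec)) stop("no proxy spec named ", proxy)
  col <- cfg$column
  h <- spec$heights %||% {
    unlist(lapply(seq_len(nrow(col)), function(i)
      seq(col$base_m[i], col$top_m[i], length.out = 7)[2:6]))
  }
  mu <- piecewise_mean(h, spec$intercept %||% 0, spec$slopes, spec$breakpoints)
  vals <- with_seed(cfg$seed + match(proxy, names(cfg$proxies)), {
    mu + stats::rnorm(length(h), 0, spec$sigma %||% 0)
  })
  out <- data.frame(height = h, value = vals)
  attr(out, "proxy") <- proxy
  attr(out, "units") <- spec$units %||% "unitless"
  class(out) <- c("proxy_series", "data.frame")
  list(series = out,
       truth = list(breakpoints = spec$breakpoints, slopes = spec$slopes,
                    intercept = spec$intercept %||% 0,
                    sigma = spec$sigma %||% 0))
}

# continuous piecewise-linear mean with given segment slopes
piecewise_mean <- function(h, intercept, slopes, breakpoints) {
  stopifnot(length(slopes) == length(breakpoints) + 1)
  mu <- intercept + slopes[1] * h
  for (j in seq_along(breakpoints))
    mu <- mu + (slopes[j + 1] - slopes[j]) * pmax(h - breakpoints[j], 0)
  mu
}

#' Simulate richness counts linked to proxies through a log-linear model
#'
#' `counts_b ~ Poisson(exp(b0 + sum_j b_j x_bj))` per bed.
#'
#' @param proxy_mat bed-by-proxy matrix or data frame.
#' @param coef named numeric: intercept first, then one coefficient per
#'   proxy column.
#' @param seed integer seed.
#' @return Integer vector of counts, one per row of `proxy_mat`.
#' @export
simulate_linked_richness <- function(proxy_mat, coef, seed) {
  X <- as.matrix(as.data.frame(proxy_mat))
  if (length(coef) != ncol(X) + 1)
    stop("coef must be intercept plus one value per proxy column")
  eta <- coef[1] + drop(X %*% coef[-1])
  if (any(eta > 30)) stop("Poisson mean overflow: eta > 30")
  with_seed(seed, stats::rpois(length(eta), exp(eta)))
}

#' The mini-Meishan synthetic fixture
#'
#' A deterministic, fully synthetic 12-bed, 40-taxon, 4-proxy dataset with a
#' known two-pulse extinction (beds 6 and 10) under recovery probability 0.9,
#' and one proxy whose piecewise trend breaks at the height of the first
#' pulse. It emulates the structure of the Meishan bed/sub-bed data at toy
#' scale and is used throughout the documentation and tests; it contains no
#' measured data.
#'
#' @return List with `column`, `occurrences`, `proxies` (named list of
#'   `proxy_series`), `glm_coef`, and the generator `truth`.
#' @export
fixture_mini_meishan <- function() {
  column <- strat_column(
    bed_id = c("1", "2", "3", "4", "5", "6", "7", "8", "9a", "9b", "10", "11"),
    base_m = seq(-6, 5, by = 1), top_m = seq(-5, 6, by = 1),
    lithology = c(rep("limestone", 5), "silty_limestone", "limestone",
                  "limestone", "clay", "clay", "silty_limestone", "limestone"),
    formation = rep("Synthetica", 12)
  )
  pulse_beds <- c("6", "10")
  mid1 <- bed_midpoints(column)[["6"]]  # height of the first pulse
  proxies <- list(
    d13C_carb = list(intercept = 2, slopes = c(0, -1.5), breakpoints = mid1,
                     sigma = 0.15, units = "permil"),
    d18O_apatite = list(intercept = 20, slopes = c(-0.1, -0.8),
                        breakpoints = mid1, sigma = 0.2, units = "permil"),
    d114_110Cd = list(intercept = 0.3, slopes = c(0.05, -0.4),
                      breakpoints = mid1, sigma = 0.05, units = "permil"),
    FeHR_FeT = list(intercept = 0.5, slopes = c(0.01), breakpoints = numeric(0),
                    sigma = 0.05, units = "ratio")
  )
  cfg <- sim_config(
    n_taxa = 40, column = column, pulse_beds = pulse_beds,
    pulse_weights = c(0.5, 0.5), recovery = 0.9,
    proxies = proxies,
    glm_coef = c(intercept = 2.5, d13C_carb = 0.25, d18O_apatite = 0,
                 d114_110Cd = 0.8, FeHR_FeT = 0),
    seed = 20260927
  )
  occ <- simulate_occurrences(cfg)
  series <- lapply(names(proxies), function(p) simulate_proxy(cfg, p)$series)
  names(series) <- names(proxies)
  list(column = column, occurrences = occ$occurrences, proxies = series,
       glm_coef = cfg$glm_coef, config = cfg, truth = occ$truth)
}

#' Write a simulated dataset in the package's CSV dialects
#'
#' Serializes a fixture (or any simulated dataset of the same shape) to the
#' `occurrences.csv`, `column.csv` and `proxies.csv` formats the loaders
#' read, so round-trips are testable.
#'
#' @param data list with `column`, `occurrences`, `proxies` as returned by
#'   [fixture_mini_meishan()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(column = file.path(dir, "column.csv"),
             occurrences = file.path(dir, "occurrences.csv"),
             proxies = file.path(dir, "proxies.csv"))
  utils::write.csv(as.data.frame(data$column)[
    c("bed_id", "base_m", "top_m", "lithology", "formation")],
    paths["column"], row.names = FALSE)
  utils::write.csv(as.data.frame(data$occurrences), paths["occurrences"],
                   row.names = FALSE)
  prox <- do.call(rbind, lapply(names(data$proxies), function(p) {
    s <- data$proxies[[p]]
    data.frame(proxy = p, height_m = s$height, bed_id = NA_character_,
               value = s$value, units = attr(s, "units") %||% NA_character_,
               source_section = "outcrop_D", reference = "synthetic",
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(prox, paths["proxies"], row.names = FALSE)
  invisible(paths)
}
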