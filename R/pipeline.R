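#' Analysis configuration
#'
#' Collects the inputs and tuning parameters of the full pipeline. Inputs may
#' be in-memory objects (as produced by the loaders or simulators) or file
#' paths to the package's CSV dialects.
#'
#' @param column a [strat_column()] or path to a column CSV.
#' @param occurrences an `occurrence_df` or path to an occurrence CSV.
#' @param proxies named list of `proxy_series`, or path to a proxy CSV (each
#'   proxy standardized via [standardize_heights()]).
#' @param synonyms optional synonym data frame (`old_name, current_name`).
#' @param window character length-2: first and last bed of the analysis
#'   window, inclusive.
#' @param ci_confidence confidence level for range CIs (default 0.95).
#' @param K_max_pulses,K_max_breaks model-size caps for pulse-count and
#'   breakpoint-count selection.
#' @param min_richness minimum non-singleton species per clade.
#' @param vif_threshold collinearity threshold for [drop_collinear()].
#' @param forced_drops proxies dropped from models unconditionally.
#' @param focal_pair two mutually exclusive proxies for the paired GLMs, or
#'   NULL to fit a single model.
#' @param n_perm permutations for dbRDA tests.
#' @param n_boot bootstrap replicates for pulse selection/confidence.
#' @param seed mandatory integer seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(column, occurrences, proxies, synonyms = NULL,
                            window, ci_confidence = 0.95,
                            K_max_pulses = 3, K_max_breaks = 3,
                            min_richness = 10, vif_threshold = 10,
                            forced_drops = character(),
                            focal_pair = c("d114_110Cd", "d18O_apatite"),
                            n_perm = 199, n_boot = 199, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Field names follow [analysis_config()]; file paths are resolved relative
#' to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (f in c("column", "occurrences", "proxies", "synonyms"))
    if (!is.null(y[[f]]) && is.character(y[[f]]) && !file.exists(y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  do.call(analysis_config, y)
}

resolve_inputs <- function(config) {
  cfg <- config
  if (is.character(cfg$column)) cfg$column <- read_column(cfg$column)
  if (is.character(cfg$occurrences))
    cfg$occurrences <- load_occurrences(cfg$occurrences, cfg$column)
  if (is.character(cfg$proxies)) {
    raw <- load_proxies(cfg$proxies)
    cfg$proxies <- lapply(split(raw, raw$proxy), standardize_heights,
                          column = cfg$column)
  }
  if (is.character(cfg$synonyms))
    cfg$synonyms <- utils::read.csv(cfg$synonyms, stringsAsFactors = FALSE)
  cfg
}

stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full extinction-dynamics analysis
#'
#' Orchestrates the whole chain with deterministic seeding: vetting and
#' range construction; pooled and per-clade extinction-pulse selection with
#' bootstrap confidence intervals; per-proxy segmented fits, bed-level
#' aggregation and imputation; window restriction; correlation screen and
#' VIF reduction; the paired Poisson GLMs; partial dbRDA of Jaccard
#' incidence distances with permutation tests; and the proxy-variance versus
#' extinction-rate check. Any stage error aborts with a stage-named message.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, summary tables are written
#'   (`fig2_pulses.tsv`, `fig3_breakpoints.tsv`, `table1_glm.tsv`,
#'   `fig4_scores.csv`, `variance_rate.tsv`, `run_log.txt`).
#' @return A report list (class `stratpulse_report`).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  cfg <- stage("inputs", resolve_inputs(config))
  column <- cfg$column
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  occs <- stage("vet", {
    v <- vet_occurrences(cfg$occurrences, cfg$synonyms)
    note("vetting: %d -> %d records (habitat/palynomorph filter, synonymy, dedup)",
         nrow(cfg$occurrences), nrow(v))
    v <- drop_unresolved(v)
    note("resolution filter: dropped %d unresolved records", attr(v, "n_dropped"))
    v
  })
  ranges <- stage("ranges", compute_ranges(occs, column))
  note("ranges: %d taxa (%d singletons)", nrow(ranges), sum(ranges$is_singleton))

  window <- stage("window", column_window(column, cfg$window))
  if (nrow(window) < 3) stop("pipeline stage 'window' failed: fewer than 3 beds in window")

  rcis <- stage("range_ci", {
    ns <- ranges[!ranges$is_singleton, , drop = FALSE]
    range_ci(ns, cfg$ci_confidence)
  })

  pulses <- stage("pulses", {
    lads <- lads_from_ranges(ranges, window)
    rec <- estimate_recovery(ranges, window)
    best <- select_pulse_count(lads, rec, window, K_max = cfg$K_max_pulses,
                               n_boot = cfg$n_boot, seed = cfg$seed + 1)
    best <- pulse_confidence(best, lads, rec, window, n_boot = cfg$n_boot,
                             C = cfg$ci_confidence, seed = cfg$seed + 2)
    note("pooled pulse model: k = %d", best$k)
    list(pooled = best, recovery = rec, lads = lads)
  })
  clades <- stage("per_clade", per_clade_pulses(
    ranges, window, min_richness = cfg$min_richness,
    K_max = cfg$K_max_pulses, n_boot = cfg$n_boot, seed = cfg$seed + 3))

  prox <- stage("proxies", {
    out <- list()
    for (p in names(cfg$proxies)) {
      s <- cfg$proxies[[p]]
      in_win <- s$height >= min(window$base_m) & s$height < max(window$top_m)
      sw <- s[in_win, , drop = FALSE]
      fit <- select_segmented(sw$height, sw$value, K_max = cfg$K_max_breaks)
      beds <- aggregate_to_beds(sw, window)
      filled <- impute_missing(beds, fit, window)
      note("proxy %s: %d samples in window, %d breakpoint(s), %d bed(s) imputed",
           p, nrow(sw), fit$n_breakpoints, sum(filled$status == "imputed"))
      out[[p]] <- list(fit = fit, beds = filled, samples = sw)
    }
    out
  })

  design <- stage("design", {
    mat <- as.data.frame(lapply(prox, function(z) z$beds$value))
    rownames(mat) <- window$bed_id
    rich <- richness_per_bed(ranges, window)
    list(mat = mat, richness = rich$richness)
  })

  screen <- stage("correlation", correlation_screen(design$mat, design$richness))
  reduced <- stage("vif", drop_collinear(design$mat, cfg$vif_threshold,
                                         cfg$forced_drops))

  glms <- stage("glm", {
    if (!is.null(cfg$focal_pair) && all(cfg$focal_pair %in% names(design$mat))) {
      keep <- union(names(reduced), cfg$focal_pair)
      run_glm_pair(design$richness, design$mat[, keep, drop = FALSE],
                   focal = cfg$focal_pair)
    } else {
      list(model_a = fit_poisson_glm(design$richness, reduced), model_b = NULL,
           aic = NULL)
    }
  })

  ordin <- stage("dbrda", {
    inc <- incidence_matrix(occs, column, window)
    d <- jaccard_distances(inc)
    res <- partial_dbrda(d, constraints = reduced)
    perm <- permutation_test_dbrda(res, n_perm = cfg$n_perm,
                                   seed = cfg$seed + 4)
    list(dbrda = res, permutation = perm, incidence = inc)
  })

  var_rate <- stage("variance_rate", {
    rates <- extinction_rate_per_bed(ranges, window)
    bv <- do.call(rbind, lapply(names(prox), function(p)
      data.frame(proxy = p, bed_id = prox[[p]]$beds$bed_id,
                 var = prox[[p]]$beds$var, stringsAsFactors = FALSE)))
    list(table = variance_vs_extinction_rate(bv, rates), rates = rates)
  })

  report <- structure(list(
    config = cfg, log = log, ranges = ranges, range_cis = rcis,
    window = window, pulses = pulses$pooled, recovery = pulses$recovery,
    per_clade = clades, proxies = prox, design = design,
    correlation = screen, reduced = reduced, glm = glms,
    ordination = ordin, variance_rate = var_rate
  ), class = "stratpulse_report")

  if (!is.null(out_dir)) write_report_tables(report, out_dir)
  report
}

# taxa x beds 0/1 sampled-incidence matrix over a window
incidence_matrix <- function(occs, column, window) {
  idx <- bed_index(column, occs$bed_id)
  keep <- idx %in% window$order_index
  taxa <- sort(unique(occs$taxon[keep]))
  inc <- matrix(0L, nrow = length(taxa), ncol = nrow(window),
                dimnames = list(taxa, window$bed_id))
  pos <- match(idx[keep], window$order_index)
  inc[cbind(match(occs$taxon[keep], taxa), pos)] <- 1L
  inc
}

write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)

  pm <- report$pulses
  pulse_rows <- if (pm$k >= 1)
    data.frame(group = "pooled", model = "pulses", k = pm$k,
               bed = pm$pulse_beds, height_m = pm$pulse_heights,
               ci_low = if (!is.null(pm$pulse_cis)) pm$pulse_cis[, "low"] else NA,
               ci_high = if (!is.null(pm$pulse_cis)) pm$pulse_cis[, "high"] else NA)
  else
    data.frame(group = "pooled", model = "interval", k = 0,
               bed = pm$interval_beds, height_m = pm$interval_bounds,
               ci_low = NA, ci_high = NA)
  for (cl in names(report$per_clade)) {
    m <- report$per_clade[[cl]]
    if (identical(m, "insufficient")) {
      pulse_rows <- rbind(pulse_rows, data.frame(
        group = cl, model = "insufficient", k = NA, bed = NA, height_m = NA,
        ci_low = NA, ci_high = NA))
    } else if (m$k >= 1) {
      pulse_rows <- rbind(pulse_rows, data.frame(
        group = cl, model = "pulses", k = m$k, bed = m$pulse_beds,
        height_m = m$pulse_heights, ci_low = NA, ci_high = NA))
    } else {
      pulse_rows <- rbind(pulse_rows, data.frame(
        group = cl, model = "interval", k = 0, bed = m$interval_beds,
        height_m = m$interval_bounds, ci_low = NA, ci_high = NA))
    }
  }
  tsv(pulse_rows, "fig2_pulses.tsv")

  bp <- do.call(rbind, lapply(names(report$proxies), function(p) {
    f <- report$proxies[[p]]$fit
    data.frame(proxy = p, n_breakpoints = f$n_breakpoints,
               breakpoints = if (f$n_breakpoints)
                 paste(sprintf("%.4f", f$breakpoints), collapse = ";")
               else "", bic = f$bic)
  }))
  tsv(bp, "fig3_breakpoints.tsv")

  gl <- report$glm
  glm_tab <- function(g, label) {
    co <- as.data.frame(g$coefficients)
    data.frame(model = label, term = rownames(co), co, aic = g$aic,
               row.names = NULL)
  }
  gt <- glm_tab(gl$model_a, "A")
  if (!is.null(gl$model_b)) gt <- rbind(gt, glm_tab(gl$model_b, "B"))
  tsv(gt, "table1_glm.tsv")

  sc <- as.data.frame(report$ordination$dbrda$site_scores)
  sc$bed_id <- report$window$bed_id
  sc$lithology <- report$window$lithology
  utils::write.csv(sc, file.path(out_dir, "fig4_scores.csv"), row.names = FALSE)

  tsv(report$variance_rate$table, "variance_rate.tsv")
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.stratpulse_report <- function(x, ...) {
  cat("stratpulse analysis report\n")
  cat("  window:", x$window$bed_id[1], "to", x$window$bed_id[nrow(x$window)],
      sprintf("(%d beds)\n", nrow(x$window)))
  cat("  taxa:", nrow(x$ranges), "\n")
  cat("  pooled extinction model: ")
  print(x$pulses)
  cat("  proxies:", paste(names(x$proxies), collapse = ", "), "\n")
  invisible(x)
}
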