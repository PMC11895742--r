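#' Load geochemical proxy samples from CSV
#'
#' Expects columns `proxy, value` and at least one of `height_m` / `bed_id`
#' per row (exactly one must be set per sample), plus optional `units,
#' source_section, reference`. To avoid mixing measurements of the same proxy
#' from different studies over the same beds, a proxy appearing under more
#' than one reference is rejected unless `allow_multiple_refs = TRUE`.
#'
#' @param path CSV path.
#' @param allow_multiple_refs permit one proxy to carry several references.
#' @return Data frame of proxy samples (class `proxy_samples`).
#' @export
load_proxies <- function(path, allow_multiple_refs = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("proxy", "value"), "proxy CSV")
  if (!"height_m" %in% names(df)) df$height_m <- NA_real_
  if (!"bed_id" %in% names(df)) df$bed_id <- NA_character_
  for (opt in c("units", "source_section", "reference"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  both <- !is.na(df$height_m) & !is.na(df$bed_id) & nzchar(df$bed_id)
  neither <- is.na(df$height_m) & (is.na(df$bed_id) | !nzchar(df$bed_id))
  if (any(both | neither))
    stop("each proxy sample needs exactly one of height_m or bed_id; bad rows: ",
         paste(utils::head(which(both | neither), 10), collapse = ", "))
  if (any(!is.finite(df$value)))
    stop("non-finite proxy values at rows: ",
         paste(utils::head(which(!is.finite(df$value)), 10), collapse = ", "))
  if (!allow_multiple_refs) {
    nref <- tapply(df$reference, df$proxy,
                   function(r) length(unique(r[!is.na(r)])))
    if (any(nref > 1, na.rm = TRUE))
      stop("proxy with measurements from multiple references (set ",
           "allow_multiple_refs = TRUE to merge deliberately): ",
           paste(names(nref)[which(nref > 1)], collapse = ", "))
  }
  class(df) <- c("proxy_samples", "data.frame")
  df
}

#' Standardize proxy sample heights to the column datum
#'
#' Expresses every sample height in meters relative to the column's datum
#' (for Meishan, 0 m at the base of bed 27c). Samples referenced to a bed
#' rather than a measured height are placed at the bed midpoint. Samples with
#' a measured height are shifted by `datum_shift` (use 0 when the source
#' already reports heights on the column datum).
#'
#' @param samples a `proxy_samples` data frame for a single proxy.
#' @param column a [strat_column()].
#' @param datum_shift meters to add to measured heights to move them onto the
#'   column datum.
#' @return A `proxy_series`: data frame `height, value` sorted by height, with
#'   attributes `proxy` and `units`.
#' @export
standardize_heights <- function(samples, column, datum_shift = 0) {
  prox <- unique(samples$proxy)
  if (length(prox) != 1) stop("standardize_heights expects a single proxy")
  h <- samples$height_m + datum_shift
  from_bed <- is.na(samples$height_m)
  if (any(from_bed)) {
    idx <- match(samples$bed_id[from_bed], column$bed_id)
    if (anyNA(idx))
      stop("proxy sample references unknown bed(s): ",
           paste(unique(samples$bed_id[from_bed][is.na(idx)]), collapse = ", "))
    h[from_bed] <- (column$base_m[idx] + column$top_m[idx]) / 2
  }
  ord <- order(h)
  out <- data.frame(height = h[ord], value = samples$value[ord])
  attr(out, "proxy") <- prox
  attr(out, "units") <- samples$units[1]
  class(out) <- c("proxy_series", "data.frame")
  out
}

#' Map core sample heights onto the outcrop height scale
#'
#' Sections measured on a core and on the outcrop differ in bed thickness, so
#' core heights are rescaled through monotone tie points (paired
#' core/outcrop heights of correlated surfaces) by piecewise-linear
#' interpolation. Heights beyond the first/last tie are linearly extrapolated
#' from the nearest segment, with a warning.
#'
#' @param series a `proxy_series` with heights on the core scale.
#' @param ties data frame with numeric columns `core_m, outcrop_m`, strictly
#'   increasing in both.
#' @return The series with heights on the outcrop scale.
#' @export
map_core_to_outcrop <- function(series, ties) {
  stopifnot_cols(ties, c("core_m", "outcrop_m"), "tie-point table")
  if (nrow(ties) < 2) stop("need at least 2 tie points")
  if (any(diff(ties$core_m) <= 0) || any(diff(ties$outcrop_m) <= 0))
    stop("tie points must be strictly increasing in both coordinates")
  h <- series$height
  out_h <- stats::approx(ties$core_m, ties$outcrop_m, xout = h,
                         rule = 1, ties = "ordered")$y
  below <- h < ties$core_m[1]
  above <- h > ties$core_m[nrow(ties)]
  if (any(below)) {
    s <- (ties$outcrop_m[2] - ties$outcrop_m[1]) / (ties$core_m[2] - ties$core_m[1])
    out_h[below] <- ties$outcrop_m[1] + s * (h[below] - ties$core_m[1])
  }
  if (any(above)) {
    n <- nrow(ties)
    s <- (ties$outcrop_m[n] - ties$outcrop_m[n - 1]) /
      (ties$core_m[n] - ties$core_m[n - 1])
    out_h[above] <- ties$outcrop_m[n] + s * (h[above] - ties$core_m[n])
  }
  if (any(below | above))
    warning(sum(below | above),
            " sample(s) outside the tie-point span; linearly extrapolated")
  out <- series
  out$height <- out_h
  out <- out[order(out$height), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(series)
  attributes(out)[c("proxy", "units")] <- attributes(series)[c("proxy", "units")]
  out
}

#' Aggregate a proxy series to bed resolution
#'
#' Takes the arithmetic mean of all samples whose height falls in each bed's
#' half-open interval `[base, top)` (a sample exactly at a bed top belongs to
#' the bed above). Beds with no samples are returned with `NA` and
#' `n_samples = 0`.
#'
#' @param series a standardized `proxy_series`.
#' @param column a [strat_column()] (possibly windowed).
#' @return Data frame `bed_id, order_index, value, n_samples, var` where
#'   `var` is the within-bed sample variance (NA for < 2 samples).
#' @export
aggregate_to_beds <- function(series, column) {
  pos <- bed_at_height(column, series$height)  # row index in `column`
  inb <- !is.na(pos)
  val <- rep(NA_real_, nrow(column))
  vr <- rep(NA_real_, nrow(column))
  ns <- integer(nrow(column))
  if (any(inb)) {
    sp <- split(series$value[inb], pos[inb])
    i <- as.integer(names(sp))
    val[i] <- vapply(sp, mean, numeric(1))
    vr[i] <- vapply(sp, function(v) if (length(v) >= 2) stats::var(v) else NA_real_,
                    numeric(1))
    ns[i] <- lengths(sp)
  }
  data.frame(bed_id = column$bed_id, order_index = column$order_index,
             value = val, n_samples = ns, var = vr,
             stringsAsFactors = FALSE)
}

#' Impute missing bed-level proxy values from a segmented fit
#'
#' Beds without proxy samples receive the segmented-regression prediction at
#' their midpoint height; observed bed means are never altered. Each value is
#' tagged `observed` or `imputed`.
#'
#' @param bed_values output of [aggregate_to_beds()].
#' @param fit a [segmented_fit][fit_segmented] of the proxy against height.
#' @param column the same [strat_column()] used for aggregation.
#' @return `bed_values` with `NA`s filled and a `status` column.
#' @export
impute_missing <- function(bed_values, fit, column) {
  out <- bed_values
  out$status <- ifelse(is.na(out$value), "imputed", "observed")
  miss <- which(is.na(out$value))
  if (length(miss)) {
    mids <- (column$base_m + column$top_m) / 2
    i <- match(out$order_index[miss], column$order_index)
    h <- mids[i]
    span <- range(fit$x)
    if (any(h < span[1] - 1e-9 | h > span[2] + 1e-9))
      stop("segmented fit does not cover midpoint(s) of missing bed(s): ",
           paste(out$bed_id[miss][h < span[1] | h > span[2]], collapse = ", "))
    out$value[miss] <- predict_segmented(fit, h)
  }
  out
}
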