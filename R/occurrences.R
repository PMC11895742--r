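#' Load fossil occurrences from CSV
#'
#' Reads a flat occurrence table and checks each record against the
#' stratigraphic column. The loader performs no vetting: duplicates, freshwater
#' taxa and palynomorphs are passed through for [vet_occurrences()] to handle.
#'
#' Required columns: `taxon, clade, bed_id, qualifier, habitat, palynomorph,
#' source, resolved`. `qualifier` is one of `none, quotes, question, aff, cf,
#' informal`; `habitat` is `marine` or `freshwater`; `palynomorph` and
#' `resolved` are logical (or 0/1).
#'
#' @param path path to the occurrence CSV.
#' @param column a [strat_column()]; every `bed_id` must resolve in it.
#' @return A data frame of occurrences (class `occurrence_df`). Rows whose
#'   `bed_id` is not in the column raise an error listing the offending rows.
#' @export
load_occurrences <- function(path, column) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "clade", "bed_id", "qualifier", "habitat",
           "palynomorph", "source", "resolved")
  stopifnot_cols(df, req, "occurrence CSV")
  if (nrow(df) == 0) {
    warning("occurrence file is empty")
    return(as_occurrences(df, column))
  }
  as_occurrences(df, column)
}

#' Validate an occurrence data frame against a column
#'
#' @param df data frame with the occurrence columns (see [load_occurrences()]).
#' @param column a [strat_column()].
#' @return The validated `occurrence_df`.
#' @export
as_occurrences <- function(df, column) {
  df$taxon <- as.character(df$taxon)
  df$bed_id <- as.character(df$bed_id)
  if (any(!nzchar(df$taxon))) stop("empty taxon name in occurrence table")
  quals <- c("none", "quotes", "question", "aff", "cf", "informal")
  if (!all(df$qualifier %in% quals))
    stop("qualifier must be one of: ", paste(quals, collapse = ", "))
  if (!all(df$habitat %in% c("marine", "freshwater")))
    stop("habitat must be marine or freshwater")
  df$palynomorph <- as.logical(df$palynomorph)
  df$resolved <- as.logical(df$resolved)
  bad <- !(df$bed_id %in% column$bed_id)
  if (any(bad))
    stop("occurrence rows with bed ids not in the column: ",
         paste(sprintf("row %d (%s)", which(bad), df$bed_id[bad])[
           seq_len(min(10, sum(bad)))], collapse = "; "))
  class(df) <- c("occurrence_df", "data.frame")
  df
}

#' Vet occurrences: habitat/palynomorph filter, synonymy, deduplication
#'
#' Applies the standard database vetting: freshwater and palynomorph records
#' are removed; taxon names are mapped through a flat synonym table (chains are
#' followed to their final name; cycles are an error); and exact duplicate
#' (taxon, bed) pairs are collapsed to one record. Open-nomenclature
#' qualifiers (quotes, ?, aff., cf., informal) are retained — qualified
#' occurrences still count toward stratigraphic ranges.
#'
#' Vetting is idempotent: `vet_occurrences(vet_occurrences(x)) ==
#' vet_occurrences(x)`.
#'
#' @param occs an `occurrence_df`.
#' @param synonyms optional data frame with columns `old_name, current_name`.
#' @return The vetted `occurrence_df`.
#' @export
vet_occurrences <- function(occs, synonyms = NULL) {
  keep <- occs$habitat == "marine" & !occs$palynomorph
  out <- occs[keep, , drop = FALSE]
  if (!is.null(synonyms) && nrow(synonyms)) {
    stopifnot_cols(synonyms, c("old_name", "current_name"), "synonym table")
    map <- stats::setNames(as.character(synonyms$current_name),
                           as.character(synonyms$old_name))
    out$taxon <- resolve_synonyms(out$taxon, map)
  }
  dup <- duplicated(out[, c("taxon", "bed_id")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrence_df", "data.frame")
  out
}

# Follow synonym chains to a fixpoint; a cycle is an error naming its members.
resolve_synonyms <- function(taxa, map) {
  final <- character(length(map))
  names(final) <- names(map)
  for (i in seq_along(map)) {
    seen <- names(map)[i]
    cur <- map[[i]]
    while (cur %in% names(map)) {
      if (cur %in% seen)
        stop("synonym cycle: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    final[i] <- cur
  }
  hit <- taxa %in% names(final)
  taxa[hit] <- final[taxa[hit]]
  taxa
}

#' Drop occurrences not resolved to a single bed/sub-bed
#'
#' Older literature often reports an occurrence over a span of today's
#' sub-beds; such records constrain extinction timing poorly and are excluded.
#'
#' @param occs an `occurrence_df` with logical column `resolved`.
#' @return The resolved subset; the number of dropped rows is attached as
#'   attribute `n_dropped`.
#' @export
drop_unresolved <- function(occs) {
  keep <- occs$resolved
  out <- occs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("occurrence_df", "data.frame")
  out
}

#' Stratigraphic ranges of taxa
#'
#' Computes, for each distinct taxon, its occupied horizons (bed order
#' indices), first and last appearance datums (FAD/LAD), and range length.
#' FAD/LAD heights are placed at the midpoint of the first/last occupied bed:
#' sub-bed thickness is the data's resolution, and midpoints avoid spurious
#' zero-length gaps between adjacent sub-beds.
#'
#' @param occs a vetted `occurrence_df`.
#' @param column a [strat_column()].
#' @return A data frame of class `taxon_ranges` with columns `taxon, clade,
#'   fad_index, lad_index, fad_height, lad_height, n_horizons, range_length,
#'   is_singleton`, plus a list-column `horizons` of sorted bed order indices.
#' @export
compute_ranges <- function(occs, column) {
  idx <- bed_index(column, occs$bed_id)
  mids <- (column$base_m + column$top_m) / 2
  sp <- split(idx, occs$taxon)
  clade <- vapply(split(as.character(occs$clade), occs$taxon),
                  function(z) z[[1]], character(1))
  horizons <- lapply(sp, function(z) sort(unique(z)))
  fad <- vapply(horizons, min, integer(1))
  lad <- vapply(horizons, max, integer(1))
  H <- lengths(horizons)
  out <- data.frame(
    taxon = names(sp), clade = clade[names(sp)],
    fad_index = fad, lad_index = lad,
    fad_height = mids[fad], lad_height = mids[lad],
    n_horizons = as.integer(H),
    range_length = mids[lad] - mids[fad],
    is_singleton = H == 1L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$horizons <- unname(horizons)
  class(out) <- c("taxon_ranges", "data.frame")
  out
}

#' Classical uniform-recovery confidence interval on a stratigraphic range
#'
#' Under the classical assumption that fossil recovery horizons are uniform
#' within a taxon's true range, the upward extension of the observed range
#' covering the true extinction horizon with confidence `C` is
#' `r * ((1 - C)^(-1/(H - 1)) - 1)`, where `r` is the observed range length
#' and `H` the number of distinct fossiliferous horizons. Undefined for
#' singletons (`H < 2`).
#'
#' @param ranges a `taxon_ranges` data frame (or a single row of one).
#' @param C confidence level in (0, 1).
#' @return A data frame `taxon, C, extension, upper_height` (extension in m).
#' @export
range_ci <- function(ranges, C = 0.95) {
  if (any(C <= 0) || any(C >= 1)) stop("C must be in (0, 1)")
  if (any(ranges$n_horizons < 2))
    stop("range CI undefined for singleton taxa (H < 2): ",
         paste(utils::head(ranges$taxon[ranges$n_horizons < 2], 5),
               collapse = ", "))
  ext <- ranges$range_length * ((1 - C)^(-1 / (ranges$n_horizons - 1)) - 1)
  data.frame(taxon = ranges$taxon, C = C, extension = ext,
             upper_height = ranges$lad_height + ext,
             stringsAsFactors = FALSE)
}

#' Per-bed species richness
#'
#' Default counting is range-through: a taxon counts in every bed between its
#' FAD and LAD bed inclusive, whether or not it was sampled there.
#' `method = "sampled"` counts only beds with an actual occurrence.
#'
#' @param ranges a `taxon_ranges` data frame.
#' @param column a [strat_column()] (or a windowed column).
#' @param method `"range_through"` (default) or `"sampled"`.
#' @return Data frame `bed_id, order_index, richness`.
#' @export
richness_per_bed <- function(ranges, column, method = c("range_through", "sampled")) {
  method <- match.arg(method)
  B <- nrow(column)
  counts <- integer(B)
  glob <- column$order_index  # after column_window these are renumbered; use match on bed position
  if (nrow(ranges)) {
    if (method == "range_through") {
      for (i in seq_len(nrow(ranges))) {
        lo <- ranges$fad_index[i]; hi <- ranges$lad_index[i]
        sel <- which(glob >= lo & glob <= hi)
        counts[sel] <- counts[sel] + 1L
      }
    } else {
      occ <- unlist(ranges$horizons, use.names = FALSE)
      tab <- table(factor(occ, levels = glob))
      counts <- as.integer(tab)
    }
  }
  data.frame(bed_id = column$bed_id, order_index = glob, richness = counts,
             stringsAsFactors = FALSE)
}

#' Per-bed extinction rate
#'
#' `rate(bed) = (# LADs in bed) / (range-through richness in bed)`, with the
#' convention 0/0 = 0. No edge correction is applied at the window's terminal
#' bed.
#'
#' @inheritParams richness_per_bed
#' @return Data frame `bed_id, order_index, n_lad, richness, rate`.
#' @export
extinction_rate_per_bed <- function(ranges, column) {
  rich <- richness_per_bed(ranges, column, method = "range_through")
  n_lad <- as.integer(table(factor(ranges$lad_index, levels = column$order_index)))
  rate <- ifelse(rich$richness > 0, n_lad / rich$richness, 0)
  data.frame(bed_id = column$bed_id, order_index = column$order_index,
             n_lad = n_lad, richness = rich$richness, rate = rate,
             stringsAsFactors = FALSE)
}
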