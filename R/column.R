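#' Stratigraphic column of beds and sub-beds
#'
#' A `strat_column` is a validated data frame of beds (or sub-beds) tiling a
#' measured section without overlap. Heights are in meters, positive up,
#' relative to a fixed datum (for the Meishan section the conventional datum
#' is the base of bed 27c, the biostratigraphic Permian/Triassic boundary).
#' Beds are half-open intervals `[base_m, top_m)`: a sample lying exactly at a
#' bed top belongs to the bed above.
#'
#' @param bed_id character bed labels, e.g. `"24d"`, `"27c"`, `"25"`. Labels
#'   sort by numeric part then letter suffix (`24a < 24e < 25`).
#' @param base_m,top_m numeric base and top heights in meters.
#' @param lithology optional character; one of `"limestone"`,
#'   `"silty_limestone"`, `"clay"`, `"other"`.
#' @param formation optional character formation name.
#' @return A data frame of class `strat_column`, sorted by `base_m`, with an
#'   `order_index` column giving the stratigraphic rank of each bed.
#' @examples
#' col <- strat_column(c("1", "2", "3"), base_m = 0:2, top_m = 1:3)
#' bed_midpoints(col)
#' @export
strat_column <- function(bed_id, base_m, top_m,
                         lithology = NULL, formation = NULL) {
  bed_id <- as.character(bed_id)
  if (anyDuplicated(bed_id)) stop("duplicated bed_id in column")
  if (length(base_m) != length(bed_id) || length(top_m) != length(bed_id))
    stop("bed_id, base_m, top_m must have equal length")
  if (any(!(base_m < top_m))) stop("each bed needs base_m < top_m")
  litho_levels <- c("limestone", "silty_limestone", "clay", "other")
  lithology <- lithology %||% rep("other", length(bed_id))
  if (!all(lithology %in% litho_levels))
    stop("lithology must be one of: ", paste(litho_levels, collapse = ", "))
  formation <- formation %||% rep(NA_character_, length(bed_id))

  ord <- order(base_m)
  col <- data.frame(
    bed_id = bed_id[ord], base_m = base_m[ord], top_m = top_m[ord],
    lithology = lithology[ord], formation = formation[ord],
    order_index = seq_along(bed_id),
    stringsAsFactors = FALSE
  )
  # beds must tile: each top equals the next base (within tolerance)
  if (nrow(col) > 1) {
    gaps <- col$base_m[-1] - col$top_m[-nrow(col)]
    if (any(abs(gaps) > 1e-9))
      stop("beds must tile the column without overlap or gap; offending top/base pair at bed ",
           col$bed_id[which(abs(gaps) > 1e-9)[1]])
  }
  # label order must agree with height order
  if (any(order_bed_labels(col$bed_id) != seq_len(nrow(col))))
    warning("bed label order disagrees with height order; heights take precedence")
  class(col) <- c("strat_column", "data.frame")
  col
}

#' Read a stratigraphic column from CSV
#'
#' Expects columns `bed_id, base_m, top_m` and optionally
#' `lithology, formation`.
#'
#' @param path path to a CSV file.
#' @return A [strat_column()].
#' @export
read_column <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("bed_id", "base_m", "top_m"), "column CSV")
  strat_column(df$bed_id, df$base_m, df$top_m,
               lithology = if ("lithology" %in% names(df)) df$lithology,
               formation = if ("formation" %in% names(df)) df$formation)
}

#' Bed midpoint heights
#' @param column a [strat_column()].
#' @return Named numeric vector of midpoint heights (m), in stratigraphic order.
#' @export
bed_midpoints <- function(column) {
  stats::setNames((column$base_m + column$top_m) / 2, column$bed_id)
}

# order_index for a vector of bed ids; error on unknown ids
bed_index <- function(column, bed_id) {
  idx <- match(as.character(bed_id), column$bed_id)
  if (anyNA(idx))
    stop("unknown bed id(s): ",
         paste(unique(bed_id[is.na(idx)]), collapse = ", "))
  column$order_index[idx]
}

# bed containing a height under the half-open convention; NA outside column
bed_at_height <- function(column, h) {
  i <- findInterval(h, c(column$base_m, column$top_m[nrow(column)]),
                    rightmost.closed = FALSE)
  i[i < 1 | i > nrow(column)] <- NA_integer_
  # findInterval treats the final top as belonging below only when
  # rightmost.closed; with FALSE a sample at the section top falls outside
  i
}

#' Restrict a column to an inclusive window of beds
#' @param column a [strat_column()].
#' @param window character of length 2, first and last bed id (inclusive).
#' @return A `strat_column` subset. `order_index` keeps its values from the
#'   parent column so ranges computed on the full column remain addressable.
#' @export
column_window <- function(column, window) {
  i <- bed_index(column, window)
  if (i[1] > i[2]) stop("window beds out of order")
  out <- column[column$order_index >= i[1] & column$order_index <= i[2], ,
                drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("strat_column", "data.frame")
  out
}

#' @export
print.strat_column <- function(x, ...) {
  cat("Stratigraphic column:", nrow(x), "beds,",
      sprintf("%.2f to %.2f m\n", min(x$base_m), max(x$top_m)))
  NextMethod()
}
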