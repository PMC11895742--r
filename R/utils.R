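# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Meishan-style bed labels sort by (numeric part, letter suffix):
# 24a < 24b < ... < 24e < 25.  Returns an order() permutation key.
bed_label_key <- function(ids) {
  ids <- as.character(ids)
  num <- as.numeric(sub("^([0-9]+).*$", "\\1", ids))
  suf <- sub("^[0-9]+", "", ids)
  if (anyNA(num)) stop("bed labels must start with a number: ",
                       paste(ids[is.na(num)], collapse = ", "))
  list(num = num, suf = suf)
}

order_bed_labels <- function(ids) {
  k <- bed_label_key(ids)
  order(k$num, k$suf)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}
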