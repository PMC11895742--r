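# shared toy objects, built in code at test time

# a uniform 20-bed column, 1 m beds, datum at the base of bed 1
col20 <- strat_column(as.character(1:20), base_m = 0:19, top_m = 1:20)

# a small column with sub-bed labels and uneven thicknesses
col_sub <- strat_column(
  bed_id = c("24a", "24b", "24c", "24d", "24e", "25", "26", "27a", "27b", "27c"),
  base_m = c(-2.0, -1.7, -1.5, -1.1, -0.9, -0.6, -0.45, -0.3, -0.2, 0),
  top_m  = c(-1.7, -1.5, -1.1, -0.9, -0.6, -0.45, -0.3, -0.2, 0, 0.3),
  lithology = c(rep("limestone", 5), "clay", "clay", "silty_limestone",
                "silty_limestone", "limestone")
)

# minimal valid occurrence data frame
occ_df <- function(taxon, bed_id, clade = "Mollusca", qualifier = "none",
                   habitat = "marine", palynomorph = FALSE,
                   source = "test", resolved = TRUE) {
  if (length(taxon) == 0)
    return(data.frame(taxon = character(0), clade = character(0),
                      bed_id = character(0), qualifier = character(0),
                      habitat = character(0), palynomorph = logical(0),
                      source = character(0), resolved = logical(0)))
  data.frame(taxon = taxon, clade = clade, bed_id = bed_id,
             qualifier = qualifier, habitat = habitat,
             palynomorph = palynomorph, source = source, resolved = resolved,
             stringsAsFactors = FALSE)
}

# LADs placed directly: named vector taxon -> order index of col20
make_lads <- function(beds) {
  stats::setNames(as.integer(beds), sprintf("t%03d", seq_along(beds)))
}
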