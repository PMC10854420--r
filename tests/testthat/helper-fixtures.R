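# Small toy genomes and profile constructors used across the suite.

toy_genome <- function(chroms = c("1", "2", "3"),
                       lengths = c(5e6, 4e6, 2.5e6),
                       centromeres = lengths / 2) {
  genome_model(chroms, lengths, centromeres)
}

# A compact multi-chromosome genome that still has the reference regions
# (2q, 4, 12q) the normalization stage needs. 20 full 1 Mb bins per
# chromosome.
mini_genome <- function() {
  chroms <- c("2", "3", "4", "8", "12")
  genome_model(chroms, rep(20e6, 5), rep(10e6 + 5e5, 5))
}

# Build a normalized_profile directly from per-bin log2 values (NA = masked);
# used to feed the callers exactly known inputs.
make_profile <- function(grid, log2_values, scaling_factor = 1) {
  stopifnot(length(log2_values) == nrow(grid))
  structure(list(
    grid = grid,
    log2 = log2_values,
    mask_reason = ifelse(is.na(log2_values), "constructed", NA_character_),
    scaling_factor = scaling_factor,
    reference_regions = character(0),
    recenter = NULL
  ), class = "normalized_profile")
}

# Fragment table shorthand.
frag_table <- function(chromosome, start, insert_size, mapq = 60L) {
  data.frame(chromosome = as.character(chromosome), start = start,
             insert_size = insert_size, mapq = mapq,
             stringsAsFactors = FALSE)
}
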