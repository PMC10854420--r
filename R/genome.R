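#' Genome coordinate model
#'
#' A `genome_model` holds the chromosome names, lengths and centromere
#' positions that define the binning grid and the arm structure used by the
#' whole pipeline. Coordinates are 0-based half-open throughout the package;
#' only WIG output converts to the 1-based fixedStep dialect on write.
#'
#' @param chromosomes Character vector of chromosome names in the order they
#'   should appear in the grid.
#' @param length_bp Integer vector of chromosome lengths in bases.
#' @param centromere_bp Integer vector of centromere midpoints; must satisfy
#'   `0 < centromere_bp < length_bp`.
#' @return An object of class `genome_model`: a data frame with columns
#'   `chromosome`, `length_bp`, `centromere_bp`.
#' @examples
#' g <- genome_model(c("1", "2"), c(5e6, 3e6), c(2.2e6, 1.1e6))
#' arm_of(g, "1", 1e6)
#' @export
genome_model <- function(chromosomes, length_bp, centromere_bp) {
  chromosomes <- as.character(chromosomes)
  if (anyDuplicated(chromosomes)) {
    stop("duplicate chromosome names in genome model")
  }
  if (length(length_bp) != length(chromosomes) ||
      length(centromere_bp) != length(chromosomes)) {
    stop("chromosomes, length_bp and centromere_bp must have equal length")
  }
  length_bp <- as.numeric(length_bp)
  centromere_bp <- as.numeric(centromere_bp)
  if (any(length_bp <= 0)) stop("chromosome lengths must be positive")
  if (any(centromere_bp <= 0 | centromere_bp >= length_bp)) {
    stop("centromere positions must lie strictly inside each chromosome")
  }
  out <- data.frame(
    chromosome = chromosomes,
    length_bp = length_bp,
    centromere_bp = centromere_bp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_model", "data.frame")
  out
}

#' Read a genome model from a tab-separated file
#'
#' The file must have a header line and columns `chromosome`, `length_bp`,
#' `centromere_bp`.
#'
#' @param path Path to the TSV file.
#' @return A [genome_model()].
#' @export
read_genome_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chromosome = "character"))
  need <- c("chromosome", "length_bp", "centromere_bp")
  if (!all(need %in% names(tab))) {
    stop("genome model file must have columns: ", paste(need, collapse = ", "))
  }
  genome_model(tab$chromosome, tab$length_bp, tab$centromere_bp)
}

#' Bundled human genome model (GRCh37-style)
#'
#' Chromosome lengths and centromere midpoints for chromosomes 1-22, X and Y
#' matching the GRCh37 assembly. The analysis itself is genome-agnostic: any
#' model with the same three columns can be swapped in.
#'
#' @return A [genome_model()] with 24 chromosomes in the fixed order
#'   1..22, X, Y.
#' @export
grch37_genome <- function() {
  path <- system.file("extdata", "genome_grch37.tsv", package = "plasmacnv")
  g <- read_genome_model(path)
  expected <- c(as.character(1:22), "X", "Y")
  stopifnot(identical(g$chromosome, expected))
  g
}

#' Which arm holds a position
#'
#' @param genome A [genome_model()].
#' @param chromosome Chromosome name.
#' @param position 0-based position.
#' @return `"p"` if the position lies before the centromere midpoint,
#'   `"q"` otherwise.
#' @export
arm_of <- function(genome, chromosome, position) {
  i <- match(chromosome, genome$chromosome)
  if (is.na(i)) stop("unknown chromosome: ", chromosome)
  ifelse(position < genome$centromere_bp[i], "p", "q")
}

#' Build the fixed bin grid
#'
#' Tiles every chromosome of the genome with half-open, 0-based bins of
#' `bin_size_bp` bases; the last bin of a chromosome may be short. Each bin is
#' assigned to the arm that holds the majority of its bases (ties go to p), so
#' the grid partitions each chromosome into p- and q-arm bins
#' deterministically.
#'
#' @param genome A [genome_model()].
#' @param bin_size_bp Bin width in bases (default 1 Mb, the resolution used
#'   for shallow-WGS copy-number profiling).
#' @return A `bin_grid`: data frame with columns `chromosome`, `start_bp`,
#'   `end_bp`, `arm`, plus attributes `bin_size_bp` and `genome`.
#' @examples
#' g <- genome_model("1", 2.5e6, 1.2e6)
#' build_bin_grid(g, 1e6)
#' @export
build_bin_grid <- function(genome, bin_size_bp = 1e6) {
  if (!inherits(genome, "genome_model")) stop("genome must be a genome_model")
  bin_size_bp <- as.numeric(bin_size_bp)
  if (length(bin_size_bp) != 1 || is.na(bin_size_bp) || bin_size_bp <= 0) {
    stop("bin_size_bp must be a single positive number")
  }
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    cen <- genome$centromere_bp[i]
    n <- ceiling(len / bin_size_bp)
    start <- (seq_len(n) - 1) * bin_size_bp
    end <- pmin(start + bin_size_bp, len)
    # majority rule: p-arm if at least half of the bin's bases precede the
    # centromere midpoint
    p_part <- pmax(0, pmin(end, cen) - start)
    arm <- ifelse(p_part >= (end - start) / 2, "p", "q")
    data.frame(
      chromosome = genome$chromosome[i],
      start_bp = start, end_bp = end, arm = arm,
      stringsAsFactors = FALSE
    )
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "bin_size_bp") <- bin_size_bp
  attr(grid, "genome") <- genome
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Bin ordinal of a genomic position
#'
#' @param grid A `bin_grid`.
#' @param chromosome Chromosome name.
#' @param position 0-based position.
#' @return 0-based bin ordinal within the full grid.
#' @export
bin_index <- function(grid, chromosome, position) {
  bin_size <- attr(grid, "bin_size_bp")
  first <- match(chromosome, grid$chromosome)
  if (anyNA(first)) {
    stop("unknown chromosome: ",
         paste(unique(chromosome[is.na(first)]), collapse = ", "))
  }
  (first - 1L) + floor(position / bin_size)
}

parse_region <- function(region) {
  region <- as.character(region)
  arm <- NA_character_
  if (grepl("[pq]$", region)) {
    arm <- substring(region, nchar(region))
    region <- substring(region, 1, nchar(region) - 1)
  }
  list(chromosome = region, arm = arm)
}

#' Bins of a chromosome or chromosome arm
#'
#' Resolves a region name ("3", "8q", "12q", ...) to the 0-based bin ordinals
#' it spans, optionally excluding bins within `exclude_centromere_bp` of the
#' centromere-adjacent end of an arm (both flanks for a whole chromosome).
#' Arm membership follows the grid's majority-rule arm assignment.
#'
#' @param grid A `bin_grid` built by [build_bin_grid()].
#' @param region Region name: a chromosome ("3") or an arm ("8q").
#' @param exclude_centromere_bp Bases to exclude next to the centromere
#'   (bins overlapping the exclusion window are dropped). Default 0.
#' @return Integer vector of 0-based bin ordinals, ordered by position.
#' @export
region_bins <- function(grid, region, exclude_centromere_bp = 0) {
  genome <- attr(grid, "genome")
  r <- parse_region(region)
  gi <- match(r$chromosome, genome$chromosome)
  if (is.na(gi)) stop("unknown region: ", region)
  cen <- genome$centromere_bp[gi]
  on_chrom <- grid$chromosome == r$chromosome
  keep <- on_chrom
  if (!is.na(r$arm)) keep <- keep & grid$arm == r$arm
  if (exclude_centromere_bp > 0) {
    if (is.na(r$arm)) {
      lo <- cen - exclude_centromere_bp
      hi <- cen + exclude_centromere_bp
    } else if (r$arm == "p") {
      lo <- cen - exclude_centromere_bp
      hi <- cen
    } else {
      lo <- cen
      hi <- cen + exclude_centromere_bp
    }
    overlaps <- grid$start_bp < hi & grid$end_bp > lo
    keep <- keep & !overlaps
  }
  which(keep) - 1L
}

#' Export the bin grid as BED
#'
#' Writes the grid as 0-based half-open BED (chromosome, start, end, name),
#' one line per bin, with the bin's arm in the name column.
#'
#' @param grid A `bin_grid`.
#' @param path Output file.
#' @export
write_grid_bed <- function(grid, path) {
  bed <- data.frame(
    chrom = grid$chromosome,
    start = format(grid$start_bp, scientific = FALSE, trim = TRUE),
    end = format(grid$end_bp, scientific = FALSE, trim = TRUE),
    name = paste0(grid$chromosome, grid$arm)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
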