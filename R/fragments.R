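#' Per-bin read counts
#'
#' The unit of all downstream computation: one non-negative count per grid
#' bin, an optional GC fraction per bin, and immutable provenance metadata
#' (which filters produced the counts).
#'
#' @param grid A `bin_grid`.
#' @param counts Numeric vector of non-negative counts, one per bin.
#' @param gc Optional numeric vector of per-bin GC fractions in `[0, 1]`
#'   (NA allowed).
#' @param meta Named list of provenance metadata (sample id, filters).
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(grid, counts, gc = NULL, meta = list()) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != nrow(grid)) {
    stop("counts length (", length(counts), ") != grid length (",
         nrow(grid), ")")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (!is.null(gc)) {
    gc <- as.numeric(gc)
    if (length(gc) != nrow(grid)) stop("gc length != grid length")
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must lie in [0, 1]")
  }
  structure(list(grid = grid, counts = counts, gc = gc, meta = meta),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("binned_counts:", length(x$counts), "bins,",
      format(sum(x$counts), big.mark = ","), "fragments\n")
  invisible(x)
}

check_fragments <- function(fragments) {
  need <- c("chromosome", "start", "insert_size", "mapq")
  if (!all(need %in% names(fragments))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "))
  }
  invisible(fragments)
}

#' Filter fragments by insert size
#'
#' Retains fragments whose insert size lies in the closed window
#' `[min_bases, max_bases]`. The default 80-150 window enriches for the
#' shorter tumor-derived (ctDNA) fragments relative to the mononucleosomal
#' background. Endpoints are inclusive; single-end records (missing insert
#' size) are refused rather than guessed at.
#'
#' @param fragments Fragment data frame (`chromosome`, `start`,
#'   `insert_size`, `mapq`).
#' @param min_bases,max_bases Window bounds in bases (inclusive).
#' @return The filtered fragment data frame, order preserved.
#' @export
filter_by_insert_size <- function(fragments, min_bases = 80, max_bases = 150) {
  check_fragments(fragments)
  if (min_bases < 0 || max_bases < 0) stop("size bounds must be non-negative")
  if (min_bases > max_bases) stop("min_bases must not exceed max_bases")
  if (any(is.na(fragments$insert_size))) {
    stop("size selection is not possible for single-end records ",
         "(missing insert sizes)")
  }
  fragments[fragments$insert_size >= min_bases &
              fragments$insert_size <= max_bases, , drop = FALSE]
}

#' Filter fragments by mapping quality
#'
#' @param fragments Fragment data frame.
#' @param min_mapq Minimum mapping quality retained (default 20, the
#'   recommended threshold for shallow-WGS read counting).
#' @return The filtered fragment data frame, order preserved.
#' @export
filter_by_mapq <- function(fragments, min_mapq = 20) {
  check_fragments(fragments)
  if (min_mapq < 0) stop("min_mapq must be non-negative")
  fragments[fragments$mapq >= min_mapq, , drop = FALSE]
}

#' Reduce fragments to per-bin counts
#'
#' Each fragment increments exactly one bin, chosen by its start coordinate
#' (0-based); total count equals the number of fragments. Matches the
#' behavior of standard read counters, which assign by the leftmost position
#' of the pair.
#'
#' @param fragments Fragment data frame.
#' @param grid A `bin_grid`.
#' @param meta Extra provenance metadata to record.
#' @return A [binned_counts()] object.
#' @export
bin_fragments <- function(fragments, grid, meta = list()) {
  check_fragments(fragments)
  known <- fragments$chromosome %in% grid$chromosome
  if (!all(known)) {
    stop("fragments on chromosomes absent from the grid: ",
         paste(unique(fragments$chromosome[!known]), collapse = ", "))
  }
  idx <- bin_index(grid, fragments$chromosome, fragments$start)
  counts <- tabulate(idx + 1L, nbins = nrow(grid))
  binned_counts(grid, counts,
                meta = c(meta, list(source = "bin_fragments",
                                    n_fragments = nrow(fragments))))
}

#' Write fragments as TSV
#'
#' Header columns: chromosome, start, insert_size, mapq (plus `origin` when
#' present from the simulator).
#'
#' @param fragments Fragment data frame.
#' @param path Output path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  check_fragments(fragments)
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read fragments from TSV
#'
#' @param path Input path (TSV with header as written by
#'   [write_fragments_tsv()]).
#' @return Fragment data frame.
#' @export
read_fragments_tsv <- function(path) {
  fr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  check_fragments(fr)
  fr
}

#' Read proper pairs from a BAM file as fragment records
#'
#' Optional adapter for real data: extracts (chromosome, start, template
#' length, mapq) for the first read of each properly paired alignment.
#' Requires the Rsamtools package; the rest of the pipeline never depends on
#' BAM input.
#'
#' @param path BAM file path.
#' @param chromosomes Optional subset of chromosomes to read.
#' @return Fragment data frame (`start` converted to 0-based).
#' @export
read_fragments_bam <- function(path, chromosomes = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_fragments_bam requires the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize", "mapq"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  fr <- data.frame(
    chromosome = sub("^chr", "", as.character(res$rname)),
    start = res$pos - 1L,
    insert_size = abs(res$isize),
    mapq = res$mapq,
    stringsAsFactors = FALSE
  )
  fr <- fr[!is.na(fr$start), , drop = FALSE]
  if (!is.null(chromosomes)) {
    fr <- fr[fr$chromosome %in% chromosomes, , drop = FALSE]
  }
  fr
}
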