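#' Write binned counts as fixedStep WIG
#'
#' Emits one `fixedStep` declaration per chromosome with
#' `start=1 step=span=bin size` (the WIG dialect is 1-based), followed by one
#' count per bin. This is the format produced by standard read counters at
#' fixed bin width.
#'
#' @param counts A [binned_counts()] object.
#' @param path Output path.
#' @export
write_wig <- function(counts, path) {
  grid <- counts$grid
  bin_size <- attr(grid, "bin_size_bp")
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in unique(grid$chromosome)) {
    idx <- grid$chromosome == chrom
    writeLines(sprintf(
      "fixedStep chrom=%s start=1 step=%d span=%d",
      chrom, as.integer(bin_size), as.integer(bin_size)), con)
    writeLines(format(counts$counts[idx], scientific = FALSE, trim = TRUE),
               con)
  }
  invisible(path)
}

#' Read fixedStep WIG into binned counts
#'
#' Accepts the dialect written by [write_wig()]: `fixedStep` blocks with
#' `step == span` equal to the bin size and `start=1` (1-based, converted to
#' the 0-based internal grid). Malformed headers, `step != span`, or
#' duplicate chromosome declarations raise a parse error that reports the
#' offending line number.
#'
#' @param path WIG file path.
#' @param grid Optional `bin_grid` to validate against; when supplied, the
#'   file's chromosomes and bin counts must match the grid exactly. Without a
#'   grid, a bare grid is reconstructed from the file (centromeres defaulted
#'   to chromosome midpoints; arm-aware operations then need a real genome).
#' @return A [binned_counts()] object.
#' @export
read_wig <- function(path, grid = NULL) {
  lines <- readLines(path)
  is_header <- grepl("^fixedStep\\b", lines)
  if (!any(is_header)) stop("no fixedStep declaration found in ", path)
  if (!is_header[1] && any(nzchar(trimws(lines[seq_len(which(is_header)[1] - 1)])))) {
    stop("data before first fixedStep declaration at line 1")
  }
  header_at <- which(is_header)
  get_field <- function(line, field, lineno) {
    m <- regmatches(line, regexec(paste0("\\b", field, "=([^ \t]+)"), line))[[1]]
    if (length(m) < 2) {
      stop("malformed fixedStep header at line ", lineno,
           ": missing ", field)
    }
    m[2]
  }
  chroms <- character(0)
  values <- list()
  step_seen <- NA_real_
  for (k in seq_along(header_at)) {
    at <- header_at[k]
    line <- lines[at]
    chrom <- get_field(line, "chrom", at)
    start <- as.numeric(get_field(line, "start", at))
    step <- as.numeric(get_field(line, "step", at))
    span <- as.numeric(get_field(line, "span", at))
    if (is.na(step) || is.na(span) || step != span) {
      stop("step != span at line ", at,
           " (fixed-width bins require step == span)")
    }
    if (!is.na(step_seen) && step != step_seen) {
      stop("inconsistent step size at line ", at)
    }
    step_seen <- step
    if (start != 1) {
      stop("fixedStep start must be 1 at line ", at,
           " (full-chromosome tiling)")
    }
    if (chrom %in% chroms) {
      stop("chromosome ", chrom, " declared twice at line ", at)
    }
    chroms <- c(chroms, chrom)
    upto <- if (k < length(header_at)) header_at[k + 1] - 1 else length(lines)
    body <- lines[seq(at + 1, upto)]
    body <- body[nzchar(trimws(body))]
    vals <- suppressWarnings(as.numeric(body))
    if (any(is.na(vals))) {
      bad <- at + which(is.na(vals))[1]
      stop("non-numeric value at line ", bad)
    }
    values[[chrom]] <- vals
  }
  counts <- unlist(values, use.names = FALSE)
  if (is.null(grid)) {
    n_bins <- lengths(values)
    lengths_bp <- n_bins * step_seen
    genome <- genome_model(chroms, lengths_bp,
                           centromere_bp = pmax(1, lengths_bp / 2))
    grid <- build_bin_grid(genome, step_seen)
  } else {
    if (step_seen != attr(grid, "bin_size_bp")) {
      stop("WIG step (", step_seen, ") does not match grid bin size (",
           attr(grid, "bin_size_bp"), ")")
    }
    grid_chroms <- unique(grid$chromosome)
    if (!identical(chroms, grid_chroms)) {
      stop("WIG chromosomes do not match grid chromosomes")
    }
    grid_n <- as.integer(table(factor(grid$chromosome, levels = grid_chroms)))
    if (!identical(as.integer(lengths(values)), grid_n)) {
      stop("per-chromosome bin counts in WIG do not match grid")
    }
  }
  binned_counts(grid, counts, meta = list(source = "read_wig", path = path))
}
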