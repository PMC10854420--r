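#' GC-correct binned counts
#'
#' Stratified median correction: bins are split into `n_strata` equal-width
#' GC strata, and each count is rescaled by the ratio of the global median
#' count to its stratum's median count (medians over non-zero bins). Bins in
#' empty strata are untouched; zero counts stay zero; if no GC values are
#' present the counts are returned unchanged with a warning flag in the
#' metadata.
#'
#' @param counts A [binned_counts()] object with per-bin GC fractions.
#' @param n_strata Number of equal-width GC strata (default 50).
#' @return A corrected [binned_counts()] object.
#' @export
gc_correct <- function(counts, n_strata = 50) {
  gc <- counts$gc
  if (is.null(gc) || all(is.na(gc))) {
    warning("no GC values present; gc_correct is a no-op")
    counts$meta$gc_corrected <- FALSE
    return(counts)
  }
  x <- width_adjusted_counts(counts)  # depth scale: width must not confound GC
  usable <- !is.na(gc) & x > 0
  if (!any(usable)) {
    counts$meta$gc_corrected <- FALSE
    return(counts)
  }
  rng <- range(gc[usable])
  if (rng[1] == rng[2]) {
    # single occupied stratum: nothing to remove
    counts$meta$gc_corrected <- TRUE
    return(counts)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_strata + 1)
  stratum <- findInterval(gc, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  global_med <- stats::median(x[usable])
  med_by_stratum <- tapply(x[usable], stratum[usable], stats::median)
  occupied <- as.integer(names(med_by_stratum))
  factor <- rep(1, length(x))
  if (length(occupied) >= 2) {
    # rolling median curve: stratum medians smoothed by a running median
    # across neighbouring strata (a GC trend is locally monotone, so the
    # running median preserves it while outvoting any single stratum whose
    # median is dominated by a copy-number event), then evaluated at each
    # bin's GC by linear interpolation
    meds <- as.numeric(med_by_stratum)
    if (length(meds) >= 9) meds <- stats::runmed(meds, 9)
    centers <- (breaks[occupied] + breaks[occupied + 1]) / 2
    expected <- stats::approx(centers, meds,
                              xout = gc[usable], rule = 2)$y
    factor[usable] <- global_med / expected
  } else {
    factor[usable] <- global_med / med_by_stratum[as.character(stratum[usable])]
  }
  out <- counts
  out$counts <- counts$counts * factor  # rescale on the raw count scale
  out$meta$gc_corrected <- TRUE
  out
}

# Counts rescaled to full-bin equivalents (count * bin_size / bin_width):
# the bin-level analogue of per-base read depth. Identity for full-width
# bins; the short terminal bin of each chromosome is scaled up so its
# expectation matches its copy number rather than its width.
width_adjusted_counts <- function(counts) {
  grid <- counts$grid
  width <- grid$end_bp - grid$start_bp
  counts$counts * attr(grid, "bin_size_bp") / width
}

#' Reference-chromosome scaling factor
#'
#' The mean depth over non-zero bins of the reference regions, expressed in
#' full-bin-equivalent counts (count scaled by `bin_size / bin_width`, the
#' bin-level analogue of per-base read depth; for full-width bins this is
#' simply the count). Chromosome arm 2q, chromosome 4 and arm 12q are the
#' default references because they are the regions least affected by
#' copy-number change in uveal melanoma (<1%, <5% and <1% of tumors
#' respectively); dividing every bin by this factor anchors the log2 ratios
#' to a copy-neutral baseline.
#'
#' @param counts A [binned_counts()] object.
#' @param regions Character vector of reference region names.
#' @return Positive scalar scaling factor.
#' @export
reference_scaling_factor <- function(counts,
                                     regions = c("2q", "4", "12q")) {
  idx <- unlist(lapply(regions, function(r) region_bins(counts$grid, r))) + 1L
  vals <- width_adjusted_counts(counts)[idx]
  vals <- vals[vals > 0]
  if (length(vals) == 0) {
    stop("all reference-region bins are zero; sample unusable")
  }
  mean(vals)
}

#' Normalized per-bin log2-ratio profile
#'
#' GC-corrects the counts, divides by the reference-chromosome scaling
#' factor, and returns per-bin `log2` ratios. Zero-count bins are masked, as
#' are sex chromosomes by default (patient sex is unknown to the model) and,
#' optionally, centromere-adjacent bins. Masked bins are excluded from every
#' downstream mean, median and HMM emission; they are never imputed. If
#' `recenter` names a region, the median log2 ratio of that region is
#' subtracted from all bins (the diploid-recentering used by the
#' fixed-threshold caller, for which arm 12q is the conventional choice).
#'
#' @param counts A [binned_counts()] object.
#' @param regions Reference regions for scaling (default 2q, 4, 12q).
#' @param recenter Optional region name to recenter around, or `NULL`.
#' @param mask_sex Mask X and Y bins (default TRUE).
#' @param mask_centromere_bp Mask bins within this many bases of each
#'   centromere (default 0 = off; synthetic data has no centromeric
#'   artifacts to hide).
#' @param min_bin_width_fraction Mask bins narrower than this fraction of
#'   the nominal bin width (default 0.5). The short terminal bin of a
#'   chromosome can cover only a few kilobases; at ~0.2X depth its depth
#'   estimate is far too noisy to feed the caller and a single such outlier
#'   can dominate the tumor-fraction likelihood.
#' @param gc_correction Apply [gc_correct()] first (default TRUE).
#' @return A `normalized_profile`: list with `grid`, `log2` (NA = masked),
#'   `mask_reason`, `scaling_factor`, `reference_regions`, `recenter`.
#' @export
to_log2_profile <- function(counts,
                            regions = c("2q", "4", "12q"),
                            recenter = NULL,
                            mask_sex = TRUE,
                            mask_centromere_bp = 0,
                            min_bin_width_fraction = 0.5,
                            gc_correction = TRUE) {
  grid <- counts$grid
  if (gc_correction) counts <- gc_correct(counts)
  sf <- reference_scaling_factor(counts, regions)
  ratio <- width_adjusted_counts(counts) / sf
  mask_reason <- rep(NA_character_, nrow(grid))
  if (mask_sex) {
    sex <- grid$chromosome %in% c("X", "Y")
    mask_reason[sex] <- "sex_chromosome"
  }
  if (min_bin_width_fraction > 0) {
    short <- (grid$end_bp - grid$start_bp) <
      min_bin_width_fraction * attr(grid, "bin_size_bp")
    mask_reason[short & is.na(mask_reason)] <- "short_bin"
  }
  if (mask_centromere_bp > 0) {
    genome <- attr(grid, "genome")
    cen <- genome$centromere_bp[match(grid$chromosome, genome$chromosome)]
    near <- grid$start_bp < cen + mask_centromere_bp &
      grid$end_bp > cen - mask_centromere_bp
    mask_reason[near & is.na(mask_reason)] <- "centromere_adjacent"
  }
  zero <- counts$counts == 0
  mask_reason[zero & is.na(mask_reason)] <- "zero_count"
  log2r <- ifelse(is.na(mask_reason), log2(pmax(ratio, .Machine$double.xmin)),
                  NA_real_)
  profile <- structure(list(
    grid = grid,
    log2 = log2r,
    mask_reason = mask_reason,
    scaling_factor = sf,
    reference_regions = regions,
    recenter = recenter
  ), class = "normalized_profile")
  if (!is.null(recenter)) {
    idx <- region_bins(grid, recenter) + 1L
    med <- stats::median(profile$log2[idx], na.rm = TRUE)
    profile$log2 <- profile$log2 - med
    profile$recenter_shift <- med
  }
  profile
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat("normalized_profile:", sum(!is.na(x$log2)), "unmasked /",
      length(x$log2), "bins; scaling factor",
      format(x$scaling_factor, digits = 6), "\n")
  invisible(x)
}

#' Export a profile as a SEG-style per-bin table
#'
#' Columns: sample, chromosome, start_bp, end_bp, log2 (masked bins omitted).
#'
#' @param profile A `normalized_profile`.
#' @param path Output TSV path.
#' @param sample Sample identifier written in the first column.
#' @export
write_log2_tsv <- function(profile, path, sample = "sample") {
  keep <- !is.na(profile$log2)
  tab <- data.frame(
    sample = sample,
    chromosome = profile$grid$chromosome[keep],
    start_bp = profile$grid$start_bp[keep],
    end_bp = profile$grid$end_bp[keep],
    log2 = signif(profile$log2[keep], 6)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
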