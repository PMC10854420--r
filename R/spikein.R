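#' In silico spike-in specification
#'
#' Defines one dilution point of the in silico spike-in experiment: the
#' region, the direction, and the spiked fraction. For a gain, `fraction` is
#' the proportion of the region's reads added on top (subsample-and-merge);
#' for a loss, `fraction` is the depleted proportion, i.e. the region is
#' thinned to retention `1 - fraction`. The canonical dilution series is
#' 0.1%, 0.2%, 0.5%, 1%, 5%, 10% and 25% (equivalently retentions 99.9%
#' down to 75% for the loss side). The depleted/added fraction is labelled
#' "tumor load" directly, following the construction's literal labelling
#' rather than monosomy copy-number algebra (a pure monosomy at tumor
#' fraction f would deplete only f/2).
#'
#' @param region Chromosome or arm name ("3", "8q").
#' @param direction "gain" or "loss".
#' @param fraction Spiked fraction in `[0, 1]`.
#' @param centromere_exclusion_bp Bases excluded next to the centromere
#'   (default 1 Mb for arm regions, 0 for whole chromosomes).
#' @param seed Integer seed for the binomial draws.
#' @return A `spikein_spec` object.
#' @export
spikein_spec <- function(region, direction = c("gain", "loss"), fraction,
                         centromere_exclusion_bp = NULL, seed = 1L) {
  direction <- match.arg(direction)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (is.null(centromere_exclusion_bp)) {
    centromere_exclusion_bp <- if (is.na(parse_region(region)$arm)) 0 else 1e6
  }
  structure(list(region = region, direction = direction, fraction = fraction,
                 centromere_exclusion_bp = centromere_exclusion_bp,
                 seed = as.integer(seed)),
            class = "spikein_spec")
}

#' Canonical spike-in fraction series
#'
#' The seven dilution fractions of the in silico experiment:
#' 0.1%, 0.2%, 0.5%, 1%, 5%, 10%, 25%.
#'
#' @return Numeric vector of fractions.
#' @export
canonical_spike_fractions <- function() {
  c(0.001, 0.002, 0.005, 0.01, 0.05, 0.10, 0.25)
}

spike_region_index <- function(counts, spec) {
  idx <- region_bins(counts$grid, spec$region, spec$centromere_exclusion_bp)
  if (length(idx) == 0) stop("region ", spec$region, " has no bins in grid")
  idx + 1L
}

#' Spike a copy-number gain into binned counts
#'
#' Count-level equivalent of subsampling a region's reads at the spike
#' fraction and merging them back: each region bin receives an independent
#' `Binomial(count, fraction)` addition. Identical in distribution to
#' fragment-level duplication followed by start-position binning.
#'
#' @param counts A [binned_counts()] object.
#' @param spec A [spikein_spec()] with direction "gain".
#' @return Spiked [binned_counts()].
#' @export
spike_gain <- function(counts, spec) {
  stopifnot(inherits(spec, "spikein_spec"))
  if (spec$direction != "gain") stop("spec direction must be 'gain'")
  idx <- spike_region_index(counts, spec)
  out <- counts
  if (spec$fraction > 0) {
    add <- with_seed(spec$seed,
                     stats::rbinom(length(idx), size = counts$counts[idx],
                                   prob = spec$fraction))
    out$counts[idx] <- counts$counts[idx] + add
  }
  out$meta$spike <- spec
  out
}

#' Spike a copy-number loss into binned counts
#'
#' Binomial thinning: each region bin's count is replaced by
#' `Binomial(count, 1 - fraction)`, the count-level equivalent of retaining
#' a subsample of the region's reads.
#'
#' @param counts A [binned_counts()] object.
#' @param spec A [spikein_spec()] with direction "loss".
#' @return Spiked [binned_counts()].
#' @export
spike_loss <- function(counts, spec) {
  stopifnot(inherits(spec, "spikein_spec"))
  if (spec$direction != "loss") stop("spec direction must be 'loss'")
  idx <- spike_region_index(counts, spec)
  out <- counts
  retention <- 1 - spec$fraction
  if (spec$fraction > 0) {
    out$counts[idx] <- with_seed(spec$seed,
                                 stats::rbinom(length(idx),
                                               size = counts$counts[idx],
                                               prob = retention))
  }
  out$meta$spike <- spec
  out
}

#' Fragment-level spike-in
#'
#' The per-fragment twin of [spike_gain()] / [spike_loss()]: region
#' fragments are independently duplicated (gain) or kept (loss) with the
#' spec probability. After binning, the result is distributionally
#' equivalent to the count-level operation.
#'
#' @param fragments Fragment data frame.
#' @param spec A [spikein_spec()].
#' @param grid A `bin_grid` (defines the region and centromere exclusion).
#' @return Spiked fragment data frame.
#' @export
spike_fragments <- function(fragments, spec, grid) {
  check_fragments(fragments)
  idx <- region_bins(grid, spec$region, spec$centromere_exclusion_bp)
  region_rows <- bin_index(grid, fragments$chromosome, fragments$start) %in% idx
  if (spec$fraction == 0) return(fragments)
  with_seed(spec$seed, {
    if (spec$direction == "gain") {
      dup <- region_rows & stats::runif(nrow(fragments)) < spec$fraction
      rbind(fragments, fragments[dup, , drop = FALSE])
    } else {
      drop <- region_rows & stats::runif(nrow(fragments)) < spec$fraction
      fragments[!drop, , drop = FALSE]
    }
  })
}

#' Scan a dilution series for the limit of detection
#'
#' For every fraction and replicate: simulate a fresh background sample (or
#' reuse supplied counts), spike the region, normalize against the
#' least-affected reference chromosomes, run the HMM caller, and make the
#' chromosome-level call. The limit of detection is the smallest fraction
#' whose detection rate across replicates reaches `detect_rule` (default 1:
#' every replicate must detect, which biases the LOD conservative).
#'
#' @param base A [sim_config()] describing the background sample (its seed
#'   is offset per replicate), or a fixed [binned_counts()] object reused
#'   across replicates.
#' @param region Region to spike and call.
#' @param direction "gain" or "loss".
#' @param fractions Increasing dilution fractions (default the canonical
#'   series).
#' @param n_replicates Replicates per fraction (default 3).
#' @param detect_rule Minimum detection rate across replicates required to
#'   declare a fraction detected (default 1 = all replicates).
#' @param replicate_seeds Optional integer vector (length `n_replicates`)
#'   of seeds; defaults to `base$seed + 0:(n_replicates-1)` for a
#'   `sim_config` base or `1:n_replicates` for fixed counts.
#' @param hmm An [hmm_config()].
#' @param reference_regions Normalization references.
#' @param min_fraction Majority rule for the chromosome-level call.
#' @param centromere_exclusion_bp Passed to the spike spec (default 1 Mb
#'   for arms, 0 for whole chromosomes).
#' @return An `lod_result`: list with `fractions`, `detected` (fractions x
#'   replicates logical matrix), `detection_rate`, `lod` (smallest
#'   qualifying fraction, or `NA` for none), `monotone` flag, and the
#'   per-run tumor-fraction estimates.
#' @export
lod_scan <- function(base, region, direction,
                     fractions = canonical_spike_fractions(),
                     n_replicates = 3,
                     detect_rule = 1,
                     replicate_seeds = NULL,
                     hmm = hmm_config(),
                     reference_regions = c("2q", "4", "12q"),
                     min_fraction = 0.5,
                     centromere_exclusion_bp = NULL) {
  if (length(fractions) == 0) stop("fractions must be non-empty")
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing")
  }
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  fixed_counts <- inherits(base, "binned_counts")
  if (is.null(replicate_seeds)) {
    replicate_seeds <- if (fixed_counts) seq_len(n_replicates) else
      base$seed + seq_len(n_replicates) - 1L
  }
  stopifnot(length(replicate_seeds) == n_replicates)
  detected <- matrix(NA, nrow = length(fractions), ncol = n_replicates,
                     dimnames = list(fraction = fractions, replicate = NULL))
  f_hats <- detected
  for (r in seq_len(n_replicates)) {
    background <- if (fixed_counts) base else {
      cfg <- base
      cfg$seed <- as.integer(replicate_seeds[r])
      simulate_bin_counts(cfg)
    }
    for (i in seq_along(fractions)) {
      spec <- spikein_spec(region, direction, fractions[i],
                           centromere_exclusion_bp = centromere_exclusion_bp,
                           seed = as.integer(replicate_seeds[r]) + 7919L * i)
      spiked <- if (direction == "gain") spike_gain(background, spec) else
        spike_loss(background, spec)
      region_idx <- spike_region_index(spiked, spec)
      if (direction == "loss" && all(spiked$counts[region_idx] == 0)) {
        # complete wipe-out: every region bin is zero-masked downstream,
        # which is the most extreme possible loss signal (supporting
        # fraction 1, still subject to the majority rule)
        detected[i, r] <- 1 >= min_fraction
        f_hats[i, r] <- NA_real_
        next
      }
      profile <- to_log2_profile(spiked, regions = reference_regions)
      fit <- hmm_call(profile, hmm)
      call <- chromosome_call(fit$segments, profile, region,
                              min_fraction = min_fraction)
      detected[i, r] <- call$call == direction
      f_hats[i, r] <- fit$estimate$f_hat
    }
  }
  rate <- rowMeans(detected)
  qualifying <- which(rate >= detect_rule)
  lod <- if (length(qualifying)) fractions[min(qualifying)] else NA_real_
  monotone <- all(diff(rate >= detect_rule) >= 0)
  structure(list(fractions = fractions, detected = detected,
                 detection_rate = rate, lod = lod, monotone = monotone,
                 tumor_fraction_estimates = f_hats,
                 region = region, direction = direction,
                 detect_rule = detect_rule,
                 replicate_seeds = replicate_seeds),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat("lod_scan:", x$direction, "of", x$region, "- LOD =",
      if (is.na(x$lod)) "none" else paste0(100 * x$lod, "%"), "\n")
  print(data.frame(fraction = x$fractions,
                   detection_rate = x$detection_rate))
  invisible(x)
}
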