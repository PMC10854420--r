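#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Copy-number profile of the simulated tumor component
#'
#' A set of copy-number events over chromosomes or arms; everything not named
#' is copy-neutral (copy number 2). Events with copy number 2 are redundant
#' and rejected, as are overlapping regions.
#'
#' @param events A data frame with columns `region` (chromosome or arm name,
#'   e.g. "3" or "8q") and `copy_number` (non-negative integer), or `NULL`
#'   for a copy-neutral profile.
#' @return A `cnv_profile` object.
#' @examples
#' cnv_profile(data.frame(region = c("3", "8q"), copy_number = c(1, 3)))
#' @export
cnv_profile <- function(events = NULL) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(region = character(), copy_number = numeric())
  }
  events$region <- as.character(events$region)
  events$copy_number <- as.numeric(events$copy_number)
  if (any(events$copy_number < 0) || any(events$copy_number != round(events$copy_number))) {
    stop("copy numbers must be non-negative integers")
  }
  if (any(events$copy_number == 2)) {
    stop("copy-number-2 events are redundant; omit them")
  }
  if (nrow(events) > 1) {
    parsed <- lapply(events$region, parse_region)
    chrom <- vapply(parsed, `[[`, "", "chromosome")
    arm <- vapply(parsed, function(p) ifelse(is.na(p$arm), "*", p$arm), "")
    for (i in seq_len(nrow(events) - 1)) {
      for (j in seq(i + 1, nrow(events))) {
        if (chrom[i] == chrom[j] &&
            (arm[i] == "*" || arm[j] == "*" || arm[i] == arm[j])) {
          stop("overlapping regions in profile: ",
               events$region[i], " and ", events$region[j])
        }
      }
    }
  }
  structure(list(events = events), class = "cnv_profile")
}

#' Uveal-melanoma copy-number archetypes
#'
#' Named profiles covering the recurrent uveal-melanoma karyotypes:
#' `monosomy3_8qgain` (chromosome 3 loss with 8q gain, the high
#' metastatic-risk combination), `fig4_metastatic` (loss of 1p, 3, 5q and
#' 10p with gain of 1q and 8q, as seen in disseminated disease),
#' `eif1ax_like` (6p gain, the low-risk pattern) and `neutral` (no events).
#'
#' @return Named list of [cnv_profile()] objects.
#' @export
uveal_archetypes <- function() {
  list(
    monosomy3_8qgain = cnv_profile(
      data.frame(region = c("3", "8q"), copy_number = c(1, 3))),
    fig4_metastatic = cnv_profile(
      data.frame(region = c("1p", "3", "5q", "10p", "1q", "8q"),
                 copy_number = c(1, 1, 1, 1, 3, 3))),
    eif1ax_like = cnv_profile(
      data.frame(region = "6p", copy_number = 3)),
    neutral = cnv_profile()
  )
}

#' Per-bin copy number implied by a profile
#'
#' @param grid A `bin_grid`.
#' @param profile A [cnv_profile()].
#' @return Numeric vector, one copy number per bin (2 outside all events).
#' @export
profile_copy_numbers <- function(grid, profile) {
  cn <- rep(2, nrow(grid))
  for (i in seq_len(nrow(profile$events))) {
    idx <- region_bins(grid, profile$events$region[i]) + 1L
    cn[idx] <- profile$events$copy_number[i]
  }
  cn
}

#' Simulation configuration for synthetic plasma cfDNA
#'
#' Defines one synthetic plasma sample: sequencing depth, tumor fraction,
#' tumor copy-number profile, GC bias, count overdispersion and the
#' fragment-length mixture. Defaults emulate the study conditions: ~0.2X
#' shallow WGS (25 million fragments), a mononucleosomal background fragment
#' distribution and a shorter tumor-derived (ctDNA) distribution.
#'
#' @param grid A `bin_grid` (carries its genome).
#' @param n_fragments Number of sequenced fragments (default 25e6, the
#'   midpoint of the 20-30 million fragments per sample the assay produces).
#' @param tumor_fraction Fraction of cfDNA of tumor origin, in `[0, 1]`.
#' @param profile Tumor [cnv_profile()].
#' @param gc_bias_strength Strength of the multiplicative GC bias
#'   `exp(gc_bias_strength * standardized GC)`; 0 disables it. Default 0.1,
#'   giving the +/-10-30% depth modulation across the GC range that
#'   megabase-binned coverage typically shows; larger values produce
#'   unrealistic multi-fold bias at the GC tails.
#' @param overdispersion Extra-Poisson dispersion: 0 gives pure multinomial
#'   sampling; d > 0 mixes bin intensities with Gamma(1/d, 1/d) noise
#'   (negative-binomial counts).
#' @param fraglen_background Mean and sd (bases) of the background cfDNA
#'   insert-size distribution, truncated to `fraglen_bounds`. Default
#'   c(167, 40): the mononucleosome peak.
#' @param fraglen_tumor Mean and sd for tumor-derived fragments. Default
#'   c(145, 35): ctDNA runs shorter than background cfDNA.
#' @param fraglen_bounds Truncation bounds for both components.
#' @param mapq_low_fraction Fraction of fragments given a low mapping quality
#'   (10) instead of 60, to exercise the MAPQ filter.
#' @param seed Integer seed; fully determines the sample.
#' @return A `sim_config` object.
#' @export
sim_config <- function(grid,
                       n_fragments = 25e6,
                       tumor_fraction = 0,
                       profile = cnv_profile(),
                       gc_bias_strength = 0.1,
                       overdispersion = 0,
                       fraglen_background = c(167, 40),
                       fraglen_tumor = c(145, 35),
                       fraglen_bounds = c(50, 400),
                       mapq_low_fraction = 0.02,
                       seed = 1L) {
  stopifnot(inherits(grid, "bin_grid"), inherits(profile, "cnv_profile"))
  if (n_fragments <= 0) stop("n_fragments must be positive")
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  if (gc_bias_strength < 0 || overdispersion < 0) {
    stop("gc_bias_strength and overdispersion must be non-negative")
  }
  structure(list(
    grid = grid,
    n_fragments = n_fragments,
    tumor_fraction = tumor_fraction,
    profile = profile,
    gc_bias_strength = gc_bias_strength,
    overdispersion = overdispersion,
    fraglen_background = fraglen_background,
    fraglen_tumor = fraglen_tumor,
    fraglen_bounds = fraglen_bounds,
    mapq_low_fraction = mapq_low_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-bin GC field in [0.3, 0.6]: a smooth component (white noise through a
# 21-bin moving average per chromosome) plus a smaller independent per-bin
# component, then rescaled. The bin-level part matters: without it every
# tail of the GC distribution is an unbroken run on a single chromosome,
# and a self-referential GC correction would absorb any copy-number event
# that happens to sit there. Real megabase GC varies bin to bin.
simulate_gc_field <- function(grid, seed) {
  with_seed(seed + 104729L, {
    gc <- numeric(nrow(grid))
    for (chrom in unique(grid$chromosome)) {
      idx <- which(grid$chromosome == chrom)
      z <- stats::rnorm(length(idx) + 20)
      sm <- stats::filter(z, rep(1 / 21, 21), sides = 2)
      sm <- sm[11:(10 + length(idx))]
      gc[idx] <- sm
    }
    gc <- as.numeric(scale(gc))
    gc <- 0.75 * gc + 0.25 * stats::rnorm(length(gc))
    gc <- (gc - min(gc)) / max(max(gc) - min(gc), .Machine$double.eps)
    0.3 + 0.3 * gc
  })
}

#' Expected per-bin sampling weights of the admixture forward model
#'
#' The probability that a sequenced fragment falls in bin `b` is proportional
#' to `width(b) * gc_factor(b) * ((1 - f) * 2 + f * c(b)) / 2`, where `f` is
#' the tumor fraction and `c(b)` the tumor copy number at `b`. This is the
#' forward model whose inverse the normalization and calling stages compute.
#'
#' @param config A [sim_config()].
#' @param gc Optional per-bin GC vector; by default the seeded GC field.
#' @return List with `weights` (sums to 1), `gc`, and `copy` per bin.
#' @export
expected_bin_weights <- function(config, gc = NULL) {
  grid <- config$grid
  if (is.null(gc)) gc <- simulate_gc_field(grid, config$seed)
  width <- grid$end_bp - grid$start_bp
  cn <- profile_copy_numbers(grid, config$profile)
  f <- config$tumor_fraction
  admix <- ((1 - f) * 2 + f * cn) / 2
  gcf <- if (config$gc_bias_strength > 0) {
    exp(config$gc_bias_strength * as.numeric(scale(gc)))
  } else {
    rep(1, nrow(grid))
  }
  w <- width * gcf * admix
  list(weights = w / sum(w), gc = gc, copy = cn)
}

#' Simulate binned read counts for one synthetic plasma sample
#'
#' Draws per-bin counts with expectation `n_fragments * weight(b)`. With
#' `overdispersion = 0` the counts are a single multinomial draw (total
#' conserved exactly); otherwise bin intensities are Gamma-perturbed before
#' Poisson sampling (negative-binomial marginals). The same seed reproduces
#' the sample bit for bit.
#'
#' @param config A [sim_config()].
#' @return A [binned_counts()] object with the simulated GC fraction attached.
#' @export
simulate_bin_counts <- function(config) {
  ebw <- expected_bin_weights(config)
  counts <- with_seed(config$seed, {
    if (config$overdispersion == 0) {
      as.numeric(stats::rmultinom(1, size = config$n_fragments,
                                  prob = ebw$weights))
    } else {
      shape <- 1 / config$overdispersion
      lam <- config$n_fragments * ebw$weights *
        stats::rgamma(length(ebw$weights), shape = shape, rate = shape)
      stats::rpois(length(lam), lam)
    }
  })
  binned_counts(config$grid, counts, gc = ebw$gc,
                meta = list(source = "simulate_bin_counts",
                            n_fragments = config$n_fragments,
                            tumor_fraction = config$tumor_fraction,
                            overdispersion = config$overdispersion,
                            seed = config$seed))
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Simulate aligned fragment records
#'
#' Per-fragment surrogate for an aligned, duplicate-marked BAM: each fragment
#' gets a bin (by the admixture weights), a uniform start within the bin, an
#' origin (tumor with probability `f * c / (2(1 - f) + f c)` in its bin), an
#' insert size drawn from the origin's truncated-normal component, and a
#' mapping quality (60, or 10 for a configured low-quality fraction). The
#' `origin` column is simulation ground truth, not part of the aligned-record
#' contract; downstream filters simply carry it along.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `chromosome`, `start`, `insert_size`,
#'   `mapq`, `origin`.
#' @export
simulate_fragments <- function(config) {
  ebw <- expected_bin_weights(config)
  grid <- config$grid
  genome <- attr(grid, "genome")
  n <- config$n_fragments
  f <- config$tumor_fraction
  with_seed(config$seed, {
    bin <- sample.int(nrow(grid), size = n, replace = TRUE,
                      prob = ebw$weights)
    p_tumor <- f * ebw$copy[bin] / ((1 - f) * 2 + f * ebw$copy[bin])
    is_tumor <- stats::runif(n) < p_tumor
    par_bg <- config$fraglen_background
    par_tu <- config$fraglen_tumor
    insert <- numeric(n)
    n_tu <- sum(is_tumor)
    if (n_tu > 0) {
      insert[is_tumor] <- rtruncnorm(n_tu, par_tu[1], par_tu[2],
                                     config$fraglen_bounds[1],
                                     config$fraglen_bounds[2])
    }
    if (n_tu < n) {
      insert[!is_tumor] <- rtruncnorm(n - n_tu, par_bg[1], par_bg[2],
                                      config$fraglen_bounds[1],
                                      config$fraglen_bounds[2])
    }
    insert <- pmax(1, round(insert))
    start <- grid$start_bp[bin] +
      floor(stats::runif(n) * (grid$end_bp[bin] - grid$start_bp[bin]))
    chrom_len <- genome$length_bp[match(grid$chromosome[bin],
                                        genome$chromosome)]
    start <- pmin(start, chrom_len - insert)
    mapq <- ifelse(stats::runif(n) < config$mapq_low_fraction, 10L, 60L)
    data.frame(
      chromosome = grid$chromosome[bin],
      start = start,
      insert_size = insert,
      mapq = mapq,
      origin = ifelse(is_tumor, "tumor", "background"),
      stringsAsFactors = FALSE
    )
  })
}
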