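#' HMM caller configuration
#'
#' Configuration of the copy-number HMM: integer copy-number states, the
#' tumor-fraction search grid, the self-transition probability, and the
#' Gaussian emission sd. The default emission sd (0.024) is the package's
#' calibration for ~0.2X shallow WGS at 1 Mb resolution: about 1.5x the
#' shot-noise floor at 25 million fragments (sigma ~ 0.016 in log2 units),
#' leaving headroom for residual GC structure and modest overdispersion.
#' `emission_sd = "estimated"` switches to a method-of-moments estimate from
#' putatively neutral bins (within median +/- 2 MAD).
#'
#' The initial state distribution defaults to the neutral row of the
#' transition matrix, i.e. each chromosome behaves as if preceded by a
#' virtual copy-neutral telomere bin. Entering an aberrant state therefore
#' costs exactly one transition whether the event covers a whole chromosome
#' or a single arm.
#'
#' @param states Integer copy numbers modelled (must include 2).
#' @param tumor_fraction_grid Increasing grid of tumor fractions searched
#'   (default 0 to 0.5 in steps of 0.005, then 0.55 to 1 in steps of 0.05).
#' @param self_transition Probability of staying in the same state between
#'   adjacent bins (default 0.9999); the remainder is spread uniformly over
#'   the other states.
#' @param emission_sd Positive number, or `"estimated"`.
#' @param state_prior `"neutral_row"` (default) or an explicit probability
#'   vector over states summing to 1.
#' @param neutral_state Copy number regarded as neutral (default 2).
#' @return An `hmm_config` object.
#' @export
hmm_config <- function(states = c(1L, 2L, 3L, 4L),
                       tumor_fraction_grid = c(seq(0, 0.5, by = 0.005),
                                               seq(0.55, 1, by = 0.05)),
                       self_transition = 0.9999,
                       emission_sd = 0.024,
                       state_prior = "neutral_row",
                       neutral_state = 2L) {
  if (!neutral_state %in% states) stop("states must include the neutral copy number")
  if (is.unsorted(tumor_fraction_grid, strictly = TRUE)) {
    stop("tumor_fraction_grid must be strictly increasing")
  }
  if (any(tumor_fraction_grid < 0 | tumor_fraction_grid > 1)) {
    stop("tumor_fraction_grid must lie in [0, 1]")
  }
  if (self_transition <= 0 || self_transition >= 1) {
    stop("self_transition must lie in (0, 1)")
  }
  if (is.numeric(state_prior)) {
    if (length(state_prior) != length(states) ||
        abs(sum(state_prior) - 1) > 1e-8) {
      stop("state_prior must be a probability vector over states")
    }
  } else if (!identical(state_prior, "neutral_row")) {
    stop("state_prior must be 'neutral_row' or a probability vector")
  }
  if (is.numeric(emission_sd)) {
    if (emission_sd <= 0) stop("emission_sd must be positive")
  } else if (!identical(emission_sd, "estimated")) {
    stop("emission_sd must be positive or 'estimated'")
  }
  structure(list(states = as.integer(states),
                 tumor_fraction_grid = tumor_fraction_grid,
                 self_transition = self_transition,
                 emission_sd = emission_sd,
                 state_prior = state_prior,
                 neutral_state = as.integer(neutral_state)),
            class = "hmm_config")
}

#' Expected log2 ratio of a copy-number state at a tumor fraction
#'
#' The admixture expectation `log2((2 (1 - f) + c f) / 2)`: a tumor of copy
#' number `c` diluted to fraction `f` in diploid background. The value is
#' floored at -8 (the degenerate case c = 0, f = 1 would be -Inf).
#'
#' @param copy_number Non-negative copy number(s).
#' @param tumor_fraction Tumor fraction(s) in `[0, 1]`.
#' @return Expected log2 ratio(s).
#' @examples
#' emission_mean(1, 0.25)  # log2(0.875)
#' @export
emission_mean <- function(copy_number, tumor_fraction) {
  if (any(copy_number < 0)) stop("copy_number must be non-negative")
  if (any(tumor_fraction < 0 | tumor_fraction > 1)) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  v <- (2 * (1 - tumor_fraction) + copy_number * tumor_fraction) / 2
  pmax(log2(pmax(v, 2^-8)), -8)
}

# Unmasked log2 values split by chromosome, with their grid ordinals.
profile_chrom_values <- function(profile) {
  keep <- !is.na(profile$log2)
  chroms <- unique(profile$grid$chromosome[keep])
  lapply(stats::setNames(chroms, chroms), function(ch) {
    idx <- which(keep & profile$grid$chromosome == ch)
    list(values = profile$log2[idx], ordinals = idx - 1L)
  })
}

resolve_emission_sd <- function(profile, config) {
  if (is.numeric(config$emission_sd)) return(config$emission_sd)
  x <- profile$log2[!is.na(profile$log2)]
  med <- stats::median(x)
  mad <- stats::mad(x)
  win <- x[abs(x - med) <= 2 * mad]
  s <- stats::sd(win)
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(x), 1e-4)
  s
}

resolve_state_prior <- function(config) {
  k <- length(config$states)
  if (is.numeric(config$state_prior)) return(config$state_prior)
  prior <- rep((1 - config$self_transition) / (k - 1), k)
  prior[config$states == config$neutral_state] <- config$self_transition
  prior
}

# Forward log-likelihood of one chromosome's values for every row of a
# means matrix (rows = candidate tumor fractions, columns = states),
# vectorized across rows. Transitions: self_transition on the diagonal,
# uniform off-diagonal.
forward_loglik_rows <- function(values, means, sd, p_self, log_prior) {
  k <- ncol(means)
  q <- (1 - p_self) / (k - 1)
  const <- -log(sd) - 0.5 * log(2 * pi)
  # alpha: n_rows x k, log scale
  alpha <- sweep(-0.5 * ((values[1] - means) / sd)^2 + const, 2, log_prior, "+")
  rows <- seq_len(nrow(alpha))
  if (length(values) > 1) {
    for (t in seq(2, length(values))) {
      amax <- alpha[cbind(rows, max.col(alpha, ties.method = "first"))]
      ex <- exp(alpha - amax)
      s <- rowSums(ex)
      trans <- log(q * s + (p_self - q) * ex)
      em <- -0.5 * ((values[t] - means) / sd)^2 + const
      alpha <- amax + trans + em
    }
  }
  amax <- alpha[cbind(rows, max.col(alpha, ties.method = "first"))]
  amax + log(rowSums(exp(alpha - amax)))
}

#' Grid-search tumor-fraction estimate
#'
#' For every tumor fraction on the grid, computes the total forward
#' log-likelihood of the unmasked profile under the copy-number HMM
#' (chromosomes are independent chains) and returns the maximizer; exact
#' likelihood ties resolve to the smallest fraction (parsimony).
#'
#' @param profile A `normalized_profile`.
#' @param config An [hmm_config()].
#' @return A `tumor_fraction_estimate`: list with `f_hat`, `log_likelihood`
#'   (one finite value per grid point), `grid`, `selected_index`, and the
#'   emission sd used.
#' @export
estimate_tumor_fraction <- function(profile, config = hmm_config()) {
  chroms <- profile_chrom_values(profile)
  if (length(chroms) == 0) stop("profile has no unmasked bins")
  sd <- resolve_emission_sd(profile, config)
  grid <- config$tumor_fraction_grid
  means <- outer(grid, config$states,
                 function(f, c) emission_mean(c, f))
  log_prior <- log(resolve_state_prior(config))
  ll <- rep(0, length(grid))
  for (ch in chroms) {
    ll <- ll + forward_loglik_rows(ch$values, means, sd,
                                   config$self_transition, log_prior)
  }
  sel <- which.max(ll)
  structure(list(f_hat = grid[sel],
                 log_likelihood = ll,
                 grid = grid,
                 selected_index = sel,
                 emission_sd = sd),
            class = "tumor_fraction_estimate")
}

# Viterbi decode of one chromosome (vector of values) at fixed means.
viterbi_chromosome <- function(values, means, sd, p_self, log_prior) {
  k <- length(means)
  n <- length(values)
  lp <- log(p_self)
  lq <- log((1 - p_self) / (k - 1))
  em <- -0.5 * ((matrix(values, n, k) -
                   matrix(means, n, k, byrow = TRUE)) / sd)^2
  delta <- log_prior + em[1, ]
  psi <- matrix(0L, n, k)
  if (n > 1) {
    for (t in seq(2, n)) {
      cand <- matrix(delta + lq, k, k)   # cand[i, j]: from state i into j
      diag(cand) <- delta + lp
      pred <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(pred, seq_len(k))] + em[t, ]
      psi[t, ] <- pred
    }
  }
  state <- integer(n)
  state[n] <- which.max(delta)  # first max = lowest copy-number state
  if (n > 1) {
    for (t in seq(n - 1, 1)) state[t] <- psi[t + 1, state[t + 1]]
  }
  state
}

#' Viterbi copy-number path
#'
#' Maximum-probability state path per unmasked bin at a fixed tumor
#' fraction: Gaussian emissions centred at [emission_mean()], diagonal
#' self-transition with uniform off-diagonal mass, chromosomes decoded as
#' independent chains. Ties resolve toward the lower copy-number state.
#'
#' @param profile A `normalized_profile`.
#' @param config An [hmm_config()].
#' @param tumor_fraction Fixed tumor fraction at which to decode.
#' @return Integer vector of copy numbers, one per unmasked bin in grid
#'   order, with the corresponding 0-based grid ordinals as attribute
#'   `ordinals`.
#' @export
viterbi_path <- function(profile, config = hmm_config(), tumor_fraction) {
  chroms <- profile_chrom_values(profile)
  if (length(chroms) == 0) stop("profile has no unmasked bins")
  sd <- resolve_emission_sd(profile, config)
  means <- emission_mean(config$states, tumor_fraction)
  log_prior <- log(resolve_state_prior(config))
  states <- integer(0)
  ordinals <- integer(0)
  for (ch in chroms) {
    s <- viterbi_chromosome(ch$values, means, sd,
                            config$self_transition, log_prior)
    states <- c(states, config$states[s])
    ordinals <- c(ordinals, ch$ordinals)
  }
  structure(states, ordinals = ordinals)
}

#' Segments from a copy-number path
#'
#' Collapses maximal runs of constant state into segments. Masked bins
#' interrupt a run only when more than `max_gap_bins` consecutive masked
#' bins separate two unmasked bins of the same state.
#'
#' @param path Result of [viterbi_path()] (or any integer state vector with
#'   an `ordinals` attribute of 0-based grid positions).
#' @param profile The `normalized_profile` the path was decoded from.
#' @param max_gap_bins Largest masked gap bridged within one segment
#'   (default 1).
#' @return Data frame of segments: `chromosome`, `start_bin`, `end_bin`
#'   (inclusive 0-based grid ordinals), `state`, `mean_log2`, `n_bins`.
#' @export
segments_from_path <- function(path, profile, max_gap_bins = 1) {
  ordinals <- attr(path, "ordinals")
  grid <- profile$grid
  chrom <- grid$chromosome[ordinals + 1L]
  segs <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    st <- as.integer(path[sel])
    ords <- ordinals[sel]
    gap <- c(0L, diff(ords) - 1L)
    new_run <- c(TRUE, st[-1] != st[-length(st)]) | gap > max_gap_bins
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      i <- which(run_id == r)
      segs[[length(segs) + 1]] <- data.frame(
        chromosome = ch,
        start_bin = ords[i[1]],
        end_bin = ords[i[length(i)]],
        state = st[i[1]],
        mean_log2 = mean(profile$log2[ords[i] + 1L]),
        n_bins = length(i),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Run the full HMM caller
#'
#' Estimates the tumor fraction by grid search, Viterbi-decodes the profile
#' at the estimate, and collapses the path to segments.
#'
#' @param profile A `normalized_profile`.
#' @param config An [hmm_config()].
#' @return List with `estimate` (the [estimate_tumor_fraction()] result),
#'   `path`, and `segments`.
#' @export
hmm_call <- function(profile, config = hmm_config()) {
  est <- estimate_tumor_fraction(profile, config)
  path <- viterbi_path(profile, config, est$f_hat)
  list(estimate = est,
       path = path,
       segments = segments_from_path(path, profile))
}

#' Fixed-threshold segment caller
#'
#' The rule-based caller: contiguous runs of unmasked bins with log2 ratio
#' at or below `loss_cut` (at or above `gain_cut`) become loss (gain)
#' segments when they contain at least `min_bins` qualifying bins and no two
#' consecutive qualifying bins are farther apart than `max_gap_bp`. The
#' default cutoffs -0.015 / 0.035 with 3 probes and 1000 kb spacing are the
#' settings used for visual-review-grade calling of shallow-WGS profiles;
#' the profile should be recentred around a diploid region (arm 12q) first.
#'
#' @param profile A `normalized_profile` (recentred).
#' @param loss_cut Log2 ratio at or below which a bin supports loss
#'   (must be negative).
#' @param gain_cut Log2 ratio at or above which a bin supports gain
#'   (must be positive).
#' @param min_bins Minimum qualifying bins per segment.
#' @param max_gap_bp Maximum spacing between consecutive qualifying bin
#'   starts within one segment.
#' @return Data frame of segments as in [segments_from_path()] (loss
#'   segments get state 1, gain segments state 3).
#' @export
threshold_call <- function(profile, loss_cut = -0.015, gain_cut = 0.035,
                           min_bins = 3, max_gap_bp = 1e6) {
  if (loss_cut >= 0) stop("loss_cut must be negative")
  if (gain_cut <= 0) stop("gain_cut must be positive")
  grid <- profile$grid
  segs <- list()
  for (direction in c("loss", "gain")) {
    qual <- if (direction == "loss") {
      !is.na(profile$log2) & profile$log2 <= loss_cut
    } else {
      !is.na(profile$log2) & profile$log2 >= gain_cut
    }
    idx <- which(qual)
    if (length(idx) == 0) next
    same_chrom <- c(FALSE, grid$chromosome[idx[-1]] ==
                      grid$chromosome[idx[-length(idx)]])
    spacing_ok <- c(FALSE, diff(grid$start_bp[idx]) <= max_gap_bp)
    run_id <- cumsum(!(same_chrom & spacing_ok))
    for (r in unique(run_id)) {
      i <- idx[run_id == r]
      if (length(i) < min_bins) next
      segs[[length(segs) + 1]] <- data.frame(
        chromosome = grid$chromosome[i[1]],
        start_bin = i[1] - 1L,
        end_bin = i[length(i)] - 1L,
        state = if (direction == "loss") 1L else 3L,
        mean_log2 = mean(profile$log2[i]),
        n_bins = length(i),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(segs) == 0) {
    return(data.frame(chromosome = character(), start_bin = integer(),
                      end_bin = integer(), state = integer(),
                      mean_log2 = numeric(), n_bins = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  out <- out[order(match(out$chromosome, unique(grid$chromosome)),
                   out$start_bin), ]
  rownames(out) <- NULL
  out
}

#' Chromosome- or arm-level call from segments
#'
#' Summarizes segments into a single loss/neutral/gain call for a region:
#' the call is loss (gain) when the fraction of the region's unmasked bins
#' covered by loss (gain) segments reaches `min_fraction` and exceeds the
#' opposing direction; otherwise neutral. A majority of bins
#' (`min_fraction = 0.5`) is the default decision rule.
#'
#' @param segments Segment data frame from [hmm_call()], [threshold_call()]
#'   or [segments_from_path()].
#' @param profile The `normalized_profile` the segments refer to.
#' @param region Chromosome or arm name (e.g. "3", "8q").
#' @param min_fraction Minimum supporting bin fraction for a non-neutral
#'   call.
#' @param neutral_state Copy number counted as neutral (default 2; lower
#'   states support loss, higher support gain).
#' @return List with `region`, `call` ("loss", "neutral" or "gain"),
#'   `supporting_bin_fraction`, `loss_fraction`, `gain_fraction`.
#' @export
chromosome_call <- function(segments, profile, region, min_fraction = 0.5,
                            neutral_state = 2L) {
  rb <- region_bins(profile$grid, region)
  unmasked <- rb[!is.na(profile$log2[rb + 1L])]
  if (length(unmasked) == 0) stop("region ", region, " has no unmasked bins")
  covered_by <- function(seg_subset) {
    if (nrow(seg_subset) == 0) return(0)
    hit <- rep(FALSE, length(unmasked))
    for (i in seq_len(nrow(seg_subset))) {
      hit <- hit | (unmasked >= seg_subset$start_bin[i] &
                      unmasked <= seg_subset$end_bin[i])
    }
    mean(hit)
  }
  loss_fraction <- covered_by(segments[segments$state < neutral_state, ,
                                       drop = FALSE])
  gain_fraction <- covered_by(segments[segments$state > neutral_state, ,
                                       drop = FALSE])
  call <- "neutral"
  if (loss_fraction >= min_fraction && loss_fraction > gain_fraction) {
    call <- "loss"
  } else if (gain_fraction >= min_fraction && gain_fraction > loss_fraction) {
    call <- "gain"
  }
  list(region = region, call = call,
       supporting_bin_fraction = max(loss_fraction, gain_fraction),
       loss_fraction = loss_fraction, gain_fraction = gain_fraction)
}

#' Write segments as a SEG file
#'
#' Tab-separated: sample, chromosome, start_bp, end_bp, n_bins, mean_log2,
#' state.
#'
#' @param segments Segment data frame.
#' @param profile The profile the segments refer to (for bp coordinates).
#' @param path Output path.
#' @param sample Sample identifier.
#' @export
write_seg <- function(segments, profile, path, sample = "sample") {
  grid <- profile$grid
  tab <- data.frame(
    sample = sample,
    chromosome = segments$chromosome,
    start_bp = grid$start_bp[segments$start_bin + 1L],
    end_bp = grid$end_bp[segments$end_bin + 1L],
    n_bins = segments$n_bins,
    mean_log2 = signif(segments$mean_log2, 6),
    state = segments$state
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
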