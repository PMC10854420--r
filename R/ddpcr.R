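#' Droplet digital PCR assay record
#'
#' Raw droplet counts and the volume bookkeeping needed to express a
#' mutation assay (e.g. GNAQ/GNA11 Q209 or PLCB4 D630 hotspots) as copies
#' per millilitre of plasma. Plasma volume varies per sample and is
#' therefore always explicit, never defaulted.
#'
#' @param n_droplets_total Total accepted droplets.
#' @param n_mutant_positive Droplets positive in the mutant channel.
#' @param n_wildtype_positive Droplets positive in the wild-type channel
#'   (optional, NA if not read).
#' @param droplet_volume_nL Droplet volume in nanolitres (default 0.85).
#' @param reaction_volume_uL PCR reaction volume in microlitres.
#' @param template_volume_uL Volume of eluate template loaded into the
#'   reaction.
#' @param elution_volume_uL Total cfDNA eluate volume.
#' @param plasma_volume_mL Plasma volume the cfDNA was extracted from.
#' @param assay Assay name.
#' @return A `droplet_assay` object.
#' @export
droplet_assay <- function(n_droplets_total,
                          n_mutant_positive,
                          n_wildtype_positive = NA,
                          droplet_volume_nL = 0.85,
                          reaction_volume_uL = 20,
                          template_volume_uL = 8,
                          elution_volume_uL = 50,
                          plasma_volume_mL = 4,
                          assay = "assay") {
  if (n_droplets_total <= 0) stop("n_droplets_total must be positive")
  if (n_mutant_positive < 0 || n_mutant_positive > n_droplets_total) {
    stop("n_mutant_positive must lie in [0, n_droplets_total]")
  }
  if (!is.na(n_wildtype_positive) &&
      (n_wildtype_positive < 0 || n_wildtype_positive > n_droplets_total)) {
    stop("n_wildtype_positive must lie in [0, n_droplets_total]")
  }
  if (template_volume_uL > elution_volume_uL) {
    stop("template volume cannot exceed the elution volume")
  }
  if (droplet_volume_nL <= 0 || reaction_volume_uL <= 0 ||
      template_volume_uL <= 0 || plasma_volume_mL <= 0) {
    stop("volumes must be positive")
  }
  structure(as.list(environment()), class = "droplet_assay")
}

#' Poisson-corrected mean copies per droplet
#'
#' In digital PCR a droplet is positive when it holds at least one template
#' molecule; under Poisson loading the mean occupancy is
#' `lambda = -ln(1 - positive fraction)`.
#'
#' @param n_positive Positive droplet count.
#' @param n_total Total droplet count.
#' @return Mean copies per droplet.
#' @export
poisson_lambda <- function(n_positive, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_positive < 0 || n_positive > n_total) {
    stop("n_positive must lie in [0, n_total]")
  }
  if (n_positive == n_total) {
    stop("all droplets positive: reaction saturated, ",
         "concentration undefined")
  }
  -log(1 - n_positive / n_total)
}

#' Quantify ctDNA as copies per millilitre of plasma
#'
#' Volume bookkeeping from droplets back to plasma: mean copies per droplet
#' (Poisson corrected) gives copies per microlitre of reaction; scaling by
#' the reaction volume gives copies in the reaction, by
#' `elution/template` the copies in the whole eluate, and dividing by the
#' plasma volume the copies per mL of plasma. The detection rule defaults
#' to at least one mutant-positive droplet; an undetected sample reports 0
#' copies/mL. When both channels are read the mutant fraction
#' `lambda_mut / (lambda_mut + lambda_wt)` is reported.
#'
#' @param assay A [droplet_assay()].
#' @param min_positive_droplets Detection threshold (default 1).
#' @param saturation_fraction Positive fraction above which a saturation
#'   flag is raised (default 0.995).
#' @return A `ctdna_quant`: list with `copies_per_ml_plasma`,
#'   `mutant_fraction` (NA when the wild-type channel is absent),
#'   `detected`, `lambda_mutant`, `saturation_flag`, `assay`.
#' @export
copies_per_ml <- function(assay, min_positive_droplets = 1,
                          saturation_fraction = 0.995) {
  stopifnot(inherits(assay, "droplet_assay"))
  lam_mut <- poisson_lambda(assay$n_mutant_positive, assay$n_droplets_total)
  detected <- assay$n_mutant_positive >= min_positive_droplets
  conc_per_ul <- lam_mut / (assay$droplet_volume_nL * 1e-3)
  copies_reaction <- conc_per_ul * assay$reaction_volume_uL
  copies_eluate <- copies_reaction *
    assay$elution_volume_uL / assay$template_volume_uL
  copies_ml <- copies_eluate / assay$plasma_volume_mL
  if (!detected) copies_ml <- 0
  mutant_fraction <- NA_real_
  if (!is.na(assay$n_wildtype_positive)) {
    lam_wt <- poisson_lambda(assay$n_wildtype_positive,
                             assay$n_droplets_total)
    if (lam_mut + lam_wt > 0) {
      mutant_fraction <- lam_mut / (lam_mut + lam_wt)
    }
  }
  structure(list(
    copies_per_ml_plasma = copies_ml,
    mutant_fraction = mutant_fraction,
    detected = detected,
    lambda_mutant = lam_mut,
    saturation_flag = assay$n_mutant_positive / assay$n_droplets_total >
      saturation_fraction,
    assay = assay$assay
  ), class = "ctdna_quant")
}

#' Detection flag for a quantification
#'
#' @param assay A [droplet_assay()].
#' @param min_positive_droplets Minimum mutant-positive droplets required
#'   (default 1; the instrument-software rule is not public, so the
#'   threshold is explicit and configurable).
#' @return Logical.
#' @export
detect_ctdna <- function(assay, min_positive_droplets = 1) {
  stopifnot(inherits(assay, "droplet_assay"))
  assay$n_mutant_positive >= min_positive_droplets
}

#' Simulate a droplet assay from a true plasma concentration
#'
#' Inverse of the [copies_per_ml()] bookkeeping: the true copies/mL implies
#' a mean droplet occupancy, and each droplet is positive with probability
#' `1 - exp(-lambda)`.
#'
#' @param copies_per_ml_true True mutant copies per mL plasma.
#' @param n_droplets_total Droplets generated.
#' @param wildtype_copies_per_ml True wild-type copies per mL (background
#'   cfDNA), NA to skip the channel.
#' @param seed Integer seed.
#' @inheritParams droplet_assay
#' @return A [droplet_assay()] with simulated positive counts.
#' @export
simulate_droplet_assay <- function(copies_per_ml_true,
                                   n_droplets_total = 15000,
                                   wildtype_copies_per_ml = NA,
                                   droplet_volume_nL = 0.85,
                                   reaction_volume_uL = 20,
                                   template_volume_uL = 8,
                                   elution_volume_uL = 50,
                                   plasma_volume_mL = 4,
                                   assay = "assay",
                                   seed = 1L) {
  lambda_of <- function(copies_ml) {
    copies_eluate <- copies_ml * plasma_volume_mL
    copies_reaction <- copies_eluate * template_volume_uL / elution_volume_uL
    conc_per_ul <- copies_reaction / reaction_volume_uL
    conc_per_ul * droplet_volume_nL * 1e-3
  }
  with_seed(seed, {
    n_mut <- stats::rbinom(1, n_droplets_total,
                           1 - exp(-lambda_of(copies_per_ml_true)))
    n_wt <- if (is.na(wildtype_copies_per_ml)) NA else
      stats::rbinom(1, n_droplets_total,
                    1 - exp(-lambda_of(wildtype_copies_per_ml)))
    droplet_assay(n_droplets_total, n_mut, n_wt,
                  droplet_volume_nL = droplet_volume_nL,
                  reaction_volume_uL = reaction_volume_uL,
                  template_volume_uL = template_volume_uL,
                  elution_volume_uL = elution_volume_uL,
                  plasma_volume_mL = plasma_volume_mL,
                  assay = assay)
  })
}

#' Compare ctDNA burden between two cohort groups
#'
#' Two-sided Mann-Whitney U test on copies/mL (exact when the combined
#' sample size is at most 20 and there are no ties, normal approximation
#' with tie correction otherwise) and two-sided Fisher's exact test on the
#' detected proportions.
#'
#' @param cohort Data frame with columns `group`, `copies_per_ml`,
#'   `detected`.
#' @param group_a,group_b Group labels to compare.
#' @return List with `U`, `p_mann_whitney`, `median_a`, `median_b`,
#'   `p_fisher`, `detected_a`, `detected_b`, `n_a`, `n_b`, `exact`.
#' @export
compare_groups <- function(cohort, group_a, group_b) {
  need <- c("group", "copies_per_ml", "detected")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  }
  a <- cohort[cohort$group == group_a, , drop = FALSE]
  b <- cohort[cohort$group == group_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be non-empty")
  x <- a$copies_per_ml
  y <- b$copies_per_ml
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !has_ties
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  tab <- matrix(c(sum(a$detected), sum(!a$detected),
                  sum(b$detected), sum(!b$detected)),
                nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(U = unname(wt$statistic),
       p_mann_whitney = wt$p.value,
       exact = use_exact,
       median_a = stats::median(x),
       median_b = stats::median(y),
       p_fisher = ft$p.value,
       detected_a = sum(a$detected) / nrow(a),
       detected_b = sum(b$detected) / nrow(b),
       n_a = nrow(a), n_b = nrow(b))
}
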