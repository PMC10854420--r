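---
title: "Copy-number profiling of plasma cfDNA at shallow depth: models and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling of plasma cfDNA at shallow depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmacnv)
```

## The problem

Uveal melanoma metastasizes almost exclusively in tumors that have lost one
copy of chromosome 3, with amplification of chromosome arm 8q compounding
the risk. Tumor tissue is often unavailable (eye-sparing radiotherapy), so
the prognostic karyotype must be read from blood: circulating tumor DNA
(ctDNA) is a minority component of plasma cell-free DNA (cfDNA), and at
~0.2X shallow whole-genome sequencing its copy-number aberrations appear as
percent-level shifts in binned read depth. `plasmacnv` implements that
read-out end to end: fragment filtering, megabase binning, normalization,
tumor-fraction and CNV calling, an in silico dilution study that measures
the limit of detection (LOD), and droplet-digital-PCR (ddPCR)
quantification of ctDNA abundance. A synthetic-data generator stands in
for patient samples so every stage is testable.

## The forward model the pipeline inverts

A plasma sample is an admixture: a fraction $f$ of fragments derive from
tumor cells with local copy number $c(b)$, the rest from diploid tissue.
The expected relative depth of bin $b$ is

$$
\mathrm{E}[\text{depth}(b)] \propto \frac{2(1-f) + f\,c(b)}{2}
\cdot g(b),
$$

where $g(b)$ is a multiplicative GC-bias factor. A monosomy at $f = 0.25$
therefore sits at $\log_2(0.875) = -0.193$; at $f = 0.01$ the same event is
a $-0.0072$ shift — the scale the LOD study probes. The generator
(`sim_config()`, `simulate_bin_counts()`, `simulate_fragments()`) samples
this model directly: multinomial counts at `overdispersion = 0`,
gamma-mixed Poisson (negative binomial) otherwise; a seeded GC field in
$[0.3, 0.6]$ (a smooth chromosome-scale component plus a smaller
independent per-bin component, since megabase GC varies bin to bin) with
bias $g(b) = \exp(\gamma \cdot \mathrm{z}(GC_b))$, default
$\gamma = 0.1$ — the $\pm$10–30% depth modulation typical of
megabase-binned coverage; and a two-component truncated-normal insert-size
mixture (background 167 ± 40 b, tumor 145 ± 35 b on $[50, 400]$ b —
ctDNA runs shorter, the basis of size selection; absolute ctDNA length
parameters are a modelling choice, not a measured quantity).

What the generator does *not* emulate: mappability structure, replication
timing waves, panel-of-normals batch effects, or sequence-level errors.
Passing tests therefore demonstrate correctness of the computation on its
stated model, not performance on any particular patient cohort.

## Pipeline stages and the parameters that matter

* **Size selection** (`filter_by_insert_size`): closed window, default
  80–150 bases inclusive. The window endpoints are conventional for
  ctDNA enrichment; inclusivity is recorded in provenance metadata.
  Single-end records are refused, never guessed at.
* **MAPQ filter** (`filter_by_mapq`): default minimum 20, the
  read-counter convention.
* **Binning** (`bin_fragments`): 1 Mb half-open bins, fragment assigned by
  its start coordinate (deterministic, matches read-counter behavior on
  the first read).
* **GC correction** (`gc_correct`): 50 equal-width GC strata; the stratum
  medians (over non-zero bins, on the depth scale) are smoothed by a
  running median across neighbouring strata and evaluated as a curve by
  linear interpolation at each bin's GC. Both refinements are
  load-bearing: a step-function correction leaves within-stratum bias of
  the same order as the shot noise at 25 M fragments, and the
  across-strata running median keeps a stratum whose occupants are mostly
  copy-number-event bins from absorbing the event into the "bias" curve
  (a GC trend is locally monotone, so the running median preserves it
  while outvoting a single contaminated stratum).
* **Reference scaling** (`reference_scaling_factor`): mean depth over
  non-zero bins of arm 2q, chromosome 4 and arm 12q — the regions least
  often altered in uveal melanoma (<1%, <5%, <1% of tumors), so the
  baseline is anchored to copy-neutral territory. Depth means
  full-bin-equivalent counts (`count × bin_size / bin_width`), the
  bin-level analogue of per-base coverage; for full bins this is simply
  the count. Note the bin-wise mean anchors the *linear* ratio at 1, so
  the mean log2 ratio of the reference bins sits a hair below 0
  (Jensen's inequality, about $-\sigma^2/2\ln 2 \approx -2\times10^{-4}$
  at design depth) — intentional, matching the coverage-based scaling
  convention rather than a log-scale recentering.
* **Masking**: zero-count bins, sex chromosomes (patient sex unknown to
  the model), and bins narrower than half the nominal width. The last
  rule is load-bearing: a 6–22 kb terminal bin carries ~50–180 reads at
  0.2X, its log2 noise is 0.1–0.2, and a single such outlier can
  dominate the tumor-fraction likelihood. Masked bins are excluded from
  every statistic and never imputed.
* **Recentering** (`recenter = "12q"`): subtracts the median log2 of a
  diploid region; required by the threshold caller, whose cutoffs are
  defined around a diploid baseline.

## The HMM caller and its calibration

States are integer copy numbers $\{1, 2, 3, 4\}$ with Gaussian emissions
centred at $\mu_c(f) = \log_2\!\big((2(1-f) + c f)/2\big)$, a shared
emission sd, self-transition 0.9999 with the remainder uniform across the
other states, and chromosomes decoded as independent chains. The tumor
fraction is estimated by forward-likelihood grid search (0 to 0.5 in steps
of 0.005, then 0.55 to 1 in steps of 0.05); exact ties resolve to the
smallest $f$ (parsimony), and Viterbi ties resolve toward the lower copy
number. Grid search was chosen over EM deliberately: it is deterministic,
its likelihood curve is reportable, and 0.005 resolution is finer than the
sampling noise of $\hat f$ at design depth.

Two defaults deserve their derivation:

* **Initial state distribution = the neutral transition row.** Each
  chromosome behaves as if preceded by a virtual copy-neutral telomere
  bin. Licensing an aberrant segment then costs one transition,
  $\log(0.9999 \cdot 3 / 10^{-4}) \approx 10.3$ nats, *identically* for a
  whole chromosome and for a single arm — no arbitrary prior vector to
  justify, and no asymmetry between monosomy-3-like and 8q-gain-like
  events.
* **Emission sd = 0.024.** At 25 M fragments over ~3,100 bins the
  binomial shot-noise floor is $\sigma \approx 0.016$ log2 units per bin;
  measured profile sd after GC correction is ~0.017. The caller is
  calibrated ~1.5× above the floor so that residual correction structure
  and modest overdispersion do not masquerade as tumor signal. The
  resulting operating point can be read off in closed form: the expected
  log-likelihood gain of a true event is
  $n \mu^2 / 2\sigma_{\mathrm{em}}^2$ over $n$ bins of shift $\mu$, i.e.
  ~36 nats for chromosome 3 (199 bins) at a 1% depletion, ~9 nats at
  0.5%, ~18 nats for 8q (~100 bins) at a 1% gain, ~4.5 at 0.5% — against
  the 10.3-nat licensing cost. One-percent events clear the bar, half-percent
  events generally do not: the caller's detection limit falls between
  0.5% and 1%, which is exactly where the dilution series jumps. A
  method-of-moments estimate (`emission_sd = "estimated"`) is available
  but sits at the shot-noise floor and therefore calls half-percent
  events a clean simulation can support while real data would not.

The per-replicate detection probability at the 0.5% boundary point is by
this design ~35%, so a three-replicate all-detect rule reports an LOD of
1% for most seeds and 0.5% occasionally; the dilution grid itself is the
resolution of the answer.

## The in silico dilution study

`spike_loss()` thins every chromosome-3 bin by `Binomial(count, 1 - d)`;
`spike_gain()` adds `Binomial(count, d)` to every 8q bin outside 1 Mb of
the centromere. At start-coordinate binning these are distributionally
identical to subsampling/merging aligned reads, and `spike_fragments()`
provides the fragment-level twin (the equivalence is property-tested).
The canonical series is 0.1, 0.2, 0.5, 1, 5, 10, 25%. One labelling
subtlety is preserved deliberately: the depleted fraction $d$ is called
the "tumor load" directly, although a pure monosomy at tumor fraction $f$
would deplete only $f/2$ — both readings are stated here and the literal
retention series is what is implemented. `lod_scan()` runs
spike → normalize → HMM call → chromosome-level majority call
(`min_fraction = 0.5` of region bins; the operational definition of a
"detected" chromosome is a design decision made explicit) for every
fraction × replicate and reports the smallest fraction detected in all
replicates (`detect_rule = 1`, conservative by construction).

```{r lod, eval = FALSE}
grid <- build_bin_grid(grch37_genome(), 1e6)
base <- sim_config(grid, n_fragments = 25e6, overdispersion = 0, seed = 1)
lod_scan(base, "3", "loss")    # canonical series, 3 replicates
```

## The threshold caller

The rule-based alternative mirrors interactive review settings: loss at
log2 ≤ −0.015, gain at ≥ 0.035, at least 3 qualifying bins, consecutive
qualifying bins at most 1000 kb apart, after 12q recentering. The loss
cutoff is deliberately shallower in magnitude than a 1% depletion
($\log_2 0.99 = -0.0145$), so a noiseless 1% event is *not* called while
5% ($-0.074$) clearly is — the two callers bracket the same sensitivity
regime by different means.

## ddPCR quantification

Droplet digital PCR partitions the reaction; under Poisson loading the
mean occupancy is $\lambda = -\ln(1 - p_+)$. `copies_per_ml()` does the
volume bookkeeping from droplet to plasma
($\lambda \to$ copies/µL reaction $\to$ reaction $\to$ eluate $\to$
copies per mL plasma); every volume is an explicit input because plasma
volume varies per sample. Detection defaults to ≥ 1 mutant-positive
droplet (instrument vendors do not publish their rule; ours is explicit
and configurable), and undetected samples report 0 copies/mL. Group
comparisons use the two-sided Mann-Whitney U test (exact below a combined
n of 21 without ties) and Fisher's exact test on detection proportions —
the two tests on this analysis path; omnibus tests (ANOVA,
Kruskal-Wallis, chi-square) are out of scope.

## Numerical choices and degenerate inputs

* Forward/Viterbi run in log space with per-bin max normalization; the
  emission mean of a homozygous deletion in pure tumor is capped at −8
  rather than $-\infty$.
* A loss spike at fraction 1.0 empties the region; the resulting
  all-masked region is reported as detected (supporting fraction 1)
  rather than an error inside `lod_scan`.
* WIG I/O enforces `step == span == bin size` and 1-based `start=1`
  headers, failing with line numbers; write∘read is the identity on
  counts.
* All randomness is seeded through configuration objects; identical
  configurations produce byte-identical artifacts (`run_pipeline()`
  manifests carry the seeds).

## Problem sizes used by the test suite

The acceptance-style tests run the dilution study and tumor-fraction
recovery at the full design depth (25 M fragments, count level, 3
replicates or 10 seeds), which completes in well under a minute per
experiment because counts are simulated directly at bin resolution.
Fragment-level tests use $2\times10^4$–$5\times10^5$ fragments, enough
for the distributional assertions at their stated tolerances.

## Known limitations

No mappability or panel-of-normals correction (download-free build); no
allele-fraction/BAF modelling, so copy-neutral loss of heterozygosity is
invisible by construction (and asserted to be); ploidy fixed at 2 with no
subclonal states; sex chromosomes masked rather than modelled. The LOD
measured here characterizes the pipeline on its own synthetic model —
cleaner than patient plasma — and the caller calibration, not the assay
chemistry, is what pins it to the percent scale. One residual hazard of
any self-referential GC correction remains by construction: when a GC
extreme is populated almost exclusively by bins of one large event (tens
of event bins among the ~1% most extreme GC values), those few bins are
partially absorbed into the bias curve; a panel of normals or an
iterative call-mask-recorrect loop would remove this and is deliberately
out of scope.
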