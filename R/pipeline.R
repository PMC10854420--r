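#' End-to-end run configuration
#'
#' Ties the stages into one reproducible run: simulate (or ingest) -> filter
#' -> bin -> normalize -> call, with every stochastic stage seeded
#' explicitly. Validation is strict: the threshold caller requires a
#' recentering region (its cutoffs are defined around a diploid baseline).
#'
#' @param genome A [genome_model()] (default the bundled GRCh37-style
#'   model).
#' @param bin_size_bp Bin width (default 1 Mb).
#' @param archetype Name of a profile in [uveal_archetypes()], used when
#'   simulating.
#' @param tumor_fraction Simulated tumor fraction.
#' @param n_fragments Simulated depth.
#' @param overdispersion Simulated count overdispersion.
#' @param fragments_path Optional fragment TSV to ingest instead of
#'   simulating counts.
#' @param wig_path Optional WIG file to ingest instead of simulating.
#' @param size_select `c(min, max)` insert-size window applied to fragment
#'   input, or `NULL` to skip.
#' @param min_mapq MAPQ threshold applied to fragment input.
#' @param reference_regions Normalization reference regions.
#' @param recenter Recentering region or `NULL`.
#' @param caller "hmm" or "threshold".
#' @param hmm An [hmm_config()].
#' @param call_regions Regions to summarize with [chromosome_call()].
#' @param seed Master seed recorded in the manifest.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(genome = grch37_genome(),
                       bin_size_bp = 1e6,
                       archetype = "neutral",
                       tumor_fraction = 0,
                       n_fragments = 25e6,
                       overdispersion = 0,
                       fragments_path = NULL,
                       wig_path = NULL,
                       size_select = c(80, 150),
                       min_mapq = 20,
                       reference_regions = c("2q", "4", "12q"),
                       recenter = NULL,
                       caller = c("hmm", "threshold"),
                       hmm = hmm_config(),
                       call_regions = c("3", "8q"),
                       seed = 1L,
                       out_dir = tempfile("plasmacnv_run_")) {
  caller <- match.arg(caller)
  if (caller == "threshold" && is.null(recenter)) {
    stop("the threshold caller requires a recentering region ",
         "(its cutoffs are relative to a diploid baseline)")
  }
  if (!archetype %in% names(uveal_archetypes())) {
    stop("unknown archetype: ", archetype)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Execute a configured pipeline run
#'
#' Runs the configured stages, writes the artifacts (WIG counts, per-bin
#' log2 TSV, SEG segments, JSON report) into the output directory together
#' with a manifest recording all parameters and seeds. The manifest and
#' artifacts are a pure function of the configuration: identical
#' configurations produce identical files.
#'
#' @param config A [run_config()].
#' @return List with `manifest`, `counts`, `profile`, `segments`, `calls`,
#'   `estimate` (HMM caller only) and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_bin_grid(config$genome, config$bin_size_bp)
  log <- list()

  if (!is.null(config$wig_path)) {
    counts <- read_wig(config$wig_path, grid)
    log$input <- list(stage = "read_wig", path = config$wig_path)
  } else if (!is.null(config$fragments_path)) {
    fr <- read_fragments_tsv(config$fragments_path)
    n0 <- nrow(fr)
    if (!is.null(config$size_select)) {
      fr <- filter_by_insert_size(fr, config$size_select[1],
                                  config$size_select[2])
    }
    n1 <- nrow(fr)
    fr <- filter_by_mapq(fr, config$min_mapq)
    log$input <- list(stage = "fragments", path = config$fragments_path,
                      n_in = n0, n_after_size = n1, n_after_mapq = nrow(fr))
    counts <- bin_fragments(fr, grid)
  } else {
    profile_def <- uveal_archetypes()[[config$archetype]]
    sim <- sim_config(grid,
                      n_fragments = config$n_fragments,
                      tumor_fraction = config$tumor_fraction,
                      profile = profile_def,
                      overdispersion = config$overdispersion,
                      seed = config$seed)
    counts <- simulate_bin_counts(sim)
    log$input <- list(stage = "simulate", archetype = config$archetype,
                      tumor_fraction = config$tumor_fraction,
                      n_fragments = config$n_fragments, seed = config$seed)
  }

  profile <- to_log2_profile(counts,
                             regions = config$reference_regions,
                             recenter = config$recenter)

  estimate <- NULL
  if (config$caller == "hmm") {
    fit <- hmm_call(profile, config$hmm)
    segments <- fit$segments
    estimate <- fit$estimate
  } else {
    segments <- threshold_call(profile)
  }
  calls <- lapply(config$call_regions, function(r) {
    chromosome_call(segments, profile, r)
  })
  names(calls) <- config$call_regions

  paths <- list(
    wig = file.path(config$out_dir, "counts.wig"),
    log2 = file.path(config$out_dir, "profile.log2.tsv"),
    seg = file.path(config$out_dir, "segments.seg"),
    report = file.path(config$out_dir, "report.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_wig(counts, paths$wig)
  write_log2_tsv(profile, paths$log2)
  write_seg(segments, profile, paths$seg)

  report <- list(
    scaling_factor = profile$scaling_factor,
    tumor_fraction_estimate = if (is.null(estimate)) NULL else estimate$f_hat,
    calls = lapply(calls, function(cl) {
      list(region = cl$region, call = cl$call,
           supporting_bin_fraction = cl$supporting_bin_fraction)
    })
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    package = "plasmacnv",
    version = as.character(utils::packageVersion("plasmacnv")),
    parameters = list(
      bin_size_bp = config$bin_size_bp,
      archetype = config$archetype,
      tumor_fraction = config$tumor_fraction,
      n_fragments = config$n_fragments,
      overdispersion = config$overdispersion,
      size_select = config$size_select,
      min_mapq = config$min_mapq,
      reference_regions = config$reference_regions,
      recenter = config$recenter,
      caller = config$caller,
      call_regions = config$call_regions
    ),
    seeds = list(master = config$seed),
    stages = log,
    artifacts = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(manifest = manifest, counts = counts, profile = profile,
       segments = segments, calls = calls, estimate = estimate,
       paths = paths)
}
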