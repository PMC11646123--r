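# Stage orchestration: run the analysis end to end (or stage by stage) from
# one configuration object, with deterministic seeds and a run manifest per
# stage.

PIPELINE_STAGES <- c("simulate", "classify", "maps", "cooccur", "kmers",
                     "coreg", "congruence", "overlap")

#' Pipeline configuration
#'
#' Collects every path, threshold and tuning parameter the staged pipeline
#' needs. Each stochastic stage draws its seed deterministically from the
#' single top-level `seed`.
#'
#' @param out_dir Output directory; every stage writes beneath it.
#' @param seed Top-level integer seed.
#' @param sim A [sim_config()] for the simulate stage (its own seed is
#'   derived from `seed` unless supplied).
#' @param thresholds A [thresholds()] object.
#' @param layout A [map_layout()].
#' @param motif_primary,motif_secondary The primary motif (RNA maps) and the
#'   secondary motif (co-occurrence partner).
#' @param n_perm,alpha Permutation settings for maps and k-mers.
#' @param link_max_gap Co-occurrence link distance (nt).
#' @param kmer_k k-mer length.
#' @param kmer_segments Segment labels counted in the k-mer stage.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            thresholds = splicemaps::thresholds(),
                            layout = map_layout(),
                            motif_primary = motif_rbpms(),
                            motif_secondary = motif_rbfox(),
                            n_perm = 1000L, alpha = 0.05,
                            link_max_gap = 25L, kmer_k = 8L,
                            kmer_segments = "intron_down_5p") {
  if (is.null(sim)) sim <- sim_config(seed = seed * 1000L)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         thresholds = thresholds, layout = layout,
         motif_primary = motif_primary, motif_secondary = motif_secondary,
         n_perm = as.integer(n_perm), alpha = alpha,
         link_max_gap = as.integer(link_max_gap),
         kmer_k = as.integer(kmer_k), kmer_segments = kmer_segments),
    class = "pipeline_config"
  )
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(sprintf(
      "Missing artifact '%s'; run the '%s' stage first to produce it.",
      path, producer
    ))
  }
  path
}

write_manifest <- function(dir, stage, config, inputs = character()) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("splicemaps")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE,
             pretty = TRUE)
}

read_classified <- function(config) {
  path <- require_artifact(
    file.path(config$out_dir, "classify", "events_tested.tsv"), "classify"
  )
  read_events(path)
}

read_sets <- function(config) {
  path <- require_artifact(
    file.path(config$out_dir, "classify", "event_sets.json"), "classify"
  )
  sets <- read_json(path, simplifyVector = TRUE)
  lapply(sets[c("activated", "repressed", "reference")], as.character)
}

pipeline_regions <- function(config, ids) {
  genome <- require_artifact(
    file.path(config$out_dir, "simulate", "genome.fa"), "simulate"
  )
  events <- read_classified(config)
  extract_regions(events[events$event_id %in% ids, ], genome, config$layout)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write the synthetic dataset), `classify`
#' (differential test + event sets), `maps` (RNA maps of the primary motif
#' for activated and repressed sets), `cooccur` (linked-pair co-occurrence
#' map with mutated control), `kmers` (k-mer table, clusters, MEME export),
#' `coreg` (eight-way co-regulation calls), `congruence` (tissue-congruence
#' calls) and `overlap` (gene-set hypergeometric test). Each stage writes
#' its artifacts plus a `manifest.json` (seed, package version, input
#' checksums) under `config$out_dir/<stage>/`; dependent stages fail with an
#' actionable error naming the missing artifact and its producer.
#'
#' @param stage Stage name (see above).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the stage's main in-memory results.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  t0 <- Sys.time()
  out <- switch(stage,
    simulate = stage_simulate(config),
    classify = stage_classify(config),
    maps = stage_maps(config),
    cooccur = stage_cooccur(config),
    kmers = stage_kmers(config),
    coreg = stage_coreg(config),
    congruence = stage_congruence(config),
    overlap = stage_overlap(config)
  )
  message(sprintf("[splicemaps] stage '%s' done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}

stage_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  res <- simulate_dataset(config$sim, d, config$layout)
  write_manifest(d, "simulate", config)
  res
}

stage_classify <- function(config) {
  d <- stage_dir(config, "classify")
  events_path <- require_artifact(
    file.path(config$out_dir, "simulate", "events.tsv"), "simulate"
  )
  events <- read_events(events_path)
  tested <- differential_test(events)
  sets <- classify_events(tested, config$thresholds, seed = config$seed + 10L)
  write_events(tested, file.path(d, "events_tested.tsv"))
  write_json(
    list(activated = sets$activated, repressed = sets$repressed,
         reference = sets$reference, seed = sets$seed, n_pool = sets$n_pool),
    file.path(d, "event_sets.json")
  )
  write_manifest(d, "classify", config, events_path)
  list(events = tested, sets = sets)
}

stage_maps <- function(config) {
  d <- stage_dir(config, "maps")
  sets <- read_sets(config)
  out <- list()
  for (set_name in c("activated", "repressed")) {
    test_ids <- sets[[set_name]]
    if (length(test_ids) == 0) next
    regions <- pipeline_regions(config, c(test_ids, sets$reference))
    m <- rna_map(regions, test_ids, sets$reference, config$motif_primary,
                 config$layout, n_perm = config$n_perm, alpha = config$alpha,
                 seed = config$seed + 20L)
    write_profile(m, file.path(d, paste0("map_", set_name, ".tsv")))
    out[[set_name]] <- m
  }
  write_manifest(d, "maps", config)
  out
}

stage_cooccur <- function(config) {
  d <- stage_dir(config, "cooccur")
  sets <- read_sets(config)
  regions <- pipeline_regions(config, c(sets$activated, sets$reference))
  cm <- cooccurrence_map(regions, sets$activated, sets$reference,
                         config$motif_primary, config$motif_secondary,
                         config$layout, link_max_gap = config$link_max_gap,
                         n_perm = config$n_perm, alpha = config$alpha,
                         seed = config$seed + 30L)
  write_profile(cm, file.path(d, "cooccurrence.tsv"))
  write_manifest(d, "cooccur", config)
  cm
}

stage_kmers <- function(config) {
  d <- stage_dir(config, "kmers")
  sets <- read_sets(config)
  regions_t <- pipeline_regions(config, sets$activated)
  regions_r <- pipeline_regions(config, sets$reference)
  kt <- kmer_table(regions_t, regions_r, k = config$kmer_k,
                   segments = config$kmer_segments,
                   n_perm = config$n_perm, seed = config$seed + 40L)
  readr::write_tsv(tidy(kt), file.path(d, "kmer_table.tsv"),
                   progress = FALSE)
  if (any(kt$table$significant)) {
    cl <- cluster_kmers(kt)
    write_json(
      map(unclass(cl), function(x) {
        list(seed = x$seed, consensus = x$consensus, members = x$members,
             pfm = x$pfm)
      }),
      file.path(d, "clusters.json"), dataframe = "columns", digits = NA
    )
    write_meme(cl, file.path(d, "clusters.meme"))
  } else {
    cl <- NULL
  }
  write_manifest(d, "kmers", config)
  list(table = kt, clusters = cl)
}

stage_coreg <- function(config) {
  d <- stage_dir(config, "coreg")
  path <- require_artifact(
    file.path(config$out_dir, "simulate", "contrast_pair.tsv"), "simulate"
  )
  contrasts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  calls <- classify_coregulation(contrasts, config$thresholds)
  readr::write_tsv(calls, file.path(d, "coregulation_calls.tsv"),
                   progress = FALSE)
  write_manifest(d, "coreg", config, path)
  calls
}

stage_congruence <- function(config) {
  d <- stage_dir(config, "congruence")
  path <- require_artifact(
    file.path(config$out_dir, "simulate", "congruence_cohort.tsv"), "simulate"
  )
  cohort <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  calls <- classify_congruence(cohort, config$thresholds)
  readr::write_tsv(calls, file.path(d, "congruence_calls.tsv"),
                   progress = FALSE)
  write_manifest(d, "congruence", config, path)
  calls
}

stage_overlap <- function(config) {
  d <- stage_dir(config, "overlap")
  sim_dir <- file.path(config$out_dir, "simulate")
  universe <- read_gene_list(require_artifact(
    file.path(sim_dir, "genes_universe.txt"), "simulate"))
  set_a <- read_gene_list(require_artifact(
    file.path(sim_dir, "genes_set_a.txt"), "simulate"))
  set_b <- read_gene_list(require_artifact(
    file.path(sim_dir, "genes_set_b.txt"), "simulate"))
  res <- gene_set_overlap(set_a, set_b, universe)
  write_json(as.list(select(res, -"overlap_genes")),
             file.path(d, "overlap.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(d, "overlap", config)
  res
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order. Rerunning with the same
#' configuration and seed reproduces every numerical output.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run, in order (default: all).
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  res <- list()
  for (s in stages) res[[s]] <- run_stage(s, config)
  invisible(res)
}
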