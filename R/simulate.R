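# Synthetic-data generator: cassette-exon events with planted dPSI effects,
# genomes with planted motif occurrences, gene sets with planted overlap,
# and contrast cohorts with known co-regulation / congruence labels. All
# outputs are deterministic given the configured seed and carry truth labels
# so every pipeline stage can be validated end to end.

#' Motif plant specification
#'
#' Describes where and how often the genome simulator writes motif instances:
#' into which map segment, at what transcript-sense offsets, in what fraction
#' of the test-group events versus all other events. Optionally a second
#' motif is written `pair_gap` nt downstream of the first, to plant linked
#' co-occurring pairs.
#'
#' @param motif A [motif_spec()] to plant.
#' @param segment Segment label (see [layout_segments()]).
#' @param positions Length-2 integer vector: admissible 0-based offset range
#'   for the instance start within the segment.
#' @param fraction_test Fraction of test-group events receiving a plant.
#' @param fraction_ref Fraction of the remaining events receiving a plant.
#' @param group Which truth group is the test group: `"activated"`,
#'   `"repressed"` or `"regulated"`.
#' @param n_copies Instances planted per selected event (default 1).
#' @param pair_motif Optional second [motif_spec()] planted `pair_gap` nt
#'   after each instance.
#' @param pair_gap Spacer between paired instances in nt (default 10).
#'
#' @return An object of class `"plant_spec"`.
#' @export
plant_spec <- function(motif, segment = "intron_down_5p",
                       positions = c(20L, 50L), fraction_test = 0.9,
                       fraction_ref = 0.05,
                       group = c("activated", "repressed", "regulated"),
                       n_copies = 1L, pair_motif = NULL, pair_gap = 10L) {
  group <- match.arg(group)
  if (!segment %in% SEGMENT_LEVELS) abort("Unknown segment label.")
  if (length(positions) != 2 || positions[1] > positions[2] ||
      positions[1] < 0) {
    abort("`positions` must be an ordered non-negative range.")
  }
  if (fraction_test < 0 || fraction_test > 1 ||
      fraction_ref < 0 || fraction_ref > 1) {
    abort("Plant fractions must lie in [0, 1].")
  }
  structure(
    list(motif = motif, segment = segment, positions = as.integer(positions),
         fraction_test = fraction_test, fraction_ref = fraction_ref,
         group = group, n_copies = as.integer(n_copies),
         pair_motif = pair_motif, pair_gap = as.integer(pair_gap)),
    class = "plant_spec"
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the statistical structure the downstream analyses assume: a
#' minority of events with substantial planted \eqn{\Delta}PSI effects in
#' both directions, replicate PSIs with beta-distributed noise
#' (concentration 280, i.e. a PSI standard deviation of about 0.03 at
#' PSI = 0.5), junction counts drawn binomially at Poisson read depth so that
#' [psi_from_counts()] recovers the PSIs, and a motif planted at controlled
#' positions downstream of activated exons far more often than elsewhere.
#'
#' @param n_events Number of cassette-exon events.
#' @param n_replicates Replicates per condition.
#' @param psi_noise_concentration Beta-distribution precision of replicate
#'   PSIs around the event mean.
#' @param planted_effects List of `list(fraction =, delta_psi =)` entries;
#'   fractions of events receiving each effect (remaining events are null).
#' @param motif_plants List of [plant_spec()]s.
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param congruent_fraction Fraction of congruent events in simulated
#'   congruence cohorts (default 0.75).
#' @param read_depth Mean junction read depth per replicate (Poisson).
#' @param inc_form_len,skip_form_len Effective form lengths written to the
#'   event table (defaults 2 and 1: two inclusion junctions versus one
#'   skipping junction).
#' @param cassette_len,intron_len,const_exon_len Length ranges (nt) for the
#'   simulated features.
#' @param n_chrom Number of chromosomes events are spread over.
#' @param spacer Intergenic spacer between simulated loci (nt).
#' @param seed Mandatory integer seed.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_events = 1000L, n_replicates = 4L,
                       psi_noise_concentration = 280,
                       planted_effects = list(
                         list(fraction = 0.10, delta_psi = 0.40),
                         list(fraction = 0.15, delta_psi = -0.40)
                       ),
                       motif_plants = list(plant_spec(motif_rbpms())),
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       congruent_fraction = 0.75,
                       read_depth = 150L,
                       inc_form_len = 2L, skip_form_len = 1L,
                       cassette_len = c(80L, 400L),
                       intron_len = c(600L, 3000L),
                       const_exon_len = c(150L, 300L),
                       n_chrom = 4L, spacer = 300L, seed) {
  if (missing(seed)) abort("`seed` is mandatory for the simulator.")
  fr <- vapply(planted_effects, function(e) e$fraction, 0)
  de <- vapply(planted_effects, function(e) e$delta_psi, 0)
  if (any(fr < 0) || sum(fr) > 1) {
    abort("Planted-effect fractions must be non-negative and sum to at most 1.")
  }
  if (any(abs(de) > 0.96)) {
    abort("Infeasible planted delta_psi: event means must fit in [0.02, 0.98].")
  }
  if (abs(sum(base_composition) - 1) > 1e-8 || any(base_composition < 0)) {
    abort("`base_composition` must be 4 non-negative reals summing to 1.")
  }
  if (congruent_fraction < 0 || congruent_fraction > 1) {
    abort("`congruent_fraction` must lie in [0, 1].")
  }
  structure(
    list(n_events = as.integer(n_events),
         n_replicates = as.integer(n_replicates),
         psi_noise_concentration = psi_noise_concentration,
         planted_effects = planted_effects, motif_plants = motif_plants,
         base_composition = base_composition,
         congruent_fraction = congruent_fraction,
         read_depth = as.integer(read_depth),
         inc_form_len = as.integer(inc_form_len),
         skip_form_len = as.integer(skip_form_len),
         cassette_len = as.integer(cassette_len),
         intron_len = as.integer(intron_len),
         const_exon_len = as.integer(const_exon_len),
         n_chrom = as.integer(n_chrom), spacer = as.integer(spacer),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a cassette-exon event table with planted effects
#'
#' Draws event geometry (feature lengths and genomic placement over
#' `n_chrom` chromosomes, both strands), assigns planted \eqn{\Delta}PSI
#' effects to exact event counts (`round(fraction * n_events)` per effect),
#' draws replicate PSIs from beta distributions around the condition means
#' (clamped to \[0.02, 0.98\]), and draws junction counts binomially at
#' Poisson depth so PSIs are recoverable from counts. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `events` (tibble in the layout of [read_events()];
#'   `fdr` is `NA` until [differential_test()] is run) and `truth` (tibble
#'   with `event_id`, `effect_delta`, `regulated`, `direction`, `mu1`).
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_events
  with_seed(config$seed, {
    counts <- vapply(config$planted_effects,
                     function(e) as.integer(round(e$fraction * n)), 0L)
    deltas <- vapply(config$planted_effects, function(e) e$delta_psi, 0)
    effect <- rep(0, n)
    at <- 1L
    for (i in seq_along(counts)) {
      if (counts[i] > 0) effect[at:(at + counts[i] - 1L)] <- deltas[i]
      at <- at + counts[i]
    }
    mu1 <- numeric(n)
    pos <- effect > 0; neg <- effect < 0; nul <- effect == 0
    mu1[pos] <- runif(sum(pos), 0.05, pmin(0.95, 0.98 - effect[pos]))
    mu1[neg] <- runif(sum(neg), pmax(0.05, 0.02 - effect[neg]), 0.95)
    mu1[nul] <- runif(sum(nul), 0.05, 0.95)
    mu2 <- clamp(mu1 + effect, 0.02, 0.98)

    conc <- config$psi_noise_concentration
    nr <- config$n_replicates
    draw_psi <- function(mu) {
      map(mu, ~ rbeta(nr, .x * conc, (1 - .x) * conc))
    }
    psi1 <- draw_psi(mu1)
    psi2 <- draw_psi(mu2)
    draw_counts <- function(psis) {
      map(psis, function(p) {
        ntot <- rpois(length(p), config$read_depth)
        padj <- p * config$inc_form_len /
          (p * config$inc_form_len + (1 - p) * config$skip_form_len)
        inc <- rbinom(length(p), ntot, padj)
        list(inc = inc, skip = ntot - inc)
      })
    }
    c1 <- draw_counts(psi1)
    c2 <- draw_counts(psi2)

    # Geometry: locus blocks [exonA][intron1][cassette][intron2][exonB],
    # placed sequentially per chromosome with an intergenic spacer.
    r <- function(rng) sample(rng[1]:rng[2], n, replace = TRUE)
    len_ea <- r(config$const_exon_len)
    len_i1 <- r(config$intron_len)
    len_ca <- r(config$cassette_len)
    len_i2 <- r(config$intron_len)
    len_eb <- r(config$const_exon_len)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom_i <- rep_len(seq_len(config$n_chrom), n)
    locus_len <- len_ea + len_i1 + len_ca + len_i2 + len_eb + config$spacer
    start <- integer(n)
    for (ci in seq_len(config$n_chrom)) {
      idx <- which(chrom_i == ci)
      start[idx] <- config$spacer +
        cumsum(c(0L, head(locus_len[idx], -1L)))
    }
    ea_s <- start;               ea_e <- ea_s + len_ea
    ca_s <- ea_e + len_i1;       ca_e <- ca_s + len_ca
    eb_s <- ca_e + len_i2;       eb_e <- eb_s + len_eb
    plus <- strand == "+"

    events <- tibble(
      event_id = sprintf("EV%06d", seq_len(n)),
      gene_id = sprintf("GENE%05d", seq_len(n)),
      event_class = "SE",
      chrom = paste0("chr", chrom_i),
      strand = strand,
      cassette_start = ca_s, cassette_end = ca_e,
      upstream_start = ifelse(plus, ea_s, eb_s),
      upstream_end = ifelse(plus, ea_e, eb_e),
      downstream_start = ifelse(plus, eb_s, ea_s),
      downstream_end = ifelse(plus, eb_e, ea_e),
      inc_form_len = config$inc_form_len,
      skip_form_len = config$skip_form_len,
      inc1 = map(c1, "inc"), skip1 = map(c1, "skip"),
      inc2 = map(c2, "inc"), skip2 = map(c2, "skip"),
      psi1 = map(psi1, ~ round(.x, 6)),
      psi2 = map(psi2, ~ round(.x, 6)),
      delta_psi = round(map_dbl(seq_len(n),
                                ~ mean(round(psi2[[.x]], 6)) -
                                  mean(round(psi1[[.x]], 6))), 6),
      fdr = NA_real_
    )
    truth <- tibble(
      event_id = events$event_id,
      effect_delta = effect,
      regulated = effect != 0,
      direction = sign(effect),
      mu1 = mu1
    )
    validate_events(events)
    list(events = events, truth = truth)
  })
}

concrete_word <- function(word) {
  paste(vapply(strsplit(word, "")[[1]], function(l) {
    b <- IUPAC_BASES[[l]]
    if (length(b) == 1) b else sample(b, 1)
  }, ""), collapse = "")
}

background_seq <- function(len, composition) {
  if (len == 0) return("")
  paste(sample(names(composition), len, replace = TRUE,
               prob = composition), collapse = "")
}

motif_instance <- function(motif, composition) {
  if (motif$kind == "iupac_word") {
    concrete_word(motif$word)
  } else {
    gap <- resample(motif$gap_min:motif$gap_max, 1)
    paste0(concrete_word(motif$left), background_seq(gap, composition),
           concrete_word(motif$right))
  }
}

#' Simulate a genome with planted motif occurrences
#'
#' Builds background chromosome sequences i.i.d. from the configured base
#' composition and writes motif instances into the configured map segments
#' for the configured fractions of events, respecting strand (instances are
#' written in transcript sense and reverse-complemented into the plus-strand
#' genome for minus-strand events). Plant locations share the exact segment
#' geometry used by [extract_regions()], so extraction recovers every
#' planted instance byte for byte.
#'
#' @param sim Output of [simulate_events()].
#' @param config The same [sim_config()].
#' @param layout A [map_layout()] (defines segment geometry for planting).
#' @return A list with `genome` (`DNAStringSet`), `plants` (tibble:
#'   `event_id`, `motif`, `segment`, `offset`, `length`, `planted_test`) and
#'   `annotation` (BED-like tibble of simulated features).
#' @export
simulate_genome <- function(sim, config, layout = map_layout()) {
  events <- sim$events
  truth <- sim$truth
  with_seed(config$seed + 1L, {
    chrom_names <- unique(events$chrom)
    chrom_len <- vapply(chrom_names, function(cn) {
      idx <- events$chrom == cn
      max(events$upstream_end[idx], events$downstream_end[idx],
          events$cassette_end[idx]) + config$spacer
    }, 0)
    chars <- lapply(chrom_len, function(L) {
      sample(names(config$base_composition), L, replace = TRUE,
             prob = config$base_composition)
    })
    names(chars) <- chrom_names

    coords <- segment_coords(events, layout)
    coords_key <- paste(coords$event_id, coords$segment, sep = "\r")
    plants <- list()
    for (ps in config$motif_plants) {
      test_ids <- switch(ps$group,
        activated = truth$event_id[truth$direction > 0],
        repressed = truth$event_id[truth$direction < 0],
        regulated = truth$event_id[truth$regulated]
      )
      ref_ids <- setdiff(truth$event_id, test_ids)
      sel_test <- resample(test_ids, round(ps$fraction_test * length(test_ids)))
      sel_ref <- resample(ref_ids, round(ps$fraction_ref * length(ref_ids)))
      for (ev in c(sel_test, sel_ref)) {
        seg_row <- coords[coords_key == paste(ev, ps$segment, sep = "\r"), ]
        if (nrow(seg_row) == 0) {
          abort(sprintf("Event %s has no '%s' segment to plant into.",
                        ev, ps$segment))
        }
        for (copy in seq_len(ps$n_copies)) {
          inst_a <- motif_instance(ps$motif, config$base_composition)
          inst <- inst_a
          if (!is.null(ps$pair_motif)) {
            inst_b <- motif_instance(ps$pair_motif, config$base_composition)
            inst <- paste0(inst_a,
                           background_seq(ps$pair_gap,
                                          config$base_composition),
                           inst_b)
          }
          max_off <- min(ps$positions[2], seg_row$seg_len - nchar(inst))
          if (max_off < ps$positions[1]) {
            abort(sprintf(
              "Plant range [%d, %d] plus instance (%d nt) exceeds segment '%s' (%d nt) of event %s.",
              ps$positions[1], ps$positions[2], nchar(inst), ps$segment,
              seg_row$seg_len, ev))
          }
          off <- resample(ps$positions[1]:max_off, 1)
          # Transcript offset -> genomic interval within the segment slice.
          li <- nchar(inst)
          if (seg_row$strand == "+") {
            g0 <- seg_row$start + off
            written <- inst
          } else {
            g0 <- seg_row$end - off - li
            written <- revcomp(inst)
          }
          chars[[seg_row$chrom]][(g0 + 1L):(g0 + li)] <-
            strsplit(written, "")[[1]]
          rec <- tibble(event_id = ev, motif = ps$motif$name,
                        segment = ps$segment, offset = off,
                        length = nchar(inst_a),
                        planted_test = ev %in% sel_test)
          if (!is.null(ps$pair_motif)) {
            rec <- bind_rows(rec, tibble(
              event_id = ev, motif = ps$pair_motif$name,
              segment = ps$segment,
              offset = off + nchar(inst_a) + ps$pair_gap,
              length = li - nchar(inst_a) - ps$pair_gap,
              planted_test = ev %in% sel_test))
          }
          plants[[length(plants) + 1L]] <- rec
        }
      }
    }
    genome <- DNAStringSet(vapply(chars, paste, "", collapse = ""))
    names(genome) <- chrom_names
    plants <- if (length(plants) > 0) {
      bind_rows(plants)
    } else {
      tibble(event_id = character(0), motif = character(0),
             segment = character(0), offset = integer(0),
             length = integer(0), planted_test = logical(0))
    }
    annotation <- tibble(
      chrom = rep(events$chrom, 3),
      start = c(events$upstream_start, events$cassette_start,
                events$downstream_start),
      end = c(events$upstream_end, events$cassette_end,
              events$downstream_end),
      name = paste0(rep(events$event_id, 3), "|",
                    rep(c("upstream_exon", "cassette", "downstream_exon"),
                        each = nrow(events))),
      score = 0L,
      strand = rep(events$strand, 3)
    )
    list(genome = genome, plants = plants, annotation = annotation)
  })
}

#' Simulate gene sets with a planted overlap
#'
#' Emits a gene universe and two subsets sharing exactly `n_overlap`
#' members, together with the hypergeometric truth for the planted overlap.
#'
#' @param n_universe Universe size.
#' @param n_a,n_b Sizes of the two sets.
#' @param n_overlap Planted overlap size.
#' @param seed Integer seed.
#' @return A list with `universe`, `set_a`, `set_b` (character vectors) and
#'   `truth` (one-row tibble from [hypergeom_upper()]).
#' @export
simulate_gene_sets <- function(n_universe = 20000L, n_a = 144L, n_b = 703L,
                               n_overlap = 21L, seed = 1L) {
  if (n_overlap > min(n_a, n_b)) {
    abort("`n_overlap` cannot exceed the smaller set size.")
  }
  if (max(n_a, n_b) > n_universe) {
    abort("Set sizes cannot exceed the universe size.")
  }
  with_seed(seed, {
    universe <- sprintf("G%06d", seq_len(n_universe))
    set_b <- sample(universe, n_b)
    common <- sample(set_b, n_overlap)
    set_a <- c(common, sample(setdiff(universe, set_b), n_a - n_overlap))
    set_a <- sample(set_a)  # shuffle so the overlap is not positional
    list(universe = universe, set_a = set_a, set_b = set_b,
         truth = hypergeom_upper(n_universe, n_b, n_a, n_overlap))
  })
}

#' Simulate a two-perturbation contrast cohort with known categories
#'
#' Emits per-event summary statistics for a factor over-expression contrast
#' and a co-factor knockdown contrast with category labels planted by
#' construction: significant contrasts receive \eqn{|\Delta PSI|} in
#' \[0.2, 0.5\] and FDR below 0.01; non-significant contrasts receive
#' \eqn{|\Delta PSI|} below 0.05 and FDR above 0.2. Category counts are
#' exact (`round(prob * n)`), with the remainder uncalled. The default
#' category mix emulates a factor regulating roughly five times as many
#' events as its co-factor, with most shared events co-ordinately regulated.
#'
#' @param n_events Cohort size.
#' @param category_probs Named numeric vector of probabilities for
#'   categories `1`-`8` (remainder is uncalled).
#' @param seed Integer seed.
#' @return A list with `contrasts` (tibble ready for
#'   [classify_coregulation()]) and `truth` (tibble `event_id`,
#'   `category`).
#' @export
simulate_contrast_pair <- function(n_events = 1000L,
                                   category_probs = c(
                                     `1` = 0.035, `2` = 0.031,
                                     `3` = 0.012, `4` = 0.012,
                                     `5` = 0.270, `6` = 0.280,
                                     `7` = 0.023, `8` = 0.022
                                   ),
                                   seed = 1L) {
  if (sum(category_probs) > 1) abort("Category probabilities sum above 1.")
  with_seed(seed, {
    counts <- round(category_probs * n_events)
    category <- rep(NA_integer_, n_events)
    at <- 1L
    for (i in seq_along(counts)) {
      if (counts[i] > 0) {
        category[at:(at + counts[i] - 1L)] <- as.integer(names(counts)[i])
      }
      at <- at + counts[i]
    }
    category <- sample(category)  # random order, counts exact
    sig_mag <- function(m) runif(m, 0.2, 0.5)
    sig_fdr <- function(m) runif(m, 1e-8, 0.01)
    ns_mag <- function(m) runif(m, 0, 0.05) * sample(c(-1, 1), m, TRUE)
    ns_fdr <- function(m) runif(m, 0.2, 1)
    n <- n_events
    dpsi_oe <- ns_mag(n); fdr_oe <- ns_fdr(n)
    dpsi_kd <- ns_mag(n); fdr_kd <- ns_fdr(n)
    oe_sig <- which(category %in% c(1L, 2L, 3L, 4L, 5L, 6L))
    kd_sig <- which(category %in% c(1L, 2L, 3L, 4L, 7L, 8L))
    oe_pos <- category %in% c(1L, 3L, 5L)
    # effect_kd = -dpsi_kd positive (co-factor promotes inclusion) for 1, 4, 7
    kd_eff_pos <- category %in% c(1L, 4L, 7L)
    dpsi_oe[oe_sig] <- sig_mag(length(oe_sig)) *
      ifelse(oe_pos[oe_sig], 1, -1)
    fdr_oe[oe_sig] <- sig_fdr(length(oe_sig))
    dpsi_kd[kd_sig] <- sig_mag(length(kd_sig)) *
      ifelse(kd_eff_pos[kd_sig], -1, 1)
    fdr_kd[kd_sig] <- sig_fdr(length(kd_sig))
    contrasts <- tibble(
      event_id = sprintf("CP%06d", seq_len(n)),
      dpsi_oe = dpsi_oe, fdr_oe = fdr_oe,
      dpsi_kd = dpsi_kd, fdr_kd = fdr_kd
    )
    list(contrasts = contrasts,
         truth = tibble(event_id = contrasts$event_id, category = category))
  })
}

#' Simulate a congruence cohort with an exact planted congruent fraction
#'
#' Emits events significant both in the factor over-expression contrast and
#' in the tissue-versus-cell contrast, with exactly
#' `round(congruent_fraction * n_events)` congruent events (factor pushes
#' PSI in the tissue direction). Congruent events split into activated and
#' repressed by `activated_fraction`; discordant events split evenly.
#'
#' @param n_events Cohort size.
#' @param congruent_fraction Planted fraction of congruent events.
#' @param activated_fraction Fraction of congruent events that are
#'   activated (default 0.76, the remainder repressed).
#' @param seed Integer seed.
#' @return A list with `events` (tibble ready for [classify_congruence()])
#'   and `truth` (tibble `event_id`, `group`).
#' @export
simulate_congruence_cohort <- function(n_events = 234L,
                                       congruent_fraction = 0.75,
                                       activated_fraction = 0.76,
                                       seed = 1L) {
  with_seed(seed, {
    n <- n_events
    n_con <- as.integer(round(congruent_fraction * n))
    n_act <- as.integer(round(activated_fraction * n_con))
    n_dis <- n - n_con
    group <- c(rep("congruent_activated", n_act),
               rep("congruent_repressed", n_con - n_act),
               rep("discordant_oe_up", ceiling(n_dis / 2)),
               rep("discordant_oe_down", floor(n_dis / 2)))
    group <- sample(group)
    oe_pos <- group %in% c("congruent_activated", "discordant_oe_up")
    tis_pos <- group %in% c("congruent_activated", "discordant_oe_down")
    dpsi_oe <- runif(n, 0.2, 0.5) * ifelse(oe_pos, 1, -1)
    td <- runif(n, 0.2, 0.5) * ifelse(tis_pos, 1, -1)
    psi_cell <- runif(n, pmax(0.02, -td + 0.02), pmin(0.98, 0.98 - td))
    events <- tibble(
      event_id = sprintf("CG%06d", seq_len(n)),
      dpsi_oe = dpsi_oe,
      fdr_oe = runif(n, 1e-8, 0.01),
      psi_cell = psi_cell,
      psi_tissue = psi_cell + td,
      tissue_fdr = runif(n, 1e-8, 0.01)
    )
    list(events = events,
         truth = tibble(event_id = events$event_id, group = group))
  })
}

#' Simulate and write a complete synthetic dataset
#'
#' Runs [simulate_events()], [simulate_genome()], [simulate_gene_sets()],
#' [simulate_contrast_pair()] and [simulate_congruence_cohort()] with seeds
#' derived from `config$seed` and writes every artifact as plain text:
#' the rMATS-dialect event table, genome FASTA, BED-like annotation,
#' gene-list files, the contrast cohorts, and a JSON truth file. Outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param layout A [map_layout()] used for motif planting.
#' @return Invisibly, a list of the in-memory objects plus `paths`.
#' @export
simulate_dataset <- function(config, dir, layout = map_layout()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_events(config)
  gen <- simulate_genome(sim, config, layout)
  sets <- simulate_gene_sets(seed = config$seed + 2L)
  pair <- simulate_contrast_pair(n_events = config$n_events,
                                 seed = config$seed + 3L)
  cong <- simulate_congruence_cohort(
    congruent_fraction = config$congruent_fraction,
    seed = config$seed + 4L
  )
  paths <- list(
    events = file.path(dir, "events.tsv"),
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    contrast_pair = file.path(dir, "contrast_pair.tsv"),
    congruence = file.path(dir, "congruence_cohort.tsv"),
    universe = file.path(dir, "genes_universe.txt"),
    set_a = file.path(dir, "genes_set_a.txt"),
    set_b = file.path(dir, "genes_set_b.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_events(sim$events, paths$events)
  writeXStringSet(gen$genome, paths$genome)
  readr::write_tsv(gen$annotation, paths$annotation, col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(pair$contrasts, paths$contrast_pair, progress = FALSE)
  readr::write_tsv(cong$events, paths$congruence, progress = FALSE)
  writeLines(sets$universe, paths$universe)
  writeLines(sets$set_a, paths$set_a)
  writeLines(sets$set_b, paths$set_b)
  truth <- list(
    seed = config$seed,
    events = sim$truth,
    plants = gen$plants,
    gene_set_overlap = sets$truth,
    coregulation = pair$truth,
    congruence = cong$truth
  )
  write_json(truth, paths$truth, dataframe = "columns", auto_unbox = TRUE,
             digits = NA)
  invisible(list(events = sim$events, truth = sim$truth, genome = gen$genome,
                 plants = gen$plants, gene_sets = sets, contrast_pair = pair,
                 congruence = cong, paths = paths, config = config))
}
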