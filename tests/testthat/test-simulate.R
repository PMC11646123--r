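# Synthetic-data generator: determinism, exactness of planted structure,
# strand handling, gene sets.

test_that("the generator is byte-deterministic given a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(n_events = 40, seed = 51)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted regulated fractions are exact by construction", {
  cfg <- sim_config(n_events = 1000, seed = 52,
                    planted_effects = list(
                      list(fraction = 0.2, delta_psi = 0.4),
                      list(fraction = 0.1, delta_psi = -0.3)),
                    motif_plants = list())
  sim <- simulate_events(cfg)
  expect_equal(sum(sim$truth$regulated), 300)
  expect_equal(sum(sim$truth$direction > 0), 200)
  expect_equal(sum(sim$truth$direction < 0), 100)
})

test_that("observed effect sizes track the configured delta", {
  cfg <- sim_config(n_events = 600, seed = 53,
                    planted_effects = list(
                      list(fraction = 0.3, delta_psi = 0.4)),
                    motif_plants = list())
  sim <- simulate_events(cfg)
  planted <- sim$truth$regulated
  obs <- sim$events$delta_psi[planted]
  # mean observed dPSI within 2 SE of the planted effect
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 0.4), 2 * se + 0.005)
  # null events centre on zero
  expect_lt(abs(mean(sim$events$delta_psi[!planted])), 0.01)
})

test_that("counts recover PSIs through psi_from_counts", {
  sim <- small_sim()
  ev <- sim$events
  for (i in c(1, 7, 20)) {
    rec <- psi_from_counts(ev$inc1[[i]], ev$skip1[[i]],
                           ev$inc_form_len[i], ev$skip_form_len[i])
    # binomial sampling noise at depth ~150
    expect_lt(max(abs(rec - ev$psi1[[i]])), 0.15)
  }
})

test_that("plants land in every selected test event at the right offsets", {
  cfg <- sim_config(
    n_events = 50, seed = 54,
    planted_effects = list(list(fraction = 0.4, delta_psi = 0.4)),
    motif_plants = list(plant_spec(motif_rbpms(), "intron_down_5p",
                                   c(20, 50), fraction_test = 1,
                                   fraction_ref = 0))
  )
  sim <- simulate_events(cfg)
  gen <- simulate_genome(sim, cfg)
  test_ids <- sim$truth$event_id[sim$truth$regulated]
  expect_setequal(unique(gen$plants$event_id), test_ids)
  regions <- extract_regions(sim$events, gen$genome)
  hits <- scan_regions(
    regions[regions$event_id %in% test_ids &
              regions$segment == "intron_down_5p", ],
    motif_rbpms()
  )
  # every test event has a dimer hit starting within the planted range
  for (ev in test_ids) {
    h <- hits[hits$event_id == ev, ]
    expect_true(any(h$start >= 20 & h$start <= 50), label = ev)
  }
})

test_that("minus-strand plants appear only after reverse-complement extraction", {
  cfg <- sim_config(
    n_events = 30, seed = 55,
    planted_effects = list(list(fraction = 1, delta_psi = 0.3)),
    motif_plants = list(plant_spec(
      motif_spec("marker", "iupac_word", word = "TTAACGGA"),
      "intron_down_5p", c(30, 30), fraction_test = 1, fraction_ref = 0
    ))
  )
  sim <- simulate_events(cfg)
  gen <- simulate_genome(sim, cfg)
  minus <- sim$events[sim$events$strand == "-", ]
  expect_gt(nrow(minus), 3)
  regions <- extract_regions(sim$events, gen$genome)
  for (ev in minus$event_id) {
    row <- regions[regions$event_id == ev &
                     regions$segment == "intron_down_5p", ]
    expect_equal(substr(row$seq, 31, 38), "TTAACGGA")
    # the raw plus-strand genome carries the reverse complement instead
    gslice <- substr(as.character(gen$genome[[row$chrom]]),
                     row$start + 1, row$end)
    expect_false(grepl("TTAACGGA", gslice) &&
                   !grepl("TCCGTTAA", gslice))
    expect_true(grepl("TCCGTTAA", gslice))
  }
})

test_that("background motif rates match the analytic expectation", {
  cfg <- sim_config(
    n_events = 150, seed = 56,
    planted_effects = list(list(fraction = 0.2, delta_psi = 0.4)),
    motif_plants = list()  # fraction 0: background only
  )
  sim <- simulate_events(cfg)
  gen <- simulate_genome(sim, cfg)
  regions <- extract_regions(sim$events, gen$genome)
  seg <- regions[regions$segment == "intron_down_5p", ]
  hits <- scan_motif(setNames(seg$seq, seg$event_id),
                     motif_rbfox("GCATG"))
  n_windows <- sum(nchar(seg$seq) - 4)
  p_true <- 0.25^5
  se <- sqrt(p_true / n_windows)
  expect_lt(abs(nrow(hits) / n_windows - p_true), 5 * se)
})

test_that("infeasible configurations error early", {
  expect_error(sim_config(seed = 1, planted_effects = list(
    list(fraction = 0.2, delta_psi = 0.99))), "Infeasible")
  expect_error(sim_config(seed = 1, planted_effects = list(
    list(fraction = 0.7, delta_psi = 0.3),
    list(fraction = 0.5, delta_psi = -0.3))), "at most 1")
  expect_error(sim_config(), "seed")
  cfg <- sim_config(
    n_events = 20, seed = 57,
    planted_effects = list(list(fraction = 0.5, delta_psi = 0.3)),
    motif_plants = list(plant_spec(motif_rbpms(), "intron_down_5p",
                                   c(240, 245), fraction_test = 1))
  )
  sim <- simulate_events(cfg)
  expect_error(simulate_genome(sim, cfg), "exceeds segment")
})

test_that("simulated gene sets carry the exact planted overlap", {
  sets <- simulate_gene_sets(n_universe = 2000, n_a = 80, n_b = 150,
                             n_overlap = 9, seed = 58)
  expect_length(intersect(sets$set_a, sets$set_b), 9)
  expect_length(sets$set_a, 80)
  expect_length(sets$set_b, 150)
  expect_true(all(c(sets$set_a, sets$set_b) %in% sets$universe))
  expect_equal(sets$truth$k, 9)
  # zero overlap is possible and yields p = 1
  s0 <- simulate_gene_sets(n_universe = 100, n_a = 5, n_b = 5,
                           n_overlap = 0, seed = 59)
  expect_length(intersect(s0$set_a, s0$set_b), 0)
  expect_equal(s0$truth$p_upper, 1)
  expect_error(simulate_gene_sets(n_universe = 100, n_a = 5, n_b = 5,
                                  n_overlap = 6, seed = 1), "exceed")
})

test_that("emitted files round-trip into truth-consistent objects", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_events = 60, seed = 60)
  res <- simulate_dataset(cfg, d)
  ev <- read_events(res$paths$events)
  expect_equal(ev$event_id, res$events$event_id)
  genome <- Biostrings::readDNAStringSet(res$paths$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  expect_setequal(names(genome), unique(ev$chrom))
  truth <- jsonlite::read_json(res$paths$truth, simplifyVector = TRUE)
  expect_equal(sum(truth$events$regulated), sum(res$truth$regulated))
  sets <- list(a = read_gene_list(res$paths$set_a),
               b = read_gene_list(res$paths$set_b),
               u = read_gene_list(res$paths$universe))
  ov <- gene_set_overlap(sets$a, sets$b, sets$u)
  expect_equal(ov$k, truth$gene_set_overlap$k)
})
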