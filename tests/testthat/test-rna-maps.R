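# Window profiles, permutation significance, linked co-occurrence.

# Regions fixture with fully controllable sequences: one full-length event
# per synthetic "sequence plan". Planting CAC dimers by hand.
plain_regions <- function(n, seed = 1, planted = NULL) {
  g_len <- 10000L
  evs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    fixture_event(sprintf("E%03d", i))
  }))
  g <- random_genome(c(chrT = g_len), seed = seed)
  regions <- extract_regions(evs, g)
  if (!is.null(planted)) {
    # overwrite a segment's sequence with a deterministic planted one
    idx <- regions$segment == planted$segment &
      regions$event_id %in% planted$event_ids
    regions$seq[idx] <- vapply(regions$seq[idx], function(s) {
      paste0(substr(s, 1, planted$at),
             planted$word,
             substr(s, planted$at + nchar(planted$word) + 1, nchar(s)))
    }, "")
  }
  regions
}

test_that("window_profile marks exactly the windows reaching a single hit", {
  ev <- fixture_event()
  g <- random_genome(c(chrT = 5000), seed = 21)
  regions <- extract_regions(ev, g)
  # neutralise all background hits, then plant one dimer at [10, 17) of the
  # downstream-intron 5' segment
  regions$seq <- vapply(regions$seq, function(s) strrep("G", nchar(s)), "")
  idx <- which(regions$segment == "intron_down_5p")
  regions$seq[idx] <- paste0(strrep("G", 10), "CACACAC",
                             strrep("G", 250 - 17))
  prof <- window_profile(regions, motif_rbpms())
  seg_prof <- prof[prof$segment == "intron_down_5p", ]
  covered <- seg_prof$offset[seg_prof$coverage == 1]
  # window half-width 15: offsets whose clipped window intersects [10, 17)
  expect_equal(covered, 0:31)
  expect_true(all(prof$coverage[prof$segment != "intron_down_5p"] == 0))
})

test_that("uniform half-coverage yields a flat 0.5 profile", {
  regions <- plain_regions(10, seed = 22)
  half <- sprintf("E%03d", 1:5)
  idx <- regions$event_id %in% half
  # motif everywhere for half the events
  len_idx <- nchar(regions$seq[idx])
  regions$seq[idx] <- substr(
    vapply(len_idx, function(L) strrep("CA", ceiling(L / 2) + 1), ""),
    1, len_idx
  )
  regions$seq[!idx] <- vapply(nchar(regions$seq[!idx]),
                              function(L) strrep("G", L), "")
  prof <- window_profile(regions, motif_rbpms())
  expect_true(all(prof$coverage == 0.5))
})

test_that("window_profile equals a naive per-event double loop", {
  sim <- small_sim()
  ids <- sim$truth$event_id[sim$truth$regulated][1:20]
  regions <- extract_regions(sim$events[sim$events$event_id %in% ids, ],
                             sim$genome)
  motif <- motif_rbpms()
  prof <- window_profile(regions, motif)
  lay <- map_layout()
  h <- (lay$window_len - 1) %/% 2
  # oracle: per event, per position, explicit window check
  num <- integer(nrow(prof)); den <- integer(nrow(prof))
  for (ev in ids) {
    rsub <- regions[regions$event_id == ev, ]
    for (r in seq_len(nrow(rsub))) {
      hits <- scan_motif(rsub$seq[r], motif)
      mask <- coverage_mask(nchar(rsub$seq[r]), hits)
      L <- rsub$seg_len[r]
      for (off in 0:(L - 1)) {
        p <- rsub$comp_start[r] + off
        den[p + 1] <- den[p + 1] + 1L
        w <- max(0, off - h):min(L - 1, off + h)
        if (any(mask[w + 1])) num[p + 1] <- num[p + 1] + 1L
      }
    }
  }
  oracle_cov <- ifelse(den > 0, num / den, NA_real_)
  expect_equal(prof$coverage, oracle_cov)
  expect_equal(prof$n_events, den)
})

test_that("rna_map validates its inputs", {
  sim <- small_sim()
  ids <- sim$events$event_id
  regions <- extract_regions(sim$events[1:30, ], sim$genome)
  expect_error(rna_map(regions, ids[1:5], ids[5:10], motif_rbpms()),
               "disjoint")
  expect_error(rna_map(regions, c(ids[1], ids[1]), ids[2:5], motif_rbpms()),
               "Duplicated")
  expect_error(rna_map(regions, character(0), ids[1:5], motif_rbpms()),
               "non-empty")
  expect_error(rna_map(regions, ids[1:5], ids[6:10], motif_rbpms(),
                       n_perm = 0), "n_perm")
})

test_that("permutation P-values honour the +1 correction and the direction guard", {
  sim <- small_sim()
  tested <- differential_test(sim$events)
  act <- sim$truth$event_id[sim$truth$direction > 0]
  rest <- setdiff(sim$events$event_id, act)[1:80]
  regions <- extract_regions(
    tested[tested$event_id %in% c(act, rest), ], sim$genome
  )
  m <- rna_map(regions, act, rest, motif_rbpms(), n_perm = 200, seed = 5)
  prof <- tidy(m)
  expect_true(all(prof$pvalue >= 1 / 201, na.rm = TRUE))
  expect_true(all(prof$pvalue <= 1, na.rm = TRUE))
  sig <- prof[which(prof$significant), ]
  expect_true(all(sig$coverage_test > sig$coverage_ref))
  # deterministic given seed
  m2 <- rna_map(regions, act, rest, motif_rbpms(), n_perm = 200, seed = 5)
  expect_identical(tidy(m), tidy(m2))
})

test_that("events without motif hits dilute coverage monotonically", {
  regions <- plain_regions(8, seed = 23)
  ids <- unique(regions$event_id)
  prof1 <- window_profile(regions[regions$event_id %in% ids[1:4], ],
                          motif_rbpms())
  # add four events with no hits at all
  extra <- regions[regions$event_id %in% ids[5:8], ]
  extra$seq <- vapply(nchar(extra$seq), function(L) strrep("G", L), "")
  prof2 <- window_profile(dplyr::bind_rows(
    regions[regions$event_id %in% ids[1:4], ], extra
  ), motif_rbpms())
  expect_true(all(prof2$coverage <= prof1$coverage + 1e-12))
})

test_that("linked_hits applies the interval-gap rule", {
  a <- tibble::tibble(start = 0, end = 7)
  expect_equal(linked_hits(a, tibble::tibble(start = 10, end = 15))$gap, 3)
  expect_equal(nrow(linked_hits(a, tibble::tibble(start = 33, end = 38))), 0)
  expect_equal(nrow(linked_hits(a, tibble::tibble(start = 32, end = 38))), 1)
  # overlapping intervals have gap 0
  expect_equal(linked_hits(a, tibble::tibble(start = 5, end = 9))$gap, 0)
  expect_equal(linked_hits(a, tibble::tibble(start = 10, end = 15))$anchor, 0)
})

test_that("linked pair counts match the all-pairs oracle", {
  withr::with_seed(24, {
    for (rep in 1:15) {
      na <- sample(0:6, 1); nb <- sample(0:6, 1)
      a <- tibble::tibble(start = sort(sample(0:150, na)),
                          end = integer(na))
      a$end <- a$start + sample(3:8, na, replace = TRUE)
      b <- tibble::tibble(start = sort(sample(0:150, nb)),
                          end = integer(nb))
      b$end <- b$start + sample(3:8, nb, replace = TRUE)
      got <- nrow(linked_hits(a, b, 25))
      want <- 0L
      for (i in seq_len(na)) {
        for (j in seq_len(nb)) {
          gap <- max(0, max(a$start[i] - b$end[j], b$start[j] - a$end[i]))
          if (gap <= 25) want <- want + 1L
        }
      }
      expect_equal(got, want)
    }
  })
})

test_that("self-co-occurrence reduces to the self-linked profile of A", {
  sim <- small_sim()
  act <- sim$truth$event_id[sim$truth$direction > 0]
  rest <- setdiff(sim$events$event_id, act)[1:60]
  regions <- extract_regions(
    sim$events[sim$events$event_id %in% c(act, rest), ], sim$genome
  )
  cm <- cooccurrence_map(regions, act, rest, motif_rbpms(), motif_rbpms(),
                         n_perm = 50, seed = 6, control = FALSE)
  # oracle: anchors of pairs of dimer hits within 25 nt, including self-pairs
  anchors <- splicemaps:::linked_anchor_hits(regions, motif_rbpms(),
                                            motif_rbpms(), 25L)
  expect_true(nrow(anchors) > 0)
  # every dimer hit is linked to itself (gap 0), so anchors contain all starts
  hits <- scan_regions(regions, motif_rbpms())
  key_h <- unique(paste(hits$event_id, hits$segment, hits$start))
  key_a <- paste(anchors$event_id, anchors$segment, anchors$start)
  expect_true(all(key_h %in% key_a))
  expect_s3_class(cm, "cooccurrence_map")
})

test_that("co-occurrence enrichment appears only with the true partner", {
  cfg <- sim_config(
    n_events = 220, seed = 777,
    planted_effects = list(list(fraction = 0.27, delta_psi = 0.4)),
    motif_plants = list(plant_spec(motif_rbpms(), "intron_down_5p",
                                   c(20, 50), fraction_test = 1,
                                   fraction_ref = 0,
                                   pair_motif = motif_rbfox(),
                                   pair_gap = 10))
  )
  sim <- simulate_events(cfg)
  gen <- simulate_genome(sim, cfg)
  act <- sim$truth$event_id[sim$truth$regulated]
  ref <- setdiff(sim$truth$event_id, act)
  regions <- extract_regions(sim$events, gen$genome)
  cm <- cooccurrence_map(regions, act, ref, motif_rbpms(), motif_rbfox(),
                         n_perm = 300, seed = 7)
  sig_true <- cm$profile[which(cm$profile$significant), ]
  expect_gt(sum(sig_true$segment == "intron_down_5p"), 10)
  # mutated control: no stretch beyond chance anywhere
  expect_lt(mean(cm$control_profile$significant, na.rm = TRUE), 0.07)
})
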