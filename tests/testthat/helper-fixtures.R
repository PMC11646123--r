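# Shared fixtures: tiny hand-built events, genomes and rMATS-dialect tables,
# plus independent brute-force oracles used across test files.

# One cassette-exon event with fully specified geometry on a single
# chromosome. Coordinates are 0-based half-open; transcript-upstream exon
# first in transcript sense.
fixture_event <- function(event_id = "EV1", chrom = "chrT", strand = "+",
                          up = c(100L, 300L), cas = c(1000L, 1400L),
                          down = c(2200L, 2500L)) {
  if (strand == "-") {
    # transcript-upstream exon lies at higher genomic coordinates
    tmp <- up
    up <- down
    down <- tmp
  }
  tibble::tibble(
    event_id = event_id, gene_id = paste0("G_", event_id),
    event_class = "SE", chrom = chrom, strand = strand,
    cassette_start = cas[1], cassette_end = cas[2],
    upstream_start = up[1], upstream_end = up[2],
    downstream_start = down[1], downstream_end = down[2],
    inc_form_len = 1L, skip_form_len = 1L,
    inc1 = list(c(30L, 28L)), skip1 = list(c(10L, 12L)),
    inc2 = list(c(35L, 33L)), skip2 = list(c(5L, 7L)),
    psi1 = list(c(0.75, 0.7)), psi2 = list(c(0.875, 0.825)),
    delta_psi = 0.125, fdr = 0.01
  )
}

random_genome <- function(chroms = c(chrT = 5000L), seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(chroms, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(chroms)
  g
}

random_dna <- function(n, len, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
  })
}

# Independent brute-force motif scanners (exhaustive double loops; no shared
# code with the package's scanner).
oracle_scan_dimer <- function(seq, left = "CAC", right = "CAC",
                              gap_min = 1, gap_max = 12) {
  n <- nchar(seq)
  nl <- nchar(left); nr <- nchar(right)
  ls <- integer(0); rs <- integer(0)
  for (i in seq_len(n - nl + 1L)) {
    if (substr(seq, i, i + nl - 1L) == left) ls <- c(ls, i - 1L)
  }
  for (i in seq_len(n - nr + 1L)) {
    if (substr(seq, i, i + nr - 1L) == right) rs <- c(rs, i - 1L)
  }
  out <- NULL
  for (a in ls) {
    for (b in rs) {
      gap <- b - (a + nl)
      if (gap >= gap_min && gap <= gap_max) {
        out <- rbind(out, c(a, b + nr))
      }
    }
  }
  if (is.null(out)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  tibble::tibble(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
}

oracle_scan_words <- function(seq, words) {
  w <- nchar(words[1])
  starts <- integer(0)
  for (i in seq_len(nchar(seq) - w + 1L)) {
    if (substr(seq, i, i + w - 1L) %in% words) starts <- c(starts, i - 1L)
  }
  tibble::tibble(start = starts, end = starts + w)
}

# Exact upper-tail hypergeometric by direct summation of binomial terms.
oracle_hyper_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Write an rMATS-dialect table from raw strings (to exercise the parser on
# files not produced by write_events).
fixture_rmats_text <- function(path, inc_levels = TRUE) {
  header <- c("ID", "GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
              "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
              "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
              "IncFormLen", "SkipFormLen")
  rows <- list(
    c("EV1", "G1", "chr1", "+", "1000", "1400", "100", "300", "2200", "2500",
      "30,28", "10,12", "35,33", "5,7", "1", "1"),
    c("EV2", "G2", "chr1", "-", "5000", "5200", "6000", "6300", "4000",
      "4400", "12,14", "12,10", "6,5", "18,19", "1", "1"),
    c("EV3", "G3", "chr2", "+", "800", "900", "100", "250", "1500", "1700",
      "0,0", "20,22", "1,2", "19,18", "1", "1")
  )
  if (inc_levels) {
    header <- c(header, "IncLevel1", "IncLevel2", "IncLevelDifference", "FDR")
    extra <- list(c("0.75,0.7", "0.875,0.825", "0.125", "0.01"),
                  c("0.5,0.583333", "0.25,0.208333", "-0.3125", "0.002"),
                  c("0,0", "0.05,0.1", "0.075", "0.9"))
    rows <- lapply(seq_along(rows), function(i) c(rows[[i]], extra[[i]]))
  }
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

# Small simulated dataset shared by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_events = 150, seed = 4242,
        planted_effects = list(list(fraction = 0.2, delta_psi = 0.4),
                               list(fraction = 0.1, delta_psi = -0.4)),
        motif_plants = list(plant_spec(motif_rbpms(), "intron_down_5p",
                                       c(20, 50), fraction_test = 1,
                                       fraction_ref = 0.05))
      )
      sim <- simulate_events(cfg)
      gen <- simulate_genome(sim, cfg)
      cache <<- list(config = cfg, events = sim$events, truth = sim$truth,
                     genome = gen$genome, plants = gen$plants)
    }
    cache
  }
})
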