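# k-mer enrichment, embedded-word scoring, clustering and consensus calls.

# Regions built directly from provided sequences (one segment per event).
seq_regions <- function(seqs, prefix = "E") {
  tibble::tibble(
    event_id = sprintf("%s%04d", prefix, seq_along(seqs)),
    segment = factor("intron_down_5p",
                     levels = splicemaps:::SEGMENT_LEVELS),
    chrom = "chrT", strand = "+",
    start = 0L, end = nchar(seqs),
    seg_len = nchar(seqs),
    comp_start = 905L, comp_end = 905L + nchar(seqs),
    seq = seqs
  )
}

test_that("enrichment scores are frequency ratios with pseudocounts", {
  # deterministic sequences: AAAAAAAA-rich test set vs uniform reference
  test_seqs <- rep(paste0(strrep("A", 20), "GCATGTTTTTTT"), 30)
  ref_seqs <- rep(paste0(strrep("A", 20), "TTTTTTTTTTTT"), 30)
  kt <- kmer_table(seq_regions(test_seqs, "T"), seq_regions(ref_seqs, "R"),
                   n_perm = 50, seed = 1)
  tab <- tidy(kt)
  a8 <- tab[tab$kmer == "AAAAAAAA", ]
  # identical A-runs in both sets: 13 windows x 30 seqs each
  expect_equal(a8$count_test, a8$count_ref)
  expect_equal(a8$enrichment_score, 1, tolerance = 1e-12)
  # frequencies sum to 1 per set before pseudocounts
  expect_equal(sum(tab$freq_test), 1, tolerance = 1e-12)
  expect_equal(sum(tab$freq_ref), 1, tolerance = 1e-12)
})

test_that("enrichment scores invert when the sets are swapped", {
  seqs_a <- random_dna(30, 120, seed = 31)
  seqs_b <- random_dna(30, 120, seed = 32)
  k1 <- kmer_table(seq_regions(seqs_a, "A"), seq_regions(seqs_b, "B"),
                   n_perm = 10, seed = 1)
  k2 <- kmer_table(seq_regions(seqs_b, "B"), seq_regions(seqs_a, "A"),
                   n_perm = 10, seed = 1)
  t1 <- dplyr::arrange(tidy(k1), kmer)
  t2 <- dplyr::arrange(tidy(k2), kmer)
  expect_equal(t1$kmer, t2$kmer)
  expect_equal(t1$enrichment_score, 1 / t2$enrichment_score,
               tolerance = 1e-12)
})

test_that("a planted word dominates the significant k-mers", {
  withr::with_seed(33, {
    bg <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                            collapse = "")
    test_seqs <- vapply(1:150, function(i) {
      s <- bg(300)
      at <- sample(1:280, 3)
      for (a in at) substr(s, a, a + 4) <- "GCATG"
      s
    }, "")
    ref_seqs <- vapply(1:150, function(i) bg(300), "")
  })
  kt <- kmer_table(seq_regions(test_seqs, "T"), seq_regions(ref_seqs, "R"),
                   n_perm = 500, seed = 2)
  top <- head(tidy(kt)[tidy(kt)$significant, ], 10)
  expect_gt(nrow(top), 0)
  expect_true(all(grepl("GCATG", top$kmer)))
})

test_that("embedded_word_score pools k-mers and matches direct counting", {
  withr::with_seed(34, {
    bg <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                            collapse = "")
    test_seqs <- vapply(1:50, function(i) {
      s <- bg(150)
      substr(s, 30, 34) <- "GCATG"
      substr(s, 90, 94) <- "GCATG"
      s
    }, "")
    ref_seqs <- vapply(1:50, function(i) bg(150), "")
  })
  kt <- kmer_table(seq_regions(test_seqs, "T"), seq_regions(ref_seqs, "R"),
                   n_perm = 300, seed = 3)
  sc <- embedded_word_score(kt, "GCATG")
  expect_lt(sc$pvalue, 0.01)
  # direct-count oracle on the raw sequences (interior occurrences are
  # covered by 4 of the k - 4 = 4 possible 8-mer windows each)
  count5 <- function(seqs) {
    sum(vapply(seqs, function(s) {
      length(gregexpr("(?=GCATG)", s, perl = TRUE)[[1]]) *
        (gregexpr("(?=GCATG)", s, perl = TRUE)[[1]][1] != -1)
    }, 0))
  }
  n_t <- count5(test_seqs); n_r <- count5(ref_seqs)
  direct_ratio <- (n_t + 0.5) / max(n_r + 0.5, 0.5)
  expect_equal(sc$enrichment_score, direct_ratio, tolerance = 0.35)
  # absent word: pseudocount path, flagged low support
  none <- embedded_word_score(kt, "GGGGGGGG")
  expect_true(none$low_support)
})

test_that("k-mers sharing a core cluster to its consensus", {
  tab <- tibble::tibble(
    kmer = c("AGCATGCA", "GGCATGCC", "CGCATGAT", "TGCATGGA"),
    enrichment_score = c(4, 3, 2.5, 2)
  )
  cl <- cluster_kmers(tab)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$consensus, "GCATG")
  expect_equal(cl[[1]]$seed, "AGCATGCA")
  expect_equal(nrow(cl[[1]]$members), 4)
})

test_that("distinct motif families separate into distinct clusters", {
  tab <- tibble::tibble(
    kmer = c("CACCACAC", "ACACCACA", "CCACCACC",
             "AGCATGCA", "GGCATGCC", "TGCATGGA"),
    enrichment_score = c(5, 4.5, 4, 3.5, 3, 2.5)
  )
  cl <- cluster_kmers(tab)
  expect_length(cl, 2)
  consensi <- vapply(cl, function(x) x$consensus, "")
  expect_equal(sum(grepl("GCATG", consensi)), 1)
  # the CAC-rich family clusters apart and its consensus is GCATG-free
  other <- consensi[!grepl("GCATG", consensi)]
  expect_false(grepl("GCATG", other))
  members <- lapply(cl, function(x) x$members$kmer)
  expect_setequal(members[[which(grepl("GCATG", consensi))]],
                  c("AGCATGCA", "GGCATGCC", "TGCATGGA"))
})

test_that("a single k-mer forms a singleton cluster", {
  tab <- tibble::tibble(kmer = "AGCATGCA", enrichment_score = 2)
  cl <- cluster_kmers(tab)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 1)
  expect_equal(nchar(cl[[1]]$consensus), 5)
  expect_error(cluster_kmers(tibble::tibble(kmer = character(0),
                                            enrichment_score = numeric(0))),
               "No significant")
})

test_that("clustering is deterministic and MEME export is well-formed", {
  tab <- tibble::tibble(
    kmer = c("AGCATGCA", "GGCATGCC", "CGCATGAT", "CACCACAC"),
    enrichment_score = c(4, 3, 2.5, 2)
  )
  c1 <- cluster_kmers(tab)
  c2 <- cluster_kmers(tab[sample(1:4), ])
  expect_equal(tidy(c1), tidy(c2))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(c1, path)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  expect_equal(sum(grepl("^MOTIF", lines)), length(c1))
  # probability rows sum to 1
  probs <- lines[grepl("^0\\.|^1\\.", lines)]
  sums <- vapply(strsplit(probs, " +"), function(x) sum(as.numeric(x)), 0)
  expect_true(all(abs(sums - 1) < 1e-4))
})

test_that("k larger than the shortest segment errors", {
  expect_error(
    kmer_table(seq_regions("ACGTACGT"), seq_regions("ACG"), k = 8,
               n_perm = 5, seed = 1),
    "shortest"
  )
})
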