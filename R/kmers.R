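# k-mer enrichment between regulated and reference region sets, clustering of
# significant k-mers, and consensus extraction.

# Per-event k-mer count matrix (sparse, events x observed k-mers) over the
# selected segments. Windows containing N are skipped (Biostrings counts only
# unambiguous windows). Processed in chunks to keep the dense 4^k count
# matrix small.
event_kmer_matrix <- function(regions, k, chunk = 64L) {
  events <- unique(regions$event_id)
  ev_idx <- match(regions$event_id, events)
  if (any(nchar(regions$seq) < k)) {
    abort(sprintf("k = %d exceeds the shortest selected segment (%d nt).",
                  k, min(nchar(regions$seq))))
  }
  trips <- list()
  kmers <- NULL
  for (off in seq(1L, nrow(regions), by = chunk)) {
    rows <- off:min(off + chunk - 1L, nrow(regions))
    counts <- oligonucleotideFrequency(DNAStringSet(regions$seq[rows]),
                                       width = k)
    if (is.null(kmers)) kmers <- colnames(counts)
    nz <- which(counts > 0, arr.ind = TRUE)
    trips[[length(trips) + 1L]] <- tibble(
      i = ev_idx[rows[nz[, 1]]],
      j = as.integer(nz[, 2]),
      x = counts[nz]
    )
  }
  tr <- bind_rows(trips)
  M <- sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                    dims = c(length(events), length(kmers)))
  observed <- which(Matrix::colSums(M) > 0)
  list(M = M[, observed, drop = FALSE], kmers = kmers[observed],
       events = events)
}

kmer_scores <- function(ct, cr, wt, wr, pseudocount) {
  ((ct + pseudocount) / wt) / ((cr + pseudocount) / wr)
}

#' k-mer enrichment between test and reference region sets
#'
#' Counts all overlapping k-nucleotide windows (windows containing `N` are
#' skipped) in the selected segments of the test and reference sets, and
#' scores each k-mer by the ratio of its per-window frequencies
#' (`freq_test / freq_ref`, with a pseudocount added to both counts).
#' Significance is assessed empirically by permuting event labels between
#' the two sets: `P = (1 + #\{null score >= observed\}) / (n_perm + 1)`.
#'
#' @param test_regions,ref_regions Regions tibbles for the two event sets
#'   (e.g. from [extract_regions()] subset to each set).
#' @param k Word length (default 8).
#' @param segments Optional character vector of segment labels to count
#'   (e.g. `"intron_down_5p"`); default uses every segment present.
#' @param n_perm Label permutations (default 1000).
#' @param seed Integer seed.
#' @param pseudocount Added to both counts in the ratio (default 0.5).
#' @param sig_level Significance threshold on the empirical P (default 0.01,
#'   strict `<`).
#'
#' @return An object of class `"kmer_table"`; `tidy()` returns the per-k-mer
#'   tibble (`kmer`, counts, frequencies, `enrichment_score`, `pvalue`,
#'   `significant`), sorted by decreasing enrichment score.
#' @export
kmer_table <- function(test_regions, ref_regions, k = 8L, segments = NULL,
                       n_perm = 1000L, seed = 1L, pseudocount = 0.5,
                       sig_level = 0.01) {
  if (!is.null(segments)) {
    test_regions <- test_regions[test_regions$segment %in% segments, ]
    ref_regions <- ref_regions[ref_regions$segment %in% segments, ]
  }
  if (nrow(test_regions) == 0 || nrow(ref_regions) == 0) {
    abort("No sequences selected for one of the sets.")
  }
  both <- bind_rows(mutate(test_regions, .set = "test"),
                    mutate(ref_regions, .set = "ref"))
  km <- event_kmer_matrix(both, k)
  set_of <- both$.set[match(km$events, both$event_id)]
  is_test <- set_of == "test"
  W <- Matrix::rowSums(km$M)            # valid windows per event
  wt <- sum(W[is_test]); wr <- sum(W[!is_test])
  ct <- Matrix::colSums(km$M[is_test, , drop = FALSE])
  cr <- Matrix::colSums(km$M[!is_test, , drop = FALSE])
  obs <- kmer_scores(ct, cr, wt, wr, pseudocount)

  n_events <- length(km$events)
  n_test <- sum(is_test)
  ctot <- ct + cr
  wtot <- wt + wr
  exceed <- numeric(length(obs))
  chunk <- 100L
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      draws <- vapply(seq_len(m), function(i) sample.int(n_events, n_test),
                      integer(n_test))
      S <- sparseMatrix(i = as.vector(draws),
                        j = rep(seq_len(m), each = n_test), x = 1,
                        dims = c(n_events, m))
      CT <- as.matrix(Matrix::crossprod(km$M, S))   # kmers x m
      WT <- as.vector(W %*% S)
      null_scores <- ((CT + pseudocount) / rep(WT, each = nrow(CT))) /
        ((ctot - CT + pseudocount) / rep(wtot - WT, each = nrow(CT)))
      exceed <- exceed + rowSums(null_scores >= obs)
      done <- done + m
    }
  })
  pval <- (1 + exceed) / (n_perm + 1)
  tab <- tibble(
    kmer = km$kmers,
    count_test = as.integer(ct), count_ref = as.integer(cr),
    freq_test = ct / wt, freq_ref = cr / wr,
    enrichment_score = as.numeric(obs),
    pvalue = pval,
    significant = pval < sig_level
  )
  tab <- arrange(tab, desc(.data$enrichment_score))
  structure(
    list(table = tab, M = km$M, kmers = km$kmers, events = km$events,
         is_test = is_test, W = W, k = as.integer(k),
         pseudocount = pseudocount, n_perm = as.integer(n_perm),
         seed = as.integer(seed), sig_level = sig_level,
         segments = segments),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf(
    "k-mer table (k = %d): %d observed k-mers, %d significant (P < %g) over %d permutations\n",
    x$k, nrow(x$table), sum(x$table$significant), x$sig_level, x$n_perm
  ))
  print(head(x$table, 5))
  invisible(x)
}

#' @rdname kmer_table
#' @param x A `"kmer_table"` object.
#' @param ... Unused.
#' @export
tidy.kmer_table <- function(x, ...) x$table

#' @rdname kmer_table
#' @export
glance.kmer_table <- function(x, ...) {
  tibble(
    k = x$k, n_kmers = nrow(x$table),
    n_significant = sum(x$table$significant),
    sig_fraction = mean(x$table$significant),
    top_kmer = x$table$kmer[1],
    top_score = x$table$enrichment_score[1]
  )
}

#' Aggregate enrichment of a word embedded in k-mers
#'
#' Pools counts over every k-mer containing `word` as a substring and applies
#' the same frequency-ratio and label-permutation machinery as
#' [kmer_table()]. This scores a short consensus (e.g. a 5-mer) against the
#' k-mer background without re-counting sequences.
#'
#' @param x A `"kmer_table"` object.
#' @param word Word of length at most `k`.
#' @param n_perm Permutations (defaults to the table's setting).
#' @param seed Integer seed.
#' @return A one-row tibble: `word`, pooled counts, `enrichment_score`,
#'   `pvalue`, `low_support` (TRUE when the word was absent from both sets).
#' @export
embedded_word_score <- function(x, word, n_perm = x$n_perm, seed = x$seed) {
  stopifnot(inherits(x, "kmer_table"))
  word <- check_dna(word, "word")
  if (nchar(word) > x$k) abort("`word` longer than the table's k.")
  sel <- which(str_detect(x$kmers, stringr::fixed(word)))
  u <- if (length(sel) > 0) {
    as.vector(Matrix::rowSums(x$M[, sel, drop = FALSE]))
  } else {
    numeric(length(x$events))
  }
  wt <- sum(x$W[x$is_test]); wr <- sum(x$W[!x$is_test])
  ct <- sum(u[x$is_test]); cr <- sum(u[!x$is_test])
  obs <- kmer_scores(ct, cr, wt, wr, x$pseudocount)
  n_events <- length(x$events)
  n_test <- sum(x$is_test)
  utot <- sum(u); w_all <- sum(x$W)
  null_scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n_events, n_test)
      kmer_scores(sum(u[idx]), utot - sum(u[idx]),
                  sum(x$W[idx]), w_all - sum(x$W[idx]), x$pseudocount)
    }, 0)
  })
  pval <- (1 + sum(null_scores >= obs)) / (n_perm + 1)
  tibble(word = word, count_test = ct, count_ref = cr,
         enrichment_score = obs, pvalue = pval,
         low_support = ct + cr == 0)
}

# Best gapless alignment of word b against word a: offset of b relative to a
# maximising the number of matching bases, requiring overlap >= overlap_min.
# Ties broken by larger overlap, then smaller offset.
best_offset <- function(a, b, overlap_min = 5L) {
  la <- nchar(a); lb <- nchar(b)
  best <- list(matches = -1L, overlap = 0L, offset = 0L)
  for (off in seq(-(lb - overlap_min), la - overlap_min)) {
    a_from <- max(1L, 1L + off); a_to <- min(la, lb + off)
    overlap <- a_to - a_from + 1L
    if (overlap < overlap_min) next
    sa <- substring(a, a_from, a_to)
    sb <- substring(b, a_from - off, a_to - off)
    matches <- sum(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]])
    better <- matches > best$matches ||
      (matches == best$matches && overlap > best$overlap) ||
      (matches == best$matches && overlap == best$overlap &&
         off < best$offset)
    if (better) best <- list(matches = matches, overlap = overlap,
                             offset = off)
  }
  best
}

column_iupac <- function(p) {
  keep <- names(p)[p >= 0.5 * max(p)]
  IUPAC_CODE[[paste(sort(keep), collapse = "")]]
}

column_ic <- function(p) {
  p <- p[p > 0]
  2 + sum(p * log2(p))
}

#' Cluster significant k-mers and extract consensus motifs
#'
#' Aligns k-mers pairwise (gapless, overlap of at least `overlap_min`
#' bases; distance `1 - matches/overlap` at the best offset), clusters them
#' by average-linkage hierarchical clustering cut at `cut_height`, aligns
#' each cluster to its seed (highest enrichment score, ties broken
#' lexicographically), and builds an enrichment-score-weighted position
#' frequency matrix. The consensus is the IUPAC rendering of the
#' `consensus_len`-column window with maximal summed information content.
#'
#' @param x A `"kmer_table"` object, or a tibble with `kmer` and
#'   `enrichment_score` columns (already filtered to significant k-mers).
#' @param overlap_min Minimum alignment overlap in bases (default 5).
#' @param cut_height Dendrogram cut height on the `1 - matches/overlap`
#'   distance (default 0.4).
#' @param consensus_len Consensus window length (default 5).
#'
#' @return An object of class `"motif_clusters"`: a list of clusters, each
#'   with `members` (kmer, offset, enrichment_score), `seed`, `pfm` (4 x L)
#'   and `consensus`. `tidy()` summarises one row per cluster, ordered by
#'   the seed's enrichment score.
#' @export
cluster_kmers <- function(x, overlap_min = 5L, cut_height = 0.4,
                          consensus_len = 5L) {
  tab <- if (inherits(x, "kmer_table")) {
    filter(x$table, .data$significant)
  } else {
    as_tibble(x)
  }
  if (nrow(tab) == 0) abort("No significant k-mers to cluster.")
  tab <- arrange(tab, desc(.data$enrichment_score), .data$kmer)
  kmers <- tab$kmer
  n <- length(kmers)
  if (n == 1) {
    membership <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        al <- best_offset(kmers[i], kmers[j], overlap_min)
        d[i, j] <- d[j, i] <- 1 - al$matches / al$overlap
      }
    }
    hc <- hclust(stats::as.dist(d), method = "average")
    membership <- cutree(hc, h = cut_height)
  }
  clusters <- map(sort(unique(membership)), function(cl) {
    idx <- which(membership == cl)
    sub <- tab[idx, ]
    # Seed: highest enrichment score, ties by lexicographic order (the table
    # is already sorted accordingly).
    seed <- sub$kmer[1]
    offsets <- vapply(sub$kmer, function(km) {
      best_offset(seed, km, overlap_min)$offset
    }, 0L)
    members <- tibble(kmer = sub$kmer, offset = unname(offsets),
                      enrichment_score = sub$enrichment_score)
    pfm <- build_pfm(members)
    cons <- consensus_window(pfm, consensus_len)
    list(members = members, seed = seed, pfm = pfm,
         consensus = cons$word, consensus_ic = cons$ic,
         consensus_start = cons$start)
  })
  ord <- order(vapply(clusters, function(cl) {
    -max(cl$members$enrichment_score)
  }, 0))
  structure(clusters[ord], class = "motif_clusters")
}

build_pfm <- function(members) {
  k <- nchar(members$kmer[1])
  lo <- min(members$offset)
  hi <- max(members$offset) + k - 1L
  L <- hi - lo + 1L
  pfm <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(members))) {
    bases <- strsplit(members$kmer[i], "")[[1]]
    cols <- (members$offset[i] - lo + 1L):(members$offset[i] - lo + k)
    w <- members$enrichment_score[i]
    for (j in seq_len(k)) {
      pfm[bases[j], cols[j]] <- pfm[bases[j], cols[j]] + w
    }
  }
  sweep(pfm, 2, pmax(colSums(pfm), .Machine$double.eps), "/")
}

consensus_window <- function(pfm, len = 5L) {
  L <- ncol(pfm)
  if (L < len) abort("PFM narrower than the consensus window.")
  ic <- apply(pfm, 2, column_ic)
  sums <- vapply(seq_len(L - len + 1L), function(s) sum(ic[s:(s + len - 1L)]),
                 0)
  s <- which.max(sums)
  word <- paste(vapply(s:(s + len - 1L), function(j) {
    column_iupac(pfm[, j])
  }, ""), collapse = "")
  list(word = word, ic = sums[s], start = s)
}

#' @export
print.motif_clusters <- function(x, ...) {
  cat(sprintf("%d motif cluster(s):\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  %d. consensus %s (seed %s, %d members)\n",
                i, x[[i]]$consensus, x[[i]]$seed, nrow(x[[i]]$members)))
  }
  invisible(x)
}

#' @rdname cluster_kmers
#' @param ... Unused.
#' @export
tidy.motif_clusters <- function(x, ...) {
  bind_rows(imap(unclass(x), function(cl, i) {
    tibble(cluster = i, consensus = cl$consensus, seed = cl$seed,
           n_members = nrow(cl$members),
           max_enrichment = max(cl$members$enrichment_score))
  }))
}

#' Write motif clusters in MEME minimal format
#'
#' @param clusters A `"motif_clusters"` object.
#' @param path Output path.
#' @param background Background base frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(clusters, path,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background["A"], background["C"],
                       background["G"], background["T"]), ""), con)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    writeLines(sprintf("MOTIF cluster%d_%s", i, cl$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(cl$pfm), nrow(cl$members)), con)
    for (j in seq_len(ncol(cl$pfm))) {
      writeLines(paste(sprintf("%.6f", cl$pfm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
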