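# Motif specifications and scanning: gapped dimers (paired short words with a
# bounded spacer) and literal/IUPAC words, plus single-nucleotide mutated
# controls.

#' Define a scannable motif
#'
#' Two kinds are supported: `"iupac_word"` (a literal word over the IUPAC
#' alphabet) and `"gapped_dimer"` (two words separated by a gap within
#' `[gap_min, gap_max]` nucleotides, modelling dimeric binding such as paired
#' CAC triplets). `N` in scanned sequences never matches.
#'
#' @param name Motif name.
#' @param kind `"iupac_word"` or `"gapped_dimer"`.
#' @param word IUPAC word (iupac_word only).
#' @param left,right Words of a gapped dimer.
#' @param gap_min,gap_max Allowed gap range in nt (gapped dimer only;
#'   `gap_min >= 1`).
#' @param control_of Optional name of the parent motif this is a mutated
#'   control for.
#'
#' @return An object of class `"motif_spec"`.
#' @export
#' @examples
#' motif_spec("rbpms", "gapped_dimer", left = "CAC", right = "CAC")
#' motif_spec("rbfox", "iupac_word", word = "GCAYG")
motif_spec <- function(name, kind = c("iupac_word", "gapped_dimer"),
                       word = NULL, left = "CAC", right = "CAC",
                       gap_min = 1L, gap_max = 12L, control_of = NULL) {
  kind <- match.arg(kind)
  if (kind == "iupac_word") {
    if (is.null(word) || nchar(word) == 0) abort("`word` must be non-empty.")
    word <- check_iupac_word(word)
    left <- right <- NULL
    gap_min <- gap_max <- NULL
  } else {
    if (nchar(left) == 0 || nchar(right) == 0) {
      abort("Dimer words must be non-empty.")
    }
    left <- check_iupac_word(left)
    right <- check_iupac_word(right)
    gap_min <- as.integer(gap_min)
    gap_max <- as.integer(gap_max)
    if (gap_min < 1L || gap_max < gap_min) {
      abort("Require gap_min >= 1 and gap_max >= gap_min.")
    }
    word <- NULL
  }
  structure(
    list(name = name, kind = kind, word = word, left = left, right = right,
         gap_min = gap_min, gap_max = gap_max, control_of = control_of),
    class = "motif_spec"
  )
}

check_iupac_word <- function(word) {
  word <- toupper(word)
  iupac_to_regex(word)  # validates the alphabet
  word
}

#' @export
print.motif_spec <- function(x, ...) {
  if (x$kind == "gapped_dimer") {
    cat(sprintf("Motif '%s': %s N(%d-%d) %s (gapped dimer)\n",
                x$name, x$left, x$gap_min, x$gap_max, x$right))
  } else {
    cat(sprintf("Motif '%s': %s (IUPAC word)\n", x$name, x$word))
  }
  if (!is.null(x$control_of)) {
    cat(sprintf("  mutated control of '%s'\n", x$control_of))
  }
  invisible(x)
}

#' The dimeric paired-CAC motif bound by RBPMS
#'
#' RBPMS binds RNA as a dimer at pairs of CAC triplets; the default motif is
#' two CAC words separated by 1-12 nt.
#'
#' @param gap_min,gap_max Allowed spacer range in nt.
#' @return A `"motif_spec"`.
#' @export
motif_rbpms <- function(gap_min = 1L, gap_max = 12L) {
  motif_spec("rbpms_cac_dimer", "gapped_dimer", left = "CAC", right = "CAC",
             gap_min = gap_min, gap_max = gap_max)
}

#' The RBFOX-family binding word
#'
#' The RBFOX word is given as `GCAYG` (`Y` = C or T), covering both GCACG and
#' GCATG DNA forms of the (U)GCAUG RNA element.
#'
#' @param word IUPAC word (default `"GCAYG"`).
#' @return A `"motif_spec"`.
#' @export
motif_rbfox <- function(word = "GCAYG") {
  motif_spec("rbfox_gcayg", "iupac_word", word = word)
}

# Overlapping occurrences of an IUPAC word: 0-based start positions.
word_starts <- function(seq, word) {
  m <- gregexpr(paste0("(?=", iupac_to_regex(word), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan sequences for a motif
#'
#' Returns every hit as a 0-based half-open interval on the scanned
#' (transcript-sense) sequence. For a gapped dimer, every (left, right) word
#' pair whose gap lies in `[gap_min, gap_max]` yields one hit spanning the
#' left word's start to the right word's end; overlapping hits are kept.
#' `N` never matches. Output is sorted by `start`, then `end`.
#'
#' @param seqs Character vector of DNA sequences (ACGTN). Names, if present,
#'   are used as `sequence_id`; otherwise the element index is used.
#' @param motif A [motif_spec()].
#'
#' @return A tibble with columns `sequence_id`, `start`, `end`, `motif`.
#' @export
#' @examples
#' scan_motif("CACACAC", motif_rbpms())        # one hit [0, 7)
#' scan_motif("AGCATGA", motif_rbfox())        # one hit [1, 6)
scan_motif <- function(seqs, motif) {
  seqs <- check_dna(seqs)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  hits <- scan_many(seqs, motif)
  tibble(sequence_id = ids[hits$seq_i], start = hits$start, end = hits$end,
         motif = rep(motif$name, length(hits$start)))
}

# Vectorised scanning core: plain integer vectors, one allocation at the end.
scan_many <- function(seqs, motif) {
  if (motif$kind == "iupac_word") {
    re <- paste0("(?=", iupac_to_regex(motif$word), ")")
    ms <- gregexpr(re, seqs, perl = TRUE)
    counts <- vapply(ms, function(m) if (m[1] == -1) 0L else length(m), 0L)
    starts <- unlist(ms, use.names = FALSE)
    starts <- starts[rep(counts > 0, times = pmax(counts, 1L))] - 1L
    return(list(seq_i = rep(seq_along(seqs), counts),
                start = as.integer(starts),
                end = as.integer(starts) + nchar(motif$word)))
  }
  re_l <- paste0("(?=", iupac_to_regex(motif$left), ")")
  same <- identical(motif$left, motif$right)
  ms_l <- gregexpr(re_l, seqs, perl = TRUE)
  ms_r <- if (same) {
    ms_l
  } else {
    gregexpr(paste0("(?=", iupac_to_regex(motif$right), ")"), seqs,
             perl = TRUE)
  }
  nl <- nchar(motif$left)
  nr <- nchar(motif$right)
  seq_i <- list(); s_out <- list(); e_out <- list()
  for (i in seq_along(seqs)) {
    if (ms_l[[i]][1] == -1 || ms_r[[i]][1] == -1) next
    ls <- as.integer(ms_l[[i]]) - 1L
    rs <- as.integer(ms_r[[i]]) - 1L
    # For each left occurrence, right starts within the admissible gap window.
    lo <- findInterval(ls + nl + motif$gap_min - 1L, rs) + 1L
    hi <- findInterval(ls + nl + motif$gap_max, rs)
    keep <- lo <= hi
    if (!any(keep)) next
    counts <- hi[keep] - lo[keep] + 1L
    k <- length(seq_i) + 1L
    seq_i[[k]] <- rep.int(i, sum(counts))
    s_out[[k]] <- rep(ls[keep], counts)
    e_out[[k]] <- rs[unlist(map2(lo[keep], hi[keep], seq.int),
                            use.names = FALSE)] + nr
  }
  list(seq_i = unlist(seq_i) %||% integer(0),
       start = unlist(s_out) %||% integer(0),
       end = unlist(e_out) %||% integer(0))
}

#' Scan extracted regions for a motif
#'
#' Applies [scan_motif()] to every segment sequence of a regions tibble,
#' keeping the event and segment identity of each hit. Coordinates are
#' 0-based half-open within the segment's transcript-sense sequence.
#'
#' @param regions Regions tibble from [extract_regions()].
#' @param motif A [motif_spec()].
#' @return A tibble with `event_id`, `segment`, `start`, `end`, `motif`.
#' @export
scan_regions <- function(regions, motif) {
  hits <- scan_motif(unname(regions$seq), motif)
  idx <- as.integer(hits$sequence_id)
  tibble(
    event_id = regions$event_id[idx],
    segment = regions$segment[idx],
    start = hits$start,
    end = hits$end,
    motif = hits$motif
  )
}

#' Base-level coverage mask of motif hits
#'
#' Marks each position of a sequence covered by the union of hit intervals.
#'
#' @param seq_len Sequence length.
#' @param hits Tibble (or data frame) with 0-based half-open `start`, `end`.
#' @return Logical vector of length `seq_len`.
#' @export
#' @examples
#' coverage_mask(10, tibble::tibble(start = c(2, 4), end = c(5, 8)))
coverage_mask <- function(seq_len, hits) {
  mask <- logical(seq_len)
  if (is.null(hits) || nrow(hits) == 0) return(mask)
  if (any(hits$start < 0 | hits$end > seq_len | hits$start >= hits$end)) {
    abort("Hits out of bounds for `seq_len`.")
  }
  for (i in seq_len(nrow(hits))) {
    mask[(hits$start[i] + 1L):hits$end[i]] <- TRUE
  }
  mask
}

#' Single-nucleotide mutated control motif
#'
#' Replaces one position of an IUPAC word motif with a concrete base,
#' producing a control motif whose `control_of` field names the parent. Used
#' to demonstrate specificity of motif enrichment: the control should show no
#' positional enrichment.
#'
#' @param motif An `"iupac_word"` [motif_spec()].
#' @param position 1-based position within the word.
#' @param base Replacement base (`A`, `C`, `G` or `T`); must not be matched
#'   by the original letter at that position.
#'
#' @return A `"motif_spec"` for the mutated word.
#' @export
#' @examples
#' mutate_control(motif_rbfox("GCATG"), 3, "G")  # GCGTG
#' mutate_control(motif_rbfox(), 4, "A")         # GCAAG, the default control
mutate_control <- function(motif, position, base) {
  if (motif$kind != "iupac_word") {
    abort("mutate_control applies to IUPAC word motifs.")
  }
  word <- motif$word
  position <- as.integer(position)
  if (position < 1L || position > nchar(word)) {
    abort("`position` outside the motif word.")
  }
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T")) {
    abort("`base` must be a concrete nucleotide (A, C, G or T).")
  }
  orig <- substr(word, position, position)
  if (base %in% IUPAC_BASES[[orig]]) {
    abort(sprintf("Base '%s' is already matched by the original letter '%s' at position %d.",
                  base, orig, position))
  }
  mutated <- word
  substr(mutated, position, position) <- base
  motif_spec(paste0(motif$name, "_mut", position, base), "iupac_word",
             word = mutated, control_of = motif$name)
}
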