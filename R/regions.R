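# Strand-aware extraction of RNA-map segments from a genome.

# Transcript-sense feature intervals (genomic, 0-based half-open) for the
# five features around each cassette exon. On the minus strand the
# transcript-upstream exon lies at higher genomic coordinates, so the
# flanking-intron intervals swap.
event_feature_intervals <- function(events) {
  plus <- events$strand == "+"
  tibble(
    event_id = rep(events$event_id, times = 5),
    feature = rep(c("exon_up", "intron_up", "cassette", "intron_down",
                    "exon_down"), each = nrow(events)),
    fstart = c(events$upstream_start,
               ifelse(plus, events$upstream_end, events$cassette_end),
               events$cassette_start,
               ifelse(plus, events$cassette_end, events$downstream_end),
               events$downstream_start),
    fend = c(events$upstream_end,
             ifelse(plus, events$cassette_start, events$upstream_start),
             events$cassette_end,
             ifelse(plus, events$downstream_start, events$cassette_start),
             events$downstream_end)
  )
}

# Genomic coordinates of every map segment for every event (no sequence).
# Shared by extract_regions() and the genome simulator's motif planting, so
# planted offsets and extracted sequences agree by construction.
segment_coords <- function(events, layout = map_layout()) {
  segs <- layout_segments(layout)
  feats <- event_feature_intervals(events)
  n <- nrow(events)
  plus <- events$strand == "+"
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    seg <- segs[k, ]
    fi <- feats[feats$feature == seg$feature, ]
    fi <- fi[match(events$event_id, fi$event_id), ]
    flen <- fi$fend - fi$fstart
    dual <- seg$feature %in% c("intron_up", "intron_down", "cassette")
    if (dual) {
      # Feature hosts both a 5' and a 3' segment: when shorter than twice the
      # requested length, split at the midpoint with no overlap (5' end gets
      # the floor half on odd lengths).
      l5 <- ifelse(flen >= 2L * seg$seg_len, seg$seg_len, flen %/% 2L)
      l <- if (seg$end == "5p") l5 else pmin(seg$seg_len, flen - l5)
    } else {
      l <- pmin(seg$seg_len, flen)
    }
    l <- pmax(0L, as.integer(l))
    at_feature_start <- (seg$end == "5p") == plus
    gstart <- ifelse(at_feature_start, fi$fstart, fi$fend - l)
    out[[k]] <- tibble(
      event_id = events$event_id,
      segment = seg$segment,
      chrom = events$chrom,
      strand = events$strand,
      start = as.integer(gstart),
      end = as.integer(gstart + l),
      seg_len = l,
      comp_start = as.integer(seg$comp_start +
                                (if (seg$end == "5p") 0L else seg$seg_len - l)),
      comp_end = NA_integer_
    )
  }
  res <- bind_rows(out)
  res$comp_end <- res$comp_start + res$seg_len
  res <- res[res$seg_len > 0L, ]
  res$segment <- factor(as.character(res$segment), levels = SEGMENT_LEVELS)
  res[order(match(res$event_id, events$event_id), res$comp_start), ]
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!inherits(genome, "DNAStringSet")) {
    abort("`genome` must be a DNAStringSet or a path to a FASTA file.")
  }
  genome
}

#' Extract RNA-map segment sequences around cassette exons
#'
#' Builds the composite coordinate system of eight segments per event
#' (constitutive-exon ends, both ends of each flanking intron, and both
#' cassette-exon ends) and extracts transcript-sense sequences from the
#' genome. Minus-strand segments are reverse-complemented; features shorter
#' than the requested segment length are truncated (split at the midpoint,
#' without overlap, when a feature hosts both a 5' and a 3' segment); bases
#' outside the chromosome are returned as `N`. Soft-masked lowercase bases
#' are uppercased and ambiguity codes other than `N` are mapped to `N` (with
#' a warning giving the count).
#'
#' @param events Events tibble (see [read_events()]).
#' @param genome A `DNAStringSet` (names = chromosome) or path to a FASTA
#'   file.
#' @param layout A [map_layout()].
#'
#' @return A regions tibble: one row per non-empty segment per event, with
#'   `event_id`, `segment`, `chrom`, `strand`, genomic `start`/`end` of the
#'   slice, transcript-sense `seq`, and its composite-axis interval
#'   `[comp_start, comp_end)`.
#' @export
extract_regions <- function(events, genome, layout = map_layout()) {
  genome <- load_genome(genome)
  coords <- segment_coords(events, layout)
  missing_chrom <- setdiff(unique(coords$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("Chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  chrom_str <- setNames(as.character(genome), names(genome))
  chrom_len <- setNames(nchar(chrom_str), names(genome))
  s_clip <- pmax(coords$start, 0L)
  e_clip <- pmin(coords$end, chrom_len[coords$chrom])
  raw <- substring(chrom_str[coords$chrom], s_clip + 1L, e_clip)
  raw[e_clip <= s_clip] <- ""
  left_pad <- pmax(0L, -coords$start)
  right_pad <- pmax(0L, coords$end - chrom_len[coords$chrom])
  seqs <- paste0(strrep("N", left_pad), raw, strrep("N", right_pad))
  seqs <- str_to_upper(seqs)
  n_ambig <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                        function(m) sum(m > 0), 0L))
  if (n_ambig > 0) {
    warn(sprintf("%d ambiguity-code base(s) mapped to N.", n_ambig))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  minus <- coords$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  coords$seq <- unname(seqs)
  attr(coords, "layout") <- layout
  coords
}

#' Export map segments as BED6
#'
#' Writes one BED record per extracted segment (`name` is
#' `event_id|segment`), for inspection in a genome browser.
#'
#' @param regions Regions tibble from [extract_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- tibble(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = paste0(regions$event_id, "|", regions$segment),
    score = 0L,
    strand = regions$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
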