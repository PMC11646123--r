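# Composite RNA-map coordinate system: eight ordered segments around a
# cassette exon, concatenated on a shared axis.

SEGMENT_LEVELS <- c(
  "exon_up_3p",      # upstream constitutive exon, 3' end
  "intron_up_5p",    # upstream intron, 5' end
  "intron_up_3p",    # upstream intron, 3' end
  "cassette_5p",     # cassette exon, 5' end
  "cassette_3p",     # cassette exon, 3' end
  "intron_down_5p",  # downstream intron, 5' end
  "intron_down_3p",  # downstream intron, 3' end
  "exon_down_5p"     # downstream constitutive exon, 5' end
)

#' RNA-map layout
#'
#' Geometry of the composite map axis: how many nucleotides are taken from
#' each feature end, and the sliding-window length used for coverage
#' profiles. Defaults follow common RNA-map practice for cassette exons:
#' 135 nt from each cassette-exon end, 250 nt from each end of both flanking
#' introns, 135 nt of each flanking constitutive exon, and a 31-nt window.
#'
#' @param exon_end_len Nucleotides taken from each cassette-exon end.
#' @param intron_end_len Nucleotides taken from each intron end.
#' @param const_exon_len Nucleotides taken from each constitutive exon
#'   (splice-site-proximal end).
#' @param window_len Sliding-window length in nt (odd).
#'
#' @return An object of class `"map_layout"`.
#' @export
#' @examples
#' map_layout()
map_layout <- function(exon_end_len = 135L, intron_end_len = 250L,
                       const_exon_len = 135L, window_len = 31L) {
  window_len <- as.integer(window_len)
  if (window_len %% 2L != 1L) abort("`window_len` must be odd.")
  lens <- c(exon_end_len, intron_end_len, const_exon_len)
  if (any(lens < window_len)) {
    abort("All segment lengths must be >= window_len.")
  }
  structure(
    list(exon_end_len = as.integer(exon_end_len),
         intron_end_len = as.integer(intron_end_len),
         const_exon_len = as.integer(const_exon_len),
         window_len = window_len),
    class = "map_layout"
  )
}

#' @export
print.map_layout <- function(x, ...) {
  cat(sprintf(
    "RNA-map layout: cassette ends %d nt, intron ends %d nt, constitutive exons %d nt, window %d nt (axis %d nt)\n",
    x$exon_end_len, x$intron_end_len, x$const_exon_len, x$window_len,
    sum(layout_segments(x)$seg_len)
  ))
  invisible(x)
}

#' Segment blocks of a map layout
#'
#' One row per composite-axis segment, in transcript order, with its maximal
#' length and half-open block interval `[comp_start, comp_end)` on the shared
#' axis. `end` records which feature end the segment represents; truncated
#' segments are anchored at that end (5' ends left-aligned within the block,
#' 3' ends right-aligned).
#'
#' @param layout A [map_layout()].
#' @return A tibble with columns `segment`, `feature`, `end`, `seg_len`,
#'   `comp_start`, `comp_end`.
#' @export
layout_segments <- function(layout = map_layout()) {
  seg_len <- c(layout$const_exon_len,
               layout$intron_end_len, layout$intron_end_len,
               layout$exon_end_len, layout$exon_end_len,
               layout$intron_end_len, layout$intron_end_len,
               layout$const_exon_len)
  tibble(
    segment = factor(SEGMENT_LEVELS, levels = SEGMENT_LEVELS),
    feature = c("exon_up", "intron_up", "intron_up", "cassette", "cassette",
                "intron_down", "intron_down", "exon_down"),
    end = c("3p", "5p", "3p", "5p", "3p", "5p", "3p", "5p"),
    seg_len = as.integer(seg_len),
    comp_start = as.integer(cumsum(c(0L, seg_len[-8]))),
    comp_end = as.integer(cumsum(seg_len))
  )
}

#' Convert between segment offsets and composite-axis positions
#'
#' `composite_position()` maps a (segment, offset) pair to the 0-based
#' position on the concatenated map axis; `composite_locate()` is its
#' inverse. Offsets are 0-based within the segment's full-length block.
#'
#' @param layout A [map_layout()].
#' @param segment Segment label (one of `layout_segments(layout)$segment`).
#' @param offset 0-based offset within the segment block.
#' @return `composite_position()`: integer axis position;
#'   `composite_locate()`: tibble with `segment` and `offset`.
#' @export
#' @examples
#' composite_position(map_layout(), "intron_down_5p", 0)
#' composite_locate(map_layout(), 0)
composite_position <- function(layout, segment, offset) {
  segs <- layout_segments(layout)
  i <- match(as.character(segment), as.character(segs$segment))
  if (anyNA(i)) abort("Unknown segment label.")
  offset <- as.integer(offset)
  if (any(offset < 0 | offset >= segs$seg_len[i])) {
    abort("`offset` out of range for segment.")
  }
  segs$comp_start[i] + offset
}

#' @rdname composite_position
#' @param position 0-based composite-axis position.
#' @export
composite_locate <- function(layout, position) {
  segs <- layout_segments(layout)
  position <- as.integer(position)
  if (any(position < 0 | position >= max(segs$comp_end))) {
    abort("`position` outside the composite axis.")
  }
  i <- findInterval(position, segs$comp_start)
  tibble(segment = segs$segment[i],
         offset = position - segs$comp_start[i])
}
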