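# Sliding-window motif coverage profiles on the composite map axis, with
# label-permutation significance against a reference event set, and linked
# two-motif co-occurrence profiles.

# Per-event window-presence (P) and contribution (C) indicator matrices over
# the composite axis. P[e, p] = 1 iff the window centred at p, clipped to the
# segment extent the event actually covers, contains >= 1 motif-covered base;
# C[e, p] = 1 iff event e covers axis position p at all (truncated segments
# contribute only to positions they cover). Windows never span two segments.
presence_matrices <- function(regions, hits, layout, event_order) {
  segs <- layout_segments(layout)
  axis_len <- max(segs$comp_end)
  h <- (layout$window_len - 1L) %/% 2L
  n <- length(event_order)
  P <- matrix(0, n, axis_len)
  C <- matrix(0, n, axis_len)
  row_of <- setNames(seq_len(n), event_order)
  region_key <- paste(regions$event_id, regions$segment, sep = "\r")
  hit_row <- if (nrow(hits) > 0) {
    match(paste(hits$event_id, hits$segment, sep = "\r"), region_key)
  } else {
    integer(0)
  }
  f <- factor(hit_row, levels = seq_len(nrow(regions)))
  hs <- split(hits$start, f)
  he <- split(hits$end, f)
  e_all <- row_of[regions$event_id]
  for (r in seq_len(nrow(regions))) {
    e <- e_all[r]
    L <- regions$seg_len[r]
    a <- regions$comp_start[r] + 1L
    b <- regions$comp_end[r]
    C[e, a:b] <- 1
    st <- hs[[r]]
    if (length(st) == 0) next
    en <- he[[r]]
    mask <- logical(L)
    for (q in seq_along(st)) mask[(st[q] + 1L):en[q]] <- TRUE
    cs <- cumsum(mask)
    j <- seq_len(L)
    win_any <- cs[pmin(L, j + h)] - c(0, cs)[pmax(1L, j - h)] > 0
    P[e, a:b] <- as.numeric(win_any)
  }
  axis <- composite_locate(layout, seq_len(axis_len) - 1L)
  list(P = P, C = C, axis = tibble(position = seq_len(axis_len) - 1L,
                                   segment = axis$segment,
                                   offset = axis$offset))
}

regions_layout <- function(regions, layout) {
  layout %||% attr(regions, "layout") %||% map_layout()
}

#' Sliding-window motif coverage profile
#'
#' For one event set, computes at every composite-axis position the fraction
#' of events whose window (length `layout$window_len`, clipped at segment
#' boundaries) centred there contains at least one motif-covered base.
#' Events whose truncated segments do not reach a position are excluded from
#' that position's denominator.
#'
#' @param regions Regions tibble from [extract_regions()] (one event set).
#' @param motif A [motif_spec()].
#' @param layout A [map_layout()]; defaults to the layout the regions were
#'   extracted with.
#'
#' @return A tibble with `position`, `segment`, `offset`, `coverage`
#'   (fraction in \[0,1\], `NA` where no event contributes) and `n_events`
#'   (per-position contributor count).
#' @export
window_profile <- function(regions, motif, layout = NULL) {
  if (nrow(regions) == 0) abort("Empty event set.")
  layout <- regions_layout(regions, layout)
  hits <- scan_regions(regions, motif)
  events <- unique(regions$event_id)
  m <- presence_matrices(regions, hits, layout, events)
  denom <- colSums(m$C)
  cov <- ifelse(denom > 0, colSums(m$P) / denom, NA_real_)
  mutate(m$axis, coverage = cov, n_events = as.integer(denom))
}

# Shared permutation machinery: given pooled presence/contribution matrices
# with the test events in the first `n_test` rows, build the label-permuted
# null and per-position empirical P-values.
permutation_profile <- function(P, C, axis, n_test, n_perm, alpha, seed) {
  n_pool <- nrow(P)
  if (n_perm < 1) abort("`n_perm` must be a positive integer.")
  if (n_test < 1 || n_test > n_pool) {
    abort("Test set size must lie in [1, pooled size].")
  }
  test_idx <- seq_len(n_test)
  ref_idx <- setdiff(seq_len(n_pool), test_idx)
  den_t <- colSums(C[test_idx, , drop = FALSE])
  den_r <- colSums(C[ref_idx, , drop = FALSE])
  obs_t <- ifelse(den_t > 0, colSums(P[test_idx, , drop = FALSE]) / den_t,
                  NA_real_)
  obs_r <- ifelse(den_r > 0, colSums(P[ref_idx, , drop = FALSE]) / den_r,
                  NA_real_)
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n_pool, n_test),
           integer(n_test))
  })
  S <- sparseMatrix(i = rep(seq_len(n_perm), each = n_test),
                    j = as.vector(draws), x = 1,
                    dims = c(n_perm, n_pool))
  num <- as.matrix(S %*% P)
  den <- as.matrix(S %*% C)
  nullcov <- num / den
  nullcov[den == 0] <- -1  # a null draw with no contributors never exceeds
  exceed <- colSums(sweep(nullcov, 2, obs_t, ">="))
  pval <- (1 + exceed) / (n_perm + 1)
  pval[is.na(obs_t)] <- NA_real_
  signif <- !is.na(pval) & pval <= alpha &
    !is.na(obs_r) & !is.na(obs_t) & obs_t > obs_r
  mutate(axis,
         coverage_test = obs_t, coverage_ref = obs_r,
         pvalue = pval, significant = signif,
         n_test = as.integer(den_t), n_ref = as.integer(den_r))
}

check_sets <- function(test_ids, ref_ids, regions) {
  if (length(test_ids) == 0 || length(ref_ids) == 0) {
    abort("Test and reference sets must be non-empty.")
  }
  if (anyDuplicated(test_ids) || anyDuplicated(ref_ids)) {
    abort("Duplicated event ids within a set are rejected (set semantics).")
  }
  if (length(intersect(test_ids, ref_ids)) > 0) {
    abort("Test and reference sets must be disjoint.")
  }
  missing <- setdiff(c(test_ids, ref_ids), regions$event_id)
  if (length(missing) > 0) {
    abort(paste0("Event id(s) absent from regions: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' RNA map: positional motif enrichment with permutation significance
#'
#' Computes sliding-window coverage profiles for a test event set (e.g.
#' activated or repressed cassette exons) and a reference set, and assesses
#' per-position significance by label permutation: the null at each position
#' is built from `n_perm` random subsets of size `|test|` drawn from the
#' pooled test + reference events. The empirical P-value uses the +1
#' correction, `P = (1 + #\{null >= observed\}) / (n_perm + 1)`, so the
#' minimum attainable value is `1/(n_perm + 1)`. A position is marked
#' significant when `P <= alpha` and the test coverage exceeds the reference
#' coverage. P-values are reported per position, unadjusted; see
#' `familywise` for an optional max-statistic correction.
#'
#' @param regions Regions tibble covering (at least) all test and reference
#'   events.
#' @param test_ids,ref_ids Disjoint, duplicate-free character vectors of
#'   event ids.
#' @param motif A [motif_spec()].
#' @param layout A [map_layout()]; defaults to the regions' layout.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed (permutations are deterministic given the seed).
#' @param familywise If `TRUE`, additionally compute a max-statistic
#'   familywise-adjusted P-value per position (off by default; the primary
#'   read-out is the unadjusted per-position P).
#'
#' @return An object of class `"rna_map"`; `tidy()` returns the per-position
#'   profile, `glance()` a one-row summary, `autoplot()` the map figure.
#' @export
rna_map <- function(regions, test_ids, ref_ids, motif, layout = NULL,
                    n_perm = 1000L, alpha = 0.05, seed = 1L,
                    familywise = FALSE) {
  layout <- regions_layout(regions, layout)
  check_sets(test_ids, ref_ids, regions)
  pooled <- c(test_ids, ref_ids)
  sub <- regions[regions$event_id %in% pooled, ]
  hits <- scan_regions(sub, motif)
  m <- presence_matrices(sub, hits, layout, pooled)
  profile <- permutation_profile(m$P, m$C, m$axis, length(test_ids),
                                 n_perm, alpha, seed)
  if (familywise) {
    profile <- add_familywise(profile, m, length(test_ids), n_perm, seed)
  }
  structure(
    list(profile = profile, motif = motif, layout = layout,
         n_test = length(test_ids), n_ref = length(ref_ids),
         n_perm = as.integer(n_perm), alpha = alpha, seed = as.integer(seed)),
    class = "rna_map"
  )
}

# Max-statistic familywise correction: compare each observed coverage excess
# to the permutation distribution of the axis-wide maximum excess.
add_familywise <- function(profile, m, n_test, n_perm, seed) {
  n_pool <- nrow(m$P)
  draws <- with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(i) sample.int(n_pool, n_test),
           integer(n_test))
  })
  S <- sparseMatrix(i = rep(seq_len(n_perm), each = n_test),
                    j = as.vector(draws), x = 1, dims = c(n_perm, n_pool))
  nullcov <- as.matrix(S %*% m$P) / as.matrix(S %*% m$C)
  nullcov[!is.finite(nullcov)] <- -1
  null_max <- apply(nullcov, 1, max)
  obs <- profile$coverage_test
  fw <- vapply(obs, function(o) {
    if (is.na(o)) NA_real_ else (1 + sum(null_max >= o)) / (n_perm + 1)
  }, 0)
  mutate(profile, pvalue_fw = fw)
}

#' @export
print.rna_map <- function(x, ...) {
  cat(sprintf(
    "RNA map of '%s': %d test vs %d reference events, %d permutations\n",
    x$motif$name, x$n_test, x$n_ref, x$n_perm
  ))
  cat(sprintf("  %d / %d positions significant at alpha = %g\n",
              sum(x$profile$significant, na.rm = TRUE), nrow(x$profile),
              x$alpha))
  invisible(x)
}

#' @rdname rna_map
#' @param x An `"rna_map"` object.
#' @param ... Unused.
#' @export
tidy.rna_map <- function(x, ...) x$profile

#' @rdname rna_map
#' @export
glance.rna_map <- function(x, ...) {
  tibble(
    motif = x$motif$name,
    n_test = x$n_test,
    n_ref = x$n_ref,
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_positions = nrow(x$profile),
    n_significant = sum(x$profile$significant, na.rm = TRUE),
    sig_fraction = mean(x$profile$significant, na.rm = TRUE),
    min_pvalue = suppressWarnings(min(x$profile$pvalue, na.rm = TRUE))
  )
}

#' Link co-occurring hits of two motifs on one sequence
#'
#' Pairs every hit of motif A with every hit of motif B whose interval gap
#' (0 when they overlap) is at most `link_max_gap` nucleotides. The anchor of
#' a linked pair is the start of the A hit.
#'
#' @param hits_a,hits_b Hit tibbles (0-based half-open `start`, `end`) from
#'   the same sequence.
#' @param link_max_gap Maximum allowed gap in nt (default 25).
#' @return A tibble with `anchor`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `gap`.
#' @export
#' @examples
#' linked_hits(tibble::tibble(start = 0, end = 7),
#'             tibble::tibble(start = 10, end = 15))  # gap 3: linked
linked_hits <- function(hits_a, hits_b, link_max_gap = 25L) {
  if (nrow(hits_a) == 0 || nrow(hits_b) == 0) {
    return(tibble(anchor = integer(0), a_start = integer(0),
                  a_end = integer(0), b_start = integer(0),
                  b_end = integer(0), gap = integer(0)))
  }
  idx <- expand.grid(a = seq_len(nrow(hits_a)), b = seq_len(nrow(hits_b)))
  a_s <- hits_a$start[idx$a]; a_e <- hits_a$end[idx$a]
  b_s <- hits_b$start[idx$b]; b_e <- hits_b$end[idx$b]
  gap <- pmax(0L, pmax(a_s - b_e, b_s - a_e))
  keep <- gap <= link_max_gap
  out <- tibble(anchor = a_s[keep], a_start = a_s[keep], a_end = a_e[keep],
                b_start = b_s[keep], b_end = b_e[keep], gap = gap[keep])
  out[order(out$anchor, out$b_start), ]
}

# Anchor-point pseudo-hits of linked A-B pairs per (event, segment).
linked_anchor_hits <- function(regions, motif_a, motif_b, link_max_gap) {
  ha <- scan_regions(regions, motif_a)
  hb <- scan_regions(regions, motif_b)
  key <- function(d) paste(d$event_id, d$segment, sep = "\r")
  sa <- split(ha, key(ha))
  sb <- split(hb, key(hb))
  common <- intersect(names(sa), names(sb))
  out <- map(common, function(k) {
    lk <- linked_hits(sa[[k]], sb[[k]], link_max_gap)
    if (nrow(lk) == 0) return(NULL)
    anchors <- unique(lk$anchor)
    tibble(event_id = sa[[k]]$event_id[1],
           segment = sa[[k]]$segment[1],
           start = anchors, end = anchors + 1L,
           motif = paste0(motif_a$name, "+", motif_b$name))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(event_id = character(0),
                  segment = factor(character(0), levels = SEGMENT_LEVELS),
                  start = integer(0), end = integer(0), motif = character(0))
  }
  res
}

#' Co-occurrence RNA map of two linked motifs
#'
#' Positional profile of linked motif pairs: an event contributes at a
#' position when the anchor (start of the motif-A hit) of a pair linked
#' within `link_max_gap` nt lies inside the clipped window centred there.
#' The same permutation machinery as [rna_map()] is applied. When
#' `control = TRUE`, the profile is recomputed in the same call with a
#' single-nucleotide mutated control of motif B (see [mutate_control()]),
#' providing the specificity contrast.
#'
#' @inheritParams rna_map
#' @param motif_a,motif_b The two [motif_spec()]s (anchors come from
#'   `motif_a` hits).
#' @param link_max_gap Maximum gap between linked hits in nt (default 25).
#' @param control Compute the mutated-control profile too (default `TRUE`).
#' @param control_motif Control motif; defaults to position 4 of `motif_b`
#'   mutated to `A` (e.g. GCAYG to GCAAG).
#'
#' @return An object of class `"cooccurrence_map"` with elements `profile`
#'   and (optionally) `control_profile`, both per-position tibbles.
#' @export
cooccurrence_map <- function(regions, test_ids, ref_ids, motif_a, motif_b,
                             layout = NULL, link_max_gap = 25L,
                             n_perm = 1000L, alpha = 0.05, seed = 1L,
                             control = TRUE, control_motif = NULL) {
  layout <- regions_layout(regions, layout)
  check_sets(test_ids, ref_ids, regions)
  pooled <- c(test_ids, ref_ids)
  sub <- regions[regions$event_id %in% pooled, ]
  anchors <- linked_anchor_hits(sub, motif_a, motif_b, link_max_gap)
  m <- presence_matrices(sub, anchors, layout, pooled)
  profile <- permutation_profile(m$P, m$C, m$axis, length(test_ids),
                                 n_perm, alpha, seed)
  control_profile <- NULL
  if (control) {
    if (is.null(control_motif)) {
      control_motif <- mutate_control(motif_b, 4L, "A")
    }
    anchors_c <- linked_anchor_hits(sub, motif_a, control_motif, link_max_gap)
    mc <- presence_matrices(sub, anchors_c, layout, pooled)
    control_profile <- permutation_profile(mc$P, mc$C, mc$axis,
                                           length(test_ids), n_perm, alpha,
                                           seed)
  }
  structure(
    list(profile = profile, control_profile = control_profile,
         motif_a = motif_a, motif_b = motif_b,
         control_motif = if (control) control_motif else NULL,
         link_max_gap = as.integer(link_max_gap), layout = layout,
         n_test = length(test_ids), n_ref = length(ref_ids),
         n_perm = as.integer(n_perm), alpha = alpha, seed = as.integer(seed)),
    class = "cooccurrence_map"
  )
}

#' @export
print.cooccurrence_map <- function(x, ...) {
  cat(sprintf(
    "Co-occurrence map '%s' + '%s' (link <= %d nt): %d / %d positions significant\n",
    x$motif_a$name, x$motif_b$name, x$link_max_gap,
    sum(x$profile$significant, na.rm = TRUE), nrow(x$profile)
  ))
  if (!is.null(x$control_profile)) {
    cat(sprintf("  mutated control '%s': %d positions significant\n",
                x$control_motif$word,
                sum(x$control_profile$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' @rdname cooccurrence_map
#' @param x A `"cooccurrence_map"` object.
#' @param ... Unused.
#' @export
tidy.cooccurrence_map <- function(x, ...) {
  out <- mutate(x$profile, motif_pair = "true")
  if (!is.null(x$control_profile)) {
    out <- bind_rows(out, mutate(x$control_profile, motif_pair = "control"))
  }
  out
}

#' Export an RNA-map profile as TSV
#'
#' @param x An `"rna_map"` or `"cooccurrence_map"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
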