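# Eight-way co-regulation classification across two perturbations, congruence
# with a reference tissue contrast, hypergeometric overlap tests, and PSI
# heatmap clustering.

COREG_LABELS <- c(
  "coordinate_included",   # 1: both promote inclusion
  "coordinate_skipped",    # 2: both promote skipping
  "antagonistic_oe_up",    # 3: factor promotes inclusion, co-factor opposes
  "antagonistic_oe_down",  # 4: factor promotes skipping, co-factor opposes
  "factor_only_included",  # 5
  "factor_only_skipped",   # 6
  "cofactor_only_included",# 7
  "cofactor_only_skipped"  # 8
)

#' Classify events by co-regulation across two perturbations
#'
#' Takes per-event results from a factor over-expression contrast
#' (`dpsi_oe`, `fdr_oe`) and a co-factor knockdown contrast (`dpsi_kd`,
#' `fdr_kd`) and assigns each event to one of eight categories. The
#' knockdown \eqn{\Delta}PSI is sign-flipped (`effect_kd = -dpsi_kd`) so
#' that a positive effect always means "the co-factor promotes inclusion".
#' Categories: both contrasts significant with agreeing signs are coordinate
#' (1 included / 2 skipped); disagreeing signs are antagonistic (3/4 by the
#' over-expression sign); events significant in only one contrast fall in
#' the single-factor categories (5/6 factor-only, 7/8 co-factor-only by
#' effect sign). Events significant in neither contrast are uncalled (`NA`).
#'
#' @param contrasts Data frame with columns `event_id`, `dpsi_oe`, `fdr_oe`,
#'   `dpsi_kd`, `fdr_kd` (the intersection of events tested in both
#'   contrasts).
#' @param thresholds A [thresholds()] object applied identically to both
#'   contrasts.
#'
#' @return The input tibble with `effect_kd`, `category` (integer 1-8 or
#'   `NA`) and `category_label` columns added.
#' @export
classify_coregulation <- function(contrasts,
                                  thresholds = splicemaps::thresholds()) {
  th <- thresholds
  d <- as_tibble(contrasts)
  effect_kd <- -d$dpsi_kd
  sig_oe <- d$fdr_oe < th$fdr_max & abs(d$dpsi_oe) >= th$dpsi_min
  sig_kd <- d$fdr_kd < th$fdr_max & abs(d$dpsi_kd) >= th$dpsi_min
  category <- rep(NA_integer_, nrow(d))
  both <- sig_oe & sig_kd
  agree <- sign(d$dpsi_oe) == sign(effect_kd)
  category[both & agree & d$dpsi_oe > 0] <- 1L
  category[both & agree & d$dpsi_oe < 0] <- 2L
  category[both & !agree & d$dpsi_oe > 0] <- 3L
  category[both & !agree & d$dpsi_oe < 0] <- 4L
  category[sig_oe & !sig_kd & d$dpsi_oe > 0] <- 5L
  category[sig_oe & !sig_kd & d$dpsi_oe < 0] <- 6L
  category[!sig_oe & sig_kd & effect_kd > 0] <- 7L
  category[!sig_oe & sig_kd & effect_kd < 0] <- 8L
  mutate(d, effect_kd = effect_kd, category = category,
         category_label = ifelse(is.na(category), NA_character_,
                                 COREG_LABELS[category]))
}

CONGRUENCE_GROUPS <- c("congruent_activated", "congruent_repressed",
                       "discordant_oe_up", "discordant_oe_down")

#' Classify congruence with a reference tissue splicing programme
#'
#' For events significantly regulated both by the factor (over-expression
#' contrast) and between reference tissue and the basal cell state, an event
#' is congruent when the factor pushes the PSI in the tissue direction:
#' `sign(dpsi_oe) == sign(psi_tissue - psi_cell)`. Congruent events split
#' into activated (both positive) and repressed (both negative); discordant
#' events are labelled by the over-expression sign. Events failing either
#' significance filter, or with an exactly zero delta, are uncalled (`NA`,
#' with a warning for the zero-delta case).
#'
#' @param events Data frame with columns `event_id`, `dpsi_oe`, `fdr_oe`,
#'   `psi_tissue`, `psi_cell`, `tissue_fdr`.
#' @param thresholds A [thresholds()] object (the same `dpsi_min` and
#'   `fdr_max` are applied to both contrasts).
#'
#' @return The input tibble with `tissue_delta` and `group` columns added.
#' @export
classify_congruence <- function(events,
                                thresholds = splicemaps::thresholds()) {
  th <- thresholds
  d <- as_tibble(events)
  tissue_delta <- d$psi_tissue - d$psi_cell
  sig_oe <- d$fdr_oe < th$fdr_max & abs(d$dpsi_oe) >= th$dpsi_min
  sig_tis <- d$tissue_fdr < th$fdr_max & abs(tissue_delta) >= th$dpsi_min
  # a delta of exactly zero cannot clear the magnitude filter, but flag it
  # explicitly when the FDRs alone would have made the event callable
  zero <- (d$dpsi_oe == 0 | tissue_delta == 0) &
    d$fdr_oe < th$fdr_max & d$tissue_fdr < th$fdr_max
  if (any(zero)) {
    warn(sprintf("%d event(s) with an exactly zero delta left uncalled.",
                 sum(zero)))
  }
  callable <- sig_oe & sig_tis & !zero
  group <- rep(NA_character_, nrow(d))
  congruent <- sign(d$dpsi_oe) == sign(tissue_delta)
  group[callable & congruent & d$dpsi_oe > 0] <- "congruent_activated"
  group[callable & congruent & d$dpsi_oe < 0] <- "congruent_repressed"
  group[callable & !congruent & d$dpsi_oe > 0] <- "discordant_oe_up"
  group[callable & !congruent & d$dpsi_oe < 0] <- "discordant_oe_down"
  mutate(d, tissue_delta = tissue_delta, group = group)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a population of `N` containing `K` successes
#' (the classical gene-set overlap test). Computed in log space via the
#' hypergeometric distribution function.
#'
#' @param N Population size (the test universe; must be supplied explicitly).
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param k Observed overlap.
#'
#' @return A one-row tibble: `N`, `K`, `n`, `k`, `p_upper`.
#' @export
#' @examples
#' hypergeom_upper(10, 5, 5, 5)  # p_upper = 1/252
hypergeom_upper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || K > N) {
    abort("Require 0 <= k <= n <= N and K <= N.")
  }
  if (k > K) {
    # more overlap than available successes is impossible
    abort("Require k <= K.")
  }
  p <- if (k == 0) {
    1
  } else {
    exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  }
  tibble::new_tibble(list(N = N, K = K, n = n, k = k, p_upper = p),
                     nrow = 1L)
}

#' Gene-set overlap test from gene lists
#'
#' Convenience wrapper around [hypergeom_upper()] taking explicit gene sets.
#' The universe must be supplied; it is never defaulted silently.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector defining the test universe; both sets
#'   are intersected with it before testing.
#' @return A one-row tibble as [hypergeom_upper()], plus `overlap_genes`
#'   (list-column).
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  ov <- intersect(set_a, set_b)
  res <- hypergeom_upper(length(unique(universe)), length(set_b),
                         length(set_a), length(ov))
  mutate(res, overlap_genes = list(sort(ov)))
}

#' Read a one-gene-per-line gene list
#'
#' @param path Text file with one gene identifier per line (blank lines and
#'   lines starting with `#` are ignored).
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != "" & !startsWith(x, "#")]
}

#' PSI matrix with row clustering for heatmap display
#'
#' Z-scores each event's PSI values across the given conditions (rows with
#' zero variance map to all-zero) and clusters events by average-linkage
#' hierarchical clustering on Euclidean distance.
#'
#' @param psi Data frame with an `event_id` column and one numeric PSI
#'   column per condition.
#' @param conditions Character vector naming (and ordering) the condition
#'   columns; all must be present.
#' @param k Number of clusters to cut (default 2).
#'
#' @return An object of class `"psi_heatmap"`: list with the z-scored
#'   `matrix`, the `hclust` tree, and `clusters` (tibble `event_id`,
#'   `cluster`). `tidy()` returns the long per-event table.
#' @export
psi_heatmap_matrix <- function(psi, conditions, k = 2L) {
  missing_cond <- setdiff(conditions, names(psi))
  if (length(missing_cond) > 0) {
    abort(paste0("Missing condition column(s): ",
                 paste(missing_cond, collapse = ", ")))
  }
  m <- as.matrix(psi[, conditions])
  rownames(m) <- psi$event_id
  if (anyNA(m)) abort("PSI matrix contains missing values.")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  cl <- cutree(hc, k = k)
  structure(
    list(matrix = z, hclust = hc,
         clusters = tibble(event_id = rownames(z), cluster = unname(cl)),
         conditions = conditions, k = as.integer(k)),
    class = "psi_heatmap"
  )
}

#' @export
print.psi_heatmap <- function(x, ...) {
  cat(sprintf("PSI heatmap matrix: %d events x %d conditions, %d clusters\n",
              nrow(x$matrix), ncol(x$matrix), x$k))
  print(table(x$clusters$cluster))
  invisible(x)
}

#' @rdname psi_heatmap_matrix
#' @param x A `"psi_heatmap"` object.
#' @param ... Unused.
#' @export
tidy.psi_heatmap <- function(x, ...) {
  long <- as_tibble(x$matrix, rownames = "event_id")
  long <- tidyr::pivot_longer(long, -"event_id",
                              names_to = "condition", values_to = "z")
  left_join(long, x$clusters, by = "event_id")
}
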