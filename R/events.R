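# Splicing-event table IO, PSI computation, differential testing and
# event-set classification.

RMATS_COLUMNS <- c(
  "ID", "GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
  "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
  "IncFormLen", "SkipFormLen"
)

EVENT_CLASSES <- c("SE", "MXE", "A5SS", "A3SS", "RI")

parse_count_vectors <- function(x, column, what = "integer") {
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    vals <- suppressWarnings(as.numeric(parts))
    bad <- is.na(vals) & parts != "NA" & !is.na(parts)
    if (length(parts) == 0 || any(bad)) {
      abort(sprintf(
        "Malformed replicate vector in column '%s' at line %d: '%s'",
        column, i + 1L, x[i]
      ))
    }
    if (what == "integer") {
      if (any(!is.na(vals) & (vals < 0 | vals != floor(vals)))) {
        abort(sprintf(
          "Counts in column '%s' at line %d must be non-negative integers: '%s'",
          column, i + 1L, x[i]
        ))
      }
      out[[i]] <- as.integer(vals)
    } else {
      out[[i]] <- as.numeric(vals)
    }
  }
  out
}

#' Compute percent spliced in (PSI) from junction counts
#'
#' Length-normalised inclusion ratio
#' \deqn{\Psi = \frac{inc/L_{inc}}{inc/L_{inc} + skip/L_{skip}}}
#' matching the rMATS junction-count convention. Returns `NA` when
#' `inc + skip == 0` (PSI undefined).
#'
#' @param inc,skip Non-negative inclusion / skipping junction counts
#'   (vectorised).
#' @param inc_form_len,skip_form_len Positive effective form lengths.
#'
#' @return Numeric vector of PSI values in \[0, 1\] (`NA` where undefined).
#' @export
#' @examples
#' psi_from_counts(30, 10, 1, 1)  # 0.75
#' psi_from_counts(15, 5, 2, 1)   # 0.6
psi_from_counts <- function(inc, skip, inc_form_len = 1L, skip_form_len = 1L) {
  if (any(inc < 0, na.rm = TRUE) || any(skip < 0, na.rm = TRUE)) {
    abort("Junction counts must be non-negative.")
  }
  if (any(inc_form_len < 1) || any(skip_form_len < 1)) {
    abort("Form lengths must be >= 1.")
  }
  num <- inc / inc_form_len
  den <- num + skip / skip_form_len
  out <- num / den
  out[!is.na(inc) & !is.na(skip) & (inc + skip) == 0] <- NA_real_
  out
}

#' Read an rMATS-dialect differential-splicing table
#'
#' Parses a TSV in the rMATS `SE.MATS.JC.txt` column dialect into a tidy
#' events tibble (one row per event, replicate-level counts and PSIs held in
#' list-columns). Genomic coordinates are 0-based half-open, as in rMATS, and
#' are not shifted. Replicate PSIs are taken from `IncLevel1`/`IncLevel2` when
#' present, otherwise computed from counts via [psi_from_counts()].
#' `IncLevelDifference` is interpreted as mean(condition 2) - mean(condition 1).
#'
#' @param path Path to a tab-separated events file with a header row.
#' @param event_class One of `"SE"`, `"MXE"`, `"A5SS"`, `"A3SS"`, `"RI"`;
#'   stored on every row (RNA maps are built for SE events only).
#'
#' @return A tibble with one row per event: identifiers, geometry, list-columns
#'   `inc1`, `skip1`, `inc2`, `skip2`, `psi1`, `psi2`, plus `delta_psi` and
#'   `fdr` (NA when absent from the file).
#' @export
read_events <- function(path, event_class = "SE") {
  event_class <- match.arg(event_class, EVENT_CLASSES)
  if (!file.exists(path)) abort(paste0("Events file not found: ", path))
  raw <- read_tsv(path, col_types = cols(.default = col_character()),
                  progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(RMATS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Events table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  int_col <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-integer value in column '%s' at line %d: '%s'",
                    col, bad[1] + 1L, raw[[col]][bad[1]]))
    }
    v
  }
  inc1 <- parse_count_vectors(raw$IJC_SAMPLE_1, "IJC_SAMPLE_1")
  skip1 <- parse_count_vectors(raw$SJC_SAMPLE_1, "SJC_SAMPLE_1")
  inc2 <- parse_count_vectors(raw$IJC_SAMPLE_2, "IJC_SAMPLE_2")
  skip2 <- parse_count_vectors(raw$SJC_SAMPLE_2, "SJC_SAMPLE_2")
  ifl <- int_col("IncFormLen")
  sfl <- int_col("SkipFormLen")

  psi_from_file <- all(c("IncLevel1", "IncLevel2") %in% names(raw))
  if (psi_from_file) {
    psi1 <- parse_count_vectors(raw$IncLevel1, "IncLevel1", what = "numeric")
    psi2 <- parse_count_vectors(raw$IncLevel2, "IncLevel2", what = "numeric")
  } else {
    psi1 <- map(seq_along(inc1),
                ~ psi_from_counts(inc1[[.x]], skip1[[.x]], ifl[.x], sfl[.x]))
    psi2 <- map(seq_along(inc2),
                ~ psi_from_counts(inc2[[.x]], skip2[[.x]], ifl[.x], sfl[.x]))
  }
  for (i in seq_along(psi1)) {
    if (length(psi1[[i]]) != length(inc1[[i]]) ||
        length(psi2[[i]]) != length(inc2[[i]])) {
      abort(sprintf(
        "Replicate vector lengths disagree within a condition at line %d.",
        i + 1L
      ))
    }
    ok1 <- psi1[[i]][!is.na(psi1[[i]])]
    ok2 <- psi2[[i]][!is.na(psi2[[i]])]
    if (any(ok1 < 0 | ok1 > 1) || any(ok2 < 0 | ok2 > 1)) {
      abort(sprintf("PSI outside [0, 1] at line %d.", i + 1L))
    }
  }

  events <- tibble(
    event_id = raw$ID,
    gene_id = raw$GeneID,
    event_class = event_class,
    chrom = raw$chr,
    strand = raw$strand,
    cassette_start = int_col("exonStart_0base"),
    cassette_end = int_col("exonEnd"),
    upstream_start = int_col("upstreamES"),
    upstream_end = int_col("upstreamEE"),
    downstream_start = int_col("downstreamES"),
    downstream_end = int_col("downstreamEE"),
    inc_form_len = ifl,
    skip_form_len = sfl,
    inc1 = inc1, skip1 = skip1, inc2 = inc2, skip2 = skip2,
    psi1 = psi1, psi2 = psi2,
    delta_psi = if ("IncLevelDifference" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$IncLevelDifference))
    } else {
      map_dbl(seq_along(psi1),
              ~ mean(psi2[[.x]], na.rm = TRUE) - mean(psi1[[.x]], na.rm = TRUE))
    },
    fdr = if ("FDR" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$FDR))
    } else {
      NA_real_
    }
  )
  validate_events(events)
  events
}

validate_events <- function(events) {
  if (!all(events$strand %in% c("+", "-"))) {
    abort("Strand must be '+' or '-'.")
  }
  plus <- events$strand == "+"
  ok_plus <- events$upstream_end[plus] <= events$cassette_start[plus] &
    events$cassette_end[plus] <= events$downstream_start[plus]
  minus <- !plus
  ok_minus <- events$downstream_end[minus] <= events$cassette_start[minus] &
    events$cassette_end[minus] <= events$upstream_start[minus]
  if (!all(ok_plus) || !all(ok_minus)) {
    abort("Event coordinates are not ordered upstream < cassette < downstream in transcript sense.")
  }
  if (anyDuplicated(events$event_id)) {
    abort("Duplicated event_id values in events table.")
  }
  invisible(events)
}

fmt_vec <- function(v) {
  vapply(v, function(x) paste(ifelse(is.na(x), "NA", as.character(x)),
                              collapse = ","), "")
}

#' Write events to an rMATS-dialect TSV
#'
#' Inverse of [read_events()]: a table written here and re-read yields an
#' identical events tibble.
#'
#' @param events Events tibble as produced by [read_events()] or
#'   [simulate_events()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble(
    ID = events$event_id,
    GeneID = events$gene_id,
    chr = events$chrom,
    strand = events$strand,
    exonStart_0base = events$cassette_start,
    exonEnd = events$cassette_end,
    upstreamES = events$upstream_start,
    upstreamEE = events$upstream_end,
    downstreamES = events$downstream_start,
    downstreamEE = events$downstream_end,
    IJC_SAMPLE_1 = fmt_vec(events$inc1),
    SJC_SAMPLE_1 = fmt_vec(events$skip1),
    IJC_SAMPLE_2 = fmt_vec(events$inc2),
    SJC_SAMPLE_2 = fmt_vec(events$skip2),
    IncFormLen = events$inc_form_len,
    SkipFormLen = events$skip_form_len,
    IncLevel1 = fmt_vec(events$psi1),
    IncLevel2 = fmt_vec(events$psi2),
    IncLevelDifference = events$delta_psi,
    FDR = events$fdr
  )
  write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Differential splicing test (synthetic-path surrogate)
#'
#' Per-event two-sided Welch t-test on logit-transformed replicate PSIs
#' (clamped to \[0.01, 0.99\] before the transform), followed by
#' Benjamini-Hochberg FDR adjustment across all tested events.
#' `delta_psi` is recomputed as mean(condition 2) - mean(condition 1) on the
#' raw PSI scale. This is a documented stand-in for an external differential
#' splicing caller when analysing synthetic tables; tables from a real caller
#' carry their own FDR and need not be re-tested.
#'
#' Events with fewer than two replicates in either condition, or with an
#' undefined (NA) PSI in any replicate, are flagged untestable: their
#' `pvalue` is `NA` and `fdr` is set to 1 (they are excluded from the BH
#' adjustment, not imputed).
#'
#' @param events Events tibble with `psi1`/`psi2` list-columns.
#' @param psi_clamp Boundary clamp applied before the logit (default 0.01).
#'
#' @return The events tibble with `delta_psi`, `pvalue`, `fdr` and `testable`
#'   columns filled; carries attribute `test_method`.
#' @export
differential_test <- function(events, psi_clamp = 0.01) {
  n <- nrow(events)
  testable <- map_lgl(seq_len(n), function(i) {
    p1 <- events$psi1[[i]]; p2 <- events$psi2[[i]]
    length(p1) >= 2 && length(p2) >= 2 && !anyNA(p1) && !anyNA(p2)
  })
  if (any(!testable)) {
    inform(sprintf("differential_test: %d event(s) untestable (fdr set to 1).",
                   sum(!testable)))
  }
  delta <- map_dbl(seq_len(n), function(i) {
    mean(events$psi2[[i]], na.rm = TRUE) - mean(events$psi1[[i]], na.rm = TRUE)
  })
  pvals <- rep(NA_real_, n)
  for (i in which(testable)) {
    x <- logit(clamp(events$psi1[[i]], psi_clamp, 1 - psi_clamp))
    y <- logit(clamp(events$psi2[[i]], psi_clamp, 1 - psi_clamp))
    n1 <- length(x); n2 <- length(y)
    v1 <- stats::var(x); v2 <- stats::var(y)
    se2 <- v1 / n1 + v2 / n2
    d <- mean(y) - mean(x)
    if (se2 == 0) {
      pvals[i] <- if (d == 0) 1 else 0
    } else {
      tt <- d / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      pvals[i] <- 2 * pt(-abs(tt), df = df)
    }
  }
  fdr_adj <- rep(1, n)
  fdr_adj[testable] <- p.adjust(pvals[testable], method = "BH")
  out <- mutate(events, delta_psi = delta, pvalue = pvals,
                fdr = .env$fdr_adj, testable = .env$testable)
  attr(out, "test_method") <- "welch_logit_psi (surrogate for external caller)"
  out
}

#' Classify events into activated, repressed and reference sets
#'
#' Regulated events pass `fdr < fdr_max` and `|delta_psi| >= dpsi_min`
#' (activated when positive, repressed when negative). The reference set is
#' sampled without replacement (seeded, deterministic) from the non-regulated
#' pool (`fdr > ref_fdr_min` and `|delta_psi| < ref_dpsi_max`). The pool is
#' ordered by `event_id` before sampling so results are reproducible across
#' table orderings. If the pool is smaller than `ref_sample_size`, the whole
#' pool is used with a warning.
#'
#' @param events Events tibble with `delta_psi` and `fdr` populated.
#' @param thresholds A [thresholds()] object.
#' @param seed Integer seed for reference sampling.
#'
#' @return An object of class `"event_sets"`: list with character vectors
#'   `activated`, `repressed`, `reference`, plus `seed`, `thresholds` and
#'   `n_pool`. Use [tidy()] for a long tibble.
#' @export
classify_events <- function(events, thresholds = splicemaps::thresholds(),
                            seed = 1L) {
  if (anyNA(events$delta_psi) || anyNA(events$fdr)) {
    abort("classify_events requires delta_psi and fdr to be populated (run differential_test or read a tested table).")
  }
  th <- thresholds
  activated <- events$event_id[events$fdr < th$fdr_max &
                                 events$delta_psi >= th$dpsi_min]
  repressed <- events$event_id[events$fdr < th$fdr_max &
                                 events$delta_psi <= -th$dpsi_min]
  pool <- events$event_id[events$fdr > th$ref_fdr_min &
                            abs(events$delta_psi) < th$ref_dpsi_max]
  pool <- sort(pool)
  if (length(pool) < th$ref_sample_size) {
    warn(sprintf(
      "Reference pool (%d) smaller than ref_sample_size (%d); using the whole pool.",
      length(pool), th$ref_sample_size
    ))
    reference <- pool
  } else {
    reference <- with_seed(seed, resample(pool, th$ref_sample_size))
  }
  structure(
    list(activated = activated, repressed = repressed, reference = reference,
         seed = as.integer(seed), thresholds = th, n_pool = length(pool)),
    class = "event_sets"
  )
}

#' @export
print.event_sets <- function(x, ...) {
  cat(sprintf(
    "Event sets: %d activated, %d repressed, %d reference (pool %d, seed %d)\n",
    length(x$activated), length(x$repressed), length(x$reference),
    x$n_pool, x$seed
  ))
  invisible(x)
}

#' @rdname classify_events
#' @param x An `"event_sets"` object.
#' @param ... Unused.
#' @export
tidy.event_sets <- function(x, ...) {
  bind_rows(
    tibble(event_id = x$activated, set = "activated"),
    tibble(event_id = x$repressed, set = "repressed"),
    tibble(event_id = x$reference, set = "reference")
  )
}
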