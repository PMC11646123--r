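# ggplot2 displays for the main result types.

segment_breaks <- function(layout) {
  segs <- layout_segments(layout)
  tibble(x = segs$comp_start[-1] - 0.5)
}

profile_plot <- function(profile, layout, alpha, title, subtitle = NULL) {
  brk <- segment_breaks(layout)
  sig <- filter(profile, .data$significant)
  p <- ggplot(profile, aes(x = .data$position)) +
    geom_vline(data = brk, aes(xintercept = .data$x),
               linetype = "dotted", colour = "grey60") +
    geom_line(aes(y = .data$coverage_ref), colour = "grey50") +
    geom_line(aes(y = .data$coverage_test), colour = "#c0392b") +
    labs(title = title, subtitle = subtitle,
         x = "composite map position (nt)",
         y = "fraction of events with motif in window") +
    theme_bw()
  if (nrow(sig) > 0) {
    p <- p + geom_point(data = sig, aes(y = .data$coverage_test),
                        colour = "#c0392b", size = 0.8)
  }
  p
}

#' @rdname rna_map
#' @param object An `"rna_map"` object.
#' @export
autoplot.rna_map <- function(object, ...) {
  profile_plot(
    object$profile, object$layout, object$alpha,
    title = sprintf("RNA map: %s", object$motif$name),
    subtitle = sprintf("%d test vs %d reference events; dots: P <= %g",
                       object$n_test, object$n_ref, object$alpha)
  )
}

#' @rdname cooccurrence_map
#' @param object A `"cooccurrence_map"` object.
#' @export
autoplot.cooccurrence_map <- function(object, ...) {
  prof <- tidy(object)
  brk <- segment_breaks(object$layout)
  sig <- filter(prof, .data$significant)
  p <- ggplot(prof, aes(x = .data$position)) +
    geom_vline(data = brk, aes(xintercept = .data$x),
               linetype = "dotted", colour = "grey60") +
    geom_line(aes(y = .data$coverage_ref), colour = "grey50") +
    geom_line(aes(y = .data$coverage_test), colour = "#2c3e50") +
    facet_grid(rows = "motif_pair") +
    labs(title = sprintf("Linked %s + %s (gap <= %d nt)",
                         object$motif_a$name, object$motif_b$name,
                         object$link_max_gap),
         x = "composite map position (nt)",
         y = "fraction of events with linked pair in window") +
    theme_bw()
  if (nrow(sig) > 0) {
    p <- p + geom_point(data = sig, aes(y = .data$coverage_test),
                        colour = "#2c3e50", size = 0.8)
  }
  p
}

#' @rdname kmer_table
#' @param object A `"kmer_table"` object.
#' @export
autoplot.kmer_table <- function(object, ...) {
  tab <- mutate(object$table,
                neglogp = -log10(.data$pvalue),
                status = ifelse(.data$significant, "significant", "other"))
  ggplot(tab, aes(x = log2(.data$enrichment_score), y = .data$neglogp,
                  colour = .data$status)) +
    geom_point(size = 0.7, alpha = 0.6) +
    labs(title = sprintf("%d-mer enrichment", object$k),
         x = "log2 enrichment score", y = "-log10 empirical P",
         colour = NULL) +
    theme_bw()
}

#' @rdname psi_heatmap_matrix
#' @param object A `"psi_heatmap"` object.
#' @export
autoplot.psi_heatmap <- function(object, ...) {
  ord <- object$hclust$order
  long <- tidy(object)
  long$event_id <- factor(long$event_id,
                          levels = rownames(object$matrix)[ord])
  long$condition <- factor(long$condition, levels = object$conditions)
  ggplot(long, aes(x = .data$condition, y = .data$event_id,
                   fill = .data$z)) +
    geom_tile() +
    labs(title = "PSI z-scores (events clustered)", x = NULL, y = NULL,
         fill = "z") +
    theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
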