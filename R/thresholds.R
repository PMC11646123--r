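#' Significance thresholds for event classification
#'
#' Bundles the cut-offs used throughout the pipeline: regulated events must
#' pass `fdr < fdr_max` and `|delta_psi| >= dpsi_min`; the non-regulated
#' reference pool requires `fdr > ref_fdr_min` and `|delta_psi| < ref_dpsi_max`,
#' from which `ref_sample_size` events are sampled. A stringent \eqn{\Delta}PSI
#' cut-off (`stringent_dpsi_min`) is available for functional-impact filtering.
#'
#' @param fdr_max Maximum FDR for a regulated call (default 0.05).
#' @param dpsi_min Minimum \eqn{|\Delta PSI|} for a regulated call
#'   (default 0.15, i.e. 15%).
#' @param stringent_dpsi_min Stringent \eqn{|\Delta PSI|} cut-off
#'   (default 0.30).
#' @param ref_fdr_min Minimum FDR for reference-pool membership (default 0.10).
#' @param ref_dpsi_max Maximum \eqn{|\Delta PSI|} for reference-pool
#'   membership (default 0.10).
#' @param ref_sample_size Number of reference events to sample (default 2000).
#'
#' @return An object of class `"splice_thresholds"` (a named list).
#' @export
#' @examples
#' thresholds()
#' thresholds(dpsi_min = 0.30)
thresholds <- function(fdr_max = 0.05, dpsi_min = 0.15,
                       stringent_dpsi_min = 0.30,
                       ref_fdr_min = 0.10, ref_dpsi_max = 0.10,
                       ref_sample_size = 2000) {
  if (!(dpsi_min > 0 && dpsi_min <= stringent_dpsi_min &&
        stringent_dpsi_min <= 1)) {
    abort("Require 0 < dpsi_min <= stringent_dpsi_min <= 1.")
  }
  if (!(ref_dpsi_max < dpsi_min)) {
    abort("Require ref_dpsi_max < dpsi_min (reference and regulated bands must not overlap).")
  }
  if (fdr_max <= 0 || fdr_max > 1 || ref_fdr_min < 0 || ref_fdr_min > 1) {
    abort("FDR thresholds must lie in (0, 1].")
  }
  structure(
    list(fdr_max = fdr_max, dpsi_min = dpsi_min,
         stringent_dpsi_min = stringent_dpsi_min,
         ref_fdr_min = ref_fdr_min, ref_dpsi_max = ref_dpsi_max,
         ref_sample_size = as.integer(ref_sample_size)),
    class = "splice_thresholds"
  )
}

#' @export
print.splice_thresholds <- function(x, ...) {
  cat("Splicing thresholds:\n")
  cat(sprintf("  regulated: FDR < %g and |dPSI| >= %g (stringent %g)\n",
              x$fdr_max, x$dpsi_min, x$stringent_dpsi_min))
  cat(sprintf("  reference: FDR > %g and |dPSI| < %g, sample %d\n",
              x$ref_fdr_min, x$ref_dpsi_max, x$ref_sample_size))
  invisible(x)
}
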