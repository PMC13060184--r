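#' Declare the experimental design
#'
#' The design names the treatment conditions (in display order), the reference
#' condition against which fold changes are computed, the subset of conditions
#' regarded as mitotically arrested (used for the arrest-shared site class),
#' and the number of replicates per condition.
#'
#' @param conditions Character vector of condition names, in display order.
#' @param reference One of `conditions`; the unarrested control (e.g. the
#'   vehicle, DMSO).
#' @param arrested Subset of `conditions` (excluding `reference`) whose cells
#'   are mitotically arrested. Defaults to all non-reference conditions.
#' @param n_replicates Integer number of replicates per condition.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' knl1_design()
#' @export
experiment_design <- function(conditions, reference = conditions[1],
                              arrested = setdiff(conditions, reference),
                              n_replicates = 3L) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("conditions must be unique")
  if (!reference %in% conditions) stop("reference condition must be one of the declared conditions")
  if (!all(arrested %in% conditions)) stop("arrested conditions must be a subset of the declared conditions")
  if (reference %in% arrested) stop("the reference condition cannot be in the arrested set")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(
    list(conditions = conditions, reference = reference,
         arrested = as.character(arrested), n_replicates = n_replicates),
    class = "experiment_design"
  )
}

#' The default four-condition microtubule-poison design
#'
#' DMSO vehicle control plus three microtubule-disrupting compounds
#' (nocodazole, paclitaxel, STLC), three replicates each; the three compound
#' treatments form the mitotically arrested set.
#'
#' @param n_replicates Number of replicates per condition (default 3).
#' @return An `experiment_design`.
#' @export
knl1_design <- function(n_replicates = 3L) {
  experiment_design(c("DMSO", "nocodazole", "paclitaxel", "STLC"),
                    reference = "DMSO", n_replicates = n_replicates)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", length(x$conditions), "conditions x",
      x$n_replicates, "replicates\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  reference: ", x$reference, "\n")
  cat("  arrested:  ", paste(x$arrested, collapse = ", "), "\n")
  invisible(x)
}

#' Phospho-site qualification thresholds
#'
#' A site observation qualifies in a replicate when its best localization
#' confidence strictly exceeds `min_confidence` (percent) and its phospho-PSM
#' count is at least `min_phospho_psms`. The defaults (>75 percent, >=2
#' phospho-PSMs) are the conventional first-pass filter for site-level
#' evidence in spectral-count phospho-proteomics.
#'
#' @param min_confidence Strict lower bound on localization confidence, in
#'   percent (default 75).
#' @param min_phospho_psms Minimum phospho-PSM count per replicate (default 2).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_confidence = 75, min_phospho_psms = 2L) {
  if (min_confidence < 0 || min_confidence > 100) stop("min_confidence must be in [0, 100]")
  min_phospho_psms <- as.integer(min_phospho_psms)
  if (is.na(min_phospho_psms) || min_phospho_psms < 1L) stop("min_phospho_psms must be >= 1")
  structure(list(min_confidence = min_confidence,
                 min_phospho_psms = min_phospho_psms),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Site filter: confidence >", x$min_confidence,
      "%; phospho-PSMs >=", x$min_phospho_psms, "per replicate\n")
  invisible(x)
}
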