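#' Tally PSM counts per (protein, condition, replicate)
#'
#' Spectral counting over a validated PSM table: one count per PSM row,
#' grouped by protein accession, condition and replicate. Cells without any
#' PSM are reported as zero for every accession seen anywhere in the table.
#'
#' @param psms Validated PSM data.frame.
#' @param design An [experiment_design()].
#' @return data.frame `protein_accession`, `condition`, `replicate`, `count`.
#' @export
psm_count_table <- function(psms, design) {
  proteins <- sort(unique(psms$protein_accession))
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      condition = design$conditions,
                      protein_accession = proteins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("protein_accession", "condition", "replicate")]
  key <- function(p, c, r) paste(p, c, r, sep = "\r")
  tab <- table(key(psms$protein_accession, psms$condition, psms$replicate))
  m <- match(key(grid$protein_accession, grid$condition, grid$replicate),
             names(tab))
  grid$count <- ifelse(is.na(m), 0L, as.integer(tab[m]))
  grid
}

#' Pseudocount fold-change matrix for interactors
#'
#' For each protein and condition, averages the raw PSM counts across the
#' declared replicates (zeros included for replicates without a count) and
#' forms the fold change against the reference condition with a single
#' pseudocount: `FC = (avg + 1) / (avg_ref + 1)`, so absence in the
#' reference never divides by zero and the reference column is exactly 1.
#'
#' @param counts data.frame `protein_accession`, `condition`, `replicate`,
#'   `count` (see [psm_count_table()]); missing cells are treated as zero.
#' @param design An [experiment_design()].
#' @param pseudocount_stage `"after_average"` (default: the pseudocount is
#'   applied to the replicate-averaged counts) or `"per_replicate"` (the fold
#'   change is computed within each replicate, `(n_r + 1)/(ref_r + 1)`, then
#'   averaged — a distinct statistic retained for sensitivity checks).
#' @return data.frame of class `interactor_matrix`: `protein_accession`,
#'   `condition`, `avg_psms`, `fold_change`, ordered by protein then design
#'   condition order.
#' @examples
#' design <- knl1_design(n_replicates = 1)
#' counts <- data.frame(protein_accession = "NDC80",
#'                      condition = c("DMSO", "STLC"), replicate = 1,
#'                      count = c(4, 24))
#' fold_change_matrix(counts, design)  # STLC fold change (24+1)/(4+1) = 5
#' @export
fold_change_matrix <- function(counts, design,
                               pseudocount_stage = c("after_average", "per_replicate")) {
  pseudocount_stage <- match.arg(pseudocount_stage)
  stopifnot(inherits(design, "experiment_design"))
  if (any(counts$count < 0)) stop("PSM counts must be >= 0")
  proteins <- unique(counts$protein_accession)

  key <- function(p, c, r) paste(p, c, r, sep = "\r")
  have <- key(counts$protein_accession, counts$condition, counts$replicate)
  full <- expand.grid(replicate = seq_len(design$n_replicates),
                      condition = design$conditions,
                      protein_accession = proteins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- match(key(full$protein_accession, full$condition, full$replicate), have)
  full$count <- ifelse(is.na(m), 0, counts$count[m])

  ckey <- paste(full$protein_accession, full$condition, sep = "\r")
  avg <- tapply(full$count, ckey, mean)
  out <- expand.grid(condition = design$conditions,
                     protein_accession = proteins,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("protein_accession", "condition")]
  out$avg_psms <- as.numeric(avg[paste(out$protein_accession, out$condition, sep = "\r")])

  ref_lookup <- out[out$condition == design$reference, ]
  ref_avg <- ref_lookup$avg_psms[match(out$protein_accession,
                                       ref_lookup$protein_accession)]

  if (pseudocount_stage == "after_average") {
    out$fold_change <- (out$avg_psms + 1) / (ref_avg + 1)
  } else {
    fkey <- paste(full$protein_accession, full$replicate, sep = "\r")
    ref_rep <- full$count[full$condition == design$reference]
    names(ref_rep) <- fkey[full$condition == design$reference]
    ratio <- (full$count + 1) / (ref_rep[fkey] + 1)
    rc <- tapply(ratio, ckey, mean)
    out$fold_change <- as.numeric(rc[paste(out$protein_accession, out$condition, sep = "\r")])
  }
  out <- out[order(out$protein_accession,
                   match(out$condition, design$conditions)), ]
  rownames(out) <- NULL
  class(out) <- c("interactor_matrix", "data.frame")
  out
}
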