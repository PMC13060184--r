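#' Per-residue PSM depth
#'
#' Depth at residue i is the number of mapped PSM spans containing i. Computed
#' with a difference array, so it scales linearly in spans + protein length.
#'
#' @param spans data.frame with `start`, `end` columns (1-based inclusive),
#'   e.g. the `spans` element of [map_psms()].
#' @param protein_length Length of the target protein.
#' @return Integer depth vector of length `protein_length`.
#' @export
per_position_depth <- function(spans, protein_length) {
  if (nrow(spans) > 0L &&
      (min(spans$start) < 1L || max(spans$end) > protein_length ||
       any(spans$start > spans$end))) {
    stop("span out of bounds [1, ", protein_length, "]")
  }
  diffs <- integer(protein_length + 1L)
  if (nrow(spans) > 0L) {
    inc <- tabulate(spans$start, nbins = protein_length + 1L)
    dec <- tabulate(spans$end + 1L, nbins = protein_length + 1L)
    diffs <- inc - dec
  }
  cumsum(diffs)[seq_len(protein_length)]
}

#' Summarize a depth vector
#'
#' Percent coverage is the percentage of residues with depth >= 1; mean depth
#' is averaged over covered residues only (so a 70 percent-covered protein
#' with mean depth 20 has ~20 PSMs over each residue it actually saw, not 14).
#'
#' @param depth Integer depth vector.
#' @return list with `percent_coverage`, `mean_depth_covered` (0 when nothing
#'   is covered, with `covered = FALSE` flag), and `n_covered`.
#' @examples
#' coverage_stats(c(2, 2, 2, 3, 3, 1, 1, 1, 0, 0))
#' @export
coverage_stats <- function(depth) {
  if (length(depth) == 0L) stop("empty depth vector")
  covered <- depth >= 1L
  n_cov <- sum(covered)
  list(percent_coverage = 100 * n_cov / length(depth),
       mean_depth_covered = if (n_cov > 0L) mean(depth[covered]) else 0,
       covered = n_cov > 0L,
       n_covered = n_cov)
}

#' Per-condition coverage summary
#'
#' Computes a coverage profile per replicate, then averages percent coverage
#' and mean depth arithmetically across replicates within each condition
#' (replicate-then-average, matching how averaged coverage maps are reported),
#' and also returns the per-position mean depth for coverage-map style output.
#'
#' @param mapped A `mapped_psms` object (all conditions pooled in one table).
#' @param design An [experiment_design()].
#' @param protein_length Target protein length; defaults to the length stored
#'   in `mapped`.
#' @return list with
#'   \describe{
#'     \item{per_replicate}{data.frame `condition`, `replicate`,
#'       `percent_coverage`, `mean_depth_covered`.}
#'     \item{per_condition}{data.frame `condition`, `percent_coverage`,
#'       `mean_depth_covered` (means over replicates).}
#'     \item{depth}{named list `condition` -> `replicate` -> depth vector.}
#'     \item{mean_depth_map}{data.frame `position`, one column per condition
#'       with the replicate-mean depth.}
#'   }
#' @export
condition_coverage <- function(mapped, design, protein_length = mapped$protein_length) {
  stopifnot(inherits(design, "experiment_design"))
  spans <- mapped$spans
  depth <- list()
  per_rep <- list()
  mean_map <- data.frame(position = seq_len(protein_length))
  for (cond in design$conditions) {
    depth[[cond]] <- list()
    acc <- numeric(protein_length)
    for (r in seq_len(design$n_replicates)) {
      sub <- spans[spans$condition == cond & spans$replicate == r, , drop = FALSE]
      d <- per_position_depth(sub, protein_length)
      depth[[cond]][[r]] <- d
      acc <- acc + d
      st <- coverage_stats(d)
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        condition = cond, replicate = r,
        percent_coverage = st$percent_coverage,
        mean_depth_covered = st$mean_depth_covered,
        stringsAsFactors = FALSE)
    }
    mean_map[[cond]] <- acc / design$n_replicates
  }
  per_rep <- do.call(rbind, per_rep)
  agg <- function(v) tapply(v, per_rep$condition, mean)[design$conditions]
  per_cond <- data.frame(condition = design$conditions,
                         percent_coverage = as.numeric(agg(per_rep$percent_coverage)),
                         mean_depth_covered = as.numeric(agg(per_rep$mean_depth_covered)),
                         stringsAsFactors = FALSE)
  list(per_replicate = per_rep, per_condition = per_cond,
       depth = depth, mean_depth_map = mean_map)
}

# coverage.tsv layout: replicate rows plus an 'avg' row per condition
coverage_table <- function(cov, design) {
  rows <- cov$per_replicate
  rows$replicate <- as.character(rows$replicate)
  avg <- cov$per_condition
  avg$replicate <- "avg"
  avg <- avg[, names(rows)]
  out <- rbind(rows, avg)
  out <- out[order(match(out$condition, design$conditions),
                   out$replicate == "avg", out$replicate), ]
  rownames(out) <- NULL
  out
}
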