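#' Bin a site average for the linear schematic
#'
#' Site averages are binned into three categories for schematic rendering:
#' below the low edge, between the edges (closed on both ends), or above the
#' high edge — with the default edges (5, 10): `< 5` low, `5-10` mid,
#' `> 10` high.
#'
#' @param avg Numeric vector of average phospho-PSM counts.
#' @param edges Length-2 increasing numeric vector (default `c(5, 10)`).
#' @return Character vector in `{"low", "mid", "high"}`.
#' @export
bin_for_schematic <- function(avg, edges = c(5, 10)) {
  if (length(edges) != 2L || !(edges[1] < edges[2])) {
    stop("edges must be two strictly increasing values")
  }
  ifelse(avg < edges[1], "low", ifelse(avg <= edges[2], "mid", "high"))
}

#' Rows for the linear phosphorylation schematic
#'
#' One row per (condition, residue detected in that condition): position,
#' condition, zero-inclusive average (per [site_averages()]), bin category,
#' and whether the site is starred in that condition (condition-unique sites
#' with enough replicate support carry the star only in their own
#' condition's row). Rows are sorted by position, then design condition
#' order.
#'
#' @param obs A `site_observations` data.frame.
#' @param sets Condition site sets ([condition_site_sets()]).
#' @param classes Site classification ([classify_sites()]).
#' @param design An [experiment_design()].
#' @param edges Bin edges for [bin_for_schematic()].
#' @return data.frame `position`, `condition`, `avg_phospho_psms`, `bin`,
#'   `starred`.
#' @export
schematic_rows <- function(obs, sets, classes, design, edges = c(5, 10)) {
  avgs <- site_averages(obs, design)
  rows <- list()
  for (cond in design$conditions) {
    detected <- sets[[cond]]
    if (length(detected) == 0L) next
    a <- avgs[avgs$condition == cond & avgs$residue_index %in% detected, ]
    m <- match(a$residue_index, classes$residue_index)
    star_here <- !is.na(m) & classes$starred[m] &
      !is.na(classes$unique_condition[m]) &
      classes$unique_condition[m] == cond
    rows[[cond]] <- data.frame(position = a$residue_index,
                               condition = cond,
                               avg_phospho_psms = a$avg_phospho_psms,
                               bin = bin_for_schematic(a$avg_phospho_psms, edges),
                               starred = star_here,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(0), condition = character(0),
                      avg_phospho_psms = numeric(0), bin = character(0),
                      starred = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, match(out$condition, design$conditions)), ]
  rownames(out) <- NULL
  out
}

#' Run the full phospho-site pipeline
#'
#' End-to-end orchestration: validate (or read) the PSM table, map the
#' target's PSMs onto the protein, compute coverage and per-residue depth,
#' aggregate and filter phospho-site evidence, classify sites across
#' conditions, count phosphorylated motifs, build the interactor fold-change
#' matrix from the non-target accessions, and assemble all report tables.
#' Identical inputs and configuration give byte-identical outputs.
#'
#' @param psms A validated PSM data.frame, an unvalidated one in the psm.tsv
#'   layout, or a path to a psm.tsv file.
#' @param protein A protein data.frame ([read_fasta()] output), a path to a
#'   FASTA file, or a plain sequence string.
#' @param design An [experiment_design()].
#' @param target_accession Accession of the target protein; defaults to the
#'   first FASTA record's accession.
#' @param thresholds A [filter_thresholds()].
#' @param motifs Optional motif coordinate data.frame or motifs.tsv path
#'   (authoritative when given); otherwise the sequence is scanned with
#'   `pattern`.
#' @param pattern A [motif_pattern()] used when `motifs` is NULL.
#' @param fdr_threshold Peptide FDR cutoff applied when `psms` needs
#'   validation (default 0.01).
#' @param ambiguity_policy Multi-mapping policy for [map_psms()].
#' @param set_mode Site-set semantics for [condition_site_sets()].
#' @param star_mode Star-rule semantics for [classify_sites()].
#' @param motif_mode Motif counting mode for [phosphorylated_motif_counts()].
#' @param pseudocount_stage Fold-change variant for [fold_change_matrix()].
#' @param edges Schematic bin edges.
#' @param out_dir Optional output directory; when given, all report TSVs are
#'   written there via [write_tables()].
#' @param overwrite Passed to [write_tables()].
#' @return A list of class `phospho_report`: `coverage`, `sites`, `venn`,
#'   `motif_counts`, `schematic`, `interactors` (NULL if the table has no
#'   other accessions), plus `site_sets`, `classes`, `observations`,
#'   `coverage_detail`, and a `log` list of row counts dropped at each
#'   stage.
#' @export
run_pipeline <- function(psms, protein, design,
                         target_accession = NULL,
                         thresholds = filter_thresholds(),
                         motifs = NULL, pattern = motif_pattern(),
                         fdr_threshold = 0.01,
                         ambiguity_policy = "first",
                         set_mode = "per_replicate",
                         star_mode = "any_evidence",
                         motif_mode = "acceptor_only",
                         pseudocount_stage = "after_average",
                         edges = c(5, 10),
                         out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.character(protein) && length(protein) == 1L && file.exists(protein)) {
    protein <- read_fasta(protein)
  }
  if (is.character(protein)) {
    protein <- data.frame(accession = target_accession %||% "TARGET",
                          description = "", sequence = protein,
                          stringsAsFactors = FALSE)
  }
  if (is.null(target_accession)) target_accession <- protein$accession[1]
  if (!target_accession %in% protein$accession) {
    stop("target accession '", target_accession, "' not found in the FASTA")
  }
  target <- protein[protein$accession == target_accession, , drop = FALSE]

  if (is.character(psms)) {
    psms <- read_psm_table(psms, design, fdr_threshold = fdr_threshold)
  } else if (is.null(psms$psm_id)) {
    psms <- validate_psm_table(psms, design, fdr_threshold = fdr_threshold)
  }
  n_fdr <- attr(psms, "n_fdr_filtered") %||% 0L

  target_psms <- psms[psms$protein_accession == target_accession, , drop = FALSE]
  other_psms <- psms[psms$protein_accession != target_accession, , drop = FALSE]

  mapped <- map_psms(target_psms, target, ambiguity_policy = ambiguity_policy)
  cov <- condition_coverage(mapped, design)
  obs <- extract_site_observations(mapped, design, depth = cov$depth)
  sets <- condition_site_sets(obs, design, thresholds, mode = set_mode)
  classes <- classify_sites(sets, design, obs, thresholds, star_mode = star_mode)
  venn <- venn_counts(sets)

  motif_tab <- if (is.null(motifs)) {
    scan_motifs(target, pattern)
  } else if (is.character(motifs)) {
    load_motifs(motifs, target)
  } else {
    motifs
  }
  motif_counts <- phosphorylated_motif_counts(sets, motif_tab, mode = motif_mode)

  interactors <- NULL
  if (nrow(other_psms) > 0L) {
    interactors <- fold_change_matrix(psm_count_table(other_psms, design),
                                      design,
                                      pseudocount_stage = pseudocount_stage)
  }

  report <- structure(list(
    coverage = coverage_table(cov, design),
    sites = site_table(obs, sets, classes, design, thresholds),
    venn = venn,
    motif_counts = motif_counts,
    schematic = schematic_rows(obs, sets, classes, design, edges),
    interactors = interactors,
    site_sets = sets,
    classes = classes,
    observations = obs,
    coverage_detail = cov,
    motif_annotations = motif_tab,
    design = design,
    log = list(n_fdr_filtered = n_fdr,
               n_unmapped = mapped$n_unmapped,
               n_ambiguous = mapped$n_ambiguous,
               n_target_psms = nrow(target_psms),
               n_other_psms = nrow(other_psms))
  ), class = "phospho_report")

  if (!is.null(out_dir)) write_tables(report, out_dir, overwrite = overwrite)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phospho_report <- function(x, ...) {
  design <- x$design
  cat("Phospho-site pipeline report\n")
  cat(sprintf("  target PSMs: %d (FDR-dropped %d, unmapped %d, ambiguous %d)\n",
              x$log$n_target_psms, x$log$n_fdr_filtered,
              x$log$n_unmapped, x$log$n_ambiguous))
  cov <- x$coverage[x$coverage$replicate == "avg", ]
  for (i in seq_len(nrow(cov))) {
    cat(sprintf("  %-12s coverage %.2f%%, mean depth %.1f, sites %d\n",
                cov$condition[i], cov$percent_coverage[i],
                cov$mean_depth_covered[i],
                length(x$site_sets[[cov$condition[i]]])))
  }
  cat(sprintf("  distinct sites: %d; shared across all conditions: %d; arrest-shared: %d; condition-unique: %d (%d starred)\n",
              attr(x$venn, "total"),
              sum(x$classes$classification == "shared_all"),
              sum(x$classes$classification == "arrested_shared"),
              sum(x$classes$classification == "condition_unique"),
              sum(x$classes$starred)))
  mc <- x$motif_counts
  cat(sprintf("  phosphorylated motifs: %s (of %d; %d overall)\n",
              paste(sprintf("%s %d", mc$condition, mc$phosphorylated_motifs),
                    collapse = ", "),
              mc$total_motifs[1] %||% 0L, attr(mc, "overall")))
  invisible(x)
}

#' Reproduce published site statistics from a deposited dataset
#'
#' Runs the default pipeline configuration against a locally available copy
#' of a deposited PSM-level dataset (for example the MassIVE deposition
#' behind a published study, exported to this package's psm.tsv dialect) and
#' returns the headline numbers: per-condition qualifying-site counts, the
#' shared/arrest-shared/unique breakdown, the total distinct site count and
#' the per-condition coverage summary. The deposited data must be supplied
#' by the user — it is not bundled and is never downloaded by this package.
#'
#' @param psm_path Path to the deposited PSM table in psm.tsv dialect.
#' @param fasta_path Path to the FASTA containing the target sequence.
#' @param target_accession Target protein accession.
#' @param design An [experiment_design()] (default [knl1_design()]).
#' @param ... Passed on to [run_pipeline()].
#' @return list with `sites_per_condition`, `shared_all`, `arrested_shared`,
#'   `total_sites`, `coverage`, and the full `report`.
#' @export
reproduce_published_counts <- function(psm_path, fasta_path, target_accession,
                                       design = knl1_design(), ...) {
  if (!file.exists(psm_path) || !file.exists(fasta_path)) {
    stop("deposited dataset not available locally: expected '", psm_path,
         "' and '", fasta_path,
         "' (export the deposition to the psm.tsv dialect first)")
  }
  report <- run_pipeline(psm_path, fasta_path, design,
                         target_accession = target_accession, ...)
  list(sites_per_condition = vapply(report$site_sets, length, integer(1)),
       shared_all = sum(report$classes$classification == "shared_all"),
       arrested_shared = sum(report$classes$classification == "arrested_shared"),
       total_sites = attr(report$venn, "total"),
       coverage = report$coverage[report$coverage$replicate == "avg", ],
       report = report)
}
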