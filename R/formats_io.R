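#' Read a protein FASTA file
#'
#' Reads a (multi-record) FASTA file and returns one row per record with the
#' accession (first whitespace-delimited token of the header), the remaining
#' description, and the uppercased amino-acid sequence. Sequences may contain
#' the 20 canonical residues plus `X`; anything else is an error naming the
#' record and offending position.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  saw_invalid <- FALSE
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        saw_invalid <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (saw_invalid) stop_at_illegal_char(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(gsub("\\s", "", as.character(set)))
  if (anyDuplicated(accession)) {
    stop("duplicate accession in FASTA: ",
         accession[duplicated(accession)][1])
  }
  for (i in seq_along(sequence)) {
    bad <- regexpr(sprintf("[^%s]", .aa_alphabet), sequence[i])
    if (bad > 0L) {
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   substr(sequence[i], bad, bad), bad, accession[i]))
    }
    if (nchar(sequence[i]) < 1L) stop("empty sequence for record ", accession[i])
  }
  out <- data.frame(accession = accession, description = description,
                    sequence = sequence, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"

# locate the first non-amino-acid character in a FASTA body for the error
# message (the parser itself would silently drop it)
stop_at_illegal_char <- function(path) {
  lines <- readLines(path)
  record <- "<none>"
  pos <- 0L
  for (line in lines) {
    if (startsWith(line, ">")) {
      record <- sub("\\s.*$", "", substring(line, 2))
      pos <- 0L
      next
    }
    body <- toupper(gsub("\\s", "", line))
    bad <- regexpr(sprintf("[^%s]", .aa_alphabet), body)
    if (bad > 0L) {
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   substr(body, bad, bad), pos + bad, record))
    }
    pos <- pos + nchar(body)
  }
  stop("invalid sequence characters in ", path)
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with `accession`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  header <- ifelse(nzchar(desc),
                   paste(proteins$accession, desc),
                   proteins$accession)
  body <- vapply(proteins$sequence, function(s) {
    paste(substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))),
          collapse = "\n")
  }, character(1))
  writeLines(paste0(">", header, "\n", body), path)
  invisible(path)
}

.mod_term_re <- "^([A-Z])([0-9]+)\\((Phospho|Oxidation|Carbamidomethyl)(?:,([0-9]*\\.?[0-9]+))?\\)$"

#' Parse a modification string
#'
#' The modification field of the PSM table is zero or more semicolon-separated
#' terms, each `<AA><pepPos>(<ModName>[,<confPercent>])`, e.g.
#' `"S3(Phospho,99.1); M5(Oxidation)"`. Positions are 1-based within the
#' peptide; the confidence, when present, is a percent in \[0, 100\].
#'
#' @param text A single modification string (may be empty).
#' @return A data.frame with columns `residue_letter`, `peptide_position`,
#'   `mod_name`, `confidence` (NA when absent), one row per term, in input
#'   order.
#' @examples
#' parse_modification_string("S3(Phospho,99.1); M5(Oxidation)")
#' @export
parse_modification_string <- function(text) {
  stopifnot(length(text) == 1L)
  flat <- parse_mods_flat(text)
  flat[, c("residue_letter", "peptide_position", "mod_name", "confidence")]
}

# Vectorised modification parser: one long table for a vector of mod strings.
# `entry` indexes the input element each term came from.
parse_mods_flat <- function(texts) {
  if (length(texts) == 0L) {
    return(data.frame(entry = integer(0), residue_letter = character(0),
                      peptide_position = integer(0), mod_name = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  texts <- ifelse(is.na(texts), "", trimws(as.character(texts)))
  terms <- strsplit(texts, ";", fixed = TRUE)
  n_terms <- lengths(terms)
  entry <- rep(seq_along(texts), n_terms)
  term <- trimws(unlist(terms, use.names = FALSE))
  keep <- nzchar(term)
  entry <- entry[keep]; term <- term[keep]
  if (length(term) == 0L) {
    return(data.frame(entry = integer(0), residue_letter = character(0),
                      peptide_position = integer(0), mod_name = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  m <- regmatches(term, regexec(.mod_term_re, term))
  bad <- which(lengths(m) == 0L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed modification term '%s' (input element %d)",
                 term[bad[1]], entry[bad[1]]))
  }
  parts <- matrix(unlist(m), ncol = 5L, byrow = TRUE)
  conf <- suppressWarnings(as.numeric(parts[, 5L]))
  if (any(conf > 100 | conf < 0, na.rm = TRUE)) {
    stop("localization confidence outside [0, 100]")
  }
  data.frame(entry = entry,
             residue_letter = parts[, 2L],
             peptide_position = as.integer(parts[, 3L]),
             mod_name = parts[, 4L],
             confidence = conf,
             stringsAsFactors = FALSE)
}

#' Serialize modification rows back to the PSM-table grammar
#'
#' Inverse of [parse_modification_string()]; confidences are printed as given
#' (no padding), so `parse(serialize(x))` round-trips exactly.
#'
#' @param mods data.frame with `residue_letter`, `peptide_position`,
#'   `mod_name`, `confidence` columns.
#' @return A single modification string.
#' @export
serialize_modifications <- function(mods) {
  if (nrow(mods) == 0L) return("")
  conf <- ifelse(is.na(mods$confidence), "",
                 paste0(",", format(mods$confidence, trim = TRUE, scientific = FALSE)))
  paste0(mods$residue_letter, mods$peptide_position, "(", mods$mod_name, conf, ")",
         collapse = "; ")
}

#' Read and validate a PSM table
#'
#' Reads the tab-separated PSM dialect (columns `sample_id`, `condition`,
#' `replicate`, `peptide_sequence`, `protein_accession`, `mods`, and optional
#' `peptide_fdr`), validates every row against the declared design, parses the
#' modification strings, and drops rows whose peptide FDR exceeds
#' `fdr_threshold`. Rows without an FDR value are assumed pre-filtered
#' upstream and kept.
#'
#' @param path Path to a psm.tsv file.
#' @param design An [experiment_design()].
#' @param fdr_threshold Maximum allowed peptide FDR as a fraction
#'   (default 0.01, i.e. peptide FDR < 1 percent).
#' @return A validated PSM data.frame with a `psm_id` column; the number of
#'   FDR-dropped rows is attached as attribute `n_fdr_filtered`.
#' @export
read_psm_table <- function(path, design, fdr_threshold = 0.01) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "condition", "replicate", "peptide_sequence",
                "protein_accession", "mods")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("PSM table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$replicate <- as.integer(raw$replicate)
  raw$peptide_fdr <- if ("peptide_fdr" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$peptide_fdr))
  } else NA_real_
  validate_psm_table(raw, design, fdr_threshold = fdr_threshold)
}

#' Validate an in-memory PSM table
#'
#' Applies the same contract as [read_psm_table()] to a data.frame already in
#' memory (e.g. produced by [simulate_psm_dataset()]): design membership,
#' modification grammar, modification-position consistency with the peptide,
#' and the peptide-FDR pre-filter.
#'
#' @inheritParams read_psm_table
#' @param psms data.frame in the psm.tsv column layout.
#' @return The validated PSM data.frame with `psm_id`; attribute
#'   `n_fdr_filtered` counts dropped rows.
#' @export
validate_psm_table <- function(psms, design, fdr_threshold = 0.01) {
  stopifnot(inherits(design, "experiment_design"))
  if (any(!nzchar(psms$peptide_sequence))) {
    stop("empty peptide_sequence at row ",
         which(!nzchar(psms$peptide_sequence))[1])
  }
  bad_cond <- which(!psms$condition %in% design$conditions)
  if (length(bad_cond) > 0L) {
    stop(sprintf("unknown condition '%s' at row %d",
                 psms$condition[bad_cond[1]], bad_cond[1]))
  }
  bad_rep <- which(is.na(psms$replicate) | psms$replicate < 1L |
                     psms$replicate > design$n_replicates)
  if (length(bad_rep) > 0L) {
    stop(sprintf("replicate outside 1..%d at row %d",
                 design$n_replicates, bad_rep[1]))
  }
  if (!"peptide_fdr" %in% names(psms)) psms$peptide_fdr <- NA_real_

  # modification grammar + position/letter consistency, vectorised
  flat <- parse_mods_flat(psms$mods)
  if (nrow(flat) > 0L) {
    pep <- psms$peptide_sequence[flat$entry]
    out_of_range <- which(flat$peptide_position < 1L |
                            flat$peptide_position > nchar(pep))
    if (length(out_of_range) > 0L) {
      i <- out_of_range[1]
      stop(sprintf("modification position %d outside peptide at row %d",
                   flat$peptide_position[i], flat$entry[i]))
    }
    letter_at <- substr(pep, flat$peptide_position, flat$peptide_position)
    mismatch <- which(letter_at != flat$residue_letter)
    if (length(mismatch) > 0L) {
      i <- mismatch[1]
      stop(sprintf(
        "modification letter '%s' does not match peptide letter '%s' at row %d",
        flat$residue_letter[i], letter_at[i], flat$entry[i]))
    }
  }

  drop <- !is.na(psms$peptide_fdr) & psms$peptide_fdr > fdr_threshold
  out <- psms[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out$psm_id <- seq_len(nrow(out))
  attr(out, "n_fdr_filtered") <- sum(drop)
  out
}

#' Write a PSM table in the package's TSV dialect
#'
#' @param psms PSM data.frame (the `psm_id` column, if present, is dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c("sample_id", "condition", "replicate", "peptide_sequence",
            "protein_accession", "mods", "peptide_fdr")
  cols <- intersect(cols, names(psms))
  utils::write.table(psms[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a motif coordinate table
#'
#' motifs.tsv columns (all coordinates 1-based, inclusive): `motif_id`,
#' `start`, `end`, `acceptor_position`.
#'
#' @param path Path to a motifs.tsv file.
#' @return data.frame of motif annotations (unvalidated; see [load_motifs()]).
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop("motif table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  required <- c("motif_id", "start", "end", "acceptor_position")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("motif table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$motif_id <- as.character(tab$motif_id)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$acceptor_position <- as.integer(tab$acceptor_position)
  tab[, required]
}

# shared formatter: fixed-precision numbers for deterministic TSV output
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the report tables
#'
#' Writes the assembled pipeline outputs as deterministic TSVs (`sites.tsv`,
#' `coverage.tsv`, `interactors.tsv`, `venn.tsv`, `schematic.tsv`,
#' `motif_counts.tsv`; tables that were not computed are skipped). Row order
#' is stable (residue index, then condition order) and numbers are printed at
#' fixed precision, so identical inputs give byte-identical files.
#'
#' @param results A `phospho_report` list as returned by [run_pipeline()], or
#'   any list with some of the elements `sites`, `coverage`, `interactors`,
#'   `venn`, `schematic`, `motif_counts`.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Overwrite existing files? Default FALSE: colliding with an
#'   existing file is an error.
#' @return Character vector of the paths written, invisibly.
#' @export
write_tables <- function(results, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(sites = "sites.tsv", coverage = "coverage.tsv",
             interactors = "interactors.tsv", venn = "venn.tsv",
             schematic = "schematic.tsv", motif_counts = "motif_counts.tsv")
  written <- character(0)
  for (key in names(files)) {
    tab <- results[[key]]
    if (is.null(tab)) next
    path <- file.path(out_dir, files[[key]])
    if (file.exists(path) && !overwrite) {
      stop("output file exists (use overwrite = TRUE): ", path)
    }
    # fixed printing precision: fold changes at 4 d.p., other doubles at 2
    for (col in names(tab)) {
      if (is.double(tab[[col]])) {
        tab[[col]] <- fmt_num(tab[[col]], if (col == "fold_change") 4L else 2L)
      }
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    written <- c(written, path)
  }
  invisible(written)
}
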