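#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) or arginine (R) except
#' when the next residue is proline (the Keil rule, the default of mainstream
#' search engines), allowing up to `max_missed` retained internal cleavage
#' sites, and length-filters the products.
#'
#' @param sequence Protein sequence (single uppercase string).
#' @param max_missed Maximum missed cleavages (default 2, the usual search
#'   constraint).
#' @param min_len,max_len Peptide length filter (defaults 6 and 50).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `missed_cleavages`, `sequence`, sorted by (start, end).
#' @examples
#' digest_protein("AKRPCK", max_missed = 1, min_len = 1)
#' @export
digest_protein <- function(sequence, max_missed = 2L, min_len = 6L, max_len = 50L) {
  stopifnot(length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop("cannot digest an empty sequence")
  if (max_missed < 0L) stop("max_missed must be >= 0")
  if (min_len < 1L || min_len > max_len) stop("need 1 <= min_len <= max_len")
  sites <- cleavage_sites(sequence)
  bounds <- c(0L, sites, n)
  bounds <- bounds[!duplicated(bounds)]   # n may itself be a cleavage site
  nb <- length(bounds)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    j <- (i + 1L):jmax
    out[[i]] <- data.frame(start = bounds[i] + 1L, end = bounds[j],
                           missed_cleavages = j - i - 1L)
  }
  peps <- do.call(rbind, out)
  len <- peps$end - peps$start + 1L
  peps <- peps[len >= min_len & len <= max_len, , drop = FALSE]
  peps <- peps[order(peps$start, peps$end), , drop = FALSE]
  peps$sequence <- substring(sequence, peps$start, peps$end)
  rownames(peps) <- NULL
  peps
}

# positions i such that trypsin cuts between residue i and i+1
cleavage_sites <- function(sequence) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  kr <- which(chars %in% c("K", "R"))
  kr[kr == n | chars[pmin(kr + 1L, n)] != "P"]
}

#' Locate a peptide on a protein
#'
#' Returns every exact occurrence of `peptide` within the protein sequence as
#' 1-based inclusive coordinates, ascending by start. Isoleucine and leucine
#' are treated as distinct (exact matching only).
#'
#' @param peptide Peptide sequence (non-empty string).
#' @param sequence Protein sequence.
#' @return data.frame with columns `start`, `end`; zero rows if no match.
#' @export
map_peptide <- function(peptide, sequence) {
  stopifnot(nzchar(peptide))
  # lookahead so that overlapping occurrences are all reported
  hits <- gregexpr(paste0("(?=", peptide, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- as.integer(hits)
  data.frame(start = starts, end = starts + nchar(peptide) - 1L)
}

#' Map PSMs onto the target protein
#'
#' Places each PSM's peptide on the target sequence by exact substring search
#' (so semi-tryptic peptides map too) and converts its phospho modifications
#' to absolute protein coordinates (`protein position = span start +
#' peptide position - 1`). Peptides absent from the protein are dropped and
#' counted; peptides occurring more than once are resolved by
#' `ambiguity_policy`.
#'
#' @param psms Validated PSM data.frame (see [validate_psm_table()]).
#' @param protein A single-row protein record (data.frame with `accession`,
#'   `sequence`) or a plain sequence string.
#' @param ambiguity_policy One of `"first"` (default; keep the left-most
#'   match and count the ambiguity), `"all"` (one mapped span per match,
#'   flagged multi-mapped), or `"drop"` (exclude multi-matching peptides).
#' @return A list of class `mapped_psms`:
#'   \describe{
#'     \item{spans}{data.frame `psm_id`, `condition`, `replicate`, `start`,
#'       `end`, `multi_mapped`.}
#'     \item{phospho}{data.frame `psm_id`, `condition`, `replicate`,
#'       `residue_index`, `residue_letter`, `confidence` — one row per
#'       phospho observation at absolute coordinates.}
#'     \item{n_unmapped}{PSMs whose peptide was not found.}
#'     \item{n_ambiguous}{PSMs whose peptide matched more than once.}
#'   }
#' @export
map_psms <- function(psms, protein, ambiguity_policy = c("first", "all", "drop")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  sequence <- if (is.character(protein)) protein else protein$sequence[1]

  peptides <- unique(psms$peptide_sequence)
  hit_list <- lapply(peptides, map_peptide, sequence = sequence)
  names(hit_list) <- peptides
  n_hits <- vapply(hit_list, nrow, integer(1))

  pep_hits <- n_hits[psms$peptide_sequence]
  n_unmapped <- sum(pep_hits == 0L)
  n_ambiguous <- sum(pep_hits > 1L)

  keep <- pep_hits >= 1L
  if (ambiguity_policy == "drop") keep <- keep & pep_hits == 1L
  kept <- psms[keep, , drop = FALSE]
  kept_hits <- hit_list[kept$peptide_sequence]

  if (ambiguity_policy == "all") {
    reps <- vapply(kept_hits, nrow, integer(1))
    idx <- rep(seq_len(nrow(kept)), reps)
    starts <- unlist(lapply(kept_hits, function(h) h$start), use.names = FALSE)
    ends <- unlist(lapply(kept_hits, function(h) h$end), use.names = FALSE)
    multi <- rep(reps > 1L, reps)
  } else {
    idx <- seq_len(nrow(kept))
    starts <- vapply(kept_hits, function(h) h$start[1], integer(1))
    ends <- vapply(kept_hits, function(h) h$end[1], integer(1))
    multi <- vapply(kept_hits, nrow, integer(1)) > 1L
  }
  spans <- data.frame(psm_id = kept$psm_id[idx],
                      condition = kept$condition[idx],
                      replicate = kept$replicate[idx],
                      start = starts, end = ends,
                      multi_mapped = multi,
                      stringsAsFactors = FALSE)
  rownames(spans) <- NULL

  # absolute phospho coordinates for the mapped spans
  flat <- parse_mods_flat(kept$mods)
  flat <- flat[flat$mod_name == "Phospho", , drop = FALSE]
  span_of_entry <- split(seq_len(nrow(spans)), match(spans$psm_id, kept$psm_id))
  if (nrow(flat) > 0L) {
    span_rows <- span_of_entry[as.character(flat$entry)]
    reps <- lengths(span_rows)
    srow <- unlist(span_rows, use.names = FALSE)
    frow <- rep(seq_len(nrow(flat)), reps)
    phospho <- data.frame(
      psm_id = spans$psm_id[srow],
      condition = spans$condition[srow],
      replicate = spans$replicate[srow],
      residue_index = spans$start[srow] + flat$peptide_position[frow] - 1L,
      residue_letter = flat$residue_letter[frow],
      confidence = flat$confidence[frow],
      stringsAsFactors = FALSE)
  } else {
    phospho <- data.frame(psm_id = integer(0), condition = character(0),
                          replicate = integer(0), residue_index = integer(0),
                          residue_letter = character(0), confidence = numeric(0),
                          stringsAsFactors = FALSE)
  }

  structure(list(spans = spans, phospho = phospho,
                 n_unmapped = n_unmapped, n_ambiguous = n_ambiguous,
                 protein_length = nchar(sequence)),
            class = "mapped_psms")
}

#' @export
print.mapped_psms <- function(x, ...) {
  cat("Mapped PSMs:", nrow(x$spans), "spans on a", x$protein_length,
      "aa target;", nrow(x$phospho), "phospho observations\n")
  cat("  unmapped:", x$n_unmapped, " ambiguous:", x$n_ambiguous, "\n")
  invisible(x)
}
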