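#' Define a motif pattern
#'
#' A motif pattern is a regular expression over amino-acid letters plus the
#' 1-based offset of the phospho-acceptor residue within each match. The
#' default is the degenerate MELT-class repeat `[MILV][ED][MILV]T` with the
#' threonine (offset 4) as acceptor; an SHT-class pattern can be expressed
#' the same way (e.g. `motif_pattern("SHT", 3, "SHT")`).
#'
#' @param regex Regular expression matched against the protein sequence.
#' @param acceptor_offset 1-based offset of the acceptor residue within a
#'   match.
#' @param id_prefix Prefix for generated motif ids.
#' @return list of class `motif_pattern`.
#' @export
motif_pattern <- function(regex = "[MILV][ED][MILV]T", acceptor_offset = 4L,
                          id_prefix = "MELT") {
  acceptor_offset <- as.integer(acceptor_offset)
  if (is.na(acceptor_offset) || acceptor_offset < 1L) {
    stop("pattern must define an acceptor slot (acceptor_offset >= 1)")
  }
  structure(list(regex = regex, acceptor_offset = acceptor_offset,
                 id_prefix = id_prefix),
            class = "motif_pattern")
}

#' Scan a protein for motif occurrences
#'
#' Finds all non-overlapping matches left-to-right and annotates each with the
#' acceptor position implied by the pattern. The acceptor residue must be
#' S, T or Y in the sequence.
#'
#' @param protein A single-row protein record or a sequence string.
#' @param pattern A [motif_pattern()].
#' @return data.frame `motif_id`, `start`, `end`, `acceptor_position`.
#' @examples
#' scan_motifs("MDLTXXMELT")   # two degenerate MELT-class motifs
#' @export
scan_motifs <- function(protein, pattern = motif_pattern()) {
  stopifnot(inherits(pattern, "motif_pattern"))
  sequence <- if (is.character(protein)) protein else protein$sequence[1]
  hits <- gregexpr(pattern$regex, sequence)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(motif_id = character(0), start = integer(0),
                      end = integer(0), acceptor_position = integer(0)))
  }
  starts <- as.integer(hits)
  lens <- attr(hits, "match.length")
  if (any(pattern$acceptor_offset > lens)) {
    stop("acceptor_offset falls outside a match")
  }
  acceptor <- starts + pattern$acceptor_offset - 1L
  acc_letter <- substring(sequence, acceptor, acceptor)
  if (any(!acc_letter %in% c("S", "T", "Y"))) {
    stop("pattern acceptor slot is not S/T/Y at position ",
         acceptor[which(!acc_letter %in% c("S", "T", "Y"))[1]])
  }
  data.frame(motif_id = paste0(pattern$id_prefix, seq_along(starts)),
             start = starts, end = starts + lens - 1L,
             acceptor_position = acceptor,
             stringsAsFactors = FALSE)
}

#' Load user-supplied motif coordinates
#'
#' Reads a motifs.tsv coordinate file and validates it against the protein:
#' coordinates in range, acceptor within the motif window, acceptor residue
#' one of S/T/Y. A user-supplied coordinate file is the authoritative path
#' (e.g. the literature's 19 established KNL1 MELT motifs); scanning is the
#' fallback convenience.
#'
#' @param path Path to a motifs.tsv file.
#' @param protein A single-row protein record or sequence string.
#' @return Validated data.frame of motif annotations.
#' @export
load_motifs <- function(path, protein) {
  tab <- read_motif_table(path)
  sequence <- if (is.character(protein)) protein else protein$sequence[1]
  n <- nchar(sequence)
  for (i in seq_len(nrow(tab))) {
    if (tab$start[i] < 1L || tab$end[i] > n || tab$start[i] > tab$end[i]) {
      stop("motif ", tab$motif_id[i], " out of range for a ", n, " aa protein")
    }
    if (tab$acceptor_position[i] < tab$start[i] ||
        tab$acceptor_position[i] > tab$end[i]) {
      stop("motif ", tab$motif_id[i], " acceptor outside the motif window")
    }
    letter <- substring(sequence, tab$acceptor_position[i], tab$acceptor_position[i])
    if (!letter %in% c("S", "T", "Y")) {
      stop("motif ", tab$motif_id[i], " acceptor residue '", letter,
           "' is not S/T/Y")
    }
  }
  tab
}

#' Count phosphorylated motifs per condition
#'
#' A motif counts as phosphorylated in a condition when its acceptor position
#' belongs to that condition's phospho-site set (`mode = "acceptor_only"`,
#' the default — MELT signaling runs through the acceptor threonine), or when
#' any residue of the motif window does (`mode = "any_in_window"`). The
#' overall count uses the union of all condition sets.
#'
#' @param sets Named list from [condition_site_sets()].
#' @param motifs Motif annotation data.frame ([scan_motifs()] or
#'   [load_motifs()]).
#' @param mode `"acceptor_only"` or `"any_in_window"`.
#' @return data.frame `condition`, `phosphorylated_motifs`, `total_motifs`;
#'   the distinct phosphorylated-motif count over the union is attached as
#'   attribute `overall`.
#' @export
phosphorylated_motif_counts <- function(sets, motifs,
                                        mode = c("acceptor_only", "any_in_window")) {
  mode <- match.arg(mode)
  hit <- function(site_set) {
    if (mode == "acceptor_only") {
      motifs$acceptor_position %in% site_set
    } else {
      vapply(seq_len(nrow(motifs)), function(i)
        any(seq(motifs$start[i], motifs$end[i]) %in% site_set), logical(1))
    }
  }
  out <- data.frame(condition = names(sets),
                    phosphorylated_motifs = vapply(sets, function(s)
                      sum(hit(s)), integer(1)),
                    total_motifs = nrow(motifs),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "overall") <- sum(hit(sort(unique(unlist(sets, use.names = FALSE)))))
  out
}
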