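# Independent brute-force oracles and tiny fixture builders. The oracles are
# deliberately naive (enumerate everything, count directly) so they share no
# code path with the implementation they check.

# All valid tryptic products of `sequence` with <= max_missed retained internal
# cleavage sites, by enumerating every (start, end) substring and testing the
# Keil-rule boundary conditions directly.
oracle_digest <- function(sequence, max_missed, min_len = 1L, max_len = 1000L) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # cut[i]: trypsin cuts between i and i+1
  cut <- logical(n)
  if (n > 1L) {
    cut[seq_len(n - 1L)] <- chars[seq_len(n - 1L)] %in% c("K", "R") &
      chars[2:n] != "P"
  }
  ncuts0 <- c(0L, cumsum(cut))   # ncuts0[i + 1] = cuts at positions <= i
  grid <- expand.grid(start = seq_len(n), end = seq_len(n))
  grid <- grid[grid$start <= grid$end, ]
  ok_start <- grid$start == 1L | cut[pmax(grid$start - 1L, 1L)]
  ok_end <- grid$end == n | cut[grid$end]
  # retained internal cut positions lie in start..end-1
  internal <- ncuts0[grid$end] - ncuts0[grid$start]
  len <- grid$end - grid$start + 1L
  keep <- ok_start & ok_end & internal <= max_missed &
    len >= min_len & len <= max_len
  out <- grid[keep, ]
  out$missed_cleavages <- as.integer(internal[keep])
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# Naive per-residue depth: loop over residues, count covering spans.
oracle_depth <- function(spans, protein_length) {
  vapply(seq_len(protein_length), function(i)
    sum(spans$start <= i & spans$end >= i), integer(1))
}

# Direct per-triple site-set oracle: a residue is in a condition's set iff
# some replicate row for it has count >= min_psms and confidence strictly
# above min_conf.
oracle_site_sets <- function(obs, design, thresholds) {
  sets <- list()
  for (cond in design$conditions) {
    hits <- integer(0)
    for (r in unique(obs$residue_index)) {
      for (rep_i in seq_len(design$n_replicates)) {
        row <- obs[obs$residue_index == r & obs$condition == cond &
                     obs$replicate == rep_i, ]
        if (nrow(row) == 1L &&
            !is.na(row$best_confidence) &&
            row$best_confidence > thresholds$min_confidence &&
            row$phospho_psm_count >= thresholds$min_phospho_psms) {
          hits <- c(hits, r)
        }
      }
    }
    sets[[cond]] <- sort(unique(hits))
  }
  sets
}

random_protein_sequence <- function(n, kr_freq = 0.2, p_freq = 0.1) {
  other <- c("A", "C", "D", "E", "G", "M", "S", "T", "V", "Y")
  probs <- c(kr_freq / 2, kr_freq / 2, p_freq,
             rep((1 - kr_freq - p_freq) / length(other), length(other)))
  paste(sample(c("K", "R", "P", other), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Observation table with counts and confidences clustered on the filter
# boundaries (counts 0..4, confidences including exactly 75).
random_observations <- function(design, n_residues = 8L) {
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      condition = design$conditions,
                      residue_index = sample(1000L, n_residues),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("residue_index", "condition", "replicate")]
  grid$residue_letter <- "S"
  grid$phospho_psm_count <- sample(0:4, nrow(grid), replace = TRUE)
  grid$best_confidence <- sample(c(50, 74.9, 75, 75.1, 90, 99.5, NA),
                                 nrow(grid), replace = TRUE)
  grid$best_confidence[grid$phospho_psm_count == 0L] <- NA
  grid$total_psm_count <- grid$phospho_psm_count + sample(0:10, nrow(grid), TRUE)
  class(grid) <- c("site_observations", "data.frame")
  grid
}

# Minimal valid PSM table around a short target protein.
tiny_psm_table <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    condition = c("DMSO", "DMSO", "nocodazole", "STLC"),
    replicate = c(1L, 1L, 2L, 1L),
    peptide_sequence = c("ELSSPK", "ELSSPK", "MTIDEK", "ELSSPK"),
    protein_accession = "P1",
    mods = c("S3(Phospho,99.1)", "S4(Phospho,80.0)",
             "T2(Phospho,75.0); M1(Oxidation)", ""),
    peptide_fdr = c(0.001, NA, 0.005, 0.02),
    stringsAsFactors = FALSE)
}

tiny_design <- function() knl1_design()

write_temp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(seq_len(nrow(records)), function(i)
    c(paste0(">", records$accession[i],
             ifelse(nzchar(records$description[i] %||% ""),
                    paste0(" ", records$description[i]), "")),
      records$sequence[i]))), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
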