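#' Configuration for the synthetic PSM generator
#'
#' The generator emulates the structure of a deep targeted AP-MS
#' phospho-proteomics experiment on a long scaffold protein: a 4-condition x
#' 3-replicate design, tryptic peptides of a >2000 aa target with roughly 10
#' percent K/R content, per-peptide spectral counts around a target mean
#' depth, planted phospho-sites whose occupancy depends on condition, a
#' localization-confidence model that separates true sites from decoys
#' imperfectly, and a low rate of spurious decoy phospho-assignments.
#'
#' @param protein_length Target protein length in residues (default 2342).
#' @param kr_freq Combined K+R frequency in the simulated sequence
#'   (default 0.10, giving realistic tryptic fragment lengths).
#' @param design An [experiment_design()] (default [knl1_design()]).
#' @param n_true_sites Number of planted phospho-sites (default 40); used
#'   only when `site_plan` is NULL.
#' @param site_plan Optional data.frame with columns `residue_letter` (S/T/Y)
#'   and one `occ_<condition>` column per condition (occupancies in \[0,1\]).
#'   By default a plan mixing shared-all, arrest-shared and condition-unique
#'   sites is built (see [default_site_plan()]).
#' @param mean_depth Target mean PSM depth per covered residue (default 20).
#' @param abundance_sigma Log-normal dispersion of per-peptide abundance
#'   (default 0.5).
#' @param conf_true,conf_decoy Beta shape pairs for localization confidences
#'   of true and decoy phospho placements, scaled to percent (defaults
#'   Beta(9,1) and Beta(2,4), so the 75 percent filter separates them
#'   imperfectly).
#' @param decoy_rate Probability that a PSM carries a spurious low-confidence
#'   phospho (default 0.01).
#' @param oxidation_rate Probability of a (carried, unused) methionine
#'   oxidation per PSM with an M (default 0.05).
#' @param target_accession Accession given to the simulated target.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(protein_length = 2342L, kr_freq = 0.10,
                              design = knl1_design(), n_true_sites = 40L,
                              site_plan = NULL, mean_depth = 20,
                              abundance_sigma = 0.5,
                              conf_true = c(9, 1), conf_decoy = c(2, 4),
                              decoy_rate = 0.01, oxidation_rate = 0.05,
                              target_accession = "SIMTARGET", seed = 1L) {
  if (protein_length < 50L) stop("protein_length must be >= 50")
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  if (is.null(site_plan)) site_plan <- default_site_plan(design, n_true_sites)
  occ_cols <- paste0("occ_", design$conditions)
  if (!all(occ_cols %in% names(site_plan))) {
    stop("site_plan must have one occ_<condition> column per condition")
  }
  occ <- as.matrix(site_plan[, occ_cols])
  if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]")
  structure(list(protein_length = as.integer(protein_length),
                 kr_freq = kr_freq, design = design,
                 site_plan = site_plan, mean_depth = mean_depth,
                 abundance_sigma = abundance_sigma, conf_true = conf_true,
                 conf_decoy = conf_decoy, decoy_rate = decoy_rate,
                 oxidation_rate = oxidation_rate,
                 target_accession = target_accession,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted-site plan
#'
#' Splits the planted sites 30/30/40 percent into shared-all sites
#' (occupancy 0.7 in every condition), arrest-shared sites (occupancy 0 in
#' the reference, 0.7 in each arrested condition) and condition-unique sites
#' (occupancy 0.8 in one condition, 0 elsewhere, cycling over conditions).
#' Residue classes cycle over S/T/Y with Y rare.
#'
#' @param design An [experiment_design()].
#' @param n_sites Total planted sites (default 40).
#' @return data.frame `site_class`, `residue_letter`, `occ_<condition>`
#'   columns.
#' @export
default_site_plan <- function(design, n_sites = 40L) {
  n_shared <- round(0.3 * n_sites)
  n_arrest <- round(0.3 * n_sites)
  n_unique <- n_sites - n_shared - n_arrest
  cls <- c(rep("shared_all", n_shared), rep("arrested_shared", n_arrest),
           rep("condition_unique", n_unique))
  plan <- data.frame(site_class = cls,
                     residue_letter = rep_len(c("S", "T", "S", "T", "Y"), n_sites),
                     stringsAsFactors = FALSE)
  # planted threonines get MELT sequence context, so the motif module is
  # exercised end-to-end on simulated data
  plan$melt_context <- plan$residue_letter == "T"
  for (cond in design$conditions) plan[[paste0("occ_", cond)]] <- 0
  plan[plan$site_class == "shared_all",
       paste0("occ_", design$conditions)] <- 0.7
  plan[plan$site_class == "arrested_shared",
       paste0("occ_", design$arrested)] <- 0.7
  uq <- which(plan$site_class == "condition_unique")
  uq_cond <- rep_len(design$conditions, length(uq))
  for (i in seq_along(uq)) {
    plan[uq[i], paste0("occ_", uq_cond[i])] <- 0.8
  }
  plan
}

#' Simulate the target protein with planted sites
#'
#' Draws a random amino-acid sequence with the configured K/R content, places
#' the planted sites of the site plan at positions that lie inside
#' detectable tryptic peptides (length 6-50 after full cleavage), at least 3
#' residues apart, and without touching K/R/P (so planting never changes the
#' cleavage pattern), and overwrites those positions with the planned S/T/Y
#' class.
#'
#' @param config A [simulation_config()].
#' @return One-row protein data.frame (`accession`, `description`,
#'   `sequence`) with the completed site plan (including `residue_index`)
#'   attached as attribute `site_plan`.
#' @export
simulate_protein <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$protein_length
  kr <- config$kr_freq
  aa <- c("A","C","D","E","F","G","H","I","L","M","N","P","Q","S","T","V","W","Y")
  w <- c(.09,.02,.06,.08,.04,.07,.03,.05,.09,.025,.05,.045,.05,.10,.08,.07,.015,.03)
  chars <- ifelse(stats::runif(n) < kr,
                  sample(c("K", "R"), n, replace = TRUE),
                  sample(aa, n, replace = TRUE, prob = w / sum(w)))
  plan <- config$site_plan
  n_sites <- nrow(plan)

  # positions must sit inside detectable peptides and leave digestion intact
  seq0 <- paste(chars, collapse = "")
  peps <- digest_protein(seq0, max_missed = 0L, min_len = 6L, max_len = 50L)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(peps))) covered[peps$start[i]:peps$end[i]] <- TRUE
  plain <- !chars %in% c("K", "R", "P")
  eligible <- which(covered & plain)
  melt <- if (is.null(plan$melt_context)) rep(FALSE, n_sites) else plan$melt_context
  # sites needing MELT context also need a clean 3-residue window upstream
  # (M/E/L are not K/R/P, so planting them never changes the digest)
  window_ok <- covered & plain
  window_ok[1:3] <- FALSE
  for (k in 1:3) window_ok <- window_ok & c(rep(FALSE, k), plain)[seq_len(n)]
  chosen <- rep(NA_integer_, n_sites)
  order_fill <- order(!melt)   # place the constrained MELT sites first
  pool <- sample(eligible)
  taken <- integer(0)
  for (s in order_fill) {
    need <- if (melt[s]) pool[window_ok[pool]] else pool
    ok <- need[vapply(need, function(p) all(abs(p - taken) >= 5L), logical(1))]
    if (length(ok) == 0L) {
      stop("could not place ", n_sites, " sites; increase protein_length")
    }
    chosen[s] <- ok[1]
    taken <- c(taken, ok[1])
    pool <- setdiff(pool, ok[1])
  }
  ord <- order(chosen)
  plan <- plan[ord, , drop = FALSE]
  chosen <- chosen[ord]
  rownames(plan) <- NULL
  chars[chosen] <- plan$residue_letter
  for (s in which(if (is.null(plan$melt_context)) rep(FALSE, n_sites) else plan$melt_context)) {
    chars[(chosen[s] - 3L):(chosen[s] - 1L)] <- c("M", "E", "L")
  }
  plan$residue_index <- chosen

  protein <- data.frame(accession = config$target_accession,
                        description = "synthetic phospho-target",
                        sequence = paste(chars, collapse = ""),
                        stringsAsFactors = FALSE)
  attr(protein, "site_plan") <- plan
  protein
}

# Analytic per-replicate probability that a planted site qualifies:
# phospho-PSM count ~ Poisson(mean_depth * occupancy); given k phospho-PSMs
# the best confidence exceeds the threshold unless all k independent
# Beta draws fall below it.
qualify_prob <- function(occ, mean_depth, conf_shape, thresholds) {
  lambda <- mean_depth * occ
  kmax <- max(20, ceiling(lambda + 10 * sqrt(lambda)))
  k <- thresholds$min_phospho_psms:kmax
  p_below <- stats::pbeta(thresholds$min_confidence / 100,
                          conf_shape[1], conf_shape[2])
  sum(stats::dpois(k, lambda) * (1 - p_below^k))
}

#' Expected classification for a site plan
#'
#' Computes, analytically from the occupancies and the sampling model, the
#' probability that each condition's replicate-union filter admits the site,
#' declares the condition active when that probability is at least 0.5, and
#' classifies the resulting membership pattern with the same shared /
#' arrest-shared / unique semantics as [classify_sites()]. Star expectation
#' uses the probability of detection (count >= count threshold) in at least
#' 2 replicates.
#'
#' @param config A [simulation_config()].
#' @param plan Completed site plan (with `residue_index`).
#' @param thresholds A [filter_thresholds()].
#' @return The plan with `expected_in_<condition>`, `expected_class` and
#'   `expected_starred` columns appended.
#' @export
expected_truth <- function(config, plan, thresholds = filter_thresholds()) {
  design <- config$design
  R <- design$n_replicates
  member <- matrix(FALSE, nrow(plan), length(design$conditions),
                   dimnames = list(NULL, design$conditions))
  for (cond in design$conditions) {
    occ <- plan[[paste0("occ_", cond)]]
    p_rep <- vapply(occ, qualify_prob, numeric(1),
                    mean_depth = config$mean_depth,
                    conf_shape = config$conf_true, thresholds = thresholds)
    member[, cond] <- (1 - (1 - p_rep)^R) >= 0.5
    plan[[paste0("expected_in_", cond)]] <- member[, cond]
  }
  n_cond <- rowSums(member)
  arrested_all <- rowSums(member[, design$arrested, drop = FALSE]) ==
    length(design$arrested)
  in_ref <- member[, design$reference]
  cls <- rep("other", nrow(plan))
  cls[n_cond == length(design$conditions)] <- "shared_all"
  cls[arrested_all & !in_ref] <- "arrested_shared"
  cls[n_cond == 1L] <- "condition_unique"
  cls[n_cond == 0L] <- "undetected"
  plan$expected_class <- cls

  starred <- rep(FALSE, nrow(plan))
  for (i in which(n_cond == 1L)) {
    cond <- design$conditions[which(member[i, ])]
    lam <- config$mean_depth * plan[[paste0("occ_", cond)]][i]
    p_det <- stats::ppois(thresholds$min_phospho_psms - 1L, lam,
                          lower.tail = FALSE)
    p_2of3 <- sum(stats::dbinom(2:R, R, p_det))
    starred[i] <- p_2of3 >= 0.5
  }
  plan$expected_starred <- starred
  plan
}

#' Simulate a PSM dataset with ground truth
#'
#' Fully cleaved tryptic peptides of the simulated target are assigned
#' log-normal abundances centred on the target mean depth; per (condition,
#' replicate) spectral counts are Poisson draws, expanded to one PSM row
#' each. Every PSM covering a planted site carries a phospho there with
#' probability equal to the site's occupancy in that PSM's condition
#' (confidence from the true-site Beta model); decoy phosphos are sprinkled
#' at `decoy_rate` on random S/T/Y positions with low-confidence draws, and
#' methionine oxidations are carried as inert modifications.
#'
#' @param config A [simulation_config()].
#' @param protein Output of [simulate_protein()] (defaults to generating it
#'   from `config`).
#' @return list with `psms` (a data.frame in the psm.tsv dialect), `truth`
#'   (the completed site plan with expected classifications, see
#'   [expected_truth()]), and `protein`.
#' @export
simulate_psm_dataset <- function(config, protein = simulate_protein(config)) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- attr(protein, "site_plan")
  design <- config$design
  set.seed(config$seed + 1L)

  peps <- digest_protein(protein$sequence[1], max_missed = 0L,
                         min_len = 6L, max_len = 50L)
  n_pep <- nrow(peps)
  lambda <- config$mean_depth *
    stats::rlnorm(n_pep, meanlog = -config$abundance_sigma^2 / 2,
                  sdlog = config$abundance_sigma)

  cells <- expand.grid(replicate = seq_len(design$n_replicates),
                       condition = design$conditions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pep_idx <- integer(0); cond <- character(0); repl <- integer(0)
  for (i in seq_len(nrow(cells))) {
    counts <- stats::rpois(n_pep, lambda)
    idx <- rep.int(seq_len(n_pep), counts)
    pep_idx <- c(pep_idx, idx)
    cond <- c(cond, rep.int(cells$condition[i], length(idx)))
    repl <- c(repl, rep.int(cells$replicate[i], length(idx)))
  }
  n_psm <- length(pep_idx)
  pstart <- peps$start[pep_idx]
  pseq <- peps$sequence[pep_idx]

  # modification assembly: true phosphos, decoys, inert oxidations
  mod_row <- integer(0); mod_letter <- character(0)
  mod_pos <- integer(0); mod_name <- character(0); mod_conf <- numeric(0)

  rows_by_pep <- split(seq_len(n_psm), pep_idx)
  occ_mat <- as.matrix(plan[, paste0("occ_", design$conditions)])
  colnames(occ_mat) <- design$conditions
  for (s in seq_len(nrow(plan))) {
    pos <- plan$residue_index[s]
    cover_pep <- which(peps$start <= pos & peps$end >= pos)
    rows <- unlist(rows_by_pep[as.character(cover_pep)], use.names = FALSE)
    if (length(rows) == 0L) next
    p_occ <- occ_mat[s, cond[rows]]
    hit <- rows[stats::runif(length(rows)) < p_occ]
    if (length(hit) == 0L) next
    mod_row <- c(mod_row, hit)
    mod_letter <- c(mod_letter, rep.int(plan$residue_letter[s], length(hit)))
    mod_pos <- c(mod_pos, pos - pstart[hit] + 1L)
    mod_name <- c(mod_name, rep.int("Phospho", length(hit)))
    mod_conf <- c(mod_conf, round(100 * stats::rbeta(length(hit),
                                                     config$conf_true[1],
                                                     config$conf_true[2]), 1))
  }

  sty_by_pep <- lapply(peps$sequence, function(s)
    which(strsplit(s, "", fixed = TRUE)[[1]] %in% c("S", "T", "Y")))
  decoy_rows <- which(stats::runif(n_psm) < config$decoy_rate)
  decoy_rows <- decoy_rows[lengths(sty_by_pep[pep_idx[decoy_rows]]) > 0L]
  if (length(decoy_rows) > 0L) {
    dpos <- vapply(decoy_rows, function(r) {
      cand <- sty_by_pep[[pep_idx[r]]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    dletter <- substr(pseq[decoy_rows], dpos, dpos)
    mod_row <- c(mod_row, decoy_rows)
    mod_letter <- c(mod_letter, dletter)
    mod_pos <- c(mod_pos, dpos)
    mod_name <- c(mod_name, rep.int("Phospho", length(decoy_rows)))
    mod_conf <- c(mod_conf, round(100 * stats::rbeta(length(decoy_rows),
                                                     config$conf_decoy[1],
                                                     config$conf_decoy[2]), 1))
  }

  m_by_pep <- lapply(peps$sequence, function(s)
    which(strsplit(s, "", fixed = TRUE)[[1]] == "M"))
  ox_rows <- which(stats::runif(n_psm) < config$oxidation_rate)
  ox_rows <- ox_rows[lengths(m_by_pep[pep_idx[ox_rows]]) > 0L]
  if (length(ox_rows) > 0L) {
    opos <- vapply(ox_rows, function(r) {
      cand <- m_by_pep[[pep_idx[r]]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    mod_row <- c(mod_row, ox_rows)
    mod_letter <- c(mod_letter, rep.int("M", length(ox_rows)))
    mod_pos <- c(mod_pos, opos)
    mod_name <- c(mod_name, rep.int("Oxidation", length(ox_rows)))
    mod_conf <- c(mod_conf, rep.int(NA_real_, length(ox_rows)))
  }

  # drop duplicate (row, position) placements (true phospho beats decoy)
  keep <- !duplicated(paste(mod_row, mod_pos, sep = "\r"))
  mod_row <- mod_row[keep]; mod_letter <- mod_letter[keep]
  mod_pos <- mod_pos[keep]; mod_name <- mod_name[keep]
  mod_conf <- mod_conf[keep]

  mods <- rep("", n_psm)
  if (length(mod_row) > 0L) {
    ord <- order(mod_row, mod_pos)
    term <- ifelse(is.na(mod_conf[ord]),
                   sprintf("%s%d(%s)", mod_letter[ord], mod_pos[ord], mod_name[ord]),
                   sprintf("%s%d(%s,%.1f)", mod_letter[ord], mod_pos[ord],
                           mod_name[ord], mod_conf[ord]))
    joined <- tapply(term, mod_row[ord], paste, collapse = "; ")
    mods[as.integer(names(joined))] <- as.character(joined)
  }

  psms <- data.frame(
    sample_id = sprintf("%s_r%d", cond, repl),
    condition = cond, replicate = repl,
    peptide_sequence = pseq,
    protein_accession = config$target_accession,
    mods = mods, peptide_fdr = NA_real_,
    stringsAsFactors = FALSE)

  truth <- expected_truth(config, plan)
  list(psms = psms, truth = truth, protein = protein)
}

#' Simulate interactor spectral counts
#'
#' Per-replicate PSM counts for a panel of co-purifying proteins are Poisson
#' draws around `baseline x multiplier`, with the reference condition's
#' multiplier fixed at 1. The analytically expected pseudocount fold change,
#' `(baseline x multiplier + 1) / (baseline + 1)`, is attached as attribute
#' `expected_fc`.
#'
#' @param design An [experiment_design()].
#' @param baseline Named numeric vector: expected reference-condition PSM
#'   count per protein.
#' @param multipliers Numeric matrix (proteins x conditions, dimnames
#'   required) of condition multipliers; the reference column must be 1.
#' @param seed Integer seed.
#' @return data.frame `protein_accession`, `condition`, `replicate`, `count`.
#' @export
simulate_interactor_counts <- function(design, baseline, multipliers, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            !is.null(names(baseline)),
            identical(sort(rownames(multipliers)), sort(names(baseline))),
            all(design$conditions %in% colnames(multipliers)))
  if (any(multipliers[, design$reference] != 1)) {
    stop("reference-condition multipliers must equal 1")
  }
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      condition = design$conditions,
                      protein_accession = names(baseline),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("protein_accession", "condition", "replicate")]
  mu <- baseline[grid$protein_accession] *
    multipliers[cbind(grid$protein_accession, grid$condition)]
  grid$count <- stats::rpois(nrow(grid), mu)
  expected <- (baseline[rownames(multipliers)] * multipliers + 1) /
    (baseline[rownames(multipliers)] + 1)
  attr(grid, "expected_fc") <- expected
  grid
}
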