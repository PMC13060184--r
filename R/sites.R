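#' Aggregate phospho evidence per (residue, condition, replicate)
#'
#' For every residue with any phospho evidence anywhere in the experiment, one
#' observation is produced for every (condition, replicate) cell of the
#' design — zero-count observations are synthesized for cells without
#' evidence, so that per-condition averages include zeros. The phospho-PSM
#' count is the number of PSMs carrying a Phospho at that residue in that
#' replicate; the confidence kept is the maximum across those PSMs (a single
#' well-localized PSM establishes the site).
#'
#' @param mapped A `mapped_psms` object.
#' @param design An [experiment_design()].
#' @param depth Optional named list `condition` -> `replicate` -> depth vector
#'   (from [condition_coverage()]); when given, each observation also records
#'   the total PSM count covering the residue.
#' @return data.frame of class `site_observations` with columns
#'   `residue_index`, `residue_letter`, `condition`, `replicate`,
#'   `phospho_psm_count`, `best_confidence`, `total_psm_count`.
#' @export
extract_site_observations <- function(mapped, design, depth = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  ph <- mapped$phospho
  residues <- sort(unique(ph$residue_index))
  letters_at <- ph$residue_letter[match(residues, ph$residue_index)]

  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      condition = design$conditions,
                      residue_index = residues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("residue_index", "condition", "replicate")]
  grid$residue_letter <- letters_at[match(grid$residue_index, residues)]

  if (nrow(ph) > 0L) {
    key <- function(res, cond, rep) paste(res, cond, rep, sep = "\r")
    k_obs <- key(ph$residue_index, ph$condition, ph$replicate)
    counts <- tapply(rep(1L, nrow(ph)), k_obs, sum)
    best <- tapply(ph$confidence, k_obs, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    k_grid <- key(grid$residue_index, grid$condition, grid$replicate)
    m <- match(k_grid, names(counts))
    grid$phospho_psm_count <- ifelse(is.na(m), 0L, as.integer(counts[m]))
    grid$best_confidence <- as.numeric(best[m])
  } else {
    grid$phospho_psm_count <- integer(0)
    grid$best_confidence <- numeric(0)
  }

  grid$total_psm_count <- rep(NA_integer_, nrow(grid))
  if (!is.null(depth)) {
    for (cond in design$conditions) {
      for (r in seq_len(design$n_replicates)) {
        sel <- grid$condition == cond & grid$replicate == r
        grid$total_psm_count[sel] <- depth[[cond]][[r]][grid$residue_index[sel]]
      }
    }
  }
  rownames(grid) <- NULL
  class(grid) <- c("site_observations", "data.frame")
  grid
}

#' Does a site observation qualify?
#'
#' A replicate-level observation qualifies when its best localization
#' confidence is strictly greater than the confidence threshold and its
#' phospho-PSM count meets the count threshold. A missing confidence with a
#' nonzero count never qualifies. Vectorised.
#'
#' @param phospho_psm_count Integer vector of per-replicate phospho-PSM counts.
#' @param best_confidence Numeric vector of confidences (percent), NA allowed.
#' @param thresholds A [filter_thresholds()].
#' @return Logical vector.
#' @examples
#' qualifies(2, 80)            # TRUE
#' qualifies(2, 75)            # FALSE: the confidence bound is strict
#' qualifies(1, 99)            # FALSE: needs >= 2 phospho-PSMs
#' @export
qualifies <- function(phospho_psm_count, best_confidence,
                      thresholds = filter_thresholds()) {
  !is.na(best_confidence) &
    best_confidence > thresholds$min_confidence &
    phospho_psm_count >= thresholds$min_phospho_psms
}

#' Build per-condition phospho-site sets
#'
#' Under the default `mode = "per_replicate"` a residue belongs to a
#' condition's site set when it qualifies in at least one replicate of that
#' condition (the filter is applied per replicate, then replicates are
#' unioned). `mode = "pooled"` instead sums counts across replicates and takes
#' the best confidence overall before applying the thresholds once per
#' condition.
#'
#' @param obs A `site_observations` data.frame.
#' @param design An [experiment_design()].
#' @param thresholds A [filter_thresholds()].
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @return Named list, one sorted integer vector of residue indices per
#'   condition.
#' @export
condition_site_sets <- function(obs, design, thresholds = filter_thresholds(),
                                mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  sets <- vector("list", length(design$conditions))
  names(sets) <- design$conditions
  for (cond in design$conditions) {
    sub <- obs[obs$condition == cond, , drop = FALSE]
    if (mode == "per_replicate") {
      ok <- qualifies(sub$phospho_psm_count, sub$best_confidence, thresholds)
      sets[[cond]] <- sort(unique(sub$residue_index[ok]))
    } else {
      total <- tapply(sub$phospho_psm_count, sub$residue_index, sum)
      best <- tapply(sub$best_confidence, sub$residue_index, function(x) {
        if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
      })
      res <- as.integer(names(total))
      ok <- qualifies(as.integer(total), as.numeric(best), thresholds)
      sets[[cond]] <- sort(res[ok])
    }
  }
  sets
}

#' Average phospho-PSM counts per (residue, condition)
#'
#' The arithmetic mean of the raw replicate phospho-PSM counts over all
#' declared replicates, zeros included and independent of the qualification
#' filter — e.g. counts (2, 0, 0) in a 3-replicate design average to 0.67.
#'
#' @param obs A `site_observations` data.frame (zero observations synthesized
#'   by [extract_site_observations()]).
#' @param design An [experiment_design()].
#' @return data.frame `residue_index`, `condition`, `avg_phospho_psms`.
#' @export
site_averages <- function(obs, design) {
  if (nrow(obs) == 0L) {
    return(data.frame(residue_index = integer(0), condition = character(0),
                      avg_phospho_psms = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(obs$residue_index, obs$condition, sep = "\r")
  avg <- tapply(obs$phospho_psm_count, key, function(x) sum(x) / design$n_replicates)
  parts <- strsplit(names(avg), "\r", fixed = TRUE)
  out <- data.frame(residue_index = as.integer(vapply(parts, `[`, "", 1L)),
                    condition = vapply(parts, `[`, "", 2L),
                    avg_phospho_psms = as.numeric(avg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_index, match(out$condition, design$conditions)), ]
  rownames(out) <- NULL
  out
}

#' Classify sites across conditions
#'
#' Each residue in the union of the condition site sets receives exactly one
#' label: `shared_all` (present in every condition's set), `arrested_shared`
#' (present in every mitotically arrested condition's set and absent from the
#' reference set), `condition_unique` (present in exactly one set), or
#' `other`. A condition-unique site is starred when it was detected in at
#' least 2 replicates of its condition; "detected" means a per-replicate
#' phospho-PSM count reaching the count threshold (`star_mode =
#' "any_evidence"`, the default) or full per-replicate qualification
#' including the confidence bound (`star_mode = "qualifying"`).
#'
#' @param sets Named list from [condition_site_sets()].
#' @param design An [experiment_design()].
#' @param obs The `site_observations` the sets were built from (used for the
#'   star rule).
#' @param thresholds A [filter_thresholds()].
#' @param star_mode `"any_evidence"` (default) or `"qualifying"`.
#' @param min_star_replicates Replicate support required for a star
#'   (default 2).
#' @return data.frame `residue_index`, `residue_letter`, `n_conditions`,
#'   `classification`, `unique_condition`, `starred`.
#' @export
classify_sites <- function(sets, design, obs,
                           thresholds = filter_thresholds(),
                           star_mode = c("any_evidence", "qualifying"),
                           min_star_replicates = 2L) {
  star_mode <- match.arg(star_mode)
  residues <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(residues) == 0L) {
    return(data.frame(residue_index = integer(0), residue_letter = character(0),
                      n_conditions = integer(0), classification = character(0),
                      unique_condition = character(0), starred = logical(0),
                      stringsAsFactors = FALSE))
  }
  membership <- vapply(design$conditions,
                       function(cond) residues %in% sets[[cond]],
                       logical(length(residues)))
  membership <- matrix(membership, nrow = length(residues),
                       dimnames = list(NULL, design$conditions))
  n_cond <- rowSums(membership)
  arrested_all <- rowSums(membership[, design$arrested, drop = FALSE]) ==
    length(design$arrested)
  in_ref <- membership[, design$reference]

  classification <- rep("other", length(residues))
  classification[n_cond == length(design$conditions)] <- "shared_all"
  classification[arrested_all & !in_ref] <- "arrested_shared"
  classification[n_cond == 1L] <- "condition_unique"

  unique_condition <- rep(NA_character_, length(residues))
  uq <- which(n_cond == 1L)
  if (length(uq) > 0L) {
    unique_condition[uq] <- design$conditions[
      apply(membership[uq, , drop = FALSE], 1L, which)]
  }

  # replicate support for the star rule
  starred <- rep(FALSE, length(residues))
  for (i in uq) {
    sub <- obs[obs$residue_index == residues[i] &
                 obs$condition == unique_condition[i], , drop = FALSE]
    detected <- if (star_mode == "qualifying") {
      qualifies(sub$phospho_psm_count, sub$best_confidence, thresholds)
    } else {
      sub$phospho_psm_count >= thresholds$min_phospho_psms
    }
    starred[i] <- sum(detected) >= min_star_replicates
  }

  letters_at <- obs$residue_letter[match(residues, obs$residue_index)]
  data.frame(residue_index = residues,
             residue_letter = letters_at,
             n_conditions = as.integer(n_cond),
             classification = classification,
             unique_condition = unique_condition,
             starred = starred,
             stringsAsFactors = FALSE)
}

#' Venn partition of the condition site sets
#'
#' Partitions the union of all sites over the 2^k - 1 non-empty membership
#' patterns and reports the count in each occupied cell plus the total number
#' of distinct sites.
#'
#' @param sets Named list of residue-index vectors per condition.
#' @return data.frame `membership_pattern` (condition names joined by `&`, in
#'   design order), `count`; the union size is attached as attribute `total`
#'   and also printed by [run_pipeline()].
#' @export
venn_counts <- function(sets) {
  conds <- names(sets)
  residues <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(residues) == 0L) {
    out <- data.frame(membership_pattern = character(0), count = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  pattern <- vapply(residues, function(r) {
    paste(conds[vapply(conds, function(cn) r %in% sets[[cn]], logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(pattern)
  out <- data.frame(membership_pattern = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$membership_pattern), ]
  rownames(out) <- NULL
  attr(out, "total") <- length(residues)
  out
}

# Wide per-site report table: one row per residue, per-condition replicate
# counts (semicolon-joined), qualifying replicate tally, zero-inclusive
# average, and set membership, then the cross-condition classification.
site_table <- function(obs, sets, classes, design,
                       thresholds = filter_thresholds()) {
  if (nrow(classes) == 0L && nrow(obs) == 0L) {
    cols <- c("residue_index", "residue_letter",
              unlist(lapply(design$conditions, function(cn)
                paste0(cn, c("_counts", "_qualifying_reps", "_avg", "_in_set")))),
              "classification", "starred", "unique_condition")
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  residues <- sort(unique(obs$residue_index))
  out <- data.frame(residue_index = residues,
                    residue_letter = obs$residue_letter[match(residues, obs$residue_index)],
                    stringsAsFactors = FALSE)
  avgs <- site_averages(obs, design)
  for (cond in design$conditions) {
    sub <- obs[obs$condition == cond, , drop = FALSE]
    sub <- sub[order(sub$residue_index, sub$replicate), , drop = FALSE]
    counts <- tapply(sub$phospho_psm_count, sub$residue_index,
                     paste, collapse = ";")
    qual <- tapply(qualifies(sub$phospho_psm_count, sub$best_confidence, thresholds),
                   sub$residue_index, sum)
    a <- avgs[avgs$condition == cond, , drop = FALSE]
    out[[paste0(cond, "_counts")]] <- as.character(counts[as.character(residues)])
    out[[paste0(cond, "_qualifying_reps")]] <-
      as.integer(qual[as.character(residues)])
    out[[paste0(cond, "_avg")]] <-
      a$avg_phospho_psms[match(residues, a$residue_index)]
    out[[paste0(cond, "_in_set")]] <- residues %in% sets[[cond]]
  }
  m <- match(residues, classes$residue_index)
  out$classification <- ifelse(is.na(m), "unclassified", classes$classification[m])
  out$starred <- ifelse(is.na(m), FALSE, classes$starred[m])
  out$unique_condition <- classes$unique_condition[m]
  out
}
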