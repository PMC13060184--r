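make_mapped <- function(phospho, protein_length = 100L) {
  structure(list(spans = data.frame(psm_id = integer(0), condition = character(0),
                                    replicate = integer(0), start = integer(0),
                                    end = integer(0), multi_mapped = logical(0)),
                 phospho = phospho, n_unmapped = 0L, n_ambiguous = 0L,
                 protein_length = protein_length),
            class = "mapped_psms")
}

test_that("site observations aggregate counts, keep max confidence, synthesize zeros", {
  design <- tiny_design()
  ph <- data.frame(psm_id = 1:3,
                   condition = c("STLC", "STLC", "STLC"),
                   replicate = c(1L, 1L, 1L),
                   residue_index = c(12L, 12L, 20L),
                   residue_letter = c("S", "S", "T"),
                   confidence = c(99.1, 80.0, 90.0))
  obs <- extract_site_observations(make_mapped(ph), design)
  # full grid: 2 residues x 4 conditions x 3 replicates
  expect_equal(nrow(obs), 24L)
  r12 <- obs[obs$residue_index == 12L & obs$condition == "STLC" &
               obs$replicate == 1L, ]
  expect_equal(r12$phospho_psm_count, 2L)
  expect_equal(r12$best_confidence, 99.1)
  # zero-count cells synthesized for the other replicates and conditions
  zeros <- obs[!(obs$condition == "STLC" & obs$replicate == 1L), ]
  expect_true(all(zeros$phospho_psm_count == 0L))
  # one PSM carrying phosphos at two residues counts once at each residue
  ph2 <- data.frame(psm_id = c(1L, 1L), condition = "DMSO", replicate = 1L,
                    residue_index = c(5L, 9L), residue_letter = "S",
                    confidence = 95)
  obs2 <- extract_site_observations(make_mapped(ph2), design)
  got <- obs2[obs2$condition == "DMSO" & obs2$replicate == 1L, ]
  expect_equal(got$phospho_psm_count[order(got$residue_index)], c(1L, 1L))
})

test_that("qualification is strict on confidence and inclusive on count", {
  expect_true(qualifies(2, 80))
  expect_false(qualifies(2, 75))     # strict > 75
  expect_true(qualifies(2, 75 + 1e-9))
  expect_false(qualifies(1, 99))
  expect_false(qualifies(3, NA))     # missing confidence never qualifies
  t2 <- filter_thresholds(min_confidence = 90, min_phospho_psms = 3)
  expect_false(qualifies(2, 95, t2))
  expect_true(qualifies(3, 90.1, t2))
})

test_that("condition sets are the union of qualifying replicates", {
  design <- tiny_design()
  obs <- random_observations(design, n_residues = 1L)
  obs$phospho_psm_count <- 0L
  obs$best_confidence <- NA_real_
  r <- obs$residue_index[1]
  sel <- obs$condition == "DMSO" & obs$replicate == 1L
  obs$phospho_psm_count[sel] <- 2L
  obs$best_confidence[sel] <- 80
  sets <- condition_site_sets(obs, design)
  expect_equal(sets$DMSO, r)                    # one qualifying replicate suffices
  expect_equal(sets$nocodazole, integer(0))
  # (1,1,1) across replicates never reaches the per-replicate count bound
  obs$phospho_psm_count[obs$condition == "STLC"] <- 1L
  obs$best_confidence[obs$condition == "STLC"] <- 99
  sets <- condition_site_sets(obs, design)
  expect_equal(sets$STLC, integer(0))
  # ... but pooled semantics admits it (3 summed phospho-PSMs)
  pooled <- condition_site_sets(obs, design, mode = "pooled")
  expect_equal(pooled$STLC, r)
})

test_that("condition sets match the per-triple oracle on randomized tables", {
  design <- tiny_design()
  th <- filter_thresholds()
  set.seed(99)
  for (i in 1:60) {
    obs <- random_observations(design)
    expect_equal(condition_site_sets(obs, design, th),
                 oracle_site_sets(obs, design, th))
  }
})

test_that("tightening thresholds never grows a condition set", {
  design <- tiny_design()
  set.seed(100)
  for (i in 1:20) {
    obs <- random_observations(design)
    loose <- condition_site_sets(obs, design, filter_thresholds(70, 1))
    tight <- condition_site_sets(obs, design, filter_thresholds(80, 3))
    for (cond in design$conditions) {
      expect_true(all(tight[[cond]] %in% loose[[cond]]))
    }
  }
})

test_that("site averages are zero-inclusive raw means at report granularity", {
  design <- tiny_design()
  obs <- random_observations(design, n_residues = 1L)
  obs$phospho_psm_count <- 0L
  obs$phospho_psm_count[obs$condition == "nocodazole"] <- c(2L, 0L, 0L)
  obs$phospho_psm_count[obs$condition == "DMSO"] <- c(17L, 17L, 17L)
  avg <- site_averages(obs, design)
  expect_equal(avg$avg_phospho_psms[avg$condition == "nocodazole"], 2 / 3)
  expect_equal(round(avg$avg_phospho_psms[avg$condition == "nocodazole"], 2), 0.67)
  expect_equal(avg$avg_phospho_psms[avg$condition == "DMSO"], 17)
  # counts are integers, so avg x n_replicates always is too
  set.seed(5)
  obs2 <- random_observations(design)
  avg2 <- site_averages(obs2, design)
  expect_equal(avg2$avg_phospho_psms * design$n_replicates,
               round(avg2$avg_phospho_psms * design$n_replicates))
})

test_that("classification partitions sites into the four labels", {
  design <- tiny_design()
  obs <- random_observations(design, n_residues = 4L)
  res <- sort(unique(obs$residue_index))
  sets <- list(DMSO = res[c(1, 4)],
               nocodazole = c(res[1], res[2], res[3]),
               paclitaxel = c(res[1], res[2], res[4]),
               STLC = c(res[1], res[2]))
  # give residue 3 evidence in >= 2 nocodazole replicates for the star rule
  obs$phospho_psm_count <- 0L
  obs$best_confidence <- NA_real_
  sel <- obs$residue_index == res[3] & obs$condition == "nocodazole" &
    obs$replicate <= 2L
  obs$phospho_psm_count[sel] <- 2L
  obs$best_confidence[sel] <- 95
  cls <- classify_sites(sets, design, obs)
  expect_equal(cls$classification[cls$residue_index == res[1]], "shared_all")
  expect_equal(cls$classification[cls$residue_index == res[2]], "arrested_shared")
  expect_equal(cls$classification[cls$residue_index == res[3]], "condition_unique")
  expect_equal(cls$unique_condition[cls$residue_index == res[3]], "nocodazole")
  expect_true(cls$starred[cls$residue_index == res[3]])
  expect_equal(cls$classification[cls$residue_index == res[4]], "other")
  # labels partition the union of the sets
  expect_equal(sort(cls$residue_index), res)
  expect_true(all(cls$classification %in%
                    c("shared_all", "arrested_shared", "condition_unique", "other")))

  # a unique site with single-replicate support is not starred
  obs$phospho_psm_count[sel & obs$replicate == 2L] <- 0L
  obs$best_confidence[sel & obs$replicate == 2L] <- NA
  cls1 <- classify_sites(sets, design, obs)
  expect_false(cls1$starred[cls1$residue_index == res[3]])
  # the qualifying star mode also demands the confidence bound per replicate
  obs$phospho_psm_count[sel] <- 2L
  obs$best_confidence[sel] <- 60
  clsq <- classify_sites(sets, design, obs, star_mode = "qualifying")
  expect_false(clsq$starred[clsq$residue_index == res[3]])
})

test_that("venn cells partition the union of sites", {
  sets <- list(A = c(1L, 2L), B = c(2L, 3L))
  v <- venn_counts(sets)
  expect_equal(attr(v, "total"), 3L)
  expect_equal(v$count[v$membership_pattern == "A"], 1L)
  expect_equal(v$count[v$membership_pattern == "A&B"], 1L)
  expect_equal(v$count[v$membership_pattern == "B"], 1L)
  expect_equal(sum(v$count), attr(v, "total"))
  same <- venn_counts(list(A = 1:3, B = 1:3))
  expect_equal(same$membership_pattern, "A&B")
  expect_equal(same$count, 3L)
  disj <- venn_counts(list(A = 1L, B = 2L))
  expect_false("A&B" %in% disj$membership_pattern)
  # random sets: conservation always holds
  set.seed(7)
  for (i in 1:20) {
    s <- lapply(1:4, function(j) sample(30L, sample(0:10, 1)))
    names(s) <- letters[1:4]
    v <- venn_counts(s)
    expect_equal(sum(v$count), length(unique(unlist(s))))
  }
})
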