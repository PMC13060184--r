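small_config <- function(seed = 1L, ...) {
  simulation_config(protein_length = 600L, n_true_sites = 10L,
                    seed = seed, ...)
}

test_that("the simulated protein is reproducible with planted residues in place", {
  cfg <- small_config(seed = 5L)
  p1 <- simulate_protein(cfg)
  p2 <- simulate_protein(cfg)
  expect_identical(p1$sequence, p2$sequence)
  plan <- attr(p1, "site_plan")
  planted <- substring(p1$sequence, plan$residue_index, plan$residue_index)
  expect_equal(planted, plan$residue_letter)
  # MELT-context threonines carry the motif and are found by the scanner
  melt <- plan[plan$melt_context, ]
  found <- scan_motifs(p1)
  expect_true(all(melt$residue_index %in% found$acceptor_position))
  expect_error(simulation_config(protein_length = 20L), ">= 50")
})

test_that("simulated K/R content tracks the configured frequency", {
  set.seed(1)
  fracs <- vapply(1:15, function(i) {
    p <- simulate_protein(simulation_config(protein_length = 1000L,
                                            kr_freq = 0.1, seed = i))
    # exclude planted positions (forced to S/T/Y) from the tally
    lengths(regmatches(p$sequence, gregexpr("[KR]", p$sequence))) / 1000
  }, numeric(1))
  expect_gt(mean(fracs), 0.08)
  expect_lt(mean(fracs), 0.12)
})

test_that("a fixed seed reproduces the PSM table byte for byte", {
  cfg <- small_config(seed = 9L)
  s1 <- simulate_psm_dataset(cfg)
  s2 <- simulate_psm_dataset(cfg)
  expect_identical(s1$psms, s2$psms)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(s1$psms, f1)
  write_psm_table(s2$psms, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the emitted PSM table is valid against its own design", {
  cfg <- small_config(seed = 2L)
  sim <- simulate_psm_dataset(cfg)
  v <- validate_psm_table(sim$psms, cfg$design)
  expect_equal(nrow(v), nrow(sim$psms))
  expect_equal(attr(v, "n_fdr_filtered"), 0L)
})

test_that("occupancy drives per-site phospho evidence", {
  design <- knl1_design()
  plan <- data.frame(site_class = c("none", "full"),
                     residue_letter = c("S", "S"),
                     melt_context = FALSE,
                     occ_DMSO = c(0, 1), occ_nocodazole = c(0, 1),
                     occ_paclitaxel = c(0, 1), occ_STLC = c(0, 1))
  cfg <- simulation_config(protein_length = 600L, site_plan = plan,
                           decoy_rate = 0, oxidation_rate = 0, seed = 31L)
  sim <- simulate_psm_dataset(cfg)
  flat <- phosphostate:::parse_mods_flat(sim$psms$mods)
  pos_zero <- sim$truth$residue_index[sim$truth$site_class == "none"]
  pos_full <- sim$truth$residue_index[sim$truth$site_class == "full"]
  mapped <- map_psms(validate_psm_table(sim$psms, design),
                     sim$protein$sequence)
  # occupancy 0: no phospho-PSM ever lands there (no decoys configured)
  expect_equal(sum(mapped$phospho$residue_index == pos_zero), 0L)
  # occupancy 1: every covering PSM carries the phospho
  depth <- per_position_depth(mapped$spans, nchar(sim$protein$sequence))
  expect_equal(sum(mapped$phospho$residue_index == pos_full), depth[pos_full])
})

test_that("expected classifications derive correctly from the occupancy plan", {
  cfg <- simulation_config(seed = 1L)
  plan <- attr(simulate_protein(cfg), "site_plan")
  truth <- expected_truth(cfg, plan)
  # with the default depth and occupancies every planted class is expected
  expect_equal(truth$expected_class, truth$site_class)
  # condition-unique sites at occupancy 0.8 and depth 20 should be starred
  expect_true(all(truth$expected_starred[truth$site_class == "condition_unique"]))
  expect_false(any(truth$expected_starred[truth$site_class != "condition_unique"]))
  # a site dead everywhere is expected undetected
  plan0 <- plan
  plan0[1, paste0("occ_", cfg$design$conditions)] <- 0
  expect_equal(expected_truth(cfg, plan0)$expected_class[1], "undetected")
})

test_that("interactor count simulation validates its multiplier contract", {
  design <- knl1_design()
  b <- c(X = 10)
  m_bad <- matrix(c(2, 1, 1, 1), 1, 4,
                  dimnames = list("X", design$conditions))
  expect_error(simulate_interactor_counts(design, b, m_bad), "reference")
})
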