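test_that("pseudocount fold changes follow the closed forms", {
  design <- knl1_design(n_replicates = 1L)
  counts <- data.frame(
    protein_accession = rep(c("NDC80", "BUB1"), each = 4),
    condition = rep(design$conditions, 2),
    replicate = 1L,
    count = c(4, 24, 4, 4,    # NDC80: avg 24 vs ref 4 -> (24+1)/(4+1) = 5
              0, 4, 0, 0))    # BUB1: ref avg 0 -> FC = avg + 1
  fc <- fold_change_matrix(counts, design)
  get <- function(p, c) fc$fold_change[fc$protein_accession == p & fc$condition == c]
  expect_identical(get("NDC80", "DMSO"), 1)       # reference is exactly 1
  expect_equal(get("NDC80", "nocodazole"), 5)
  expect_equal(get("BUB1", "nocodazole"), 5)      # zero reference: avg + 1
  expect_identical(get("BUB1", "DMSO"), 1)
  expect_true(all(fc$fold_change > 0))
})

test_that("fold change averages replicates with zeros for absent cells", {
  design <- knl1_design(n_replicates = 3L)
  # only one replicate observed: avg = 9/3 = 3 -> FC = (3+1)/(0+1) = 4
  counts <- data.frame(protein_accession = "TTK", condition = "STLC",
                       replicate = 1L, count = 9)
  fc <- fold_change_matrix(counts, design)
  expect_equal(fc$avg_psms[fc$condition == "STLC"], 3)
  expect_equal(fc$fold_change[fc$condition == "STLC"], 4)
  # replicate order is irrelevant
  c2 <- data.frame(protein_accession = "TTK", condition = "STLC",
                   replicate = c(3L, 1L, 2L), count = c(3, 3, 3))
  c3 <- data.frame(protein_accession = "TTK", condition = "STLC",
                   replicate = c(1L, 2L, 3L), count = c(3, 3, 3))
  expect_equal(fold_change_matrix(c2, design)$fold_change,
               fold_change_matrix(c3, design)$fold_change)
})

test_that("equal counts everywhere give unit fold changes; monotonicity holds", {
  design <- knl1_design()
  grid <- expand.grid(replicate = 1:3, condition = design$conditions,
                      protein_accession = "MIS12", stringsAsFactors = FALSE)
  grid$count <- 7
  fc <- fold_change_matrix(grid, design)
  expect_equal(fc$fold_change, rep(1, 4))
  # FC strictly increases in the condition average
  grid2 <- grid; grid2$count[grid2$condition == "STLC"] <- 8
  fc2 <- fold_change_matrix(grid2, design)
  expect_true(fc2$fold_change[fc2$condition == "STLC"] >
                fc$fold_change[fc$condition == "STLC"])
  # ... and strictly decreases in the reference average
  grid3 <- grid; grid3$count[grid3$condition == "DMSO"] <- 8
  fc3 <- fold_change_matrix(grid3, design)
  expect_true(fc3$fold_change[fc3$condition == "STLC"] <
                fc$fold_change[fc$condition == "STLC"])
  expect_error(fold_change_matrix(transform(grid, count = -1), design), ">= 0")
})

test_that("per-replicate pseudocount staging is a distinct but consistent statistic", {
  design <- knl1_design()
  grid <- expand.grid(replicate = 1:3, condition = design$conditions,
                      protein_accession = "ZW10", stringsAsFactors = FALSE)
  grid$count <- c(5, 5, 5, 20, 20, 20, 5, 5, 5, 5, 5, 5)
  a <- fold_change_matrix(grid, design, pseudocount_stage = "after_average")
  b <- fold_change_matrix(grid, design, pseudocount_stage = "per_replicate")
  # identical replicate counts: both stagings agree, reference stays 1
  expect_equal(a$fold_change, b$fold_change)
  expect_identical(b$fold_change[b$condition == "DMSO"], 1)
})

test_that("simulated multiplier-5 interactors recover their fold change", {
  design <- knl1_design()
  baseline <- c(NDC80 = 40, BUB1 = 25, MIS12 = 60)
  mult <- matrix(1, 3, 4, dimnames = list(names(baseline), design$conditions))
  mult[, "STLC"] <- 5
  counts <- simulate_interactor_counts(design, baseline, mult, seed = 17L)
  fc <- fold_change_matrix(counts, design)
  expected <- attr(counts, "expected_fc")
  for (p in names(baseline)) {
    got <- fc$fold_change[fc$protein_accession == p & fc$condition == "STLC"]
    expect_equal(got, expected[p, "STLC"], tolerance = 0.15)
  }
  # reference column is exactly 1; multiplier-1 conditions hover near 1
  expect_true(all(fc$fold_change[fc$condition == "DMSO"] == 1))
  expect_true(all(abs(fc$fold_change[fc$condition == "nocodazole"] - 1) < 0.5))
  # zero-baseline protein: pseudocount dominates, FC ~ 1
  b0 <- c(GHOST = 0)
  m0 <- matrix(c(1, 7, 7, 7), 1, 4,
               dimnames = list("GHOST", design$conditions))
  c0 <- simulate_interactor_counts(design, b0, m0, seed = 3L)
  fc0 <- fold_change_matrix(c0, design)
  expect_equal(fc0$fold_change, rep(1, 4))
})
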