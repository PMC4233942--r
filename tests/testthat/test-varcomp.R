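test_that("PCA component count tracks the cumulative PVE target", {
  d <- tiny_design(2, 3)
  ## rank-1 matrix: one component, pve 1
  v <- matrix(rnorm(6), 1)
  m <- matrix(rep(v, each = 4), 4, dimnames = list(sprintf("g%d", 1:4),
                                                   d$sample_id))
  m <- m * c(1, 2, 3, 4)
  pc <- omics_pca(omics_matrix(m, d))
  expect_equal(length(pc$pve), 1)
  expect_equal(pc$pve[1], 1, tolerance = 1e-12)
  expect_error(omics_pca(omics_matrix(matrix(1, 3, 6,
                                             dimnames = list(letters[1:3],
                                                             d$sample_id)),
                                      d)),
               "rank")
})

test_that("PCA agrees with a direct SVD oracle", {
  d <- generate_design(5, 2, "BM")
  set.seed(6)
  m <- matrix(rnorm(200), 20, dimnames = list(sprintf("g%d", 1:20),
                                              d$sample_id))
  pc <- omics_pca(omics_matrix(m, d), pve_target = 1)
  centered <- m - rowMeans(m)
  sv <- svd(t(centered))
  pve_oracle <- sv$d^2 / sum(sv$d^2)
  expect_equal(unname(pc$pve_all[seq_along(pve_oracle)]), pve_oracle,
               tolerance = 1e-10)
  ## scores match up to sign
  for (i in seq_len(length(pc$pve))) {
    s_or <- sv$u[, i] * sv$d[i]
    expect_equal(min(sum(abs(pc$scores[, i] - s_or)),
                     sum(abs(pc$scores[, i] + s_or))), 0, tolerance = 1e-8)
  }
  ## pve ordering and coverage invariants
  pc9 <- omics_pca(omics_matrix(m, d), pve_target = 0.9)
  expect_true(all(diff(pc9$pve) <= 1e-12))
  expect_gte(sum(pc9$pve), 0.9)
  expect_lte(sum(pc9$pve), 1)
})

test_that("weighted R2 is 1 for animal-determined scores and null-calibrated otherwise", {
  d <- generate_design(5, 7, "BM")
  set.seed(3)
  ## scores that are a pure function of animal
  m <- animal_matrix(d, 10) + matrix(rnorm(10 * 35, 0, 1e-8), 10)
  pc <- omics_pca(m, pve_target = 0.99)
  vc <- pc_variance_components(pc, factor_name = "animal")
  expect_equal(vc$weighted_r2, 1, tolerance = 1e-4)
  ## independent scores: E[R2] = (levels-1)/(n-1)
  null_r2 <- replicate(300, {
    y <- rnorm(35)
    g <- factor(d$animal)
    gm <- tapply(y, g, mean)
    sum(table(g) * (gm - mean(y))^2) / sum((y - mean(y))^2)
  })
  expect_equal(mean(null_r2), 4 / 34, tolerance = 0.02)
  ## weighted average identity and sign-flip invariance
  set.seed(8)
  r <- omics_matrix(matrix(rnorm(35 * 50), 50,
                           dimnames = list(sprintf("g%d", 1:50),
                                           d$sample_id)), d)
  pcr <- omics_pca(r)
  vca <- pc_variance_components(pcr, factor_name = "animal")
  expect_equal(vca$weighted_r2,
               sum(vca$pve * vca$per_pc_r2) / sum(vca$pve))
  pcr_flip <- pcr
  pcr_flip$scores <- -pcr$scores
  expect_equal(pc_variance_components(pcr_flip,
                                      factor_name = "animal")$weighted_r2,
               vca$weighted_r2)
})

test_that("planted variance fractions are recovered by the PC procedure", {
  d <- generate_design(5, 7, "BM")
  tr <- simulate_transcriptome(d, null_params(seed = 21))
  bm <- normalize_log2(tr$counts$BM, design_compartment(d, "BM"))
  pc <- omics_pca(bm)
  wa <- pc_variance_components(pc, factor_name = "animal")$weighted_r2
  wt <- pc_variance_components(pc, factor_name = "timepoint")$weighted_r2
  expect_lt(abs(wa - 0.6), 0.08)
  expect_lt(abs(wt - 0.15), 0.08)
  ## balanced orthogonal factors: joint attribution bounded
  expect_lt(wa + wt, 1 + 0.05)
})

test_that("per-PC factor ANOVA matches closed forms", {
  d <- generate_design(2, 6, "BM")  # two animals -> t-test identity
  set.seed(5)
  m <- omics_matrix(matrix(rnorm(12 * 30), 30,
                           dimnames = list(sprintf("g%d", 1:30),
                                           d$sample_id)), d)
  pc <- omics_pca(m, pve_target = 0.8)
  an <- pc_factor_anova(pc, factor_name = "animal")
  g <- factor(design_of(m)$animal)
  for (i in seq_len(nrow(an))) {
    tt <- t.test(pc$scores[, i] ~ g, var.equal = TRUE)
    expect_equal(an$p[i], tt$p.value, tolerance = 1e-10)
  }
  ## identical group means push p toward 1: scores a pure timepoint
  ## function have equal animal means in a balanced design
  d5 <- generate_design(5, 4, "BM")
  base <- rep(rnorm(4), each = 5)   # expand.grid order: animal fastest
  flat <- rbind(a = base, b = 2 * base, c = -base)
  colnames(flat) <- d5$sample_id
  pc_flat <- omics_pca(omics_matrix(flat + rnorm(60, 0, 1e-6), d5),
                       pve_target = 0.5)
  an_flat <- pc_factor_anova(pc_flat, factor_name = "animal")
  expect_gt(min(an_flat$p), 0.9)
  ## extreme-level report present
  expect_true(all(an$direction %in% c("high", "low")))
})

test_that("varcomp table has the expected shape", {
  d <- generate_design(5, 7, "BM")
  tr <- simulate_transcriptome(d, null_params(seed = 2))
  bm <- normalize_log2(tr$counts$BM, design_compartment(d, "BM"))
  tab <- varcomp_table(omics_pca(bm))
  expect_equal(nrow(tab), 5)
  expect_named(tab, c("pc", "pve", "animal_r2", "timepoint_r2", "drug_p",
                      "drug_extreme"))
  expect_true(all(tab$animal_r2 >= 0 & tab$animal_r2 <= 1))
})
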