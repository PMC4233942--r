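test_that("simulation is bit-identical under a fixed seed", {
  p <- sim_params(n_features = c(transcript = 200, metabolite = 100),
                  n_drug_genes = 10, lag_genes = 10, seed = 33)
  d <- generate_design(5, 7, c("BM", "PB", "plasma", "CBC"))
  a <- simulate_transcriptome(d, p)
  b <- simulate_transcriptome(d, p)
  expect_identical(a$counts$BM, b$counts$BM)
  expect_identical(a$truth$drug_genes, b$truth$drug_genes)
  expect_identical(unclass(simulate_metabolome(d, p)$table),
                   unclass(simulate_metabolome(d, p)$table))
  expect_identical(unclass(simulate_cbc(d, p)), unclass(simulate_cbc(d, p)))
  ## different seed changes the draw
  p2 <- sim_params(n_features = c(transcript = 200, metabolite = 100),
                   n_drug_genes = 10, lag_genes = 10, seed = 34)
  expect_false(identical(a$counts$BM, simulate_transcriptome(d, p2)$counts$BM))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(animal_var_frac = 0.7, timepoint_var_frac = 0.5),
               "exceed 1")
  expect_error(sim_params(animal_var_frac = -0.1), "fractions")
  expect_error(sim_params(planted_clusters = data.frame(size = 3000,
                                                        within_cor = 0.9)),
               "exceed")
  expect_error(
    sim_params(planted_edges = data.frame(from = 1, to = 9, strength = 0.5)),
    "beyond")
})

test_that("null animal structure gives nominal one-way ANOVA rejection", {
  d <- generate_design(5, 7, "BM")
  p <- null_params(seed = 3, animal = 0, timepoint = 0)
  tr <- simulate_transcriptome(d, p)
  bm <- normalize_log2(tr$counts$BM, design_compartment(d, "BM"))
  pv <- apply(unclass(bm), 1, function(y)
    summary(stats::aov(y ~ factor(design_of(bm)$animal)))[[1]][1, "Pr(>F)"])
  ## binomial tolerance around 5% at 2000 features
  expect_gt(mean(pv < 0.05), 0.035)
  expect_lt(mean(pv < 0.05), 0.065)
})

test_that("planted variance fractions are recovered empirically", {
  d <- generate_design(5, 7, "BM")
  p <- null_params(seed = 11)
  tr <- simulate_transcriptome(d, p)
  bm <- normalize_log2(tr$counts$BM, design_compartment(d, "BM"))
  des <- design_of(bm)
  a <- factor(des$animal); t <- factor(des$timepoint)
  ## method-of-moments two-way variance components, pooled over features
  ## (unbiased for the generating sigma^2s in this balanced design)
  Y <- t(unclass(bm))
  Xa <- model.matrix(~a); Xt <- model.matrix(~t); X2 <- model.matrix(~a + t)
  ssa <- colSums(qr.resid(qr(matrix(1, 35)), Y)^2) -
    colSums(qr.resid(qr(Xa), Y)^2)
  sst_ <- colSums(qr.resid(qr(matrix(1, 35)), Y)^2) -
    colSums(qr.resid(qr(Xt), Y)^2)
  sse <- colSums(qr.resid(qr(X2), Y)^2)
  mse <- sum(sse) / (24 * ncol(Y))
  sig_a <- (sum(ssa) / (4 * ncol(Y)) - mse) / 7
  sig_t <- (sum(sst_) / (6 * ncol(Y)) - mse) / 5
  tot <- sig_a + sig_t + mse
  expect_lt(abs(sig_a / tot - 0.6), 0.05)
  expect_lt(abs(sig_t / tot - 0.15), 0.05)
})

test_that("planted cluster members are tightly correlated after residualizing", {
  d <- generate_design(5, 7, "BM")
  p <- sim_params(n_features = c(transcript = 300, metabolite = 50),
                  planted_clusters = data.frame(size = c(15, 15),
                                                within_cor = c(0.9, 0.9)),
                  planted_edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             strength = numeric(0)),
                  n_drug_genes = 0, lag_genes = 0, seed = 8)
  tr <- simulate_transcriptome(d, p)
  res <- residualize_animal(normalize_log2(tr$counts$BM,
                                           design_compartment(d, "BM")))
  for (cl in tr$truth$clusters) {
    cc <- cor(t(unclass(res)[cl, ]))
    expect_gt(min(cc[upper.tri(cc)]), 0.9 - 0.25)  # sampling tolerance, n=35
    expect_gt(mean(cc[upper.tri(cc)]), 0.75)
  }
})

test_that("metabolome table has the replicate structure and missingness", {
  d <- generate_design(5, 7, "plasma")
  p <- null_params(seed = 5, n_features = c(transcript = 50,
                                            metabolite = 400),
                   missing_frac = 0.10)
  mb <- simulate_metabolome(d, p)
  expect_equal(ncol(mb$table), 25 * 3)
  rep_map <- attr(mb$table, "rep_map")
  expect_equal(nrow(rep_map), 75)
  expect_equal(length(unique(rep_map$sample_id)), 25)
  ## zero replicate noise makes the triplicates identical
  p0 <- null_params(seed = 5, n_features = c(transcript = 50,
                                             metabolite = 60),
                    replicate_sd = 0, missing_frac = 0)
  mb0 <- simulate_metabolome(d, p0)
  for (s in unique(attr(mb0$table, "rep_map")$sample_id)) {
    cols <- attr(mb0$table, "rep_map")$column[
      attr(mb0$table, "rep_map")$sample_id == s]
    block <- unclass(mb0$table)[, cols]
    expect_equal(block[, 1], block[, 2])
    expect_equal(block[, 1], block[, 3])
  }
  ## planted high-missing features mostly exceed the 30% filter threshold
  realized <- mb$truth$missing_frac_realized
  expect_gt(mean(realized[mb$truth$high_missing] > 0.3), 0.8)
  expect_lt(mean(realized[setdiff(names(realized),
                                  mb$truth$high_missing)] > 0.3), 0.05)
})

test_that("CBC table has five cell types, positive values, animal structure", {
  d <- generate_design(5, 6, "CBC")
  cbc <- simulate_cbc(d, sim_params(seed = 2))
  expect_equal(rownames(cbc), c("R", "L", "M", "P", "G"))
  expect_equal(ncol(cbc), 30)
  expect_true(all(cbc > 0))
  ## zero-noise variant: identical columns within animal
  p0 <- sim_params(cbc_animal_var_frac = 1, cbc_timepoint_var_frac = 0,
                   seed = 2)
  cbc0 <- simulate_cbc(d, p0)
  des <- design_of(cbc0)
  for (a in unique(des$animal)) {
    cols <- unclass(cbc0)[, des$animal == a, drop = FALSE]
    expect_equal(max(apply(cols, 1, function(v) diff(range(v)))), 0)
  }
})
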