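test_that("size factors match the median-of-ratios formula", {
  ## single feature (4, 9): geometric mean 6, factors 4/6 and 9/6
  m <- matrix(c(4L, 9L), 1, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(4 / 6, 9 / 6))

  ## proportional columns: factors proportional to the scaling constants
  set.seed(1)
  base <- rpois(50, 100) + 1L
  sc <- c(1, 2, 0.5, 1.5)
  m2 <- outer(base, sc)
  dimnames(m2) <- list(sprintf("g%d", 1:50), sprintf("s%d", 1:4))
  sf <- size_factors(m2)
  expect_equal(unname(sf / sf[1]), sc, tolerance = 1e-12)

  ## permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(size_factors(m2[, perm])), unname(sf[perm]))

  expect_error(size_factors(matrix(c(0L, 5L, 3L, 0L), 2)), "zero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rpois(300, 50) + 1L, 30, 10,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("log2 normalization handles pseudocounts and factors", {
  d <- tiny_design(1, 2)
  m <- matrix(c(0L, 1024L), 1, dimnames = list("g1", d$sample_id))
  x <- normalize_log2(m, d, factors = c(1, 1), pseudocount = 1)
  expect_equal(unclass(x)[1, 1], 0)
  x0 <- normalize_log2(matrix(c(4L, 1024L), 1,
                              dimnames = list("g1", d$sample_id)),
                       d, factors = c(1, 1), pseudocount = 0)
  expect_equal(unclass(x0)[1, 2], 10)
  expect_error(normalize_log2(m, d, factors = c(1, 1), pseudocount = 0),
               "log")
  ## doubling a large count adds about one log2 unit
  big <- matrix(c(5000L, 10000L), 1, dimnames = list("g1", d$sample_id))
  xb <- normalize_log2(big, d, factors = c(1, 1))
  expect_equal(diff(unclass(xb)[1, ]), 1, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("abundance filter is a strict mean-threshold filter", {
  d <- tiny_design(2, 2, "BM")
  vals <- matrix(c(rep(4.9, 4), rep(5.0, 4), rep(7, 4)), 3, byrow = TRUE,
                 dimnames = list(c("low", "edge", "high"), d$sample_id))
  x <- omics_matrix(vals, d)
  kept <- filter_low_abundance(x, 5)
  expect_equal(rownames(kept), c("edge", "high"))
  ## identity on all-above matrices
  expect_equal(nrow(filter_low_abundance(x, 0)), 3)
  expect_error(filter_low_abundance(x, 100), "every feature")
  ## random matrix agrees with a brute-force mean filter
  set.seed(2)
  r <- matrix(rnorm(200, 5, 2), 20,
              dimnames = list(sprintf("g%d", 1:20),
                              tiny_design(5, 2, "BM")$sample_id))
  xr <- omics_matrix(r, tiny_design(5, 2, "BM"))
  expect_equal(rownames(filter_low_abundance(xr, 5)),
               rownames(r)[rowMeans(r) >= 5])
})

test_that("replicate collapse takes per-cell medians over available values", {
  rep_map <- data.frame(column = c("s1_r1", "s1_r2", "s1_r3"),
                        sample_id = "s1", replicate = 1:3)
  tab <- matrix(c(2, 4, 100,
                  5, NA, 7,
                  NA, NA, NA), 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"),
                                c("s1_r1", "s1_r2", "s1_r3")))
  out <- collapse_replicates(tab, rep_map)
  expect_equal(unname(out[, "s1"]), c(4, 6, NA))
  expect_error(collapse_replicates(tab, rep_map[1:2, ]), "mapping")
})

test_that("metabolite QC applies both filters with documented boundaries", {
  d <- generate_design(2, 7, "plasma")  # 10 samples
  n_s <- nrow(d)
  mk <- function(val, n_miss) c(rep(NA, n_miss), rep(val, n_s - n_miss))
  m <- rbind(miss31 = mk(1000, 4),   # 40% missing  -> dropped
             miss30 = mk(1000, 3),   # 30% missing  -> kept
             low = mk(255, 0),       # median 255   -> dropped
             edge = mk(256, 0),      # median 256   -> kept
             high = mk(5000, 1))     # imputed cell
  colnames(m) <- d$sample_id
  out <- filter_metabolite_qc(m, d)
  expect_equal(sort(rownames(out)), c("edge", "high", "miss30"))
  ## imputation: half the minimum observed value, then log2
  expect_equal(unclass(out)["high", 1], log2(2500))
  expect_false(anyNA(out))
  ## random-table oracle: two independent filters then half-min imputation
  set.seed(9)
  r <- matrix(2^runif(400, 4, 14), 40, n_s)
  r[sample(length(r), 80)] <- NA
  rownames(r) <- sprintf("m%d", 1:40); colnames(r) <- d$sample_id
  keep <- rowMeans(is.na(r)) <= 0.3 &
    apply(r, 1, median, na.rm = TRUE) >= 256
  if (any(keep)) {
    out_r <- filter_metabolite_qc(r, d)
    expect_equal(rownames(out_r), rownames(r)[keep])
  }
})

test_that("feature standardization matches the z-score definition", {
  d <- tiny_design(3, 1, "BM")
  m <- matrix(c(1, 2, 3), 1, dimnames = list("g1", d$sample_id))
  z <- standardize_features(omics_matrix(m, d))
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))
  ## idempotence and row moments
  z2 <- standardize_features(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-12)
  expect_lt(abs(mean(unclass(z)[1, ])), 1e-12)
  expect_error(standardize_features(rbind(m, const = c(5, 5, 5))),
               "constant")
})

test_that("animal residualization equals one-factor OLS residuals", {
  d <- tiny_design(3, 4)
  x <- animal_matrix(d)   # pure function of animal
  res <- residualize_animal(x)
  expect_equal(max(abs(res)), 0)
  ## random matrix: compare against lm per feature, group means are zero
  set.seed(4)
  r <- matrix(rnorm(5 * nrow(d)), 5,
              dimnames = list(sprintf("g%d", 1:5), d$sample_id))
  xr <- omics_matrix(r, d)
  rr <- residualize_animal(xr)
  for (i in 1:5) {
    fit <- lm(r[i, ] ~ factor(d$animal))
    expect_equal(unname(unclass(rr)[i, ]), unname(resid(fit)),
                 tolerance = 1e-12)
  }
  gm <- rowsum(t(unclass(rr)), d$animal)
  expect_lt(max(abs(gm)), 1e-12)
  ## single-animal design rejected
  d1 <- generate_design(1, 4, "BM")
  x1 <- omics_matrix(matrix(rnorm(8), 2,
                            dimnames = list(c("a", "b"), d1$sample_id)), d1)
  expect_error(residualize_animal(x1), "2 animals")
})
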