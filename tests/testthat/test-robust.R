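## two coupled planted clusters + one independent, as an observation table
## coupling kept moderate so the QT diameter threshold still separates the
## coupled clusters (cross-cluster member correlation ~ within * strength);
## a mostly sample-level latent (low tp share) avoids chance collisions of
## 7-point timepoint profiles between clusters
coupled_fixture <- function(seed = 7, strength = 0.75, n_clusters = 3) {
  d <- generate_design(5, 7, c("BM", "PB"))
  p <- sim_params(
    n_features = c(transcript = 1000, metabolite = 20),
    planted_clusters = data.frame(size = rep(15, n_clusters),
                                  within_cor = rep(0.92, n_clusters)),
    planted_edges = data.frame(from = 1, to = 2, strength = strength),
    cluster_tp_share = 0.2,
    n_drug_genes = 0, lag_genes = 0, seed = seed)
  tr <- simulate_transcriptome(d, p)
  res <- residualize_animal(normalize_log2(tr$counts$BM,
                                           design_compartment(d, "BM")))
  feats <- unlist(tr$truth$clusters)
  cs <- qt_cluster(res[feats, ], d = 0.3, min_size = 10)
  ## map QT clusters back to planted indices
  mapping <- vapply(cs$clusters, function(cl) {
    which.max(vapply(tr$truth$clusters, function(tc)
      length(intersect(cl$members, tc)), numeric(1)))
  }, numeric(1))
  list(tab = concatenate_observations(cs, res[feats, ], top_n = 10),
       mapping = mapping, truth = tr$truth, res = res, design = d,
       counts_pb = tr$counts$PB, cs = cs)
}

test_that("planted cluster couplings are robust; null pairs are not", {
  fx <- coupled_fixture()
  expect_length(fx$tab$nodes, 3)
  rn <- robust_network(fx$tab, n_subsamples = 30, n_shuffles = 2, levels = 5, seed = 11)
  key <- function(i) fx$tab$nodes[which(fx$mapping == i)]
  planted <- sort(c(key(1), key(2)))
  rob <- rn$edges[rn$edges$robust, ]
  ## the planted coupling is robust; chance latent collisions may add at
  ## most one further edge (gene-block concatenation replicates each
  ## sample-level latent, so even modest dependences are detectable)
  expect_true(any(apply(rob[, c("from", "to")], 1,
                        function(e) setequal(e, planted))))
  expect_lte(nrow(rob), 2)
  expect_true(all(rn$edges$freq_original >= 0 & rn$edges$freq_original <= 1))
})

test_that("degenerate subsampling and overlap conventions", {
  fx <- coupled_fixture(seed = 8)
  rn1 <- robust_network(fx$tab, n_subsamples = 1, n_shuffles = 1, levels = 5, seed = 2)
  expect_true(all(rn1$edges$freq_original %in% c(0, 1)))
  ## shuffling with zero shuffles: overlap empty, robustness = original only
  rn0 <- robust_network(fx$tab, n_subsamples = 5, n_shuffles = 0, levels = 5, seed = 2)
  expect_length(rn0$overlap, 0)
  ## identical "shuffle" degenerates to 100% overlap when the threshold
  ## edge sets coincide (seeded shuffles of a strongly coupled pair)
  rn <- robust_network(fx$tab, n_subsamples = 20, n_shuffles = 2, levels = 5, seed = 3)
  expect_true(all(is.na(rn$overlap) | rn$overlap >= 0))
})

test_that("edge frequencies are reproducible across seed sets", {
  fx <- coupled_fixture(seed = 9)
  rn_a <- robust_network(fx$tab, n_subsamples = 60, n_shuffles = 0,
                         levels = 5, seed = 100)
  rn_b <- robust_network(fx$tab, n_subsamples = 60, n_shuffles = 0,
                         levels = 5, seed = 200)
  shared <- merge(rn_a$edges[, c("from", "to", "freq_original")],
                  rn_b$edges[, c("from", "to", "freq_original")],
                  by = c("from", "to"), all = TRUE)
  shared[is.na(shared)] <- 0
  expect_lt(max(abs(shared$freq_original.x - shared$freq_original.y)), 0.15)
})

test_that("conservation test matches its KS oracle and calibrates on null", {
  fx <- coupled_fixture(seed = 12)
  pb <- residualize_animal(normalize_log2(fx$counts_pb,
                                          design_compartment(fx$design,
                                                             "PB")))
  cons <- conservation_test(fx$cs, pb, n_random = 40, seed = 5)
  ## planted clusters share latents across compartments: conserved
  expect_true(all(cons$n_significant >= 35))
  ## KS statistic oracle
  set.seed(6)
  x <- rnorm(30, 0.5); y <- rnorm(40)
  expect_equal(unname(ks.test(x, y, alternative = "less")$statistic),
               oracle_ks_less(x, y), tolerance = 1e-12)
  ## a cluster of arbitrary pool genes is conserved at about the alpha rate
  fake_cs <- fx$cs
  pool <- unlist(lapply(fx$cs$clusters, `[[`, "members"))
  set.seed(9)
  fake_cs$clusters <- list(list(members = sample(pool, 12),
                                centroid = NULL, diameter = NA, size = 12))
  cons_null <- conservation_test(fake_cs, pb, n_random = 60, seed = 7)
  expect_lt(cons_null$n_significant, 25)
})

test_that("integrated analysis finds no cross-type edges in independent data", {
  fx <- coupled_fixture(seed = 13)
  ## independent "metabolite" cluster nodes: a second simulation with its
  ## own seed, restricted to the metabolome timepoints 3..7
  fx2 <- coupled_fixture(seed = 55)
  mtab <- restrict_observations(fx2$tab, 3:7)
  mtab$node_type[] <- "metabolite"
  rn <- integrated_network(fx$tab, mtab, n_subsamples = 25, n_shuffles = 1,
                           levels_transcript = 7, levels_metabolite = 5,
                           seed = 3)
  ## observation counts align at 10 x 25 after timepoint restriction
  expect_equal(sum(rn$cross_edges$robust), 0)
  ## within-type planted couplings can still show up; cross-type pairs
  ## never reach the robustness criterion
  ty <- rn$node_type
  cross <- rn$edges[ty[rn$edges$from] != ty[rn$edges$to], ]
  if (nrow(cross)) expect_true(all(cross$freq_pooled < 0.5))
})

test_that("a planted transcript-metabolite coupling beats every null pair", {
  fx <- coupled_fixture(seed = 21, n_clusters = 3)
  ## "metabolite" table echoing transcript cluster 3's latent: reuse the
  ## same simulation's third cluster as the metabolite node, plus one
  ## independent node from another seed
  tab_t <- fx$tab
  key3 <- which(fx$mapping == 3)
  fx_ind <- coupled_fixture(seed = 34, n_clusters = 3)
  mtab <- fx_ind$tab
  ## overwrite node 1 of the metabolite table with transcript node 3's
  ## values plus noise: a planted cross-type dependency
  set.seed(2)
  mtab$values[, 1] <- tab_t$values[, key3] +
    rnorm(nrow(mtab$values), 0, 0.3 * sd(tab_t$values[, key3]))
  mtab <- restrict_observations(mtab, 3:7)
  mtab$node_type[] <- "metabolite"
  rn <- integrated_network(tab_t, mtab, n_subsamples = 25, n_shuffles = 1,
                           levels_transcript = 7, levels_metabolite = 5,
                           seed = 9)
  ty <- rn$node_type
  cross <- rn$edges[ty[rn$edges$from] != ty[rn$edges$to], ]
  planted_name_t <- tab_t$nodes[key3]
  hit <- cross$from == planted_name_t | cross$to == planted_name_t
  expect_true(any(hit))
  expect_gt(max(cross$freq_pooled[hit]), max(c(cross$freq_pooled[!hit], 0)))
})
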