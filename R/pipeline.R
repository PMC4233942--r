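#' Run the full synthetic-study analysis pipeline
#'
#' End-to-end exercise of every stage on generated data: simulation;
#' normalization, filtering and replicate collapsing; PC variance
#' components per dataset; the cross-omic PC correlation grid; the lagged
#' marrow-to-blood sign test with its control contrast; axis scoring and
#' ANOVA; differential expression with and without the animal term plus the
#' consistent-response lists; pathway PC1 profiles, Ward clusters and the
#' cross-compartment association; and the QT-cluster Bayesian network with
#' subsample/shuffle robustness. Every stochastic step derives its stream
#' from `params$seed`, so two runs with the same parameters are
#' bit-identical.
#'
#' @param params a [sim_params()] object; `params$seed` drives everything.
#' @param n_top_features drug-F feature count carried into clustering.
#' @param n_subsamples,n_shuffles robustness effort (kept small by default
#'   so a full run stays interactive; raise for production-quality edge
#'   frequencies).
#' @param levels discretization levels for the transcript network.
#' @param axis_file,gmt_file definition files; the shipped synthetic
#'   placeholders by default.
#' @return a nested list with one element per stage (see the vignette for a
#'   walk-through).
#' @export
run_study_pipeline <- function(params = sim_params(),
                               n_top_features = 500,
                               n_subsamples = 50, n_shuffles = 2,
                               levels = 5,
                               axis_file = system.file(
                                 "extdata", "bit_axes_synthetic.tsv",
                                 package = "lomnet"),
                               gmt_file = system.file(
                                 "extdata", "gene_sets_synthetic.gmt",
                                 package = "lomnet")) {
  study <- simulate_study(params)
  d <- study$design

  ## -- preprocessing ------------------------------------------------------
  bm <- filter_low_abundance(
    normalize_log2(study$counts$BM, design_compartment(d, "BM")), 5)
  pb <- filter_low_abundance(
    normalize_log2(study$counts$PB, design_compartment(d, "PB")), 5)
  mets <- lapply(study$metabolome, function(tab)
    filter_low_abundance(filter_metabolite_qc(collapse_replicates(tab)), 17))
  cbc <- omics_matrix(log2(unclass(study$cbc)), design_of(study$cbc),
                      provenance = "log2")

  ## -- variance components ------------------------------------------------
  omics <- c(list(BM = bm, PB = pb), mets, list(CBC = cbc))
  pcs <- lapply(omics, omics_pca)
  varcomp <- lapply(pcs, function(p) {
    list(animal = pc_variance_components(p, factor_name = "animal"),
         timepoint = pc_variance_components(p, factor_name = "timepoint"),
         table = varcomp_table(p))
  })

  ## -- integration --------------------------------------------------------
  grid <- pc_correlation_grid(pcs[c("PB", "BM", "AE", "C18")], k = 10)
  sign_test <- lagged_sign_test(bm, pb, 4, 5, min_abs = 0.5)
  sign_control <- lagged_sign_test(bm, pb, 6, 7, min_abs = 0.5)

  ## -- axes ----------------------------------------------------------------
  defs <- read_axis_definitions(axis_file)
  axes <- suppressWarnings(
    lapply(list(BM = bm, PB = pb), function(x) {
      ax <- axis_scores(x, defs)
      if (length(ax)) axis_anova(ax, design_of(x)) else NULL
    }))

  ## -- differential expression --------------------------------------------
  de <- list()
  for (nm in names(omics)) {
    de[[nm]] <- list(
      with_animal = feature_anova(omics[[nm]], factor_name = "timepoint",
                                  include_animal = TRUE),
      without_animal = feature_anova(omics[[nm]], factor_name = "timepoint",
                                     include_animal = FALSE))
  }
  de_summary <- data.frame(
    dataset = names(de),
    with_animal = vapply(de, function(x)
      sum(x$with_animal$q <= 0.05), numeric(1)),
    without_animal = vapply(de, function(x)
      sum(x$without_animal$q <= 0.05), numeric(1)))
  consistent <- consistent_response(bm)

  ## -- pathways ------------------------------------------------------------
  sets <- filter_sets_expressed(read_gmt(gmt_file), list(bm, pb),
                                min_genes = 5)
  path_bm <- pathway_pc1(bm, sets)
  path_pb <- pathway_pc1(pb, sets)
  prof_bm <- profile_matrix(path_bm)
  prof_pb <- profile_matrix(path_pb)
  k_clusters <- max(2, min(4, nrow(prof_bm) - 1))
  lab_bm <- cluster_profiles(prof_bm, k = k_clusters)
  lab_pb <- cluster_profiles(prof_pb, k = k_clusters)
  assoc <- compartment_association(lab_bm, lab_pb)

  ## -- network -------------------------------------------------------------
  drug_f <- feature_anova(bm, factor_name = "drug_phase",
                          include_animal = TRUE)
  top <- select_top_features(drug_f, n_top_features)
  res_bm <- residualize_animal(bm)[top, ]
  clusters <- qt_cluster(res_bm, d = 0.3, min_size = 10)
  network <- NULL
  conservation <- NULL
  if (length(clusters$clusters) >= 2) {
    tab <- concatenate_observations(clusters, res_bm, top_n = 10)
    network <- robust_network(tab, n_subsamples = n_subsamples,
                              n_shuffles = n_shuffles, levels = levels,
                              seed = params$seed)
    conservation <- conservation_test(clusters, residualize_animal(pb),
                                      n_random = 50, seed = params$seed)
  }

  list(design = d, omics = omics, pcs = pcs, varcomp = varcomp,
       grid = grid, sign_test = sign_test, sign_control = sign_control,
       axes = axes, de_summary = de_summary, consistent = consistent,
       pathways = list(pve_bm = path_bm$pve_pc1, pve_pb = path_pb$pve_pc1,
                       profiles_bm = prof_bm, profiles_pb = prof_pb,
                       labels_bm = lab_bm, labels_pb = lab_pb,
                       association = assoc),
       clusters = clusters, network = network, conservation = conservation,
       truth = study$truth)
}
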