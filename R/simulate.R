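#' Simulation parameters for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults chosen to emulate a five-animal, seven-timepoint, two-compartment
#' longitudinal drug study: dominant among-animal variance in the
#' transcriptomes, weaker and roughly equal animal/timepoint structure in the
#' plasma metabolome, a modest drug-responsive gene subset, planted
#' co-expression clusters with directed inter-cluster couplings, and a
#' bone-marrow-to-blood one-timepoint lag signal.
#'
#' Variance fractions are on the log2 scale: for each feature the total log2
#' standard deviation `s_f` comes from an abundance-dependent curve
#' (`sd_base * (1 + cv_boost * 2^(-(mu - mu_min)/tau))`, so low-abundance
#' features have a higher coefficient of variation), and the animal,
#' timepoint and residual components get `s_f * sqrt(frac)` of it.
#'
#' @param n_features named counts, `c(transcript = , metabolite = )`.
#' @param animal_var_frac,timepoint_var_frac transcriptome variance
#'   fractions in `[0, 1]`, summing to at most 1.
#' @param metab_animal_var_frac,metab_timepoint_var_frac metabolome
#'   fractions (defaults weaker than the transcriptome).
#' @param cbc_animal_var_frac,cbc_timepoint_var_frac blood-count fractions.
#' @param drug_effect_size log2-unit shift applied to drug-responsive genes
#'   in post-drug samples.
#' @param n_drug_genes number of drug-responsive genes.
#' @param planted_clusters data frame with columns `size` and `within_cor`:
#'   co-expression clusters planted in the transcriptome residual space.
#' @param cluster_tp_share fraction of each cluster latent's variance tied
#'   to a shared timepoint profile (gives cluster genes a drug-phase signal).
#' @param planted_edges data frame with columns `from`, `to`, `strength`:
#'   directed couplings between cluster latents.
#' @param lag_genes number of genes whose bone-marrow timepoint-4 excursion
#'   is echoed in peripheral blood at timepoint 5.
#' @param lag_magnitude log2 magnitude of that excursion (sign randomized
#'   per gene).
#' @param noise_cv_curve list with `sd_base`, `cv_boost`, `tau` (see above).
#' @param missing_frac fraction of metabolite features planted with high
#'   (about 45 percent) per-sample missingness; remaining features miss at a
#'   2 percent background rate.
#' @param replicate_sd log2 sd of technical replicate noise (much smaller
#'   than biological noise).
#' @param depth_range per-sample sequencing depth factors are drawn
#'   log-uniformly over this interval.
#' @param seed single global seed; every stochastic operation derives its
#'   own sub-stream deterministically from it.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_features = c(transcript = 2000, metabolite = 1000),
                       animal_var_frac = 0.6,
                       timepoint_var_frac = 0.15,
                       metab_animal_var_frac = 0.15,
                       metab_timepoint_var_frac = 0.15,
                       cbc_animal_var_frac = 0.3,
                       cbc_timepoint_var_frac = 0.1,
                       drug_effect_size = 1,
                       n_drug_genes = 100,
                       planted_clusters = data.frame(size = rep(20, 5),
                                                     within_cor = rep(0.9, 5)),
                       cluster_tp_share = 0.6,
                       planted_edges = data.frame(from = c(1, 3), to = c(2, 4),
                                                  strength = c(0.7, 0.7)),
                       lag_genes = 100,
                       lag_magnitude = 1,
                       noise_cv_curve = list(sd_base = 0.5, cv_boost = 1.5,
                                             tau = 2),
                       missing_frac = 0.10,
                       replicate_sd = 0.1,
                       depth_range = c(0.5, 2),
                       seed = 1L) {
  p <- list(n_features = n_features,
            animal_var_frac = animal_var_frac,
            timepoint_var_frac = timepoint_var_frac,
            metab_animal_var_frac = metab_animal_var_frac,
            metab_timepoint_var_frac = metab_timepoint_var_frac,
            cbc_animal_var_frac = cbc_animal_var_frac,
            cbc_timepoint_var_frac = cbc_timepoint_var_frac,
            drug_effect_size = drug_effect_size,
            n_drug_genes = n_drug_genes,
            planted_clusters = planted_clusters,
            cluster_tp_share = cluster_tp_share,
            planted_edges = planted_edges,
            lag_genes = lag_genes,
            lag_magnitude = lag_magnitude,
            noise_cv_curve = noise_cv_curve,
            missing_frac = missing_frac,
            replicate_sd = replicate_sd,
            depth_range = depth_range,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  fr <- c(p$animal_var_frac, p$timepoint_var_frac,
          p$metab_animal_var_frac, p$metab_timepoint_var_frac,
          p$cbc_animal_var_frac, p$cbc_timepoint_var_frac,
          p$missing_frac)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]",
                                 call. = FALSE)
  pairs <- rbind(c(p$animal_var_frac, p$timepoint_var_frac),
                 c(p$metab_animal_var_frac, p$metab_timepoint_var_frac),
                 c(p$cbc_animal_var_frac, p$cbc_timepoint_var_frac))
  if (any(rowSums(pairs) > 1)) {
    stop("animal_var_frac + timepoint_var_frac must not exceed 1",
         call. = FALSE)
  }
  counts <- c(p$n_features, p$n_drug_genes, p$lag_genes)
  if (any(counts < 0)) stop("all counts must be non-negative", call. = FALSE)
  cl <- p$planted_clusters
  if (nrow(cl) > 0) {
    stopifnot(all(c("size", "within_cor") %in% names(cl)))
    if (any(cl$within_cor < 0 | cl$within_cor > 1)) {
      stop("within_cor must lie in [0, 1]", call. = FALSE)
    }
    if (sum(cl$size) > p$n_features[["transcript"]]) {
      stop("planted cluster sizes exceed the number of transcript features",
           call. = FALSE)
    }
    ed <- p$planted_edges
    if (nrow(ed) > 0 && any(c(ed$from, ed$to) > nrow(cl))) {
      stop("planted_edges refer to clusters beyond planted_clusters",
           call. = FALSE)
    }
  }
  invisible(p)
}

## total log2 sd as a function of mean abundance: low-abundance features get
## a higher coefficient of variation
total_sd_curve <- function(mu, curve, mu_min) {
  curve$sd_base * (1 + curve$cv_boost * 2^(-(mu - mu_min) / curve$tau))
}

## shared latent machinery for planted clusters: one standardized latent per
## cluster and sample, with a timepoint-structured share, plus directed
## couplings between cluster latents
cluster_latents <- function(design_cp, clusters, edges, tp_share) {
  n_cl <- nrow(clusters)
  tps <- sort(unique(design_cp$timepoint))
  L <- matrix(0, nrow(design_cp), n_cl)
  for (c_i in seq_len(n_cl)) {
    u_tp <- stats::rnorm(length(tps))
    names(u_tp) <- as.character(tps)
    w <- stats::rnorm(nrow(design_cp))
    L[, c_i] <- sqrt(tp_share) * u_tp[as.character(design_cp$timepoint)] +
      sqrt(1 - tp_share) * w
  }
  if (nrow(edges) > 0) {
    for (e_i in seq_len(nrow(edges))) {
      s <- edges$strength[e_i]
      L[, edges$to[e_i]] <- s * L[, edges$from[e_i]] +
        sqrt(1 - s^2) * L[, edges$to[e_i]]
    }
  }
  scale(L)[, , drop = FALSE]
}

#' Simulate transcriptome count matrices with planted ground truth
#'
#' Per-feature log2 signal is grand mean + animal effect + timepoint effect
#' + drug-phase effect (drug genes, post-drug samples only) + cluster latent
#' factor (cluster members) + heteroscedastic noise; counts are obtained by
#' exponentiating, applying a per-sample depth factor, and rounding. Lag
#' genes additionally receive their bone-marrow timepoint-4 excursion at
#' peripheral-blood timepoint 5.
#'
#' @param design a `sample_design` containing BM and/or PB rows.
#' @param params a [sim_params()] object.
#' @return list with `counts` (named list of integer count matrices, one per
#'   compartment) and `truth` (planted assignments; see Details).
#' @details `truth` records, per compartment where relevant: the variance
#'   fractions used, per-feature means and total sds, drug gene ids and
#'   signs, cluster memberships, planted directed cluster edges, lag gene
#'   ids with signed magnitudes, and per-sample depth factors.
#' @export
simulate_transcriptome <- function(design, params = sim_params()) {
  comps <- intersect(c("BM", "PB"), unique(design$compartment))
  if (length(comps) == 0L) stop("design contains no BM or PB samples",
                                call. = FALSE)
  n_feat <- params$n_features[["transcript"]]
  features <- sprintf("g%05d", seq_len(n_feat))
  cl <- params$planted_clusters
  with_seed(subseed(params$seed, "transcriptome"), {
    mu <- stats::runif(n_feat, 4, 14)
    s_f <- total_sd_curve(mu, params$noise_cv_curve, 4)
    fa <- params$animal_var_frac
    ft <- params$timepoint_var_frac
    sd_a <- s_f * sqrt(fa)
    sd_t <- s_f * sqrt(ft)
    sd_e <- s_f * sqrt(max(0, 1 - fa - ft))

    ## planted assignments over the feature universe
    n_cl_genes <- if (nrow(cl)) sum(cl$size) else 0L
    cluster_members <- if (n_cl_genes) {
      split(features[seq_len(n_cl_genes)],
            rep(seq_len(nrow(cl)), cl$size))
    } else list()
    pool <- setdiff(features, unlist(cluster_members))
    drug_genes <- utils::head(pool, params$n_drug_genes)
    pool <- setdiff(pool, drug_genes)
    lag_ids <- utils::head(pool, params$lag_genes)
    drug_sign <- stats::setNames(sample(c(-1, 1), length(drug_genes), TRUE),
                                 drug_genes)
    lag_eff <- stats::setNames(
      params$lag_magnitude * sample(c(-1, 1), length(lag_ids), TRUE), lag_ids)

    counts <- list()
    for (cp in comps) {
      dcp <- design_compartment(design, cp)
      n_s <- nrow(dcp)
      animals <- levels(factor(dcp$animal))
      tps <- sort(unique(dcp$timepoint))
      mu_cp <- mu + stats::rnorm(n_feat, 0, 0.3)
      a_eff <- matrix(stats::rnorm(n_feat * length(animals)), n_feat) * sd_a
      t_eff <- matrix(stats::rnorm(n_feat * length(tps)), n_feat) * sd_t
      colnames(a_eff) <- animals
      colnames(t_eff) <- as.character(tps)
      y <- mu_cp +
        a_eff[, as.character(dcp$animal), drop = FALSE] +
        t_eff[, as.character(dcp$timepoint), drop = FALSE]
      ## drug-phase effect on drug genes
      if (length(drug_genes)) {
        post <- dcp$drug_phase == "post"
        idx <- match(drug_genes, features)
        y[idx, post] <- y[idx, post] +
          params$drug_effect_size * drug_sign
      }
      ## residual noise; cluster members instead share a latent factor that
      ## carries their whole after-animal variance (so the planted
      ## within-correlation governs exactly the residualized profiles the
      ## clustering stage sees)
      raw_e <- matrix(stats::rnorm(n_feat * n_s), n_feat)
      e <- raw_e * sd_e
      if (length(cluster_members)) {
        L <- cluster_latents(dcp, cl, params$planted_edges,
                             params$cluster_tp_share)
        sd_na <- s_f * sqrt(1 - fa)   # all non-animal variance
        for (c_i in seq_along(cluster_members)) {
          idx <- match(cluster_members[[c_i]], features)
          rho <- cl$within_cor[c_i]
          e[idx, ] <- sd_na[idx] * (sqrt(rho) * rep(1, length(idx)) %o%
                                      L[, c_i] +
                                    sqrt(1 - rho) * raw_e[idx, ])
          ## zero out the independent timepoint effect for members
          y[idx, ] <- y[idx, ] -
            t_eff[idx, as.character(dcp$timepoint), drop = FALSE]
        }
      }
      y <- y + e
      ## lag signal: a signed excursion at BM TP4, echoed at PB TP5
      if (length(lag_ids)) {
        idx <- match(lag_ids, features)
        if (cp == "BM" && 4L %in% tps) {
          y[idx, dcp$timepoint == 4L] <- y[idx, dcp$timepoint == 4L] + lag_eff
        }
        if (cp == "PB" && 5L %in% tps) {
          y[idx, dcp$timepoint == 5L] <- y[idx, dcp$timepoint == 5L] + lag_eff
        }
      }
      depth <- exp(stats::runif(n_s, log(params$depth_range[1]),
                                log(params$depth_range[2])))
      cnt <- round(t(t(2^y) * depth))
      storage.mode(cnt) <- "integer"
      dimnames(cnt) <- list(features, dcp$sample_id)
      if (cp %in% comps) {
        counts[[cp]] <- cnt
        attr(counts[[cp]], "depth") <- stats::setNames(depth, dcp$sample_id)
      }
    }
    truth <- list(
      var_fracs = c(animal = fa, timepoint = ft),
      feature_mean = stats::setNames(mu, features),
      total_sd = stats::setNames(s_f, features),
      drug_genes = drug_genes,
      drug_sign = drug_sign,
      clusters = cluster_members,
      edges = params$planted_edges,
      lag_genes = lag_ids,
      lag_effect = lag_eff)
    list(counts = counts, truth = truth)
  })
}

#' Simulate an LC-MS metabolite feature table with technical replicates
#'
#' Raw-intensity features by (sample x 3 replicates); replicate noise is much
#' smaller than biological noise; a params-controlled fraction of features is
#' planted with high per-sample missingness, and low-abundance features fall
#' below the peak-area cutoff used by the QC filter.
#'
#' @param design a `sample_design` with plasma rows (timepoints 3..7).
#' @param params a [sim_params()] object.
#' @param column LC column label ("AE" or "C18"); each column draws its own
#'   random stream, emulating two feature sets measured from the same
#'   plasma samples.
#' @param n_replicates technical replicates per biological sample.
#' @return list with `table` (a `replicated_table`: intensity matrix with
#'   replicate-suffixed columns and a replicate map attribute) and `truth`.
#' @export
simulate_metabolome <- function(design, params = sim_params(),
                                column = "AE", n_replicates = 3L) {
  dcp <- design_compartment(design, "plasma")
  if (nrow(dcp) == 0L) stop("design contains no plasma samples",
                            call. = FALSE)
  n_feat <- params$n_features[["metabolite"]]
  features <- sprintf("%s%05d", tolower(column), seq_len(n_feat))
  with_seed(subseed(params$seed, paste0("metabolome", column)), {
    mu <- stats::runif(n_feat, 6, 20)
    s_f <- total_sd_curve(mu, params$noise_cv_curve, 6)
    fa <- params$metab_animal_var_frac
    ft <- params$metab_timepoint_var_frac
    animals <- levels(factor(dcp$animal))
    tps <- sort(unique(dcp$timepoint))
    a_eff <- matrix(stats::rnorm(n_feat * length(animals)), n_feat) *
      (s_f * sqrt(fa))
    t_eff <- matrix(stats::rnorm(n_feat * length(tps)), n_feat) *
      (s_f * sqrt(ft))
    colnames(a_eff) <- animals
    colnames(t_eff) <- as.character(tps)
    n_s <- nrow(dcp)
    bio <- mu +
      a_eff[, as.character(dcp$animal), drop = FALSE] +
      t_eff[, as.character(dcp$timepoint), drop = FALSE] +
      matrix(stats::rnorm(n_feat * n_s), n_feat) *
        (s_f * sqrt(max(0, 1 - fa - ft)))
    ## sample-level missingness (a missing sample loses all its replicates)
    n_high <- round(params$missing_frac * n_feat)
    high_missing <- sample(features, n_high)
    miss_p <- ifelse(features %in% high_missing, 0.45, 0.02)
    miss <- matrix(stats::runif(n_feat * n_s), n_feat) < miss_p
    cols <- as.vector(outer(dcp$sample_id, seq_len(n_replicates),
                            function(s, r) sprintf("%s_r%d", s, r)))
    tab <- matrix(NA_real_, n_feat, n_s * n_replicates,
                  dimnames = list(features, cols))
    for (r in seq_len(n_replicates)) {
      rep_log2 <- bio + matrix(stats::rnorm(n_feat * n_s), n_feat) *
        params$replicate_sd
      block <- 2^rep_log2
      block[miss] <- NA_real_
      tab[, (r - 1) * n_s + seq_len(n_s)] <- block
    }
    tab <- tab[, order(rep(seq_len(n_s), n_replicates)), drop = FALSE]
    rep_map <- data.frame(
      column = colnames(tab),
      sample_id = rep(dcp$sample_id, each = n_replicates),
      replicate = rep(seq_len(n_replicates), n_s),
      stringsAsFactors = FALSE)
    table <- structure(tab, rep_map = rep_map, design = dcp,
                       class = c("replicated_table", class(tab)))
    truth <- list(
      var_fracs = c(animal = fa, timepoint = ft),
      feature_mean = stats::setNames(mu, features),
      high_missing = high_missing,
      missing_frac_realized = stats::setNames(rowMeans(miss), features),
      below_cutoff = features[mu < 8])
    list(table = table, truth = truth)
  })
}

#' Simulate a complete blood count table
#'
#' Five cell types (red blood cells, lymphocytes, monocytes, platelets,
#' granulocytes) by samples, positive values, with animal-level offsets and
#' timepoint effects at the configured variance fractions.
#'
#' @param design a `sample_design`; rows with compartment "CBC" are used if
#'   present, otherwise all rows.
#' @param params a [sim_params()] object.
#' @param total_sd log2-scale total sd per cell type.
#' @return an [omics_matrix()] of positive counts (raw scale).
#' @export
simulate_cbc <- function(design, params = sim_params(), total_sd = 0.35) {
  dcp <- if ("CBC" %in% design$compartment) {
    design_compartment(design, "CBC")
  } else design
  cell_types <- c("R", "L", "M", "P", "G")
  base <- c(R = 12.3, L = 11.2, M = 8.1, P = 13.9, G = 11.5)
  fa <- params$cbc_animal_var_frac
  ft <- params$cbc_timepoint_var_frac
  with_seed(subseed(params$seed, "cbc"), {
    animals <- levels(factor(dcp$animal))
    tps <- sort(unique(dcp$timepoint))
    a_eff <- matrix(stats::rnorm(5 * length(animals)), 5) *
      (total_sd * sqrt(fa))
    t_eff <- matrix(stats::rnorm(5 * length(tps)), 5) *
      (total_sd * sqrt(ft))
    colnames(a_eff) <- animals
    colnames(t_eff) <- as.character(tps)
    y <- base +
      a_eff[, as.character(dcp$animal), drop = FALSE] +
      t_eff[, as.character(dcp$timepoint), drop = FALSE] +
      matrix(stats::rnorm(5 * nrow(dcp)), 5) *
        (total_sd * sqrt(max(0, 1 - fa - ft)))
    vals <- 2^y
    dimnames(vals) <- list(cell_types, dcp$sample_id)
    omics_matrix(vals, dcp, provenance = "simulated")
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper: design + transcriptomes + metabolome + blood counts
#' under one seed.
#' @param params a [sim_params()] object.
#' @param n_animals,timepoints design dimensions.
#' @return list with `design`, `counts`, `metabolome`, `cbc`, `truth`.
#' @export
simulate_study <- function(params = sim_params(), n_animals = 5,
                           timepoints = 7) {
  design <- generate_design(n_animals, timepoints,
                            c("BM", "PB", "plasma", "CBC"))
  tr <- simulate_transcriptome(design, params)
  ae <- simulate_metabolome(design, params, column = "AE")
  c18 <- simulate_metabolome(design, params, column = "C18")
  cbc <- simulate_cbc(design, params)
  list(design = design,
       counts = tr$counts,
       metabolome = list(AE = ae$table, C18 = c18$table),
       cbc = cbc,
       truth = list(transcriptome = tr$truth,
                    metabolome = list(AE = ae$truth, C18 = c18$truth)))
}
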