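#' Subsample/shuffle edge-robustness estimation
#'
#' For the original observation table and each of `n_shuffles`
#' gene-order-shuffled copies: discretize, then learn a network on each of
#' `n_subsamples` random row subsets of relative size `subsample_frac`,
#' recording how often every directed edge appears. An edge is robust when
#' its frequency reaches `edge_freq_threshold` in the original and in
#' every shuffled dataset (`mode = "strict"`); `mode = "pooled"` instead
#' requires the threshold on the frequency pooled over all datasets.
#' Shuffling the gene-block order guards against edges driven by a single
#' gene-to-gene alignment rather than by the clusters themselves.
#'
#' @param table a `cluster_obs_table`.
#' @param n_subsamples subsample replicates per dataset (default 1000).
#' @param subsample_frac fraction of rows per subsample (default 0.90).
#' @param n_shuffles shuffled datasets (default 3).
#' @param edge_freq_threshold robustness frequency cutoff (default 0.50).
#' @param levels discretization levels (scalar or per node; default 7).
#' @param k_candidates,max_parents,ess passed to
#'   [sparse_candidate_learn()].
#' @param seed global seed for shuffles and subsampling.
#' @param mode `"strict"` (threshold in every dataset) or `"pooled"`.
#' @param directed count directed edges (default) or collapse to the
#'   undirected skeleton before counting.
#' @return a `robust_edge_set`: list with `edges` (data frame: `from`,
#'   `to`, `freq_original`, `freq_shuffle<k>`, `freq_pooled`, `robust`),
#'   `overlap` (percent edge-set overlap original vs each shuffle at the
#'   threshold), and the call parameters.
#' @export
robust_network <- function(table, n_subsamples = 1000, subsample_frac = 0.90,
                           n_shuffles = 3, edge_freq_threshold = 0.50,
                           levels = 7, k_candidates = 5, max_parents = 3,
                           ess = 1, seed = 1,
                           mode = c("strict", "pooled"), directed = TRUE) {
  mode <- match.arg(mode)
  stopifnot(subsample_frac > 0, subsample_frac <= 1,
            edge_freq_threshold > 0, edge_freq_threshold <= 1)
  datasets <- c(list(original = table),
                stats::setNames(
                  lapply(seq_len(n_shuffles), function(s)
                    shuffle_gene_order(table, subseed(seed, paste0("shf", s)))),
                  if (n_shuffles > 0) paste0("shuffle", seq_len(n_shuffles))
                  else character(0)))
  n_obs <- nrow(table$values)
  n_keep <- round(subsample_frac * n_obs)
  freq <- list()
  for (ds in names(datasets)) {
    disc <- discretize_mi(datasets[[ds]], levels = levels)
    if (n_keep < max(disc$levels)) {
      stop("subsample smaller than the discretization support",
           call. = FALSE)
    }
    counts <- new.env(parent = emptyenv())
    for (s in seq_len(n_subsamples)) {
      rows <- with_seed(subseed(seed, paste(ds, "sub", s)),
                        sample(n_obs, n_keep))
      sub <- disc
      sub$codes <- disc$codes[rows, , drop = FALSE]
      net <- suppressWarnings(
        sparse_candidate_learn(sub, k_candidates = k_candidates,
                               max_parents = max_parents, ess = ess))
      keys <- edge_keys(net$edges, directed)
      for (k in keys) counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
    freq[[ds]] <- unlist(as.list(counts)) / n_subsamples
  }
  all_keys <- sort(unique(unlist(lapply(freq, names))))
  fm <- matrix(0, length(all_keys), length(datasets),
               dimnames = list(all_keys, names(datasets)))
  for (ds in names(datasets)) {
    f <- freq[[ds]]
    if (length(f)) fm[names(f), ds] <- f
  }
  pooled <- rowMeans(fm)
  robust <- if (mode == "strict") {
    rowSums(fm >= edge_freq_threshold) == ncol(fm)
  } else pooled >= edge_freq_threshold
  above <- lapply(names(datasets),
                  function(ds) all_keys[fm[, ds] >= edge_freq_threshold])
  names(above) <- names(datasets)
  overlap <- vapply(setdiff(names(datasets), "original"), function(ds) {
    u <- union(above$original, above[[ds]])
    if (length(u) == 0L) return(NA_real_)
    100 * length(intersect(above$original, above[[ds]])) / length(u)
  }, numeric(1))
  if (length(all_keys)) {
    ft <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
    edges <- data.frame(from = ft[, 1], to = ft[, 2],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- cbind(edges, as.data.frame(fm))
  names(edges)[-(1:2)] <- paste0("freq_", names(datasets))
  edges$freq_pooled <- pooled
  edges$robust <- robust
  rownames(edges) <- NULL
  structure(list(edges = edges, overlap = overlap,
                 threshold = edge_freq_threshold, mode = mode,
                 directed = directed, n_subsamples = n_subsamples,
                 subsample_frac = subsample_frac,
                 node_type = table$node_type),
            class = "robust_edge_set")
}

edge_keys <- function(edges, directed) {
  if (nrow(edges) == 0L) return(character(0))
  if (directed) {
    paste(edges$from, edges$to, sep = "\r")
  } else {
    paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
  }
}

#' @export
print.robust_edge_set <- function(x, ...) {
  cat(sprintf("robust_edge_set: %d candidate edges, %d robust at %.0f%% (%s)\n",
              nrow(x$edges), sum(x$edges$robust), 100 * x$threshold, x$mode))
  invisible(x)
}

#' Cross-compartment cluster conservation test
#'
#' Asks whether clusters found in one compartment remain coherent in
#' another. For each cluster: compute every member's Pearson correlation
#' to the cluster centroid in the other compartment's data, then compare
#' that distribution against `n_random` same-size random gene sets drawn
#' from the pool of all clustered genes (each random set correlated to its
#' own centroid) with a one-tailed Kolmogorov-Smirnov test for the real
#' distribution being right-shifted. Reports, per cluster, how many of the
#' random comparisons are significant at `alpha`.
#'
#' @param clusters a `cluster_set` (from the source compartment).
#' @param x_other expression matrix of the other compartment (same gene
#'   universe; animal-residualized in the pipeline).
#' @param n_random random gene sets per cluster (default 100).
#' @param alpha per-comparison KS significance level (default 0.05).
#' @param seed seed for the random draws.
#' @return data frame with one row per cluster: `cluster`, `size`,
#'   `n_significant` (of `n_random`), `median_r`.
#' @export
conservation_test <- function(clusters, x_other, n_random = 100,
                              alpha = 0.05, seed = 1) {
  m <- unclass(x_other)
  pool <- intersect(unique(unlist(lapply(clusters$clusters, `[[`,
                                         "members"))), rownames(m))
  rows <- lapply(seq_along(clusters$clusters), function(ci) {
    cl <- clusters$clusters[[ci]]
    members <- intersect(cl$members, rownames(m))
    if (length(pool) < length(members)) {
      stop("gene pool smaller than cluster ", ci, call. = FALSE)
    }
    real <- member_centroid_cors(m, members)
    n_sig <- 0L
    with_seed(subseed(seed, paste0("conserve", ci)), {
      for (r in seq_len(n_random)) {
        rnd <- member_centroid_cors(m, sample(pool, length(members)))
        p <- suppressWarnings(
          stats::ks.test(real, rnd, alternative = "less")$p.value)
        if (p < alpha) n_sig <- n_sig + 1L
      }
    })
    data.frame(cluster = ci, size = length(members),
               n_significant = n_sig, median_r = stats::median(real))
  })
  do.call(rbind, rows)
}

member_centroid_cors <- function(m, members) {
  centroid <- colMeans(m[members, , drop = FALSE])
  as.numeric(stats::cor(t(m[members, , drop = FALSE]), centroid))
}

#' Integrated transcript-metabolite network
#'
#' Restricts the transcript observation table to the timepoints shared
#' with the metabolome, unit-normalizes the metabolite node values, aligns
#' the two tables by (gene block, animal, timepoint), discretizes jointly
#' (different level counts per data type), and runs the subsample/shuffle
#' robustness procedure on the combined node set. Cross-data-type edges
#' are reported separately.
#'
#' @param transcript_table,metabolite_table `cluster_obs_table` objects.
#' @param levels_transcript,levels_metabolite discretization levels per
#'   data type (defaults 7 and 5).
#' @param ... further arguments to [robust_network()] (`n_subsamples`,
#'   `seed`, ...).
#' @return a `robust_edge_set` with an extra `cross_edges` element (the
#'   robust edges joining a transcript node to a metabolite node).
#' @export
integrated_network <- function(transcript_table, metabolite_table,
                               levels_transcript = 7, levels_metabolite = 5,
                               ...) {
  shared_tp <- intersect(unique(transcript_table$design$timepoint),
                         unique(metabolite_table$design$timepoint))
  if (length(shared_tp) == 0L) stop("no shared timepoints", call. = FALSE)
  tt <- restrict_observations(transcript_table, shared_tp)
  mt <- restrict_observations(metabolite_table, shared_tp)
  combined <- combine_observations(tt, mt, unit_normalize_b = TRUE)
  n_t <- ncol(tt$values)
  n_m <- ncol(mt$values)
  levels <- c(rep(levels_transcript, n_t), rep(levels_metabolite, n_m))
  combined$node_type <- stats::setNames(
    rep(c("transcript", "metabolite"), c(n_t, n_m)), combined$nodes)
  res <- robust_network(combined, levels = levels, ...)
  ty <- res$node_type
  res$cross_edges <- res$edges[res$edges$robust &
                                 ty[res$edges$from] != ty[res$edges$to], ,
                               drop = FALSE]
  res
}
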