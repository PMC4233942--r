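#' Quality-threshold clustering of feature profiles
#'
#' Iterated greedy QT procedure on the correlation distance
#' `1 - Pearson r` between feature rows (jackknifed correlation available
#' as an option). For every remaining feature as seed, a candidate cluster
#' is grown by repeatedly adding the feature whose inclusion keeps the
#' cluster diameter (maximum pairwise distance) minimal and at most `d`;
#' the largest candidate wins (ties: smaller diameter, then earlier seed),
#' its members are removed, and the process repeats until the largest
#' candidate falls below `min_size`.
#'
#' Input is expected to be animal-residualized (mean-centered within
#' animal) so the dominant among-animal variance does not drive the
#' clusters.
#'
#' @param x an [omics_matrix()] or matrix, features x samples.
#' @param d diameter threshold on the correlation distance (default 0.3).
#' @param min_size smallest cluster retained (default 10).
#' @param jackknife use the leave-one-sample-out minimum correlation
#'   instead of plain Pearson (more robust to single outlier samples,
#'   slower).
#' @return a `cluster_set`: list with `clusters` (each: `members`,
#'   `centroid`, `diameter`, `size`), `d`, `min_size`, `n_features`.
#' @export
qt_cluster <- function(x, d = 0.3, min_size = 10, jackknife = FALSE) {
  stopifnot(d > 0, d < 2)
  m <- unclass(x)
  feats <- rownames(m)
  n <- nrow(m)
  if (n < min_size) {
    warning("fewer than min_size features; returning an empty cluster set",
            call. = FALSE)
    return(empty_cluster_set(d, min_size, n))
  }
  D <- correlation_distance(m, jackknife)
  remaining <- seq_len(n)
  clusters <- list()
  repeat {
    best <- NULL
    for (seed_i in remaining) {
      cand <- qt_grow(D, remaining, seed_i, d)
      if (is.null(best) ||
          length(cand$members) > length(best$members) ||
          (length(cand$members) == length(best$members) &&
           cand$diameter < best$diameter)) {
        best <- cand
      }
    }
    if (is.null(best) || length(best$members) < min_size) break
    members <- feats[best$members]
    clusters[[length(clusters) + 1L]] <- list(
      members = members,
      centroid = colMeans(m[members, , drop = FALSE]),
      diameter = best$diameter,
      size = length(members))
    remaining <- setdiff(remaining, best$members)
    if (length(remaining) < min_size) break
  }
  structure(list(clusters = clusters, d = d, min_size = min_size,
                 n_features = n),
            class = "cluster_set")
}

empty_cluster_set <- function(d, min_size, n) {
  structure(list(clusters = list(), d = d, min_size = min_size,
                 n_features = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, numeric(1), "size")
  cat(sprintf("cluster_set: %d clusters (d = %g, min_size = %d)\n",
              length(x$clusters), x$d, x$min_size))
  if (length(sizes)) cat("sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

## grow one candidate cluster from a seed; greedy minimal-diameter growth
qt_grow <- function(D, remaining, seed_i, d) {
  members <- seed_i
  maxd <- D[remaining, seed_i]
  names(maxd) <- NULL
  in_cluster <- remaining == seed_i
  diameter <- 0
  repeat {
    ok <- !in_cluster & maxd <= d
    if (!any(ok)) break
    j_rel <- which(ok)[which.min(maxd[ok])]
    diameter <- max(diameter, maxd[j_rel])
    in_cluster[j_rel] <- TRUE
    members <- c(members, remaining[j_rel])
    maxd <- pmax(maxd, D[remaining, remaining[j_rel]])
  }
  list(members = members, diameter = diameter)
}

correlation_distance <- function(m, jackknife = FALSE) {
  if (!jackknife) return(1 - stats::cor(t(m)))
  n_s <- ncol(m)
  r_min <- matrix(Inf, nrow(m), nrow(m))
  for (s in seq_len(n_s)) {
    r_min <- pmin(r_min, stats::cor(t(m[, -s, drop = FALSE])))
  }
  1 - r_min
}

#' Cluster-count permutation check
#'
#' Permutes each feature's values independently under one of three schemes
#' and reruns QT clustering, reporting how much cluster structure survives:
#' `"full"` permutes all samples (destroys everything), `"within_animal"`
#' permutes timepoints within each animal (destroys temporal but not
#' animal-level structure; on residualized data this should destroy the
#' clusters), `"within_timepoint"` permutes animals within each timepoint
#' (leaves timepoint-driven co-expression intact).
#'
#' @param x matrix or `omics_matrix` (residualized, as for
#'   [qt_cluster()]).
#' @param design `sample_design` (needed for the within-* modes).
#' @param mode permutation scheme.
#' @param d,min_size passed to [qt_cluster()].
#' @param n_perm number of permutation replicates.
#' @param seed seed; replicate r uses a sub-seed derived from it.
#' @return data frame with one row per replicate: `replicate`,
#'   `n_clusters`, `largest`, `total_clustered`.
#' @export
cluster_permutation_check <- function(x, design = design_of(x),
                                      mode = c("full", "within_animal",
                                               "within_timepoint"),
                                      d = 0.3, min_size = 10, n_perm = 3,
                                      seed = 1) {
  mode <- match.arg(mode)
  m <- unclass(x)
  idx <- match(colnames(m), design$sample_id)
  animal <- factor(design$animal[idx])
  tp <- factor(design$timepoint[idx])
  blocks <- switch(mode,
                   full = list(seq_len(ncol(m))),
                   within_animal = split(seq_len(ncol(m)), animal),
                   within_timepoint = split(seq_len(ncol(m)), tp))
  rows <- lapply(seq_len(n_perm), function(r) {
    perm <- with_seed(subseed(seed, paste0("perm", mode, r)), {
      mp <- m
      for (i in seq_len(nrow(m))) {
        for (b in blocks) mp[i, b] <- m[i, sample(b)]
      }
      mp
    })
    cs <- suppressWarnings(qt_cluster(perm, d = d, min_size = min_size))
    sizes <- vapply(cs$clusters, `[[`, numeric(1), "size")
    data.frame(replicate = r,
               n_clusters = length(cs$clusters),
               largest = if (length(sizes)) max(sizes) else 0L,
               total_clustered = sum(sizes))
  })
  do.call(rbind, rows)
}
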