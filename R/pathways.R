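#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' @param path file path.
#' @return named list: set name -> character vector of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene-set file", call. = FALSE)
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Restrict gene sets to those expressed in every compartment
#'
#' A set is retained when at least `min_genes` of its members are present
#' (i.e. survived the abundance filter) in each supplied expression matrix.
#'
#' @param sets gene-set list (e.g. from [read_gmt()]).
#' @param matrices list of expression matrices (one per compartment).
#' @param min_genes minimum expressed members (default 5).
#' @return the filtered set list.
#' @export
filter_sets_expressed <- function(sets, matrices, min_genes = 5) {
  if (!is.list(matrices)) matrices <- list(matrices)
  keep <- vapply(sets, function(g) {
    all(vapply(matrices, function(m) sum(g %in% rownames(m)) >= min_genes,
               logical(1)))
  }, logical(1))
  if (!any(keep)) stop("no gene set passes the expressed-size filter",
                       call. = FALSE)
  sets[keep]
}

#' Per-pathway PC1 summary scores
#'
#' For each gene set, the first principal component of the standardized
#' member-gene submatrix, sign-oriented so the majority of gene loadings
#' are positive. Computed per compartment independently (loadings can
#' legitimately flip sign between compartments).
#'
#' @param x an [omics_matrix()].
#' @param sets gene-set list, already size-filtered (see
#'   [filter_sets_expressed()]).
#' @param min_genes sets with fewer expressed members are dropped here too.
#' @return a `pathway_scores` list: `scores` (pathways x samples matrix),
#'   `pve_pc1` (named vector), `loadings` (list of named vectors),
#'   `design`.
#' @export
pathway_pc1 <- function(x, sets, min_genes = 5) {
  scores <- list(); pve <- c(); loadings <- list()
  for (nm in names(sets)) {
    present <- intersect(sets[[nm]], rownames(x))
    if (length(present) < min_genes) next
    sub <- standardize_features(unclass(x)[present, , drop = FALSE])
    pr <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
    l1 <- pr$rotation[, 1]
    flip <- if (sum(l1 > 0) != sum(l1 < 0)) sum(l1 > 0) < sum(l1 < 0) else
      sum(l1) < 0
    s <- if (flip) -pr$x[, 1] else pr$x[, 1]
    scores[[nm]] <- s
    pve[nm] <- pr$sdev[1]^2 / sum(pr$sdev^2)
    loadings[[nm]] <- if (flip) -l1 else l1
  }
  if (length(scores) == 0L) stop("no pathway passes the size filter",
                                 call. = FALSE)
  structure(list(scores = do.call(rbind, scores),
                 pve_pc1 = pve, loadings = loadings,
                 design = design_of(x)),
            class = "pathway_scores")
}

#' Pathway-by-timepoint profile matrix
#'
#' Averages each pathway's per-sample PC1 score over animals within each
#' timepoint, producing the pathways-by-timepoints matrix used for profile
#' clustering.
#'
#' @param ps a `pathway_scores` object from [pathway_pc1()].
#' @param design `sample_design` (defaults to the bound one); every animal
#'   must be present at every timepoint.
#' @return numeric matrix pathways x timepoints (columns `TP1`, `TP2`, ...).
#' @export
profile_matrix <- function(ps, design = ps$design) {
  idx <- match(colnames(ps$scores), design$sample_id)
  tp <- design$timepoint[idx]
  animal <- design$animal[idx]
  cells <- table(animal, tp)
  if (any(cells != 1L)) {
    stop("design must have exactly one sample per animal x timepoint",
         call. = FALSE)
  }
  tps <- sort(unique(tp))
  out <- vapply(tps, function(t) rowMeans(ps$scores[, tp == t, drop = FALSE]),
                numeric(nrow(ps$scores)))
  out <- matrix(out, nrow = nrow(ps$scores),
                dimnames = list(rownames(ps$scores), paste0("TP", tps)))
  out
}

#' Ward clustering of pathway profiles
#'
#' Hierarchical clustering (Ward's method on Euclidean distances) of
#' pathway time profiles, cut either at a fixed number of clusters `k` or
#' at a dendrogram height `h`.
#'
#' @param ppm profile matrix from [profile_matrix()].
#' @param k number of clusters (used when given).
#' @param h dendrogram cut height (used when `k` is NULL).
#' @return named integer cluster labels (one per pathway), with the
#'   `hclust` object as attribute `"hclust"`.
#' @export
cluster_profiles <- function(ppm, k = NULL, h = NULL) {
  if (nrow(ppm) < 2L) stop("need at least 2 pathways", call. = FALSE)
  if (!is.null(k) && k > nrow(ppm)) {
    stop("k exceeds the number of pathways", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(ppm), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else
    if (!is.null(h)) stats::cutree(hc, h = h) else
      stats::cutree(hc, k = min(7, nrow(ppm)))
  attr(labels, "hclust") <- hc
  labels
}

#' Association between cluster labelings of two compartments
#'
#' Pearson chi-square test of the cross-tabulation of the two labelings
#' over a shared pathway universe, with Cramer's V and its square (the
#' fraction of one labeling's identity "explained" by the other) as effect
#' sizes.
#'
#' @param labels_a,labels_b named cluster labels over the same pathways.
#' @return list: `table`, `statistic`, `p`, `cramer_v`,
#'   `explained_fraction`.
#' @export
compartment_association <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0L) stop("no shared pathways", call. = FALSE)
  a <- factor(labels_a[common]); b <- factor(labels_b[common])
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both labelings need at least 2 clusters", call. = FALSE)
  }
  tab <- table(a, b)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v2 <- as.numeric(ct$statistic) / (n * (min(dim(tab)) - 1))
  list(table = tab, statistic = as.numeric(ct$statistic),
       p = ct$p.value, cramer_v = sqrt(v2), explained_fraction = v2)
}
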