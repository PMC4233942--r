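#' Select the most drug-responsive features
#'
#' Top-n features by ANOVA F statistic (ties broken by feature id), the
#' feature-selection step ahead of QT clustering. Defaults in the pipeline:
#' 1000 transcripts, 500 metabolite features.
#'
#' @param test_results `feature_tests` data frame from [feature_anova()].
#' @param n number of features to keep.
#' @return character vector of feature ids, in rank order.
#' @export
select_top_features <- function(test_results, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  n <- min(n, nrow(test_results))
  ord <- order(-test_results$f, test_results$feature)
  test_results$feature[ord][seq_len(n)]
}

#' Concatenate top cluster members into a node observation table
#'
#' Bayesian network inference on a handful of samples is underpowered, so
#' each cluster's top members (by correlation with the cluster centroid)
#' are treated as repeated observations of the cluster: with `top_n = 10`
#' genes and 35 samples each node gets 350 observations (250 for a
#' 25-sample metabolome).
#'
#' @param clusters a `cluster_set` from [qt_cluster()].
#' @param x the matrix the clusters were built on (e.g.
#'   animal-residualized expression); values are taken from here.
#' @param top_n members concatenated per cluster (default 10).
#' @return a `cluster_obs_table`: list with `values` (observations x
#'   nodes), `nodes`, `members` (top_n x nodes gene ids, block order),
#'   `gene_block`, `sample_id`, `design`, `node_type`.
#' @export
concatenate_observations <- function(clusters, x, top_n = 10) {
  m <- unclass(x)
  d <- design_of(x)
  small <- vapply(clusters$clusters, function(cl) cl$size < top_n,
                  logical(1))
  if (any(small)) {
    stop("cluster(s) smaller than top_n: ",
         paste(which(small), collapse = ", "), call. = FALSE)
  }
  n_s <- ncol(m)
  nodes <- sprintf("C%d", seq_along(clusters$clusters))
  members <- matrix(NA_character_, top_n, length(nodes),
                    dimnames = list(NULL, nodes))
  values <- matrix(NA_real_, top_n * n_s, length(nodes),
                   dimnames = list(NULL, nodes))
  for (ci in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[ci]]
    cors <- apply(m[cl$members, , drop = FALSE], 1, stats::cor,
                  y = cl$centroid)
    top <- cl$members[order(-cors, cl$members)][seq_len(top_n)]
    members[, ci] <- top
    values[, ci] <- as.vector(t(m[top, , drop = FALSE]))
  }
  structure(list(values = values,
                 nodes = nodes,
                 members = members,
                 gene_block = rep(seq_len(top_n), each = n_s),
                 sample_id = rep(colnames(m), top_n),
                 design = d,
                 node_type = stats::setNames(rep("transcript",
                                                 length(nodes)), nodes)),
            class = "cluster_obs_table")
}

#' @export
print.cluster_obs_table <- function(x, ...) {
  cat(sprintf("cluster_obs_table: %d nodes x %d observations (%d gene blocks)\n",
              ncol(x$values), nrow(x$values), max(x$gene_block)))
  invisible(x)
}

#' Shuffle the gene-block order of each node independently
#'
#' Permutes the order of the top-n gene blocks within every node (each
#' block's internal sample order preserved), independently across nodes.
#' Used to build the shuffled datasets of the robustness procedure: if the
#' member genes are good representatives of their cluster, edges should
#' not depend on which particular gene of one cluster lines up with which
#' gene of another.
#'
#' @param table a `cluster_obs_table`.
#' @param seed integer seed (each node draws its permutation from a
#'   sub-stream).
#' @return a new `cluster_obs_table` with permuted block order per node.
#' @export
shuffle_gene_order <- function(table, seed) {
  top_n <- max(table$gene_block)
  n_s <- length(unique(table$sample_id))
  out <- table
  with_seed(subseed(seed, "shuffle_gene_order"), {
    for (j in seq_len(ncol(table$values))) {
      perm <- sample(top_n)
      blockwise <- matrix(table$values[, j], nrow = n_s)
      out$values[, j] <- as.vector(blockwise[, perm])
      if (!is.null(out$members)) out$members[, j] <- table$members[perm, j]
    }
  })
  out
}

#' Restrict an observation table to a set of timepoints
#'
#' Drops observation rows from samples outside `timepoints` (used to align
#' the transcriptome with a metabolome collected at later timepoints
#' only).
#'
#' @param table a `cluster_obs_table`.
#' @param timepoints timepoints to keep.
#' @return the restricted table.
#' @export
restrict_observations <- function(table, timepoints) {
  d <- table$design
  tp <- d$timepoint[match(table$sample_id, d$sample_id)]
  keep <- tp %in% timepoints
  if (!any(keep)) stop("no observations at the requested timepoints",
                       call. = FALSE)
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$gene_block <- table$gene_block[keep]
  out$sample_id <- table$sample_id[keep]
  out$design <- d[d$timepoint %in% timepoints, , drop = FALSE]
  class(out$design) <- c("sample_design", "data.frame")
  out
}

#' Combine two observation tables over a shared design
#'
#' Aligns rows of two tables (e.g. transcript and metabolite cluster
#' nodes) by (gene block, animal, timepoint) and binds their node columns.
#' Optionally scales each node of the second table to unit variance, the
#' convention used when integrating metabolite clusters with transcript
#' clusters.
#'
#' @param table_a,table_b `cluster_obs_table` objects with equal
#'   observation counts after alignment.
#' @param unit_normalize_b scale table_b node columns to sd 1?
#' @return a combined `cluster_obs_table`; node names get `"t_"` / `"m_"`
#'   style prefixes only if the inputs share names.
#' @export
combine_observations <- function(table_a, table_b, unit_normalize_b = TRUE) {
  key <- function(tab) {
    d <- tab$design
    i <- match(tab$sample_id, d$sample_id)
    paste(tab$gene_block, d$animal[i], d$timepoint[i], sep = "|")
  }
  ka <- key(table_a); kb <- key(table_b)
  if (nrow(table_a$values) != nrow(table_b$values) ||
      anyNA(match(ka, kb))) {
    stop("observation tables do not align on (block, animal, timepoint); ",
         "restrict to shared timepoints first", call. = FALSE)
  }
  vb <- table_b$values[match(ka, kb), , drop = FALSE]
  if (unit_normalize_b) vb <- scale(vb, center = FALSE,
                                    scale = apply(vb, 2, stats::sd))
  nodes_b <- colnames(table_b$values)
  if (any(nodes_b %in% colnames(table_a$values))) {
    nodes_b <- paste0("b_", nodes_b)
  }
  vals <- cbind(table_a$values, vb)
  colnames(vals) <- c(colnames(table_a$values), nodes_b)
  out <- table_a
  out$values <- vals
  out$nodes <- colnames(vals)
  out$members <- NULL
  out$node_type <- c(table_a$node_type,
                     stats::setNames(table_b$node_type, nodes_b))
  out
}
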