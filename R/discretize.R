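#' Mutual-information-preserving discretization
#'
#' Hartemink-style stepwise coalescence: every node starts at a fine
#' quantile binning, then adjacent bin pairs are merged greedily — at each
#' step, over all nodes still above their target level count, the merge
#' losing the least total pairwise mutual information with all other nodes
#' is applied — until every node reaches its target number of levels.
#' With `levels = "auto"` the remaining-MI-versus-level-count curve is
#' computed down to 2 levels and the elbow (maximum distance to the chord
#' joining the curve's endpoints) picks the level count. Pipeline
#' defaults: 7 levels for transcript nodes, 5 for metabolite nodes.
#'
#' @param table a `cluster_obs_table`, or a plain observations x nodes
#'   matrix.
#' @param levels target level count: scalar, per-node named/positional
#'   vector, or `"auto"`.
#' @param init_bins starting quantile bin count (default 20).
#' @return a `disc_table`: list with `codes` (integer observations x
#'   nodes, monotone in the input values), `levels` (per node),
#'   `boundaries` (per node, monotone numeric cut points), and `mi_curve`
#'   (when `levels = "auto"`).
#' @export
discretize_mi <- function(table, levels = 7, init_bins = 20) {
  vals <- if (inherits(table, "cluster_obs_table")) table$values else
    as.matrix(table)
  n_nodes <- ncol(vals)
  node_names <- colnames(vals) %||% sprintf("N%d", seq_len(n_nodes))
  colnames(vals) <- node_names
  auto <- identical(levels, "auto")
  target <- if (auto) rep(2L, n_nodes) else {
    lv <- if (length(levels) == 1L) rep(levels, n_nodes) else {
      stopifnot(length(levels) == n_nodes)
      if (!is.null(names(levels))) as.integer(levels[node_names]) else
        as.integer(levels)
    }
    as.integer(lv)
  }
  stopifnot(all(target >= 2L))

  ## initial fine quantile binning
  codes <- matrix(NA_integer_, nrow(vals), n_nodes,
                  dimnames = list(NULL, node_names))
  breaks <- vector("list", n_nodes)
  for (j in seq_len(n_nodes)) {
    v <- vals[, j]
    if (length(unique(v)) < 2L) {
      stop("node '", node_names[j], "' is constant", call. = FALSE)
    }
    br <- unique(stats::quantile(v, probs = seq(0, 1,
                                                length.out = init_bins + 1),
                                 names = FALSE, type = 7))
    br[1] <- -Inf; br[length(br)] <- Inf
    codes[, j] <- as.integer(cut(v, br))
    breaks[[j]] <- br
  }
  n_bins <- apply(codes, 2, max)

  ## pairwise joint count matrices, kept up to date across merges
  joint <- vector("list", n_nodes)
  for (a in seq_len(n_nodes)) joint[[a]] <- vector("list", n_nodes)
  for (a in seq_len(n_nodes)) {
    for (b in seq_len(n_nodes)) {
      if (b <= a) next
      joint[[a]][[b]] <- count_matrix(codes[, a], codes[, b],
                                      n_bins[a], n_bins[b])
    }
  }
  get_joint <- function(a, b) if (a < b) joint[[a]][[b]] else
    t(joint[[b]][[a]])
  node_mi <- function(a, C_a = NULL) {
    tot <- 0
    for (b in seq_len(n_nodes)) {
      if (b == a) next
      C <- if (is.null(C_a)) get_joint(a, b) else C_a[[b]]
      tot <- tot + mi_from_counts(C)
    }
    tot
  }

  mi_curve <- NULL
  if (auto) {
    lv0 <- max(n_bins)
    mi_curve <- data.frame(levels = lv0, total_mi = total_mi(joint, n_nodes))
    snapshots <- list()
    snapshots[[as.character(lv0)]] <- list(codes = codes, breaks = breaks)
  }

  while (any(n_bins > target)) {
    best <- NULL
    for (a in which(n_bins > target)) {
      base <- node_mi(a)
      for (b in seq_len(n_bins[a] - 1L)) {
        merged_mi <- 0
        for (j in seq_len(n_nodes)) {
          if (j == a) next
          C <- get_joint(a, j)
          merged_mi <- merged_mi + mi_from_counts(merge_rows(C, b))
        }
        loss <- base - merged_mi
        if (is.null(best) || loss < best$loss - 1e-12) {
          best <- list(node = a, bin = b, loss = loss)
        }
      }
    }
    a <- best$node; b <- best$bin
    codes[, a] <- ifelse(codes[, a] > b, codes[, a] - 1L, codes[, a])
    breaks[[a]] <- breaks[[a]][-(b + 1L)]
    n_bins[a] <- n_bins[a] - 1L
    for (j in seq_len(n_nodes)) {
      if (j == a) next
      if (a < j) joint[[a]][[j]] <- merge_rows(joint[[a]][[j]], b) else
        joint[[j]][[a]] <- t(merge_rows(t(joint[[j]][[a]]), b))
    }
    if (auto && max(n_bins) < utils::tail(mi_curve$levels, 1)) {
      lv <- max(n_bins)
      mi_curve <- rbind(mi_curve,
                        data.frame(levels = lv,
                                   total_mi = total_mi(joint, n_nodes)))
      snapshots[[as.character(lv)]] <- list(codes = codes, breaks = breaks)
    }
  }

  if (auto) {
    lv_star <- elbow_point(mi_curve$levels, mi_curve$total_mi)
    snap <- snapshots[[as.character(lv_star)]]
    codes <- snap$codes; breaks <- snap$breaks
    n_bins <- apply(codes, 2, max)
  }
  structure(list(codes = codes,
                 levels = stats::setNames(as.integer(n_bins), node_names),
                 boundaries = stats::setNames(breaks, node_names),
                 mi_curve = mi_curve),
            class = "disc_table")
}

count_matrix <- function(ca, cb, na_, nb_) {
  matrix(tabulate((cb - 1L) * na_ + ca, nbins = na_ * nb_), na_, nb_)
}

merge_rows <- function(C, b) {
  C[b, ] <- C[b, ] + C[b + 1L, ]
  C[-(b + 1L), , drop = FALSE]
}

## mutual information (nats) from a joint count matrix
mi_from_counts <- function(C) {
  N <- sum(C)
  if (N == 0) return(0)
  P <- C / N
  pr <- rowSums(P); pc <- colSums(P)
  pos <- P > 0
  sum(P[pos] * log(P[pos] / outer(pr, pc)[pos]))
}

total_mi <- function(joint, n_nodes) {
  tot <- 0
  for (a in seq_len(n_nodes)) {
    for (b in seq_len(n_nodes)) {
      if (b <= a) next
      tot <- tot + mi_from_counts(joint[[a]][[b]])
    }
  }
  tot
}

## elbow of a decreasing curve by maximum distance to the chord between its
## endpoints
elbow_point <- function(x, y) {
  if (length(x) < 3L) return(x[length(x)])
  x1 <- x[1]; y1 <- y[1]
  x2 <- x[length(x)]; y2 <- y[length(x)]
  dx <- x2 - x1; dy <- y2 - y1
  dist <- abs(dy * x - dx * y + x2 * y1 - y2 * x1) / sqrt(dx^2 + dy^2)
  x[which.max(dist)]
}
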