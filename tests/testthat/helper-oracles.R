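## Independent brute-force oracles used to cross-check the package
## implementations. These deliberately use the most naive formulation.

## Benjamini-Hochberg step-up by the textbook definition:
## q_i = min_{j >= rank(i)} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) m * p[ord][j] / j, numeric(1)), 1)
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

## one-sided KS statistic: sup over x of ECDF_y(x) - ECDF_x(x)
## (positive when x is right-shifted relative to y)
oracle_ks_less <- function(x, y) {
  grid <- sort(c(x, y))
  max(stats::ecdf(y)(grid) - stats::ecdf(x)(grid))
}

## Pearson chi-square from the definition
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

## exhaustive QT first-cluster search: the largest subset (ties: smallest
## diameter) whose diameter (max pairwise distance) is <= d
oracle_qt_first <- function(D, d) {
  n <- nrow(D)
  best <- NULL
  for (size in n:1) {
    combos <- utils::combn(n, size)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      diam <- if (size == 1) 0 else max(D[idx, idx][upper.tri(D[idx, idx])])
      if (diam <= d && (is.null(best) || size > length(best$idx) ||
                        (size == length(best$idx) && diam < best$diam))) {
        best <- list(idx = idx, diam = diam)
      }
    }
    if (!is.null(best)) break
  }
  best
}

## mutual information of two discrete codes, from the definition
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
    }
  }
  tot
}

## brute-force best merge sequence for a 2-node system: enumerate every
## sequence of adjacent-bin merges of node 1 down to `target` levels and
## return the maximum retained MI with node 2
oracle_best_merge_mi <- function(codes1, codes2, target) {
  explore <- function(codes1) {
    L <- max(codes1)
    if (L == target) return(oracle_mi(codes1, codes2))
    best <- -Inf
    for (b in seq_len(L - 1)) {
      merged <- ifelse(codes1 > b, codes1 - 1L, codes1)
      best <- max(best, explore(merged))
    }
    best
  }
  explore(codes1)
}

## adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxidx - expected)
}

## small design + matrix fixtures built in code
tiny_design <- function(n_animals = 3, timepoints = 4, compartment = "BM") {
  generate_design(n_animals, timepoints, compartment)
}

## matrix with known group structure: feature value = animal index
animal_matrix <- function(design, n_features = 6) {
  a <- as.integer(factor(design$animal))
  m <- matrix(rep(a, each = n_features), n_features,
              dimnames = list(sprintf("f%d", seq_len(n_features)),
                              design$sample_id))
  omics_matrix(m, design)
}

## null-config simulation parameters (no planted structure beyond fractions)
null_params <- function(seed, animal = 0.6, timepoint = 0.15, ...) {
  sim_params(animal_var_frac = animal, timepoint_var_frac = timepoint,
             n_drug_genes = 0, lag_genes = 0,
             planted_clusters = data.frame(size = integer(0),
                                           within_cor = numeric(0)),
             planted_edges = data.frame(from = integer(0), to = integer(0),
                                        strength = numeric(0)),
             seed = seed, ...)
}

## sample a discrete chain X -> Y -> Z with strong conditional dependence
chain_codes <- function(n, levels = 3, noise = 0.1, seed = 1) {
  set.seed(seed)
  x <- sample(seq_len(levels), n, replace = TRUE)
  flip <- function(v) ifelse(stats::runif(n) < noise,
                             sample(seq_len(levels), n, replace = TRUE), v)
  y <- flip(x)
  z <- flip(y)
  codes <- cbind(X = x, Y = y, Z = z)
  structure(list(codes = codes,
                 levels = c(X = levels, Y = levels, Z = levels),
                 boundaries = NULL, mi_curve = NULL),
            class = "disc_table")
}

## brute-force optimum for multi-node adjacent-bin coarsening: any sequence
## of adjacent merges can reach any ordered partition of each node's bins,
## so the optimum is the max total pairwise MI over all adjacent partitions
## into the target level counts
oracle_best_partition_mi <- function(codes, targets) {
  n_nodes <- ncol(codes)
  comps <- function(n_bins, k) {
    ## all ways to cut n_bins ordered bins into k adjacent groups
    cuts <- utils::combn(n_bins - 1, k - 1)
    lapply(seq_len(ncol(cuts)), function(i) {
      b <- c(0, cuts[, i], n_bins)
      rep(seq_len(k), diff(b))
    })
  }
  maps <- lapply(seq_len(n_nodes), function(j)
    comps(max(codes[, j]), targets[j]))
  grid <- do.call(expand.grid, lapply(maps, seq_along))
  best <- -Inf
  for (g in seq_len(nrow(grid))) {
    rec <- sapply(seq_len(n_nodes), function(j)
      maps[[j]][[grid[g, j]]][codes[, j]])
    tot <- 0
    for (a in seq_len(n_nodes - 1)) {
      for (b in (a + 1):n_nodes) tot <- tot + oracle_mi(rec[, a], rec[, b])
    }
    best <- max(best, tot)
  }
  best
}
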