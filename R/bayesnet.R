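#' Sparse Candidate Bayesian network structure learning
#'
#' Alternates a restrict step — each node's candidate parent set is the
#' `k_candidates` other nodes with the highest pairwise mutual
#' information, always retaining the node's current parents — with a
#' maximize step: greedy hill climbing over edge addition, deletion and
#' reversal confined to the candidate sets, scored by the decomposable
#' BDeu Bayesian score (uniform structure prior) and maintaining
#' acyclicity. Iterates until the score stops improving or `max_iter`
#' rounds. Fully deterministic for fixed input (ties resolve toward the
#' lowest node index).
#'
#' @param disc a `disc_table` from [discretize_mi()].
#' @param k_candidates candidate parents per node (default 5).
#' @param max_parents parent-set size cap (default 3).
#' @param max_iter restrict/maximize rounds (default 20).
#' @param ess equivalent sample size of the BDeu prior (default 1).
#' @return a `bayes_net`: list with `nodes`, `parents` (named list of
#'   parent index vectors), `edges` (data frame `from`, `to`), `score`.
#' @export
sparse_candidate_learn <- function(disc, k_candidates = 5, max_parents = 3,
                                   max_iter = 20, ess = 1) {
  if (k_candidates < 1) stop("k_candidates must be >= 1", call. = FALSE)
  codes <- disc$codes
  n <- ncol(codes)
  nodes <- colnames(codes)
  arity <- as.integer(disc$levels)
  if (nrow(codes) < 50) {
    warning("fewer than 50 observations; structure estimates will be noisy",
            call. = FALSE)
  }
  ## pairwise MI for the restrict step
  mi <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      C <- count_matrix(codes[, a], codes[, b], arity[a], arity[b])
      mi[a, b] <- mi[b, a] <- mi_from_counts(C)
    }
  }
  cache <- new.env(parent = emptyenv())
  fam_score <- function(i, pa) {
    key <- paste(i, paste(sort(pa), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- bdeu_family_score(codes, arity, i, sort(pa), ess)
    cache[[key]] <- s
    s
  }
  parents <- rep(list(integer(0)), n)
  total <- sum(vapply(seq_len(n), function(i) fam_score(i, parents[[i]]),
                      numeric(1)))
  for (iter in seq_len(max_iter)) {
    prev_total <- total
    ## restrict: top-MI candidates, current parents always retained
    cand <- lapply(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      ranked <- others[order(-mi[i, others], others)]
      unique(c(parents[[i]], ranked))[seq_len(min(k_candidates, n - 1L))]
    })
    ## maximize: greedy hill climbing within candidate sets
    repeat {
      best <- NULL
      for (i in seq_len(n)) {
        base_i <- fam_score(i, parents[[i]])
        for (j in cand[[i]]) {
          if (j %in% parents[[i]]) next
          if (length(parents[[i]]) >= max_parents) next
          if (creates_cycle(parents, j, i)) next
          delta <- fam_score(i, c(parents[[i]], j)) - base_i
          if (is.null(best) || delta > best$delta + 1e-9) {
            best <- list(op = "add", i = i, j = j, delta = delta)
          }
        }
        for (j in parents[[i]]) {
          delta <- fam_score(i, setdiff(parents[[i]], j)) - base_i
          if (is.null(best) || delta > best$delta + 1e-9) {
            best <- list(op = "del", i = i, j = j, delta = delta)
          }
          ## reversal j -> i  becomes  i -> j
          if (i %in% cand[[j]] && length(parents[[j]]) < max_parents) {
            p2 <- parents
            p2[[i]] <- setdiff(p2[[i]], j)
            if (!creates_cycle(p2, i, j)) {
              delta_r <- (fam_score(i, p2[[i]]) - base_i) +
                (fam_score(j, c(parents[[j]], i)) -
                   fam_score(j, parents[[j]]))
              if (is.null(best) || delta_r > best$delta + 1e-9) {
                best <- list(op = "rev", i = i, j = j, delta = delta_r)
              }
            }
          }
        }
      }
      if (is.null(best) || best$delta <= 1e-9) break
      parents <- apply_move(parents, best)
      total <- total + best$delta
    }
    if (total <= prev_total + 1e-9 && iter > 1L) break
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(parents[[i]]) == 0L) return(NULL)
    data.frame(from = nodes[parents[[i]]], to = nodes[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(from = character(0),
                                          to = character(0))
  structure(list(nodes = nodes,
                 parents = stats::setNames(parents, nodes),
                 edges = edges,
                 score = total),
            class = "bayes_net")
}

apply_move <- function(parents, mv) {
  if (mv$op == "add") {
    parents[[mv$i]] <- sort(c(parents[[mv$i]], mv$j))
  } else if (mv$op == "del") {
    parents[[mv$i]] <- setdiff(parents[[mv$i]], mv$j)
  } else {
    parents[[mv$i]] <- setdiff(parents[[mv$i]], mv$j)
    parents[[mv$j]] <- sort(c(parents[[mv$j]], mv$i))
  }
  parents
}

## would adding edge j -> i create a directed cycle? (i.e. is there already
## a path i -> ... -> j following parent-to-child direction)
creates_cycle <- function(parents, j, i) {
  if (i == j) return(TRUE)
  ## search ancestors of j for i
  seen <- logical(length(parents))
  stack <- parents[[j]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == i) return(TRUE)
    if (!seen[v]) {
      seen[v] <- TRUE
      stack <- c(stack, parents[[v]])
    }
  }
  FALSE
}

## BDeu family score with equivalent sample size `ess`
bdeu_family_score <- function(codes, arity, i, pa, ess) {
  r_i <- arity[i]
  if (length(pa) == 0L) {
    Nk <- tabulate(codes[, i], nbins = r_i)
    a_k <- ess / r_i
    return(lgamma(ess) - lgamma(ess + sum(Nk)) +
             sum(lgamma(a_k + Nk) - lgamma(a_k)))
  }
  q_i <- prod(arity[pa])
  cfg <- codes[, pa[1]]
  if (length(pa) > 1L) {
    mult <- arity[pa[1]]
    for (t in 2L:length(pa)) {
      cfg <- cfg + (codes[, pa[t]] - 1L) * mult
      mult <- mult * arity[pa[t]]
    }
  }
  Njk <- matrix(tabulate((codes[, i] - 1L) * q_i + cfg, nbins = q_i * r_i),
                q_i, r_i)
  Nj <- rowSums(Njk)
  a_j <- ess / q_i
  a_jk <- ess / (q_i * r_i)
  nz <- Nj > 0
  sum(lgamma(a_j) - lgamma(a_j + Nj[nz])) +
    sum(lgamma(a_jk + Njk[Njk > 0]) - lgamma(a_jk))
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("bayes_net: %d nodes, %d edges, score %.2f\n",
              length(x$nodes), nrow(x$edges), x$score))
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
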