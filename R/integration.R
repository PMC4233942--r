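#' Cross-omic PC correlation grid
#'
#' Pairwise Pearson correlations among the first `k` PC score vectors of
#' several datasets, matched on (animal, timepoint) keys so that datasets
#' with different sample coverage (e.g. a metabolome restricted to later
#' timepoints) are compared on their overlap. Significance is assessed
#' against a Bonferroni-adjusted threshold over all pairs: with 4 datasets
#' and 10 PCs each, `choose(40, 2) = 780` tests.
#'
#' @param pcrs named list of `pc_result` objects.
#' @param k number of leading PCs per dataset (default 10).
#' @param alpha family-wise error rate before Bonferroni division.
#' @return a `correlation_grid`: list with `pairs` (long data frame: axis
#'   labels, r, n, p, significant flag), `r` (full symmetric matrix),
#'   `n_tests`, `alpha`.
#' @export
pc_correlation_grid <- function(pcrs, k = 10, alpha = 0.05) {
  stopifnot(is.list(pcrs), length(pcrs) >= 1)
  if (is.null(names(pcrs))) names(pcrs) <- paste0("ds", seq_along(pcrs))
  short <- lapply(names(pcrs), function(nm) {
    p <- pcrs[[nm]]
    if (ncol(p$scores) < k) {
      stop("dataset '", nm, "' has only ", ncol(p$scores),
           " PCs, fewer than k = ", k, call. = FALSE)
    }
    idx <- match(rownames(p$scores), p$design$sample_id)
    key <- paste(p$design$animal[idx], p$design$timepoint[idx], sep = "|")
    list(scores = p$scores[, seq_len(k), drop = FALSE], key = key)
  })
  names(short) <- names(pcrs)
  labels <- as.vector(t(outer(names(pcrs), seq_len(k), paste, sep = "_PC")))
  n_axes <- length(labels)
  n_tests <- choose(n_axes, 2)
  rmat <- matrix(NA_real_, n_axes, n_axes, dimnames = list(labels, labels))
  rows <- vector("list", n_tests)
  ri <- 0L
  for (a in seq_along(short)) {
    for (b in a:length(short)) {
      keys <- intersect(short[[a]]$key, short[[b]]$key)
      if (length(keys) < 3L) {
        stop("datasets '", names(short)[a], "' and '", names(short)[b],
             "' share fewer than 3 samples", call. = FALSE)
      }
      sa <- short[[a]]$scores[match(keys, short[[a]]$key), , drop = FALSE]
      sb <- short[[b]]$scores[match(keys, short[[b]]$key), , drop = FALSE]
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          if (a == b && j <= i) next
          r <- stats::cor(sa[, i], sb[, j])
          n <- length(keys)
          p <- cor_p(r, n)
          ri <- ri + 1L
          la <- sprintf("%s_PC%d", names(short)[a], i)
          lb <- sprintf("%s_PC%d", names(short)[b], j)
          rmat[la, lb] <- rmat[lb, la] <- r
          rows[[ri]] <- data.frame(axis1 = la, axis2 = lb, r = r, n = n,
                                   p = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- do.call(rbind, rows[seq_len(ri)])
  pairs$significant <- pairs$p < alpha / n_tests
  structure(list(pairs = pairs, r = rmat, n_tests = n_tests, alpha = alpha),
            class = "correlation_grid")
}

## two-sided p-value for a Pearson correlation via the t transform
cor_p <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("correlation_grid: %d axis pairs, %d significant at Bonferroni %g\n",
              x$n_tests, sum(x$pairs$significant), x$alpha / x$n_tests))
  invisible(x)
}

#' Two-way hierarchical clustering of features and samples
#'
#' Euclidean-distance hierarchical clustering of rows and columns, the view
#' behind a clustered heat map. Leaf order is deterministic for a fixed
#' input (ties resolve by input order).
#'
#' @param x an `omics_matrix` or matrix; no missing values (impute
#'   upstream).
#' @param linkage `"ward"` (Ward's method on squared distances) or
#'   `"average"`.
#' @param standardized standardize feature rows to z-scores first?
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   and `values` reordered accordingly.
#' @export
two_way_hierarchical <- function(x, linkage = c("ward", "average"),
                                 standardized = FALSE) {
  linkage <- match.arg(linkage)
  m <- unclass(x)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values present; impute before clustering",
                     call. = FALSE)
  if (standardized) m <- standardize_features(m)
  method <- if (linkage == "ward") "ward.D2" else "average"
  hr <- stats::hclust(stats::dist(m), method = method)
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  list(row_hclust = hr, col_hclust = hc,
       row_order = rownames(m)[hr$order],
       col_order = colnames(m)[hc$order],
       values = m[hr$order, hc$order, drop = FALSE])
}

#' Lagged cross-compartment concordance sign test
#'
#' Selects genes deviating in one direction in the source compartment at
#' `source_tp` (by default: positive deviation of the animal-averaged
#' timepoint mean from the gene's grand mean, on animal-residualized data)
#' and tests, by an exact two-sided binomial test against 0.5, whether the
#' same genes deviate in the same direction in the target compartment at
#' `target_tp`. Genes with a zero target deviation are excluded.
#'
#' @param source,target `omics_matrix` objects sharing a gene universe
#'   (e.g. bone marrow and peripheral blood).
#' @param source_tp,target_tp timepoints compared (e.g. 4 and 5 for a
#'   one-timepoint marrow-to-blood lag).
#' @param direction `"up"` selects source-positive genes, `"down"` the
#'   mirror.
#' @param min_abs minimum absolute source deviation (log2 units) for a gene
#'   to count as regulated; 0 keeps every gene with the right sign.
#' @param gene_rule optional function(deviations) returning a logical
#'   selection vector, replacing the default sign-and-magnitude rule.
#' @param residualize remove animal means before computing deviations
#'   (default TRUE).
#' @return list: `n_concordant`, `n_total`, `p` (exact binomial), `genes`
#'   (selected ids).
#' @export
lagged_sign_test <- function(source, target, source_tp = 4, target_tp = 5,
                             direction = c("up", "down"), min_abs = 0,
                             gene_rule = NULL, residualize = TRUE) {
  direction <- match.arg(direction)
  genes <- intersect(rownames(source), rownames(target))
  if (length(genes) == 0L) stop("no shared genes", call. = FALSE)
  dev_src <- tp_deviation(source, source_tp, residualize)[genes]
  dev_tgt <- tp_deviation(target, target_tp, residualize)[genes]
  sel <- if (is.null(gene_rule)) {
    if (direction == "up") dev_src > min_abs else dev_src < -min_abs
  } else gene_rule(dev_src)
  if (!any(sel)) stop("gene rule selected no genes", call. = FALSE)
  src_sign <- sign(dev_src[sel])
  tgt_sign <- sign(dev_tgt[sel])
  usable <- tgt_sign != 0
  n_conc <- sum(src_sign[usable] == tgt_sign[usable])
  n_tot <- sum(usable)
  p <- stats::binom.test(n_conc, n_tot, p = 0.5,
                         alternative = "two.sided")$p.value
  list(n_concordant = n_conc, n_total = n_tot, p = p,
       genes = genes[sel])
}

## per-gene deviation of the timepoint mean (across animals) from the grand
## mean, optionally on animal-residualized values
tp_deviation <- function(x, tp, residualize = TRUE) {
  d <- design_of(x)
  if (residualize) x <- residualize_animal(x, d)
  at_tp <- d$timepoint == tp
  if (!any(at_tp)) stop("timepoint ", tp, " absent from design",
                        call. = FALSE)
  rowMeans(unclass(x)[, at_tp, drop = FALSE]) - rowMeans(unclass(x))
}
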