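#' Read blood-informative-transcript axis definitions
#'
#' Axis definitions are supplied as a TSV with columns `axis_id` and `gene`,
#' ten genes per axis. The package ships a synthetic placeholder set
#' (`inst/extdata/bit_axes_synthetic.tsv`) aligned with the synthetic-data
#' generator's gene ids; real analyses supply the published transcript
#' lists.
#'
#' @param path TSV file path.
#' @return named list: axis id -> character vector of gene ids.
#' @export
read_axis_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("axis_id", "gene") %in% names(df)))
  defs <- split(df$gene, df$axis_id)
  bad <- names(defs)[vapply(defs, function(g) length(unique(g)) != 10L,
                            logical(1))]
  if (length(bad)) {
    stop("axes must list exactly 10 unique genes; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defs
}

#' Axis scores: PC1 of each 10-gene blood-informative-transcript set
#'
#' For each axis, the first principal component of the standardized
#' submatrix of its member genes gives a per-sample activity score. The
#' score's sign is oriented so that the majority of gene loadings are
#' positive (PCA routinely flips signs), and scores are scaled to unit
#' variance. Axes with fewer than `min_genes` members present in the matrix
#' are skipped with a warning.
#'
#' @param x an [omics_matrix()] of log2 expression.
#' @param defs axis definitions from [read_axis_definitions()].
#' @param min_genes minimum members present to score an axis (default 5).
#' @return named list of `axis_scores` objects: `axis_id`, `scores` (named
#'   per-sample, unit variance), `pve_pc1`, `loadings`, `n_genes`. A
#'   `pve_pc1` above about 0.35 indicates strong covariance of the set.
#' @export
axis_scores <- function(x, defs, min_genes = 5) {
  out <- list()
  for (axis_id in names(defs)) {
    present <- intersect(defs[[axis_id]], rownames(x))
    if (length(present) < min_genes) {
      warning("axis ", axis_id, ": only ", length(present),
              " of 10 genes present; skipped", call. = FALSE)
      next
    }
    sub <- standardize_features(unclass(x)[present, , drop = FALSE])
    pr <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
    pve1 <- pr$sdev[1]^2 / sum(pr$sdev^2)
    load1 <- pr$rotation[, 1]
    flip <- if (sum(load1 > 0) != sum(load1 < 0)) {
      sum(load1 > 0) < sum(load1 < 0)
    } else sum(load1) < 0
    s <- if (flip) -pr$x[, 1] else pr$x[, 1]
    if (flip) load1 <- -load1
    out[[axis_id]] <- structure(
      list(axis_id = axis_id,
           scores = s / stats::sd(s),
           pve_pc1 = pve1,
           loadings = load1,
           n_genes = length(present)),
      class = "axis_scores")
  }
  out
}

#' ANOVA of axis scores on animal and drug phase
#'
#' Animal effect: one-way ANOVA on the scores. Drug effect: one-way ANOVA
#' on the animal-residualized scores (per-animal means removed), with the
#' residual degrees of freedom charged for both factors
#' (`n - animals - phases + 1`) so removing the animal effect does not
#' inflate the drug test. Flags whether the post-drug phase is the extreme
#' level.
#'
#' @param ax an `axis_scores` object (or list of them).
#' @param design `sample_design` for the scored samples.
#' @return data frame with `axis`, `pve_pc1`, `animal_p`, `drug_p`,
#'   `extreme_phase`, `post_extreme`.
#' @export
axis_anova <- function(ax, design) {
  if (inherits(ax, "axis_scores")) ax <- list(ax)
  rows <- lapply(ax, function(a) {
    idx <- match(names(a$scores), design$sample_id)
    if (anyNA(idx)) stop("axis scores contain samples missing from design",
                         call. = FALSE)
    animal <- droplevels(factor(design$animal[idx]))
    phase <- droplevels(factor(design$drug_phase[idx]))
    if (nlevels(animal) < 2L || nlevels(phase) < 2L) {
      stop("animal and drug phase each need at least 2 levels",
           call. = FALSE)
    }
    animal_p <- one_way_stats(a$scores, animal)$p
    resid <- a$scores - stats::ave(a$scores, animal)
    gm <- tapply(resid, phase, mean)
    cnt <- tabulate(phase)
    ssb <- sum(cnt * (gm - mean(resid))^2)
    sst <- sum((resid - mean(resid))^2)
    df1 <- nlevels(phase) - 1L
    df2 <- length(resid) - nlevels(animal) - nlevels(phase) + 1L
    sse <- max(sst - ssb, 0)
    f_stat <- if (sse == 0) Inf else (ssb / df1) / (sse / df2)
    drug_p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    ext <- names(gm)[which.max(abs(gm - mean(resid)))]
    data.frame(axis = a$axis_id, pve_pc1 = a$pve_pc1,
               animal_p = animal_p, drug_p = drug_p,
               extreme_phase = ext, post_extreme = ext == "post",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
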