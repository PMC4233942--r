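#' Principal components of an omics matrix
#'
#' PCA on feature-centered (not scaled) log2 data, retaining the smallest
#' number of components whose cumulative percent variance explained reaches
#' `pve_target` (capped at samples - 1). Leaving features unscaled keeps the
#' component weights on the raw log2 variance scale the variance-component
#' procedure expects.
#'
#' @param x an [omics_matrix()] (features x samples).
#' @param pve_target cumulative fraction of variance to cover (default 0.90).
#' @return a `pc_result`: list with `scores` (samples x k), `loadings`
#'   (features x k, orthonormal), `pve` (length k), `pve_all`, `design`.
#' @export
omics_pca <- function(x, pve_target = 0.90) {
  stopifnot(pve_target > 0, pve_target <= 1)
  m <- unclass(x)
  if (ncol(m) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (sum(ev) <= 0) stop("matrix has rank 0 (no variance)", call. = FALSE)
  pve_all <- ev / sum(ev)
  k <- which(cumsum(pve_all) >= pve_target - 1e-12)[1]
  if (is.na(k)) k <- length(pve_all)
  k <- min(k, ncol(m) - 1L)
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 pve = pve_all[seq_len(k)],
                 pve_all = pve_all,
                 design = design_of(x)),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("pc_result: %d components covering %.1f%% of variance\n",
              length(x$pve), 100 * sum(x$pve)))
  invisible(x)
}

## one-way group statistics for a numeric response: R^2 (between-group sum
## of squares over total), F and its p-value, level means
one_way_stats <- function(y, g) {
  g <- droplevels(factor(g))
  k <- nlevels(g)
  if (k < 2L) stop("factor must have at least 2 levels", call. = FALSE)
  cnt <- tabulate(g)
  if (any(cnt == 0L)) stop("factor has an empty level", call. = FALSE)
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(cnt * (gm - grand)^2)
  sst <- sum((y - grand)^2)
  n <- length(y)
  df1 <- k - 1L
  df2 <- n - k
  sse <- max(sst - ssb, 0)
  f_stat <- if (sse == 0) Inf else (ssb / df1) / (sse / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(r2 = if (sst > 0) ssb / sst else NA_real_, f = f_stat, p = p,
       means = gm, df1 = df1, df2 = df2)
}

#' PC-based variance components for a design factor
#'
#' Regresses each retained PC score vector on a design factor (group-means
#' fit), takes the squared correlation coefficient (= between-group sum of
#' squares over total) per PC, and averages these R-squared values weighted
#' by each PC's percent variance explained. The result attributes the
#' matrix's overall variance to the factor.
#'
#' @param pcr a `pc_result` from [omics_pca()].
#' @param design `sample_design` (defaults to the one bound to `pcr`).
#' @param factor_name `"animal"` or `"timepoint"` (any design column works).
#' @return a `variance_components` list: `factor`, `per_pc_r2`, `pve`
#'   (weights), `weighted_r2`.
#' @export
pc_variance_components <- function(pcr, design = pcr$design,
                                   factor_name = c("animal", "timepoint")) {
  factor_name <- match.arg(factor_name, c("animal", "timepoint",
                                          "drug_phase", "compartment"))
  g <- design_factor(pcr, design, factor_name)
  if (nlevels(droplevels(g)) < 2L) {
    stop("factor '", factor_name, "' is constant in this design",
         call. = FALSE)
  }
  r2 <- apply(pcr$scores, 2, function(y) one_way_stats(y, g)$r2)
  w <- pcr$pve
  structure(list(factor = factor_name,
                 per_pc_r2 = r2,
                 pve = w,
                 weighted_r2 = sum(w * r2) / sum(w)),
            class = "variance_components")
}

design_factor <- function(pcr, design, factor_name) {
  idx <- match(rownames(pcr$scores), design$sample_id)
  if (anyNA(idx)) stop("PC scores contain samples missing from the design",
                       call. = FALSE)
  factor(design[[factor_name]][idx])
}

#' Per-PC one-way ANOVA for a design factor
#'
#' F-test of each retained PC score vector against a factor, reporting which
#' factor level is extreme (largest absolute deviation of the level mean
#' from the grand mean) and in which direction.
#'
#' @inheritParams pc_variance_components
#' @param factor_name design factor; for metabolome designs `drug_phase`
#'   carries only the post/inter levels.
#' @return data frame with one row per PC: `pc`, `pve`, `f`, `p`,
#'   `extreme_level`, `direction` ("high"/"low").
#' @export
pc_factor_anova <- function(pcr, design = pcr$design,
                            factor_name = c("drug_phase", "animal",
                                            "timepoint")) {
  factor_name <- match.arg(factor_name)
  g <- design_factor(pcr, design, factor_name)
  res <- lapply(seq_len(ncol(pcr$scores)), function(i) {
    st <- one_way_stats(pcr$scores[, i], g)
    dev <- st$means - mean(pcr$scores[, i])
    ext <- which.max(abs(dev))
    data.frame(pc = colnames(pcr$scores)[i],
               pve = pcr$pve[i],
               f = st$f, p = st$p,
               extreme_level = names(st$means)[ext],
               direction = if (dev[ext] >= 0) "high" else "low",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Variance-component summary table
#'
#' Table view over the leading PCs of one dataset: percent variance
#' explained, animal and timepoint R-squared, and the drug-phase ANOVA
#' p-value with its extreme level.
#'
#' @param pcr a `pc_result`.
#' @param design bound design by default.
#' @param n_pc number of leading PCs to show (default 5).
#' @return data frame, one row per PC.
#' @export
varcomp_table <- function(pcr, design = pcr$design, n_pc = 5) {
  n_pc <- min(n_pc, ncol(pcr$scores))
  ga <- design_factor(pcr, design, "animal")
  gt <- design_factor(pcr, design, "timepoint")
  drug <- pc_factor_anova(pcr, design, "drug_phase")
  out <- data.frame(
    pc = colnames(pcr$scores)[seq_len(n_pc)],
    pve = pcr$pve[seq_len(n_pc)],
    animal_r2 = apply(pcr$scores[, seq_len(n_pc), drop = FALSE], 2,
                      function(y) one_way_stats(y, ga)$r2),
    timepoint_r2 = apply(pcr$scores[, seq_len(n_pc), drop = FALSE], 2,
                         function(y) one_way_stats(y, gt)$r2),
    drug_p = drug$p[seq_len(n_pc)],
    drug_extreme = paste(drug$extreme_level, drug$direction)[seq_len(n_pc)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
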