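#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median, over features
#' with all-positive counts, of the ratio of the feature's count in that
#' sample to its geometric mean across samples.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(4L, 9L), 1, dimnames = list("g1", c("s1", "s2")))
#' size_factors(m)  # 4/6, 9/6
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos)) {
    stop("every feature contains a zero count; ",
         "size factors require at least one all-positive feature",
         call. = FALSE)
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(lc)
  ## median taken on the log-ratio scale (geometric interpolation between
  ## the two middle ratios for an even feature count), matching the
  ## reference normalization tool
  sf <- exp(apply(lc - geo, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts and log2-transform
#'
#' @param counts count matrix (features x samples).
#' @param design `sample_design` for the samples.
#' @param factors per-sample positive size factors; computed with
#'   [size_factors()] when omitted.
#' @param pseudocount added before the log (default 1, keeping zero counts
#'   finite at 0).
#' @return an [omics_matrix()] of `log2(count/factor + pseudocount)` values.
#' @export
normalize_log2 <- function(counts, design, factors = NULL, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  stopifnot(length(factors) == ncol(counts))
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0)) {
    stop("zero counts with zero pseudocount would produce log(0)",
         call. = FALSE)
  }
  vals <- log2(t(t(counts) / as.numeric(factors)) + pseudocount)
  omics_matrix(vals, design, provenance = c("normalized", "log2"))
}

#' Drop low-abundance features
#'
#' Removes features whose mean log2 abundance falls strictly below the
#' threshold. Defaults used in the pipeline: 5 log2 units for transcripts,
#' 17 for metabolites (low-abundance features have high coefficients of
#' variation and mostly add measurement noise to the variance components).
#'
#' @param x an [omics_matrix()] on the log2 scale.
#' @param threshold log2 abundance threshold.
#' @return the filtered `omics_matrix`.
#' @export
filter_low_abundance <- function(x, threshold = 5) {
  keep <- rowMeans(unclass(x)) >= threshold
  if (!any(keep)) stop("abundance threshold removes every feature",
                       call. = FALSE)
  rewrap(unclass(x)[keep, , drop = FALSE], x, "filtered")
}

#' Collapse technical replicates to per-sample medians
#'
#' Per (feature, sample) cell, the median over non-missing replicates; cells
#' with every replicate missing stay missing. Values remain on the raw
#' intensity scale.
#'
#' @param table a `replicated_table` (see [simulate_metabolome()]) or a
#'   matrix plus `rep_map`.
#' @param rep_map data frame with columns `column`, `sample_id` mapping
#'   replicate columns to biological samples (taken from the table attribute
#'   when omitted).
#' @return matrix features x biological samples (raw scale, NAs preserved),
#'   with the design attached when known.
#' @export
collapse_replicates <- function(table, rep_map = NULL) {
  if (is.null(rep_map)) rep_map <- attr(table, "rep_map")
  if (is.null(rep_map)) stop("replicate map missing", call. = FALSE)
  if (!all(colnames(table) %in% rep_map$column) ||
      !all(rep_map$column %in% colnames(table))) {
    stop("replicate mapping does not cover the table columns", call. = FALSE)
  }
  samples <- unique(rep_map$sample_id)
  out <- vapply(samples, function(s) {
    cols <- rep_map$column[rep_map$sample_id == s]
    apply(unclass(table)[, cols, drop = FALSE], 1,
          function(v) if (all(is.na(v))) NA_real_ else
            stats::median(v, na.rm = TRUE))
  }, numeric(nrow(table)))
  rownames(out) <- rownames(table)
  attr(out, "design") <- attr(table, "design")
  out
}

#' Metabolite quality filters, imputation and log transform
#'
#' Fixed filter order on a replicate-collapsed raw-intensity matrix: drop
#' features missing in more than `max_missing_frac` of samples (strictly
#' greater; exactly 30 percent is kept); drop features whose median
#' non-missing intensity falls below `abundance_cutoff` peak-area units;
#' impute remaining missing cells as half the feature's minimum observed
#' intensity; log2-transform.
#'
#' @param collapsed matrix from [collapse_replicates()] (raw scale).
#' @param design `sample_design` for the samples.
#' @param max_missing_frac missingness tolerance (default 0.30).
#' @param abundance_cutoff raw peak-area cutoff (default 256).
#' @return an [omics_matrix()] of complete log2 intensities.
#' @export
filter_metabolite_qc <- function(collapsed, design = attr(collapsed, "design"),
                                 max_missing_frac = 0.30,
                                 abundance_cutoff = 256) {
  m <- as.matrix(collapsed)
  miss_frac <- rowMeans(is.na(m))
  keep <- miss_frac <= max_missing_frac
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  keep <- keep & !is.na(med) & med >= abundance_cutoff
  if (!any(keep)) stop("quality filters remove every metabolite feature",
                       call. = FALSE)
  m <- m[keep, , drop = FALSE]
  for (i in which(rowSums(is.na(m)) > 0L)) {
    m[i, is.na(m[i, ])] <- min(m[i, ], na.rm = TRUE) / 2
  }
  omics_matrix(log2(m), design,
               provenance = c("replicates_collapsed", "qc_filtered",
                              "imputed", "log2"))
}

#' Standardize features to z-scores
#'
#' Each feature row is centered to mean 0 and scaled to sample sd 1
#' (n - 1 denominator).
#' @param x an `omics_matrix` (or plain matrix).
#' @return the standardized matrix, same class as input where possible.
#' @export
standardize_features <- function(x) {
  m <- unclass(x)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- (m - rowMeans(m)) / sds
  if (inherits(x, "omics_matrix")) out <- rewrap(out, x, "standardized")
  out
}

#' Remove the animal effect from every feature
#'
#' Subtracts each feature's per-animal mean, i.e. the residuals of a
#' one-factor (animal) least-squares fit. This removes the dominant
#' among-animal variance before clustering and network inference.
#'
#' @param x an [omics_matrix()].
#' @param design `sample_design` (defaults to the bound design).
#' @return residualized `omics_matrix`.
#' @export
residualize_animal <- function(x, design = design_of(x)) {
  animal <- factor(design$animal[match(colnames(x), design$sample_id)])
  if (nlevels(animal) < 2L) {
    stop("residualizing animal needs at least 2 animals", call. = FALSE)
  }
  gm <- row_group_means(x, animal)
  out <- unclass(x) - gm[, as.character(animal), drop = FALSE]
  rewrap(out, x, "residualized")
}
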