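#' Per-feature ANOVA across timepoints or drug phases
#'
#' Ordinary-least-squares ANOVA of every feature against a design factor,
#' optionally blocking on animal. With animal in the model the factor F-test
#' uses the residual mean square after removing the animal term (a two-way
#' additive fit); in the balanced single-replicate designs this package
#' targets, that is identical to treating animal as a random effect for the
#' purpose of the factor F-test, while staying dependency-free.
#'
#' @param x an [omics_matrix()] of log2 values.
#' @param design `sample_design` (defaults to the bound design).
#' @param factor_name `"timepoint"` or `"drug_phase"`.
#' @param include_animal block on animal (default TRUE)?
#' @return data frame (`feature_tests`): `feature`, `f`, `p`, `q`
#'   (Benjamini-Hochberg), `model`, `factor`, sorted by input feature
#'   order.
#' @export
feature_anova <- function(x, design = design_of(x),
                          factor_name = c("timepoint", "drug_phase"),
                          include_animal = TRUE) {
  factor_name <- match.arg(factor_name)
  idx <- match(colnames(x), design$sample_id)
  fac <- droplevels(factor(design[[factor_name]][idx]))
  animal <- droplevels(factor(design$animal[idx]))
  if (nlevels(fac) < 2L) stop("factor has fewer than 2 levels",
                              call. = FALSE)
  Y <- t(unclass(x))
  n <- nrow(Y)
  if (include_animal) {
    X1 <- stats::model.matrix(~ animal + fac)
    X0 <- stats::model.matrix(~ animal)
  } else {
    X1 <- stats::model.matrix(~ fac)
    X0 <- matrix(1, n, 1)
  }
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    stop("design is confounded: '", factor_name,
         "' is collinear with the blocking structure", call. = FALSE)
  }
  rss1 <- colSums(qr.resid(q1, Y)^2)
  rss0 <- colSums(qr.resid(qr(X0), Y)^2)
  df1 <- nlevels(fac) - 1L
  dfe <- n - q1$rank
  f_stat <- ((rss0 - rss1) / df1) / (rss1 / dfe)
  f_stat[rss1 == 0] <- Inf
  p <- stats::pf(f_stat, df1, dfe, lower.tail = FALSE)
  out <- data.frame(feature = rownames(x), f = f_stat, p = p,
                    q = bh_fdr(p)$q,
                    model = if (include_animal) "with_animal"
                            else "without_animal",
                    factor = factor_name,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values with a significance flag at the given FDR.
#'
#' @param pvals numeric p-values in `[0, 1]`; NA/NaN is an error.
#' @param alpha FDR level for the flag column (default 0.05).
#' @return data frame with `p`, `q`, `significant`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (anyNA(pvals)) stop("p-values contain NA/NaN", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, significant = q <= alpha)
}

#' Consistent post-drug response across all three dosing cycles
#'
#' A gene responds "up" when each post-drug timepoint exceeds the
#' immediately preceding inter/pre timepoint (TP3 > TP2, TP5 > TP4,
#' TP7 > TP6) with a paired t-test (pairing by animal, two-sided) at
#' `p < alpha` and a positive mean difference at every one of the three
#' contrasts; "down" is symmetric.
#'
#' @param x an [omics_matrix()].
#' @param design `sample_design`; every animal must be present at all six
#'   contrast timepoints.
#' @param alpha per-contrast significance level (default 0.05).
#' @param contrasts 2-row matrix of (earlier, later) timepoint pairs.
#' @return list with `up` and `down` character vectors of feature ids, plus
#'   `p` (features x contrasts matrix) and `delta` (mean paired
#'   differences).
#' @export
consistent_response <- function(x, design = design_of(x), alpha = 0.05,
                                contrasts = rbind(c(2, 4, 6), c(3, 5, 7))) {
  idx <- match(colnames(x), design$sample_id)
  animal <- factor(design$animal[idx])
  tp <- design$timepoint[idx]
  animals <- levels(animal)
  n_a <- length(animals)
  m <- unclass(x)
  p_mat <- matrix(NA_real_, nrow(m), ncol(contrasts))
  d_mat <- matrix(NA_real_, nrow(m), ncol(contrasts))
  for (ci in seq_len(ncol(contrasts))) {
    lo <- contrasts[1, ci]; hi <- contrasts[2, ci]
    col_lo <- vapply(animals, function(a) {
      w <- which(animal == a & tp == lo)
      if (length(w) != 1L) NA_integer_ else w
    }, integer(1))
    col_hi <- vapply(animals, function(a) {
      w <- which(animal == a & tp == hi)
      if (length(w) != 1L) NA_integer_ else w
    }, integer(1))
    if (anyNA(col_lo) || anyNA(col_hi)) {
      stop("missing animal x timepoint cell for contrast TP", hi, " vs TP",
           lo, call. = FALSE)
    }
    diffs <- m[, col_hi, drop = FALSE] - m[, col_lo, drop = FALSE]
    md <- rowMeans(diffs)
    sdd <- apply(diffs, 1, stats::sd)
    t_stat <- md / (sdd / sqrt(n_a))
    p_mat[, ci] <- 2 * stats::pt(abs(t_stat), n_a - 1, lower.tail = FALSE)
    d_mat[, ci] <- md
  }
  sig <- p_mat < alpha
  up <- rownames(m)[rowSums(sig & d_mat > 0) == ncol(contrasts)]
  down <- rownames(m)[rowSums(sig & d_mat < 0) == ncol(contrasts)]
  dimnames(p_mat) <- dimnames(d_mat) <-
    list(rownames(m), paste0("TP", contrasts[2, ], "_vs_TP", contrasts[1, ]))
  list(up = up, down = down, p = p_mat, delta = d_mat)
}
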