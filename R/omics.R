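#' Construct an omics matrix bound to a sample design
#'
#' Thin wrapper around a numeric features-by-samples matrix that carries the
#' sample design and a provenance record (which preprocessing steps have been
#' applied). Columns must match the design's `sample_id`s one-to-one.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param design `sample_design` whose rows describe the columns.
#' @param provenance character vector of processing flags (e.g.
#'   `"normalized"`, `"log2"`, `"filtered"`, `"residualized"`,
#'   `"standardized"`).
#' @return an `omics_matrix`.
#' @export
omics_matrix <- function(values, design, provenance = character()) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("values must have sample ids as column names", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%05d", seq_len(nrow(values)))
  }
  missing_ids <- setdiff(colnames(values), design$sample_id)
  if (length(missing_ids) > 0L) {
    stop("sample ids not in design: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  class(design) <- c("sample_design", "data.frame")
  structure(values,
            design = design,
            provenance = provenance,
            class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
design_of <- function(x) attr(x, "design")

#' @rdname omics_matrix
#' @export
provenance_of <- function(x) attr(x, "provenance") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

## rebuild an omics_matrix from possibly-subset values, inheriting design
rewrap <- function(values, template, add_provenance = NULL) {
  omics_matrix(values, design_of(template),
               provenance = unique(c(provenance_of(template), add_provenance)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  pv <- provenance_of(x)
  if (length(pv)) cat("provenance:", paste(pv, collapse = " -> "), "\n")
  d <- design_of(x)
  cat(sprintf("design: %d animals, %d timepoints, compartment(s) %s\n",
              nlevels(factor(d$animal)), length(unique(d$timepoint)),
              paste(unique(d$compartment), collapse = "/")))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  um <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(um))
  if (missing(j)) j <- seq_len(ncol(um))
  out <- um[i, j, drop = FALSE]
  d <- design_of(x)
  d2 <- d[match(colnames(out), d$sample_id), , drop = FALSE]
  rownames(d2) <- NULL
  class(d2) <- c("sample_design", "data.frame")
  structure(out, design = d2, provenance = provenance_of(x),
            class = class(x))
}

#' Subset samples of an omics matrix
#' @param x an `omics_matrix`.
#' @param sample_ids sample ids to keep (order preserved).
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(all(sample_ids %in% colnames(x)))
  omics_matrix(unclass(x)[, sample_ids, drop = FALSE],
               design_of(x), provenance_of(x))
}

#' Write / read an omics matrix as TSV
#'
#' Features as rows (first column `feature`), samples as columns.
#' @param x matrix to write.
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param design optional `sample_design` to bind on read.
#' @export
read_matrix_tsv <- function(path, design = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(design)) m <- omics_matrix(m, design)
  m
}
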