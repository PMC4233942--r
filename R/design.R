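#' Drug phase for a timepoint
#'
#' The dosing schedule defines three phases relative to drug administration:
#' timepoints 1 and 2 precede the first dose ("pre"), timepoints 3, 5 and 7
#' fall about a week after a dose ("post"), and timepoints 4 and 6 fall about
#' a month after the most recent dose, immediately before the next
#' ("inter").
#'
#' @param timepoint integer vector of timepoints.
#' @param phase_map optional named character vector mapping timepoint (as
#'   character) to phase; required when timepoints outside 1..7 are used.
#' @return character vector of phases ("pre", "post", "inter").
#' @export
drug_phase_for <- function(timepoint, phase_map = NULL) {
  if (is.null(phase_map)) phase_map <- default_phase_map()
  key <- as.character(timepoint)
  bad <- setdiff(unique(key), names(phase_map))
  if (length(bad) > 0L) {
    stop("no drug phase defined for timepoint(s) ", paste(bad, collapse = ", "),
         "; supply a custom phase_map", call. = FALSE)
  }
  unname(phase_map[key])
}

default_phase_map <- function() {
  c(`1` = "pre", `2` = "pre", `3` = "post", `4` = "inter",
    `5` = "post", `6` = "inter", `7` = "post")
}

#' Generate a longitudinal multi-compartment sample design
#'
#' Builds the full factorial animal-by-timepoint sample sheet for each
#' requested compartment. Transcriptome compartments ("BM", "PB") and "CBC"
#' cover all timepoints; the plasma metabolome is only collected from
#' timepoint 3 onward, mirroring a design in which metabolite profiling
#' starts after the first drug administration.
#'
#' @param n_animals number of animals (>= 2 in the default design; 1 allowed
#'   for degenerate test designs).
#' @param timepoints number of timepoints (1..7 unless `phase_map` given).
#' @param compartments character vector drawn from
#'   `c("BM", "PB", "plasma", "CBC")`.
#' @param phase_map optional custom timepoint-to-phase map (see
#'   [drug_phase_for()]).
#' @param metabolome_timepoints timepoints at which plasma is collected
#'   (default 3:7).
#' @return a `sample_design` data frame with columns `sample_id`, `animal`,
#'   `timepoint`, `compartment`, `drug_phase`.
#' @examples
#' d <- generate_design(5, 7, c("BM", "PB"))
#' table(d$compartment)
#' @export
generate_design <- function(n_animals = 5, timepoints = 7,
                            compartments = c("BM", "PB"),
                            phase_map = NULL,
                            metabolome_timepoints = 3:7) {
  stopifnot(n_animals >= 1, timepoints >= 1)
  if (timepoints > 7 && is.null(phase_map)) {
    stop("the built-in drug-phase map covers timepoints 1..7 only; ",
         "supply phase_map for longer designs", call. = FALSE)
  }
  compartments <- match.arg(compartments, c("BM", "PB", "plasma", "CBC"),
                            several.ok = TRUE)
  animals <- sprintf("A%d", seq_len(n_animals))
  rows <- lapply(compartments, function(cp) {
    tps <- seq_len(timepoints)
    if (cp == "plasma") tps <- intersect(tps, metabolome_timepoints)
    expand.grid(animal = animals, timepoint = tps,
                compartment = cp, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d$drug_phase <- drug_phase_for(d$timepoint, phase_map)
  d$sample_id <- sprintf("%s_%s_T%d", d$compartment, d$animal, d$timepoint)
  d <- d[, c("sample_id", "animal", "timepoint", "compartment", "drug_phase")]
  d$animal <- factor(d$animal, levels = animals)
  d$drug_phase <- factor(d$drug_phase, levels = c("pre", "post", "inter"))
  rownames(d) <- NULL
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Subset a design to one compartment
#' @param design a `sample_design`.
#' @param compartment compartment label.
#' @return the subset, still a `sample_design`.
#' @export
design_compartment <- function(design, compartment) {
  out <- design[design$compartment == compartment, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Read / write a design sheet
#'
#' CSV round-trip for the sample sheet (columns `sample_id`, `animal`,
#' `timepoint`, `compartment`, `drug_phase`).
#' @param design a `sample_design`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal", "timepoint", "compartment", "drug_phase")
  if (!all(need %in% names(d))) {
    stop("design sheet must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d$animal <- factor(d$animal)
  d$drug_phase <- factor(d$drug_phase, levels = c("pre", "post", "inter"))
  class(d) <- c("sample_design", "data.frame")
  d
}
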