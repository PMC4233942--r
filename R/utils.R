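## Deterministic sub-seed derivation: every stochastic operation in the
## package derives its own stream from one global seed plus a text tag, so a
## pipeline run is reproducible end to end and independent operations do not
## consume each other's random numbers. Kept below 2^31 - 1.
subseed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## row-wise means by sample group; groups as factor over columns
row_group_means <- function(x, group) {
  group <- factor(group)
  gm <- t(rowsum(t(unclass(x)), group) / as.vector(table(group)))
  gm  # features x levels
}
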