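# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cohort, per-stage seed derived from the study seed.
# Kept well below 2^31 for any study seed a user would pass.
stage_seed <- function(seed, cohort, stage) {
  (seed %% 1000000L) * 1000L + cohort * 10L + stage
}

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
}

# Column-wise matrix check for genes x samples containers.
is_gene_matrix <- function(x) {
  is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}
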