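# Internal helpers shared across modules.

# Deterministic stage-seed derivation. A single top-level seed fans out to
# per-stage seeds so stages can be rerun independently yet reproducibly.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + 1000003 * as.numeric(offset) + 17) %% 2147483629)
}

# with_seed: evaluate expr under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_character_set <- function(x, what) {
  if (!is.character(x)) abort(paste0(what, " must be a character vector"))
  unique(x)
}

# area under the ROC curve via the rank-sum identity (ties get midranks)
auroc <- function(score, label) {
  stopifnot(length(score) == length(label))
  keep <- is.finite(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
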