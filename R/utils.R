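# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

#' Derive a reproducible child seed from a pipeline seed
#'
#' One global seed fans out deterministically to the split, the fold
#' assignment, every base learner and the permutation draws. Kept below
#' 2^31 so the result is always a valid R integer.
#'
#' @param seed integer master seed.
#' @param offset integer stream offset (one per consumer).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483647L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that both classes are
#' spread as evenly as possible across folds.
#'
#' @param labels binary vector (0/1).
#' @param k number of folds, `2 <= k <= min(class count)`.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- check_binary_labels(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > min(table(labels))) {
    stop(sprintf("k = %d exceeds the size of the smallest class (%d)",
                 k, min(table(labels))), call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Validate/coerce a 0/1 label vector with both classes present.
check_binary_labels <- function(labels, require_both = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (require_both && length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}
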