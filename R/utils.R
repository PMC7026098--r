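#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions stay deterministic without clobbering
#' the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' One master seed fans out to per-stage seeds so a pipeline run is fully
#' reproducible while stages remain independently re-runnable.  Kept below
#' 2^31 to stay a valid R integer.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647L)
}

#' Stratified fold assignment
#'
#' Partitions observations into `k` folds preserving class proportions:
#' within each class, shuffled indices are dealt round-robin, so per-fold
#' class counts differ by at most one.
#'
#' @param y Factor (or coercible) of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per observation.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  if (k < 2) stop("k must be at least 2")
  if (any(table(y) < k)) stop("each class needs at least k rows for stratified folds")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Jaccard index of two sets
#' @param a,b Vectors treated as sets.
#' @return |a n b| / |a u b|; 1 for two empty sets.
#' @keywords internal
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

# mode of a vector (ties broken by first-observed order); NA-safe
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}
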