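#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so generators are reproducible under a
# fixed seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Ties among scores contribute 1/2 per tied positive-negative pair, so the
#' result equals the fraction of concordant pairs with ties counted half.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(as.integer(as.logical(labels)))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need both classes in the partition")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified train/validation split: per class, floor(frac * n_c) embryos
# train (at least 1), rest validation.
stratified_split <- function(labels, train_frac = 0.9) {
  stopifnot(train_frac > 0, train_frac < 1)
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(g) {
    k <- max(1L, floor(train_frac * length(g)))
    sample(g, k)
  }), use.names = FALSE)
  list(train = sort(train), valid = sort(setdiff(idx, train)))
}

# Median imputation fitted on training rows only.
fit_impute <- function(x_train) {
  med <- vapply(x_train, function(col) stats::median(col, na.rm = TRUE),
                numeric(1))
  med[!is.finite(med)] <- 0
  med
}

apply_impute <- function(x, medians) {
  for (j in names(medians)) {
    miss <- is.na(x[[j]])
    if (any(miss)) x[[j]][miss] <- medians[[j]]
  }
  x
}
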