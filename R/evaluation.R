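#' Binary classification metrics
#'
#' AUROC is computed by the rank statistic (Mann-Whitney) with midranks, so
#' tied scores contribute 1/2; sensitivity, specificity, precision (PPV) and
#' F1 are computed at the given threshold (scores >= threshold are called
#' positive; the conventional operating point is 0.5).
#'
#' @param scores numeric vector of predicted probabilities/scores.
#' @param labels 0/1 vector of the same length; both classes must be present
#'   (AUROC is undefined otherwise).
#' @param threshold decision threshold for the thresholded metrics.
#' @return list with `auroc`, `f1`, `sensitivity`, `specificity`, `ppv`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L) stop("AUROC undefined: only one class present")
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- tp / P
  spec <- tn / N
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(auroc = auroc, f1 = f1, sensitivity = sens, specificity = spec,
       ppv = ppv)
}

#' Worklist sensitivity at a reading fraction
#'
#' Frames the exam set as a worklist sorted by decreasing predicted
#' probability (ties broken stably by input order): if only the first
#' `ceiling(f * N)` exams are read, what fraction of the truly positive
#' exams is captured? Reading the whole list (`f = 1`) always yields 1, and
#' the curve is monotone non-decreasing in `f`. A perfect detector attains
#' `min(1, f * N / P)`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector; at least one positive required.
#' @param f fraction of the worklist read, in (0, 1\].
#' @return sensitivity in \[0, 1\].
#' @export
worklist_sensitivity <- function(scores, labels, f) {
  stopifnot(length(scores) == length(labels), f > 0, f <= 1)
  P <- sum(labels == 1)
  if (P == 0L) stop("no positive exams in the worklist")
  n_read <- ceiling(f * length(scores))
  ord <- order(-scores)  # stable: ties keep input order
  sum(labels[ord[seq_len(n_read)]] == 1) / P
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the score vector with replacement `n_boot` times and reports
#' the percentile interval of the resampled means. Used to summarize the
#' per-seed score samples (typically n = 5 training seeds).
#'
#' @param scores numeric vector (e.g. one AUROC per seed).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list with `mean`, `lo`, `hi`.
#' @export
bootstrap_ci <- function(scores, n_boot = 10000L, level = 0.95, seed = NULL) {
  stopifnot(length(scores) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(scores[sample.int(n, n, replace = TRUE)]), 0)
  a <- (1 - level) / 2
  q <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 7)
  list(mean = mean(scores), lo = q[1L], hi = q[2L])
}

#' Paired permutation test
#'
#' Sign-flip permutation test on paired differences: the observed statistic
#' is the mean difference `mean(a - b)`; under the null the sign of each
#' pair's difference is exchangeable, so signs are flipped uniformly at
#' random `n_iter` times and
#' `p = (1 + #\{permuted statistic at least as extreme\}) / (1 + n_iter)`
#' (one-sided: permuted >= observed; two-sided: |permuted| >= |observed|).
#' The add-one rule bounds p below by `1/(n_iter + 1)`. With `exact = TRUE`
#' all `2^n` sign patterns are enumerated instead and
#' `p = #extreme / 2^n` (the identity pattern makes this positive).
#'
#' @param a,b paired score vectors of equal length (one entry per paired
#'   unit, e.g. region x seed).
#' @param sides 1 (one-sided, tests mean(a) > mean(b)) or 2.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param exact enumerate all sign patterns (requires length <= 20).
#' @param seed optional integer seed.
#' @return p-value.
#' @export
paired_permutation_test <- function(a, b, sides = 1L, n_iter = 10000L,
                                    exact = FALSE, seed = NULL) {
  stopifnot(length(a) == length(b), sides %in% c(1L, 2L))
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  is_extreme <- function(stat) {
    if (sides == 1L) stat >= obs - 1e-12 else abs(stat) >= abs(obs) - 1e-12
  }
  if (exact) {
    stopifnot(n <= 20L)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_all <- as.numeric(signs %*% d) / n
    return(mean(is_extreme(stats_all)))
  }
  if (!is.null(seed)) set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), n_iter, n)
  stats_all <- as.numeric(flips %*% d) / n
  (1 + sum(is_extreme(stats_all))) / (1 + n_iter)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons (capped at 1), as
#' applied when permutation tests are run at several mortality horizons.
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p) pmin(1, p * length(p))

#' Median-of-seeds ensemble
#'
#' Elementwise median across per-seed prediction vectors; for an even number
#' of seeds the mean of the central two values is used (stats::median
#' convention).
#'
#' @param per_seed_predictions list of equal-length numeric vectors, one per
#'   training seed.
#' @return numeric vector of ensembled scores.
#' @export
ensemble_median <- function(per_seed_predictions) {
  stopifnot(length(per_seed_predictions) >= 1L)
  m <- do.call(cbind, per_seed_predictions)
  apply(m, 1L, stats::median)
}
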