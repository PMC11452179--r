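## Statistical procedures used by the detection analysis: two-sample
## permutation test on group means, percentile bootstrap CIs, Cohen's d,
## Pearson correlation, Bonferroni correction.

#' Two-sample permutation test on the absolute difference of means
#'
#' Statistic `|mean(a) - mean(b)|`; the null distribution is generated by
#' shuffling the group labels jointly `n_perm` times. The p-value is the
#' proportion of null samples strictly larger than the observed statistic
#' (as defined), with two refinements: an observed statistic of exactly 0
#' reports p = 1 (nothing can be less extreme), and the finite-sample-safe
#' variant `(sum(null >= obs) + 1) / (n_perm + 1)` is reported alongside.
#' With `exact = TRUE` (only for small samples) all label partitions are
#' enumerated instead.
#'
#' @param a,b numeric vectors (at least `min_n` each)
#' @param n_perm number of label shuffles
#' @param seed integer seed
#' @param min_n minimum group size
#' @param exact enumerate all partitions (requires `choose(n, na) <= 1e5`)
#' @return list of class `permutation_result`: `observed`, `p_value`,
#'   `p_value_safe`, `null_samples`, `seed`
#' @export
permutation_test <- function(a, b, n_perm = 100000L, seed = 0L,
                             min_n = 4L, exact = FALSE) {
  if (length(a) < min_n || length(b) < min_n)
    stop("each group needs at least N=", min_n, " members")
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  if (exact) {
    if (choose(n, na) > 1e5) stop("too many partitions for exact mode")
    idx <- utils::combn(n, na)
    null <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      s <- sample.int(n, na)
      abs(mean(pool[s]) - mean(pool[-s]))
    }, numeric(1))
  }
  p <- if (obs == 0) 1 else mean(null > obs)
  out <- list(observed = obs, p_value = p,
              p_value_safe = (sum(null >= obs) + 1) / (length(null) + 1),
              null_samples = null, n_perm = length(null), seed = seed,
              exact = exact)
  class(out) <- "permutation_result"
  out
}

#' Percentile bootstrap confidence interval
#'
#' Resamples with replacement `n_boot` times and reports the 2.5th and
#' 97.5th percentiles of the bootstrapped statistic. `x` may be a vector
#' (statistic takes one sample) or a list of two vectors (each group is
#' resampled independently; statistic takes two samples -- for group
#' differences like delta-AUC).
#'
#' @param x numeric vector or list of two vectors
#' @param statistic function of one (or two) resampled vectors
#' @param n_boot number of bootstrap resamples
#' @param seed integer seed
#' @param probs CI percentiles
#' @return list of class `bootstrap_ci`: `estimate`, `lower`, `upper`,
#'   `samples`, `seed`
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 100L, seed = 0L,
                         probs = c(0.025, 0.975)) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  set.seed(seed)
  if (is.list(x)) {
    stopifnot(length(x) == 2, length(x[[1]]) >= 2, length(x[[2]]) >= 2)
    est <- statistic(x[[1]], x[[2]])
    samples <- vapply(seq_len(n_boot), function(i)
      statistic(sample(x[[1]], replace = TRUE),
                sample(x[[2]], replace = TRUE)), numeric(1))
  } else {
    stopifnot(length(x) >= 2)
    est <- statistic(x)
    samples <- vapply(seq_len(n_boot), function(i)
      statistic(sample(x, replace = TRUE)), numeric(1))
  }
  q <- quantile(samples, probs, names = FALSE)
  out <- list(estimate = est, lower = q[1], upper = q[2],
              samples = samples, n_boot = n_boot, seed = seed)
  class(out) <- "bootstrap_ci"
  out
}

#' Cohen's d effect size
#'
#' `|mean(a) - mean(b)|` divided by the pooled standard deviation
#' `sqrt(((Na-1) sa^2 + (Nb-1) sb^2) / (Na + Nb - 2))`.
#'
#' @param a,b numeric vectors of length >= 2
#' @return scalar effect size
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  s <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
              (length(a) + length(b) - 2))
  if (s == 0) stop("zero pooled standard deviation")
  abs(mean(a) - mean(b)) / s
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation; constant inputs are flagged and
#' reported as 0 rather than NA so evaluation loops never fail.
#'
#' @param x,y equal-length numeric vectors (length >= 2)
#' @return correlation in \[-1, 1\]
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  safe_cor(x, y)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha nominal level
#' @param m number of comparisons
#' @return `alpha / m`, rounded to 4 decimals for display parity
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(m >= 1)
  round(alpha / m, 4)
}
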