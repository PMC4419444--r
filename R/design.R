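#' Permutation granularity of a phenotype
#'
#' With a continuous expression matrix and a phenotype taking K distinct
#' values with tie-group sizes n_1, ..., n_K, the smallest attainable
#' permutation p-value is eps = prod_k n_k! / n!; its reciprocal is the
#' number of distinct label arrangements. Two balanced groups of 5 give
#' eps = 1/252. A warning flag is raised when the distinct count falls
#' below 100,000, where granularity starts to bite in large multiple
#' testing problems.
#'
#' @param group_sizes positive integer tie-group sizes (use `rep(1, n)` or
#'   [design_summary()] for an all-distinct phenotype).
#' @return list of class `"design_summary"`: `epsilon`, `distinct_count`
#'   (exact when below 2^53, otherwise `Inf` with `log10_distinct` still
#'   exact), `log10_distinct`, `warn_low_count`, `group_sizes`.
#' @export
granularity <- function(group_sizes) {
  group_sizes <- as.numeric(group_sizes)
  if (length(group_sizes) == 0L || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes)))
    stop("group sizes must be positive integers")
  n <- sum(group_sizes)
  log_count <- lfactorial(n) - sum(lfactorial(group_sizes))
  if (log_count / log(10) < 15.6) {
    # exact multinomial coefficient via a product of binomials
    count <- 1
    tot <- 0
    for (nk in group_sizes) {
      tot <- tot + nk
      count <- count * choose(tot, nk)
    }
    eps <- 1 / count
  } else {
    count <- Inf
    eps <- exp(-log_count)
  }
  structure(list(epsilon = eps, distinct_count = count,
                 log10_distinct = log_count / log(10),
                 warn_low_count = log_count < log(1e5),
                 group_sizes = group_sizes),
            class = "design_summary")
}

#' Granularity summary for an observed phenotype
#'
#' Exact floating-point ties define the tie groups; a continuous phenotype
#' without ties has n singleton groups and eps = 1/n!.
#'
#' @param y phenotype vector.
#' @return see [granularity()].
#' @export
design_summary <- function(y) {
  granularity(as.integer(table(y)))
}

#' Power of the k/eps - 1 permutation-count rule
#'
#' Running M = k/eps - 1 permutations, one can claim p <= eps when at most
#' k - 1 sampled statistics are as extreme as the observed one; with true
#' (enumeration) p-value p the power is Pr(Bin(M, p) <= k - 1).
#'
#' @param k integer multiplier.
#' @param epsilon target smallest p-value, 0 < eps < 1.
#' @param true_p_fraction the true p-value as a fraction of eps.
#' @param method exact binomial summation (default) or its Poisson limit.
#' @return the power (numeric scalar).
#' @export
perm_count_power <- function(k, epsilon, true_p_fraction = 0.8,
                             method = c("binomial", "poisson")) {
  method <- match.arg(method)
  m <- round(k / epsilon) - 1
  p <- true_p_fraction * epsilon
  if (method == "binomial") stats::pbinom(k - 1, m, p)
  else stats::ppois(k - 1, m * p)
}

#' Smallest permutation multiplier achieving a target power
#'
#' Finds the smallest integer k such that M = k/eps - 1 sampled
#' permutations give at least the target power to report p <= eps when the
#' true p-value is `true_p_fraction * eps`, by exact binomial summation.
#' The answer is insensitive to eps: k = 19 for a true p of 0.8 eps and
#' 80% power, and k = 3 when the true p is only 0.5 eps.
#'
#' @param epsilon target smallest p-value, 0 < eps < 1.
#' @param true_p_fraction true p-value as a fraction of eps, in (0, 1].
#' @param target_power required power, in (0, 1).
#' @param max_k search bound; k beyond this raises an error.
#' @return list with `k`, `m_required` (= k/eps - 1), `power`.
#' @export
min_k_for_power <- function(epsilon, true_p_fraction = 0.8,
                            target_power = 0.8, max_k = 1000L) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)")
  if (!(true_p_fraction > 0 && true_p_fraction <= 1))
    stop("true_p_fraction must be in (0, 1]")
  if (!(target_power > 0 && target_power < 1))
    stop("target_power must be in (0, 1)")
  for (k in seq_len(max_k)) {
    pw <- perm_count_power(k, epsilon, true_p_fraction)
    if (pw >= target_power)
      return(list(k = k, m_required = round(k / epsilon) - 1, power = pw))
  }
  stop("no k <= ", max_k, " achieves the target power")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Permutation granularity\n")
  cat("  tie groups:       ", paste(x$group_sizes, collapse = " "), "\n")
  cat("  distinct arrangements:",
      if (is.finite(x$distinct_count)) format(x$distinct_count, big.mark = ",")
      else sprintf("10^%.1f", x$log10_distinct), "\n")
  cat("  smallest attainable p (epsilon):", format(x$epsilon), "\n")
  if (x$warn_low_count)
    cat("  warning: fewer than 100,000 distinct permutations;",
        "permutation p-values will be coarse\n")
  invisible(x)
}
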