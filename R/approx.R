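#' Gaussian p-values for the linear statistic
#'
#' Matches a N(0, var(T~)) reference to the exact permutation variance and
#' reports p_left = Phi(T^ / sd), p_right = 1 - p_left and the central
#' (two-sided) p = min(1, 2 min(p_left, p_right)).
#'
#' @param t_hat observed linear statistic.
#' @param var_t exact permutation variance of the statistic.
#' @return list with `p_left`, `p_right`, `p_central`, `degenerate`.
#' @export
normal_pvalues <- function(t_hat, var_t) {
  if (var_t <= 0)
    return(list(p_left = 1, p_right = 1, p_central = 1, degenerate = TRUE))
  pl <- stats::pnorm(t_hat / sqrt(var_t))
  list(p_left = pl, p_right = 1 - pl,
       p_central = min(1, 2 * min(pl, 1 - pl)), degenerate = FALSE)
}

#' Fit a scaled-beta reference to the permutation distribution
#'
#' The permuted linear statistic is bounded; a scaled beta on its exact
#' attainable range \[A, B\] matches four features (min, max, mean 0,
#' variance) instead of the Gaussian's two. Shapes are
#' alpha = A/(B-A) (AB/var + 1) and beta = -B/(B-A) (AB/var + 1); both are
#' positive because AB < 0 and, by the Bhatia-Davis inequality,
#' var <= -AB with equality only in degenerate two-point cases.
#'
#' @param lm a [linear_moments()] result.
#' @return list of class `"beta_approx"` with `a`, `b`, `alpha`, `beta`,
#'   `var_t`.
#' @export
beta_fit <- function(lm) {
  a <- lm$range_a
  b <- lm$range_b
  v <- lm$var_t
  if (!(a < 0 && b > 0))
    stop("degenerate range [", format(a), ", ", format(b),
         "]: statistic is constant under permutation")
  if (v >= -a * b)
    stop("variance reaches the Bhatia-Davis bound: the statistic only takes ",
         "one or two distinct values under permutation")
  fac <- a * b / v + 1   # negative
  structure(list(a = a, b = b,
                 alpha = a / (b - a) * fac,
                 beta = -b / (b - a) * fac,
                 var_t = v),
            class = "beta_approx")
}

#' p-values from a fitted scaled-beta reference
#'
#' p_left = Pr(beta(alpha, beta) <= (T^ - A)/(B - A)). Because the support
#' equals the exact attainable range, the observed statistic can sit at an
#' endpoint and yield p exactly 0 or 1; see [epsilon_adjust()] for the
#' granularity-aware correction.
#'
#' @param fit a [beta_fit()] result.
#' @param t_hat observed linear statistic; must lie in \[A, B\].
#' @return list with `p_left`, `p_right`, `p_central`.
#' @export
beta_pvalues <- function(fit, t_hat) {
  span <- fit$b - fit$a
  tol <- 1e-12 * max(span, 1)
  if (t_hat < fit$a - tol || t_hat > fit$b + tol)
    stop("observed statistic outside its attainable range; ",
         "inconsistent inputs")
  u <- min(1, max(0, (t_hat - fit$a) / span))
  pl <- stats::pbeta(u, fit$alpha, fit$beta)
  list(p_left = pl, p_right = 1 - pl,
       p_central = min(1, 2 * min(pl, 1 - pl)))
}

#' Granularity-aware adjustment of a bounded-reference p-value
#'
#' Replaces the left-tail p by p~_L = eps + (1 - 2 eps) p_L, where eps is
#' the smallest attainable permutation p-value (the data granularity, see
#' [granularity()]). This keeps the beta reference from ever reporting
#' exactly 0 or 1: the smallest reportable value is eps, matching what any
#' exhaustive permutation test could claim. Right and central values follow
#' as p~_R = 1 - p~_L and p~_C = 2 min(p~_L, p~_R).
#'
#' @param p_left unadjusted left-tail p-value in \[0, 1\].
#' @param epsilon granularity, 0 < eps < 1/2.
#' @return list with `p_left`, `p_right`, `p_central`, `epsilon`.
#' @export
epsilon_adjust <- function(p_left, epsilon) {
  if (!(epsilon > 0 && epsilon < 0.5))
    stop("epsilon must lie in (0, 1/2)")
  pl <- epsilon + (1 - 2 * epsilon) * p_left
  list(p_left = pl, p_right = 1 - pl,
       p_central = min(1, 2 * min(pl, 1 - pl)),
       epsilon = epsilon)
}

#' Fit a scaled chi-squared reference to the quadratic statistic
#'
#' Matches sigma^2 chi^2_(nu) (equivalently a gamma) to the exact
#' permutation mean and variance of C~:
#' nu = 2 E(C~)^2 / var(C~), sigma^2 = E(C~)/nu. `nu` need not be an
#' integer.
#'
#' @param qm a [quad_moments()] result.
#' @return list of class `"chisq_approx"` with `nu`, `sigma2`.
#' @export
chisq_fit <- function(qm) {
  if (!(qm$mean_c > 0 && qm$var_c > 0))
    stop("degenerate quadratic moments: mean and variance must be positive")
  nu <- 2 * qm$mean_c^2 / qm$var_c
  structure(list(nu = nu, sigma2 = qm$mean_c / nu), class = "chisq_approx")
}

#' Upper-tail p-value from a fitted scaled chi-squared reference
#'
#' p_Q = Pr(sigma^2 chi^2_(nu) >= C^), the two-sided p-value for the
#' quadratic statistic (large C^ is evidence against the null in either
#' direction of association).
#'
#' @param fit a [chisq_fit()] result.
#' @param c_hat observed quadratic statistic.
#' @return list with `p_q`.
#' @export
chisq_pvalue <- function(fit, c_hat) {
  list(p_q = stats::pchisq(c_hat / fit$sigma2, df = fit$nu,
                           lower.tail = FALSE))
}
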