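#' Even permutation moments of the phenotype
#'
#' For a centered phenotype under uniform random permutation, the joint
#' moments of permuted values at distinct indices reduce to functions of
#' mu2 = (1/n) sum y^2 and mu4 = (1/n) sum y^4. The five derived moments are
#' named after the index pattern: four of a kind, three of a kind, two pair,
#' one pair, and no repeats.
#'
#' @param y centered phenotype vector.
#' @return list with `n`, `mu2`, `mu4` and (when n >= 4) the derived
#'   `mu_4k`, `mu_3k`, `mu_2p`, `mu_1p`, `mu_empty`.
#' @export
y_moments <- function(y) {
  n <- length(y)
  if (n < 2L) stop("need n >= 2")
  if (abs(sum(y)) > 1e-8 * max(1, sum(abs(y))))
    stop("phenotype must be centered")
  mu2 <- mean(y^2)
  mu4 <- mean(y^4)
  out <- list(n = n, mu2 = mu2, mu4 = mu4)
  if (n >= 4L) {
    out$mu_4k <- mu4
    out$mu_3k <- -mu4 / (n - 1)
    out$mu_2p <- (n * mu2^2 - mu4) / (n - 1)
    out$mu_1p <- (-n * mu2^2 + 2 * mu4) / ((n - 1) * (n - 2))
    out$mu_empty <- (3 * n * mu2^2 - 6 * mu4) / ((n - 1) * (n - 2) * (n - 3))
  }
  out
}

#' Coefficient matrices for fourth permutation moments
#'
#' The 5 x 2 matrix `A` maps (mu2^2, mu4) to the five derived phenotype
#' moments (four of a kind, ..., no repeats); the constant 5 x 2 matrix `B`
#' collects the combinatorial coefficients with which those moments multiply
#' the expression cross-moments. Only the 2 x 2 product `ATB` = t(A) B enters
#' the fourth-moment formulas.
#'
#' @param n sample count, at least 4.
#' @return list with `A`, `B` and `ATB`.
#' @export
moment_matrices <- function(n) {
  if (n < 4L) stop("fourth permutation moments require n >= 4")
  d1 <- n - 1
  d2 <- (n - 1) * (n - 2)
  d3 <- (n - 1) * (n - 2) * (n - 3)
  A <- cbind(c(0, 0, n / d1, -n / d2, 3 * n / d3),
             c(1, -1 / d1, -1 / d1, 2 / d2, -6 / d3))
  B <- cbind(c(0, 0, 1, -2, 1),
             c(1, -4, -3, 12, -6))
  list(A = A, B = B, ATB = crossprod(A, B))
}

#' Permutation covariance of two per-gene coefficients
#'
#' cov(beta~_g, beta~_h) = mu2 Xbar_gh / (n-1), where
#' Xbar_gh = (1/n) sum_i x_gi x_hi. In particular the permutation correlation
#' of two per-gene coefficients equals the sample correlation of the two
#' gene profiles.
#'
#' @param xg,xh centered expression vectors for the two genes (length n).
#' @param y centered phenotype vector.
#' @return the covariance under uniform random permutation of `y`.
#' @export
beta_pair_cov <- function(xg, xh, y) {
  n <- length(y)
  if (n < 2L) stop("need n >= 2")
  mean(y^2) * mean(xg * xh) / (n - 1)
}

#' Permutation covariance of two squared per-gene coefficients
#'
#' cov(beta~_g^2, beta~_h^2) from the closed-form fourth-moment expansion:
#' (mu2^2, mu4) ATB (Xbar*_gghh / n^2, Xbar_gghh / n^3)' -
#' mu2^2 Xbar_gg Xbar_hh / (n-1)^2, with
#' Xbar*_gghh = Xbar_gg Xbar_hh + 2 Xbar_gh^2.
#'
#' @inheritParams beta_pair_cov
#' @return the covariance of the squared coefficients under permutation.
#' @export
beta_sq_pair_cov <- function(xg, xh, y) {
  n <- length(y)
  mm <- moment_matrices(n)
  ym <- y_moments(y)
  xgg <- mean(xg^2)
  xhh <- mean(xh^2)
  xgh <- mean(xg * xh)
  xgghh <- mean(xg^2 * xh^2)
  xstar <- xgg * xhh + 2 * xgh^2
  drop(c(ym$mu2^2, ym$mu4) %*% mm$ATB %*% c(xstar / n^2, xgghh / n^3)) -
    ym$mu2^2 * xgg * xhh / (n - 1)^2
}

#' Exact permutation moments of the linear set statistic
#'
#' Given the pseudo-gene profile X_G and centered phenotype, returns the
#' observed statistic T^ = (1/n) sum_i X_Gi y_i together with its exact
#' moments under uniform random permutation of `y`:
#' E(T~) = 0, var(T~) = mu2 Xbar_GG / (n-1), the attainable range
#' \[A, B\] from the rearrangement inequality (B pairs both sorted
#' ascending, A pairs them in opposite order), and (for n >= 4) the fourth
#' moment E(T~^4) = (mu2^2, mu4) ATB (3 Xbar_GG^2/n^2, Xbar_GGGG/n^3)'.
#'
#' @param x_g pseudo-gene profile (length-n vector, weights absorbed).
#' @param y centered phenotype vector.
#' @return list of class `"linear_moments"` with `t_hat`, `var_t`,
#'   `range_a`, `range_b`, `fourth` (NA when n < 4), `n`, and a
#'   `degenerate` flag (pseudo-gene identically zero).
#' @export
linear_moments <- function(x_g, y) {
  n <- length(y)
  if (length(x_g) != n) stop("dimension mismatch")
  if (n < 2L) stop("need n >= 2")
  ym <- y_moments(y)
  xbar_gg <- mean(x_g^2)
  xs <- sort(x_g)
  ys <- sort(y)
  out <- list(
    t_hat = mean(x_g * y),
    var_t = ym$mu2 * xbar_gg / (n - 1),
    range_a = mean(xs * rev(ys)),
    range_b = mean(xs * ys),
    fourth = NA_real_,
    n = n,
    degenerate = xbar_gg == 0)
  if (n >= 4L) {
    mm <- moment_matrices(n)
    xbar_gggg <- mean(x_g^4)
    out$fourth <- drop(c(ym$mu2^2, ym$mu4) %*% mm$ATB %*%
                         c(3 * xbar_gg^2 / n^2, xbar_gggg / n^3))
  }
  class(out) <- "linear_moments"
  out
}

#' Excess-kurtosis diagnostic for the permuted linear statistic
#'
#' Reports E(T~^4) - 3 var(T~)^2. Negative values (the usual case) mean the
#' permutation distribution has lighter tails than the normal, which is why
#' a scaled-beta reference is offered rather than a t reference (t has
#' positive excess kurtosis).
#'
#' @param lm a [linear_moments()] result with the fourth moment available.
#' @return the excess fourth cumulant (numeric).
#' @export
kurtosis_excess <- function(lm) {
  if (is.na(lm$fourth)) stop("fourth moment unavailable (n < 4)")
  lm$fourth - 3 * lm$var_t^2
}

#' Exact permutation moments of the quadratic set statistic
#'
#' With set rows pre-scaled by sqrt(w_g) (so all weights can be taken as 1),
#' returns the observed statistic C^ = sum_g beta_g^2, its exact permutation
#' mean E(C~) = mu2 sum_g Xbar_gg / (n-1) and variance assembled from the
#' aggregation sums
#' S1 = (sum_g Xbar_gg)^2, S2 = (1/n) sum_i (sum_g x_gi^2)^2 and
#' S3 = sum_gh Xbar_gh^2:
#' var(C~) = (mu2^2, mu4) ATB ((S1 + 2 S3)/n^2, S2/n^3)' -
#' mu2^2 S1 / (n-1)^2.
#' S3 is computed in O(n p^2) via the p x p Gram matrix when p <= n and in
#' O(n^2 p) via the n x n Gram matrix otherwise.
#'
#' @param xs matrix of the set's gene rows (p x n), centered; pass weighted
#'   rows through [pseudo_gene()] with `mode = "quadratic"` or give
#'   `weights`.
#' @param y centered phenotype vector.
#' @param weights optional non-negative per-gene weights applied as
#'   sqrt(w_g) row scaling before the computation.
#' @return list of class `"quad_moments"` with `c_hat`, `mean_c`, `var_c`,
#'   `s1`, `s2`, `s3`, `n`, `p` and a `degenerate` flag.
#' @export
quad_moments <- function(xs, y, weights = NULL) {
  xs <- rbind(xs)
  n <- length(y)
  if (ncol(xs) != n) stop("dimension mismatch")
  if (n < 4L) stop("quadratic moments require n >= 4")
  if (!is.null(weights))
    xs <- pseudo_gene(xs, weights, mode = "quadratic")
  p <- nrow(xs)
  ym <- y_moments(y)
  mm <- moment_matrices(n)

  beta <- drop(xs %*% y) / n
  c_hat <- sum(beta^2)
  xbar_gg <- rowMeans(xs^2)
  mean_c <- ym$mu2 * sum(xbar_gg) / (n - 1)

  s1 <- sum(xbar_gg)^2
  s2 <- mean(colSums(xs^2)^2)
  s3 <- if (p <= n) {
    sum((tcrossprod(xs) / n)^2)          # O(n p^2): p x p Gram of gene rows
  } else {
    sum(crossprod(xs)^2) / n^2           # O(n^2 p): n x n Gram of samples
  }

  var_c <- drop(c(ym$mu2^2, ym$mu4) %*% mm$ATB %*%
                  c((s1 + 2 * s3) / n^2, s2 / n^3)) -
    ym$mu2^2 * s1 / (n - 1)^2
  if (var_c < 0) {
    if (var_c > -1e-10 * max(mean_c^2, .Machine$double.xmin)) {
      var_c <- 0
    } else {
      stop("negative variance from moment assembly: ", format(var_c))
    }
  }

  structure(list(c_hat = c_hat, mean_c = mean_c, var_c = var_c,
                 s1 = s1, s2 = s2, s3 = s3, n = n, p = p,
                 degenerate = mean_c == 0),
            class = "quad_moments")
}
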