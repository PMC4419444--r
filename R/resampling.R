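#' All permutations of 1..n
#'
#' Exhaustive enumeration used by the small-sample oracles; refuses n > 8
#' (8! = 40,320 rows) because larger n are combinatorially out of reach at
#' desk scale and the closed-form moments exist precisely to avoid them.
#'
#' @param n integer, 1 <= n <= 8.
#' @return an n! x n integer matrix, one permutation per row.
#' @export
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n < 1L || n > 8L) stop("enumeration supported for 1 <= n <= 8 only")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  unname(do.call(rbind, out))
}

#' A matrix of independently sampled phenotype permutations
#'
#' Permutations are sampled uniformly with replacement (independent uniform
#' permutations), the classical Monte Carlo permutation scheme. A shared
#' permutation matrix lets many gene sets be scored against the same draws.
#'
#' @param y phenotype vector.
#' @param m number of permutations.
#' @param seed optional integer seed (set before sampling when given).
#' @return an n x m matrix whose columns are permuted copies of `y`.
#' @export
perm_matrix <- function(y, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(m), function(i) sample(y), numeric(length(y)))
}

#' Monte Carlo or exhaustive permutation draws of a set statistic
#'
#' Recomputes the linear statistic T~ (from a pseudo-gene vector) or the
#' quadratic statistic C~ (from sqrt-weight-scaled set rows) under permuted
#' phenotypes. With `exhaustive = TRUE` all n! permutations are used
#' (n <= 8) and the result is seed-independent.
#'
#' @param x pseudo-gene vector (linear) or p x n matrix of set rows
#'   (quadratic).
#' @param y centered phenotype vector.
#' @param m number of Monte Carlo draws (ignored when exhaustive).
#' @param stat `"linear"` or `"quadratic"`.
#' @param seed optional integer seed.
#' @param exhaustive enumerate all n! permutations instead of sampling?
#' @param yperm optional precomputed permutation matrix from
#'   [perm_matrix()] (overrides `m`/`seed`).
#' @return list of class `"resample_draws"`: `draws`, `m`, `kind`
#'   (`"permutation"` or `"exhaustive"`), `stat`, `seed`.
#' @export
perm_draws <- function(x, y, m = 9999L, stat = c("linear", "quadratic"),
                       seed = NULL, exhaustive = FALSE, yperm = NULL) {
  stat <- match.arg(stat)
  n <- length(y)
  if (exhaustive) {
    perms <- all_permutations(n)
    yperm <- apply(perms, 1L, function(p) y[p])
    kind <- "exhaustive"
    seed <- NA_integer_
  } else {
    if (is.null(yperm)) yperm <- perm_matrix(y, m, seed)
    kind <- "permutation"
  }
  draws <- if (stat == "linear") {
    drop(crossprod(yperm, as.numeric(x))) / n
  } else {
    b <- rbind(x) %*% yperm / n
    colSums(b^2)
  }
  structure(list(draws = draws, m = ncol(yperm), kind = kind, stat = stat,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "resample_draws")
}

#' Permutation p-values with the +1 convention
#'
#' The observed statistic counts as one of the permutations (an identity
#' permutation is automatically included), so
#' p_L = (#\{T~ <= T^\} + 1)/(M + 1) and similarly for the right, central
#' (|T~| >= |T^|) and quadratic (C~ >= C^) versions. Under exhaustive
#' enumeration with continuous data the resulting p-value is uniform on
#' \{1/(M+1), ..., 1\}.
#'
#' @param draws a [perm_draws()] result (or any list with `draws` and
#'   `stat`).
#' @param observed the observed statistic value.
#' @return list with `p_left`, `p_right`, `p_central` (linear) or `p_q`
#'   (quadratic), plus `m`.
#' @export
perm_pvalues <- function(draws, observed) {
  d <- draws$draws
  if (length(d) == 0L) stop("no permutation draws")
  m <- length(d)
  if (identical(draws$stat, "quadratic")) {
    list(p_q = (sum(d >= observed) + 1) / (m + 1), m = m)
  } else {
    list(p_left = (sum(d <= observed) + 1) / (m + 1),
         p_right = (sum(d >= observed) + 1) / (m + 1),
         p_central = (sum(abs(d) >= abs(observed)) + 1) / (m + 1),
         m = m)
  }
}

#' Exact permutation moments by exhaustive enumeration
#'
#' The arbiter oracle for the closed-form moment formulas: statistics are
#' recomputed under all n! permutations and moments taken directly.
#'
#' @inheritParams perm_draws
#' @return list with `mean`, `var` (population, divisor n!), and `fourth`
#'   (raw fourth moment, linear statistic only).
#' @export
exhaustive_moments <- function(x, y, stat = c("linear", "quadratic")) {
  stat <- match.arg(stat)
  d <- perm_draws(x, y, stat = stat, exhaustive = TRUE)$draws
  m <- length(d)
  mu <- mean(d)
  list(mean = mu, var = sum((d - mu)^2) / m,
       fourth = if (stat == "linear") mean(d^4) else NA_real_)
}

#' Orthonormal contrast matrix
#'
#' An n x (n-1) matrix W with W'W = I and W'1 = 0 (normalized Helmert
#' construction), mapping data into the centered subspace for rotation
#' sampling. Any such W is valid; moments of the linear statistic do not
#' depend on the choice, while the fourth moments of the quadratic
#' statistic do.
#'
#' @param n sample count, at least 2.
#' @return an n x (n-1) numeric matrix.
#' @export
contrast_matrix <- function(n) {
  if (n < 2L) stop("need n >= 2")
  w <- stats::contr.helmert(n)
  sweep(w, 2L, sqrt(colSums(w^2)), "/")
}

#' Uniform (Haar) random rotation matrix
#'
#' QR decomposition of a Gaussian matrix with the signs of R's diagonal
#' folded into Q, which makes the draw exactly Haar-uniform over the
#' orthogonal group O(m).
#'
#' @param m dimension.
#' @return an m x m orthogonal matrix.
#' @export
random_rotation <- function(m) {
  z <- matrix(stats::rnorm(m * m), m, m)
  qz <- qr(z)
  q <- qr.Q(qz)
  d <- sign(diag(qr.R(qz)))
  d[d == 0] <- 1
  sweep(q, 2L, d, "*")
}

#' Rotation-sampled per-gene coefficients
#'
#' Mean-preserving rotation replaces y by Q y with
#' Q = (1/n) 11' + W Q* W', Q* a Haar-uniform (n-1) x (n-1) rotation, so
#' each rotated phenotype keeps sum 0 and sum of squares. The per-gene
#' coefficients beta~ = (1/n) X y~ are returned for each draw; their first
#' and second rotation moments equal the permutation ones for any W,
#' whereas var(C~) under rotation depends on W. Used as a verification
#' oracle, not for p-value production.
#'
#' @param x genes-by-samples matrix (or a single profile vector).
#' @param y centered phenotype vector.
#' @param m number of rotation draws.
#' @param w contrast matrix; defaults to [contrast_matrix()].
#' @param seed optional integer seed.
#' @return list of class `"resample_draws"` with `draws` (p x m matrix of
#'   beta~ values), `m`, `kind = "rotation"`, `w`, `seed`.
#' @export
rotation_beta_draws <- function(x, y, m, w = NULL, seed = NULL) {
  x <- rbind(x)
  n <- length(y)
  if (n < 3L) stop("rotation sampling needs n >= 3")
  if (is.null(w)) w <- contrast_matrix(n)
  if (!is.null(seed)) set.seed(seed)
  yc <- drop(crossprod(w, y))
  xw <- x %*% w / n               # p x (n-1); beta~ = xw %*% (Q* yc)
  draws <- matrix(NA_real_, nrow(x), m)
  for (j in seq_len(m)) {
    q <- random_rotation(n - 1L)
    draws[, j] <- xw %*% (q %*% yc)
  }
  structure(list(draws = draws, m = m, kind = "rotation", stat = "beta",
                 w = w, seed = if (is.null(seed)) NA_integer_ else seed),
            class = "resample_draws")
}
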