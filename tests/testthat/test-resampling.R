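test_that("permutation p-values follow the +1 counting convention", {
  d <- structure(list(draws = seq(-1, -0.01, length.out = 99),
                      stat = "linear"), class = "resample_draws")
  pv <- perm_pvalues(d, observed = 0)
  expect_equal(pv$p_right, 1 / 100)   # no draw at least as large
  expect_equal(pv$p_left, 1)          # every draw below
  dq <- structure(list(draws = rep(5, 10), stat = "quadratic"),
                  class = "resample_draws")
  expect_equal(perm_pvalues(dq, observed = 1)$p_q, 1)
  expect_error(perm_pvalues(structure(list(draws = numeric(0),
                                           stat = "linear"),
                                      class = "resample_draws"), 0),
               "no permutation draws")
})

test_that("exhaustive permutation p-values are uniform on the p-value grid", {
  n <- 5
  x <- centered_vector(n, seed = 101)
  y <- centered_vector(n, seed = 102)
  d <- perm_draws(x, y, stat = "linear", exhaustive = TRUE)$draws
  m <- length(d)
  expect_equal(m, factorial(n))
  p <- vapply(seq_len(m), function(i) {
    perm_pvalues(structure(list(draws = d[-i], stat = "linear"),
                           class = "resample_draws"), d[i])$p_left
  }, 0)
  expect_equal(sort(p), seq_len(m) / m, tolerance = 1e-12)
})

test_that("Monte Carlo permutation p converges on the exhaustive value", {
  n <- 6
  x <- centered_vector(n, seed = 111)
  y <- centered_vector(n, seed = 112)
  ex <- perm_draws(x, y, stat = "linear", exhaustive = TRUE)
  p_ex <- perm_pvalues(ex, mean(x * y))$p_left
  m <- 20000L
  mc <- perm_draws(x, y, m = m, stat = "linear", seed = 7)
  p_mc <- perm_pvalues(mc, mean(x * y))$p_left
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / m) + 2 / m)
})

test_that("enumeration over distinct arrangements matches full enumeration for tied y", {
  x <- centered_vector(5, seed = 121)
  y <- c(-1, -1, 0, 1, 1)
  full <- perm_draws(x, y, stat = "linear", exhaustive = TRUE)$draws
  yp <- apply(all_permutations(5), 1L, function(p) y[p])
  distinct <- unique(t(yp))
  expect_equal(nrow(distinct), 1 / granularity(c(2, 1, 2))$epsilon)
  d_dist <- drop(distinct %*% x) / 5
  expect_equal(mean(full), mean(d_dist), tolerance = 1e-12)
  expect_equal(mean(full^2), mean(d_dist^2), tolerance = 1e-12)
})

test_that("contrast matrices are orthonormal and orthogonal to the ones vector", {
  for (n in c(2, 3, 10)) {
    w <- contrast_matrix(n)
    expect_equal(dim(w), c(n, n - 1L))
    expect_lt(max(abs(crossprod(w) - diag(n - 1L))), 1e-10)
    expect_lt(max(abs(colSums(w))), 1e-10)
  }
  expect_error(contrast_matrix(1), "n >= 2")
})

test_that("quartic coefficients of the centered image depend on the contrast matrix", {
  # For any n = 3 contrast matrix the coefficient of y_k^4 in
  # sum_i (W'y)_i^4 is sum_j W_kj^4; rows of W have squared norm 2/3, so
  # each coefficient lies in [2/9, 4/9] and one sample is distinguished.
  w <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  expect_lt(max(abs(crossprod(w) - diag(2))), 1e-12)
  expect_lt(max(abs(colSums(w))), 1e-12)
  coefs <- rowSums(w^4)
  # independent check: fit the quartic by evaluating at unit vectors
  quartic <- function(wm, y) sum((crossprod(wm, y))^4)
  coefs_eval <- vapply(1:3, function(k) quartic(w, diag(3)[, k]), 0)
  expect_equal(coefs, coefs_eval, tolerance = 1e-12)
  expect_equal(coefs, c(5 / 18, 5 / 18, 4 / 9), tolerance = 1e-12)
  # permuting the rows of W moves the distinguished coefficient
  w2 <- w[c(3, 1, 2), ]
  expect_equal(rowSums(w2^4), coefs[c(3, 1, 2)], tolerance = 1e-12)
})

test_that("rotation moments of the coefficients match the permutation closed forms", {
  n <- 8
  m <- 20000L
  x <- centered_matrix(2, n, seed = 131, scale = TRUE)
  x[2, ] <- x[2, ] + 0.6 * x[1, ]
  x[2, ] <- (x[2, ] - mean(x[2, ]))
  y <- centered_vector(n, seed = 132)
  rd <- rotation_beta_draws(x, y, m = m, seed = 9)
  b <- rd$draws
  # E(beta~_g) = 0
  se1 <- sd(b[1, ]) / sqrt(m)
  expect_lt(abs(mean(b[1, ])), 4 * se1)
  # E(beta~_g beta~_h) = mu2 Xbar_gh / (n-1)
  prod_gh <- b[1, ] * b[2, ]
  se2 <- sd(prod_gh) / sqrt(m)
  expect_lt(abs(mean(prod_gh) - beta_pair_cov(x[1, ], x[2, ], y)), 4 * se2)
  # rotated phenotypes keep their first two moments
  w <- contrast_matrix(n)
  set.seed(10)
  yt <- w %*% (random_rotation(n - 1L) %*% crossprod(w, y))
  expect_lt(abs(sum(yt)), 1e-10)
  expect_equal(sum(yt^2), sum(y^2), tolerance = 1e-10)
})

test_that("Haar rotation fourth moments match their closed forms", {
  n <- 6
  m <- 5000L
  set.seed(11)
  m4 <- num_sc <- num_dist <- numeric(m)
  for (k in seq_len(m)) {
    q <- random_rotation(n)
    s4 <- sum(q^4)
    m4[k] <- s4 / n^2
    num_sc[k] <- (n - s4) / (n * n * (n - 1))   # same-column distinct rows
    num_dist[k] <- (n^2 - 2 * n + s4) / (n^2 * (n - 1)^2)
  }
  th4 <- 3 / (n * (n + 2))
  th_sc <- 1 / (n * (n + 2))
  th_dist <- (n + 1) / (n * (n - 1) * (n + 2))
  expect_lt(abs(mean(m4) - th4), 4 * sd(m4) / sqrt(m))
  expect_lt(abs(mean(num_sc) - th_sc), 4 * sd(num_sc) / sqrt(m))
  expect_lt(abs(mean(num_dist) - th_dist), 4 * sd(num_dist) / sqrt(m))
  # E(Q_ij^2) = 1/n
  set.seed(12)
  q11 <- vapply(seq_len(m), function(i) random_rotation(n)[1, 1]^2, 0)
  expect_lt(abs(mean(q11) - 1 / n), 4 * sd(q11) / sqrt(m))
})

test_that("rotation var(C) departs from the permutation variance but not from W", {
  # Under Haar-uniform Q*, the rotated phenotype W Q* W'y is uniform on
  # the centered sphere whatever contrast matrix is used (W is an isometry
  # of that sphere), so every rotation moment is invariant to the choice
  # of W. What rotation does NOT share with permutation is var(C~): the
  # matched moments are E(T~), var(T~) and E(C~) only.
  set.seed(2)
  n <- 5
  m <- 50000L
  x <- matrix(rnorm(2 * n), 2, n)
  x <- x - rowMeans(x)
  y <- rnorm(n)^3          # skewed phenotype widens the var(C~) gap
  y <- y - mean(y)
  w1 <- contrast_matrix(n)
  set.seed(20)
  w2 <- w1[sample(n), ]    # row permutation is again a valid contrast
  stat_c <- function(w, seed) {
    b <- rotation_beta_draws(x, y, m = m, w = w, seed = seed)$draws
    cdr <- colSums(b^2)
    c(var = var(cdr), se = sd((cdr - mean(cdr))^2) / sqrt(m),
      mean = mean(cdr), mean_se = sd(cdr) / sqrt(m),
      var_t = var(colSums(b)))
  }
  s1 <- stat_c(w1, 201)
  s2 <- stat_c(w2, 202)
  qm <- quad_moments(x, y)
  # W-invariance of the rotation distribution
  expect_lt(abs(s1["var"] - s2["var"]),
            4 * sqrt(s1["se"]^2 + s2["se"]^2))
  # E(C~) matches permutation under rotation (Corollary-3 moments)...
  expect_lt(abs(s1["mean"] - qm$mean_c), 4 * s1["mean_se"])
  # ...but var(C~) does not
  expect_gt(abs(s1["var"] - qm$var_c), 10 * s1["se"])
  expect_gt(abs(s2["var"] - qm$var_c), 10 * s2["se"])
})
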