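# Small centered/scaled fixtures built in code; no stored data.

centered_matrix <- function(p, n, seed = NULL, scale = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)), NULL))
  x <- x - rowMeans(x)
  if (scale) x <- x * sqrt(n / rowSums(x^2))
  x
}

centered_vector <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rnorm(n)
  y - mean(y)
}

# Independent brute-force moments: statistics recomputed under every
# permutation with plain loops (no shared code with the package paths
# under test beyond the statistic's definition).
brute_linear_moments <- function(x_g, y) {
  perms <- mbgst::all_permutations(length(y))
  d <- apply(perms, 1L, function(p) mean(x_g * y[p]))
  list(mean = mean(d), var = mean((d - mean(d))^2), fourth = mean(d^4),
       min = min(d), max = max(d), draws = d)
}

brute_quad_moments <- function(xs, y) {
  xs <- rbind(xs)
  perms <- mbgst::all_permutations(length(y))
  d <- apply(perms, 1L, function(p) sum((xs %*% y[p] / length(y))^2))
  list(mean = mean(d), var = mean((d - mean(d))^2), draws = d)
}
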