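#' Synthetic expression data with designated signal sets
#'
#' Generates a genes-by-samples Gaussian expression matrix, an optional
#' block-correlation structure among genes, a binary or continuous
#' phenotype, a collection of random gene sets, and an optional
#' phenotype-linked mean shift in designated "signal" sets. Emulates the
#' centered/standardized matrices the tests operate on: raw draws are
#' returned and [center_scale()] is expected downstream. All randomness
#' comes from `seed`.
#'
#' @param n_samples number of samples (default 20).
#' @param n_genes number of genes (default 200).
#' @param n_sets number of gene sets (default 20).
#' @param set_size length-2 range of set sizes, sampled uniformly.
#' @param block_size genes per correlated block (1 = independent genes).
#' @param block_cor within-block correlation rho in \[0, 1).
#' @param n_signal_sets how many of the sets carry signal (the first ones).
#' @param effect_size mean-shift delta added to signal-set genes along the
#'   standardized phenotype direction.
#' @param phenotype `"continuous"` (standard normal) or `"binary"`.
#' @param group_sizes for a binary phenotype, the two group sizes
#'   (default an even split).
#' @param seed integer seed; required for reproducibility, default 1.
#' @return list with `x` (raw matrix, gene rownames g0001...), `y`,
#'   `sets` (named list), `signal_sets` (names), and the generating
#'   parameters in `spec`.
#' @export
synth_dataset <- function(n_samples = 20, n_genes = 200, n_sets = 20,
                          set_size = c(5, 20), block_size = 1,
                          block_cor = 0, n_signal_sets = 0,
                          effect_size = 0,
                          phenotype = c("continuous", "binary"),
                          group_sizes = NULL, seed = 1) {
  phenotype <- match.arg(phenotype)
  if (!(block_cor >= 0 && block_cor < 1)) stop("block_cor must be in [0, 1)")
  if (n_signal_sets > n_sets) stop("more signal sets than sets")
  set.seed(seed)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  x <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(gene_ids, sprintf("s%02d", seq_len(n_samples))))
  if (block_cor > 0 && block_size > 1) {
    block <- rep(seq_len(ceiling(n_genes / block_size)),
                 each = block_size)[seq_len(n_genes)]
    z <- matrix(stats::rnorm(max(block) * n_samples), max(block), n_samples)
    x <- sqrt(block_cor) * z[block, , drop = FALSE] +
      sqrt(1 - block_cor) * x
  }

  y <- if (phenotype == "continuous") {
    stats::rnorm(n_samples)
  } else {
    if (is.null(group_sizes))
      group_sizes <- c(floor(n_samples / 2), ceiling(n_samples / 2))
    if (sum(group_sizes) != n_samples) stop("group sizes must sum to n")
    rep(c(0, 1), group_sizes)
  }
  names(y) <- colnames(x)

  size_range <- seq(set_size[1L], set_size[2L])
  sizes <- if (length(size_range) == 1L) rep(size_range, n_sets)
           else sample(size_range, n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- sprintf("set%03d", seq_len(n_sets))

  signal <- character(0)
  if (n_signal_sets > 0 && effect_size != 0) {
    ys <- (y - mean(y)) / stats::sd(y)
    signal <- names(sets)[seq_len(n_signal_sets)]
    for (s in signal) {
      g <- sets[[s]]
      x[g, ] <- x[g, ] + effect_size *
        matrix(ys, length(g), n_samples, byrow = TRUE)
    }
  }

  list(x = x, y = y, sets = sets, signal_sets = signal,
       spec = list(n_samples = n_samples, n_genes = n_genes,
                   n_sets = n_sets, set_size = set_size,
                   block_size = block_size, block_cor = block_cor,
                   n_signal_sets = n_signal_sets,
                   effect_size = effect_size, phenotype = phenotype,
                   group_sizes = group_sizes, seed = seed))
}
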