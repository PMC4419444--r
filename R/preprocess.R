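#' Center (and optionally scale) an expression matrix and phenotype
#'
#' Each gene row of `x` is centered to sum zero and, by default, scaled so
#' that its sum of squares equals `n` (unit mean square). The phenotype `y`
#' is always centered, never scaled: with unit-mean-square genes the p-values
#' downstream are invariant to the scale of `y`, so per-gene covariances
#' coincide with correlations. Preprocessing of `x` never reads `y` and vice
#' versa. Optionally each gene row is first replaced by its ranks
#' (a robustness transform for heavy-tailed expression values).
#'
#' @param x numeric matrix, genes in rows, samples in columns. Rownames are
#'   taken as gene identifiers.
#' @param y numeric phenotype vector, one value per sample (column of `x`).
#' @param scale logical; scale each gene row to sum of squares `n`?
#' @param rank logical; replace each gene row by its ranks before
#'   centering/scaling?
#' @return A list of class `"gst_data"` with components `x` (centered/scaled
#'   matrix), `y` (centered vector), and flags `centered`, `scaled`, `rank`.
#' @examples
#' d <- center_scale(matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), NULL)),
#'                   y = c(0, 1, 2))
#' rowSums(d$x)            # ~ 0
#' rowSums(d$x^2)          # = 3
#' @export
center_scale <- function(x, y, scale = TRUE, rank = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- ncol(x)
  if (n < 2L)
    stop("need at least two samples")
  if (length(y) != n)
    stop("phenotype length (", length(y), ") does not match sample count (",
         n, ")")
  if (anyNA(x) || anyNA(y))
    stop("missing values are not supported; the moment formulas assume complete data")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("gene identifiers must be unique")

  if (rank)
    x <- t(apply(x, 1L, base::rank))

  x <- x - rowMeans(x)
  if (scale) {
    ss <- rowSums(x^2)
    bad <- ss <= 0
    if (any(bad))
      stop("cannot scale constant gene row(s): ",
           paste(utils::head(rownames(x)[bad], 5L), collapse = ", "))
    x <- x * sqrt(n / ss)
  }

  y <- y - mean(y)
  if (all(y == 0))
    stop("phenotype is constant; no association is testable")

  structure(list(x = x, y = y, centered = TRUE, scaled = scale, rank = rank),
            class = "gst_data")
}

#' Per-gene association statistics
#'
#' For centered data the per-gene measure of association is the sample
#' covariance beta_g = (1/n) sum_i x_gi y_i. When gene rows and `y` are both
#' standardized to unit mean square this equals the sample correlation rho_g.
#' The classical t statistic and its fourth-order Taylor approximation in
#' rho are also returned (the latter shows why permutation analyses of sums
#' of correlations track analyses of sums of t statistics).
#'
#' @param x centered (optionally scaled) genes-by-samples matrix.
#' @param y centered phenotype vector.
#' @return data frame with one row per gene: `beta` (covariance), `rho`
#'   (correlation), `t` and `t_taylor` (NA where |rho| >= 1 or n < 3).
#' @export
gene_stats <- function(x, y) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (length(y) != n)
    stop("dimension mismatch between x (", n, " samples) and y (",
         length(y), ")")
  beta <- drop(x %*% y) / n
  xs <- sqrt(rowMeans(x^2))
  ys <- sqrt(mean(y^2))
  rho <- ifelse(xs > 0, beta / (xs * ys), NA_real_)
  tt <- rep(NA_real_, length(rho))
  ta <- rep(NA_real_, length(rho))
  ok <- !is.na(rho) & abs(rho) < 1 & n >= 3L
  if (any(ok)) {
    tv <- t_taylor(rho[ok], n)
    tt[ok] <- tv$t
    ta[ok] <- tv$t_approx
  }
  data.frame(gene = rownames(x), beta = beta, rho = rho,
             t = tt, t_taylor = ta, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' t statistic and its Taylor approximation in the correlation
#'
#' t = sqrt(n-2) rho / sqrt(1 - rho^2), and the fourth-order expansion
#' t ~= sqrt(n-2) (rho + rho^3/2), accurate to O(rho^5). Gene set tests are
#' most useful when each |rho_g| is small, where the two are nearly
#' proportional.
#'
#' @param rho correlation value(s), |rho| < 1.
#' @param n sample count, at least 3.
#' @return list with components `t` and `t_approx`.
#' @export
t_taylor <- function(rho, n) {
  if (n < 3L) stop("need n >= 3 for a t statistic")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  list(t = sqrt(n - 2) * rho / sqrt(1 - rho^2),
       t_approx = sqrt(n - 2) * (rho + rho^3 / 2))
}

#' Collapse a gene set to a pseudo-gene profile
#'
#' For the linear statistic a set is reduced to a single profile
#' X_Gi = sum_g w_g x_gi (weights absorbed), so the set statistic is the
#' covariance of one pseudo-gene with the phenotype, computable in O(n |G|).
#' For the quadratic statistic each row is instead rescaled to sqrt(w_g) x_gi
#' (valid only for non-negative weights), after which all downstream moment
#' formulas can take every weight to be 1.
#'
#' @param xg numeric matrix of the set's gene rows (|G| x n).
#' @param weights per-gene weights, recycled; default 1.
#' @param mode `"linear"` (returns a length-n vector) or `"quadratic"`
#'   (returns the sqrt-weight-scaled matrix).
#' @return numeric vector (linear) or matrix (quadratic).
#' @export
pseudo_gene <- function(xg, weights = 1, mode = c("linear", "quadratic")) {
  mode <- match.arg(mode)
  xg <- rbind(xg)  # keeps a single gene as a 1 x n matrix
  w <- rep_len(as.numeric(weights), nrow(xg))
  if (mode == "linear") {
    drop(crossprod(xg, w))
  } else {
    if (any(w < 0))
      stop("quadratic statistic requires non-negative weights")
    xg * sqrt(w)
  }
}
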