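#' Read a gene set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicated members within a line are removed with a warning; set order
#' is preserved.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene identifiers, with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " in ", path,
         ": need name, description and at least one gene")
  sets <- vector("list", length(parts))
  desc <- character(length(parts))
  for (i in seq_along(parts)) {
    genes <- parts[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicated gene(s) in set '", parts[[i]][1L],
              "' removed", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- genes
    desc[i] <- parts[[i]][2L]
  }
  names(sets) <- vapply(parts, `[`, "", 1L)
  names(desc) <- names(sets)
  attr(sets, "description") <- desc
  sets
}

#' Read a delimited expression matrix
#'
#' First column gene identifiers, header row sample identifiers; tab- or
#' comma-delimited (guessed from the extension unless `sep` is given).
#'
#' @param path file path.
#' @param sep field separator; default `"\t"`, or `","` for `.csv`.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read a phenotype vector
#'
#' Either one value per line, or two columns (sample identifier, value) in
#' which case the values are reconciled against `sample_ids`.
#'
#' @param path file path.
#' @param sample_ids sample identifiers of the expression matrix, used to
#'   order a two-column file.
#' @param sep field separator, default tab.
#' @return named numeric vector.
#' @export
read_phenotype <- function(path, sample_ids = NULL, sep = "\t") {
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    y <- as.numeric(df[[1L]])
    if (!is.null(sample_ids)) {
      if (length(y) != length(sample_ids))
        stop("phenotype length does not match sample count")
      names(y) <- sample_ids
    }
  } else {
    y <- as.numeric(df[[2L]])
    names(y) <- as.character(df[[1L]])
    if (!is.null(sample_ids)) {
      if (!all(sample_ids %in% names(y)))
        stop("phenotype file is missing sample(s): ",
             paste(utils::head(setdiff(sample_ids, names(y)), 5L),
                   collapse = ", "))
      y <- y[sample_ids]
    }
  }
  if (anyNA(y)) stop("non-numeric or missing phenotype values")
  y
}

#' Write a gene set test result table
#'
#' Tab-delimited, one row per set, fixed column order, full-precision
#' p-values (values round-trip through [utils::read.delim()] to ~1e-15
#' relative).
#'
#' @param x a `mbgst` fit or its result data frame.
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_results <- function(x, path) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L) stop("no results to write")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
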