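#' Write a numeric matrix as a TSV file with an id column
#'
#' Writes gene-by-sample (or module-by-sample) matrices in the package's
#' exchange format: tab-separated, header row of sample ids, row ids in the
#' first column.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path output file path.
#' @param id_col name for the first (row id) column.
#' @export
write_tsv_matrix <- function(x, path, id_col = "gene_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#'
#' @param path file path; first column is taken as rownames.
#' @return numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used to score recovery of planted module labels. 1 means identical
#' partitions (up to label names), 0 the chance level.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# standardize columns of a samples x genes matrix to mean 0, sd 1 (sd with n-1)
.standardize_cols <- function(x) {
  x <- sweep(x, 2, colMeans(x), "-")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) stop("zero-variance column in standardization")
  sweep(x, 2, s, "/")
}
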