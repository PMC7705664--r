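#' Assemble a count matrix from files
#'
#' Reads gene-level counts either from a single TSV matrix (genes in rows,
#' samples in columns, gene ids in the first column) or from per-sample
#' two-column files in the HTSeq-count convention (gene id, count; summary
#' rows whose ids start with `__`, such as `__no_feature`, are dropped).
#' Gene lengths are read from a two-column TSV (gene id, length in bp).
#'
#' @param matrix_path path to a counts TSV matrix (exclusive with
#'   `sample_paths`).
#' @param sample_paths named character vector of per-sample count files;
#'   names become sample ids (basenames are used if unnamed).
#' @param lengths_path path to the gene length TSV.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `gene_lengths` (named numeric, bp).
#' @export
read_counts <- function(matrix_path = NULL, sample_paths = NULL, lengths_path) {
  if (is.null(matrix_path) == is.null(sample_paths)) {
    stop("supply exactly one of matrix_path or sample_paths")
  }
  if (!is.null(matrix_path)) {
    counts <- read_tsv_matrix(matrix_path)
  } else {
    if (is.null(names(sample_paths))) {
      names(sample_paths) <- sub("\\.[^.]+$", "", basename(sample_paths))
    }
    cols <- lapply(seq_along(sample_paths), function(i) {
      df <- utils::read.delim(sample_paths[[i]], header = FALSE,
                              stringsAsFactors = FALSE,
                              col.names = c("gene_id", "count"))
      df <- df[!startsWith(df$gene_id, "__"), , drop = FALSE]
      if (anyDuplicated(df$gene_id)) {
        stop("duplicate gene id in ", sample_paths[[i]], ": ",
             paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
      }
      df
    })
    genes <- cols[[1]]$gene_id
    for (i in seq_along(cols)) {
      if (!setequal(cols[[i]]$gene_id, genes)) {
        bad <- c(setdiff(genes, cols[[i]]$gene_id),
                 setdiff(cols[[i]]$gene_id, genes))
        stop("gene sets differ across per-sample files (offending file: ",
             sample_paths[[i]], "; offending ids: ",
             paste(utils::head(bad, 5), collapse = ", "), ")")
      }
    }
    counts <- vapply(cols, function(df) {
      df$count[match(genes, df$gene_id)]
    }, numeric(length(genes)))
    counts <- matrix(counts, nrow = length(genes),
                     dimnames = list(genes, names(sample_paths)))
  }
  if (any(counts < 0)) stop("negative counts in input")

  len_df <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  gene_lengths <- stats::setNames(as.numeric(len_df[[2]]), len_df[[1]])
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing) > 0) {
    stop("missing gene length for: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  list(counts = counts, gene_lengths = gene_lengths)
}

#' FPKM from a count matrix
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length_g * library_size_s)`.
#' Library sizes default to the column sums of the count matrix, the only
#' computable proxy for total mapped reads when alignments are unavailable.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths numeric vector of transcript lengths in bp, in row
#'   order or named by gene id.
#' @param library_sizes optional per-sample totals of mapped reads.
#' @return FPKM matrix of the same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  stopifnot(is.matrix(counts))
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts))
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("gene lengths must be positive and finite")
  }
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  stopifnot(length(library_sizes) == ncol(counts))
  if (any(library_sizes <= 0)) stop("zero or negative library size")
  counts * 1e9 / outer(gene_lengths, library_sizes)
}

#' Filter genes by an expression threshold
#'
#' Keeps a gene when its FPKM summary over a sample scope reaches a cutoff
#' (inclusive). The default summary is the maximum over the scoped samples,
#' the most permissive literal reading of an "FPKM >= threshold" expressed
#' filter; `stat = "mean"` is provided as the stricter alternative.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param threshold expression cutoff (default 0.01).
#' @param samples optional character or integer vector restricting the scope
#'   (e.g. one cultivar's samples); default all samples.
#' @param stat summary over the scope: `"max"` (default) or `"mean"`.
#' @return the filtered FPKM matrix (gene order preserved).
#' @export
filter_expressed <- function(fpkm, threshold = 0.01, samples = NULL,
                             stat = c("max", "mean")) {
  stat <- match.arg(stat)
  stopifnot(threshold >= 0)
  scope <- if (is.null(samples)) fpkm else fpkm[, samples, drop = FALSE]
  if (ncol(scope) == 0) stop("empty sample scope")
  summary_fun <- if (stat == "max") function(x) max(x) else function(x) mean(x)
  keep <- apply(scope, 1, summary_fun) >= threshold
  fpkm[keep, , drop = FALSE]
}

#' Principal component analysis of samples
#'
#' Samples are observations and genes variables. By default the FPKM matrix
#' is log2(x + 1)-transformed and gene-centred but not scaled, the standard
#' treatment for FPKM before PCA. Returns per-sample scores, the fraction of
#' variance explained per component, and cos2 (squared coordinate shares),
#' the representation quality of each sample on each axis.
#'
#' @param fpkm FPKM (or other expression) matrix, genes x samples.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param center,scale. centring/scaling of genes (defaults TRUE/FALSE).
#' @return list with `scores` (samples x components),
#'   `variance_explained`, `cos2` (samples x components, rows sum to 1).
#' @export
pca_samples <- function(fpkm, log_transform = TRUE, center = TRUE,
                        scale. = FALSE) {
  if (ncol(fpkm) < 2) stop("PCA needs at least 2 samples")
  x <- t(if (log_transform) log2(fpkm + 1) else fpkm)  # samples x genes
  if (scale.) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      message("dropping ", sum(v == 0), " zero-variance genes before scaling")
      x <- x[, v > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  scores <- pc$x
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cos2 <- scores^2 / rowSums(scores^2)
  list(scores = scores, variance_explained = ve, cos2 = cos2)
}
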