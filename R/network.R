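#' Pearson correlation matrix of genes
#'
#' Gene-gene correlations across samples, computed by default on
#' log2(FPKM + 1). Zero-variance genes are excluded with a warning.
#'
#' @param expr expression matrix, genes x samples (FPKM unless
#'   `log_transform = FALSE` and already transformed).
#' @param genes optional subset of gene ids (e.g. the DEG union).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, genes = NULL, log_transform = TRUE) {
  if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
  if (ncol(expr) < 3) stop("need at least 3 samples for correlations")
  x <- if (log_transform) log2(expr + 1) else expr
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance genes")
    x <- x[v > 0, , drop = FALSE]
  }
  stats::cor(t(x))
}

#' Soft-thresholded adjacency
#'
#' Unsigned adjacency `a_ij = |cor_ij|^beta` (or signed,
#' `((1 + cor_ij) / 2)^beta`). The diagonal is set to 0 so that row sums are
#' the network connectivities `k_i`.
#'
#' @param cor_mat correlation matrix.
#' @param beta soft-thresholding power (integer >= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency_matrix <- function(cor_mat, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  stopifnot(beta >= 1)
  a <- if (type == "unsigned") abs(cor_mat)^beta else ((1 + cor_mat) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Bins the connectivities `k_i = sum_j a_ij` into `n_bins` equal-width
#' bins, regresses log10 of the bin frequency on log10 of the bin mean
#' connectivity over occupied bins, and returns the regression R^2 with the
#' sign flipped to negative when the slope is positive (a scale-free
#' network has a negative slope).
#'
#' @param adj adjacency matrix (zero diagonal).
#' @param n_bins number of connectivity bins (default 10).
#' @return signed R^2 in \[-1, 1\], or NA with a warning when all
#'   connectivities fall in one bin.
#' @export
scale_free_fit_index <- function(adj, n_bins = 10) {
  k <- rowSums(adj)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) {
    warning("all connectivities identical; fit index undefined")
    return(NA_real_)
  }
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  occupied <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(occupied) < 2) {
    warning("fewer than 2 occupied connectivity bins; fit index undefined")
    return(NA_real_)
  }
  x <- log10(mean_k[occupied])
  y <- log10(freq[occupied] / length(k))
  if (stats::sd(y) == 0) return(0)  # flat p(k): no decay, slope 0
  slope <- stats::cov(x, y) / stats::var(x)
  r2 <- stats::cor(x, y)^2
  if (is.finite(slope) && slope > 0) -r2 else r2
}

#' Soft-threshold power scan and selection
#'
#' Evaluates candidate powers and picks the lowest one whose signed
#' scale-free fit index reaches `r2_cut`, the conventional reading of
#' "the lowest power for a proper fit of the scale-free topology index".
#' When no power qualifies, `chosen_beta` is NA; `fallback_beta` then
#' carries the field's sample-count rule of thumb for data whose fit index
#' plateaus below the cut (unsigned networks: 9 below 20 samples, 8 for
#' 20-30, 7 for 30-40, 6 above 40; doubled for signed networks), which is
#' what [run_pipeline()] uses in that case.
#'
#' @param expr expression matrix, genes x samples (see
#'   [correlation_matrix()]).
#' @param powers candidate powers (default 1:20, ascending).
#' @param r2_cut fit-index threshold (default 0.8).
#' @param type network type passed to [adjacency_matrix()].
#' @param log_transform passed to [correlation_matrix()].
#' @return list with `scan` (data frame: power, signed_r2, mean_k,
#'   median_k, max_k), `chosen_beta`, and `fallback_beta`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cut = 0.8,
                                type = "unsigned", log_transform = TRUE) {
  stopifnot(length(powers) > 0, !is.unsorted(powers))
  cm <- correlation_matrix(expr, log_transform = log_transform)
  scan <- do.call(rbind, lapply(powers, function(b) {
    a <- adjacency_matrix(cm, b, type = type)
    k <- rowSums(a)
    data.frame(power = b,
               signed_r2 = suppressWarnings(scale_free_fit_index(a)),
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  }))
  n <- ncol(expr)
  fallback <- if (n < 20) 9L else if (n <= 30) 8L else if (n <= 40) 7L else 6L
  if (type == "signed") fallback <- 2L * fallback
  ok <- which(!is.na(scan$signed_r2) & scan$signed_r2 >= r2_cut)
  if (length(ok) > 0) {
    chosen <- scan$power[ok[1]]
  } else {
    chosen <- NA_integer_
    warning("no power reaches the fit cut ", r2_cut, "; the sample-count ",
            "fallback power is ", fallback, " (max-R2 power: ",
            scan$power[which.max(scan$signed_r2)], ")")
  }
  list(scan = scan, chosen_beta = chosen, fallback_beta = fallback)
}

#' Topological overlap matrix
#'
#' For an adjacency `a` with connectivities `k_i = sum_(u != i) a_iu` and
#' shared-neighbour sums `l_ij = sum_(u != i,j) a_iu a_uj`, the topological
#' overlap is `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and 1 on the diagonal. `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adj adjacency matrix in \[0, 1\] with zero diagonal.
#' @return TOM similarity matrix (symmetric, unit diagonal, in \[0, 1\]).
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), isTRUE(all.equal(adj, t(adj))),
            all(diag(adj) == 0), all(adj >= 0), all(adj <= 1))
  l <- adj %*% adj           # zero diagonal makes this sum_(u != i,j)
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  denom[denom <= 0] <- .Machine$double.eps  # unreachable for a in [0,1); guard
  tom <- (l + adj) / denom
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Average-linkage dendrogram on a dissimilarity matrix
#'
#' @param diss square symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @return an object of class `hclust`.
#' @export
cluster_dendrogram <- function(diss) {
  if (!is.matrix(diss) || nrow(diss) != ncol(diss)) {
    stop("dissimilarity must be a square matrix")
  }
  if (!isTRUE(all.equal(diss, t(diss), tolerance = 1e-8))) {
    stop("dissimilarity must be symmetric")
  }
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  stats::hclust(stats::as.dist(diss), method = "average")
}

# module color aliases, ordered by module rank (grey reserved for unassigned)
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

# relabel clusters by decreasing size; 0 stays 0 (grey); ties keep old order
.relabel_by_size <- function(labels) {
  tab <- table(labels[labels != 0])
  if (length(tab) == 0) return(labels)
  old <- as.integer(names(sort(tab, decreasing = TRUE)))
  new <- integer(max(labels) + 1)
  new[old + 1] <- seq_along(old)
  out <- labels
  out[labels != 0] <- new[labels[labels != 0] + 1]
  out
}

# attach color aliases to integer labels
.label_df <- function(gene_ids, labels) {
  color <- ifelse(labels == 0, "grey",
                  .module_colors[((labels - 1) %% length(.module_colors)) + 1])
  data.frame(gene_id = unname(gene_ids), module = unname(labels),
             color = unname(color), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Static-cut module detection with size filter and reassignment
#'
#' Cuts the average-linkage dendrogram at a fixed dissimilarity height
#' (default 0.95, the static-cut convention for TOM dissimilarities, where
#' unconnected genes sit near 1); alternatively `cut_quantile` places the
#' cut at a quantile of the merge heights. Candidate clusters smaller than
#' `min_module_size` are dissolved to grey (module 0). A second pass
#' reassigns each grey gene to the module with the smallest average
#' dissimilarity when that average is below `reassign_threshold` (set to
#' NULL to skip). Modules are labelled 1, 2, ... by decreasing size, with
#' color aliases; grey is never counted as a module.
#'
#' @param dendro `hclust` object from [cluster_dendrogram()].
#' @param diss the dissimilarity matrix that produced it.
#' @param min_module_size smallest retained cluster (default 30; >= 2).
#' @param cut_height fixed dissimilarity at which to cut (default 0.95).
#' @param cut_quantile optional quantile of merge heights overriding
#'   `cut_height`.
#' @param reassign_threshold maximum average dissimilarity for rescuing a
#'   grey gene into its nearest module (default 0.6).
#' @return data frame with columns `gene_id`, `module`, `color`.
#' @export
cut_modules <- function(dendro, diss, min_module_size = 30,
                        cut_height = 0.95, cut_quantile = NULL,
                        reassign_threshold = 0.6) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  h <- if (!is.null(cut_quantile)) {
    stats::quantile(dendro$height, cut_quantile, names = FALSE)
  } else cut_height
  labels <- stats::cutree(dendro, h = h)
  gene_ids <- dendro$labels
  sizes <- table(labels)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- ifelse(labels %in% keep, labels, 0L)
  out[out != 0] <- match(out[out != 0], sort(keep))  # compact labels

  if (!is.null(reassign_threshold) && any(out == 0) && any(out != 0)) {
    grey <- which(out == 0)
    mods <- sort(unique(out[out != 0]))
    avg <- vapply(mods, function(m) {
      rowMeans(diss[grey, out == m, drop = FALSE])
    }, numeric(length(grey)))
    avg <- matrix(avg, nrow = length(grey))
    best <- max.col(-avg, ties.method = "first")
    best_d <- avg[cbind(seq_along(grey), best)]
    rescue <- best_d < reassign_threshold
    out[grey[rescue]] <- mods[best[rescue]]
  }
  .label_df(gene_ids, .relabel_by_size(out))
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the pair of modules with the smallest eigengene
#' dissimilarity `1 - cor(ME_i, ME_j)` while that dissimilarity is below
#' `cut_height` (default 0.25, i.e. eigengene correlation above 0.75),
#' recomputing eigengenes after every merge. Ties are resolved toward the
#' lowest module labels. The result is a fixpoint: a second call leaves the
#' assignment unchanged. Labels are reassigned by decreasing size.
#'
#' @param expr expression matrix used for eigengenes (genes x samples, on
#'   the same scale as the network input, e.g. log2(FPKM + 1)).
#' @param assignment data frame from [cut_modules()].
#' @param cut_height eigengene dissimilarity below which modules merge.
#' @return data frame with columns `gene_id`, `module`, `color`.
#' @export
merge_close_modules <- function(expr, assignment, cut_height = 0.25) {
  labels <- stats::setNames(assignment$module, assignment$gene_id)
  repeat {
    mods <- sort(unique(labels[labels != 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, .label_df(names(labels), labels))
    d <- 1 - stats::cor(t(me$eigengenes))
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= cut_height) break
    pair <- sort(as.integer(sub("^ME", "", rownames(d)[idx])))
    labels[labels == pair[2]] <- pair[1]
    # compact labels so eigengene recomputation sees consecutive modules
    labels[labels != 0] <- match(labels[labels != 0],
                                 sort(unique(labels[labels != 0])))
  }
  .label_df(assignment$gene_id, .relabel_by_size(unname(labels)))
}
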