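#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member genes' expression across samples: each member gene is
#' standardized to zero mean and unit variance, the first right-singular
#' sample direction is taken, rescaled to unit variance across samples, and
#' sign-aligned so that it correlates non-negatively with the module's mean
#' standardized expression. `variance_explained` is the share of the
#' standardized variance carried by that component.
#'
#' @param expr expression matrix, genes x samples (e.g. log2(FPKM + 1)).
#' @param assignment data frame with columns `gene_id`, `module` (module 0
#'   = grey is skipped).
#' @return list with `eigengenes` (module x sample matrix, rows named
#'   `ME<label>`) and `variance_explained` (named vector).
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(unique(assignment$module[assignment$module != 0]))
  if (length(mods) == 0) stop("no non-grey modules")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), rownames(me))
  for (i in seq_along(mods)) {
    genes <- assignment$gene_id[assignment$module == mods[i]]
    x <- expr[genes, , drop = FALSE]
    if (nrow(x) == 1) {
      warning("module ", mods[i], " has a single gene; eigengene is its ",
              "standardized profile")
      prof <- as.numeric(scale(as.numeric(x)))
      me[i, ] <- prof
      ve[i] <- 1
      next
    }
    xs <- .standardize_cols(t(x))          # samples x genes, unit variance
    sv <- svd(xs, nu = 1, nv = 0)
    scores <- sv$u[, 1] * sv$d[1]
    scores <- scores / stats::sd(scores)
    align <- stats::cor(scores, rowMeans(xs))
    if (!is.na(align) && align < 0) scores <- -scores
    me[i, ] <- scores
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, variance_explained = ve)
}

#' Intramodular connectivity (module membership, kME)
#'
#' `K_ME(i) = cor(x_i, ME)`: the Pearson correlation of gene i's expression
#' profile with its own module's eigengene. Optionally also returns the
#' correlation of every gene with every module eigengene.
#'
#' @param expr expression matrix, genes x samples.
#' @param eigengenes result of [module_eigengenes()] (or its `eigengenes`
#'   matrix).
#' @param assignment data frame with `gene_id`, `module`.
#' @param all_modules also return the full gene x eigengene table.
#' @return data frame with `gene_id`, `module`, `k_me`; with
#'   `all_modules = TRUE`, additional `kME_ME<label>` columns.
#' @export
intramodular_connectivity <- function(expr, eigengenes, assignment,
                                      all_modules = FALSE) {
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else eigengenes
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) warning(sum(v == 0), " zero-variance genes get NA kME")
  kme_all <- suppressWarnings(stats::cor(t(expr), t(me)))  # genes x modules
  own_col <- match(paste0("ME", assignment$module),
                   colnames(kme_all))
  idx <- match(assignment$gene_id, rownames(kme_all))
  k_me <- ifelse(is.na(own_col), NA_real_, kme_all[cbind(idx, own_col)])
  out <- data.frame(gene_id = assignment$gene_id, module = assignment$module,
                    k_me = k_me, row.names = NULL, stringsAsFactors = FALSE)
  if (all_modules) {
    extra <- kme_all[idx, , drop = FALSE]
    colnames(extra) <- paste0("kME_", colnames(kme_all))
    out <- cbind(out, as.data.frame(extra, row.names = NULL))
  }
  out
}

#' Trait-based gene significance
#'
#' GS of a gene for a sample trait is the Pearson correlation between the
#' gene's expression profile and the trait across samples.
#'
#' @param expr expression matrix, genes x samples.
#' @param trait numeric trait vector, one value per sample (same order as
#'   the columns of `expr`).
#' @return named numeric vector of GS values in \[-1, 1\].
#' @export
gene_significance <- function(expr, trait) {
  stopifnot(length(trait) == ncol(expr))
  if (stats::sd(trait) == 0) stop("constant trait has no gene significance")
  gs <- suppressWarnings(as.numeric(stats::cor(t(expr), trait)))
  stats::setNames(gs, rownames(expr))
}

#' Module eigengene-trait correlations
#'
#' Pearson correlation of each module eigengene with each trait, with
#' two-sided p-values from the Student t distribution of
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#'
#' @param eigengenes result of [module_eigengenes()] (or its matrix).
#' @param traits data frame or matrix of traits, one row per sample in the
#'   eigengenes' column order (e.g. columns LT, Ac_LT, ELR).
#' @return list of matrices `r` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  me <- if (is.list(eigengenes)) eigengenes$eigengenes else eigengenes
  tr <- as.matrix(traits)
  n <- ncol(me)
  stopifnot(nrow(tr) == n)
  if (n < 3) stop("need at least 3 samples")
  r <- stats::cor(t(me), tr)
  r_cl <- pmin(pmax(r, -1), 1)
  t_stat <- r_cl * sqrt(n - 2) / sqrt(pmax(1 - r_cl^2, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(r_cl) == 1] <- 0
  list(r = r, p = p)
}

#' Assemble the per-gene score table
#'
#' Convenience wrapper combining kME and the three trait gene
#' significances into one table for the hub screen.
#'
#' @param expr expression matrix, genes x samples.
#' @param eigengenes result of [module_eigengenes()].
#' @param assignment data frame with `gene_id`, `module`.
#' @param traits data frame with columns `LT`, `Ac_LT`, `ELR` (rows in the
#'   sample order of `expr`).
#' @return data frame with `gene_id`, `module`, `k_me`, `gs_lt`,
#'   `gs_ac_lt`, `gs_elr`.
#' @export
gene_score_table <- function(expr, eigengenes, assignment, traits) {
  kme <- intramodular_connectivity(expr, eigengenes, assignment)
  kme$gs_lt <- as.numeric(gene_significance(expr, traits$LT)[kme$gene_id])
  kme$gs_ac_lt <- as.numeric(gene_significance(expr, traits$Ac_LT)[kme$gene_id])
  kme$gs_elr <- as.numeric(gene_significance(expr, traits$ELR)[kme$gene_id])
  kme
}

#' Hub-gene screen by top-quantile intersections
#'
#' Within each module, genes are ranked by |kME|, |GS_LT| and |GS_ELR|
#' (absolute values by default, since hub genes of chilling-responsive
#' modules carry strongly negative correlations). The top 20% by each
#' score (`ceiling(0.2 * module size)` genes, ties at the boundary
#' included) form three sets; the hub genes are the union of the three
#' pairwise intersections: kME & GS_LT, kME & GS_ELR, GS_LT & GS_ELR.
#'
#' @param scores data frame from [gene_score_table()] (columns `gene_id`,
#'   `module`, `k_me`, `gs_lt`, `gs_elr`).
#' @param quantile lower bound of the top fraction (default 0.80, i.e. the
#'   top 20%).
#' @param use_abs rank on absolute values (default) or signed values.
#' @return data frame of hub genes: `gene_id`, `module`, and logical
#'   qualifier columns `kme_gslt`, `kme_gselr`, `gslt_gselr`.
#' @export
screen_hub_genes <- function(scores, quantile = 0.80, use_abs = TRUE) {
  stopifnot(all(c("gene_id", "module", "k_me", "gs_lt", "gs_elr") %in%
                  colnames(scores)))
  frac <- 1 - quantile
  top_set <- function(values, ids) {
    v <- if (use_abs) abs(values) else values
    n_top <- ceiling(frac * length(v))
    cut <- sort(v, decreasing = TRUE)[n_top]
    ids[v >= cut]  # boundary ties included
  }
  out <- lapply(split(scores, scores$module), function(s) {
    if (s$module[1] == 0) return(NULL)
    if (nrow(s) < 5) {
      warning("module ", s$module[1], " has fewer than 5 genes; ",
              "top sets have a single gene")
    }
    t_kme <- top_set(s$k_me, s$gene_id)
    t_lt <- top_set(s$gs_lt, s$gene_id)
    t_elr <- top_set(s$gs_elr, s$gene_id)
    hubs <- union(union(intersect(t_kme, t_lt), intersect(t_kme, t_elr)),
                  intersect(t_lt, t_elr))
    if (length(hubs) == 0) return(NULL)
    data.frame(gene_id = sort(hubs), module = s$module[1],
               kme_gslt = sort(hubs) %in% intersect(t_kme, t_lt),
               kme_gselr = sort(hubs) %in% intersect(t_kme, t_elr),
               gslt_gselr = sort(hubs) %in% intersect(t_lt, t_elr),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), module = integer(),
                      kme_gslt = logical(), kme_gselr = logical(),
                      gslt_gselr = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
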