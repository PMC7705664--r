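#' Median-of-ratios normalization factors
#'
#' Per-sample scaling factors computed as the median, over reference genes
#' with all-positive counts, of the ratio of the sample's count to the
#' gene's geometric mean across samples; factors are rescaled to geometric
#' mean 1. Counts divided by these factors are comparable across samples.
#' If no gene has all-positive counts the column-sum ratios are used with a
#' warning.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
normalize_library_sizes <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene with all-positive counts; falling back to column-sum ratios")
    f <- colSums(counts)
    if (any(f == 0)) stop("all-zero sample column")
  } else {
    x <- counts[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(x)))
    f <- apply(x / geo, 2, stats::median)
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Common negative-binomial dispersion by method of moments
#'
#' Under the NB model used throughout the package the count variance is
#' `mu + phi * mu^2`. For each gene, within every group that has at least two
#' replicates, the moment estimate `(s^2 - m) / m^2` is formed on normalized
#' counts and combined across groups with df weights; negative values are
#' clipped to zero. The common dispersion pools the per-gene values by their
#' mean, which is moment-consistent even at two replicates per group (a
#' median pool would be biased low by more than half at that replication
#' because the per-gene statistic is driven by a 1-df variance estimate).
#'
#' @param counts gene x sample count matrix.
#' @param groups factor/vector of group memberships, one per sample.
#' @param norm_factors optional normalization factors
#'   (default [normalize_library_sizes()]).
#' @return list with `phi` (common dispersion), `per_gene_phi`, and
#'   `norm_factors`.
#' @export
estimate_common_dispersion <- function(counts, groups, norm_factors = NULL) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (!any(sizes >= 2)) stop("no group has replication; cannot estimate dispersion")
  if (is.null(norm_factors)) norm_factors <- normalize_library_sizes(counts)
  y <- sweep(counts, 2, norm_factors, "/")

  num <- numeric(nrow(counts))   # df-weighted sum of per-group phi estimates
  den <- 0
  for (g in levels(groups)[sizes >= 2]) {
    idx <- which(groups == g)
    df <- length(idx) - 1
    m <- rowMeans(y[, idx, drop = FALSE])
    s2 <- apply(y[, idx, drop = FALSE], 1, stats::var)
    phi_g <- ifelse(m > 0, (s2 - m) / m^2, 0)
    num <- num + df * phi_g
    den <- den + df
  }
  per_gene <- pmax(0, num / den)
  list(phi = mean(per_gene), per_gene_phi = per_gene,
       norm_factors = norm_factors)
}

#' Exact conditional p-value for one gene
#'
#' Two-group comparison of NB counts, conditioning on the total. With `nA`
#' and `nB` samples per group at common mean and dispersion `phi`, the group
#' sums are NB with means proportional to the group sizes and shapes
#' `nA / phi` and `nB / phi`. Conditional on the total `t = yA + yB`, the
#' two-sided p-value sums the probabilities of all splits as or less likely
#' than the observed one. `phi = 0` reduces to the conditional binomial with
#' success probability `nA / (nA + nB)`.
#'
#' @param ya,yb observed (normalized, rounded) group-sum counts.
#' @param n_a,n_b effective numbers of samples per group.
#' @param phi common NB dispersion (>= 0).
#' @return p-value in (0, 1\].
#' @export
nb_exact_pvalue <- function(ya, yb, n_a, n_b, phi = 0) {
  stopifnot(ya >= 0, yb >= 0, n_a > 0, n_b > 0, phi >= 0)
  t <- ya + yb
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(y, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu_a <- t * n_a / (n_a + n_b)
    mu_b <- t * n_b / (n_a + n_b)
    logp <- stats::dnbinom(y, size = n_a / phi, mu = mu_a, log = TRUE) +
      stats::dnbinom(t - y, size = n_b / phi, mu = mu_b, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[ya + 1]
  sum(p[p <= obs * (1 + 1e-10)])
}

#' Negative-binomial exact test across genes
#'
#' Applies [nb_exact_pvalue()] per gene after scaling counts to a common
#' effective library size via normalization factors and summing within
#' groups (sums are rounded to integers).
#'
#' @param counts gene x sample count matrix.
#' @param group_a,group_b disjoint sample index/name vectors.
#' @param phi common NB dispersion.
#' @param norm_factors per-sample normalization factors
#'   (default [normalize_library_sizes()] on the two groups' columns).
#' @return numeric vector of p-values, named by gene.
#' @export
nb_exact_test <- function(counts, group_a, group_b, phi,
                          norm_factors = NULL) {
  a_idx <- if (is.character(group_a)) match(group_a, colnames(counts)) else group_a
  b_idx <- if (is.character(group_b)) match(group_b, colnames(counts)) else group_b
  if (length(a_idx) == 0 || length(b_idx) == 0) stop("empty group")
  if (length(intersect(a_idx, b_idx)) > 0) stop("groups overlap")
  if (is.null(norm_factors)) {
    norm_factors <- rep(1, ncol(counts))
    nf <- normalize_library_sizes(counts[, c(a_idx, b_idx), drop = FALSE])
    norm_factors[c(a_idx, b_idx)] <- nf
  }
  y <- sweep(counts, 2, norm_factors, "/")
  ya <- round(rowSums(y[, a_idx, drop = FALSE]))
  yb <- round(rowSums(y[, b_idx, drop = FALSE]))
  n_a <- length(a_idx)
  n_b <- length(b_idx)
  p <- vapply(seq_along(ya), function(i) {
    nb_exact_pvalue(ya[i], yb[i], n_a, n_b, phi)
  }, numeric(1))
  stats::setNames(p, rownames(counts))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1, with the input order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return FDR (adjusted p) vector of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values")
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# normalized group means and log2 fold change with pseudo-count
.log2_fold_change <- function(counts, a_idx, b_idx, norm_factors,
                              pseudo = 0.5) {
  y <- sweep(counts, 2, norm_factors, "/")
  ma <- rowMeans(y[, a_idx, drop = FALSE])
  mb <- rowMeans(y[, b_idx, drop = FALSE])
  log2((mb + pseudo) / (ma + pseudo))
}

#' DEGs between the chilling treatment and each freezing treatment
#'
#' For one cultivar, compares the 4 degC (chilling) replicates to the
#' replicates of each freezing temperature with the NB exact test. A gene
#' is called differentially expressed when `p <= 0.05` and
#' `FDR <= 0.001` (both inclusive); FDR is Benjamini-Hochberg within each
#' comparison. The log2 fold change is freezing over chilling on normalized
#' group means with a pseudo-count of 0.5.
#'
#' @param counts gene x sample count matrix.
#' @param metadata data frame with columns `sample_id`, `cultivar`,
#'   `temperature` (a row per sample, ids matching `colnames(counts)`).
#' @param cultivar which cultivar to analyse.
#' @param dispersion optional common dispersion; estimated from this
#'   cultivar's temperature groups when NULL.
#' @param p_cut,fdr_cut significance thresholds (defaults 0.05 and 0.001).
#' @return data frame with columns `gene_id`, `temperature`, `log2_fc`,
#'   `p_value`, `fdr`, `direction`, `is_deg`.
#' @export
call_degs_chill_vs_freeze <- function(counts, metadata, cultivar,
                                      dispersion = NULL,
                                      p_cut = 0.05, fdr_cut = 0.001) {
  md <- metadata[metadata$cultivar == cultivar, , drop = FALSE]
  if (nrow(md) == 0) stop("no samples for cultivar ", cultivar)
  chill <- md$sample_id[md$temperature == 4]
  if (length(chill) == 0) stop("missing chilling (4 degC) group for ", cultivar)
  freeze_temps <- sort(unique(md$temperature[md$temperature < 0]),
                       decreasing = TRUE)
  cm <- counts[, md$sample_id, drop = FALSE]
  nf <- normalize_library_sizes(cm)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      cm, groups = md$temperature[match(colnames(cm), md$sample_id)],
      norm_factors = nf)$phi
  }
  out <- lapply(freeze_temps, function(temp) {
    grp <- md$sample_id[md$temperature == temp]
    if (length(grp) == 0) stop("missing freezing group at ", temp, " degC")
    p <- nb_exact_test(cm, chill, grp, phi = dispersion, norm_factors = nf)
    fdr <- bh_fdr(p)
    lfc <- .log2_fold_change(cm, match(chill, colnames(cm)),
                             match(grp, colnames(cm)), nf)
    data.frame(gene_id = rownames(cm), temperature = temp,
               log2_fc = lfc, p_value = p, fdr = fdr,
               direction = ifelse(lfc >= 0, "up", "down"),
               is_deg = p <= p_cut & fdr <= fdr_cut,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' DEGs of each colder freezing treatment against -4 degC
#'
#' Compares each freezing temperature below -4 degC to the -4 degC
#' reference within one cultivar. A gene is called when
#' `|log2 fold change| >= 1` (fold change >= 2, inclusive) and
#' `p <= 0.05`; no FDR threshold is applied in this comparison. The test is
#' restricted to expressed genes when an FPKM matrix and threshold are
#' given.
#'
#' @inheritParams call_degs_chill_vs_freeze
#' @param fpkm optional FPKM matrix used to restrict to expressed genes.
#' @param expressed_threshold FPKM cutoff for the expressed filter (0.01).
#' @param lfc_cut minimum absolute log2 fold change (default 1).
#' @return data frame as in [call_degs_chill_vs_freeze()].
#' @export
call_degs_vs_minus4 <- function(counts, metadata, cultivar,
                                dispersion = NULL, fpkm = NULL,
                                expressed_threshold = 0.01,
                                p_cut = 0.05, lfc_cut = 1) {
  md <- metadata[metadata$cultivar == cultivar, , drop = FALSE]
  ref <- md$sample_id[md$temperature == -4]
  if (length(ref) == 0) stop("missing -4 degC reference group for ", cultivar)
  temps <- sort(unique(md$temperature[md$temperature < -4]), decreasing = TRUE)
  cm <- counts[, md$sample_id, drop = FALSE]
  if (!is.null(fpkm)) {
    expressed <- rownames(filter_expressed(fpkm[, md$sample_id, drop = FALSE],
                                           threshold = expressed_threshold))
    cm <- cm[expressed, , drop = FALSE]
  }
  nf <- normalize_library_sizes(cm)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      cm, groups = md$temperature[match(colnames(cm), md$sample_id)],
      norm_factors = nf)$phi
  }
  out <- lapply(temps, function(temp) {
    grp <- md$sample_id[md$temperature == temp]
    if (length(grp) == 0) stop("missing group at ", temp, " degC")
    p <- nb_exact_test(cm, ref, grp, phi = dispersion, norm_factors = nf)
    lfc <- .log2_fold_change(cm, match(ref, colnames(cm)),
                             match(grp, colnames(cm)), nf)
    data.frame(gene_id = rownames(cm), temperature = temp,
               log2_fc = lfc, p_value = p, fdr = NA_real_,
               direction = ifelse(lfc >= 0, "up", "down"),
               is_deg = abs(lfc) >= lfc_cut & p <= p_cut,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Union of per-temperature DEG sets
#'
#' @param deg_table output of [call_degs_chill_vs_freeze()] (or a list of
#'   gene id vectors).
#' @return character vector of DEG ids (union over comparisons).
#' @export
union_deg_set <- function(deg_table) {
  if (is.data.frame(deg_table)) {
    unique(deg_table$gene_id[deg_table$is_deg])
  } else {
    unique(unlist(deg_table))
  }
}

#' Classify DEGs by freezing-stress phase pattern
#'
#' The six freezing temperatures split into the early phase (Phase I: -4,
#' -9, -14 degC) and the late phase (Phase II: -19, -24, -29 degC).
#' Per direction of change, a DEG is classified as:
#' \describe{
#'   \item{PhaseI_II}{differentially expressed at >= 1 Phase I temperature
#'     AND >= 1 Phase II temperature (`mode = "any"`, the default) or at all
#'     six temperatures (`mode = "all"`);}
#'   \item{PhaseII_only}{at >= 1 Phase II temperature and none in Phase I;}
#'   \item{PhaseI_only}{at >= 1 Phase I temperature and not PhaseI_II.}
#' }
#' Genes in no per-temperature set are class `none`.
#'
#' @param deg_table output of [call_degs_chill_vs_freeze()] for one cultivar.
#' @param phase1_temps,phase2_temps temperature groups (degC).
#' @param mode interpretation of PhaseI_II; see above.
#' @return data frame with columns `gene_id`, `direction`, `class`.
#' @export
classify_deg_phases <- function(deg_table,
                                phase1_temps = c(-4, -9, -14),
                                phase2_temps = c(-19, -24, -29),
                                mode = c("any", "all")) {
  mode <- match.arg(mode)
  hits <- deg_table[deg_table$is_deg, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(gene_id = character(), direction = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  key <- interaction(hits$gene_id, hits$direction, drop = TRUE)
  out <- lapply(split(hits, key), function(h) {
    n1 <- length(unique(h$temperature[h$temperature %in% phase1_temps]))
    n2 <- length(unique(h$temperature[h$temperature %in% phase2_temps]))
    both <- if (mode == "any") n1 >= 1 && n2 >= 1 else
      n1 == length(phase1_temps) && n2 == length(phase2_temps)
    cls <- if (both) "PhaseI_II" else if (n2 >= 1 && n1 == 0) "PhaseII_only"
      else if (n1 >= 1) "PhaseI_only" else "none"
    data.frame(gene_id = h$gene_id[1], direction = h$direction[1],
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$direction), , drop = FALSE]
}
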