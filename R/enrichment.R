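#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of over-representation
#' of annotation terms in a study set (e.g. the hub genes of a module)
#' relative to an explicit background universe, with Benjamini-Hochberg
#' correction across terms. The background universe must be supplied by the
#' caller; whether it is the whole genome or the expressed genes is an
#' analysis choice, not a default.
#'
#' @param study character vector of study gene ids (subset of background).
#' @param background character vector of background gene ids.
#' @param term_map data frame with columns `gene_id` and `term` mapping
#'   background genes to annotation terms (one row per gene-term pair).
#' @return data frame with one row per term: `term`, `k` (study hits),
#'   `K` (background hits), `n` (study size), `N` (background size),
#'   `p_value` (upper tail, P(X >= k)), `fdr`.
#' @export
hypergeometric_enrichment <- function(study, background, term_map) {
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0) stop("empty study set")
  missing <- setdiff(study, background)
  if (length(missing) > 0) {
    stop("study genes absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  stopifnot(all(c("gene_id", "term") %in% colnames(term_map)))
  term_map <- unique(term_map[term_map$gene_id %in% background,
                              c("gene_id", "term")])
  n <- length(study)
  N <- length(background)
  terms <- sort(unique(term_map$term))
  K <- as.integer(table(factor(term_map$term, levels = terms)))
  in_study <- term_map$gene_id %in% study
  k <- as.integer(table(factor(term_map$term[in_study], levels = terms)))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(term = terms, k = k, K = K, n = n, N = N,
             p_value = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
}

#' Percentage of the transcriptome covered by a gene set
#'
#' Share of the whole-genome transcript catalogue represented by a DEG (or
#' other) set, as a percentage rounded half-up to two decimals, the precision
#' used when reporting such fractions.
#'
#' @param count size of the gene set.
#' @param total total number of transcripts in the genome annotation.
#' @return percentage with two decimals.
#' @examples
#' deg_genome_fraction(4173, 63517)  # 6.57
#' @export
deg_genome_fraction <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  pct <- 100 * count / total
  trunc(pct * 100 + 0.5) / 100
}
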