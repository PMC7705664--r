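#' Run the full cold-stress coexpression pipeline
#'
#' Executes the analysis stages in order: FPKM quantification and
#' expressed-gene filtering; differential expression between chilling and
#' each freezing treatment per cultivar, with phase classification; the
#' coexpression network on the cross-cultivar DEG union (soft-threshold
#' selection, adjacency, TOM, average-linkage module detection, eigengene
#' merging); and module eigengene / kME / gene significance / module-trait
#' / hub-gene analysis. Writes stage TSVs, a JSON summary and a plain-text
#' run log when `out_dir` is given. Any stage error aborts with the stage
#' name; outputs written so far are retained next to a `FAILED` marker.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths transcript lengths (bp) named by gene id.
#' @param metadata sample metadata (`sample_id`, `cultivar`, `temperature`).
#' @param traits trait table (`sample_id`, `LT`, `Ac_LT`, `ELR`).
#' @param config list of stage parameters overriding the defaults:
#'   `expressed_threshold` (0.01), `powers` (1:20), `r2_cut` (0.8), `beta`
#'   (NULL = auto), `min_module_size` (30), `cut_height` (0.95),
#'   `merge_cut` (0.25), `reassign_threshold` (0.6), `network_type`
#'   ("unsigned"), `phase_mode` ("any").
#' @param out_dir optional output directory.
#' @return list with `fpkm`, `degs` (per cultivar), `phases` (per
#'   cultivar), `deg_union`, `soft_threshold`, `modules`, `eigengenes`,
#'   `scores`, `hubs`, `module_trait`, `summary`.
#' @export
run_pipeline <- function(counts, gene_lengths, metadata, traits,
                         config = list(), out_dir = NULL) {
  defaults <- list(expressed_threshold = 0.01, powers = 1:20, r2_cut = 0.8,
                   beta = NULL, min_module_size = 30, cut_height = 0.95,
                   merge_cut = 0.25, reassign_threshold = 0.6,
                   network_type = "unsigned", phase_mode = "any")
  config <- utils::modifyList(defaults, config)
  log_lines <- c(paste0("frostnet pipeline run ", format(Sys.time())),
                 paste0("parameters: ",
                        paste(names(config), vapply(config, function(x)
                          paste(format(x), collapse = ","), ""),
                          sep = "=", collapse = "; ")))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                       conditionMessage(e))),
                   file.path(out_dir, "FAILED"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stopifnot(all(metadata$sample_id %in% colnames(counts)),
            all(traits$sample_id == metadata$sample_id))
  counts <- counts[, metadata$sample_id, drop = FALSE]
  cultivars <- unique(metadata$cultivar)

  fpkm <- stage("expression", {
    compute_fpkm(counts, gene_lengths)
  })
  expressed <- stage("expression", {
    lapply(stats::setNames(cultivars, cultivars), function(cv) {
      rownames(filter_expressed(fpkm, config$expressed_threshold,
                                samples = metadata$sample_id[
                                  metadata$cultivar == cv]))
    })
  })

  degs <- stage("diffexpr", {
    lapply(stats::setNames(cultivars, cultivars), function(cv) {
      call_degs_chill_vs_freeze(counts[expressed[[cv]], , drop = FALSE],
                                metadata, cv)
    })
  })
  phases <- stage("diffexpr", {
    lapply(degs, classify_deg_phases, mode = config$phase_mode)
  })
  deg_union <- stage("diffexpr", {
    sort(unique(unlist(lapply(degs, union_deg_set))))
  })
  if (length(deg_union) < config$min_module_size) {
    stop("pipeline stage 'network' failed: DEG union smaller than one module")
  }

  log_fpkm <- log2(fpkm[deg_union, , drop = FALSE] + 1)
  st <- stage("network", {
    pick_soft_threshold(fpkm[deg_union, , drop = FALSE],
                        powers = config$powers, r2_cut = config$r2_cut,
                        type = config$network_type)
  })
  beta <- if (!is.null(config$beta)) config$beta else st$chosen_beta
  if (is.na(beta)) beta <- st$fallback_beta
  modules <- stage("network", {
    cm <- correlation_matrix(fpkm[deg_union, , drop = FALSE])
    adj <- adjacency_matrix(cm, beta, type = config$network_type)
    diss <- 1 - tom_similarity(adj)
    diag(diss) <- 0
    dend <- cluster_dendrogram(diss)
    pre <- cut_modules(dend, diss, min_module_size = config$min_module_size,
                       cut_height = config$cut_height,
                       reassign_threshold = config$reassign_threshold)
    merge_close_modules(log_fpkm, pre, cut_height = config$merge_cut)
  })

  traits_m <- traits[match(colnames(counts), traits$sample_id),
                     c("LT", "Ac_LT", "ELR")]
  me <- stage("module_traits", module_eigengenes(log_fpkm, modules))
  scores <- stage("module_traits", {
    gene_score_table(log_fpkm, me, modules, traits_m)
  })
  hubs <- stage("module_traits", screen_hub_genes(scores))
  mt <- stage("module_traits", module_trait_correlation(me, traits_m))

  mod_sizes <- table(factor(modules$module))
  summary <- list(
    n_genes = nrow(counts), n_samples = ncol(counts),
    n_expressed = vapply(expressed, length, 0L),
    n_deg = vapply(degs, function(d) length(union_deg_set(d)), 0L),
    n_deg_union = length(deg_union),
    phase_class_counts = lapply(phases, function(ph)
      as.list(table(paste(ph$class, ph$direction, sep = "_")))),
    beta = beta,
    module_sizes = as.list(mod_sizes),
    n_hubs = as.list(table(factor(hubs$module))),
    module_trait_r = mt$r, module_trait_p = mt$p)

  if (!is.null(out_dir)) {
    for (cv in cultivars) {
      write_tsv(degs[[cv]], file.path(out_dir, paste0("deg_", cv, ".tsv")))
      write_tsv(phases[[cv]], file.path(out_dir, paste0("phases_", cv, ".tsv")))
    }
    write_tsv(st$scan, file.path(out_dir, "soft_threshold_scan.tsv"))
    write_tsv(modules, file.path(out_dir, "modules.tsv"))
    write_tsv_matrix(me$eigengenes, file.path(out_dir, "eigengenes.tsv"),
                     id_col = "module")
    write_tsv(scores, file.path(out_dir, "gene_scores.tsv"))
    write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
    mt_df <- data.frame(module = rep(rownames(mt$r), ncol(mt$r)),
                        trait = rep(colnames(mt$r), each = nrow(mt$r)),
                        r = as.vector(mt$r), p = as.vector(mt$p))
    write_tsv(mt_df, file.path(out_dir, "module_trait.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(log_lines, paste0("completed: beta=", beta,
                                   ", modules=", length(mod_sizes) -
                                     as.integer("0" %in% names(mod_sizes)))),
               file.path(out_dir, "run_log.txt"))
  }
  list(fpkm = fpkm, expressed = expressed, degs = degs, phases = phases,
       deg_union = deg_union, soft_threshold = st, beta = beta,
       modules = modules, eigengenes = me, scores = scores, hubs = hubs,
       module_trait = mt, summary = summary)
}
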