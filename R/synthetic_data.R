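#' Simulation configuration for the two-cultivar cold-stress design
#'
#' Defines the synthetic study: two cultivars ("G", cold-sensitive, and
#' "H", cold-hardy) x seven temperature treatments (4, -4, -9, -14, -19,
#' -24, -29 degC, applied as successive 24 h stages) x two transcriptome
#' replicates = 28 samples. Planted structure: coexpression modules whose
#' latent profiles are constructed to correlate with a chosen trait (LT,
#' Ac_LT or ELR) at an exact target r, and phase-patterned differentially
#' expressed genes shifted in one cultivar at early (-4/-9/-14 degC), late
#' (-19/-24/-29 degC) or both phases.
#'
#' Default conditions: 1000 genes of which 5 modules x 100 genes; trait
#' couplings +0.9 (LT), -0.9 (ELR), +0.6 (LT), -0.6 (Ac_LT), +0.45 (ELR)
#' (no two modules are coupled near +/-0.9 to the same trait, which an
#' unsigned network could not separate); gene-level biological noise 0.3
#' log2 units; NB dispersion 0.05; 10 planted DEGs per phase class per
#' direction per cultivar, shifted by 2 log2 units; library sizes 15-25
#' million mapped reads (the simulated genes are a 1000-gene subset of a
#' larger transcriptome, so column sums are smaller); gene lengths 0.5-3
#' kb; baseline log2 FPKM uniform on \[2, 8\].
#'
#' @param n_genes total genes.
#' @param module_sizes planted module sizes (sum + planted DEGs <= n_genes).
#' @param trait_coupling target correlation of each module's latent profile
#'   with its coupled trait, in \[-1, 1\].
#' @param coupled_trait one of "LT", "Ac_LT", "ELR" per module.
#' @param noise_sd per-gene, per-sample log2 noise sd (>= 0).
#' @param loading_range range of per-gene loadings on the module latent.
#' @param n_phase1_degs,n_phase2_degs,n_phase12_degs planted DEGs per
#'   direction per cultivar for the three phase classes.
#' @param deg_shift additive log2 shift for planted DEGs (>= 0).
#' @param baseline_log_mean_range range of baseline log2 FPKM.
#' @param dispersion NB dispersion phi (variance mu + phi mu^2; 0 = Poisson).
#' @param library_size_range range of per-sample total mapped reads.
#' @param gene_length_range range of transcript lengths (bp).
#' @param elr_profile 7 x 2 matrix of mean ELR (%) per temperature (rows,
#'   4 to -29 degC) and cultivar (columns G, H); the default is flat near
#'   24% with G rising below -19 degC and H rising only at -29 degC.
#' @param elr_rep_sd sd of ELR assay replicates (%, 3 replicates averaged
#'   per treatment; the papered design measures ELR on separate assay
#'   material, so the treatment-level mean is assigned to both
#'   transcriptome replicates).
#' @param seed integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       module_sizes = rep(100L, 5),
                       trait_coupling = c(0.9, -0.9, 0.6, -0.6, 0.45),
                       coupled_trait = c("LT", "ELR", "LT", "Ac_LT", "ELR"),
                       noise_sd = 0.3,
                       loading_range = c(0.8, 1.2),
                       n_phase1_degs = 10L,
                       n_phase2_degs = 10L,
                       n_phase12_degs = 10L,
                       deg_shift = 2,
                       baseline_log_mean_range = c(2, 8),
                       dispersion = 0.05,
                       library_size_range = c(1.5e7, 2.5e7),
                       gene_length_range = c(500L, 3000L),
                       elr_profile = NULL,
                       elr_rep_sd = 1.5,
                       seed = 20160201L) {
  if (is.null(elr_profile)) {
    elr_profile <- cbind(G = c(24, 24, 24, 24, 27, 46, 62),
                         H = c(23, 23, 23, 23, 23, 24, 31))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              trait_coupling = trait_coupling,
              coupled_trait = coupled_trait,
              noise_sd = noise_sd, loading_range = loading_range,
              n_phase1_degs = as.integer(n_phase1_degs),
              n_phase2_degs = as.integer(n_phase2_degs),
              n_phase12_degs = as.integer(n_phase12_degs),
              deg_shift = deg_shift,
              baseline_log_mean_range = baseline_log_mean_range,
              dispersion = dispersion,
              library_size_range = library_size_range,
              gene_length_range = gene_length_range,
              elr_profile = elr_profile, elr_rep_sd = elr_rep_sd,
              seed = as.integer(seed))
  n_deg <- 2 * 2 * (cfg$n_phase1_degs + cfg$n_phase2_degs + cfg$n_phase12_degs)
  if (sum(cfg$module_sizes) + n_deg > cfg$n_genes) {
    stop("module sizes plus planted DEGs exceed n_genes")
  }
  if (length(cfg$trait_coupling) != length(cfg$module_sizes) ||
      length(cfg$coupled_trait) != length(cfg$module_sizes)) {
    stop("trait_coupling and coupled_trait must match module_sizes in length")
  }
  if (any(abs(cfg$trait_coupling) > 1)) stop("|trait coupling| must be <= 1")
  if (cfg$noise_sd < 0 || cfg$dispersion < 0 || cfg$deg_shift < 0) {
    stop("noise_sd, dispersion and deg_shift must be >= 0")
  }
  if (any(c(cfg$n_phase1_degs, cfg$n_phase2_degs, cfg$n_phase12_degs) < 0)) {
    stop("planted DEG counts must be >= 0")
  }
  stopifnot(all(cfg$coupled_trait %in% c("LT", "Ac_LT", "ELR")))
  class(cfg) <- "sim_config"
  cfg
}

# treatment temperatures in application order
.treatment_temps <- c(4, -4, -9, -14, -19, -24, -29)

#' Sample metadata and trait table for the cold-stress design
#'
#' Builds the 28-sample design: cultivars G and H, the seven-stage
#' temperature schedule, two replicates. Traits per sample: LT is the
#' treatment temperature (degC); Ac_LT accumulates temperature x 24 h over
#' the stages the sample passed through (degC h); ELR is the mean of three
#' simulated assay replicates drawn around the configured per-cultivar
#' profile, assigned to both transcriptome replicates of a treatment.
#' Uses the current RNG state (seeded by [generate_dataset()]).
#'
#' @param cfg a [sim_config()].
#' @return list with `metadata` (sample_id, cultivar, temperature,
#'   stress_class, phase, replicate) and `traits` (sample_id, LT, Ac_LT,
#'   ELR).
#' @export
build_design <- function(cfg = sim_config()) {
  temps <- .treatment_temps
  grid <- expand.grid(replicate = 1:2, temperature = temps,
                      cultivar = c("G", "H"), stringsAsFactors = FALSE)
  stage <- match(grid$temperature, temps)
  code <- ifelse(grid$temperature == 4, "C.1", paste0("F.", stage - 1))
  metadata <- data.frame(
    sample_id = paste0(grid$cultivar, code, "_r", grid$replicate),
    cultivar = grid$cultivar,
    temperature = grid$temperature,
    stress_class = ifelse(grid$temperature < 0, "freezing", "chilling"),
    phase = ifelse(grid$temperature == 4, "none",
                   ifelse(grid$temperature >= -14, "I", "II")),
    replicate = grid$replicate, stringsAsFactors = FALSE)

  ac_lt <- vapply(stage, function(s) compute_ac_lt(temps[1:s], 24), numeric(1))
  elr_mean <- matrix(NA_real_, nrow = length(temps), ncol = 2,
                     dimnames = list(NULL, c("G", "H")))
  for (cv in c("G", "H")) {
    for (s in seq_along(temps)) {
      reps <- stats::rnorm(3, cfg$elr_profile[s, cv], cfg$elr_rep_sd)
      elr_mean[s, cv] <- mean(pmin(pmax(reps, 0), 100))
    }
  }
  traits <- data.frame(
    sample_id = metadata$sample_id,
    LT = metadata$temperature,
    Ac_LT = ac_lt,
    ELR = elr_mean[cbind(stage, match(grid$cultivar, c("G", "H")))],
    stringsAsFactors = FALSE)
  list(metadata = metadata, traits = traits)
}

# standardize a vector to mean 0, sd 1 (sample sd)
.std <- function(x) as.numeric(scale(x))

#' Plant trait-coupled module latent profiles
#'
#' Each module's latent sample profile is built as
#' `r * t + sqrt(1 - r^2) * o`, where `t` is the standardized coupled trait
#' and `o` a standardized random vector orthogonalized (Gram-Schmidt)
#' against all three traits and against the other modules' random
#' components, so that the latent has zero mean, unit variance,
#' correlation with the coupled trait exactly equal to the target, and
#' cross-module latent correlation exactly `r_i * r_j * cor(t_i, t_j)` --
#' distinct modules share structure only through the traits. The latent is
#' a treatment-level response: the random component is drawn per
#' cultivar-temperature cell and shared by the replicates (replicate
#' scatter belongs to the per-gene noise term), which keeps the
#' within-group variance of module genes comparable to that of other
#' genes. Per-gene loadings are drawn uniformly from the configured range.
#'
#' @param cfg a [sim_config()].
#' @param design output of [build_design()].
#' @return list with `latents` (module x sample matrix) and `loadings`
#'   (list of per-gene loading vectors per module).
#' @export
plant_modules <- function(cfg, design) {
  if (any(abs(cfg$trait_coupling) > 1)) stop("impossible coupling |r| > 1")
  n <- nrow(design$metadata)
  n_mod <- length(cfg$module_sizes)
  latents <- matrix(NA_real_, n_mod, n,
                    dimnames = list(paste0("module", seq_len(n_mod)),
                                    design$metadata$sample_id))
  cell <- interaction(design$metadata$cultivar, design$metadata$temperature)
  # basis the random components must be orthogonal to: intercept, all
  # traits, and the previous modules' components
  basis <- cbind(1, .std(design$traits$LT), .std(design$traits$Ac_LT),
                 .std(design$traits$ELR))
  for (m in seq_len(n_mod)) {
    t_std <- .std(design$traits[[cfg$coupled_trait[m]]])
    o <- stats::rnorm(nlevels(cell))[as.integer(cell)]  # shared by replicates
    o <- stats::lm.fit(basis, o)$residuals
    if (sum(o^2) < 1e-10) stop("degenerate random component; too many modules")
    o <- .std(o)
    basis <- cbind(basis, o)
    r <- cfg$trait_coupling[m]
    latents[m, ] <- r * t_std + sqrt(1 - r^2) * o
  }
  loadings <- lapply(cfg$module_sizes, function(sz) {
    stats::runif(sz, cfg$loading_range[1], cfg$loading_range[2])
  })
  list(latents = latents, loadings = loadings)
}

#' Plant phase-patterned differential expression
#'
#' Adds an additive log2 shift to selected candidate genes in one
#' cultivar's samples at the temperatures defining each phase class:
#' PhaseI_II at all six freezing temperatures, PhaseII_only at -19/-24/-29
#' degC, PhaseI_only at a random non-empty subset of -4/-9/-14 degC.
#' Directions up (positive shift) and down are planted in equal numbers.
#' A zero shift is recorded as class `none` (no gene consumed).
#'
#' @param cfg a [sim_config()].
#' @param design output of [build_design()].
#' @param log_expr log2 expression matrix (genes x samples) to modify.
#' @param candidate_genes gene ids eligible for planting (no planted module
#'   members); must be at least the total requested DEG count.
#' @return list with `log_expr` (modified) and `truth` (data frame:
#'   gene_id, cultivar, class, direction, shift, temperatures).
#' @export
plant_phase_degs <- function(cfg, design, log_expr, candidate_genes) {
  classes <- c(PhaseI_II = cfg$n_phase12_degs,
               PhaseII_only = cfg$n_phase2_degs,
               PhaseI_only = cfg$n_phase1_degs)
  n_needed <- 2 * 2 * sum(classes)
  if (cfg$deg_shift == 0) n_needed <- 0
  if (n_needed > length(candidate_genes)) {
    stop("requested DEG counts exceed available genes")
  }
  truth <- data.frame(gene_id = character(), cultivar = character(),
                      class = character(), direction = character(),
                      shift = numeric(), temperatures = character(),
                      stringsAsFactors = FALSE)
  if (n_needed == 0) return(list(log_expr = log_expr, truth = truth))

  pool <- sample(candidate_genes, n_needed)
  i <- 0
  early <- c(-4, -9, -14)
  late <- c(-19, -24, -29)
  md <- design$metadata
  rows <- list()
  for (cv in c("G", "H")) {
    for (cls in names(classes)) {
      for (dir in c("up", "down")) {
        n_cls <- classes[[cls]]
        if (n_cls == 0) next
        for (g in seq_len(n_cls)) {
          gene <- pool[i <- i + 1]
          temps <- switch(cls,
            PhaseI_II = c(early, late),
            PhaseII_only = late,
            PhaseI_only = sort(sample(early, sample(1:3, 1)), decreasing = TRUE))
          cols <- md$sample_id[md$cultivar == cv & md$temperature %in% temps]
          shift <- if (dir == "up") cfg$deg_shift else -cfg$deg_shift
          log_expr[gene, cols] <- log_expr[gene, cols] + shift
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = gene, cultivar = cv, class = cls, direction = dir,
            shift = shift, temperatures = paste(temps, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  list(log_expr = log_expr, truth = truth)
}

#' Draw NB counts from a log2 expression matrix
#'
#' Inverts the FPKM formula to get expected counts
#' `mu = 2^log_expr * length_bp * library_size / 1e9` and draws
#' `NB(mean mu, variance mu + phi mu^2)`; `phi = 0` gives Poisson draws.
#'
#' @param log_expr log2 FPKM matrix, genes x samples.
#' @param gene_lengths transcript lengths (bp), one per gene.
#' @param library_sizes total mapped reads, one per sample.
#' @param dispersion NB dispersion phi (>= 0).
#' @param seed optional seed for reproducible draws.
#' @return integer count matrix of the same shape.
#' @export
expression_to_counts <- function(log_expr, gene_lengths, library_sizes,
                                 dispersion, seed = NULL) {
  if (!all(is.finite(log_expr))) stop("non-finite log expression")
  stopifnot(all(gene_lengths > 0), all(library_sizes > 0), dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- 2^log_expr * outer(gene_lengths, library_sizes) / 1e9
  n <- length(mu)
  draws <- if (dispersion == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
  }
  matrix(draws, nrow = nrow(log_expr), dimnames = dimnames(log_expr))
}

#' Generate a complete synthetic cold-stress dataset
#'
#' Composes [build_design()], [plant_modules()], [plant_phase_degs()] and
#' [expression_to_counts()] under the configured seed. Gene order:
#' module members first (module 1, 2, ...), then planted DEGs, then pure
#' noise genes. Optionally writes the fixture tables (counts.tsv,
#' lengths.tsv, metadata.tsv, traits.tsv, truth_modules.tsv,
#' truth_phases.tsv) to a directory.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory for the fixture files.
#' @return list with `counts`, `gene_lengths`, `metadata`, `traits`, and
#'   `truth` (list: `modules` data frame gene_id/module, `phases` data
#'   frame from [plant_phase_degs()], `latents` matrix, `log_expr`).
#' @export
generate_dataset <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  design <- build_design(cfg)
  planted <- plant_modules(cfg, design)

  n <- cfg$n_genes
  n_samples <- nrow(design$metadata)
  gene_ids <- sprintf("gene_%04d", seq_len(n))
  baseline <- stats::runif(n, cfg$baseline_log_mean_range[1],
                           cfg$baseline_log_mean_range[2])
  gene_lengths <- stats::setNames(
    round(stats::runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2])),
    gene_ids)
  library_sizes <- stats::setNames(
    round(stats::runif(n_samples, cfg$library_size_range[1],
                       cfg$library_size_range[2])),
    design$metadata$sample_id)

  log_expr <- baseline +
    matrix(stats::rnorm(n * n_samples, 0, cfg$noise_sd), n, n_samples)
  dimnames(log_expr) <- list(gene_ids, design$metadata$sample_id)

  module_label <- rep("noise", n)
  offset <- 0
  for (m in seq_along(cfg$module_sizes)) {
    idx <- offset + seq_len(cfg$module_sizes[m])
    log_expr[idx, ] <- log_expr[idx, ] +
      planted$loadings[[m]] %o% planted$latents[m, ]
    module_label[idx] <- paste0("module", m)
    offset <- offset + cfg$module_sizes[m]
  }

  candidates <- gene_ids[(offset + 1):n]
  degs <- plant_phase_degs(cfg, design, log_expr, candidates)

  counts <- expression_to_counts(degs$log_expr, gene_lengths, library_sizes,
                                 cfg$dispersion)
  truth_modules <- data.frame(gene_id = gene_ids, module = module_label,
                              stringsAsFactors = FALSE)
  out <- list(counts = counts, gene_lengths = gene_lengths,
              metadata = design$metadata, traits = design$traits,
              truth = list(modules = truth_modules, phases = degs$truth,
                           latents = planted$latents,
                           log_expr = degs$log_expr))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_matrix(counts, file.path(dir, "counts.tsv"))
    write_tsv(data.frame(gene_id = gene_ids, length = unname(gene_lengths)),
              file.path(dir, "lengths.tsv"))
    write_tsv(design$metadata, file.path(dir, "metadata.tsv"))
    write_tsv(design$traits, file.path(dir, "traits.tsv"))
    write_tsv(truth_modules, file.path(dir, "truth_modules.tsv"))
    write_tsv(degs$truth, file.path(dir, "truth_phases.tsv"))
  }
  out
}
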