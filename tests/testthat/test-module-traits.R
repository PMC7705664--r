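make_module_expr <- function(n_genes = 10, n_samples = 28, seed = 41) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  x
}

test_that("eigengenes match an eigendecomposition oracle", {
  x <- make_module_expr()
  assignment <- data.frame(gene_id = rownames(x), module = 1,
                           stringsAsFactors = FALSE)
  me <- module_eigengenes(x, assignment)
  # oracle: first eigenvector of the gene-gene correlation matrix defines
  # the component; sample scores from projecting standardized profiles
  xs <- scale(t(x))
  ev <- eigen(cor(t(x)), symmetric = TRUE)
  oracle <- as.numeric(xs %*% ev$vectors[, 1])
  oracle <- oracle / sd(oracle)
  expect_equal(abs(as.numeric(me$eigengenes["ME1", ])), abs(oracle),
               tolerance = 1e-8)
  expect_equal(unname(me$variance_explained["ME1"]),
               ev$values[1] / sum(ev$values), tolerance = 1e-8)
  expect_equal(sd(me$eigengenes["ME1", ]), 1)
  # sign alignment: correlation with the mean standardized profile >= 0
  expect_gte(cor(me$eigengenes["ME1", ], rowMeans(xs)), 0)
})

test_that("rank-1 modules and sign conventions behave", {
  prof <- rnorm(12)
  x <- outer(c(2, 3, 5), prof)
  dimnames(x) <- list(c("a", "b", "c"), paste0("s", 1:12))
  a1 <- data.frame(gene_id = rownames(x), module = 1)
  me <- module_eigengenes(x, a1)
  expect_equal(unname(me$variance_explained["ME1"]), 1)
  expect_equal(as.numeric(me$eigengenes["ME1", ]),
               as.numeric(scale(prof)), tolerance = 1e-10)
  # flipping every gene's sign flips nothing after sign alignment
  me_flip <- module_eigengenes(-x, a1)
  expect_equal(me_flip$eigengenes["ME1", ], -me$eigengenes["ME1", ],
               tolerance = 1e-10)
  expect_gte(cor(me_flip$eigengenes["ME1", ], rowMeans(scale(t(-x)))), 0)
  # single-gene module warns and returns the standardized profile
  a2 <- data.frame(gene_id = "a", module = 1)
  expect_warning(me1 <- module_eigengenes(x["a", , drop = FALSE], a2),
                 "single gene")
  expect_equal(as.numeric(me1$eigengenes["ME1", ]),
               as.numeric(scale(x["a", ])))
})

test_that("kME equals the gene-eigengene correlation", {
  x <- make_module_expr(n_genes = 8)
  assignment <- data.frame(gene_id = rownames(x), module = 1)
  me <- module_eigengenes(x, assignment)
  eg <- me$eigengenes["ME1", ]
  # gene proportional to ME, orthogonal residual, and negated ME
  y <- rbind(x, aligned = 3 * eg + 5, anti = -eg)
  a2 <- data.frame(gene_id = rownames(y), module = 1)
  kme <- intramodular_connectivity(y, me, a2)
  expect_equal(kme$k_me[kme$gene_id == "aligned"], 1)
  expect_equal(kme$k_me[kme$gene_id == "anti"], -1)
  expect_equal(kme$k_me, as.numeric(cor(t(y), eg)))
  # kME invariant under per-gene affine transforms
  kme2 <- intramodular_connectivity(y * 7 - 2, me, a2)
  expect_equal(kme2$k_me, kme$k_me)
  # full kME table contains the own-module column
  kme_all <- intramodular_connectivity(y, me, a2, all_modules = TRUE)
  expect_equal(kme_all$kME_ME1, kme_all$k_me)
  # zero-variance gene gets NA with a warning
  z <- rbind(y, flat = rep(1, ncol(y)))
  a3 <- data.frame(gene_id = rownames(z), module = 1)
  expect_warning(kme3 <- intramodular_connectivity(z, me, a3), "zero-variance")
  expect_true(is.na(kme3$k_me[kme3$gene_id == "flat"]))
})

test_that("gene significance is a trait correlation with its symmetries", {
  x <- make_module_expr(n_genes = 6, n_samples = 28)
  trait <- rnorm(28)
  gs <- gene_significance(rbind(x, tr = trait), trait)
  expect_equal(unname(gs["tr"]), 1)
  expect_equal(gene_significance(x, -trait), -gs[1:6])
  expect_error(gene_significance(x, rep(2, 28)), "constant")
  # null check: independent gene and trait at n = 28 rarely exceed |0.6|
  set.seed(53)
  null_gs <- replicate(500, cor(rnorm(28), rnorm(28)))
  expect_true(all(abs(null_gs) < 0.8))
  expect_lt(mean(abs(null_gs) > 0.6), 0.01)
})

test_that("module-trait correlation p-values match the t-distribution", {
  # r = 0.65, n = 28 -> t = 4.36..., p ~ 1.8e-4 (cor.test as oracle)
  set.seed(61)
  n <- 28
  x <- rnorm(n)
  # build y with sample correlation exactly 0.65
  e <- resid(lm(rnorm(n) ~ x))
  y <- 0.65 * scale(x)[, 1] + sqrt(1 - 0.65^2) * scale(e)[, 1]
  me <- matrix(y, 1, n, dimnames = list("ME1", paste0("s", 1:n)))
  res <- module_trait_correlation(me, data.frame(tr = x))
  expect_equal(res$r["ME1", "tr"], 0.65, tolerance = 1e-12)
  expect_equal(res$p["ME1", "tr"], cor.test(as.numeric(y), x)$p.value,
               tolerance = 1e-10)
  expect_equal(res$p["ME1", "tr"], 1.8e-4, tolerance = 0.05)
  # sign flip of the trait flips r, keeps p
  res2 <- module_trait_correlation(me, data.frame(tr = -x))
  expect_equal(res2$r["ME1", "tr"], -res$r["ME1", "tr"])
  expect_equal(res2$p["ME1", "tr"], res$p["ME1", "tr"])
  # |r| = 1 gives p = 0; r = 0 gives p = 1
  res3 <- module_trait_correlation(me, data.frame(tr = as.numeric(y)))
  expect_equal(res3$p["ME1", "tr"], 0)
  ortho <- scale(resid(lm(rnorm(n) ~ as.numeric(y))))[, 1]
  res4 <- module_trait_correlation(me, data.frame(tr = ortho))
  expect_equal(res4$p["ME1", "tr"], 1, tolerance = 1e-10)
})

test_that("hub screen equals an exhaustive enumeration oracle", {
  hub_oracle <- function(s, frac = 0.2) {
    top <- function(v) {
      n_top <- ceiling(frac * length(v))
      cut <- sort(abs(v), decreasing = TRUE)[n_top]
      s$gene_id[abs(v) >= cut]
    }
    t1 <- top(s$k_me); t2 <- top(s$gs_lt); t3 <- top(s$gs_elr)
    sort(unique(c(intersect(t1, t2), intersect(t1, t3), intersect(t2, t3))))
  }
  set.seed(71)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    s <- data.frame(gene_id = sprintf("g%02d", 1:n), module = 1,
                    k_me = runif(n, -1, 1), gs_lt = runif(n, -1, 1),
                    gs_elr = runif(n, -1, 1), stringsAsFactors = FALSE)
    hubs <- screen_hub_genes(s)
    expect_equal(hubs$gene_id, hub_oracle(s))
    # every hub satisfies at least one qualifier; bound on the set size
    if (nrow(hubs) > 0) {
      expect_true(all(hubs$kme_gslt | hubs$kme_gselr | hubs$gslt_gselr))
      expect_lte(nrow(hubs), 3 * ceiling(0.2 * n))
    }
  }
})

test_that("hub screen corner cases: dominant gene, disjoint sets, ties", {
  # one gene top on all three scores
  s <- data.frame(gene_id = c("top", paste0("g", 1:9)), module = 2,
                  k_me = c(0.99, runif(9, 0, 0.5)),
                  gs_lt = c(-0.98, runif(9, 0, 0.5)),
                  gs_elr = c(0.97, runif(9, 0, 0.5)))
  hubs <- screen_hub_genes(s)
  expect_equal(hubs$gene_id, "top")
  expect_true(all(unlist(hubs[, c("kme_gslt", "kme_gselr", "gslt_gselr")])))
  # three pairwise-disjoint top sets -> no hubs (5 genes: top set size 1,
  # distinct values so no boundary ties)
  s2 <- data.frame(gene_id = paste0("g", 1:5), module = 1,
                   k_me = c(0.9, 0.1, 0.2, 0.3, 0.4),
                   gs_lt = c(0.1, 0.9, 0.2, 0.3, 0.4),
                   gs_elr = c(0.1, 0.2, 0.9, 0.3, 0.4))
  expect_equal(nrow(screen_hub_genes(s2)), 0)
  # boundary ties are all included
  s3 <- data.frame(gene_id = paste0("g", 1:10), module = 1,
                   k_me = c(0.9, rep(0.8, 4), rep(0.1, 5)),
                   gs_lt = c(0.9, rep(0.8, 4), rep(0.1, 5)),
                   gs_elr = rep(0.1, 10))
  hubs3 <- screen_hub_genes(s3)
  # top-20% of 10 = 2 genes, but four tie at the boundary value 0.8
  expect_setequal(hubs3$gene_id, paste0("g", 1:5))
  # tiny module warns
  s4 <- data.frame(gene_id = paste0("g", 1:3), module = 1,
                   k_me = c(0.9, 0.5, 0.1), gs_lt = c(0.8, 0.5, 0.1),
                   gs_elr = c(0.7, 0.5, 0.1))
  expect_warning(h4 <- screen_hub_genes(s4), "fewer than 5")
  expect_equal(h4$gene_id, "g1")
})

test_that("planted trait couplings are recovered by the module-trait stage", {
  ds <- default_dataset()
  net <- default_network()
  cfg <- sim_config()
  me <- module_eigengenes(net$log_fpkm, net$modules)
  traits <- ds$traits[, c("LT", "Ac_LT", "ELR")]
  mt <- module_trait_correlation(me, traits)
  truth <- setNames(ds$truth$modules$module, ds$truth$modules$gene_id)
  # map each recovered module to the planted module it mostly contains
  for (m in seq_along(cfg$module_sizes)) {
    planted <- paste0("module", m)
    genes <- names(truth)[truth == planted]
    overlap <- table(net$modules$module[net$modules$gene_id %in% genes])
    overlap <- overlap[names(overlap) != "0"]
    rec <- as.integer(names(which.max(overlap)))
    r_rec <- mt$r[paste0("ME", rec), cfg$coupled_trait[m]]
    expect_lt(abs(unname(r_rec) - cfg$trait_coupling[m]), 0.15)
  }
  # kME of module members is high; the best-aligned gene beats the median
  scores <- gene_score_table(net$log_fpkm, me, net$modules, traits)
  for (mod in 1:2) {
    k <- scores$k_me[scores$module == mod]
    expect_gt(max(abs(k)), median(abs(k)))
    expect_gt(median(abs(k)), 0.7)
  }
})
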