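test_that("correlation matrix handles duplicates, negation and a toy pair", {
  set.seed(2)
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  x <- rbind(x, g6 = x["g1", ], g7 = -x["g1", ])
  cc <- correlation_matrix(2^x - 1)  # log2(x+1) inside recovers x
  expect_equal(cc["g1", "g6"], 1)
  expect_equal(cc["g1", "g7"], -1)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 7))
  # textbook two-vector formula on a printed 4-sample pair
  a <- c(1, 2, 4, 3); b <- c(2, 1, 5, 4)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cc2 <- correlation_matrix(rbind(p = a, q = b), log_transform = FALSE)
  expect_equal(cc2["p", "q"], hand)
  expect_warning(
    correlation_matrix(rbind(p = a, flat = c(2, 2, 2, 2)),
                       log_transform = FALSE), "zero-variance")
  expect_error(correlation_matrix(rbind(p = a[1:2], q = b[1:2]),
                                  log_transform = FALSE), "3 samples")
})

test_that("soft-threshold adjacency follows |cor|^beta", {
  cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.25, -0.5, 0.25, 1), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacency_matrix(cc, beta = 8)
  expect_equal(a["a", "b"], 0.5^8)      # 0.00390625
  expect_equal(a["a", "c"], 0.5^8)      # unsigned: sign dropped
  expect_equal(unname(diag(a)), rep(0, 3))
  expect_equal(adjacency_matrix(cc, 1)["b", "c"], 0.25)
  # raising beta weakly decreases every off-diagonal entry for |cor| < 1
  a2 <- adjacency_matrix(cc, 9)
  off <- upper.tri(a)
  expect_true(all(a2[off] <= a[off]))
  # signed variant
  s <- adjacency_matrix(cc, 2, type = "signed")
  expect_equal(s["a", "c"], ((1 - 0.5) / 2)^2)
})

test_that("scale-free fit index is exact on a constructed power law", {
  # adjacency of disjoint gene pairs: each pair's single edge weight is
  # that pair's connectivity, so the k multiset is fully controlled
  pair_adjacency <- function(k_values, counts) {
    k <- rep(k_values, counts)
    n <- 2 * length(k)
    a <- matrix(0, n, n)
    for (i in seq_along(k)) {
      a[2 * i - 1, 2 * i] <- a[2 * i, 2 * i - 1] <- k[i]
    }
    a
  }
  # p(k) ~ k^-2 exactly: doubling k quarters the frequency -> R^2 = 1
  a <- pair_adjacency(c(0.1, 0.2, 0.4), c(32, 8, 2))
  expect_equal(scale_free_fit_index(a), 1)
  # frequency rising with k -> positive slope -> sign-flipped negative
  a2 <- pair_adjacency(c(0.1, 0.4), c(2, 32))
  expect_lt(scale_free_fit_index(a2), 0)
  # all genes at one connectivity: single occupied bin -> NA with warning
  a3 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_warning(r <- scale_free_fit_index(a3), "undefined")
  expect_true(is.na(r))
})

test_that("the lowest qualifying power is chosen", {
  ds <- default_dataset()
  fpkm <- compute_fpkm(ds$counts, ds$gene_lengths)
  net <- default_network()
  st <- net$soft
  expect_equal(st$scan$power, 1:20)
  expect_true(all(st$scan$signed_r2 >= -1 & st$scan$signed_r2 <= 1,
                  na.rm = TRUE))
  # rule application on a synthetic scan: lowest power above the cut
  qualifying <- st$scan$power[!is.na(st$scan$signed_r2) &
                                st$scan$signed_r2 >= 0.8]
  if (length(qualifying) > 0) {
    expect_equal(st$chosen_beta, min(qualifying))
  } else {
    expect_true(is.na(st$chosen_beta))
    expect_equal(st$fallback_beta, 8L)  # 28 samples, unsigned
  }
  # a cut below every attainable index selects the lowest candidate power
  set.seed(47)
  sub <- matrix(2^rnorm(50 * 20), 50, 20,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  st0 <- suppressWarnings(pick_soft_threshold(sub, powers = c(2, 4),
                                              r2_cut = -1))
  expect_equal(st0$chosen_beta, 2)
})

test_that("TOM matches the hand value and the triple-loop oracle", {
  # 3 genes, all adjacencies 0.5: TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5)
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(unname(diag(tom)), rep(1, 3))
  # isolated gene has TOM 0 with everyone
  a2 <- rbind(cbind(a, 0), 0)
  diag(a2) <- 0
  tom2 <- tom_similarity(a2)
  expect_equal(unname(tom2[4, 1:3]), rep(0, 3))
  # brute-force oracle on random matrices
  set.seed(17)
  for (i in 1:20) {
    a3 <- random_adjacency(10)
    expect_equal(tom_similarity(a3), tom_oracle(a3), tolerance = 1e-12)
  }
  # symmetry and range on a larger random case
  a4 <- random_adjacency(40)
  t4 <- tom_similarity(a4)
  expect_equal(t4, t(t4))
  expect_true(all(t4 >= 0 & t4 <= 1))
})

test_that("TOM is monotone in a single adjacency entry", {
  set.seed(23)
  a <- random_adjacency(8)
  vals <- seq(0.05, 0.95, by = 0.1)
  toms <- vapply(vals, function(v) {
    b <- a; b[1, 2] <- b[2, 1] <- v
    tom_similarity(b)[1, 2]
  }, numeric(1))
  expect_true(all(diff(toms) > 0))
})

test_that("average-linkage dendrogram matches a naive UPGMA oracle", {
  set.seed(19)
  for (i in 1:5) {
    d <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    dend <- cluster_dendrogram(d)
    expect_equal(sort(dend$height), upgma_heights_oracle(d),
                 tolerance = 1e-12)
    expect_length(dend$height, 5)  # n - 1 merges
  }
  # two identical rows merge first at height 0
  x <- matrix(rnorm(10), 5, 2)
  x[2, ] <- x[1, ]
  d0 <- as.matrix(dist(x))
  expect_equal(min(cluster_dendrogram(d0)$height), 0)
  # non-symmetric input rejected
  bad <- matrix(runif(9), 3, 3); diag(bad) <- 0
  expect_error(cluster_dendrogram(bad), "symmetric")
})

test_that("static cut dissolves small clusters and recovers planted ones", {
  # two tight clusters with orthogonal latents (exactly uncorrelated)
  set.seed(27)
  l1 <- rnorm(12)
  l2 <- resid(lm(rnorm(12) ~ l1))
  expr <- rbind(outer(rep(1, 40), l1) + matrix(rnorm(40 * 12, 0, 0.05), 40),
                outer(rep(1, 40), l2) + matrix(rnorm(40 * 12, 0, 0.05), 40))
  rownames(expr) <- sprintf("g%02d", 1:80)
  colnames(expr) <- paste0("s", 1:12)
  cc <- correlation_matrix(expr, log_transform = FALSE)
  diss <- 1 - tom_similarity(adjacency_matrix(cc, 6))
  diag(diss) <- 0
  dend <- cluster_dendrogram(diss)
  mod <- cut_modules(dend, diss, min_module_size = 30)
  expect_setequal(unique(mod$module), c(1, 2))
  truth <- rep(1:2, each = 40)
  expect_equal(adjusted_rand_index(mod$module, truth), 1)
  # labels are size-ordered: module 1 at least as large as module 2
  expect_gte(sum(mod$module == 1), sum(mod$module == 2))
  # min size above the cluster sizes sends everything to grey
  all_grey <- cut_modules(dend, diss, min_module_size = 50,
                          reassign_threshold = NULL)
  expect_true(all(all_grey$module == 0))
  expect_true(all(all_grey$color == "grey"))
  expect_error(cut_modules(dend, diss, min_module_size = 1), ">= 2")
})

test_that("eigengene-based merging joins only close modules and is idempotent", {
  set.seed(29)
  n_s <- 16
  shared <- rnorm(n_s)
  # modules A and B nearly share an eigengene; C is independent
  make_mod <- function(latent, n, noise) {
    t(replicate(n, latent + rnorm(n_s, 0, noise)))
  }
  expr <- rbind(make_mod(shared, 35, 0.1),
                make_mod(shared + rnorm(n_s, 0, 0.15), 34, 0.1),
                make_mod(rnorm(n_s), 33, 0.1))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", 1:n_s)
  assignment <- data.frame(gene_id = rownames(expr),
                           module = rep(1:3, c(35, 34, 33)),
                           color = "x", stringsAsFactors = FALSE)
  me <- module_eigengenes(expr, assignment)
  r_ab <- cor(me$eigengenes["ME1", ], me$eigengenes["ME2", ])
  expect_gt(r_ab, 0.75)  # construction premise: diss < 0.25
  merged <- merge_close_modules(expr, assignment, cut_height = 0.25)
  expect_equal(length(unique(merged$module)), 2)
  # A and B now share a label, C keeps its own
  lab <- merged$module
  expect_equal(length(unique(lab[1:69])), 1)
  expect_false(unique(lab[1:69]) == unique(lab[70:102]))
  # largest merged module gets label 1
  expect_equal(unique(lab[1:69]), 1)
  # idempotent
  again <- merge_close_modules(expr, merged, cut_height = 0.25)
  expect_equal(again$module, merged$module)
  # a cut below the A-B eigengene dissimilarity merges nothing
  not_merged <- merge_close_modules(expr, assignment,
                                    cut_height = (1 - r_ab) / 2)
  expect_equal(length(unique(not_merged$module)), 3)
})

test_that("module recovery on the default fixture reaches high fidelity", {
  ds <- default_dataset()
  net <- default_network()
  truth <- setNames(ds$truth$modules$module, ds$truth$modules$gene_id)
  keep <- net$modules$module != 0
  ari <- adjusted_rand_index(net$modules$module[keep],
                             truth[net$modules$gene_id[keep]])
  expect_gte(ari, 0.8)
  # grey is never counted as a module; labels are 1..K by size
  labs <- sort(unique(net$modules$module[keep]))
  expect_equal(labs, seq_along(labs))
  sizes <- table(net$modules$module[keep])
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_true(all(sizes >= 30))
})

test_that("our ARI agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
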