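# Shared fixtures, built once per test run and cached.
#
# The default dataset and the network stage on it are the expensive pieces
# (the exact tests enumerate conditional distributions over totals in the
# tens of thousands), so they are computed lazily and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_dataset <- function() {
  memo("default_dataset", generate_dataset())
}

# DEG tables for both cultivars on the default dataset
default_degs <- function() {
  memo("default_degs", {
    ds <- default_dataset()
    lapply(stats::setNames(c("G", "H"), c("G", "H")), function(cv) {
      call_degs_chill_vs_freeze(ds$counts, ds$metadata, cv)
    })
  })
}

# full network stage (auto beta) on the default dataset's DEG union
default_network <- function() {
  memo("default_network", {
    ds <- default_dataset()
    degs <- default_degs()
    deg_union <- sort(unique(unlist(lapply(degs, union_deg_set))))
    fpkm <- compute_fpkm(ds$counts, ds$gene_lengths)
    st <- suppressWarnings(pick_soft_threshold(fpkm[deg_union, ]))
    beta <- if (is.na(st$chosen_beta)) st$fallback_beta else st$chosen_beta
    cm <- correlation_matrix(fpkm[deg_union, ])
    adj <- adjacency_matrix(cm, beta)
    diss <- 1 - tom_similarity(adj)
    diag(diss) <- 0
    dend <- cluster_dendrogram(diss)
    pre <- cut_modules(dend, diss)
    log_fpkm <- log2(fpkm[deg_union, ] + 1)
    modules <- merge_close_modules(log_fpkm, pre)
    list(deg_union = deg_union, fpkm = fpkm, log_fpkm = log_fpkm,
         beta = beta, soft = st, modules = modules)
  })
}

# small random adjacency matrix in [0, 1], zero diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# independent triple-loop TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# independent brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# naive O(n^3) average-linkage (UPGMA) merge heights
upgma_heights_oracle <- function(d) {
  n <- nrow(d)
  heights <- numeric(n - 1)
  clusters <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    best <- Inf
    pair <- NULL
    idx <- which(vapply(clusters, Negate(is.null), TRUE))
    for (a in idx) for (b in idx) {
      if (a >= b) next
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      if (avg < best) { best <- avg; pair <- c(a, b) }
    }
    heights[step] <- best
    clusters[[pair[1]]] <- c(clusters[[pair[1]]], clusters[[pair[2]]])
    clusters[pair[2]] <- list(NULL)
  }
  sort(heights)
}
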