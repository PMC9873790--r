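test_that("graph connectivity scores induced subgraph components", {
  # single well-connected type -> 1.0
  set.seed(40)
  emb <- matrix(rnorm(20), 10, 2)
  expect_equal(graph_connectivity(emb, rep("a", 10), k_metric = 3), 1)

  # a type splitting into components of 3 and 2 cells -> 0.6; with a
  # connected second type of 3 cells the mean is (1 + 0.6) / 2 = 0.8.
  # the whole type sits between the two split islands so neither island
  # reaches the other within k = 2 neighbors
  far <- rbind(matrix(rnorm(6, 0, 0.01), 3, 2),
               matrix(rnorm(4, 100, 0.01), 2, 2),
               matrix(rnorm(6, 40, 0.01), 3, 2))
  labs <- c(rep("split", 5), rep("whole", 3))
  expect_equal(graph_connectivity(far, labs, k_metric = 2), 0.8)

  # brute-force oracle: adjacency from knn, components by reachability
  set.seed(41)
  emb2 <- matrix(rnorm(24), 12, 2)
  labs2 <- rep(c("x", "y"), 6)
  k <- 3
  D <- as.matrix(dist(emb2)); diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[1:k]))
  per_type <- sapply(unique(labs2), function(tt) {
    mem <- which(labs2 == tt)
    adj <- matrix(FALSE, length(mem), length(mem))
    for (i in seq_along(mem)) for (j in seq_along(mem))
      if (mem[j] %in% nn[mem[i], ] || mem[i] %in% nn[mem[j], ])
        adj[i, j] <- adj[j, i] <- TRUE
    diag(adj) <- TRUE
    reach <- adj
    for (s in seq_along(mem)) reach <- reach | (reach %*% adj > 0)
    max(table(apply(reach, 1, function(r) paste(which(r), collapse = ","))))/
      length(mem)
  })
  expect_equal(graph_connectivity(emb2, labs2, k_metric = k),
               mean(per_type))
  expect_warning(graph_connectivity(emb2, c(rep("a", 11), "solo"),
                                    k_metric = 3), "single cell")
})

test_that("ARI matches the pair-counting formula and its invariances", {
  a <- c(1, 1, 2, 2, 3, 3, 3, 1)
  b <- c(2, 2, 3, 3, 1, 1, 2, 2)
  # brute-force pair-counting oracle over all unordered pairs
  n <- length(a)
  s_both <- s_a <- s_b <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s_both <- s_both + 1
    if (sa) s_a <- s_a + 1
    if (sb) s_b <- s_b + 1
  }
  expected <- s_a * s_b / tot
  oracle <- (s_both - expected) / ((s_a + s_b) / 2 - expected)
  expect_equal(adjusted_rand_index(a, b), oracle, tolerance = 1e-12)

  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c(3, 1, 2)[a]  # relabeled copy
  expect_equal(adjusted_rand_index(a, perm), 1)
  expect_warning(adjusted_rand_index(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("NMI uses arithmetic-mean normalization and label invariance", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(normalized_mutual_info(a, a), 1)
  expect_equal(normalized_mutual_info(a, c(2, 2, 3, 3, 1, 1)), 1)
  b <- c(1, 2, 1, 2, 1, 2)
  # entropy oracle computed from the contingency table by hand
  tab <- table(a, b) / 6
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- sum(ifelse(tab > 0, tab * log(tab / outer(pa, pb)), 0))
  expect_equal(normalized_mutual_info(a, b),
               mi / ((-sum(pa * log(pa)) - sum(pb * log(pb))) / 2),
               tolerance = 1e-12)
  expect_gte(normalized_mutual_info(a, b), 0)
})

test_that("kNN agreement matches brute-force neighbor counting", {
  expect_equal(knn_agreement(matrix(rnorm(40), 10, 4), rep("a", 10), k = 3),
               1)
  # planted bipartite geometry: nearest neighbor always opposite label
  x <- matrix(0, 6, 2)
  x[, 1] <- c(0, 0.1, 10, 10.1, 20, 20.1)
  labs <- rep(c("u", "v"), 3)
  expect_equal(knn_agreement(x, labs, k = 1, n_components = 1), 0)

  set.seed(43)
  y <- matrix(rnorm(12 * 5), 12, 5)
  labs2 <- sample(c("p", "q"), 12, replace = TRUE)
  k <- 4
  red <- prcomp(y)$x[, 1:4]
  D <- as.matrix(dist(red)); diag(D) <- Inf
  fr <- sapply(1:12, function(i) {
    nb <- order(D[i, ])[1:k]
    mean(labs2[nb] == labs2[i])
  })
  expect_equal(knn_agreement(y, labs2, k = k, n_components = 4), mean(fr))
  expect_error(knn_agreement(y, labs2, k = 12), "k must be")
})

test_that("kNN agreement degrades as label noise increases", {
  set.seed(44)
  x <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
             matrix(rnorm(60, 6, 0.2), 30, 2))
  clean <- rep(c("a", "b"), each = 30)
  scores <- sapply(c(0, 0.2, 0.45), function(noise) {
    labs <- clean
    flip <- sample(60, round(noise * 60))
    labs[flip] <- ifelse(labs[flip] == "a", "b", "a")
    knn_agreement(x, labs, k = 5, n_components = 1)
  })
  expect_true(all(diff(scores) <= 0))
})

test_that("rare-type F1 picks the maximum-overlap cluster", {
  mask <- c(rep(TRUE, 4), rep(FALSE, 8))
  pred <- c(rep(1, 4), rep(2, 8))
  expect_equal(f1_rare(pred, mask), 1)
  # precision 0.5, recall 1 -> 2/3
  pred2 <- c(rep(1, 8), rep(2, 4))
  expect_equal(f1_rare(pred2, mask), 2 * 0.5 * 1 / 1.5)
  # exhaustive-overlap oracle on a two-candidate toy
  pred3 <- c(1, 1, 2, 2, 2, 1, 1, 2, 2, 2, 1, 1)
  mask3 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
             FALSE, FALSE, FALSE, FALSE)
  ov <- sapply(unique(pred3), function(cl) sum(mask3[pred3 == cl]))
  best <- unique(pred3)[which.max(ov)]
  pr <- sum(pred3 == best & mask3) / sum(pred3 == best)
  rc <- sum(pred3 == best & mask3) / sum(mask3)
  expect_equal(f1_rare(pred3, mask3), 2 * pr * rc / (pr + rc))
  expect_error(f1_rare(pred, rep(FALSE, 12)), "no true rare")
})

test_that("Kendall tau matches all-pairs concordance counting", {
  expect_equal(kendall_tau(letters[1:5], letters[1:5]), 1)
  expect_equal(kendall_tau(letters[1:5], rev(letters[1:5])), -1)
  set.seed(45)
  a <- sample(letters[1:5]); b <- sample(letters[1:5])
  ra <- seq_along(a); rb <- match(a, b)
  conc <- disc <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    s <- sign(ra[i] - ra[j]) * sign(rb[i] - rb[j])
    if (s > 0) conc <- conc + 1 else disc <- disc + 1
  }
  expect_equal(kendall_tau(a, b), (conc - disc) / 10, tolerance = 1e-12)
  expect_error(kendall_tau(letters[1:4], letters[2:5]), "item set")
})

test_that("clustering_scores reports independent ARI and NMI maxima", {
  set.seed(46)
  blob <- function(mu, n) matrix(rnorm(n * 2, mu, 0.05), n, 2)
  fac <- list(a = rbind(blob(0, 8), blob(4, 8)),
              b = rbind(blob(0, 8), blob(4, 8)))
  g <- normalize_distances(neighbor_graph(fac, k = 5, r = 1))
  truth <- rep(c(1, 2, 1, 2), each = 8)
  cs <- clustering_scores(g, truth, resolutions = c(0.1, 0.6, 1.1), seed = 2)
  expect_equal(cs$ari, 1)
  expect_equal(cs$nmi, 1)
  expect_equal(nrow(cs$sweep), 3L)
  expect_length(cs$labels, 32L)
})

test_that("dataset-level kNN agreement averages over all matrices", {
  d <- make_toy_dataset(seed = 70, n1 = 12, n2 = 10, pg = 6, pr = 8)
  labs <- list(b1 = rep(c("x", "y"), 6), b2 = rep(c("x", "y"), 5))
  per_matrix <- c(
    knn_agreement(mosaic_matrix(d, "b1", "rna"), labs$b1, k = 3,
                  modality = "rna"),
    knn_agreement(mosaic_matrix(d, "b1", "atac"), labs$b1, k = 3,
                  modality = "atac"),
    knn_agreement(mosaic_matrix(d, "b2", "rna"), labs$b2, k = 3,
                  modality = "rna"))
  expect_equal(knn_agreement_mosaic(d, labs, k = 3), mean(per_matrix))
  expect_equal(knn_agreement_mosaic(d, unlist(labs, use.names = FALSE), k = 3),
               mean(per_matrix))
})
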