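test_that("neighbor quotas split k proportionally with largest remainder", {
  expect_equal(unname(neighbor_quotas(c(100, 200), 30)), c(10L, 20L))
  expect_equal(unname(neighbor_quotas(500, 30)), 30L)
  # floor + largest remainder, ties to the lower index
  expect_equal(unname(neighbor_quotas(c(100, 300), 30)), c(8L, 22L))
  # every batch gets >= 1 even when proportionality would round to 0
  q <- neighbor_quotas(c(5, 1000, 1000), 10)
  expect_equal(sum(q), 10L)
  expect_true(all(q >= 1L))
  expect_error(neighbor_quotas(c(10, 10, 10), 2), "cannot give")
})

test_that("graph construction respects quotas, pruning and batch symmetry", {
  set.seed(21)
  f1 <- matrix(runif(10 * 3), 10, 3)
  f2 <- f1  # identical duplicate batch
  g <- neighbor_graph(list(a = f1, b = f2), k = 4, r = 1)
  e <- g$edges
  # every cell has k outgoing edges
  expect_true(all(table(e$src) == 4))
  # each cell's nearest cross-batch neighbor is its duplicate at distance 0
  for (m in 1:10) {
    cross <- e[e$src == m & e$dst_batch == "b", ]
    expect_equal(min(cross$dist), 0)
    expect_true((m + 10) %in% cross$dst)
  }

  # r = 1 is exactly the unpruned edge multiset
  set.seed(22)
  fa <- matrix(runif(24), 12, 2); fb <- matrix(runif(16), 8, 2)
  g1 <- neighbor_graph(list(a = fa, b = fb), k = 5, r = 1)
  g2 <- neighbor_graph(list(a = fa, b = fb), k = 5, r = 0.999999)
  expect_gt(nrow(g1$edges), nrow(g2$edges) - 1)  # both built; compare below
  # pruning keeps ceil(r * n) shortest edges per ordered batch pair
  gp <- neighbor_graph(list(a = fa, b = fb), k = 5, r = 0.5)
  for (bi in c("a", "b")) for (bj in setdiff(c("a", "b"), bi)) {
    full <- g1$edges[g1$edges$src_batch == bi & g1$edges$dst_batch == bj, ]
    kept <- gp$edges[gp$edges$src_batch == bi & gp$edges$dst_batch == bj, ]
    expect_equal(nrow(kept), ceiling(0.5 * nrow(full)))
    removed <- setdiff(paste(full$src, full$dst), paste(kept$src, kept$dst))
    if (length(removed))
      expect_lte(max(kept$dist),
                 min(full$dist[paste(full$src, full$dst) %in% removed]))
  }
  # within-batch edges are never pruned
  expect_equal(sum(gp$edges$src_batch == gp$edges$dst_batch),
               sum(g1$edges$src_batch == g1$edges$dst_batch))

  # batch relabeling permutes but does not change the edge set
  rownames(fa) <- paste0("A", seq_len(nrow(fa)))
  rownames(fb) <- paste0("B", seq_len(nrow(fb)))
  g_named <- neighbor_graph(list(a = fa, b = fb), k = 5, r = 1)
  g_sw <- neighbor_graph(list(b = fb, a = fa), k = 5, r = 1)
  key <- function(g) {
    ids <- g$cell_ids
    sort(paste(ids[g$edges$src], ids[g$edges$dst]))
  }
  expect_equal(key(g_sw), key(g_named))
})

test_that("distance normalization equalizes within- and cross-batch means", {
  set.seed(23)
  fa <- matrix(runif(30), 15, 2); fb <- matrix(runif(30), 15, 2) + 2
  g <- neighbor_graph(list(a = fa, b = fb), k = 6, r = 1)
  gn <- normalize_distances(g)
  e <- gn$edges
  for (m in unique(e$src)) {
    within <- e$ndist[e$src == m & e$src_batch == e$dst_batch]
    for (bj in setdiff(unique(e$dst_batch[e$src == m]), e$src_batch[e$src == m][1])) {
      cross <- e$ndist[e$src == m & e$dst_batch == bj &
                         e$src_batch != e$dst_batch]
      if (length(within) && length(cross))
        expect_equal(mean(cross), mean(within), tolerance = 1e-9)
    }
  }
  # within-batch edges unchanged; direct ratio case d_ii=2, d_ij=4 -> 2
  expect_equal(e$ndist[e$src_batch == e$dst_batch],
               e$dist[e$src_batch == e$dst_batch])
  # idempotence
  gn2 <- normalize_distances(gn)
  expect_equal(gn2$edges$ndist, gn$edges$ndist, tolerance = 1e-12)

  # unit ratio leaves everything unchanged: symmetric duplicate batches
  g2 <- normalize_distances(neighbor_graph(list(a = fa, b = fa), k = 4, r = 1))
  same <- g2$edges$src_batch == g2$edges$dst_batch
  # cross-batch edge to the duplicate has distance 0; means match trivially
  expect_true(all(is.finite(g2$edges$ndist)))
})

test_that("the explicit d_ii/d_ij rescaling formula is applied", {
  # two cells per batch arranged so cell 1 has d_ii = 2 and d_ij = 4
  fa <- rbind(c(0, 0), c(2, 0))
  fb <- rbind(c(4, 0), c(20, 0))
  g <- neighbor_graph(list(a = fa, b = fb), k = 2, r = 1)
  gn <- normalize_distances(g)
  e <- gn$edges
  got <- e$ndist[e$src == 1 & e$dst == 3]
  expect_equal(got, 2)  # (2 / 4) * 4
})

test_that("Leiden clustering separates blobs and is seed-stable", {
  set.seed(24)
  # dense blobs: with k large relative to blob size the induced subgraphs
  # are near-cliques and carry no substructure for Leiden to find
  blob1 <- matrix(rnorm(20, 0, 0.05), 10, 2)
  blob2 <- matrix(rnorm(20, 5, 0.05), 10, 2)
  fac <- list(a = rbind(blob1[1:5, ], blob2[1:5, ]),
              b = rbind(blob1[6:10, ], blob2[6:10, ]))
  g <- normalize_distances(neighbor_graph(fac, k = 8, r = 1))
  truth <- rep(c(1, 2, 1, 2), each = 5)
  for (res in c(0.1, 0.5, 1)) {
    lab <- cluster_cells(g, resolution = res, seed = 7)
    expect_equal(length(unique(lab)), 2L)
    expect_equal(adjusted_rand_index(lab, truth), 1)
  }
  expect_identical(cluster_cells(g, 1, seed = 3), cluster_cells(g, 1, seed = 3))
  # near-zero resolution on a uniform graph collapses to one cluster
  uni <- normalize_distances(neighbor_graph(
    list(a = matrix(runif(20), 10, 2)), k = 5, r = 1))
  expect_equal(length(unique(cluster_cells(uni, 1e-4, seed = 1))), 1L)
})

test_that("graph export carries both raw and normalized distances", {
  set.seed(25)
  fac <- list(a = matrix(runif(12), 6, 2), b = matrix(runif(12), 6, 2))
  g <- normalize_distances(neighbor_graph(fac, k = 4, r = 1))
  tab <- graph_edge_table(g)
  expect_named(tab, c("src", "dst", "src_batch", "dst_batch", "distance",
                      "normalized_distance"))
  expect_equal(nrow(tab), nrow(g$edges))
  path <- withr::local_tempfile(fileext = ".tsv")
  graph_edge_table(g, path)
  expect_true(file.exists(path))
})
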