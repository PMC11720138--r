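test_that("kNN graph matches brute-force distances and tie conventions", {
  # 1-D fixture with a distance tie: 1 is equidistant from 0 and 2
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  g <- build_knn_graph(X, kappa = 1)
  expect_identical(as.vector(g$index), c(2L, 1L, 2L, 3L))  # tie -> lower index
  # no self-neighbours, duplicated points pair up
  Xd <- matrix(c(5, 5, 9), ncol = 1)
  gd <- build_knn_graph(Xd, kappa = 1)
  expect_identical(gd$index[1, 1], 2L)
  expect_identical(gd$index[2, 1], 1L)
  expect_true(all(gd$index != seq_len(3)))
  # random fixture vs an independent R oracle
  set.seed(101)
  X <- matrix(rnorm(1000 * 4), 1000, 4)
  g <- build_knn_graph(X, kappa = 7)
  expect_identical(unname(g$index), unname(knn_oracle(X, 7)))
  # the two exact backends agree away from ties
  g_km <- build_knn_graph(X, kappa = 7, brute_threshold = 10)
  expect_identical(unname(g_km$index), unname(g$index))
  expect_error(build_knn_graph(X[1:5, , drop = FALSE], kappa = 7), "smaller kappa")
})

test_that("Jaccard weights follow the neighbour-set arithmetic", {
  # N(1) = {2,3,4}, N(2) = {3,4,5}: intersection 2, union 4 -> 1/2
  idx <- rbind(c(2L, 3L, 4L),
               c(3L, 4L, 5L),
               c(1L, 2L, 4L),
               c(1L, 2L, 3L),
               c(2L, 3L, 4L))
  g <- structure(list(index = idx, kappa = 3L), class = "knn_graph")
  g <- jaccard_weights(g)
  e12 <- g$edges[g$edges$from == 1 & g$edges$to == 2, ]
  expect_equal(e12$weight, 0.5)
  # weights follow inter / (2k - inter) for every edge (R oracle); the
  # theoretical maximum of 1 needs identical neighbour sets, which no
  # realisable kNN edge can have (one endpoint always sits in the other's
  # list), so (k-1)/(k+1) is the attainable ceiling
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges$from[r]; b <- g$edges$to[r]
    inter <- length(intersect(idx[a, ], idx[b, ]))
    expect_equal(g$edges$weight[r], inter / (2 * 3 - inter))
  }
  expect_true(all(g$edges$weight > 0 & g$edges$weight <= (3 - 1) / (3 + 1)))
  # disjoint neighbour sets: edge dropped
  idx2 <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L),
                c(5L, 6L), c(4L, 6L), c(4L, 5L),
                c(4L, 5L), c(1L, 2L))  # 7,8 bridge with disjoint sets
  g2 <- jaccard_weights(structure(list(index = idx2, kappa = 2L),
                                  class = "knn_graph"))
  expect_false(any(g2$edges$from == 7 & g2$edges$to == 8))
})

test_that("community detection attains the exhaustive modularity optimum", {
  fixtures <- list(
    # two triangles joined by one weak edge
    list(n = 6,
         from = c(1, 1, 2, 4, 4, 5, 3),
         to   = c(2, 3, 3, 5, 6, 6, 4),
         weight = c(1, 1, 1, 1, 1, 1, 0.1),
         k_expected = 2L),
    # complete graph with uniform weights: one community
    list(n = 5,
         from = rep(1:4, times = 4:1),
         to = unlist(lapply(2:5, function(j) seq(j, 5))),
         weight = NULL, k_expected = 1L),
    # two 4-cliques plus a bridge
    list(n = 8,
         from = c(1, 1, 1, 2, 2, 3, 5, 5, 5, 6, 6, 7, 4),
         to   = c(2, 3, 4, 3, 4, 4, 6, 7, 8, 7, 8, 8, 5),
         weight = NULL, k_expected = 2L)
  )
  for (fx in fixtures) {
    from <- fx$from
    to <- unlist(fx$to)
    w <- if (is.null(fx$weight)) rep(1, length(from)) else fx$weight
    g <- graph_fixture(fx$n, from, to, w)
    part <- louvain_communities(g, seed = 1)
    oracle <- best_partition_oracle(g$edges, fx$n)
    q_part <- modularity_oracle(g$edges, part$assignment)
    expect_equal(q_part, oracle$modularity, tolerance = 1e-12)
    expect_identical(part$n_clusters, fx$k_expected)
    # returned modularity beats the trivial partitions
    expect_gte(q_part, modularity_oracle(g$edges, rep(1, fx$n)))
    expect_gte(q_part, modularity_oracle(g$edges, seq_len(fx$n)))
    # same seed -> identical partition
    expect_identical(part$assignment,
                     louvain_communities(g, seed = 1)$assignment)
  }
})

test_that("complete-graph fixture is built correctly", {
  # guard for the fixture arithmetic above (K5 has 10 edges)
  from <- rep(1:4, times = 4:1)
  to <- unlist(lapply(2:5, function(j) seq(j, 5)))
  expect_length(from, 10)
  expect_true(all(from < to))
})

test_that("partition recovers well-separated synthetic populations", {
  cfg <- test_config()
  hits <- 0L
  for (seed in 1:5) {
    s <- small_sample(seed = seed, n = 6000)
    an <- analyze_sample(s, method = "cluster", config = cfg, seed = seed)
    mask <- an$partition$mask
    truth <- s$truth$population_id[mask]
    ari <- ari_oracle(truth, an$partition$assignment)
    if (ari >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("a small aberrant spike concentrates into its own cluster", {
  cfg <- test_config()
  good <- 0L
  for (seed in 1:5) {
    s <- small_sample(seed = 100 + seed, n = 15000, spike_events = 82)
    an <- analyze_sample(s, method = "cluster", config = cfg, seed = seed)
    mask <- an$partition$mask
    spike_cl <- an$partition$assignment[s$truth$population_id[mask] == "spike"]
    if (!length(spike_cl)) next
    main <- as.integer(names(which.max(table(spike_cl))))
    purity <- sum(spike_cl == main) / sum(an$partition$assignment == main)
    if (purity >= 0.8) good <- good + 1L
  }
  expect_gte(good, 4L)
})

test_that("merging respects tolerance and the clonality side constraint", {
  cfg <- test_config()
  # one population over-clustered artificially: identical medians merge
  s <- small_sample(seed = 55, n = 6000)
  pre <- pregate(s$events, cfg)
  mask <- pre$gates$masks$t_cells
  X <- clustering_matrix(pre$transformed, cfg)[mask, , drop = FALSE]
  thr <- default_thresholds()[["TRBC1"]]
  # split the CD4 population into two fake clusters; everything else cluster 3
  truth <- s$truth$population_id[mask]
  fake <- ifelse(truth == "cd4_t", 1L + (seq_len(sum(mask)) %% 2L == 0L), 3L)
  part <- structure(list(assignment = as.integer(fake), n_clusters = 3L),
                    class = "cluster_partition")
  part <- cluster_profiles(part, pre$transformed, s$events, mask, thr, cfg)
  merged <- merge_overclustered(part, pre$transformed, s$events, thr,
                                tolerance = 0.5, config = cfg)
  # the two artificial CD4 halves re-join; the rest stays apart
  cd4_cl <- unique(merged$assignment[truth == "cd4_t"])
  expect_length(cd4_cl, 1)
  expect_gte(merged$n_clusters, 2)

  # same medians but opposite clonality sides must NOT merge:
  # synthetic two-cluster profile fixture
  panel <- default_panel()
  n <- 400
  Xf <- matrix(1000, n, length(panel$channels),
               dimnames = list(NULL, panel$channels))
  Xf[, "TRBC1"] <- c(rep(9000, 190), rep(10, 10), rep(9000, 80), rep(10, 120))
  ev <- event_table(Xf, panel)
  tr <- transform_intensities(ev)
  p2 <- structure(list(assignment = rep(c(1L, 2L), each = 200), n_clusters = 2L),
                  class = "cluster_partition")
  p2 <- cluster_profiles(p2, tr, ev, rep(TRUE, n), thr, cfg)
  m2 <- merge_overclustered(p2, tr, ev, thr, tolerance = 0.5, config = cfg)
  expect_identical(m2$n_clusters, 2L)   # 0.95 vs 0.40: different sides
  # same side and identical medians -> merges into one
  Xf[, "TRBC1"] <- c(rep(9000, 190), rep(10, 10), rep(9000, 194), rep(10, 6))
  ev <- event_table(Xf, panel)
  tr <- transform_intensities(ev)
  p3 <- structure(list(assignment = rep(c(1L, 2L), each = 200), n_clusters = 2L),
                  class = "cluster_partition")
  p3 <- cluster_profiles(p3, tr, ev, rep(TRUE, n), thr, cfg)
  m3 <- merge_overclustered(p3, tr, ev, thr, tolerance = 0.5, config = cfg)
  expect_identical(m3$n_clusters, 1L)
  # monotypic clusters never lose their purity class through merging
  expect_true(all(m3$profiles$trbc1_fraction > 0.85))
})

test_that("QC embedding has the right shape and is seed-stable", {
  set.seed(7)
  X <- matrix(rnorm(300 * 4), 300, 4)
  Y1 <- embed_qc(X, perplexity = 20, iterations = 120, seed = 3)
  expect_identical(dim(Y1), c(300L, 2L))
  Y2 <- embed_qc(X, perplexity = 20, iterations = 120, seed = 3)
  expect_identical(Y1, Y2)
})
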