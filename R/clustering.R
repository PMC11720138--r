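#' Feature matrix for clustering
#'
#' The ten clustering channels on a common analysis scale: fluorescence
#' channels as arcsinh(x / cofactor), scatter channels as
#' arcsinh(x / scatter_cofactor). TRBC1 is excluded by the panel definition,
#' so clonality never shapes the clusters.
#'
#' @param transformed transformed [event_table()].
#' @param config a [default_config()].
#' @return numeric matrix, events x clustering channels.
#' @export
clustering_matrix <- function(transformed, config = default_config()) {
  stopifnot(inherits(transformed, "event_table"), transformed$transformed)
  panel <- transformed$panel
  X <- transformed$exprs[, panel$clustering, drop = FALSE]
  sc <- intersect(panel$scatter, panel$clustering)
  X[, sc] <- asinh(X[, sc] / config$scatter_cofactor)
  X
}

#' Exact k-nearest-neighbour graph
#'
#' Exact Euclidean kNN per event, self excluded. Small inputs (up to
#' `brute_threshold` events) use an in-package brute-force search whose
#' distance ties break towards the lower event index; larger inputs use
#' BiocNeighbors' exact KMKNN search (tie order there is unspecified, but
#' ties have probability zero for continuous intensities).
#'
#' @param X numeric matrix of events x features (see [clustering_matrix()]).
#' @param kappa neighbourhood size; must be smaller than the number of
#'   events.
#' @param brute_threshold switch-over size between the two exact backends.
#' @return A `knn_graph`: list with `index` (n x kappa integer matrix,
#'   nearest first) and `kappa`.
#' @export
build_knn_graph <- function(X, kappa = 40, brute_threshold = 2048) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= kappa) {
    stop("need more than kappa = ", kappa,
         " events to build a kNN graph; use a smaller kappa", call. = FALSE)
  }
  idx <- if (n <= brute_threshold) {
    .brute_knn(X, as.integer(kappa))
  } else {
    BiocNeighbors::findKNN(X, k = as.integer(kappa),
                           BNPARAM = BiocNeighbors::KmknnParam(),
                           get.distance = FALSE)$index
  }
  structure(list(index = idx, kappa = as.integer(kappa)), class = "knn_graph")
}

#' Jaccard edge weights over a kNN graph
#'
#' Symmetrises the directed kNN links and weights each edge (a, b) by the
#' Jaccard similarity of the two k-neighbour sets,
#' |N(a) & N(b)| / |N(a) | N(b)|. Edges whose neighbourhoods are disjoint
#' are dropped.
#'
#' @param g a `knn_graph` from [build_knn_graph()].
#' @return The graph with an `edges` data.frame (`from`, `to`, `weight`),
#'   weights in (0, 1].
#' @export
jaccard_weights <- function(g) {
  stopifnot(inherits(g, "knn_graph"))
  e <- .knn_jaccard_edges(g$index)
  g$edges <- data.frame(from = e$from, to = e$to, weight = e$weight)
  g
}

#' Louvain community detection on the weighted kNN graph
#'
#' Greedy modularity optimisation in the classic two-phase scheme (local
#' moving, then graph aggregation, repeated to a fixpoint), implemented
#' in-package for determinism and speed: nodes are visited in ascending
#' index order and modularity-gain ties break towards the lower community
#' id, so the partition is a pure function of the graph. The `seed`
#' argument is accepted for interface stability but the documented node
#' order makes the result seed-independent. Events whose every edge was
#' dropped form singleton communities.
#'
#' @param g a `knn_graph` with Jaccard `edges` (see [jaccard_weights()]).
#' @param seed integer seed (kept for API compatibility; see Details).
#' @return A `cluster_partition`: list with `assignment` (integer cluster id
#'   per event, contiguous from 1) and `n_clusters`.
#' @export
louvain_communities <- function(g, seed = 1L) {
  stopifnot(inherits(g, "knn_graph"))
  if (is.null(g$edges)) g <- jaccard_weights(g)
  n <- nrow(g$index)
  if (n == 0) stop("empty graph", call. = FALSE)
  memb <- .louvain_cpp(n, as.integer(g$edges$from), as.integer(g$edges$to),
                       as.numeric(g$edges$weight))
  memb <- match(memb, sort(unique(memb)))
  structure(list(assignment = memb, n_clusters = max(memb)),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", length(x$assignment), "events in", x$n_clusters,
      "clusters\n")
  invisible(x)
}

#' Per-cluster profiles
#'
#' Attaches to a partition: cluster sizes, per-clustering-channel medians on
#' the analysis scale (the merge metric space), raw-scale MFIs for the seven
#' recorded antigens, TRBC1-positive fractions, and a TCRgd-positivity flag
#' (TCRgd-positive clusters are excluded from clonality assessment).
#'
#' @param partition a `cluster_partition`.
#' @param transformed transformed [event_table()] (all events).
#' @param raw raw [event_table()] (all events).
#' @param mask logical mask of the clustered (CD3-positive) events; its
#'   `sum` must equal `length(partition$assignment)`.
#' @param threshold TRBC1 positivity threshold (transformed scale).
#' @param config a [default_config()].
#' @return The partition with `profiles` (data.frame), `medians` (matrix)
#'   and `mask` attached.
#' @export
cluster_profiles <- function(partition, transformed, raw, mask, threshold,
                             config = default_config()) {
  stopifnot(inherits(partition, "cluster_partition"),
            sum(mask) == length(partition$assignment))
  X <- clustering_matrix(transformed, config)[mask, , drop = FALSE]
  trbc1 <- chan(transformed, "TRBC1")[mask]
  tcrgd <- chan(transformed, "TCRgd")[mask]
  raw_sub <- raw$exprs[mask, , drop = FALSE]
  ids <- sort(unique(partition$assignment))
  med <- matrix(NA_real_, length(ids), ncol(X),
                dimnames = list(ids, colnames(X)))
  mfi_markers <- c("CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD45")
  mfi <- matrix(NA_real_, length(ids), length(mfi_markers),
                dimnames = list(ids, paste0("mfi_", mfi_markers)))
  n <- integer(length(ids))
  frac <- numeric(length(ids))
  gd_flag <- logical(length(ids))
  for (i in seq_along(ids)) {
    in_cl <- partition$assignment == ids[i]
    n[i] <- sum(in_cl)
    med[i, ] <- apply(X[in_cl, , drop = FALSE], 2, median)
    mfi[i, ] <- apply(raw_sub[in_cl, mfi_markers, drop = FALSE], 2, median)
    frac[i] <- mean(trbc1[in_cl] > threshold)
    gd_flag[i] <- median(tcrgd[in_cl]) > config$thresholds[["TCRgd"]]
  }
  partition$profiles <- data.frame(
    cluster = ids, n = n, trbc1_fraction = frac, tcrgd_positive = gd_flag,
    mfi, row.names = NULL
  )
  partition$medians <- med
  partition$mask <- mask
  partition
}

.clonality_side <- function(frac, params) {
  ifelse(frac > params$upper_bound, "high",
         ifelse(frac < params$lower_bound, "low", "mid"))
}

#' Merge over-clustered partitions
#'
#' A kappa of 40 or less over-clusters large homogeneous populations;
#' fragments of one population are re-joined here, emulating the Boolean
#' gating with which split clusters are merged and analysed as a single
#' population. Two clusters merge when the Chebyshev distance between their
#' clustering-channel medians is at most `tolerance` AND their TRBC1
#' fractions fall on the same side of the clonality rule (both above the
#' upper bound, both below the lower bound, or both inside) AND they agree
#' on TCRgd positivity. The closest eligible pair merges first and profiles
#' are recomputed after every merge until a fixpoint, so fragment medians
#' chain towards the population centre.
#'
#' The 0.8 default tolerance sits between the median jitter of fragments of
#' one lognormal population split at kappa = 40 (up to ~0.75 units) and the
#' smallest designed marker aberrancy on the analysis scale (~1.6 units for
#' dim CD3); 0.5 was found to leave single clones fragmented.
#'
#' @param partition a profiled `cluster_partition` (see
#'   [cluster_profiles()]).
#' @param transformed,raw,threshold,config as in [cluster_profiles()].
#' @param tolerance Chebyshev merge tolerance on the analysis scale.
#' @return A re-profiled `cluster_partition` with contiguous ids.
#' @export
merge_overclustered <- function(partition, transformed, raw, threshold,
                                tolerance = 0.8, config = default_config()) {
  stopifnot(inherits(partition, "cluster_partition"),
            !is.null(partition$profiles))
  params <- config$clonality
  repeat {
    pr <- partition$profiles
    med <- partition$medians
    k <- nrow(pr)
    if (k < 2) break
    side <- .clonality_side(pr$trbc1_fraction, params)
    best <- NULL
    best_d <- Inf
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        d <- max(abs(med[a, ] - med[b, ]))
        if (d <= tolerance && side[a] == side[b] &&
            pr$tcrgd_positive[a] == pr$tcrgd_positive[b] && d < best_d) {
          best <- c(a, b)
          best_d <- d
        }
      }
    }
    if (is.null(best)) break
    from_id <- pr$cluster[best[2]]
    to_id <- pr$cluster[best[1]]
    partition$assignment[partition$assignment == from_id] <- to_id
    partition$assignment <- match(partition$assignment,
                                  sort(unique(partition$assignment)))
    partition$n_clusters <- max(partition$assignment)
    partition <- cluster_profiles(partition, transformed, raw,
                                  partition$mask, threshold, config)
  }
  partition
}

#' 2-D t-SNE embedding for visual QC
#'
#' Library-backed embedding used only for figures; it never feeds the
#' clustering or clonality decisions.
#'
#' @param X clustering feature matrix.
#' @param perplexity,iterations t-SNE parameters (defaults 30 / 1000).
#' @param seed integer seed; the layout is reproducible given the seed.
#' @return numeric matrix of n x 2 coordinates.
#' @export
embed_qc <- function(X, perplexity = 30, iterations = 1000, seed = 1L) {
  X <- as.matrix(X)
  perplexity <- min(perplexity, floor((nrow(X) - 1) / 3))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                      max_iter = iterations, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE)
  fit$Y
}
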