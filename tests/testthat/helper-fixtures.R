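# shared fixtures and independent oracles for the test suite

# config scaled for test-sized samples (the acquisition-floor warning is a
# cohort-protocol check, not a correctness property)
test_config <- function() {
  cfg <- default_config()
  cfg$min_cd45_events <- 1000
  cfg
}

# an event_table carrying just a TRBC1 intensity vector on the analysis
# scale (all other channels at zero); for exercising the clonality rule
trbc1_events <- function(values) {
  panel <- default_panel()
  X <- matrix(0, length(values), length(panel$channels),
              dimnames = list(NULL, panel$channels))
  X[, "TRBC1"] <- values
  event_table(X, panel, transformed = TRUE, cofactor = 150)
}

# brute-force kNN oracle in plain R: order by distance, ties by lower index
knn_oracle <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

# hand-computed Newman modularity for a weighted undirected edge list
modularity_oracle <- function(edges, membership) {
  m <- sum(edges$weight)
  deg <- numeric(max(c(edges$from, edges$to)))
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + edges$weight[i]
    deg[edges$to[i]] <- deg[edges$to[i]] + edges$weight[i]
  }
  q <- 0
  for (i in seq_len(nrow(edges))) {
    if (membership[edges$from[i]] == membership[edges$to[i]]) {
      q <- q + edges$weight[i] / m
    }
  }
  for (comm in unique(membership)) {
    q <- q - (sum(deg[membership == comm]) / (2 * m))^2
  }
  q
}

# exhaustive modularity maximisation over all set partitions of n nodes
# (restricted-growth-string enumeration); the independent oracle for the
# community-detection stage
best_partition_oracle <- function(edges, n) {
  best_q <- -Inf
  best <- NULL
  a <- integer(n)
  enumerate <- function(i, maxv) {
    if (i > n) {
      q <- modularity_oracle(edges, a)
      if (q > best_q) {
        best_q <<- q
        best <<- a
      }
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      a[i] <<- v
      enumerate(i + 1L, max(maxv, v))
    }
  }
  enumerate(1L, 0L)
  list(membership = best, modularity = best_q)
}

# fabricate a knn_graph carrying an explicit weighted edge list (for feeding
# arbitrary graphs to the community-detection stage)
graph_fixture <- function(n, from, to, weight = rep(1, length(from))) {
  structure(list(index = matrix(1L, n, 1), kappa = 1L,
                 edges = data.frame(from = from, to = to, weight = weight)),
            class = "knn_graph")
}

# adjusted Rand index from the contingency table
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# tiny well-separated sample for pipeline tests
small_sample <- function(seed = 1, n = 8000, spike_events = NULL,
                         spike_maker = spike_cd8_t_cus) {
  spike <- if (!is.null(spike_events)) spike_maker(n_events = spike_events)
  generate_sample(default_sample_spec(total_cd45_events = n, spike = spike,
                                      seed = seed))
}
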