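#' Analyse one sample for monotypic T-cell populations
#'
#' Runs the full chain on an event table: pre-gating to the CD3-positive
#' analysis population, TRBC1 threshold estimation, then either the
#' clustering pipeline (kNN graph, Jaccard weights, Louvain communities,
#' over-cluster merging, per-cluster clonality) or the quadrant-subset
#' manual baseline, followed by sizing, MFI recording, lineage assignment
#' and the lymphoma-like/T-CUS-like heuristic.
#'
#' @param sample a `synthetic_sample` or raw [event_table()].
#' @param method `"cluster"`, `"manual"` or `"both"`.
#' @param config a [default_config()].
#' @param seed seed for the community detection stage.
#' @param subgated when `TRUE` the manual method also sub-gates each
#'   quadrant on marker loss before assessment (revised-analysis emulation,
#'   see [assess_subsets_subgated()]).
#' @return A `trbc_analysis` object (for `"both"`, a named list of two):
#'   list with `calls` (population-call data.frame), `call_events` (list of
#'   event-index vectors per call row), `gates`, `threshold`, `cd45_total`,
#'   `cd3_total`, and for the clustering method the merged `partition`.
#' @export
analyze_sample <- function(sample, method = c("cluster", "manual", "both"),
                           config = default_config(), seed = 1L,
                           subgated = FALSE) {
  method <- match.arg(method)
  events <- if (inherits(sample, "synthetic_sample")) sample$events else sample
  stopifnot(inherits(events, "event_table"))
  pre <- pregate(events, config)
  gates <- pre$gates
  tr <- pre$transformed
  threshold <- .resolve_trbc1_threshold(tr, gates, config)
  if (method == "both") {
    return(list(
      cluster = .analyze_core(events, tr, gates, threshold, "cluster", config, seed, subgated),
      manual = .analyze_core(events, tr, gates, threshold, "manual", config, seed, subgated)
    ))
  }
  .analyze_core(events, tr, gates, threshold, method, config, seed, subgated)
}

.resolve_trbc1_threshold <- function(tr, gates, config) {
  fixed <- suppressWarnings(as.numeric(config$clonality$trbc1_threshold))
  if (length(fixed) == 1 && is.finite(fixed)) return(fixed)
  ref <- chan(tr, "TRBC1")[gates$masks$alphabeta_t]
  tryCatch(
    estimate_trbc1_threshold(ref),
    error = function(e) {
      warning("TRBC1 threshold estimation failed (", conditionMessage(e),
              "); falling back to the configured midpoint", call. = FALSE)
      default_thresholds(config$cofactor)[["TRBC1"]]
    }
  )
}

.call_row <- function(source, method, n, frac, verdict, size, mfi, lineage) {
  df <- data.frame(
    source = source, method = method, n_events = as.integer(n),
    trbc1_fraction = frac, verdict = verdict,
    size_pct_cd45 = size$pct_cd45, size_pct_cd3 = size$pct_cd3,
    lineage = lineage, stringsAsFactors = FALSE
  )
  for (m in names(mfi)) df[[m]] <- unname(mfi[[m]])
  df
}

.finalize_analysis <- function(calls, call_events, gates, threshold, config,
                               extra = list()) {
  if (nrow(calls)) {
    ref <- reference_profile(calls, config$classification$reference_min_events)
    calls$aberrancy_count <- NA_integer_
    calls$classification <- "none"
    for (i in seq_len(nrow(calls))) {
      if (calls$verdict[i] != "monotypic") next
      lin <- calls$lineage[i]
      if (is.null(ref[[lin]])) {
        warning("no polytypic ", lin, " reference in this sample; ",
                "classification skipped for ", calls$source[i], call. = FALSE)
        calls$classification[i] <- "none"
        next
      }
      ab <- score_aberrancy(unlist(calls[i, grep("^mfi_", names(calls))]),
                            ref[[lin]], config$classification$loss_ratio)
      calls$aberrancy_count[i] <- ab$count
      calls$classification[i] <- classify_population(
        calls$verdict[i], ab$count, calls$size_pct_cd45[i],
        config$classification)
    }
  } else {
    calls$aberrancy_count <- integer(0)
    calls$classification <- character(0)
  }
  structure(c(list(calls = calls, call_events = call_events, gates = gates,
                   threshold = threshold,
                   cd45_total = sum(gates$masks$cd45_positive),
                   cd3_total = sum(gates$masks$t_cells)),
              extra),
            class = "trbc_analysis")
}

#' @export
print.trbc_analysis <- function(x, ...) {
  cat("trbc_analysis (", x$method, "): ", x$cd45_total, " CD45+, ",
      x$cd3_total, " CD3+ events; TRBC1 threshold ",
      round(x$threshold, 3), "\n", sep = "")
  mono <- x$calls[x$calls$verdict == "monotypic", , drop = FALSE]
  cat(nrow(x$calls), "population calls,", nrow(mono), "monotypic\n")
  if (nrow(mono)) {
    print(mono[, c("source", "n_events", "trbc1_fraction", "verdict",
                   "size_pct_cd45", "lineage", "classification")])
  }
  invisible(x)
}

.analyze_core <- function(events, tr, gates, threshold, method, config, seed,
                          subgated = FALSE) {
  cd45_total <- sum(gates$masks$cd45_positive)
  cd3_total <- sum(gates$masks$t_cells)
  params <- config$clonality
  if (method == "cluster") {
    mask <- gates$masks$t_cells
    X <- clustering_matrix(tr, config)[mask, , drop = FALSE]
    g <- build_knn_graph(X, config$clustering$kappa,
                         config$clustering$brute_threshold)
    g <- jaccard_weights(g)
    part <- louvain_communities(g, seed = seed)
    part <- cluster_profiles(part, tr, events, mask, threshold, config)
    part <- merge_overclustered(part, tr, events, threshold,
                                config$clustering$merge_tolerance, config)
    idx_gate <- which(mask)
    pr <- part$profiles
    calls <- list(); call_events <- list()
    for (i in seq_len(nrow(pr))) {
      if (pr$tcrgd_positive[i]) next   # gamma-delta clusters: no TRBC1 call
      ev <- idx_gate[part$assignment == pr$cluster[i]]
      verdict <- if (pr$n[i] < params$min_events) "not_assessed"
        else if (pr$trbc1_fraction[i] < params$lower_bound ||
                 pr$trbc1_fraction[i] > params$upper_bound) "monotypic"
        else "polytypic"
      med <- part$medians[i, ]
      lin <- assign_lineage(med[["CD4"]], med[["CD8"]],
                            config$thresholds[["CD4"]],
                            config$thresholds[["CD8"]])
      mfi <- unlist(pr[i, grep("^mfi_", names(pr))])
      calls[[length(calls) + 1L]] <- .call_row(
        paste0("cluster_", pr$cluster[i]), "cluster", pr$n[i],
        pr$trbc1_fraction[i], verdict,
        population_size(pr$n[i], cd45_total, cd3_total), mfi, lin)
      call_events[[length(call_events) + 1L]] <- ev
    }
    calls <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
    return(.finalize_analysis(calls, call_events, gates, threshold, config,
                              extra = list(method = "cluster", partition = part)))
  }

  # manual baseline
  subsets <- quadrant_subsets(tr, gates$masks$alphabeta_t,
                              config$thresholds[["CD4"]],
                              config$thresholds[["CD8"]])
  lineage_of <- c(cd4_pos = "CD4+", cd8_pos = "CD8+",
                  double_positive = "double_positive",
                  double_negative = "double_negative")
  if (subgated) {
    sg <- assess_subsets_subgated(tr, subsets, threshold,
                                  config$thresholds, params)
    assess <- sg$assessments
    masks <- sg$masks
  } else {
    assess <- assess_subsets(tr, subsets, threshold, params)
    masks <- subsets[assess$subset]
  }
  calls <- list(); call_events <- list()
  for (i in seq_len(nrow(assess))) {
    m <- masks[[i]]
    n <- assess$n_events[i]
    if (n == 0) next
    mfi <- compute_mfi(events, m)
    names(mfi) <- paste0("mfi_", names(mfi))
    src <- if (!is.null(assess$marker)) {
      paste0(assess$subset[i], "/", assess$marker[i])
    } else assess$subset[i]
    calls[[length(calls) + 1L]] <- .call_row(
      src, "manual", n, assess$trbc1_fraction[i], assess$verdict[i],
      population_size(n, cd45_total, cd3_total), mfi,
      lineage_of[[assess$subset[i]]])
    call_events[[length(call_events) + 1L]] <- which(m)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
  .finalize_analysis(calls, call_events, gates, threshold, config,
                     extra = list(method = "manual", subsets = subsets))
}

.empty_calls <- function() {
  df <- data.frame(source = character(0), method = character(0),
                   n_events = integer(0), trbc1_fraction = numeric(0),
                   verdict = character(0), size_pct_cd45 = numeric(0),
                   size_pct_cd3 = numeric(0), lineage = character(0),
                   stringsAsFactors = FALSE)
  for (m in c("CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD45")) {
    df[[paste0("mfi_", m)]] <- numeric(0)
  }
  df
}

#' Population-call table of an analysis
#'
#' @param analysis a `trbc_analysis`.
#' @return the calls data.frame (schema version 1: source, method,
#'   n_events, trbc1_fraction, verdict, size_pct_cd45, size_pct_cd3,
#'   lineage, mfi_CD2..mfi_CD45, aberrancy_count, classification).
#' @export
population_calls <- function(analysis) {
  stopifnot(inherits(analysis, "trbc_analysis"))
  analysis$calls
}
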