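#' CD4/CD8 quadrant subsets of the alpha-beta T cells
#'
#' The four disjoint masks (CD4+, CD8+, double-positive, double-negative)
#' partition the alpha-beta T-cell gate exactly.
#'
#' @param events transformed [event_table()].
#' @param alphabeta_t logical mask of CD3+ TCRgd- events.
#' @param cd4_threshold,cd8_threshold transformed-scale positivity
#'   thresholds.
#' @return named list of four logical masks.
#' @export
quadrant_subsets <- function(events, alphabeta_t,
                             cd4_threshold = default_thresholds()[["CD4"]],
                             cd8_threshold = default_thresholds()[["CD8"]]) {
  stopifnot(inherits(events, "event_table"), events$transformed)
  cd4 <- chan(events, "CD4") > cd4_threshold
  cd8 <- chan(events, "CD8") > cd8_threshold
  list(
    cd4_pos = alphabeta_t & cd4 & !cd8,
    cd8_pos = alphabeta_t & !cd4 & cd8,
    double_positive = alphabeta_t & cd4 & cd8,
    double_negative = alphabeta_t & !cd4 & !cd8
  )
}

#' Subset-level TRBC1 assessment (the manual-gating baseline)
#'
#' Each quadrant subset with at least `min_events` events is assessed as a
#' whole against the 15%/85% rule. This deliberately emulates subset-level
#' manual analysis without operator sub-gating: a small clone blended into a
#' large polyclonal quadrant leaves the subset fraction near the polyclonal
#' value and is missed, which is exactly the failure mode the clustering
#' pipeline addresses.
#'
#' @param events transformed [event_table()].
#' @param subsets list of masks from [quadrant_subsets()].
#' @param threshold TRBC1 positivity threshold (transformed scale).
#' @param params clonality parameter block (bounds, `min_events`).
#' @return data.frame of subset assessments: `subset`, `n_events`,
#'   `trbc1_fraction`, `assessed`, `verdict`.
#' @export
assess_subsets <- function(events, subsets, threshold,
                           params = default_config()$clonality) {
  rows <- lapply(names(subsets), function(nm) {
    cl <- call_clonality(events, subsets[[nm]], threshold, params)
    data.frame(subset = nm, n_events = cl$n_events,
               trbc1_fraction = cl$trbc1_fraction,
               assessed = cl$verdict != "not_assessed",
               verdict = cl$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Marker-loss sub-gated manual assessment (revised-analysis emulation)
#'
#' Experienced operators inspect N x N dot plots and will sub-gate a
#' marker-negative subpopulation inside a quadrant before assessing TRBC1;
#' a revised manual re-analysis typically recovers populations first found
#' algorithmically exactly this way. This emulation splits each quadrant on
#' each aberrancy marker (CD2, CD5, CD7 negativity and dim CD3) and
#' assesses every resulting sub-gate with at least `min_events` events. It
#' is intended for concordance experiments, not as the primary baseline.
#'
#' @inheritParams assess_subsets
#' @param thresholds named transformed-scale marker thresholds.
#' @return list with `assessments` (data.frame as [assess_subsets()], plus
#'   a `marker` column) and `masks` (list of logical masks per row).
#' @export
assess_subsets_subgated <- function(events, subsets, threshold,
                                    thresholds = default_thresholds(),
                                    params = default_config()$clonality) {
  rows <- list()
  masks <- list()
  for (nm in names(subsets)) {
    candidates <- list(whole = subsets[[nm]])
    for (m in c("CD2", "CD5", "CD7")) {
      candidates[[paste0(m, "_neg")]] <-
        subsets[[nm]] & chan(events, m) <= thresholds[[m]]
    }
    candidates[["CD3_dim"]] <- subsets[[nm]] &
      chan(events, "CD3") <= thresholds[["CD3"]] + 1 &
      chan(events, "CD3") > thresholds[["CD3"]] - 1
    for (cand in names(candidates)) {
      cl <- call_clonality(events, candidates[[cand]], threshold, params)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, marker = cand, n_events = cl$n_events,
        trbc1_fraction = cl$trbc1_fraction,
        assessed = cl$verdict != "not_assessed",
        verdict = cl$verdict, stringsAsFactors = FALSE)
      masks[[length(masks) + 1L]] <- candidates[[cand]]
    }
  }
  list(assessments = do.call(rbind, rows), masks = masks)
}
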