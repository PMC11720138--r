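#' Lineage assignment from population CD4/CD8 medians
#'
#' @param cd4_median,cd8_median population medians on the transformed scale.
#' @param cd4_threshold,cd8_threshold positivity thresholds.
#' @return one of `"CD4+"`, `"CD8+"`, `"double_positive"`,
#'   `"double_negative"`.
#' @export
assign_lineage <- function(cd4_median, cd8_median,
                           cd4_threshold = default_thresholds()[["CD4"]],
                           cd8_threshold = default_thresholds()[["CD8"]]) {
  cd4 <- cd4_median > cd4_threshold
  cd8 <- cd8_median > cd8_threshold
  if (cd4 && cd8) "double_positive"
  else if (cd4) "CD4+"
  else if (cd8) "CD8+"
  else "double_negative"
}

#' Reference profile of the polyclonal background
#'
#' Raw-scale MFIs of the polytypic (non-clonal) CD4+ and CD8+ populations of
#' the same sample, built only from sources with a polytypic verdict and at
#' least `min_events` events. Aberrancy in a monotypic population is always
#' judged against the lineage-matched polyclonal background of its own
#' sample.
#'
#' @param calls a population-call data.frame (see [population_calls()])
#'   including `verdict`, `lineage`, `n_events` and `mfi_*` columns.
#' @param min_events floor for a usable reference population.
#' @return named list with one MFI vector per lineage (possibly empty).
#' @export
reference_profile <- function(calls, min_events = 500) {
  mfi_cols <- grep("^mfi_", names(calls), value = TRUE)
  out <- list()
  for (lin in c("CD4+", "CD8+")) {
    rows <- calls$verdict == "polytypic" & calls$lineage == lin &
      calls$n_events >= min_events
    if (!any(rows)) next
    # weight by population size when several polytypic sources qualify
    w <- calls$n_events[rows]
    m <- as.matrix(calls[rows, mfi_cols, drop = FALSE])
    out[[lin]] <- setNames(colSums(m * w) / sum(w), mfi_cols)
  }
  out
}

#' Score antigen aberrancies against the polyclonal reference
#'
#' Ratios of population MFI to lineage-matched reference MFI for the T-cell
#' lineage antigens; expression loss is flagged when the ratio drops below
#' `loss_ratio`. The aberrancy count is the number of flagged markers among
#' CD2, CD3, CD5 and CD7.
#'
#' @param mfi named population MFI vector (`mfi_*` names).
#' @param ref reference MFI vector of the matching lineage.
#' @param loss_ratio loss flag cutoff (default 0.25).
#' @return list with `ratios`, `loss` (logical), and `count`.
#' @export
score_aberrancy <- function(mfi, ref, loss_ratio = 0.25) {
  markers <- paste0("mfi_", c("CD2", "CD3", "CD5", "CD7"))
  ratios <- mfi[markers] / ref[markers]
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("aberrancy ratios must be positive and finite", call. = FALSE)
  }
  loss <- ratios < loss_ratio
  list(ratios = ratios, loss = loss, count = sum(loss))
}

#' Heuristic lymphoma-like vs T-CUS-like classification
#'
#' A declared convention, not a clinical rule: a monotypic population is
#' called lymphoma-like when it carries at least
#' `lymphoma_min_aberrancies` (2) aberrant lineage markers, or one aberrancy
#' together with a size of at least
#' `lymphoma_single_aberrancy_min_size_pct` (5) percent of CD45+ events;
#' anything else is T-CUS-like. Deterministic and order-independent.
#'
#' @param verdict clonality verdict of the population.
#' @param aberrancy_count number of flagged lineage markers.
#' @param size_pct_cd45 population size, percent of CD45+ events.
#' @param params classification block of [default_config()].
#' @return `"lymphoma_like"`, `"t_cus_like"`, or `"none"` for non-monotypic
#'   populations.
#' @export
classify_population <- function(verdict, aberrancy_count, size_pct_cd45,
                                params = default_config()$classification) {
  if (!identical(verdict, "monotypic")) return("none")
  if (is.na(aberrancy_count)) return("t_cus_like")
  if (aberrancy_count >= params$lymphoma_min_aberrancies ||
      (aberrancy_count >= 1 &&
       size_pct_cd45 >= params$lymphoma_single_aberrancy_min_size_pct)) {
    "lymphoma_like"
  } else {
    "t_cus_like"
  }
}

#' Confusion matrix of the classification heuristic on labelled data
#'
#' @param calls population-call data.frame with a `classification` column.
#' @param truth_class character vector of matched ground-truth classes
#'   (`"lymphoma"` / `"t_cus"`), one per call row.
#' @return a table of truth vs heuristic classification.
#' @export
classification_confusion <- function(calls, truth_class) {
  stopifnot(nrow(calls) == length(truth_class))
  table(truth = truth_class, classified = calls$classification)
}
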