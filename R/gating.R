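#' Arcsinh-transform fluorescence channels
#'
#' Replaces every fluorescence channel by `asinh(x / cofactor)`; scatter
#' channels (per the panel definition) are left untouched. The transform is
#' the analysis scale for thresholds, clustering distances and mixture
#' modelling; raw values are kept for MFI reporting by working on copies.
#'
#' @param events an [event_table()] on the raw scale.
#' @param cofactor positive arcsinh cofactor; 150 is the conventional choice
#'   for this generation of flow instruments.
#' @return A transformed [event_table()].
#' @export
#' @examples
#' s <- generate_sample(default_sample_spec(total_cd45_events = 1000))
#' tr <- transform_intensities(s$events)
transform_intensities <- function(events, cofactor = 150) {
  stopifnot(inherits(events, "event_table"))
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop("cofactor must be a positive scalar", call. = FALSE)
  }
  if (events$transformed) {
    stop("events are already transformed", call. = FALSE)
  }
  fluoro <- setdiff(events$panel$channels, events$panel$scatter)
  ex <- events$exprs
  ex[, fluoro] <- asinh(ex[, fluoro] / cofactor)
  event_table(ex, events$panel, transformed = TRUE, cofactor = cofactor)
}

#' Gate set
#'
#' Named boolean event masks with a parent relation; child masks are always
#' intersected with their parent, so gate-tree containment holds by
#' construction.
#'
#' @param n number of events.
#' @return A `gate_set` object.
#' @keywords internal
new_gate_set <- function(n) {
  structure(list(masks = list(all = rep(TRUE, n)),
                 parents = c(all = NA_character_)),
            class = "gate_set")
}

add_gate <- function(gates, name, mask, parent) {
  stopifnot(parent %in% names(gates$masks))
  gates$masks[[name]] <- mask & gates$masks[[parent]]
  gates$parents[[name]] <- parent
  gates
}

#' @export
print.gate_set <- function(x, ...) {
  print(gate_summary(x))
  invisible(x)
}

#' Gating summary table
#'
#' @param gates a `gate_set`.
#' @return data.frame with gate name, parent, event count and percent of
#'   parent (3 decimals).
#' @export
gate_summary <- function(gates) {
  nm <- names(gates$masks)
  n <- vapply(gates$masks, sum, numeric(1))
  parent <- gates$parents[nm]
  pn <- ifelse(is.na(parent), n, n[ifelse(is.na(parent), nm, parent)])
  data.frame(
    gate = nm, parent = unname(parent), events = unname(n),
    pct_of_parent = round(100 * unname(n) / pmax(unname(pn), 1), 3),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Viability and singlet gates
#'
#' Emulates the first two plots of the conventional analysis: an FSC-A vs
#' SSC-A box excluding the low-scatter debris corner, then doublet exclusion
#' on the FSC-H / FSC-A ratio (coincident events have roughly additive area
#' but near-singlet height, halving the ratio).
#'
#' @param events [event_table()] (raw or transformed; scatter is raw either
#'   way).
#' @param scatter_box list with numeric `fsc` and `ssc` ranges
#'   (`c(lo, hi)`).
#' @param hw_ratio_min minimum FSC-H / FSC-A ratio for singlets.
#' @return A `gate_set` with `viable` and `singlet` gates.
#' @export
gate_viable_singlets <- function(events,
                                 scatter_box = default_scatter_box(),
                                 hw_ratio_min = 0.6) {
  stopifnot(inherits(events, "event_table"))
  fsc_a <- chan(events, "FSC-A")
  fsc_h <- chan(events, "FSC-H")
  ssc_a <- chan(events, "SSC-A")
  gates <- new_gate_set(length(fsc_a))
  viable <- fsc_a >= scatter_box$fsc[1] & fsc_a <= scatter_box$fsc[2] &
    ssc_a >= scatter_box$ssc[1] & ssc_a <= scatter_box$ssc[2]
  if (!any(viable)) {
    warning("viable gate is empty; downstream gates will be empty", call. = FALSE)
  }
  gates <- add_gate(gates, "viable", viable, "all")
  gates <- add_gate(gates, "singlet", fsc_h / fsc_a >= hw_ratio_min, "viable")
  gates
}

#' @rdname gate_viable_singlets
#' @export
default_scatter_box <- function() {
  # calibrated against the generator's lymphocyte / debris scatter levels;
  # real-data use requires operator-supplied coordinates
  list(fsc = c(30000, 450000), ssc = c(0, 250000))
}

#' Lineage gates
#'
#' Sequential lineage identification under CD45: T cells (CD3+), B cells
#' (CD19+), NK cells (CD3- CD7+) and the alpha-beta T-cell analysis
#' population (CD3+ TCRgd-), in which alone TRBC1 is ever assessed.
#'
#' @param events transformed [event_table()].
#' @param gates `gate_set` holding the `singlet` gate.
#' @param thresholds named numeric vector of positivity thresholds on the
#'   transformed scale; must name CD45, CD3, CD19, CD7 and TCRgd. See
#'   [default_thresholds()].
#' @param min_cd45_events acquisition floor; a warning is raised when fewer
#'   CD45-positive events were recorded.
#' @return The extended `gate_set`.
#' @export
gate_lineages <- function(events, gates, thresholds = default_thresholds(),
                          min_cd45_events = 50000) {
  stopifnot(inherits(events, "event_table"), events$transformed)
  need <- c("CD45", "CD3", "CD19", "CD7", "TCRgd")
  if (!all(need %in% names(thresholds))) {
    stop("thresholds must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  cd45 <- chan(events, "CD45") > thresholds[["CD45"]]
  cd3 <- chan(events, "CD3") > thresholds[["CD3"]]
  cd19 <- chan(events, "CD19") > thresholds[["CD19"]]
  cd7 <- chan(events, "CD7") > thresholds[["CD7"]]
  gd <- chan(events, "TCRgd") > thresholds[["TCRgd"]]
  gates <- add_gate(gates, "cd45_positive", cd45, "singlet")
  n45 <- sum(gates$masks$cd45_positive)
  if (n45 < min_cd45_events) {
    warning(sprintf("only %d CD45-positive events (minimum acquisition %d)",
                    n45, min_cd45_events), call. = FALSE)
  }
  gates <- add_gate(gates, "t_cells", cd3, "cd45_positive")
  gates <- add_gate(gates, "b_cells", cd19, "cd45_positive")
  gates <- add_gate(gates, "nk_cells", !cd3 & cd7, "cd45_positive")
  gates <- add_gate(gates, "alphabeta_t", !gd, "t_cells")
  gates
}

#' Default marker positivity thresholds
#'
#' Midpoints, on the arcsinh scale, between the generator's negative and
#' positive staining levels for each marker. These reproduce what an
#' operator would draw between the two visually separated modes; real-data
#' use requires user-supplied values.
#'
#' @param cofactor arcsinh cofactor matching [transform_intensities()].
#' @return Named numeric vector of transformed-scale thresholds.
#' @export
default_thresholds <- function(cofactor = 150) {
  lv <- generator_levels()
  pos <- c(lv$pos, TRBC1 = lv$trbc1_pos)
  neg <- asinh(lv$neg / cofactor)
  setNames((asinh(pos / cofactor) + neg) / 2, names(pos))
}

#' Full pre-gating chain
#'
#' Convenience wrapper: viability and singlet gates on the raw events,
#' then lineage gates on the transformed events.
#'
#' @inheritParams gate_lineages
#' @inheritParams gate_viable_singlets
#' @param events raw [event_table()].
#' @param config a [default_config()] list.
#' @return list with `gates` (`gate_set`) and `transformed`
#'   ([event_table()]).
#' @export
pregate <- function(events, config = default_config()) {
  tr <- transform_intensities(events, config$cofactor)
  gates <- gate_viable_singlets(events, config$scatter_box, config$hw_ratio_min)
  gates <- gate_lineages(tr, gates, config$thresholds, config$min_cd45_events)
  list(gates = gates, transformed = tr)
}
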