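#' Panel definition
#'
#' Describes the channel layout of the TRBC1 tube: three scatter parameters
#' and ten antibodies. The clustering subset is the ten channels used for the
#' graph-based analysis (scatter plus the T-cell antigens); it deliberately
#' excludes FSC-H (only used for doublet exclusion), CD19 (B-cell lineage
#' gate only) and TRBC1 itself, so that clonality is never allowed to drive
#' cluster formation.
#'
#' @param channels character vector of unique channel names.
#' @param clustering character vector, subset of `channels`, used as the
#'   feature space for the kNN graph. Must not contain `"TRBC1"`.
#' @param scatter character vector of scatter channels (left untransformed
#'   by [transform_intensities()]).
#'
#' @return An object of class `panel_definition`.
#' @export
#' @examples
#' p <- default_panel()
#' p$clustering
panel_definition <- function(channels, clustering, scatter = c("FSC-A", "FSC-H", "SSC-A")) {
  if (anyDuplicated(channels)) {
    stop("panel channel names must be unique", call. = FALSE)
  }
  if (!all(clustering %in% channels)) {
    stop("clustering subset must be a subset of the panel channels", call. = FALSE)
  }
  if (!"TRBC1" %in% channels) {
    stop("panel must contain a TRBC1 channel", call. = FALSE)
  }
  if ("TRBC1" %in% clustering) {
    stop("TRBC1 must never be part of the clustering subset", call. = FALSE)
  }
  if (!all(scatter %in% channels)) {
    stop("scatter channels must be part of the panel", call. = FALSE)
  }
  structure(
    list(channels = channels, clustering = clustering, scatter = scatter),
    class = "panel_definition"
  )
}

#' @rdname panel_definition
#' @export
default_panel <- function() {
  panel_definition(
    channels = c(
      "FSC-A", "FSC-H", "SSC-A",
      "CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD19", "CD45",
      "TCRgd", "TRBC1"
    ),
    clustering = c(
      "FSC-A", "SSC-A",
      "CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD45", "TCRgd"
    )
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("panel_definition:", length(x$channels), "channels\n")
  cat("  channels:  ", paste(x$channels, collapse = ", "), "\n")
  cat("  clustering:", paste(x$clustering, collapse = ", "), "\n")
  invisible(x)
}

#' Event table
#'
#' A thin container for an events-by-channels intensity matrix plus its
#' [panel_definition()]. Values are raw linear intensities unless
#' `transformed` is `TRUE`, in which case fluorescence channels hold
#' `asinh(x / cofactor)` values (see [transform_intensities()]).
#'
#' @param exprs numeric matrix, events in rows, channels in columns. Column
#'   names must match the panel channel order.
#' @param panel a [panel_definition()].
#' @param transformed logical flag.
#' @param cofactor the arcsinh cofactor used, `NA` when raw.
#'
#' @return An object of class `event_table`.
#' @export
event_table <- function(exprs, panel = default_panel(), transformed = FALSE,
                        cofactor = NA_real_) {
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs))) {
    if (ncol(exprs) != length(panel$channels)) {
      stop("unnamed intensity matrix does not match panel width", call. = FALSE)
    }
    colnames(exprs) <- panel$channels
  }
  if (!identical(colnames(exprs), panel$channels)) {
    missing <- setdiff(panel$channels, colnames(exprs))
    if (length(missing)) {
      stop("missing required channel(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    exprs <- exprs[, panel$channels, drop = FALSE]
  }
  if (!all(is.finite(exprs))) {
    stop("event intensities must be finite", call. = FALSE)
  }
  structure(
    list(exprs = exprs, panel = panel, transformed = transformed,
         cofactor = cofactor),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table:", nrow(x$exprs), "events x", ncol(x$exprs), "channels (",
      if (x$transformed) sprintf("arcsinh, cofactor %g", x$cofactor) else "raw",
      ")\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$exprs)

n_events <- function(events) nrow(events$exprs)

chan <- function(events, name) {
  if (!name %in% colnames(events$exprs)) {
    stop("missing required channel(s): ", name, call. = FALSE)
  }
  events$exprs[, name]
}
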