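#' Read and write event tables
#'
#' Two encodings of the same matrix: delimited text (CSV, one column per
#' channel, header row of channel names) and minimal FCS 3.1 (list-mode,
#' little-endian, DATATYPE D by default so values round-trip exactly;
#' DATATYPE F files are also read). Channels are mapped by `$PnN` name (FCS)
#' or column name (CSV); event order is preserved.
#'
#' @param events an [event_table()] (raw scale).
#' @param path output path; format chosen by extension (`.fcs` vs anything
#'   else = CSV).
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   [event_table()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    .write_fcs(events$exprs, path)
  } else {
    data.table::fwrite(data.table::as.data.table(events$exprs), path)
  }
  invisible(path)
}

#' @rdname write_events
#' @param panel expected [panel_definition()].
#' @export
read_events <- function(path, panel = default_panel()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  X <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    .read_fcs(path)
  } else {
    as.matrix(data.table::fread(path))
  }
  missing <- setdiff(panel$channels, colnames(X))
  if (length(missing)) {
    stop("file ", path, " is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  event_table(X[, panel$channels, drop = FALSE], panel)
}

# --- minimal FCS 3.1 ------------------------------------------------------
# HEADER (58 bytes) + TEXT (primary, keyword/value with '/' delimiter) +
# DATA (contiguous list mode). Only what this package writes is supported:
# $MODE L, $BYTEORD 1,2,3,4, $DATATYPE D or F. Offsets wider than the
# 8-char header fields fall back to the $BEGINDATA/$ENDDATA keywords, as
# FCS 3.1 prescribes.

.write_fcs <- function(X, path) {
  n <- nrow(X); p <- ncol(X)
  bytes_per <- 8L
  text_start <- 256L
  make_text <- function(begin, end) {
    kw <- c(
      "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
      "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
      "$BEGINDATA", formatC(begin, width = 12, flag = "0", format = "d"),
      "$ENDDATA", formatC(end, width = 12, flag = "0", format = "d"),
      "$BYTEORD", "1,2,3,4", "$DATATYPE", "D", "$MODE", "L",
      "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p)
    )
    for (j in seq_len(p)) {
      kw <- c(kw,
              sprintf("$P%dN", j), colnames(X)[j],
              sprintf("$P%dB", j), "64",
              sprintf("$P%dE", j), "0,0",
              sprintf("$P%dR", j), format(2^19, scientific = FALSE))
    }
    paste0("/", paste(kw, collapse = "/"), "/")
  }
  # offsets are written at a fixed 12-digit width, so the TEXT length is
  # independent of their values and can be computed in one dry run
  text_len <- nchar(make_text(0, 0))
  data_start <- text_start + text_len
  data_end <- data_start + bytes_per * n * p - 1
  text <- make_text(data_start, data_end)
  hdr_off <- function(x) formatC(x, width = 8, flag = " ")
  text_end <- text_start + text_len - 1L
  header <- paste0(
    "FCS3.1    ",
    hdr_off(text_start), hdr_off(text_end),
    # data offsets go in the header when they fit in 8 characters
    hdr_off(if (data_end <= 99999999) data_start else 0),
    hdr_off(if (data_end <= 99999999) data_end else 0),
    hdr_off(0), hdr_off(0)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(strrep(" ", text_start - nchar(header)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(X)), con, size = bytes_per, endian = "little")
  invisible(path)
}

.read_fcs <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.1") {
    stop("not an FCS 3.1 file (offset 0): ", path, call. = FALSE)
  }
  off <- suppressWarnings(as.integer(substring(header,
                                               10 + 8 * (0:5) + 1,
                                               10 + 8 * (1:6))))
  if (any(is.na(off[1:2]))) {
    stop("malformed FCS header (offsets at byte 10)", call. = FALSE)
  }
  seek(con, off[1])
  text <- readChar(con, off[2] - off[1] + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- setNames(vals, toupper(trimws(keys)))
  need <- c("$TOT", "$PAR", "$DATATYPE", "$MODE", "$BYTEORD")
  if (!all(need %in% names(kw))) {
    stop("malformed FCS TEXT segment (offset ", off[1], "): missing ",
         paste(setdiff(need, names(kw)), collapse = ", "), call. = FALSE)
  }
  if (kw[["$MODE"]] != "L") stop("only list-mode FCS is supported", call. = FALSE)
  if (!kw[["$DATATYPE"]] %in% c("D", "F")) {
    stop("only DATATYPE D or F is supported, got ", kw[["$DATATYPE"]], call. = FALSE)
  }
  if (kw[["$BYTEORD"]] != "1,2,3,4") {
    stop("only little-endian FCS is supported", call. = FALSE)
  }
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  data_start <- off[3]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
  }
  bytes <- if (kw[["$DATATYPE"]] == "D") 8L else 4L
  if (data_start + bytes * n * p - 1 > sz) {
    stop("malformed FCS: data segment at offset ", data_start,
         " extends past end of file", call. = FALSE)
  }
  seek(con, data_start)
  v <- readBin(con, "double", n = n * p, size = bytes, endian = "little")
  X <- matrix(v, nrow = n, ncol = p, byrow = TRUE)
  colnames(X) <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]],
                        character(1))
  X
}

#' Write / read a ground-truth sidecar table
#'
#' TSV with columns event_index, population_id, trbc1_state, is_debris,
#' is_doublet, is_cd45.
#'
#' @param truth truth data.frame of a `synthetic_sample`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  out <- cbind(event_index = seq_len(nrow(truth)), truth)
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  df$event_index <- NULL
  df$trbc1_state <- as.character(df$trbc1_state)
  df$population_id <- as.character(df$population_id)
  df
}

#' Serialise a sample specification
#'
#' JSON round-trip of a [sample_spec()] so that `simulate` runs are fully
#' described by a text file.
#'
#' @param spec a [sample_spec()].
#' @param path file path.
#' @export
write_sample_spec <- function(spec, path) {
  pops <- lapply(spec$populations, function(p) {
    Filter(Negate(is.null),
           list(name = p$name, n_events = p$n_events,
                fraction_of_cd45 = p$fraction_of_cd45,
                means = as.list(p$means), cvs = as.list(p$cvs),
                trbc1_mode = p$trbc1_mode, trbc1_p = p$trbc1_p,
                stain_error = p$stain_error, truth_class = p$truth_class))
  })
  jsonlite::write_json(
    list(populations = pops,
         total_cd45_events = spec$total_cd45_events,
         debris_fraction = spec$debris_fraction,
         doublet_fraction = spec$doublet_fraction,
         non_cd45_fraction = spec$non_cd45_fraction,
         seed = spec$seed),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_sample_spec
#' @export
read_sample_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nul <- function(x) if (is.null(x) || (is.list(x) && !length(x))) NULL else x
  pops <- lapply(j$populations, function(p) {
    population_spec(
      name = p$name, n_events = nul(p$n_events),
      fraction_of_cd45 = nul(p$fraction_of_cd45),
      means = unlist(p$means), cvs = if (length(p$cvs)) unlist(p$cvs) else numeric(),
      trbc1_mode = p$trbc1_mode, trbc1_p = p$trbc1_p,
      stain_error = p$stain_error, truth_class = p$truth_class)
  })
  sample_spec(pops, total_cd45_events = j$total_cd45_events,
              debris_fraction = j$debris_fraction,
              doublet_fraction = j$doublet_fraction,
              non_cd45_fraction = j$non_cd45_fraction,
              seed = j$seed)
}

#' Write an analysis report
#'
#' Population-call TSV (percentages to 3 decimals, preserving sizes like
#' 0.014%), a JSON summary whose totals equal the TSV row aggregates, a
#' gating-summary TSV, and optionally QC t-SNE figures coloured by cluster
#' and by TRBC1 state.
#'
#' @param analysis a `trbc_analysis`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param qc_plots draw t-SNE QC PNGs (slow; off by default).
#' @param transformed transformed [event_table()], required for
#'   `qc_plots`.
#' @param config a [default_config()] (for `qc_plots`).
#' @return invisibly, the paths written.
#' @export
write_report <- function(analysis, dir, name = "sample", qc_plots = FALSE,
                         transformed = NULL, config = default_config()) {
  stopifnot(inherits(analysis, "trbc_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  calls <- analysis$calls
  for (cl in c("size_pct_cd45", "size_pct_cd3")) {
    calls[[cl]] <- round(calls[[cl]], 3)
  }
  calls$trbc1_fraction <- round(calls$trbc1_fraction, 5)
  calls_path <- file.path(dir, paste0(name, "_calls.tsv"))
  data.table::fwrite(calls, calls_path, sep = "\t", na = "NA")
  gating_path <- file.path(dir, paste0(name, "_gating.tsv"))
  data.table::fwrite(gate_summary(analysis$gates), gating_path, sep = "\t")
  summary <- list(
    schema_version = 1L,
    method = analysis$method,
    trbc1_threshold = analysis$threshold,
    cd45_total = analysis$cd45_total,
    cd3_total = analysis$cd3_total,
    n_calls = nrow(calls),
    n_monotypic = sum(calls$verdict == "monotypic"),
    n_polytypic = sum(calls$verdict == "polytypic"),
    n_not_assessed = sum(calls$verdict == "not_assessed")
  )
  json_path <- file.path(dir, paste0(name, "_summary.json"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(calls_path, gating_path, json_path)
  if (qc_plots) {
    if (is.null(transformed) || is.null(analysis$partition)) {
      stop("qc_plots requires the transformed events and a clustering analysis",
           call. = FALSE)
    }
    part <- analysis$partition
    X <- clustering_matrix(transformed, config)[part$mask, , drop = FALSE]
    Y <- embed_qc(X, config$clustering$perplexity,
                  config$clustering$iterations, seed = 1L)
    png_path <- file.path(dir, paste0(name, "_tsne.png"))
    grDevices::png(png_path, width = 1200, height = 600)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::plot(Y, col = part$assignment, pch = 16, cex = 0.4,
                   xlab = "tSNE1", ylab = "tSNE2", main = "clusters")
    trbc1_pos <- chan(transformed, "TRBC1")[part$mask] > analysis$threshold
    graphics::plot(Y, col = ifelse(trbc1_pos, "firebrick", "grey60"),
                   pch = 16, cex = 0.4, xlab = "tSNE1", ylab = "tSNE2",
                   main = "TRBC1 state")
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
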