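#' Run configuration
#'
#' Every constant consumed by the pipeline in one place: transform cofactors,
#' gate geometry, marker thresholds, clustering parameters (kappa defaults to
#' 40, the re-analysis value being 20), the 15%/85% clonality rule with its
#' 50-event floor, classification constants and the PCR oracle detection
#' limit (1% of all nucleated events).
#'
#' @return A nested named list of class `trbc_config`.
#' @export
default_config <- function() {
  structure(list(
    cofactor = 150,
    scatter_cofactor = 30000,
    scatter_box = default_scatter_box(),
    hw_ratio_min = 0.6,
    thresholds = default_thresholds(),
    min_cd45_events = 50000,
    clustering = list(
      kappa = 40L,
      perplexity = 30,
      iterations = 1000L,
      merge_tolerance = 0.8,
      brute_threshold = 2048L,
      seed = 1L
    ),
    clonality = list(
      lower_bound = 0.15,
      upper_bound = 0.85,
      min_events = 50L,
      trbc1_threshold = NA_real_   # NA = estimate per sample from the data
    ),
    classification = list(
      loss_ratio = 0.25,
      lymphoma_min_aberrancies = 2L,
      lymphoma_single_aberrancy_min_size_pct = 5,
      reference_min_events = 500L
    ),
    pcr = list(
      detection_limit_pct_total = 1,
      miss_prob = 0
    )
  ), class = "trbc_config")
}

#' Read / write a configuration file
#'
#' JSON serialisation that round-trips exactly
#' (write -> read -> write is byte-identical).
#'
#' @param config a `trbc_config` list.
#' @param path file path.
#' @return `read_config` returns the `trbc_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$thresholds <- as.list(cfg$thresholds)   # keep channel names in JSON
  # digits = I(17) so doubles survive the text round trip bit-exactly;
  # na = "null" so the NA threshold sentinel round-trips (not the string "NA")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  cfg <- modifyList(unclass(cfg), raw, keep.null = TRUE)
  cfg$thresholds <- unlist(cfg$thresholds)
  cfg$scatter_box <- lapply(cfg$scatter_box, as.numeric)
  for (f in c("kappa", "iterations", "brute_threshold", "seed")) {
    cfg$clustering[[f]] <- as.integer(cfg$clustering[[f]])
  }
  if (is.null(cfg$clonality$trbc1_threshold)) {
    cfg$clonality$trbc1_threshold <- NA_real_   # JSON null round-trips to NA
  }
  cfg$clonality$min_events <- as.integer(cfg$clonality$min_events)
  cfg$classification$lymphoma_min_aberrancies <-
    as.integer(cfg$classification$lymphoma_min_aberrancies)
  cfg$classification$reference_min_events <-
    as.integer(cfg$classification$reference_min_events)
  structure(cfg, class = "trbc_config")
}
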