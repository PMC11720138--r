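#' Deterministic PCR clonality oracle
#'
#' Emulates the ~1% sensitivity of multiplex PCR clonality assays: a clone
#' is detected iff its events account for at least
#' `detection_limit_pct_total` percent of ALL nucleated events in the tube.
#' The denominator includes CD45-negative nucleated events (erythroblast-like
#' dilution) and doublets, but not debris; this is the mechanism by which a
#' clone above 1% of CD45+ events can still sit below the PCR limit in a
#' dilute marrow. Optionally each clone is missed outright with probability
#' `miss_prob` (primer coverage failure; default 0, keeping the oracle
#' deterministic).
#'
#' @param sample a `synthetic_sample` (truth labels identify the clonal
#'   populations: `truth_class` of `"lymphoma"` or `"t_cus"`).
#' @param detection_limit_pct_total detection limit, percent of nucleated
#'   events.
#' @param miss_prob per-clone miss probability.
#' @param seed seed used only when `miss_prob > 0`.
#' @return data.frame per clone: `population`, `n_events`, `pct_total`,
#'   `detected`; attribute `any_detected`.
#' @export
pcr_oracle <- function(sample, detection_limit_pct_total = 1,
                       miss_prob = 0, seed = 1L) {
  stopifnot(inherits(sample, "synthetic_sample"))
  truth <- sample$truth
  nucleated <- sum(!truth$is_debris)
  clones <- vapply(sample$spec$populations, function(p) {
    p$truth_class %in% c("lymphoma", "t_cus")
  }, logical(1))
  pops <- sample$spec$populations[clones]
  if (!length(pops)) {
    out <- data.frame(population = character(0), n_events = integer(0),
                      pct_total = numeric(0), detected = logical(0))
    attr(out, "any_detected") <- FALSE
    return(out)
  }
  nm <- vapply(pops, `[[`, character(1), "name")
  n <- vapply(nm, function(x) sum(truth$population_id == x), numeric(1))
  pct <- 100 * n / nucleated
  detected <- pct >= detection_limit_pct_total
  if (miss_prob > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    detected <- detected & (runif(length(detected)) >= miss_prob)
  }
  out <- data.frame(population = nm, n_events = as.integer(n),
                    pct_total = pct, detected = detected,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "any_detected") <- any(out$detected)
  out
}

#' Did an analysis detect the spiked clone?
#'
#' A truth population counts as detected when some monotypic population call
#' overlaps at least `min_overlap` of the truth population's events.
#'
#' @param analysis a `trbc_analysis`.
#' @param truth truth data.frame of the sample.
#' @param population truth population id (default `"spike"`).
#' @param min_overlap required fraction of truth events covered by the call.
#' @return logical.
#' @export
spike_detected <- function(analysis, truth, population = "spike",
                           min_overlap = 0.5) {
  stopifnot(inherits(analysis, "trbc_analysis"))
  spike_idx <- which(truth$population_id == population)
  if (!length(spike_idx)) return(FALSE)
  mono <- which(analysis$calls$verdict == "monotypic")
  for (i in mono) {
    ov <- length(intersect(analysis$call_events[[i]], spike_idx)) /
      length(spike_idx)
    if (ov >= min_overlap) return(TRUE)
  }
  FALSE
}

#' Spike-in detection ladder
#'
#' Generates one sample per (size, seed) pair from `base`, runs the chosen
#' method, and records whether the spiked clone was detected. The smallest
#' size whose detection rate reaches `required_rate` is reported. With
#' `scan = "ascending"` sizes are visited from small to large and scanning
#' stops at the first size that reaches the required rate (which by
#' definition is the smallest such size); within a size, scanning aborts
#' early once the rate can no longer be reached.
#'
#' @param base a [sample_spec()] with a population named `"spike"`.
#' @param sizes spike sizes in events.
#' @param seeds integer seeds (one generated sample per size x seed).
#' @param method `"cluster"` or `"manual"`.
#' @param required_rate required per-size detection rate (default 0.9).
#' @param config a [default_config()].
#' @param scan `"all"` evaluates every size; `"ascending"` stops early.
#' @param subgated passed to [analyze_sample()] for the manual method.
#' @return A `ladder_result`: data.frame (`size`, `n_seeds`, `n_detected`,
#'   `rate`) plus attribute `smallest_reliable` (NA when no size qualifies).
#' @export
run_ladder <- function(base, sizes, seeds, method = c("cluster", "manual"),
                       required_rate = 0.9, config = default_config(),
                       scan = c("all", "ascending"), subgated = FALSE) {
  method <- match.arg(method)
  scan <- match.arg(scan)
  if (!length(sizes)) stop("sizes must be non-empty", call. = FALSE)
  ord <- if (scan == "ascending") order(sizes) else seq_along(sizes)
  rows <- list()
  smallest <- NA_real_
  for (s in sizes[ord]) {
    spec_s <- set_spike_size(base, s)
    max_fail <- floor((1 - required_rate) * length(seeds))
    det <- logical(0)
    for (seed in seeds) {
      smp <- generate_sample(spec_s, seed = seed)
      an <- analyze_sample(smp, method = method, config = config,
                           seed = seed, subgated = subgated)
      det <- c(det, spike_detected(an, smp$truth))
      if (scan == "ascending" && sum(!det) > max_fail) break
    }
    rate <- sum(det) / length(seeds)
    rows[[length(rows) + 1L]] <- data.frame(
      size = s, n_seeds = length(seeds), n_run = length(det),
      n_detected = sum(det), rate = rate)
    if (rate >= required_rate) {
      if (is.na(smallest) || s < smallest) smallest <- s
      if (scan == "ascending") break
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ladder_result", class(out))
  attr(out, "smallest_reliable") <- smallest
  out
}

#' Per-sample method outcomes over a synthetic cohort
#'
#' Generates `n_samples` samples, each with one spiked clone whose size (as
#' percent of CD45+ events) is drawn log-uniformly from `size_range_pct`,
#' runs the manual baseline, the clustering pipeline and the PCR oracle on
#' each, and tabulates per-method detection.
#'
#' @param n_samples cohort size.
#' @param size_range_pct numeric length-2, percent of CD45+ events.
#' @param total_cd45_events per-sample CD45+ count.
#' @param seed cohort seed; per-sample seeds derive from it.
#' @param spike_maker function(n_events) returning a spike
#'   [population_spec()], default [spike_cd8_t_cus()].
#' @param config a [default_config()].
#' @param methods which FC methods to run.
#' @param subgated manual sub-gating flag.
#' @return data.frame, one row per sample: spike size, per-method detection
#'   flags, and per-method size estimates (% CD45, NA when undetected).
#' @export
cohort_outcomes <- function(n_samples, size_range_pct = c(0.03, 5),
                            total_cd45_events = 20000, seed = 1L,
                            spike_maker = spike_cd8_t_cus,
                            config = default_config(),
                            methods = c("cluster", "manual"),
                            subgated = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  lsz <- runif(n_samples, log(size_range_pct[1]), log(size_range_pct[2]))
  spike_pct <- exp(lsz)
  rows <- list()
  for (i in seq_len(n_samples)) {
    n_spike <- max(1L, round(spike_pct[i] / 100 * total_cd45_events))
    spec <- default_sample_spec(total_cd45_events = total_cd45_events,
                                spike = spike_maker(n_events = n_spike),
                                seed = sample_seeds[i])
    smp <- generate_sample(spec)
    row <- data.frame(sample = i, spike_pct = spike_pct[i],
                      spike_events = n_spike)
    for (m in methods) {
      an <- analyze_sample(smp, method = m, config = config,
                           seed = sample_seeds[i], subgated = subgated)
      det <- spike_detected(an, smp$truth)
      row[[paste0(m, "_detected")]] <- det
      row[[paste0(m, "_size_pct")]] <- if (det) {
        .matched_call_size(an, smp$truth)
      } else NA_real_
    }
    pcr <- pcr_oracle(smp, config$pcr$detection_limit_pct_total,
                      config$pcr$miss_prob, seed = sample_seeds[i])
    row$pcr_detected <- attr(pcr, "any_detected")
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

# size (% CD45) of the monotypic call best overlapping the truth spike
.matched_call_size <- function(analysis, truth, population = "spike") {
  spike_idx <- which(truth$population_id == population)
  mono <- which(analysis$calls$verdict == "monotypic")
  best <- NA_real_; best_ov <- 0
  for (i in mono) {
    ov <- length(intersect(analysis$call_events[[i]], spike_idx)) /
      length(spike_idx)
    if (ov > best_ov) {
      best_ov <- ov
      best <- analysis$calls$size_pct_cd45[i]
    }
  }
  best
}

#' Table-1-shaped cohort summary
#'
#' @param outcomes data.frame from [cohort_outcomes()].
#' @return data.frame with one row per method: detected / not-detected
#'   counts and sensitivity.
#' @export
summarize_cohort <- function(outcomes) {
  det_cols <- grep("_detected$", names(outcomes), value = TRUE)
  rows <- lapply(det_cols, function(cl) {
    d <- sum(outcomes[[cl]])
    data.frame(method = sub("_detected$", "", cl),
               monotypic_detected = d,
               not_detected = nrow(outcomes) - d,
               sensitivity = d / nrow(outcomes))
  })
  do.call(rbind, rows)
}
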