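#' Default raw-scale intensity levels of the synthetic generator
#'
#' The stated world of the generator: median raw intensities (arbitrary
#' linear fluorescence units, FACSCanto-like scale) for negative and positive
#' staining on each marker, scatter locations for lymphocytes, debris and
#' CD45-low erythroblast-like events, and the TRBC1 positive/negative levels.
#' Gating thresholds default to transformed-scale midpoints between these
#' negative and positive levels, so generator and gater agree by
#' construction.
#'
#' @return A named list of level constants.
#' @export
generator_levels <- function() {
  list(
    neg = 120,
    pos = c(
      CD2 = 15000, CD3 = 20000, CD4 = 15000, CD5 = 12000, CD7 = 10000,
      CD8 = 18000, CD19 = 12000, CD45 = 50000, TCRgd = 9000
    ),
    trbc1_pos = 9000,
    trbc1_neg = 120,
    lymph_fsc = 100000, lymph_ssc = 30000,
    debris_fsc = 12000, debris_ssc = 5000,
    ery_fsc = 70000, ery_ssc = 12000, ery_cd45 = 200,
    singlet_hw_ratio = 0.97, singlet_hw_sd = 0.02,
    cv_scatter_fsc = 0.13, cv_scatter_ssc = 0.30, cv_marker = 0.45
  )
}

marker_channels <- function() {
  c("CD2", "CD3", "CD4", "CD5", "CD7", "CD8", "CD19", "CD45", "TCRgd")
}

#' Build per-channel median intensities for a synthetic population
#'
#' @param positive character vector of markers stained positive; all other
#'   markers sit at the negative level.
#' @param overrides named numeric vector of raw medians overriding individual
#'   channels (used for aberrancies, e.g. `c(CD3 = 4000)` for dim CD3 or
#'   `c(CD7 = 120)` for CD7 loss).
#' @param fsc,ssc scatter medians.
#' @return Named numeric vector over FSC-A, SSC-A and the nine markers.
#' @export
channel_means <- function(positive = character(), overrides = numeric(),
                          fsc = generator_levels()$lymph_fsc,
                          ssc = generator_levels()$lymph_ssc) {
  lv <- generator_levels()
  m <- setNames(rep(lv$neg, length(marker_channels())), marker_channels())
  m[positive] <- lv$pos[positive]
  if (length(overrides)) m[names(overrides)] <- overrides
  c(`FSC-A` = unname(fsc), `SSC-A` = unname(ssc), m)
}

#' Specify one synthetic population
#'
#' @param name population label, unique within a sample.
#' @param n_events absolute event count; exactly one of `n_events` and
#'   `fraction_of_cd45` must be given.
#' @param fraction_of_cd45 size as a percentage (0-100) of CD45-positive
#'   events.
#' @param means named raw-scale medians from [channel_means()].
#' @param cvs named per-channel lognormal coefficients of variation;
#'   unspecified channels fall back to the generator defaults.
#' @param trbc1_mode `"polyclonal"` (per-event Bernoulli(`trbc1_p`) state),
#'   `"positive"` / `"negative"` (monotypic, state flipped with probability
#'   `stain_error`), or `"na"` (non-alpha-beta events; TRBC1 stays at
#'   background and the truth state is not applicable).
#' @param trbc1_p TRBC1-positive probability for polyclonal mode. The normal
#'   polyclonal fraction defaults to 0.40.
#' @param stain_error probability that a monotypic event's TRBC1 state is
#'   misread; must lie in \[0, 0.1\].
#' @param truth_class ground-truth class label used for evaluating the
#'   lymphoma/T-CUS heuristic.
#' @return A `population_spec` object.
#' @export
population_spec <- function(name, n_events = NULL, fraction_of_cd45 = NULL,
                            means = channel_means(),
                            cvs = numeric(),
                            trbc1_mode = c("polyclonal", "positive", "negative", "na"),
                            trbc1_p = 0.40, stain_error = 0.02,
                            truth_class = c("polyclonal", "lymphoma", "t_cus", "non_t")) {
  trbc1_mode <- match.arg(trbc1_mode)
  truth_class <- match.arg(truth_class)
  if (is.null(n_events) == is.null(fraction_of_cd45)) {
    stop("exactly one of n_events / fraction_of_cd45 must be set for '",
         name, "'", call. = FALSE)
  }
  if (!is.null(n_events) && n_events < 1) {
    stop("population '", name, "' implies < 1 event", call. = FALSE)
  }
  if (trbc1_mode == "polyclonal" && (trbc1_p <= 0 || trbc1_p >= 1)) {
    stop("polyclonal mode requires 0 < trbc1_p < 1", call. = FALSE)
  }
  if (stain_error < 0 || stain_error > 0.1) {
    stop("stain_error must lie in [0, 0.1]", call. = FALSE)
  }
  need <- c("FSC-A", "SSC-A", marker_channels())
  if (!all(need %in% names(means))) {
    stop("means must name all of: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, n_events = n_events, fraction_of_cd45 = fraction_of_cd45,
         means = means[need], cvs = cvs, trbc1_mode = trbc1_mode,
         trbc1_p = trbc1_p, stain_error = stain_error,
         truth_class = truth_class),
    class = "population_spec"
  )
}

#' Specify a whole synthetic sample
#'
#' Fractions for debris, doublets and CD45-negative (erythroblast-like)
#' events are proportions of *total recorded* events; the CD45-positive
#' viable singlets always number `total_cd45_events`, mirroring an
#' acquisition protocol that records a fixed number of CD45-positive events.
#'
#' @param populations list of [population_spec()] objects; their sizes must
#'   add up to `total_cd45_events` (each within one rounding event).
#' @param total_cd45_events number of CD45-positive viable singlet events,
#'   at least 1000.
#' @param debris_fraction,doublet_fraction,non_cd45_fraction proportions of
#'   total recorded events; each in \[0, 1) and jointly summing below 1.
#' @param seed integer driving the single PRNG stream of the generator.
#' @return A `sample_spec` object.
#' @export
sample_spec <- function(populations, total_cd45_events = 100000,
                        debris_fraction = 0.05, doublet_fraction = 0.02,
                        non_cd45_fraction = 0.03, seed = 1L) {
  fr <- c(debris_fraction, doublet_fraction, non_cd45_fraction)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1) {
    stop("debris/doublet/non-CD45 fractions must lie in [0,1) and sum below 1",
         call. = FALSE)
  }
  if (total_cd45_events < 1000) {
    stop("total_cd45_events must be at least 1000", call. = FALSE)
  }
  nm <- vapply(populations, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("population names must be unique", call. = FALSE)
  counts <- .population_counts(populations, total_cd45_events)
  structure(
    list(populations = populations, counts = counts,
         total_cd45_events = as.integer(total_cd45_events),
         debris_fraction = debris_fraction,
         doublet_fraction = doublet_fraction,
         non_cd45_fraction = non_cd45_fraction,
         seed = as.integer(seed)),
    class = "sample_spec"
  )
}

# Resolve per-population event counts: fractions are percentages of CD45+,
# rounded to whole events; any residual (at most one event per population,
# from rounding) is absorbed by the largest populations so that the counts
# sum exactly to total_cd45_events.
.population_counts <- function(populations, total) {
  n <- vapply(populations, function(p) {
    if (!is.null(p$n_events)) as.numeric(p$n_events)
    else round(p$fraction_of_cd45 / 100 * total)
  }, numeric(1))
  if (any(n < 1)) {
    bad <- populations[[which(n < 1)[1]]]$name
    stop("population '", bad, "' implies < 1 event", call. = FALSE)
  }
  resid <- total - sum(n)
  if (abs(resid) > length(populations)) {
    stop("population sizes are inconsistent with total_cd45_events (off by ",
         resid, " events)", call. = FALSE)
  }
  ord <- order(n, decreasing = TRUE)
  i <- 1L
  while (resid != 0) {
    n[ord[i]] <- n[ord[i]] + sign(resid)
    resid <- resid - sign(resid)
    i <- i %% length(populations) + 1L
  }
  setNames(as.integer(n), vapply(populations, `[[`, character(1), "name"))
}

.lognorm <- function(n, med, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

.pop_cv <- function(pop, channel) {
  lv <- generator_levels()
  if (channel %in% names(pop$cvs)) return(pop$cvs[[channel]])
  switch(channel,
         `FSC-A` = lv$cv_scatter_fsc,
         `SSC-A` = lv$cv_scatter_ssc,
         lv$cv_marker)
}

#' Generate a labelled synthetic flow-cytometry sample
#'
#' Draws per-event raw intensities (lognormal around each population's
#' channel medians), per-event TRBC1 states, singlet FSC-H from a
#' near-unity height/area ratio, and appends debris, CD45-low
#' erythroblast-like events and doublets (two random CD45-positive singlets
#' with summed area channels and near-singlet height). Event order is
#' shuffled. Deterministic given `spec$seed`.
#'
#' @param spec a [sample_spec()].
#' @param seed optional override of `spec$seed`.
#' @return A list of class `synthetic_sample` with elements `events`
#'   ([event_table()], raw scale), `truth` (data.frame: `population_id`,
#'   `trbc1_state`, `is_debris`, `is_doublet`, `is_cd45`) and `spec`.
#' @export
#' @examples
#' s <- generate_sample(default_sample_spec(total_cd45_events = 2000, seed = 7))
#' table(s$truth$population_id)
generate_sample <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sample_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  lv <- generator_levels()
  panel <- default_panel()
  chans <- panel$channels

  lost <- spec$debris_fraction + spec$doublet_fraction + spec$non_cd45_fraction
  total_rec <- round(spec$total_cd45_events / (1 - lost))
  n_debris <- round(spec$debris_fraction * total_rec)
  n_doublet <- round(spec$doublet_fraction * total_rec)
  n_ery <- round(spec$non_cd45_fraction * total_rec)

  draw_pop <- function(pop, n) {
    X <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
    for (ch in c("FSC-A", "SSC-A", marker_channels())) {
      X[, ch] <- .lognorm(n, pop$means[[ch]], .pop_cv(pop, ch))
    }
    ratio <- pmin(pmax(rnorm(n, lv$singlet_hw_ratio, lv$singlet_hw_sd), 0.85), 1.05)
    X[, "FSC-H"] <- X[, "FSC-A"] * ratio
    state <- switch(pop$trbc1_mode,
      polyclonal = rbinom(n, 1, pop$trbc1_p),
      positive = {
        s <- rep(1L, n)
        flip <- runif(n) < pop$stain_error
        s[flip] <- 0L
        s
      },
      negative = {
        s <- rep(0L, n)
        flip <- runif(n) < pop$stain_error
        s[flip] <- 1L
        s
      },
      na = rep(NA_integer_, n)
    )
    med <- ifelse(is.na(state) | state == 0L, lv$trbc1_neg, lv$trbc1_pos)
    X[, "TRBC1"] <- .lognorm(n, 1, .pop_cv(pop, "TRBC1")) * med
    list(X = X, state = state)
  }

  blocks <- list(); states <- list(); ids <- list()
  for (pop in spec$populations) {
    n <- spec$counts[[pop$name]]
    d <- draw_pop(pop, n)
    blocks[[pop$name]] <- d$X
    states[[pop$name]] <- d$state
    ids[[pop$name]] <- rep(pop$name, n)
  }
  cd45 <- do.call(rbind, blocks)
  cd45_state <- unlist(states, use.names = FALSE)
  cd45_id <- unlist(ids, use.names = FALSE)

  # debris: low-scatter, marker-negative junk below the viability box
  debris <- matrix(0, n_debris, length(chans), dimnames = list(NULL, chans))
  if (n_debris > 0) {
    debris[, "FSC-A"] <- .lognorm(n_debris, lv$debris_fsc, 0.4)
    debris[, "SSC-A"] <- .lognorm(n_debris, lv$debris_ssc, 0.5)
    debris[, "FSC-H"] <- debris[, "FSC-A"] *
      pmin(pmax(rnorm(n_debris, lv$singlet_hw_ratio, lv$singlet_hw_sd), 0.85), 1.05)
    for (ch in c(marker_channels(), "TRBC1")) {
      debris[, ch] <- .lognorm(n_debris, 60, 0.6)
    }
  }

  # erythroblast-like: nucleated, CD45-low, excluded by the CD45 gate but
  # counted by the PCR oracle denominator
  ery <- matrix(0, n_ery, length(chans), dimnames = list(NULL, chans))
  if (n_ery > 0) {
    ery[, "FSC-A"] <- .lognorm(n_ery, lv$ery_fsc, 0.2)
    ery[, "SSC-A"] <- .lognorm(n_ery, lv$ery_ssc, 0.3)
    ery[, "FSC-H"] <- ery[, "FSC-A"] *
      pmin(pmax(rnorm(n_ery, lv$singlet_hw_ratio, lv$singlet_hw_sd), 0.85), 1.05)
    for (ch in marker_channels()) ery[, ch] <- .lognorm(n_ery, lv$neg, 0.5)
    ery[, "CD45"] <- .lognorm(n_ery, lv$ery_cd45, 0.4)
    ery[, "TRBC1"] <- .lognorm(n_ery, lv$trbc1_neg, 0.5)
  }

  # doublets: coincident pairs of CD45+ singlets; area channels add, height
  # stays near the larger singlet, so FSC-H/FSC-A drops to roughly 1/2
  doublet <- matrix(0, n_doublet, length(chans), dimnames = list(NULL, chans))
  if (n_doublet > 0) {
    i1 <- sample.int(nrow(cd45), n_doublet, replace = TRUE)
    i2 <- sample.int(nrow(cd45), n_doublet, replace = TRUE)
    area_ch <- setdiff(chans, "FSC-H")
    doublet[, area_ch] <- cd45[i1, area_ch] + cd45[i2, area_ch]
    doublet[, "FSC-H"] <- pmax(cd45[i1, "FSC-H"], cd45[i2, "FSC-H"])
  }

  X <- rbind(cd45, debris, ery, doublet)
  truth <- data.frame(
    population_id = c(cd45_id,
                      rep("debris", n_debris),
                      rep("non_cd45", n_ery),
                      rep("doublet", n_doublet)),
    trbc1_state = c(ifelse(is.na(cd45_state), NA_character_,
                           ifelse(cd45_state == 1L, "positive", "negative")),
                    rep(NA_character_, n_debris + n_ery + n_doublet)),
    is_debris = c(rep(FALSE, nrow(cd45)), rep(TRUE, n_debris),
                  rep(FALSE, n_ery + n_doublet)),
    is_doublet = c(rep(FALSE, nrow(cd45) + n_debris + n_ery),
                   rep(TRUE, n_doublet)),
    is_cd45 = c(rep(TRUE, nrow(cd45)), rep(FALSE, n_debris + n_ery),
                rep(TRUE, n_doublet)),
    stringsAsFactors = FALSE
  )
  perm <- sample.int(nrow(X))
  out <- list(
    events = event_table(X[perm, , drop = FALSE], panel),
    truth = truth[perm, , drop = FALSE],
    spec = spec
  )
  rownames(out$truth) <- NULL
  class(out) <- "synthetic_sample"
  out
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("synthetic_sample:", nrow(x$events$exprs), "events,",
      x$spec$total_cd45_events, "CD45+; populations:",
      paste(names(x$spec$counts), collapse = ", "), "\n")
  invisible(x)
}

#' A realistic default sample specification
#'
#' Polyclonal T-cell background (CD4, CD8, double-negative and
#' gamma-delta subsets), B cells, NK cells, and optionally one spiked
#' monotypic population. The composition (59% T cells among CD45-positive
#' events) reflects a lymphoma-workup cohort in which many samples carry a
#' substantial B-cell component. A spike displaces all background
#' populations proportionally, as an expanding clone does, so the
#' CD45-positive total stays fixed.
#'
#' @param total_cd45_events CD45-positive event count.
#' @param spike optional [population_spec()] with `n_events` set.
#' @param trbc1_p polyclonal TRBC1-positive probability.
#' @param stain_error monotypic misread probability passed to the spike
#'   helpers only; the polyclonal background draws exact Bernoulli states.
#' @param seed integer seed.
#' @param debris_fraction,doublet_fraction,non_cd45_fraction see
#'   [sample_spec()].
#' @return A [sample_spec()].
#' @export
default_sample_spec <- function(total_cd45_events = 100000, spike = NULL,
                                trbc1_p = 0.40, seed = 1L,
                                debris_fraction = 0.05,
                                doublet_fraction = 0.02,
                                non_cd45_fraction = 0.03,
                                stain_error = 0.02) {
  frac <- c(cd4_t = 36, cd8_t = 18, dn_t = 3, gd_t = 2, b_cells = 27, nk_cells = 14)
  pops <- list(
    population_spec("cd4_t", fraction_of_cd45 = frac[["cd4_t"]],
                    means = channel_means(c("CD2", "CD3", "CD4", "CD5", "CD7", "CD45")),
                    trbc1_mode = "polyclonal", trbc1_p = trbc1_p),
    population_spec("cd8_t", fraction_of_cd45 = frac[["cd8_t"]],
                    means = channel_means(c("CD2", "CD3", "CD5", "CD7", "CD8", "CD45")),
                    trbc1_mode = "polyclonal", trbc1_p = trbc1_p),
    population_spec("dn_t", fraction_of_cd45 = frac[["dn_t"]],
                    means = channel_means(c("CD2", "CD3", "CD5", "CD7", "CD45")),
                    trbc1_mode = "polyclonal", trbc1_p = trbc1_p),
    population_spec("gd_t", fraction_of_cd45 = frac[["gd_t"]],
                    means = channel_means(c("CD2", "CD3", "CD5", "CD7", "CD45", "TCRgd")),
                    trbc1_mode = "negative", stain_error = 0,
                    truth_class = "polyclonal"),
    population_spec("b_cells", fraction_of_cd45 = frac[["b_cells"]],
                    means = channel_means(c("CD19", "CD45")),
                    trbc1_mode = "na", truth_class = "non_t"),
    population_spec("nk_cells", fraction_of_cd45 = frac[["nk_cells"]],
                    means = channel_means(c("CD2", "CD7", "CD45")),
                    trbc1_mode = "na", truth_class = "non_t")
  )
  if (!is.null(spike)) {
    if (is.null(spike$n_events)) {
      spike$n_events <- as.integer(round(spike$fraction_of_cd45 / 100 * total_cd45_events))
      spike$fraction_of_cd45 <- NULL
      if (spike$n_events < 1) stop("spike implies < 1 event", call. = FALSE)
    }
    scale <- (total_cd45_events - spike$n_events) / total_cd45_events
    if (round(frac[["cd4_t"]] / 100 * total_cd45_events * scale) < 500) {
      stop("spike too large for the polyclonal background to absorb", call. = FALSE)
    }
    pops <- lapply(pops, function(p) {
      p$n_events <- max(1L, as.integer(round(
        p$fraction_of_cd45 / 100 * total_cd45_events * scale)))
      p$fraction_of_cd45 <- NULL
      p
    })
    pops <- c(pops, list(spike))
  }
  sample_spec(pops, total_cd45_events = total_cd45_events, seed = seed,
              debris_fraction = debris_fraction,
              doublet_fraction = doublet_fraction,
              non_cd45_fraction = non_cd45_fraction)
}

#' Canned monotypic spikes
#'
#' `spike_cd8_t_cus()` is a CD8-positive clone with a single aberrancy (CD5
#' loss), the immunophenotype of a typical CD8+ T-CUS. `spike_cd4_lymphoma()`
#' is a CD4-positive clone with two aberrancies (CD7 loss and dim CD3),
#' the common mature CD4+ T-cell lymphoma pattern.
#'
#' @param n_events spike size in events (alternatively `fraction_of_cd45`,
#'   percent).
#' @param fraction_of_cd45 spike size as percent of CD45-positive events.
#' @param trbc1_mode `"positive"` or `"negative"`; clones are TRBC1-uniform.
#' @param stain_error misread probability, default 0.02.
#' @return A [population_spec()].
#' @export
spike_cd8_t_cus <- function(n_events = NULL, fraction_of_cd45 = NULL,
                            trbc1_mode = "positive", stain_error = 0.02) {
  population_spec("spike", n_events = n_events,
                  fraction_of_cd45 = fraction_of_cd45,
                  means = channel_means(c("CD2", "CD3", "CD7", "CD8", "CD45"),
                                        overrides = c(CD5 = generator_levels()$neg)),
                  trbc1_mode = trbc1_mode, stain_error = stain_error,
                  truth_class = "t_cus")
}

#' @rdname spike_cd8_t_cus
#' @export
spike_cd4_lymphoma <- function(n_events = NULL, fraction_of_cd45 = NULL,
                               trbc1_mode = "positive", stain_error = 0.02) {
  population_spec("spike", n_events = n_events,
                  fraction_of_cd45 = fraction_of_cd45,
                  means = channel_means(c("CD2", "CD4", "CD5", "CD45"),
                                        overrides = c(CD3 = 4000,
                                                      CD7 = generator_levels()$neg)),
                  trbc1_mode = trbc1_mode, stain_error = stain_error,
                  truth_class = "lymphoma")
}

#' Regenerate one base sample at a ladder of spike sizes
#'
#' @param base a [sample_spec()] containing a population named `spike_name`.
#' @param sizes vector of spike sizes in events.
#' @param seeds vector of integer seeds; one sample is generated per
#'   (size, seed) pair.
#' @param spike_name name of the population to resize.
#' @return A flat list of `synthetic_sample` objects, each carrying
#'   `$spike_size` and `$seed`.
#' @export
spike_ladder <- function(base, sizes, seeds = base$seed, spike_name = "spike") {
  stopifnot(inherits(base, "sample_spec"))
  if (length(sizes) < 1) stop("sizes must be non-empty", call. = FALSE)
  if (any(sizes < 1)) stop("sizes must be positive", call. = FALSE)
  out <- list()
  for (size in sizes) {
    sp <- set_spike_size(base, size, spike_name)
    for (seed in seeds) {
      s <- generate_sample(sp, seed = seed)
      s$spike_size <- size
      s$seed <- seed
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' @rdname spike_ladder
#' @param spec a [sample_spec()].
#' @param size new spike size in events; the largest other population absorbs
#'   the difference so the CD45-positive total is unchanged.
#' @export
set_spike_size <- function(spec, size, spike_name = "spike") {
  nm <- names(spec$counts)
  if (!spike_name %in% nm) {
    stop("no population named '", spike_name, "' in the sample spec", call. = FALSE)
  }
  delta <- as.integer(round(size)) - spec$counts[[spike_name]]
  counts <- spec$counts
  counts[[spike_name]] <- counts[[spike_name]] + delta
  donor <- nm[nm != spike_name][which.max(counts[nm != spike_name])]
  counts[[donor]] <- counts[[donor]] - delta
  if (counts[[donor]] < 1) stop("spike size too large for the sample", call. = FALSE)
  pops <- lapply(spec$populations, function(p) {
    p$n_events <- counts[[p$name]]
    p$fraction_of_cd45 <- NULL
    p
  })
  sample_spec(pops, total_cd45_events = spec$total_cd45_events,
              debris_fraction = spec$debris_fraction,
              doublet_fraction = spec$doublet_fraction,
              non_cd45_fraction = spec$non_cd45_fraction,
              seed = spec$seed)
}
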