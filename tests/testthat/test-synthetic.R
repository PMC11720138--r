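test_that("population and sample spec invariants are enforced", {
  expect_error(population_spec("x"), "exactly one of")
  expect_error(population_spec("x", n_events = 10, fraction_of_cd45 = 1),
               "exactly one of")
  expect_error(population_spec("x", n_events = 0.2), "< 1 event")
  expect_error(population_spec("x", n_events = 10, trbc1_p = 1), "0 < trbc1_p < 1")
  expect_error(population_spec("x", n_events = 10, stain_error = 0.2),
               "stain_error")
  pops <- list(population_spec("a", fraction_of_cd45 = 100))
  expect_error(sample_spec(pops, total_cd45_events = 500), "at least 1000")
  expect_error(sample_spec(pops, debris_fraction = 0.7, doublet_fraction = 0.4),
               "sum below 1")
  expect_error(
    sample_spec(list(population_spec("a", fraction_of_cd45 = 60),
                     population_spec("b", fraction_of_cd45 = 20)),
                total_cd45_events = 10000),
    "inconsistent")
})

test_that("generated samples honour counts, fractions and determinism", {
  spec <- default_sample_spec(total_cd45_events = 10000,
                              spike = spike_cd8_t_cus(n_events = 82), seed = 3)
  s <- generate_sample(spec)
  # exact truth count for the spiked population
  expect_identical(sum(s$truth$population_id == "spike"), 82L)
  # CD45+ events match the requested total exactly
  expect_identical(sum(s$truth$is_cd45 & !s$truth$is_doublet), 10000L)
  # per-population sizes match the spec within one event
  for (nm in names(spec$counts)) {
    expect_lte(abs(sum(s$truth$population_id == nm) - spec$counts[[nm]]), 1)
  }
  # total recorded events = cd45 / (1 - fractions) within rounding
  lost <- spec$debris_fraction + spec$doublet_fraction + spec$non_cd45_fraction
  expect_lte(abs(nrow(s$events$exprs) - 10000 / (1 - lost)), 3)
  # fixed-seed determinism, byte-identical
  s2 <- generate_sample(spec)
  expect_identical(s$events$exprs, s2$events$exprs)
  expect_identical(s$truth, s2$truth)
  # different seed differs
  s3 <- generate_sample(spec, seed = 4)
  expect_false(identical(s$events$exprs, s3$events$exprs))
})

test_that("polyclonal TRBC1 fractions behave binomially", {
  one_pop <- function(seed, n = 10000, p = 0.4) {
    spec <- sample_spec(
      list(population_spec("poly", n_events = n, trbc1_mode = "polyclonal",
                           trbc1_p = p, means = channel_means(c("CD3", "CD45")))),
      total_cd45_events = n, debris_fraction = 0, doublet_fraction = 0,
      non_cd45_fraction = 0, seed = seed)
    s <- generate_sample(spec)
    mean(s$truth$trbc1_state == "positive")
  }
  # single draw within binomial 3 sigma of p = 0.4
  expect_lt(abs(one_pop(11) - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  # exact 99% binomial CIs cover p in (almost) all of 100 seeded replicates
  n_rep <- 100; n <- 2000
  cover <- vapply(seq_len(n_rep), function(seed) {
    x <- round(one_pop(seed, n = n) * n)
    ci <- stats::binom.test(x, n, conf.level = 0.99)$conf.int
    ci[1] <= 0.4 && 0.4 <= ci[2]
  }, logical(1))
  expect_gte(sum(cover), 96)
})

test_that("monotypic populations reflect the stain error", {
  for (mode in c("positive", "negative")) {
    spec <- sample_spec(
      list(population_spec("mono", n_events = 20000, trbc1_mode = mode,
                           stain_error = 0.02,
                           means = channel_means(c("CD3", "CD45")))),
      total_cd45_events = 20000, debris_fraction = 0, doublet_fraction = 0,
      non_cd45_fraction = 0, seed = 5)
    s <- generate_sample(spec)
    frac_pos <- mean(s$truth$trbc1_state == "positive")
    expected <- if (mode == "positive") 0.98 else 0.02
    expect_lt(abs(frac_pos - expected), 3 * sqrt(0.02 * 0.98 / 20000))
  }
})

test_that("spike ladders resize only the spike", {
  base <- default_sample_spec(total_cd45_events = 5000,
                              spike = spike_cd8_t_cus(n_events = 500), seed = 9)
  lad <- spike_ladder(base, sizes = c(500, 174, 41), seeds = 9)
  expect_length(lad, 3)
  counts <- vapply(lad, function(s) sum(s$truth$population_id == "spike"),
                   numeric(1))
  expect_identical(counts, c(500, 174, 41))
  # CD45 total unchanged across the ladder
  for (s in lad) expect_identical(sum(s$truth$is_cd45 & !s$truth$is_doublet), 5000L)
  # a fraction-specified spike reproduces the requested size within 1 event
  sfr <- generate_sample(default_sample_spec(
    total_cd45_events = 5000, seed = 9,
    spike = spike_cd8_t_cus(fraction_of_cd45 = 2)))
  expect_lte(abs(sum(sfr$truth$population_id == "spike") - 0.02 * 5000), 1)
  # two seeds differ only by noise realisation: same truth counts
  lad2 <- spike_ladder(base, sizes = 100, seeds = c(1, 2))
  expect_length(lad2, 2)
  expect_identical(
    table(lad2[[1]]$truth$population_id),
    table(lad2[[2]]$truth$population_id))
  expect_false(identical(lad2[[1]]$events$exprs, lad2[[2]]$events$exprs))
  expect_error(spike_ladder(base, sizes = numeric(0)), "non-empty")
})

test_that("doublets are distinguishable by the height/area convention", {
  s <- small_sample(seed = 21, n = 20000)
  ratio <- s$events$exprs[, "FSC-H"] / s$events$exprs[, "FSC-A"]
  dbl <- s$truth$is_doublet
  # generated doublets fall below the 0.6 cutoff almost surely; singlets above
  expect_gte(mean(ratio[dbl] < 0.6), 0.98)
  expect_equal(mean(ratio[!dbl] >= 0.6), 1)
})
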