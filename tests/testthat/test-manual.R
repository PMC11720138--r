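test_that("quadrant subsets partition the alpha-beta gate exactly", {
  s <- small_sample(seed = 41, n = 6000)
  pre <- pregate(s$events, test_config())
  ab <- pre$gates$masks$alphabeta_t
  q <- quadrant_subsets(pre$transformed, ab)
  # union is the gate, intersections are empty
  un <- q$cd4_pos | q$cd8_pos | q$double_positive | q$double_negative
  expect_identical(un, ab)
  expect_identical(sum(q$cd4_pos) + sum(q$cd8_pos) + sum(q$double_positive) +
                     sum(q$double_negative), sum(ab))
  # membership matches single-event phenotypes
  thr <- default_thresholds()
  ev <- pre$transformed$exprs
  hi4 <- ab & ev[, "CD4"] > thr[["CD4"]] & ev[, "CD8"] <= thr[["CD8"]]
  expect_identical(q$cd4_pos, hi4)
  both <- ab & ev[, "CD4"] > thr[["CD4"]] & ev[, "CD8"] > thr[["CD8"]]
  expect_identical(q$double_positive, both)
})

test_that("subset-level assessment follows the clonality rule and the floor", {
  thr <- 2
  # 49-event subset: never assessed
  ev <- trbc1_events(c(rep(5, 10), rep(0, 39), rep(5, 60)))
  subsets <- list(small = c(rep(TRUE, 49), rep(FALSE, 60)),
                  big = c(rep(FALSE, 49), rep(TRUE, 60)))
  out <- assess_subsets(ev, subsets, thr)
  expect_false(out$assessed[out$subset == "small"])
  expect_identical(out$verdict[out$subset == "small"], "not_assessed")
  expect_identical(out$verdict[out$subset == "big"], "monotypic")
})

test_that("blending arithmetic decides what the baseline can see", {
  # mixture fraction p(1-q) + q for a TRBC1+ clone at within-subset
  # proportion q over a p = 0.4 polyclonal background
  thr <- 2
  p <- 0.4
  mix_events <- function(n, q) {
    n_clone <- round(n * q)
    n_poly <- n - n_clone
    n_pos <- round(p * n_poly)
    trbc1_events(c(rep(5, n_clone), rep(5, n_pos), rep(0, n_poly - n_pos)))
  }
  # q = 0.95: fraction ~ 0.97 -> detected
  ev <- mix_events(2000, 0.95)
  out <- assess_subsets(ev, list(s = rep(TRUE, 2000)), thr)
  expect_identical(out$verdict, "monotypic")
  expect_gt(out$trbc1_fraction, 0.93)
  # q = 0.02 (a 0.2%-of-CD45 spike inside a large quadrant): fraction ~ p,
  # the spike is invisible at subset level
  ev <- mix_events(5000, 0.02)
  out <- assess_subsets(ev, list(s = rep(TRUE, 5000)), thr)
  expect_identical(out$verdict, "polytypic")
  expect_lt(abs(out$trbc1_fraction - (p * 0.98 + 0.02)), 0.03)
  # direct computation over a grid: inside-the-band mixtures stay polytypic
  for (q in c(0.1, 0.3, 0.6)) {
    f <- p * (1 - q) + q
    ev <- mix_events(4000, q)
    out <- assess_subsets(ev, list(s = rep(TRUE, 4000)), thr)
    expect_identical(out$verdict,
                     if (f > 0.15 && f < 0.85) "polytypic" else "monotypic")
  }
})

test_that("the end-to-end baseline misses small spikes but sub-gating finds them", {
  cfg <- test_config()
  s <- small_sample(seed = 43, n = 20000, spike_events = 120)  # 0.6% of CD45
  plain <- analyze_sample(s, method = "manual", config = cfg)
  expect_false(spike_detected(plain, s$truth))
  sub <- analyze_sample(s, method = "manual", config = cfg, subgated = TRUE)
  expect_true(spike_detected(sub, s$truth))
  # the sub-gated size estimate tracks the true spike size closely
  idx <- which(s$truth$population_id == "spike")
  mono <- which(sub$calls$verdict == "monotypic")
  best <- mono[which.max(vapply(mono, function(i) {
    length(intersect(sub$call_events[[i]], idx))
  }, numeric(1)))]
  expect_lt(abs(sub$calls$n_events[best] - 120) / 120, 0.1)
})

test_that("a clone dominating its quadrant is detected by the plain baseline", {
  cfg <- test_config()
  # CD8+ spike at 45% of CD45 against an 8% CD8 background: within-quadrant
  # proportion q ~ 0.85, mixture fraction ~ 0.89 > 0.85
  pops <- list(
    population_spec("cd4_t", fraction_of_cd45 = 30,
                    means = channel_means(c("CD2", "CD3", "CD4", "CD5", "CD7", "CD45"))),
    population_spec("cd8_t", fraction_of_cd45 = 8,
                    means = channel_means(c("CD2", "CD3", "CD5", "CD7", "CD8", "CD45"))),
    population_spec("gd_t", fraction_of_cd45 = 2,
                    means = channel_means(c("CD2", "CD3", "CD5", "CD7", "CD45", "TCRgd")),
                    trbc1_mode = "negative", stain_error = 0),
    population_spec("b_cells", fraction_of_cd45 = 10,
                    means = channel_means(c("CD19", "CD45")),
                    trbc1_mode = "na", truth_class = "non_t"),
    population_spec("nk_cells", fraction_of_cd45 = 5,
                    means = channel_means(c("CD2", "CD7", "CD45")),
                    trbc1_mode = "na", truth_class = "non_t"),
    spike_cd8_t_cus(fraction_of_cd45 = 45)
  )
  s <- generate_sample(sample_spec(pops, total_cd45_events = 10000, seed = 44))
  # the clone owns its quadrant, so no polytypic CD8+ reference exists and
  # classification is (expectedly) skipped with a warning
  an <- suppressWarnings(analyze_sample(s, method = "manual", config = cfg))
  expect_true(spike_detected(an, s$truth))
  cd8 <- an$calls[an$calls$source == "cd8_pos", ]
  expect_identical(cd8$verdict, "monotypic")
})
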