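test_that("exact McNemar behaves on the anchor cases", {
  # 20 discordant one way: p = 2 * 0.5^20
  expect_equal(mcnemar_exact(20, 0), 2 * 0.5^20)
  expect_lt(mcnemar_exact(20, 0), 0.001)
  expect_identical(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(5, 5), 1)
  expect_equal(mcnemar_exact(3, 9), mcnemar_exact(9, 3))  # symmetry
  expect_error(mcnemar_exact(-1, 2), "non-negative")
})

test_that("Wilcoxon signed-rank matches brute-force sign enumeration", {
  expect_identical(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "length")
  set.seed(61)
  for (rep in 1:5) {
    x <- round(rnorm(6, 0.4, 1), 3)
    y <- rep(0, 6)
    d <- x - y
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    # enumerate all 2^6 sign assignments of the observed |d| ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    v_all <- signs %*% r
    p_enum <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
    expect_equal(wilcoxon_signed_rank(x, y), p_enum)
  }
  # antisymmetric under swapping the pair order
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4); y <- c(0, 0.2, 0.1, -0.3, 2, 0.5)
  expect_equal(wilcoxon_signed_rank(x, y), wilcoxon_signed_rank(y, x))
})

test_that("Spearman matches Pearson-on-ranks and handles edge cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 0.2)
  y <- c(2, 0.5, 5, 1, 8, 3, 6, 5.5, 11, 1.2)
  expect_equal(spearman_rs(x, y), cor(rank(x), rank(y)))  # oracle
  expect_equal(spearman_rs(1:5, (1:5)^3), 1)               # monotone
  expect_equal(spearman_rs(1:5, rev(1:5)), -1)             # reversed
  expect_warning(rs <- spearman_rs(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rs))
  expect_error(spearman_rs(1:2, 1:2), "at least 3")
})

test_that("the PCR oracle applies the 1% whole-sample detection limit", {
  # clone at 0.3% of CD45+, no dilution: undetected
  spec0 <- default_sample_spec(total_cd45_events = 20000,
                               spike = spike_cd8_t_cus(n_events = 60),
                               seed = 71, debris_fraction = 0,
                               doublet_fraction = 0, non_cd45_fraction = 0)
  pcr <- pcr_oracle(generate_sample(spec0))
  expect_false(pcr$detected[pcr$population == "spike"])
  # clone at 5% of all cells: detected
  spec1 <- default_sample_spec(total_cd45_events = 20000,
                               spike = spike_cd8_t_cus(n_events = 1000),
                               seed = 71, debris_fraction = 0,
                               doublet_fraction = 0, non_cd45_fraction = 0)
  pcr1 <- pcr_oracle(generate_sample(spec1))
  expect_true(pcr1$detected[pcr1$population == "spike"])
  # 2.34% of CD45+ under 42% CD45 purity: 0.98% of the tube -> missed
  spec2 <- default_sample_spec(total_cd45_events = 20000,
                               spike = spike_cd8_t_cus(n_events = 468),
                               seed = 72, debris_fraction = 0,
                               doublet_fraction = 0, non_cd45_fraction = 0.58)
  s2 <- generate_sample(spec2)
  pcr2 <- pcr_oracle(s2)
  expect_equal(pcr2$pct_total[pcr2$population == "spike"],
               100 * 468 / round(20000 / 0.42), tolerance = 1e-3)
  expect_false(pcr2$detected[pcr2$population == "spike"])
  # size-monotone: enlarging the clone at fixed dilution can only detect
  spec3 <- default_sample_spec(total_cd45_events = 20000,
                               spike = spike_cd8_t_cus(n_events = 1000),
                               seed = 72, debris_fraction = 0,
                               doublet_fraction = 0, non_cd45_fraction = 0.58)
  pcr3 <- pcr_oracle(generate_sample(spec3))
  expect_true(pcr3$pct_total[pcr3$population == "spike"] >
                pcr2$pct_total[pcr2$population == "spike"])
  expect_true(pcr3$detected[pcr3$population == "spike"])
})

test_that("ladders report the smallest reliably detected size", {
  cfg <- test_config()
  base <- default_sample_spec(total_cd45_events = 12000,
                              spike = spike_cd8_t_cus(n_events = 300),
                              seed = 1)
  lad <- run_ladder(base, sizes = c(300, 60), seeds = 1:3,
                    method = "cluster", required_rate = 1,
                    config = cfg, scan = "ascending")
  expect_identical(attr(lad, "smallest_reliable"), 60)
  # pure-clone limit: every method sees a clone that owns the whole gate
  spec_pure <- sample_spec(
    list(spike_cd8_t_cus(n_events = 5000),
         population_spec("b_cells", fraction_of_cd45 = 20,
                         means = channel_means(c("CD19", "CD45")),
                         trbc1_mode = "na", truth_class = "non_t")),
    total_cd45_events = 6250, seed = 5)
  s <- generate_sample(spec_pure)
  cfg2 <- cfg
  cfg2$clonality$trbc1_threshold <- default_thresholds()[["TRBC1"]]
  for (m in c("cluster", "manual")) {
    # a pure clone leaves no polyclonal reference; the classification
    # warning is expected and irrelevant to detection
    an <- suppressWarnings(analyze_sample(s, method = m, config = cfg2, seed = 5))
    expect_true(spike_detected(an, s$truth))
  }
})

test_that("cohort outcomes keep the sensitivity ordering and summary shape", {
  cfg <- test_config()
  out <- cohort_outcomes(n_samples = 6, size_range_pct = c(0.2, 10),
                         total_cd45_events = 8000, seed = 81, config = cfg)
  expect_identical(nrow(out), 6L)
  sm <- summarize_cohort(out)
  expect_setequal(sm$method, c("cluster", "manual", "pcr"))
  sens <- setNames(sm$sensitivity, sm$method)
  expect_gte(sens[["cluster"]], sens[["manual"]])
})
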