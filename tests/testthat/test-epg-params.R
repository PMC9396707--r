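test_that("hand-summed parameter values are reproduced", {
  # NP 10 min, C 110 min, E1 10 min, E2 350 min (truncated final bout)
  rec <- epg_recording("r1", "g1", c("NP", "C", "E1", "E2"),
                       onset_s = c(0, 600, 7200, 7800),
                       offset_s = c(600, 7200, 7800, 28800))
  p <- compute_parameters(rec)
  expect_equal(p$total_np_min, 10)
  expect_equal(p$n_c, 1L)
  expect_equal(p$total_c_min, 110)
  expect_equal(p$n_e1, 1L)
  expect_equal(p$total_e1_min, 10)
  expect_equal(p$n_e2, 1L)
  expect_equal(p$total_e2_min, 350)
  expect_equal(p$max_e2_min, 350)
  expect_equal(p$total_e2_sustained_min, 350)
  expect_equal(p$latency_first_e1_min, 120)
})

test_that("absent waveforms get zero totals, missing means, full-length latency", {
  rec <- rec_from_labels(c("NP", "C", "NP"), c(600, 1200, 27000))
  p <- compute_parameters(rec)
  expect_equal(p$total_e1_min, 0)
  expect_true(is.na(p$mean_e1_min))
  expect_equal(p$latency_first_e1_min, 480)
  expect_equal(p$max_e1_min, 0)
  expect_true(is.na(p$pct_e1_of_phloem_phase))
  expect_true(is.na(p$pd_rate_per_min_c) == FALSE)  # C present here
})

test_that("an all-nonprobing recording yields 480 NP minutes and zero counts", {
  rec <- epg_recording("r", "g", "NP", 0, 28800)
  p <- compute_parameters(rec)
  expect_equal(p$total_np_min, 480)
  expect_equal(p$n_c + p$n_pd + p$n_e1 + p$n_e2 + p$n_f + p$n_g + p$n_rpd, 0L)
  expect_equal(p$total_c_min + p$total_e1_min + p$total_e2_min +
               p$total_f_min + p$total_g_min + p$total_rpd_min, 0)
  expect_true(is.na(p$pd_rate_per_min_c))
  expect_equal(p$share_np, 1)
})

test_that("salivation bouts not followed by ingestion are counted correctly", {
  r1 <- rec_from_labels(c("C", "E1", "E2", "C", "E1", "C", "E1"),
                        c(100, 60, 300, 100, 60, 100, 60))
  expect_equal(count_e1_not_followed_by_e2(r1), 2L)
  # potential drops between E1 and E2 are ignored in the look-ahead
  r2 <- rec_from_labels(c("C", "E1", "PD", "E2"), c(100, 60, 5, 300))
  expect_equal(count_e1_not_followed_by_e2(r2), 0L)
  r3 <- rec_from_labels(c("C", "E1", "E2"), c(100, 60, 300))
  expect_equal(count_e1_not_followed_by_e2(r3), 0L)
})

test_that("pathway bouts merge across potential drops and the PD rate uses C time", {
  rec <- rec_from_labels(c("NP", "C", "PD", "C", "NP", "C"),
                         c(60, 120, 6, 120, 60, 300))
  p <- compute_parameters(rec)
  expect_equal(p$n_c, 2L)                      # C-PD-C is one bout
  expect_equal(p$mean_c_min, mean(c(4, 5)))
  expect_equal(p$total_c_min, 9)
  expect_equal(p$total_pd_min, 0.1)            # PD time not in total C
  expect_equal(p$pd_rate_per_min_c, 1 / 9)

  p2 <- compute_parameters(rec, param_config(merge_c_across_pd = FALSE))
  expect_equal(p2$n_c, 3L)
  expect_equal(p2$n_c_short, 2L)  # the 5-min piece is no longer short
})

test_that("repetitive potential drops are derived from close-spaced PD runs", {
  cfg <- param_config(rpd_mode = "derived")
  # PD C(5s) PD C(4s) PD -> one RPD spanning all five segments
  rec <- rec_from_labels(c("C", "PD", "C", "PD", "C", "PD", "C"),
                         c(100, 5, 5, 5, 4, 5, 100))
  out <- detect_rpd(rec, cfg)
  expect_equal(out$segments$label, c("C", "RPD", "C"))
  expect_equal(out$segments$offset_ms[2] - out$segments$onset_ms[2], 24000)
  expect_length(validate_recording(out), 0L)

  # wide gap: no run
  rec2 <- rec_from_labels(c("C", "PD", "C", "PD", "C"), c(100, 5, 60, 5, 100))
  expect_equal(sum(detect_rpd(rec2, cfg)$segments$label == "RPD"), 0L)

  # isolated PD: untouched
  rec3 <- rec_from_labels(c("C", "PD", "C"), c(100, 5, 100))
  expect_identical(detect_rpd(rec3, cfg)$segments, rec3$segments)

  expect_error(detect_rpd(rec3, param_config(rpd_mode = "annotated")),
               "disabled")
})

test_that("derived-RPD statistics flow into the parameter record", {
  cfg <- param_config(rpd_mode = "derived")
  rec <- rec_from_labels(c("C", "PD", "C", "PD", "C"), c(100, 5, 5, 5, 1000))
  p <- compute_parameters(rec, cfg)
  expect_equal(p$n_rpd, 1L)
  expect_equal(p$total_rpd_min, 15 / 60)
  expect_equal(p$n_pd, 0L)   # PDs absorbed into the RPD
})

test_that("activity time shares partition the recording", {
  rec <- rec_from_labels(c("NP", "G"), c(14400, 14400))
  sh <- activity_time_shares(rec)
  expect_equal(sh[["NP"]], 0.5)
  expect_equal(sh[["G"]], 0.5)
  set.seed(33)
  for (i in 1:25) {
    sh <- activity_time_shares(random_recording())
    expect_equal(sum(sh), 1, tolerance = 1e-12)
  }
})

test_that("cohort aggregation: percent-performing, SE rules, error paths", {
  recs <- c(
    replicate(3, rec_from_labels(c("C", "E2"), c(600, 1200)), simplify = FALSE),
    replicate(6, rec_from_labels(c("C", "F"), c(600, 300)), simplify = FALSE))
  params <- compute_parameter_table(recs)
  co <- aggregate_cohort(params)
  expect_equal(unname(co$pct_performing["E2"]), 33)   # 3/9 rounds to 33
  expect_equal(unname(co$pct_performing["F"]), 67)    # 6/9 rounds up to 67
  expect_equal(unname(co$pct_performing["G"]), 0)
  expect_equal(co$n, 9L)

  one <- aggregate_cohort(params[1, ])
  expect_equal(one$summary$se[one$summary$variable == "total_c_min"], 0)

  params2 <- params
  params2$genotype_id[1] <- "other"
  expect_error(aggregate_cohort(params2), "mixed genotypes")
  expect_error(aggregate_cohort(params[0, ]), "empty")
})

test_that("every field matches the brute-force oracle on random recordings", {
  set.seed(404)
  for (i in 1:300) {
    rec <- random_recording()
    expect_equal(compute_parameters(rec), oracle_params(rec))
  }
})

test_that("per-label totals conserve the recording duration", {
  set.seed(505)
  for (i in 1:50) {
    rec <- random_recording()
    p <- compute_parameters(rec)
    expect_equal(p$total_np_min + p$total_c_min + p$total_pd_min +
                 p$total_rpd_min + p$total_e1_min + p$total_e2_min +
                 p$total_f_min + p$total_g_min,
                 rec$total_ms / 60000)
  }
})

test_that("bout statistics obey their algebraic invariants", {
  set.seed(606)
  for (i in 1:40) {
    rec <- random_recording()
    p <- compute_parameters(rec)
    expect_lte(p$max_e1_min, p$total_e1_min + 1e-12)
    expect_lte(p$max_e2_min, p$total_e2_min + 1e-12)
    if (p$n_e2 > 0) expect_equal(p$mean_e2_min * p$n_e2, p$total_e2_min)
    if (p$n_e1 > 0) expect_equal(p$mean_e1_min * p$n_e1, p$total_e1_min)
    # a stricter sustained threshold never increases the sustained total
    p20 <- compute_parameters(rec, param_config(sustained_E2_threshold_min = 20))
    expect_lte(p20$total_e2_sustained_min, p$total_e2_sustained_min + 1e-12)
  }
})

test_that("appending a phloem-ingestion bout raises the E2 statistics", {
  base <- rec_from_labels(c("C", "E2", "C"), c(600, 900, 600))
  more <- rec_from_labels(c("C", "E2", "C", "E1", "E2"),
                          c(600, 900, 600, 60, 1800))
  pb <- compute_parameters(base); pm <- compute_parameters(more)
  expect_gt(pm$n_e2, pb$n_e2)
  expect_gt(pm$total_e2_min, pb$total_e2_min)
  expect_gte(pm$max_e2_min, pb$max_e2_min)
})
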