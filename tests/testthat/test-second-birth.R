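cs <- default_codesets()
spec11 <- builtin_algorithms(11)[[1]]
spec2 <- builtin_algorithms(2)[[1]]

gold_two <- function() {
  pop <- rbind(make_population("w1", "1990-01", 1),   # two births
               make_population("w2", "1991-01", 1))   # one birth
  links <- rbind(make_links("w1", "2016-03"), make_links("w1", "2018-04"),
                 make_links("w2", "2017-06"))
  build_gold_standard(pop, links)
}

test_that("second-birth gold uses earliest as anchor, second as reference", {
  g2 <- second_birth_gold(gold_two())
  w1 <- g2[g2$woman_id == "w1", ]
  expect_equal(w1$first_month, parse_month("2016-03"))
  expect_true(w1$second_positive)
  expect_equal(w1$second_month, parse_month("2018-04"))
  w2 <- g2[g2$woman_id == "w2", ]
  expect_false(w2$second_positive)
  expect_true(is.na(w2$second_month))

  # three births: reference is the second-earliest, not the latest
  pop <- make_population("w1", "1990-01", 1)
  links <- rbind(make_links("w1", "2015-01"), make_links("w1", "2017-02"),
                 make_links("w1", "2019-03"))
  g3 <- second_birth_gold(build_gold_standard(pop, links))
  expect_equal(g3$second_month, parse_month("2017-02"))
  g3l <- second_birth_gold(build_gold_standard(pop, links), reference = "latest")
  expect_equal(g3l$second_month, parse_month("2019-03"))
})

test_that("washout restriction hides early claims and dates the next event", {
  g2 <- second_birth_gold(gold_two())
  first <- parse_month("2016-03")

  # qualifying code 8 months after the first birth, washout 11: no detection
  claims <- make_claims("w1", format_month_index(first + 8L), "procedure", cs$procedure[1])
  ev <- detect_second_events(claims, spec2, cs, g2, k = 11)
  expect_equal(nrow(ev), 0L)

  # postpartum echo at +1 plus a true second event at +25: washout 11 keeps
  # only the second, dated at its earliest month
  claims <- rbind(
    make_claims("w1", format_month_index(first + 1L), "procedure", cs$procedure[1]),
    make_claims("w1", format_month_index(first + 25L), "procedure", cs$procedure[1]),
    make_claims("w1", format_month_index(first + 26L), "procedure", cs$procedure[1])
  )
  ev <- detect_second_events(claims, spec2, cs, g2, k = 11)
  expect_equal(ev$event_month, first + 25L)

  # short washout turns a postpartum echo into a false positive for a
  # one-child woman
  first2 <- parse_month("2017-06")
  claims <- make_claims("w2", format_month_index(first2 + 3L), "diagnosis", "O86")
  ev <- detect_second_events(claims, spec11, cs, g2, k = 2)
  expect_equal(ev$woman_id, "w2")
  ev <- detect_second_events(claims, spec11, cs, g2, k = 4)
  expect_equal(nrow(ev), 0L)
})

test_that("washout scan covers the k range, reuses the metrics path, breaks ties low", {
  ds <- generate_synthetic_claims(synth_config(n_women = 4000, seed = 7,
                                               p_second_birth = 0.5))
  gold <- build_gold_standard(ds$population, ds$links)
  scan <- washout_scan(gold, ds$claims, spec11, cs)
  expect_s3_class(scan, "washout_scan")
  expect_equal(nrow(scan$results), 23L)
  expect_equal(scan$results$k, 2:24)
  # population fixed across k
  expect_equal(unique(scan$results$tp + scan$results$fn),
               sum(scan$population$second_positive))
  expect_equal(unique(scan$results$tn + scan$results$fp),
               sum(!scan$population$second_positive))
  # Youden identity holds row-wise (single metrics code path)
  expect_equal(scan$results$youden,
               scan$results$sens / 100 + scan$results$spec / 100 - 1)
  # argmax with ties broken toward the smaller k
  expect_equal(scan$best_k,
               scan$results$k[which(scan$results$youden ==
                                      max(scan$results$youden))][1])

  # single-k scan
  scan1 <- washout_scan(gold, ds$claims, spec11, cs, k_range = 11)
  expect_equal(nrow(scan1$results), 1L)
  expect_equal(scan1$best_k, 11L)
})

test_that("noiseless claims give Youden 1 below the minimum inter-birth gap", {
  # every birth coded exactly in its month, no echoes/noise/silence
  cfg <- synth_config(n_women = 3000, seed = 11, p_silent_birth = 0,
                      p_dx = 1, p_proc = 0, p_med = 0, p_suspected = 0,
                      p_discharge_shift = 0, echo_pre = 0, echo_post = 0,
                      fp_rate = 0, p_second_birth = 0.6,
                      gap_mean = 30, gap_sd = 0, gap_min = 30,
                      p_ineligible_age = 0, window_end = "2022-01",
                      # cap maternal age below the 15-49 boundary so no
                      # second birth can fall outside age eligibility
                      age_band_weights = c(0.01, 0.086, 0.241, 0.347,
                                           0.25, 0.066, 0))
  # births can sit near the window end; restrict to women whose second
  # birth (if any) is observed: generator drops out-of-window seconds, so
  # single-birth women near the end are genuine negatives here
  ds <- generate_synthetic_claims(cfg)
  gold <- build_gold_standard(ds$population, ds$links,
                              c(parse_month("2014-04"), parse_month("2022-02")))
  scan <- washout_scan(gold, ds$claims, builtin_algorithms(1)[[1]], cs,
                       k_range = 2:29)
  below <- scan$results[scan$results$k < 30, ]
  expect_true(all(below$youden == 1))
})
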