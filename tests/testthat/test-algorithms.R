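cs <- default_codesets()

test_that("the built-in roster has 32 algorithms with the published structure", {
  specs <- builtin_algorithms()
  expect_length(specs, 32)
  expect_equal(vapply(specs, `[[`, 1L, "id"), 1:32)
  get <- function(i) specs[[i]]
  expect_equal(get(2)$conditions, "B")
  expect_equal(get(3)$conditions, "C")
  expect_equal(sort(get(10)$conditions), c("A_susp", "B", "C"))
  expect_equal(get(10)$op, "and")
  expect_equal(sort(get(11)$conditions), c("A_susp", "B", "C"))
  expect_equal(get(11)$op, "or")
  expect_equal(get(18)$conditions, c("A", "B", "C"))
  expect_equal(get(18)$op, "or")
  # 19-32: preterm-excluded duplicates of the 14 diagnosis-referencing
  # algorithms; the 4 diagnosis-free ones are not duplicated
  expect_equal(get(19)$conditions, "A_pre_susp")
  expect_equal(sort(get(25)$conditions), c("A_pre_susp", "B", "C"))
  expect_equal(get(25)$op, "or")
  expect_equal(get(32)$conditions, c("A_pre", "B", "C"))
  expect_equal(get(32)$op, "or")
  pre <- vapply(specs[19:32], function(s)
    any(s$conditions %in% c("A_pre", "A_pre_susp")), TRUE)
  expect_true(all(pre))
  dxfree <- vapply(specs[19:32], function(s)
    all(s$conditions %in% c("B", "C")), TRUE)
  expect_false(any(dxfree))
})

test_that("suspected-flag semantics: A requires unflagged, A+susp permits both", {
  m <- "2020-05"
  unflagged <- make_claims("w", m, "diagnosis", "O80", 0L)
  flagged <- make_claims("w", m, "diagnosis", "O80", 1L)
  expect_equal(condition_months(unflagged, "A", cs), parse_month(m))
  expect_equal(condition_months(unflagged, "A_susp", cs), parse_month(m))
  expect_equal(condition_months(flagged, "A", cs), integer(0))
  expect_equal(condition_months(flagged, "A_susp", cs), parse_month(m))
  # preterm variant drops O60 even when flagged
  pre <- make_claims("w", m, "diagnosis", "O60", 1L)
  expect_equal(condition_months(pre, "A_pre_susp", cs), integer(0))
  expect_equal(condition_months(pre, "A_susp", cs), parse_month(m))
  # suspected flag is meaningless outside the diagnosis domain
  proc <- make_claims("w", m, "procedure", cs$procedure[1], 1L)
  expect_equal(condition_months(proc, "B", cs), parse_month(m))
})

test_that("event dating takes the latest recorded month across code types", {
  spec_b <- builtin_algorithms(2)[[1]]
  one <- make_claims("w", "2020-05", "procedure", cs$procedure[1])
  expect_equal(detect_event(one, spec_b, cs),
               list(detected = TRUE, event_month = parse_month("2020-05")))

  # postpartum echo pushes the date to the latest month
  echo <- rbind(make_claims("w", "2020-04", "diagnosis", "O80"),
                make_claims("w", "2020-06", "diagnosis", "O80"))
  got <- detect_event(echo, builtin_algorithms(1)[[1]], cs)
  expect_equal(got$event_month, parse_month("2020-06"))

  # AND across domains: diagnosis alone does not satisfy [A+susp] and [B]
  dx_only <- make_claims("w", "2020-05", "diagnosis", "O80")
  expect_false(detect_event(dx_only, builtin_algorithms(4)[[1]], cs)$detected)

  # but different months jointly define one event under woman-level AND
  both <- rbind(make_claims("w", "2020-05", "diagnosis", "O80"),
                make_claims("w", "2020-07", "procedure", cs$procedure[1]))
  got <- detect_event(both, builtin_algorithms(4)[[1]], cs)
  expect_true(got$detected)
  expect_equal(got$event_month, parse_month("2020-07"))

  # same-month mode requires co-occurrence
  expect_false(detect_event(both, builtin_algorithms(4)[[1]], cs,
                            and_mode = "same-month")$detected)
  same <- rbind(make_claims("w", "2020-05", "diagnosis", "O80"),
                make_claims("w", "2020-05", "procedure", cs$procedure[1]))
  expect_true(detect_event(same, builtin_algorithms(4)[[1]], cs,
                           and_mode = "same-month")$detected)
})

test_that("claims outside the observation window are ignored", {
  spec_b <- builtin_algorithms(2)[[1]]
  before <- make_claims("w", "2014-03", "procedure", cs$procedure[1])
  after <- make_claims("w", "2023-02", "procedure", cs$procedure[1])
  expect_false(detect_event(before, spec_b, cs)$detected)
  expect_false(detect_event(after, spec_b, cs)$detected)
})

test_that("detect_event and detect_events match the brute-force oracle", {
  set.seed(402)
  specs <- builtin_algorithms()
  for (rep in 1:120) {
    claims <- random_claims("w")
    spec <- specs[[sample.int(32, 1)]]
    want <- oracle_detect(claims, spec, cs)
    expect_identical(detect_event(claims, spec, cs), want)
    ev <- detect_events(claims, list(spec), cs)
    if (want$detected) {
      expect_equal(nrow(ev), 1L)
      expect_equal(ev$event_month, want$event_month)
    } else {
      expect_equal(nrow(ev), 0L)
    }
  }
})

test_that("condition month-sets nest: A in A+susp, preterm-excluded in full", {
  set.seed(403)
  for (rep in 1:40) {
    claims <- random_claims("w")
    a <- condition_months(claims, "A", cs)
    asusp <- condition_months(claims, "A_susp", cs)
    apre <- condition_months(claims, "A_pre", cs)
    apresusp <- condition_months(claims, "A_pre_susp", cs)
    expect_true(all(a %in% asusp))
    expect_true(all(apre %in% a))
    expect_true(all(apresusp %in% asusp))
  }
})

test_that("AND detections are a subset of OR detections over the same conditions", {
  set.seed(404)
  claims <- do.call(rbind, lapply(sprintf("w%02d", 1:40), random_claims))
  and_or <- list(c(4L, 5L), c(8L, 9L), c(10L, 11L), c(17L, 18L))
  for (pair in and_or) {
    ev_and <- detect_events(claims, builtin_algorithms(pair[1]), cs)
    ev_or <- detect_events(claims, builtin_algorithms(pair[2]), cs)
    expect_true(all(ev_and$woman_id %in% ev_or$woman_id))
  }
})
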