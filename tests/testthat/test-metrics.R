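test_that("month matching tolerates a one-month claim lag, asymmetrically", {
  expect_true(months_match(parse_month("2020-06"), parse_month("2020-05")))
  expect_true(months_match(parse_month("2020-05"), parse_month("2020-05")))
  expect_false(months_match(parse_month("2020-05"), parse_month("2020-06")))
  expect_false(months_match(parse_month("2020-07"), parse_month("2020-05")))
  expect_false(months_match(NA_integer_, parse_month("2020-05")))
})

test_that("confusion tabulation follows the woman-level rules", {
  gold_of <- function(pos_months, neg_n) {
    women <- data.table::data.table(
      woman_id = c(names(pos_months), sprintf("n%d", seq_len(neg_n))),
      gold_positive = c(rep(TRUE, length(pos_months)), rep(FALSE, neg_n)),
      gold_month = c(unlist(pos_months), rep(NA_integer_, neg_n))
    )
    list(women = women)
  }
  m0 <- parse_month("2020-05")

  # detected and matching
  g <- gold_of(list(p1 = m0), 0)
  ct <- build_confusion(g, data.frame(woman_id = "p1", event_month = m0))
  expect_equal(unclass(ct), c(tp = 1L, tn = 0L, fn = 0L, fp = 0L))

  # detected three months late: FN, not FP
  ct <- build_confusion(g, data.frame(woman_id = "p1", event_month = m0 + 3L))
  expect_equal(unclass(ct), c(tp = 0L, tn = 0L, fn = 1L, fp = 0L))

  # 5-woman fixture: 2 positives (one matched, one undetected),
  # 3 negatives (one detected)
  g <- gold_of(list(p1 = m0, p2 = m0), 3)
  ev <- data.frame(woman_id = c("p1", "n1"), event_month = c(m0, m0))
  ct <- build_confusion(g, ev)
  expect_equal(unclass(ct), c(tp = 1L, tn = 2L, fn = 1L, fp = 1L))

  # events must reference cohort women
  expect_error(build_confusion(g, data.frame(woman_id = "ghost", event_month = m0)),
               "referential error")
  expect_error(build_confusion(g, data.frame(woman_id = c("p1", "p1"),
                                             event_month = c(m0, m0))),
               "multiple events")
})

test_that("metric formulas agree with an independent recomputation", {
  set.seed(911)
  has_e1071 <- requireNamespace("e1071", quietly = TRUE)
  for (rep in 1:1000) {
    tp <- sample(0:500, 1); tn <- sample(0:500, 1)
    fn <- sample(0:500, 1); fp <- sample(0:500, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- compute_metrics(confusion_table(tp, tn, fn, fp))
    n <- tp + tn + fn + fp
    expect_equal(m$sensitivity[["est"]], tp / (tp + fn))
    expect_equal(m$specificity[["est"]], tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$ppv[["est"]], tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv[["est"]], tn / (tn + fn))
    expect_equal(m$youden, m$sensitivity[["est"]] + m$specificity[["est"]] - 1)
    po <- (tp + tn) / n
    pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
    expect_equal(m$kappa, (po - pe) / (1 - pe))
    if (has_e1071 && rep <= 50) {
      tab <- matrix(c(tp, fp, fn, tn), nrow = 2)
      expect_equal(m$kappa, e1071::classAgreement(tab)$kappa)
    }
  }
})

test_that("degenerate tables give perfect or undefined metrics, not errors", {
  perfect <- compute_metrics(confusion_table(50, 50, 0, 0))
  expect_equal(perfect$sensitivity[["est"]], 1)
  expect_equal(perfect$specificity[["est"]], 1)
  expect_equal(perfect$ppv[["est"]], 1)
  expect_equal(perfect$npv[["est"]], 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$youden, 1)

  no_pos <- compute_metrics(confusion_table(0, 10, 0, 5))
  expect_true(is.na(no_pos$sensitivity[["est"]]))
  expect_false(is.na(no_pos$specificity[["est"]]))
  all_zero <- compute_metrics(confusion_table(0, 0, 0, 0))
  expect_true(is.na(all_zero$kappa))
})

test_that("kappa is near zero when detection is independent of gold status", {
  # expectation under independence: cells proportional to marginal products
  p_pos <- 0.3; p_det <- 0.4; n <- 1e6
  ct <- confusion_table(tp = n * p_pos * p_det, fn = n * p_pos * (1 - p_det),
                        fp = n * (1 - p_pos) * p_det, tn = n * (1 - p_pos) * (1 - p_det))
  expect_equal(compute_metrics(ct)$kappa, 0, tolerance = 1e-6)
})

test_that("Wald and Wilson intervals behave and clip to [0, 1]", {
  expect_equal(proportion_ci(0, 100)[1], 0)
  expect_equal(proportion_ci(100, 100)[2], 1)
  expect_true(all(is.na(proportion_ci(0, 0))))
  wald <- proportion_ci(30, 100)
  expect_equal(wald, 0.3 + c(-1, 1) * qnorm(0.975) * sqrt(0.3 * 0.7 / 100))
  wilson <- proportion_ci(30, 100, method = "wilson")
  expect_true(wilson[1] > 0 && wilson[2] < 1)
  # the two methods agree closely at large n
  expect_equal(proportion_ci(25361, 37934),
               proportion_ci(25361, 37934, method = "wilson"), tolerance = 1e-4)
  # Wilson never collapses at the boundary
  expect_gt(proportion_ci(0, 100, method = "wilson")[2], 0)
})

test_that("report rows share the gold marginals and cover every algorithm", {
  pop <- rbind(make_population("w1", "1990-01", 1),
               make_population("w2", "1991-01", 1),
               make_population("w3", "1992-01", 1))
  links <- make_links("w1", "2018-05")
  gold <- build_gold_standard(pop, links)
  claims <- rbind(
    make_claims("w1", "2018-05", "procedure", default_codesets()$procedure[1]),
    make_claims("w2", "2019-01", "diagnosis", "O80")
  )
  rep32 <- report_table(gold, claims)
  expect_equal(nrow(rep32), 32L)
  expect_equal(unique(rep32$tp + rep32$fn), 1L)
  expect_equal(unique(rep32$tn + rep32$fp), 2L)

  # empty claims: nothing detected anywhere
  rep0 <- report_table(gold, empty_claims())
  expect_true(all(rep0$tp == 0L & rep0$fp == 0L))
  expect_true(all(rep0$fn == 1L & rep0$tn == 2L))
})
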