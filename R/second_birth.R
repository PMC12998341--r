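## Second-birth washout scan.
##
## Delivery diagnosis codes recur at prepartum and postpartum visits, so a
## single birth can masquerade as several closely spaced ones. To decide
## how long after a first birth new childbirth codes should count as a NEW
## event, detection is re-run with claims restricted to months at least k
## after the first (gold) birth, for k = 2..24 months, and the k
## maximising the Youden index is selected. The population is the women
## with at least one qualifying gold birth; a woman is second-positive
## when she has two or more.

#' Per-woman first/second birth reference from the gold standard
#'
#' @param gold a [build_gold_standard] result (its `births` table must be
#'   retained).
#' @param reference `"second"` (default; the second-earliest qualifying
#'   birth) or `"latest"` (the most recent one) as the second-birth
#'   reference month for women with three or more births.
#' @return data.table, one row per woman with at least one qualifying
#'   birth: `woman_id`, `first_month`, `second_positive`, `second_month`
#'   (NA for single-birth women).
#' @export
second_birth_gold <- function(gold, reference = c("second", "latest")) {
  reference <- match.arg(reference)
  births <- gold$births
  if (is.null(births)) stop("gold standard lacks the per-birth table")
  births[, .(
    first_month = min(birth_month),
    second_positive = .N >= 2L,
    second_month = if (.N >= 2L) {
      if (reference == "second") sort(birth_month)[2L] else max(birth_month)
    } else NA_integer_
  ), by = woman_id]
}

#' Detect a second birth after a washout window
#'
#' Applies an algorithm to each woman's claims restricted to months at
#' least `k` months after her first (gold) birth; the event month is the
#' EARLIEST qualifying month in the restricted range — the next distinct
#' event after the washout, so that dating does not alias onto a later
#' third birth.
#'
#' @param claims full claims table.
#' @param spec an [algorithm_spec].
#' @param cs a [codesets] object.
#' @param gold2 a [second_birth_gold] result (defines the population and
#'   each woman's `first_month`).
#' @param k washout length in months, 2..24.
#' @param window half-open month-index window.
#' @param and_mode see [detect_event].
#' @return data.table of detected events: `woman_id`, `event_month`.
#' @export
detect_second_events <- function(claims, spec, cs, gold2, k,
                                 window = default_window(),
                                 and_mode = c("anytime", "same-month")) {
  and_mode <- match.arg(and_mode)
  stopifnot(k >= 0)
  cl <- classify_claims(claims, cs)
  cl <- cl[month_idx >= window[1] & month_idx < window[2]]
  cl <- merge(cl, gold2[, .(woman_id, cutoff = first_month + as.integer(k))],
              by = "woman_id")  # restricts to the >=1-birth population
  cl <- cl[month_idx >= cutoff]
  long <- qualifying_months_long(cl)
  agg <- aggregate_months(long, min)
  ev <- evaluate_specs(agg, long, list(spec), and_mode, extreme = min)
  ev[, .(woman_id, event_month)]
}

#' Washout-window scan for second births
#'
#' Runs [detect_second_events()] for each washout length `k`, tabulates
#' against the second-birth gold reference with the same month-tolerant
#' matching rule as the first-birth validation, and selects the `k` with
#' the highest Youden index (ties broken toward the smaller `k`).
#'
#' @inheritParams detect_second_events
#' @param gold a [build_gold_standard] result.
#' @param k_range integer vector of washout lengths (months), default
#'   `2:24`.
#' @param reference passed to [second_birth_gold].
#' @param ci_level,ci_method passed to [compute_metrics].
#' @return object of class `washout_scan`: list with `results` (one row
#'   per `k`: counts and metrics, same columns as [report_table] plus
#'   `k`), `best_k`, `algorithm_id`, and `population` (the
#'   [second_birth_gold] table).
#' @export
washout_scan <- function(gold, claims, spec, cs = default_codesets(),
                         k_range = 2:24, window = gold$window,
                         and_mode = "anytime", reference = "second",
                         ci_level = 0.95, ci_method = "wald") {
  gold2 <- second_birth_gold(gold, reference)
  # adapt to the metrics module's gold interface: positives are the
  # multi-birth women, reference month is the second birth
  gold_like <- list(women = gold2[, .(woman_id, gold_positive = second_positive,
                                      gold_month = second_month)])
  rows <- lapply(k_range, function(k) {
    ev <- detect_second_events(claims, spec, cs, gold2, k, window, and_mode)
    m <- compute_metrics(build_confusion(gold_like, ev), ci_level, ci_method)
    cbind(data.table::data.table(k = as.integer(k)),
          metric_row(spec$id, spec$label, m))
  })
  results <- data.table::rbindlist(rows)
  best_k <- results$k[which.max(results$youden)]  # which.max takes first tie
  structure(list(results = results[], best_k = best_k,
                 algorithm_id = spec$id, population = gold2[]),
            class = "washout_scan")
}

#' @export
print.washout_scan <- function(x, ...) {
  n_pos <- sum(x$population$second_positive)
  cat(sprintf("<washout_scan> algorithm %d, k = %d..%d; %d women (%d second-positive)\n",
              x$algorithm_id, min(x$results$k), max(x$results$k),
              nrow(x$population), n_pos))
  best <- x$results[k == x$best_k]
  cat(sprintf("  best k = %d months (Youden %.2f, sensitivity %.1f%%, specificity %.1f%%)\n",
              x$best_k, round_half_up(best$youden, 2),
              round_half_up(best$sens, 1), round_half_up(best$spec, 1)))
  invisible(x)
}
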