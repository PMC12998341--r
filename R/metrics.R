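## Validation metrics.
##
## Matching is month-tolerant and asymmetric: a claim-dated event may lag
## the linkage-based birth month by one month (discharge claims are billed
## in the discharge month) but may not precede it. Classification is at
## woman level: a gold-positive woman is a true positive only when
## detected AND dated within tolerance; a detected-but-mismatched
## gold-positive is a false negative (not also a false positive), so the
## gold marginals tp+fn and tn+fp are identical for every algorithm run
## on one dataset.

#' Month-tolerant event matching
#'
#' True when the gold month equals the algorithm month or the month
#' before it (`gold == alg` or `gold == alg - 1`).
#'
#' @param alg_month,gold_month month-index vectors.
#' @return logical vector (`FALSE` where either side is `NA`).
#' @examples
#' months_match(month_index(2020, 6), month_index(2020, 5))  # TRUE
#' months_match(month_index(2020, 5), month_index(2020, 6))  # FALSE
#' @export
months_match <- function(alg_month, gold_month) {
  out <- gold_month == alg_month | gold_month == alg_month - 1L
  out & !is.na(out)
}

#' Construct a woman-level confusion table
#'
#' @param tp,tn,fn,fp non-negative integer counts.
#' @return object of class `confusion_table` (named integer vector).
#' @export
confusion_table <- function(tp, tn, fn, fp) {
  ct <- c(tp = as.integer(tp), tn = as.integer(tn),
          fn = as.integer(fn), fp = as.integer(fp))
  if (anyNA(ct) || any(ct < 0L)) stop("confusion counts must be non-negative integers")
  structure(ct, class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion table: TP=%d TN=%d FN=%d FP=%d (n=%d)\n",
              x["tp"], x["tn"], x["fn"], x["fp"], sum(x)))
  invisible(x)
}

#' Tabulate one algorithm's detections against the gold standard
#'
#' @param gold a [build_gold_standard] result (or any list with a `women`
#'   data.table holding `woman_id`, `gold_positive`, `gold_month`).
#' @param events data.table/data.frame of detected women for ONE
#'   algorithm: columns `woman_id`, `event_month`; women absent from
#'   `events` are undetected.
#' @return a [confusion_table].
#' @export
build_confusion <- function(gold, events) {
  women <- gold$women
  events <- data.table::as.data.table(events)
  if (nrow(events)) {
    if (anyDuplicated(events$woman_id)) {
      stop("referential error: multiple events for one woman")
    }
    unknown <- setdiff(events$woman_id, women$woman_id)
    if (length(unknown)) {
      stop("referential error: events for women absent from the gold standard: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  w <- merge(women[, .(woman_id, gold_positive, gold_month)],
             events[, .(woman_id, event_month = as.integer(event_month))],
             by = "woman_id", all.x = TRUE)
  detected <- !is.na(w$event_month)
  hit <- detected & w$gold_positive & months_match(w$event_month, w$gold_month)
  confusion_table(
    tp = sum(hit),
    fn = sum(w$gold_positive & !hit),
    fp = sum(!w$gold_positive & detected),
    tn = sum(!w$gold_positive & !detected)
  )
}

#' Binomial proportion confidence interval
#'
#' Wald normal-approximation interval (default), clipped to `[0, 1]`, or
#' the Wilson score interval.
#'
#' @param successes,n integer counts, `0 <= successes <= n`.
#' @param level confidence level.
#' @param method `"wald"` or `"wilson"`.
#' @return numeric `c(lo, hi)`; `c(NA, NA)` when `n == 0`.
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, centre - half), min(1, centre + half))
  }
}

## Cohen's kappa from a 2x2 table: chance-corrected agreement between the
## algorithm classification and the gold standard, expected agreement from
## the two-rater marginal products.
cohen_kappa <- function(tp, tn, fn, fp) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)  # avoid integer overflow at claims scale
  fn <- as.numeric(fn); fp <- as.numeric(fp)
  n <- tp + tn + fn + fp
  if (n == 0) return(NA_real_)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Validation metrics from a confusion table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value (each with a binomial confidence interval), Cohen's kappa and the
#' Youden index (`sensitivity + specificity - 1`). A metric whose
#' denominator is zero is returned as `NA` rather than raising an error.
#'
#' @param ct a [confusion_table] (or anything accepted by
#'   `confusion_table(tp, tn, fn, fp)` supplied as a named vector/list).
#' @param ci_level confidence level for the proportion intervals.
#' @param ci_method `"wald"` (default) or `"wilson"`; see [proportion_ci].
#' @return object of class `metric_set`: list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv` (each `c(est, lo, hi)` on
#'   the proportion scale), `kappa`, `youden`, and `counts`.
#' @examples
#' m <- compute_metrics(confusion_table(tp = 25361, tn = 807660,
#'                                      fn = 12573, fp = 9032))
#' m
#' @export
compute_metrics <- function(ct, ci_level = 0.95,
                            ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (!inherits(ct, "confusion_table")) {
    ct <- confusion_table(ct[["tp"]], ct[["tn"]], ct[["fn"]], ct[["fp"]])
  }
  tp <- ct[["tp"]]; tn <- ct[["tn"]]; fn <- ct[["fn"]]; fp <- ct[["fp"]]
  prop <- function(x, n) {
    if (n == 0) return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- proportion_ci(x, n, ci_level, ci_method)
    c(est = x / n, lo = ci[1], hi = ci[2])
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  structure(
    list(
      sensitivity = sens,
      specificity = spec,
      ppv = prop(tp, tp + fp),
      npv = prop(tn, tn + fn),
      kappa = cohen_kappa(tp, tn, fn, fp),
      youden = sens[["est"]] + spec[["est"]] - 1,
      counts = ct,
      ci_level = ci_level,
      ci_method = ci_method
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, digits = 1, ...) {
  pct <- function(v) {
    if (anyNA(v)) return("     --")
    sprintf("%5.1f%% (%.1f-%.1f)", round_half_up(100 * v[["est"]], digits),
            round_half_up(100 * v[["lo"]], digits),
            round_half_up(100 * v[["hi"]], digits))
  }
  print(x$counts)
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat("  PPV:        ", pct(x$ppv), "\n")
  cat("  NPV:        ", pct(x$npv), "\n")
  cat(sprintf("  kappa: %.2f   Youden: %.2f   (%s %.0f%% CI)\n",
              round_half_up(x$kappa, 2), round_half_up(x$youden, 2),
              x$ci_method, 100 * x$ci_level))
  invisible(x)
}

## round half away from zero (presentation rounding; base round() is
## round-half-even). Internal values are never rounded.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full validation report over a set of algorithms
#'
#' Runs [detect_events()] and [build_confusion()] for every algorithm and
#' assembles a one-row-per-algorithm table of counts and metrics.
#' Proportions are reported as percentages (0-100, unrounded); kappa and
#' Youden on their natural scale.
#'
#' @inheritParams detect_events
#' @param gold a [build_gold_standard] result.
#' @param ci_level,ci_method passed to [compute_metrics].
#' @return data.table with columns `algorithm_id`, `definition`, `tp`,
#'   `tn`, `fn`, `fp`, `sens`, `sens_lo`, `sens_hi`, `spec`, `spec_lo`,
#'   `spec_hi`, `ppv`, `ppv_lo`, `ppv_hi`, `npv`, `npv_lo`, `npv_hi`,
#'   `kappa`, `youden`.
#' @export
report_table <- function(gold, claims, specs = builtin_algorithms(),
                         cs = default_codesets(), window = gold$window,
                         and_mode = "anytime", ci_level = 0.95,
                         ci_method = "wald") {
  events <- detect_events(claims, specs, cs, window, and_mode)
  # the validation cohort is the eligible (husband-identified) population;
  # claims of out-of-cohort women play no role
  events <- events[woman_id %in% gold$women$woman_id]
  rows <- lapply(specs, function(spec) {
    ev <- events[algorithm_id == spec$id, .(woman_id, event_month)]
    m <- compute_metrics(build_confusion(gold, ev), ci_level, ci_method)
    metric_row(spec$id, spec$label, m)
  })
  data.table::rbindlist(rows)
}

metric_row <- function(id, label, m) {
  ct <- m$counts
  data.table::data.table(
    algorithm_id = id, definition = label,
    tp = ct[["tp"]], tn = ct[["tn"]], fn = ct[["fn"]], fp = ct[["fp"]],
    sens = 100 * m$sensitivity[["est"]],
    sens_lo = 100 * m$sensitivity[["lo"]], sens_hi = 100 * m$sensitivity[["hi"]],
    spec = 100 * m$specificity[["est"]],
    spec_lo = 100 * m$specificity[["lo"]], spec_hi = 100 * m$specificity[["hi"]],
    ppv = 100 * m$ppv[["est"]],
    ppv_lo = 100 * m$ppv[["lo"]], ppv_hi = 100 * m$ppv[["hi"]],
    npv = 100 * m$npv[["est"]],
    npv_lo = 100 * m$npv[["lo"]], npv_hi = 100 * m$npv[["hi"]],
    kappa = m$kappa, youden = m$youden
  )
}

#' Pretty-print a validation report
#'
#' Presentation rounding only: percentages half-up to one decimal, kappa
#' and Youden half-up to two decimals.
#'
#' @param report a [report_table()] result.
#' @return character vector of formatted lines, invisibly; printed as a
#'   side effect.
#' @export
format_report <- function(report) {
  f1 <- function(x) sprintf("%.1f", round_half_up(x, 1))
  f2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  lines <- c(
    sprintf("%-3s %-34s %7s %7s %6s %6s %6s %6s %6s %6s %6s %6s",
            "id", "definition", "TP", "TN", "FN", "FP",
            "sens", "spec", "PPV", "NPV", "kappa", "Youden"),
    vapply(seq_len(nrow(report)), function(i) {
      r <- report[i]
      sprintf("%-3d %-34s %7d %7d %6d %6d %6s %6s %6s %6s %6s %6s",
              r$algorithm_id, substr(r$definition, 1, 34),
              r$tp, r$tn, r$fn, r$fp,
              f1(r$sens), f1(r$spec), f1(r$ppv), f1(r$npv),
              f2(r$kappa), f2(r$youden))
    }, character(1))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
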