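## Phenotyping algorithms.
##
## Six condition symbols over a woman's claims:
##   A          delivery diagnosis code, suspected flag absent
##   A_susp     delivery diagnosis code, suspected flag permitted
##              (superset of A: flagged and unflagged records both qualify)
##   A_pre      as A, preterm-excluded diagnosis set
##   A_pre_susp as A_susp, preterm-excluded diagnosis set
##   B          delivery procedure code
##   C          delivery medication code (oxytocin/dinoprostone class)
##
## An algorithm is a flat AND/OR combination of condition symbols. The
## claims-derived childbirth month is the latest month recorded for any
## referenced condition ("latest month" dating), so codes from different
## months jointly define one event; by default an AND is satisfied at
## woman level (each condition somewhere in the window), with a stricter
## same-month co-occurrence mode available.

CONDITION_SYMBOLS <- c("A", "A_susp", "A_pre", "A_pre_susp", "B", "C")

#' Define a phenotyping algorithm
#'
#' @param id integer identifier (built-in roster uses 1..32).
#' @param conditions character vector of condition symbols among
#'   `r paste(CONDITION_SYMBOLS, collapse = ", ")`.
#' @param op `"or"` or `"and"`; irrelevant for a single condition.
#' @param label optional display label; a bracketed form such as
#'   `"[A+susp] or [B] or [C]"` is generated when omitted.
#' @return object of class `algorithm_spec`.
#' @examples
#' algorithm_spec(11, c("A_susp", "B", "C"), "or")
#' @export
algorithm_spec <- function(id, conditions, op = c("or", "and"), label = NULL) {
  op <- match.arg(op)
  conditions <- as.character(conditions)
  bad <- setdiff(conditions, CONDITION_SYMBOLS)
  if (length(bad)) stop("unknown condition symbol(s): ", paste(bad, collapse = ", "))
  if (length(conditions) == 0L) stop("an algorithm needs at least one condition")
  if (anyDuplicated(conditions)) stop("duplicated condition symbols")
  if (is.null(label)) {
    pretty <- c(A = "[A]", A_susp = "[A+susp]", A_pre = "[A(pre(-))]",
                A_pre_susp = "[A(pre(-))+susp]", B = "[B]", C = "[C]")
    label <- paste(pretty[conditions], collapse = paste0(" ", op, " "))
  }
  structure(list(id = as.integer(id), conditions = conditions, op = op,
                 label = label),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("Algorithm %d: %s\n", x$id, x$label))
  invisible(x)
}

#' The 32 built-in childbirth algorithms
#'
#' Algorithms 1-18 are every AND/OR combination of `[A+susp]`/`[A]`,
#' `[B]` and `[C]` in the published roster; algorithms 19-32 repeat the 14
#' of those that reference a diagnosis condition with the preterm-excluded
#' diagnosis set substituted (`A -> A_pre`, `A_susp -> A_pre_susp`); the
#' four diagnosis-free algorithms (`[B]`, `[C]`, `[B] and [C]`,
#' `[B] or [C]`) are not duplicated.
#'
#' @param ids optional integer vector to subset the roster.
#' @return list of [algorithm_spec] objects.
#' @examples
#' builtin_algorithms(11)[[1]]
#' @export
builtin_algorithms <- function(ids = 1:32) {
  base <- list(
    list(1L,  "A_susp",                   "or"),
    list(2L,  "B",                        "or"),
    list(3L,  "C",                        "or"),
    list(4L,  c("A_susp", "B"),           "and"),
    list(5L,  c("A_susp", "B"),           "or"),
    list(6L,  c("A_susp", "C"),           "and"),
    list(7L,  c("A_susp", "C"),           "or"),
    list(8L,  c("B", "C"),                "and"),
    list(9L,  c("B", "C"),                "or"),
    list(10L, c("A_susp", "B", "C"),      "and"),
    list(11L, c("A_susp", "B", "C"),      "or"),
    list(12L, "A",                        "or"),
    list(13L, c("A", "B"),                "and"),
    list(14L, c("A", "B"),                "or"),
    list(15L, c("A", "C"),                "and"),
    list(16L, c("A", "C"),                "or"),
    list(17L, c("A", "B", "C"),           "and"),
    list(18L, c("A", "B", "C"),           "or")
  )
  specs <- lapply(base, function(b) algorithm_spec(b[[1]], b[[2]], b[[3]]))
  # preterm-excluded duplicates of the diagnosis-referencing algorithms,
  # in roster order (1,4,5,6,7,10,11,12,...,18 -> 19..32)
  dx_ids <- vapply(specs, function(s) any(s$conditions %in% c("A", "A_susp")), TRUE)
  next_id <- 19L
  for (s in specs[dx_ids]) {
    conds <- s$conditions
    conds[conds == "A"] <- "A_pre"
    conds[conds == "A_susp"] <- "A_pre_susp"
    specs[[length(specs) + 1L]] <- algorithm_spec(next_id, conds, s$op)
    next_id <- next_id + 1L
  }
  stopifnot(length(specs) == 32L)
  specs[vapply(specs, `[[`, 1L, "id") %in% ids]
}

## classify claim records against the six condition symbols.
## Returns the claims data.table with one logical column per symbol.
classify_claims <- function(claims, cs) {
  cl <- validate_claims(claims)
  is_dx <- cl$domain == "diagnosis"
  dx_all <- is_dx & matches_diagnosis(cl$code, cs, exclude_preterm = FALSE)
  dx_pre <- is_dx & matches_diagnosis(cl$code, cs, exclude_preterm = TRUE)
  unflagged <- !cl$suspected
  cl[, `:=`(
    A          = dx_all & unflagged,
    A_susp     = dx_all,
    A_pre      = dx_pre & unflagged,
    A_pre_susp = dx_pre,
    B          = domain == "procedure" & code %in% cs$procedure,
    C          = domain == "medication" & code %in% cs$medication
  )]
  cl
}

validate_claims <- function(claims) {
  need <- c("woman_id", "year", "month", "domain", "code", "suspected")
  miss <- setdiff(need, names(claims))
  if (length(miss)) stop("schema error: claims table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cl <- data.table::as.data.table(claims)[, ..need]
  dom <- as.character(cl$domain)
  bad <- setdiff(unique(dom), c("diagnosis", "procedure", "medication"))
  if (length(bad)) stop("schema error: unknown claim domain(s): ",
                        paste(bad, collapse = ", "))
  cl[, .(woman_id = as.character(woman_id),
         month_idx = month_index(year, month),
         domain = dom,
         code = as.character(code),
         # the suspected flag is meaningful for diagnoses only
         suspected = as.logical(suspected) & dom == "diagnosis")]
}

#' Months in which a woman's claims satisfy one condition
#'
#' @param claims claims for a single woman (columns `woman_id`, `year`,
#'   `month`, `domain`, `code`, `suspected`).
#' @param condition a condition symbol (see [builtin_algorithms]).
#' @param cs a [codesets] object.
#' @param window optional half-open month-index window to restrict to.
#' @return sorted integer vector of month indices with at least one
#'   qualifying record.
#' @export
condition_months <- function(claims, condition, cs, window = NULL) {
  condition <- match.arg(condition, CONDITION_SYMBOLS)
  cl <- classify_claims(claims, cs)
  if (length(unique(cl$woman_id)) > 1L) stop("claims must belong to one woman")
  if (!is.null(window)) cl <- cl[month_idx >= window[1] & month_idx < window[2]]
  sort(unique(cl$month_idx[cl[[condition]]]))
}

#' Evaluate one algorithm on one woman's claims
#'
#' The expression is satisfied when, treating each referenced condition as
#' "has at least one qualifying month in the window", the AND/OR
#' combination evaluates true (`and_mode = "same-month"` additionally
#' requires the conditions of an AND to co-occur in a single month). If
#' satisfied, the event month is the latest month over all referenced
#' conditions with a non-empty month set.
#'
#' @param claims claims for a single woman.
#' @param spec an [algorithm_spec].
#' @param cs a [codesets] object.
#' @param window half-open month-index window.
#' @param and_mode `"anytime"` (woman-level AND, default) or
#'   `"same-month"`.
#' @return list with `detected` (logical) and `event_month` (month index
#'   or `NA`).
#' @export
detect_event <- function(claims, spec, cs, window = default_window(),
                         and_mode = c("anytime", "same-month")) {
  and_mode <- match.arg(and_mode)
  months <- lapply(spec$conditions, condition_months,
                   claims = claims, cs = cs, window = window)
  names(months) <- spec$conditions
  nonempty <- lengths(months) > 0L
  detected <- if (spec$op == "or") {
    any(nonempty)
  } else if (and_mode == "anytime") {
    all(nonempty)
  } else {
    length(Reduce(intersect, months)) > 0L
  }
  list(detected = detected,
       event_month = if (detected) max(unlist(months[nonempty])) else NA_integer_)
}

#' Evaluate algorithms over all women (vectorised)
#'
#' Fast path over a full claims table: equivalent to calling
#' [detect_event()] per woman and per algorithm.
#'
#' @param claims full claims table (see [detect_event] for schema).
#' @param specs list of [algorithm_spec] objects.
#' @param cs a [codesets] object.
#' @param window half-open month-index window.
#' @param and_mode see [detect_event].
#' @return data.table of detected events only: `algorithm_id`, `woman_id`,
#'   `event_month`.
#' @export
detect_events <- function(claims, specs = builtin_algorithms(),
                          cs = default_codesets(), window = default_window(),
                          and_mode = c("anytime", "same-month")) {
  and_mode <- match.arg(and_mode)
  if (inherits(specs, "algorithm_spec")) specs <- list(specs)
  cl <- classify_claims(claims, cs)
  cl <- cl[month_idx >= window[1] & month_idx < window[2]]
  long <- qualifying_months_long(cl)
  # latest qualifying month per woman x condition
  agg <- aggregate_months(long, max)
  evaluate_specs(agg, long, specs, and_mode, extreme = max)
}

## long table of distinct (woman, condition, month) qualifying triples
qualifying_months_long <- function(cl) {
  long <- data.table::melt(
    cl, id.vars = c("woman_id", "month_idx"),
    measure.vars = CONDITION_SYMBOLS,
    variable.name = "cond", value.name = "has", variable.factor = FALSE
  )
  unique(long[has == TRUE, .(woman_id, month_idx, cond)])
}

## grouped extreme with an explicit empty prototype (data.table probes j on
## an empty subset, which would warn on min/max of nothing)
aggregate_months <- function(long, extreme) {
  if (nrow(long) == 0L) {
    return(data.table::data.table(woman_id = character(), cond = character(),
                                  m_agg = integer()))
  }
  long[, .(m_agg = extreme(month_idx)), by = .(woman_id, cond)]
}

## shared spec evaluator for the vectorised paths.
## agg: per (woman, cond) a single month m_agg (latest for first-birth
## dating, earliest-after-cutoff for the washout scan); long: distinct
## (woman, month, cond) rows, used for same-month AND co-occurrence.
evaluate_specs <- function(agg, long, specs, and_mode, extreme) {
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    sub <- agg[cond %in% spec$conditions]
    if (nrow(sub) == 0L) {
      out[[i]] <- data.table::data.table(algorithm_id = integer(),
                                         woman_id = character(),
                                         event_month = integer())
      next
    }
    per_woman <- sub[, .(n_cond = .N, event_month = extreme(m_agg)),
                     by = woman_id]
    detected <- if (spec$op == "or") {
      per_woman
    } else {
      per_woman[n_cond == length(spec$conditions)]
    }
    if (spec$op == "and" && and_mode == "same-month" && nrow(detected)) {
      co <- long[cond %in% spec$conditions,
                 .(n_cond = data.table::uniqueN(cond)),
                 by = .(woman_id, month_idx)]
      ok <- unique(co[n_cond == length(spec$conditions), woman_id])
      detected <- detected[woman_id %in% ok]
    }
    out[[i]] <- detected[, .(algorithm_id = spec$id, woman_id, event_month)]
  }
  data.table::rbindlist(out)
}
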