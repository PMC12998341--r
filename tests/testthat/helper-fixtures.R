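# Shared fixture builders and independent (brute-force) oracles.
# The oracles deliberately use naive per-record loops, separate from the
# package's vectorised evaluation path.

library(data.table)

make_claims <- function(woman_id, month_str, domain, code, suspected = 0L) {
  mi <- parse_month(month_str)
  data.frame(
    woman_id = woman_id,
    year = month_index_year(mi),
    month = month_index_month(mi),
    domain = domain,
    code = code,
    suspected = suspected,
    stringsAsFactors = FALSE
  )
}

empty_claims <- function() {
  data.frame(woman_id = character(), year = integer(), month = integer(),
             domain = character(), code = character(), suspected = integer())
}

make_population <- function(woman_id, birth_month_str, husband_identified = 1L) {
  mi <- parse_month(birth_month_str)
  data.frame(woman_id = woman_id,
             birth_year = month_index_year(mi),
             birth_month = month_index_month(mi),
             husband_identified = husband_identified)
}

make_links <- function(mother_id, child_month_str) {
  mi <- parse_month(child_month_str)
  data.frame(mother_id = mother_id,
             child_birth_year = month_index_year(mi),
             child_birth_month = month_index_month(mi))
}

# record-by-record qualification check, one condition
oracle_condition_months <- function(claims, cond, cs, window = default_window()) {
  ms <- integer(0)
  for (i in seq_len(nrow(claims))) {
    r <- claims[i, ]
    mi <- month_index(r$year, r$month)
    if (mi < window[1] || mi >= window[2]) next
    susp <- as.logical(r$suspected) && r$domain == "diagnosis"
    ok <- switch(cond,
      A          = r$domain == "diagnosis" && !susp && matches_diagnosis(r$code, cs),
      A_susp     = r$domain == "diagnosis" && matches_diagnosis(r$code, cs),
      A_pre      = r$domain == "diagnosis" && !susp && matches_diagnosis(r$code, cs, TRUE),
      A_pre_susp = r$domain == "diagnosis" && matches_diagnosis(r$code, cs, TRUE),
      B          = r$domain == "procedure" && r$code %in% cs$procedure,
      C          = r$domain == "medication" && r$code %in% cs$medication
    )
    if (ok) ms <- c(ms, mi)
  }
  sort(unique(ms))
}

# truth-table evaluation of a flat AND/OR spec over condition month sets
oracle_detect <- function(claims, spec, cs, window = default_window()) {
  sets <- lapply(spec$conditions, oracle_condition_months,
                 claims = claims, cs = cs, window = window)
  nonempty <- lengths(sets) > 0L
  detected <- if (spec$op == "or") any(nonempty) else all(nonempty)
  list(detected = detected,
       event_month = if (detected) max(unlist(sets[nonempty])) else NA_integer_)
}

# random small claims fixture for one woman (mix of qualifying and
# non-qualifying codes, in- and slightly out-of-window months)
random_claims <- function(woman_id = "w", n_max = 10L) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(empty_claims())
  cs <- default_codesets()
  dom <- sample(c("diagnosis", "procedure", "medication"), n, replace = TRUE)
  code <- character(n)
  for (i in seq_len(n)) {
    code[i] <- switch(dom[i],
      diagnosis = sample(c(sample(cs$diagnosis, 1), "O20", "Z99", "O601", "XYZ"), 1),
      procedure = sample(c(cs$procedure, "PROC-OTHER"), 1),
      medication = sample(c(cs$medication, "MED-OTHER"), 1))
  }
  mi <- month_index(2014, 1) + sample.int(12 * 10, n, replace = TRUE)  # 2014-02 .. 2024-01
  data.frame(woman_id = woman_id,
             year = month_index_year(mi), month = month_index_month(mi),
             domain = dom, code = code,
             suspected = sample(0:1, n, replace = TRUE))
}
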