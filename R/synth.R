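## Synthetic claims-data generator.
##
## Emulates the statistical structure a claims extract shows around
## childbirth: month-granular live births among women aged 15-49 (linked
## to the mother via parent-child identifiers), "silent" uncomplicated
## deliveries that generate no reimbursed claim at all, delivery claims
## billed in the birth month or shifted one month to the discharge month,
## prepartum/postpartum repeats ("echoes") of diagnosis codes, suspected
## (rule-out) flags on diagnoses, low-rate childbirth-code noise among
## non-birthing women, and roughly two-year inter-birth intervals.
## Ground truth (every birth month and its silent flag) is retained so
## algorithm behaviour can be checked against known generative parameters.

#' Configuration for the synthetic claims generator
#'
#' Defaults encode the study conditions the package's validation targets:
#' a 4.4% in-window birth rate, the reported maternal-age band
#' distribution at childbirth, inter-birth gaps of about two years, and a
#' claims footprint in which roughly 30% of deliveries are uncovered
#' normal births with no claim at all.
#'
#' @param n_women number of women.
#' @param p_husband_identified probability the husband is identifiable
#'   (the cohort filter of the gold standard).
#' @param age_band_weights probabilities over maternal age bands
#'   15-19, 20-24, ..., 45-49 at the (first) birth; must sum to 1.
#' @param birth_rate probability a woman has at least one birth in the
#'   window.
#' @param p_second_birth probability a birthing woman has a second birth
#'   (dropped if it would fall outside the window).
#' @param gap_mean,gap_sd,gap_min inter-birth gap in months: rounded
#'   normal, truncated at `gap_min`.
#' @param p_silent_birth probability a birth generates no claims at all
#'   (uncomplicated normal delivery, not covered by insurance).
#' @param p_dx,p_proc,p_med per-birth emission probability of a delivery
#'   diagnosis / procedure / medication claim (independent domains).
#' @param p_suspected probability a diagnosis record carries the
#'   suspected flag.
#' @param p_discharge_shift probability a delivery claim is billed in the
#'   month after the birth (discharge month).
#' @param echo_pre per-month probability of a diagnosis repeat in each of
#'   the nine months before a (non-silent) birth.
#' @param echo_post per-month probability of a diagnosis repeat in months
#'   +2 and +3 after a (non-silent) birth.
#' @param p_preterm probability the birth's diagnosis code is drawn from
#'   the preterm-exclusion categories.
#' @param p_ineligible_age probability a birth is assigned a maternal age
#'   outside 15-49 (exercises the age filter; mirrors the rare linkage
#'   anomalies real registries show).
#' @param fp_rate monthly probability that a non-birthing woman emits a
#'   childbirth-set diagnosis code (rule-out noise; such records carry the
#'   suspected flag with doubled probability).
#' @param window_start,window_end `"YYYY-MM"` strings, both inclusive.
#' @param seed integer random seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_women = 10000,
                         p_husband_identified = 0.95,
                         age_band_weights = c(`15-19` = 0.010, `20-24` = 0.086,
                                              `25-29` = 0.241, `30-34` = 0.347,
                                              `35-39` = 0.247, `40-44` = 0.066,
                                              `45-49` = 0.003),
                         birth_rate = 0.044,
                         p_second_birth = 0.30,
                         gap_mean = 24, gap_sd = 6, gap_min = 10,
                         p_silent_birth = 0.30,
                         p_dx = 0.85, p_proc = 0.60, p_med = 0.55,
                         p_suspected = 0.12,
                         p_discharge_shift = 0.30,
                         echo_pre = 0.15, echo_post = 0.05,
                         p_preterm = 0.056,
                         p_ineligible_age = 0.002,
                         fp_rate = 1e-4,
                         window_start = "2014-04", window_end = "2023-01",
                         seed = 1L) {
  cfg <- list(n_women = as.integer(n_women),
              p_husband_identified = p_husband_identified,
              age_band_weights = age_band_weights,
              birth_rate = birth_rate, p_second_birth = p_second_birth,
              gap_mean = gap_mean, gap_sd = gap_sd, gap_min = gap_min,
              p_silent_birth = p_silent_birth,
              p_dx = p_dx, p_proc = p_proc, p_med = p_med,
              p_suspected = p_suspected,
              p_discharge_shift = p_discharge_shift,
              echo_pre = echo_pre, echo_post = echo_post,
              p_preterm = p_preterm, p_ineligible_age = p_ineligible_age,
              fp_rate = fp_rate,
              window_start = window_start, window_end = window_end,
              seed = as.integer(seed))
  probs <- c("p_husband_identified", "birth_rate", "p_second_birth",
             "p_silent_birth", "p_dx", "p_proc", "p_med", "p_suspected",
             "p_discharge_shift", "echo_pre", "echo_post", "p_preterm",
             "p_ineligible_age", "fp_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be a probability in [0, 1]")
  }
  if (abs(sum(age_band_weights) - 1) > 1e-8) stop("age_band_weights must sum to 1")
  if (length(age_band_weights) != 7L) stop("expected 7 five-year age bands (15-19 .. 45-49)")
  if (cfg$n_women < 1L) stop("n_women must be positive")
  win <- c(parse_month(window_start), parse_month(window_end))
  if (win[1] > win[2]) stop("window_start after window_end")
  if (cfg$p_second_birth > 0 && win[2] - win[1] < cfg$gap_min) {
    stop("infeasible config: window shorter than the minimum inter-birth gap")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic claims dataset
#'
#' Reproducible given `config$seed`. Claims outside the extract window
#' are not generated (a database extract has no claims beyond its
#' submission range).
#'
#' @param config a [synth_config].
#' @param cs a [codesets] object supplying the code vocabularies.
#' @return object of class `synthetic_claims`: list with `population`,
#'   `links`, `claims` (schemas as accepted by [build_gold_standard] and
#'   [detect_events]), `truth` (per birth: `woman_id`, `birth_month`
#'   month index, `birth_no`, `silent`, `maternal_age`), and `config`.
#' @export
generate_synthetic_claims <- function(config = synth_config(),
                                      cs = default_codesets()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  n <- config$n_women
  win_lo <- parse_month(config$window_start)
  win_hi <- parse_month(config$window_end)  # inclusive
  win_len <- win_hi - win_lo + 1L

  woman_id <- sprintf("W%07d", seq_len(n))
  husband <- stats::runif(n) < config$p_husband_identified
  has_birth <- stats::runif(n) < config$birth_rate
  nb <- sum(has_birth)

  ## ---- births and maternal ages -------------------------------------
  b1 <- win_lo + sample.int(win_len, nb, replace = TRUE) - 1L
  band_lo <- seq(15L, 45L, by = 5L)
  band <- sample.int(7L, nb, replace = TRUE, prob = config$age_band_weights)
  age1 <- band_lo[band] + sample.int(5L, nb, replace = TRUE) - 1L
  inelig <- stats::runif(nb) < config$p_ineligible_age
  if (any(inelig)) {
    age1[inelig] <- sample(c(13L, 14L, 50L, 51L, 52L), sum(inelig), replace = TRUE)
  }
  mother_birth_b <- b1 - (age1 * 12L + sample.int(12L, nb, replace = TRUE) - 1L)

  second <- stats::runif(nb) < config$p_second_birth
  gap <- pmax(config$gap_min, round(stats::rnorm(nb, config$gap_mean, config$gap_sd)))
  b2 <- ifelse(second, b1 + as.integer(gap), NA_integer_)
  b2[!is.na(b2) & b2 > win_hi] <- NA_integer_

  birth_ids <- woman_id[has_birth]
  births <- data.table::rbindlist(list(
    data.table::data.table(woman_id = birth_ids, birth_month = b1, birth_no = 1L),
    data.table::data.table(woman_id = birth_ids[!is.na(b2)],
                           birth_month = b2[!is.na(b2)], birth_no = 2L)
  ))
  births[, silent := stats::runif(.N) < config$p_silent_birth]
  mb_lookup <- data.table::data.table(woman_id = birth_ids, mother_birth = mother_birth_b)
  births <- merge(births, mb_lookup, by = "woman_id", sort = FALSE)
  births[, age := compute_age_years(mother_birth, birth_month)]
  data.table::setorder(births, woman_id, birth_month)

  ## non-birthing women: age 15-74 completed years at window end
  mother_birth_all <- integer(n)
  mother_birth_all[has_birth] <- mother_birth_b
  n_nb <- n - nb
  mother_birth_all[!has_birth] <-
    win_hi - (sample(15:74, n_nb, replace = TRUE) * 12L +
                sample.int(12L, n_nb, replace = TRUE) - 1L)

  population <- data.table::data.table(
    woman_id = woman_id,
    birth_year = month_index_year(mother_birth_all),
    birth_month = month_index_month(mother_birth_all),
    husband_identified = as.integer(husband)
  )

  ## parent-child links: every (live) birth is linked
  links <- births[, .(mother_id = woman_id,
                      child_birth_year = month_index_year(birth_month),
                      child_birth_month = month_index_month(birth_month))]

  ## ---- claims from the birth emission process -----------------------
  live <- births[silent == FALSE]
  nl <- nrow(live)
  dx_pool <- setdiff(cs$diagnosis, cs$preterm_exclusion)
  draw_dx <- function(k) {
    pre <- stats::runif(k) < config$p_preterm
    cat3 <- ifelse(pre,
                   sample(cs$preterm_exclusion, k, replace = TRUE),
                   sample(dx_pool, k, replace = TRUE))
    paste0(cat3, sample(c("", "0", "1", "9"), k, replace = TRUE))
  }
  shift <- function(k) as.integer(stats::runif(k) < config$p_discharge_shift)

  claim_parts <- list()
  if (nl > 0) {
    dx_code_birth <- draw_dx(nl)  # the birth's own diagnosis code; echoes repeat it
    emit <- function(p, domain, codes, suspected_p) {
      keep <- stats::runif(nl) < p
      k <- sum(keep)
      if (k == 0L) return(NULL)
      data.table::data.table(
        woman_id = live$woman_id[keep],
        month_idx = live$birth_month[keep] + shift(k),
        domain = domain,
        code = codes[keep],
        suspected = as.integer(stats::runif(k) < suspected_p & domain == "diagnosis")
      )
    }
    claim_parts$dx <- emit(config$p_dx, "diagnosis", dx_code_birth, config$p_suspected)
    claim_parts$proc <- emit(config$p_proc, "procedure",
                             sample(cs$procedure, nl, replace = TRUE), 0)
    claim_parts$med <- emit(config$p_med, "medication",
                            sample(cs$medication, nl, replace = TRUE), 0)

    ## echoes: diagnosis repeats around a non-silent birth
    echo_offsets <- c(-(9:1), 2L, 3L)
    echo_p <- c(rep(config$echo_pre, 9L), rep(config$echo_post, 2L))
    if (any(echo_p > 0)) {
      idx <- rep(seq_len(nl), each = length(echo_offsets))
      off <- rep(echo_offsets, times = nl)
      hit <- stats::runif(length(idx)) < rep(echo_p, times = nl)
      if (any(hit)) {
        claim_parts$echo <- data.table::data.table(
          woman_id = live$woman_id[idx[hit]],
          month_idx = live$birth_month[idx[hit]] + off[hit],
          domain = "diagnosis",
          code = dx_code_birth[idx[hit]],
          suspected = as.integer(stats::runif(sum(hit)) < config$p_suspected)
        )
      }
    }
  }

  ## ---- rule-out noise among non-birthing women ----------------------
  if (config$fp_rate > 0 && n_nb > 0) {
    k_noise <- stats::rbinom(n_nb, win_len, config$fp_rate)
    tot <- sum(k_noise)
    if (tot > 0) {
      ids_nb <- woman_id[!has_birth]
      claim_parts$noise <- data.table::data.table(
        woman_id = rep(ids_nb, k_noise),
        month_idx = win_lo + sample.int(win_len, tot, replace = TRUE) - 1L,
        domain = "diagnosis",
        code = sample(cs$diagnosis, tot, replace = TRUE),
        suspected = as.integer(stats::runif(tot) < min(1, 2 * config$p_suspected))
      )
    }
  }

  claims <- data.table::rbindlist(claim_parts, use.names = TRUE)
  if (nrow(claims) == 0L) {
    claims <- data.table::data.table(woman_id = character(), month_idx = integer(),
                                     domain = character(), code = character(),
                                     suspected = integer())
  }
  # the extract contains only claims submitted within the window
  claims <- claims[month_idx >= win_lo & month_idx <= win_hi]
  claims <- claims[, .(woman_id, year = month_index_year(month_idx),
                       month = month_index_month(month_idx),
                       domain, code, suspected)]
  data.table::setorder(claims, woman_id, year, month, domain, code)

  truth <- births[, .(woman_id, birth_month, birth_no, silent, maternal_age = age)]

  structure(list(population = population[], links = links[],
                 claims = claims[], truth = truth[], config = config),
            class = "synthetic_claims")
}

#' @export
print.synthetic_claims <- function(x, ...) {
  cat(sprintf("<synthetic_claims> %d women, %d births (%d silent), %d claim rows; seed %d\n",
              nrow(x$population), nrow(x$truth), sum(x$truth$silent),
              nrow(x$claims), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `population.csv`, `links.csv`, `claims.csv`, `truth.csv` and the
#' resolved configuration (`config.yaml`) to a directory.
#'
#' @param ds a [generate_synthetic_claims] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_claims"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(ds$population, file.path(dir, "population.csv"))
  data.table::fwrite(ds$links, file.path(dir, "links.csv"))
  data.table::fwrite(ds$claims, file.path(dir, "claims.csv"))
  data.table::fwrite(ds$truth, file.path(dir, "truth.csv"))
  yaml::write_yaml(unclass(ds$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Closed-form expected sensitivity under the generator
#'
#' Analytic probability that a woman's (single) birth is detected and
#' dated within the 0/+1-month tolerance, for independent-domain emission:
#' `(1 - p_silent_birth) * P(expression)` with per-condition
#' probabilities `P(A_susp) = p_dx`, `P(A) = p_dx (1 - p_suspected)`,
#' `P(A_pre_susp) = p_dx (1 - p_preterm)`,
#' `P(A_pre) = p_dx (1 - p_suspected)(1 - p_preterm)`, `P(B) = p_proc`,
#' `P(C) = p_med`; AND is a product, OR is inclusion-exclusion.
#'
#' The closed form requires echoes off (`echo_pre = echo_post = 0`;
#' echoes land outside the 0/+1 tolerance and would break the dating
#' term), single births (`p_second_birth = 0`), and at most one diagnosis
#' condition in the expression (two diagnosis conditions share the same
#' record and are not independent). Unsupported configurations raise an
#' error.
#'
#' @param config a [synth_config].
#' @param spec an [algorithm_spec].
#' @return probability.
#' @examples
#' cfg <- synth_config(p_proc = 0.4, p_med = 0.5, p_silent_birth = 0,
#'                     echo_pre = 0, echo_post = 0, p_second_birth = 0)
#' expected_sensitivity(cfg, algorithm_spec(9, c("B", "C"), "or"))  # 0.7
#' @export
expected_sensitivity <- function(config, spec) {
  stopifnot(inherits(config, "synth_config"), inherits(spec, "algorithm_spec"))
  if (config$echo_pre > 0 || config$echo_post > 0) {
    stop("unsupported oracle configuration: echoes extend beyond the +1-month tolerance")
  }
  if (config$p_second_birth > 0) {
    stop("unsupported oracle configuration: multi-birth women couple claims across births")
  }
  dx_conditions <- intersect(spec$conditions, c("A", "A_susp", "A_pre", "A_pre_susp"))
  if (length(dx_conditions) > 1L) {
    stop("unsupported oracle expression: multiple diagnosis conditions share one record")
  }
  p_cond <- c(
    A          = config$p_dx * (1 - config$p_suspected),
    A_susp     = config$p_dx,
    A_pre      = config$p_dx * (1 - config$p_suspected) * (1 - config$p_preterm),
    A_pre_susp = config$p_dx * (1 - config$p_preterm),
    B          = config$p_proc,
    C          = config$p_med
  )
  p <- p_cond[spec$conditions]
  p_expr <- if (spec$op == "and") prod(p) else 1 - prod(1 - p)
  unname((1 - config$p_silent_birth) * p_expr)
}
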