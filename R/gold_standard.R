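## Linkage-based gold standard.
##
## The reference classification comes from parent-child identifiers, which
## insurers assign from family-relationship registry information and only
## for live births. A woman is gold-positive when at least one linked
## child was born inside the observation window while she was aged 15-49
## (completed years at the child's birth month). Women with multiple
## qualifying births contribute only the most recent one, mirroring the
## claims-side dating rule. The cohort is restricted to women whose
## husband can be identified: otherwise a child may be registered only
## under the father and a true birth would be unverifiable, deflating
## apparent algorithm performance.

#' Build the parent-child-linkage gold standard
#'
#' @param population data.frame with columns `woman_id`, `birth_year`,
#'   `birth_month` (the woman's own birth), `husband_identified` (0/1 or
#'   logical). `woman_id` must be unique.
#' @param links data.frame with columns `mother_id`, `child_birth_year`,
#'   `child_birth_month`. Every `mother_id` must appear in `population`.
#' @param window length-2 integer vector of month indices, half-open
#'   `[start, end)`; defaults to 2014-04 through 2023-01 inclusive.
#' @return an object of class `gold_standard`: a list with
#'   \describe{
#'     \item{`women`}{data.table, one row per eligible (husband-identified)
#'       woman: `woman_id`, `mother_birth` (month index), `gold_positive`,
#'       `gold_month` (month index of the most recent qualifying birth, NA
#'       for negatives), `age_ineligible` (had in-window links but none at
#'       maternal age 15-49).}
#'     \item{`births`}{data.table of all qualifying births (`woman_id`,
#'       `birth_month`), ordered, for multi-birth analyses.}
#'     \item{`window`}{the half-open window used.}
#'     \item{`log`}{counts of filtered entities (non-husband-identified
#'       women, out-of-window links, age-ineligible links and women) so
#'       cohort attrition is auditable.}
#'   }
#' @examples
#' pop <- data.frame(woman_id = c("a", "b"), birth_year = 1990, birth_month = 1,
#'                   husband_identified = c(1, 1))
#' lnk <- data.frame(mother_id = "a", child_birth_year = 2020, child_birth_month = 6)
#' gs <- build_gold_standard(pop, lnk)
#' gs$women
#' @export
build_gold_standard <- function(population, links, window = default_window()) {
  pop <- validate_population(population)
  lnk <- validate_links(links)
  stopifnot(length(window) == 2L, window[1] < window[2])

  if (anyDuplicated(pop$woman_id)) {
    stop("schema error: duplicated woman_id in population table")
  }
  unknown <- setdiff(lnk$mother_id, pop$woman_id)
  if (length(unknown)) {
    stop("referential error: links reference unknown mother_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  n_not_husband <- sum(!pop$husband_identified)
  eligible <- pop[husband_identified == TRUE]

  lnk <- merge(lnk, eligible[, .(mother_id = woman_id, mother_birth)],
               by = "mother_id")  # drops links of non-eligible women
  in_window <- lnk$child_month >= window[1] & lnk$child_month < window[2]
  n_out_of_window <- sum(!in_window)
  lnk <- lnk[in_window]

  if (nrow(lnk) && any(lnk$child_month < lnk$mother_birth)) {
    stop("invalid linkage: child born before the mother's own birth month")
  }
  lnk[, age := compute_age_years(mother_birth, child_month)]
  lnk[, qualifying := age >= 15L & age <= 49L]
  n_age_ineligible_links <- sum(!lnk$qualifying)

  per_woman <- lnk[, .(
    gold_positive = any(qualifying),
    gold_month = if (any(qualifying)) max(child_month[qualifying]) else NA_integer_,
    age_ineligible = !any(qualifying)
  ), by = .(woman_id = mother_id)]

  women <- merge(eligible[, .(woman_id, mother_birth)], per_woman,
                 by = "woman_id", all.x = TRUE)
  women[is.na(gold_positive), `:=`(gold_positive = FALSE, age_ineligible = FALSE)]
  data.table::setkey(women, woman_id)

  births <- lnk[qualifying == TRUE,
                .(woman_id = mother_id, birth_month = child_month)]
  data.table::setorder(births, woman_id, birth_month)

  structure(
    list(
      women = women[],
      births = births[],
      window = window,
      log = list(
        n_women_total = nrow(pop),
        n_not_husband_identified = n_not_husband,
        n_eligible = nrow(eligible),
        n_links_out_of_window = n_out_of_window,
        n_age_ineligible_links = n_age_ineligible_links,
        n_age_ineligible_women = sum(women$age_ineligible),
        n_gold_positive = sum(women$gold_positive)
      )
    ),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  lg <- x$log
  cat("<gold_standard> window", format_month_index(x$window[1]), "to",
      format_month_index(x$window[2] - 1L), "(inclusive)\n")
  cat(sprintf("  %d women in population; %d not husband-identified; %d eligible\n",
              lg$n_women_total, lg$n_not_husband_identified, lg$n_eligible))
  cat(sprintf("  %d gold-positive (%.1f%% of eligible); %d age-ineligible linked women\n",
              lg$n_gold_positive, 100 * lg$n_gold_positive / max(lg$n_eligible, 1L),
              lg$n_age_ineligible_women))
  cat(sprintf("  links dropped: %d out-of-window, %d outside maternal age 15-49\n",
              lg$n_links_out_of_window, lg$n_age_ineligible_links))
  invisible(x)
}

validate_population <- function(population) {
  need <- c("woman_id", "birth_year", "birth_month", "husband_identified")
  miss <- setdiff(need, names(population))
  if (length(miss)) stop("schema error: population table lacks column(s): ",
                         paste(miss, collapse = ", "))
  pop <- data.table::as.data.table(population)[, ..need]
  pop[, `:=`(
    woman_id = as.character(woman_id),
    mother_birth = month_index(birth_year, birth_month),
    husband_identified = as.logical(husband_identified)
  )]
  if (anyNA(pop$husband_identified)) stop("schema error: husband_identified must be 0/1")
  pop[, .(woman_id, mother_birth, husband_identified)]
}

validate_links <- function(links) {
  need <- c("mother_id", "child_birth_year", "child_birth_month")
  miss <- setdiff(need, names(links))
  if (length(miss)) stop("schema error: link table lacks column(s): ",
                         paste(miss, collapse = ", "))
  lnk <- data.table::as.data.table(links)[, ..need]
  lnk[, .(mother_id = as.character(mother_id),
          child_month = month_index(child_birth_year, child_birth_month))]
}
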