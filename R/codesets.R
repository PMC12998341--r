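## Childbirth-related code sets.
##
## Diagnosis matching is at ICD-10 three-character category level: the
## published ranges are category ranges, so full codes ("O80.1", "O801")
## normalise by dropping the dot and truncating to three characters.
## Procedure and medication codes are opaque exact-match strings supplied
## by configuration: domestic fee-schedule code values are not portable
## across databases, so they are configuration, not constants.

# canonical category ranges for delivery-related diagnoses
.default_diagnosis_ranges <- c(
  "O14-O15", "O32-O34", "O42", "O45", "O48", "O60-O69", "O70-O72",
  "O74-O75", "O80-O84", "O86-O87", "O90", "O99", "Z37-Z38"
)

# categories removed for the preterm-excluded variant: placental abruption,
# preterm labour, cord complications
.default_preterm_exclusion <- c("O45", "O60", "O69")

# clearly-synthetic placeholders (labour induction, vacuum extraction,
# forceps delivery, caesarean section; oxytocin, dinoprostone) for use with
# the synthetic generator; real deployments supply fee-schedule codes
.default_procedure_codes <- c("PROC-LI", "PROC-VE", "PROC-FD", "PROC-CS")
.default_medication_codes <- c("MED-OXY", "MED-DIN")

#' Expand an ICD-10 category range
#'
#' Ranges are written `"O60-O69"` (same letter, ascending numeric part) or
#' as a single category `"O42"`.
#'
#' @param range character scalar.
#' @return character vector of three-character categories.
#' @examples
#' expand_icd10_range("O80-O84")
#' @export
expand_icd10_range <- function(range) {
  range <- toupper(trimws(range))
  single <- grepl("^[A-Z][0-9]{2}$", range)
  if (single) return(range)
  m <- regmatches(range, regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", range))[[1]]
  if (length(m) != 5L) {
    stop("malformed ICD-10 range: '", range,
         "' (expected e.g. 'O60-O69' or a single category 'O42')")
  }
  if (m[2] != m[4]) stop("malformed ICD-10 range '", range, "': mixed letters")
  lo <- as.integer(m[3]); hi <- as.integer(m[5])
  if (lo > hi) stop("malformed ICD-10 range '", range, "': start > end")
  sprintf("%s%02d", m[2], lo:hi)
}

#' Construct a childbirth code-set bundle
#'
#' Bundles the four code sets the phenotyping conditions draw on:
#' the delivery diagnosis categories (condition symbols `A`/`A_susp`),
#' the preterm-exclusion categories defining the `A_pre`/`A_pre_susp`
#' variants, and exact-match procedure (`B`) and medication (`C`) codes.
#'
#' @param diagnosis_ranges character vector of ICD-10 category ranges or
#'   single categories.
#' @param preterm_exclusion character vector of categories (or ranges)
#'   removed in the preterm-excluded variant; must be a subset of the
#'   expanded diagnosis set.
#' @param procedure_codes,medication_codes non-empty, mutually disjoint
#'   character vectors of opaque claim codes.
#' @return an object of class `codesets` with elements `diagnosis`,
#'   `preterm_exclusion`, `procedure`, `medication`.
#' @seealso [default_codesets()], [load_codesets()], [restrict_preterm()]
#' @export
codesets <- function(diagnosis_ranges = .default_diagnosis_ranges,
                     preterm_exclusion = .default_preterm_exclusion,
                     procedure_codes = .default_procedure_codes,
                     medication_codes = .default_medication_codes) {
  expand_all <- function(r) as.character(sort(unique(unlist(lapply(r, expand_icd10_range)))))
  diagnosis <- expand_all(diagnosis_ranges)
  exclusion <- expand_all(preterm_exclusion)
  if (length(diagnosis) == 0L) stop("configuration error: empty diagnosis set")
  bad <- setdiff(exclusion, diagnosis)
  if (length(bad)) {
    stop("configuration error: preterm exclusion categories not in the diagnosis set: ",
         paste(bad, collapse = ", "))
  }
  procedure <- unique(as.character(procedure_codes))
  medication <- unique(as.character(medication_codes))
  if (length(procedure) == 0L || length(medication) == 0L) {
    stop("configuration error: procedure and medication code sets must be non-empty")
  }
  if (length(intersect(procedure, medication))) {
    stop("configuration error: procedure and medication code sets overlap")
  }
  structure(
    list(diagnosis = diagnosis, preterm_exclusion = exclusion,
         procedure = procedure, medication = medication),
    class = "codesets"
  )
}

#' @rdname codesets
#' @export
default_codesets <- function() codesets()

#' @export
print.codesets <- function(x, ...) {
  cat("<codesets>\n")
  cat("  diagnosis categories: ", length(x$diagnosis), " (",
      paste(utils::head(x$diagnosis, 6), collapse = ", "), ", ...)\n", sep = "")
  cat("  preterm exclusion:    ", paste(x$preterm_exclusion, collapse = ", "), "\n", sep = "")
  cat("  procedure codes:      ", paste(x$procedure, collapse = ", "), "\n", sep = "")
  cat("  medication codes:     ", paste(x$medication, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a code-set configuration file
#'
#' The configuration is YAML or JSON (by file extension) with keys
#' `diagnosis_ranges`, `preterm_exclusion`, `procedure_codes`,
#' `medication_codes`; any omitted key falls back to the package default.
#'
#' @param path file path; `.yaml`/`.yml` or `.json`.
#' @return `load_codesets()` returns a [codesets] object;
#'   `write_codesets()` returns `path` invisibly.
#' @export
load_codesets <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  cfg <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop("configuration error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  known <- c("diagnosis_ranges", "preterm_exclusion", "procedure_codes", "medication_codes")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
  # a key that is present but empty (e.g. `preterm_exclusion: []`) is kept
  # as empty, not replaced by the default
  pick <- function(key, default) {
    if (key %in% names(cfg)) as.character(unlist(cfg[[key]])) else default
  }
  diag_ranges <- pick("diagnosis_ranges", .default_diagnosis_ranges)
  # a default exclusion category absent from a narrowed diagnosis set is
  # simply not applicable
  default_excl <- intersect(
    .default_preterm_exclusion,
    unlist(lapply(diag_ranges, expand_icd10_range))
  )
  codesets(
    diagnosis_ranges = diag_ranges,
    preterm_exclusion = pick("preterm_exclusion", default_excl),
    procedure_codes = pick("procedure_codes", .default_procedure_codes),
    medication_codes = pick("medication_codes", .default_medication_codes)
  )
}

#' @rdname load_codesets
#' @param cs a [codesets] object.
#' @export
write_codesets <- function(cs, path) {
  stopifnot(inherits(cs, "codesets"))
  cfg <- list(diagnosis_ranges = cs$diagnosis,
              preterm_exclusion = cs$preterm_exclusion,
              procedure_codes = cs$procedure,
              medication_codes = cs$medication)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

## normalise a full ICD-10 code to its 3-character category
icd10_category <- function(code) {
  code <- gsub(".", "", toupper(trimws(code)), fixed = TRUE)
  substr(code, 1L, 3L)
}

#' Match an ICD-10 code against the childbirth diagnosis set
#'
#' A code matches when its three-character category is in the diagnosis
#' set; with `exclude_preterm = TRUE` the preterm-exclusion categories are
#' removed first. Strings that do not normalise to a valid category simply
#' fail to match.
#'
#' @param code character vector of ICD-10 codes (sub-categories allowed,
#'   with or without a dot).
#' @param cs a [codesets] object.
#' @param exclude_preterm use the preterm-excluded diagnosis set.
#' @return logical vector.
#' @examples
#' matches_diagnosis("O821", default_codesets())        # TRUE
#' matches_diagnosis("O60", default_codesets(), TRUE)   # FALSE
#' @export
matches_diagnosis <- function(code, cs, exclude_preterm = FALSE) {
  stopifnot(inherits(cs, "codesets"))
  set <- if (exclude_preterm) setdiff(cs$diagnosis, cs$preterm_exclusion) else cs$diagnosis
  icd10_category(code) %in% set
}

#' Preterm-excluded variant of a code-set bundle
#'
#' Removes the preterm-exclusion categories from the diagnosis set (and
#' empties the exclusion list, making the operation idempotent); procedure
#' and medication codes are unchanged.
#'
#' @param cs a [codesets] object.
#' @return a [codesets] object.
#' @export
restrict_preterm <- function(cs) {
  stopifnot(inherits(cs, "codesets"))
  out <- cs
  out$diagnosis <- setdiff(cs$diagnosis, cs$preterm_exclusion)
  out$preterm_exclusion <- character(0)
  out
}
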