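## End-to-end entry points: read the three CSV inputs (or take in-memory
## tables), run the full validation or the washout scan, and write outputs
## with a reproducibility manifest. These back the `claimsbirth`
## command-line script installed under exec/.

read_table_arg <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("no such ", what, " file: ", x)
    data.table::fread(x)
  } else if (is.data.frame(x)) {
    data.table::as.data.table(x)
  } else {
    stop(what, " must be a file path or data.frame")
  }
}

#' Run the full childbirth-algorithm validation
#'
#' Builds the gold standard, evaluates the requested algorithms over the
#' claims, and returns (optionally writes) the Table-style validation
#' report.
#'
#' @param population,links,claims file paths or data.frames (schemas: see
#'   [build_gold_standard] and [detect_events]).
#' @param codesets a [codesets] object or a config file path for
#'   [load_codesets].
#' @param window half-open month-index window, or `c("YYYY-MM","YYYY-MM")`
#'   (start inclusive, end exclusive).
#' @param algorithms integer ids into [builtin_algorithms()], or a list of
#'   [algorithm_spec]s.
#' @param and_mode,ci_level,ci_method see [report_table].
#' @param out_dir when non-NULL, `validation_report.csv` and
#'   `manifest.json` are written there.
#' @param verbose print cohort attrition and the formatted report.
#' @return list with `report` (see [report_table]) and `gold`.
#' @export
run_validation <- function(population, links, claims,
                           codesets = default_codesets(),
                           window = default_window(),
                           algorithms = 1:32,
                           and_mode = "anytime", ci_level = 0.95,
                           ci_method = "wald", out_dir = NULL,
                           verbose = FALSE) {
  cs <- if (is.character(codesets)) load_codesets(codesets) else codesets
  win <- resolve_window(window)
  specs <- if (is.list(algorithms) && inherits(algorithms[[1]], "algorithm_spec")) {
    algorithms
  } else {
    builtin_algorithms(algorithms)
  }
  pop <- read_table_arg(population, "population")
  lnk <- read_table_arg(links, "links")
  cl <- read_table_arg(claims, "claims")

  gold <- build_gold_standard(pop, lnk, win)
  if (verbose) print(gold)
  report <- report_table(gold, cl, specs, cs, win, and_mode, ci_level, ci_method)
  if (verbose) format_report(report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(report, file.path(out_dir, "validation_report.csv"))
    write_manifest(out_dir,
                   inputs = list(population = population, links = links,
                                 claims = claims),
                   params = list(window = format_month_index(c(win[1], win[2] - 1L)),
                                 algorithms = vapply(specs, `[[`, 1L, "id"),
                                 and_mode = and_mode, ci_level = ci_level,
                                 ci_method = ci_method),
                   codesets = cs)
  }
  list(report = report, gold = gold)
}

#' Run the second-birth washout scan
#'
#' @inheritParams run_validation
#' @param algorithm a single algorithm id or [algorithm_spec].
#' @param k_min,k_max washout range in months.
#' @param reference see [second_birth_gold].
#' @return a [washout_scan] object.
#' @export
run_second_birth_scan <- function(population, links, claims,
                                  codesets = default_codesets(),
                                  window = default_window(),
                                  algorithm = 11L, k_min = 2L, k_max = 24L,
                                  and_mode = "anytime", reference = "second",
                                  ci_level = 0.95, ci_method = "wald",
                                  out_dir = NULL, verbose = FALSE) {
  cs <- if (is.character(codesets)) load_codesets(codesets) else codesets
  win <- resolve_window(window)
  spec <- if (inherits(algorithm, "algorithm_spec")) algorithm else
    builtin_algorithms(algorithm)[[1]]
  gold <- build_gold_standard(read_table_arg(population, "population"),
                              read_table_arg(links, "links"), win)
  scan <- washout_scan(gold, read_table_arg(claims, "claims"), spec, cs,
                       k_range = seq.int(k_min, k_max), window = win,
                       and_mode = and_mode, reference = reference,
                       ci_level = ci_level, ci_method = ci_method)
  if (verbose) print(scan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(scan$results, file.path(out_dir, "washout_scan.csv"))
    write_manifest(out_dir,
                   inputs = list(population = population, links = links,
                                 claims = claims),
                   params = list(window = format_month_index(c(win[1], win[2] - 1L)),
                                 algorithm = spec$id, k_min = k_min,
                                 k_max = k_max, and_mode = and_mode,
                                 reference = reference, ci_method = ci_method,
                                 best_k = scan$best_k),
                   codesets = cs)
  }
  scan
}

#' Metrics from raw confusion counts
#'
#' Direct replication path: compute the full metric set from published or
#' hand-tallied TP/TN/FN/FP counts.
#'
#' @param tp,tn,fn,fp counts.
#' @param ci_level,ci_method see [compute_metrics].
#' @return a `metric_set` (printed when called interactively).
#' @examples
#' metrics_from_counts(25361, 807660, 12573, 9032)
#' @export
metrics_from_counts <- function(tp, tn, fn, fp, ci_level = 0.95,
                                ci_method = "wald") {
  compute_metrics(confusion_table(tp, tn, fn, fp), ci_level, ci_method)
}

#' Simulate a dataset and write it to disk
#'
#' @param out_dir output directory.
#' @param config a [synth_config].
#' @param cs a [codesets] object.
#' @return the `synthetic_claims` object, invisibly.
#' @export
simulate_dataset <- function(out_dir, config = synth_config(),
                             cs = default_codesets()) {
  ds <- generate_synthetic_claims(config, cs)
  write_synthetic_dataset(ds, out_dir)
  write_manifest(out_dir, inputs = list(),
                 params = list(seed = config$seed, n_women = config$n_women),
                 codesets = cs)
  invisible(ds)
}

resolve_window <- function(window) {
  if (is.character(window)) {
    # both ends "YYYY-MM": start inclusive, end exclusive
    window <- parse_month(window)
  }
  stopifnot(length(window) == 2L, window[1] < window[2])
  as.integer(window)
}

## reproducibility manifest: input checksums + parameters + tool version.
## Deliberately timestamp-free so re-runs are byte-identical.
write_manifest <- function(out_dir, inputs, params, codesets = NULL) {
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      list(path = x, md5 = unname(tools::md5sum(x)))
    } else {
      list(path = NA, md5 = NA)  # in-memory input
    }
  }
  manifest <- list(
    tool = "claimsbirth",
    version = as.character(utils::packageVersion("claimsbirth")),
    inputs = lapply(inputs, checksum),
    params = params
  )
  if (!is.null(codesets)) {
    manifest$codesets <- list(
      diagnosis = codesets$diagnosis,
      preterm_exclusion = codesets$preterm_exclusion,
      procedure = codesets$procedure,
      medication = codesets$medication
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
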