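#' Published reference confusion counts
#'
#' Woman-level confusion counts (TP, TN, FN, FP) reported by a nationwide
#' Japanese claims-database validation of the 18 base childbirth
#' algorithms against the parent-child-linkage gold standard (854,626
#' husband-identified women, 37,934 of them with a qualifying birth;
#' validation-cohort birth rate 4.4%). Useful for re-deriving the
#' published metric columns with [compute_metrics()] and as a fixed input
#' for regression checks.
#'
#' @return data.table with columns `algorithm_id`, `definition`, `tp`,
#'   `tn`, `fn`, `fp`.
#' @examples
#' counts <- reference_validation_counts()
#' compute_metrics(counts[algorithm_id == 11, confusion_table(tp, tn, fn, fp)])
#' @export
reference_validation_counts <- function() {
  defs <- vapply(builtin_algorithms(1:18), `[[`, "", "label")
  dt <- data.table::data.table(
    algorithm_id = 1:18,
    definition = defs,
    tp = c(21857L, 15123L, 18275L, 11805L, 24960L, 14949L, 24991L, 13083L,
           20230L, 10157L, 25361L, 20950L, 11680L, 24226L, 14819L, 24259L,
           10052L, 24662L),
    tn = c(809174L, 811960L, 810683L, 813103L, 808123L, 811989L, 807959L,
           812797L, 809885L, 813629L, 807660L, 809610L, 813147L, 808497L,
           812028L, 808335L, 813659L, 808019L),
    fn = c(16077L, 22811L, 19659L, 26129L, 12974L, 22985L, 12943L, 24851L,
           17704L, 27777L, 12573L, 16984L, 26254L, 13708L, 23115L, 13675L,
           27882L, 13272L),
    fp = c(7518L, 4732L, 6009L, 3589L, 8569L, 4703L, 8733L, 3895L, 6807L,
           3063L, 9032L, 7082L, 3545L, 8195L, 4664L, 8357L, 3033L, 8673L)
  )
  dt[]
}
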