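# Searchable store of classified abnormal karyotypes: distinct strings with
# occurrence counts, filterable by chromosome, mosaicism level, structural
# class and balance status.

#' Build a karyotype query store
#'
#' Collapses a classified cohort to its distinct abnormal karyotype strings
#' (normal results are excluded) with occurrence counts and the four-level
#' annotation.
#'
#' @param classified A cohort classified by [classify_cohort()].
#' @param karyotype Name of the karyotype column.
#' @return A tibble of class `karyotype_store` with columns `karyotype`,
#'   `n`, `level1`, `level2_all`, `level2_primary`, `level3`, `level4`,
#'   sorted by decreasing count then karyotype.
#' @export
build_store <- function(classified, karyotype = "karyotype") {
  .check_classified(classified, c("level1", "level2_all", "level2_primary",
                                  "level3", "level4", karyotype))
  ab <- classified[classified$level1 != "normal", , drop = FALSE]
  store <- ab |>
    dplyr::count(.data[[karyotype]], .data$level1, .data$level2_all,
                 .data$level2_primary, .data$level3, .data$level4,
                 name = "n") |>
    dplyr::rename(karyotype = 1) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$karyotype) |>
    dplyr::relocate("karyotype", "n")
  class(store) <- c("karyotype_store", class(store))
  store
}

.validate_filter <- function(value, valid, what) {
  if (is.null(value)) return(invisible())
  if (length(value) != 1 || !value %in% valid) {
    stop("invalid ", what, " filter '", value, "'; valid values: ",
         paste(valid, collapse = ", "))
  }
  invisible()
}

#' Query a karyotype store
#'
#' Returns the records matching the conjunction of the provided filters;
#' omitted filters match everything. The chromosome filter matches when the
#' chromosome is in the record's Level-3 set; `"None"` retrieves the records
#' (triploidy, hermaphroditism) annotated without a specific chromosome.
#' Results are deterministic: decreasing occurrence count, then
#' lexicographic karyotype order.
#'
#' @param store A `karyotype_store` from [build_store()].
#' @param chromosome Chromosome label (1-22, X, Y, `"mar"`) or `"None"`.
#' @param level1 Mosaicism class filter.
#' @param level2 Structural-class filter (matches the full label set).
#' @param level4 `"balanced"` or `"unbalanced"`.
#' @return The matching subset of `store`. An invalid filter value raises an
#'   error listing the valid values.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 500, seed = 3))
#' store <- build_store(classify_cohort(cohort[!is.na(cohort$karyotype), ]))
#' query_karyotypes(store, chromosome = "21", level2 = "aneuploidy")
query_karyotypes <- function(store, chromosome = NULL, level1 = NULL,
                             level2 = NULL, level4 = NULL) {
  stopifnot(inherits(store, "karyotype_store"))
  .validate_filter(chromosome, c(.chrom_levels_mar, "None"), "chromosome")
  .validate_filter(level1, .level1_levels, "level1")
  .validate_filter(level2, .level2_levels, "level2")
  .validate_filter(level4, c("balanced", "unbalanced"), "level4")
  keep <- rep(TRUE, nrow(store))
  if (!is.null(chromosome)) {
    keep <- keep & .split_has(store$level3, chromosome)
  }
  if (!is.null(level1)) keep <- keep & store$level1 == level1
  if (!is.null(level2)) keep <- keep & .split_has(store$level2_all, level2)
  if (!is.null(level4)) keep <- keep & store$level4 == level4
  store[keep, , drop = FALSE]
}
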