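# Four-level hierarchical classification of a parsed karyotype:
# Level 1 mosaicism class, Level 2 structural category (full set + one
# primary label), Level 3 chromosome involvement, Level 4 balance status.

.level1_levels <- c("non_mosaic", "mosaic", "polymorphism", "normal")
.level2_levels <- c("inversion", "translocation", "duplication", "deletion",
                    "isochromosome", "psu_dic", "robertsonian", "derivative",
                    "addition", "structural_aberration", "aneuploidy",
                    "triploid", "hermaphroditism", "length_polymorphism",
                    "normal")

# precedence used to pick the single reported Level-2 label when a sample
# carries several (e.g. a mosaic with an aneuploid and a translocated clone)
.level2_precedence <- c("hermaphroditism", "triploid", "aneuploidy",
                        "robertsonian", "translocation", "derivative",
                        "psu_dic", "isochromosome", "deletion", "duplication",
                        "addition", "inversion", "structural_aberration",
                        "length_polymorphism", "normal")

.kind_to_level2 <- c(
  numerical_gain = "aneuploidy", numerical_loss = "aneuploidy",
  marker_gain = "aneuploidy",
  inversion = "inversion", reciprocal_translocation = "translocation",
  robertsonian = "robertsonian", deletion = "deletion",
  duplication = "duplication", isochromosome = "isochromosome",
  psu_dic = "psu_dic", derivative = "derivative", addition = "addition",
  heterochromatin_variant = "length_polymorphism",
  satellite_variant = "length_polymorphism",
  satellite_stalk_variant = "length_polymorphism",
  other_structural = "structural_aberration"
)

# abnormality kinds that are material-neutral (no net gain or loss)
.balanced_kinds <- c("inversion", "reciprocal_translocation", "robertsonian",
                     "heterochromatin_variant", "satellite_variant",
                     "satellite_stalk_variant")

.as_karyotype <- function(k) {
  if (is.character(k)) parse_karyotype(k) else k
}

all_abnormalities <- function(k) {
  unlist(lapply(k$clones, `[[`, "abnormalities"), recursive = FALSE)
}

# A polymorphism-class variant: qh/ps/pstk length variants, or any inversion
# of chromosome 9 (the classical pericentric inv(9)), with or without
# printed breakpoints.
is_polymorphic_abnormality <- function(a) {
  a$kind %in% .variant_kinds ||
    (a$kind == "inversion" && identical(a$chromosomes, "9"))
}

# Hermaphroditism: exactly the coexistence of a normal 46,XX and a normal
# 46,XY cell line, nothing else.
is_hermaphroditism <- function(k) {
  if (length(k$clones) != 2) return(FALSE)
  sexes <- vapply(k$clones, `[[`, character(1), "sex_designation")
  modals <- vapply(k$clones, `[[`, integer(1), "modal_number")
  n_abn <- vapply(k$clones, function(cl) length(cl$abnormalities), integer(1))
  all(modals == 46L) && all(n_abn == 0L) && setequal(sexes, c("XX", "XY"))
}

is_triploid <- function(k) {
  any(vapply(k$clones, `[[`, integer(1), "modal_number") == 69L)
}

#' Level 1: mosaicism class
#'
#' Classifies a karyotype as `mosaic` (two or more genetically distinct cell
#' lines, hermaphroditism excepted), `polymorphism` (a single clone whose
#' only findings are clinically neutral variants: inv(9), heterochromatin,
#' satellite or satellite-stalk length variants), `normal` (single 46-count
#' clone with no abnormality) or `non_mosaic` (any other abnormal result).
#'
#' @param k An `iscn_karyotype` or an ISCN string.
#' @return One of `"mosaic"`, `"non_mosaic"`, `"polymorphism"`, `"normal"`.
#' @export
#' @examples
#' classify_level1("46,XY")
#' classify_level1("46,XN,inv(9)(p12q13)")
#' classify_level1("mos 45,X[12]/46,XX[18]")
classify_level1 <- function(k) {
  k <- .as_karyotype(k)
  sigs <- unique(vapply(k$clones, clone_signature, character(1)))
  if (length(sigs) >= 2) {
    return(if (is_hermaphroditism(k)) "non_mosaic" else "mosaic")
  }
  cl <- k$clones[[1]]
  if (length(cl$abnormalities) == 0) {
    return(if (cl$modal_number == 46L) "normal" else "non_mosaic")
  }
  if (all(vapply(cl$abnormalities, is_polymorphic_abnormality, logical(1)))) {
    return("polymorphism")
  }
  "non_mosaic"
}

#' Level 2: structural classification
#'
#' Maps every abnormality in every clone to a structural category and keeps
#' the full label set alongside one primary label chosen by a fixed
#' precedence (hermaphroditism > triploid > aneuploidy > Robertsonian >
#' translocation > derivative > psu dic > isochromosome > deletion >
#' duplication > addition > inversion > structural aberration > length
#' polymorphism > normal), so samples carrying several abnormality types are
#' reported once without losing information.
#'
#' @inheritParams classify_level1
#' @return A list with `labels` (character set) and `primary` (one label).
#' @export
#' @examples
#' classify_level2("45,XY,rob(13;14)(q10;q10)")
#' classify_level2("46,XX/46,XY")
classify_level2 <- function(k) {
  k <- .as_karyotype(k)
  if (is_hermaphroditism(k)) {
    return(list(labels = "hermaphroditism", primary = "hermaphroditism"))
  }
  kinds <- vapply(all_abnormalities(k), `[[`, character(1), "kind")
  labels <- unique(unname(.kind_to_level2[kinds]))
  if (is_triploid(k)) labels <- c(labels, "triploid")
  if (length(labels) == 0) labels <- "normal"
  labels <- .level2_precedence[.level2_precedence %in% labels]
  list(labels = labels, primary = labels[1])
}

#' Level 3: chromosome involvement
#'
#' Returns the set of chromosomes involved in any abnormality (marker
#' chromosomes keep the label `"mar"`), in karyogram order. Hermaphroditism,
#' triploidy and normal karyotypes carry no specific chromosome and return
#' the `NA` sentinel (rendered `"None"` in tables).
#'
#' @inheritParams classify_level1
#' @param level2_primary Optional pre-computed primary Level-2 label.
#' @return Character vector of chromosome labels, or `NA_character_`.
#' @export
#' @examples
#' classify_level3("46,XX,t(11;22)(q23;q11)")
#' classify_level3("69,XXX")
classify_level3 <- function(k, level2_primary = NULL) {
  k <- .as_karyotype(k)
  if (is.null(level2_primary)) level2_primary <- classify_level2(k)$primary
  if (level2_primary %in% c("hermaphroditism", "triploid", "normal")) {
    return(NA_character_)
  }
  chrs <- unique(unlist(lapply(all_abnormalities(k), `[[`, "chromosomes")))
  chrom_sort(chrs)
}

#' Level 4: balance status
#'
#' A result is `balanced` when no clone gains or loses chromosomal material:
#' inversions, reciprocal translocations, Robertsonian translocations with
#' intact long arms, and all polymorphism-class variants are
#' material-neutral, as is a normal karyotype. Any whole-chromosome gain or
#' loss, marker, deletion, duplication, addition, non-Robertsonian
#' derivative, isochromosome, psu dic, triploidy or hermaphroditism makes the
#' result `unbalanced`.
#'
#' @inheritParams classify_level1
#' @return `"balanced"` or `"unbalanced"`.
#' @export
#' @examples
#' classify_level4("45,XX,rob(13;14)(q10;q10)")
#' classify_level4("46,X,i(X)(q10)")
classify_level4 <- function(k) {
  k <- .as_karyotype(k)
  if (is_hermaphroditism(k) || is_triploid(k)) return("unbalanced")
  kinds <- vapply(all_abnormalities(k), `[[`, character(1), "kind")
  if (all(kinds %in% .balanced_kinds)) "balanced" else "unbalanced"
}

#' Classify a karyotype on all four hierarchical levels
#'
#' Sequential composition of [classify_level1()] through [classify_level4()].
#' Deterministic: the same input string always yields the same result.
#'
#' @inheritParams classify_level1
#' @return An object of class `classified_result`: a list with `level1`,
#'   `level2` (full label set), `level2_primary`, `level3` (chromosome set or
#'   `NA` sentinel) and `level4`.
#' @export
#' @examples
#' classify("47,XX,+21")
#' classify("46,XN,inv(9)(p12q13)")
classify <- function(k) {
  k <- .as_karyotype(k)
  l2 <- classify_level2(k)
  structure(
    list(level1 = classify_level1(k),
         level2 = l2$labels,
         level2_primary = l2$primary,
         level3 = classify_level3(k, l2$primary),
         level4 = classify_level4(k)),
    class = "classified_result"
  )
}

#' @export
print.classified_result <- function(x, ...) {
  l3 <- if (length(x$level3) == 1 && is.na(x$level3)) "None" else
    paste(x$level3, collapse = ";")
  cat(sprintf("<classified_result> %s | %s (primary: %s) | chr %s | %s\n",
              x$level1, paste(x$level2, collapse = ";"), x$level2_primary,
              l3, x$level4))
  invisible(x)
}

.level3_string <- function(level3) {
  if (length(level3) == 1 && is.na(level3)) "None" else paste(level3, collapse = ";")
}

#' Classify every karyotype in a cohort table
#'
#' Adds the four-level classification to a cohort data frame. Rows with a
#' missing karyotype (failed cultures) get `NA` in every added column; they
#' must be excluded before computing rates. Classification is performed once
#' per distinct string, so study-scale cohorts dominated by `46,XX`/`46,XY`
#' classify quickly.
#'
#' @param data A data frame with one row per sample.
#' @param karyotype Name of the column holding ISCN strings.
#' @return `data` with columns `level1`, `level2_all` (semicolon-joined),
#'   `level2_primary`, `level3` (semicolon-joined chromosomes or `"None"`)
#'   and `level4` appended.
#' @export
classify_cohort <- function(data, karyotype = "karyotype") {
  stopifnot(is.data.frame(data), karyotype %in% names(data))
  ks <- data[[karyotype]]
  uk <- unique(ks[!is.na(ks)])
  res <- lapply(uk, function(s) classify(parse_karyotype(s)))
  lut <- tibble::tibble(
    level1 = vapply(res, `[[`, character(1), "level1"),
    level2_all = vapply(res, function(r) paste(r$level2, collapse = ";"), character(1)),
    level2_primary = vapply(res, `[[`, character(1), "level2_primary"),
    level3 = vapply(res, function(r) .level3_string(r$level3), character(1)),
    level4 = vapply(res, `[[`, character(1), "level4")
  )
  idx <- match(ks, uk)
  out <- dplyr::bind_cols(
    data[setdiff(names(data), names(lut))],
    lut[idx, , drop = FALSE]
  )
  tibble::as_tibble(out)
}
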