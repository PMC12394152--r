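# Cohort summary tables: detection rates and proportions by Level-1 class,
# year, Level-2 category, chromosome and indication group. All percentages
# use round-half-up to two decimals so that printed clinical tables
# recompute exactly from their count/denominator columns.

round_half_up <- function(x, digits = 2) {
  # base round() is round-half-even; clinical tables round halves up.
  # The tiny offset absorbs binary representation error in count/denominator
  # quotients (~1e-13) without moving genuinely sub-half values.
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Two-decimal detection rate
#'
#' `100 * count / denominator`, rounded half-up to two decimals — the
#' convention under which published fraction/percent pairs such as
#' 353/38,636 = 0.91\% recompute exactly.
#'
#' @param count Integer vector of event counts.
#' @param denominator Integer vector (or scalar) of denominators, all > 0.
#' @return Numeric vector of percentages with two decimals.
#' @export
#' @examples
#' rate(353, 38636)
#' rate(690, 1663)
rate <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(count < 0 | count > denominator)) {
    stop("count must lie in [0, denominator]")
  }
  round_half_up(100 * count / denominator, 2)
}

.check_classified <- function(classified, cols = "level1") {
  stopifnot(is.data.frame(classified))
  missing <- setdiff(cols, names(classified))
  if (length(missing) > 0) {
    stop("classified cohort lacks column(s): ", paste(missing, collapse = ", "),
         "; run classify_cohort() first")
  }
  if (anyNA(classified$level1)) {
    stop("cohort contains unclassified (failed) samples; exclude rows with NA level1 before computing rates")
  }
  invisible(classified)
}

#' Level-1 proportions, overall or by year
#'
#' Counts and percentages of the four mosaicism classes. The four classes
#' partition the denominator, so within any year (and overall) the counts
#' sum to the denominator and the percentages to 100 up to rounding.
#'
#' @param classified A cohort classified by [classify_cohort()], failed
#'   samples already excluded.
#' @param by_year If `TRUE`, one partition per calendar year (column `year`).
#' @return A tibble with (optionally `year`,) `level1`, `count`,
#'   `denominator`, `percent`.
#' @export
level1_table <- function(classified, by_year = FALSE) {
  .check_classified(classified)
  if (nrow(classified) == 0) stop("empty cohort")
  lev <- factor(classified$level1, levels = .level1_levels)
  if (by_year) {
    stopifnot("year" %in% names(classified))
    out <- classified |>
      dplyr::mutate(level1 = factor(.data$level1, levels = .level1_levels)) |>
      dplyr::count(.data$year, .data$level1, .drop = FALSE, name = "count") |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(denominator = sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$denominator > 0)
  } else {
    tb <- table(lev)
    out <- tibble::tibble(level1 = names(tb), count = as.integer(tb),
                          denominator = nrow(classified))
  }
  out$level1 <- as.character(out$level1)
  out$percent <- rate(out$count, out$denominator)
  tibble::as_tibble(out)
}

.split_has <- function(joined, label) {
  vapply(strsplit(joined, ";", fixed = TRUE), function(x) label %in% x,
         logical(1))
}

# chromosomes carried by abnormalities of one Level-2 label in one karyotype
.label_chromosomes <- function(k, label) {
  if (label %in% c("hermaphroditism", "triploid", "normal")) return(character(0))
  abns <- all_abnormalities(k)
  hit <- vapply(abns, function(a) .kind_to_level2[[a$kind]] == label, logical(1))
  chrom_sort(unique(unlist(lapply(abns[hit], `[[`, "chromosomes"))))
}

#' Per-chromosome rates of one Level-2 category
#'
#' Counts samples carrying the given structural category on each chromosome.
#' Unstratified, the denominator is the whole classified cohort (population
#' incidence); stratified by Level-1 class, the denominator is the number of
#' category carriers within each stratum, giving within-stratum shares (the
#' mosaic-versus-non-mosaic comparison used for aneuploidies). A sample
#' involving several chromosomes counts once per chromosome.
#'
#' @inheritParams level1_table
#' @param label A Level-2 category label (e.g. `"aneuploidy"`).
#' @param stratify_by_level1 Split into within-stratum shares.
#' @param karyotype Name of the karyotype column.
#' @return A tibble with (optionally `level1`,) `chromosome`, `count`,
#'   `denominator`, `percent`; zero rows when no sample carries the label.
#' @export
category_rates <- function(classified, label, stratify_by_level1 = FALSE,
                           karyotype = "karyotype") {
  .check_classified(classified, c("level1", "level2_all", karyotype))
  if (!label %in% .level2_levels) {
    stop("unknown Level-2 label '", label, "'; valid labels: ",
         paste(.level2_levels, collapse = ", "))
  }
  sub <- classified[.split_has(classified$level2_all, label), , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(chromosome = character(), count = integer(),
                          denominator = integer(), percent = double()))
  }
  uk <- unique(sub[[karyotype]])
  chrom_by_string <- lapply(uk, function(s) .label_chromosomes(parse_karyotype(s), label))
  idx <- match(sub[[karyotype]], uk)
  long <- tibble::tibble(
    level1 = rep(sub$level1, lengths(chrom_by_string)[idx]),
    chromosome = unlist(chrom_by_string[idx])
  )
  if (nrow(long) == 0) {
    return(tibble::tibble(chromosome = character(), count = integer(),
                          denominator = integer(), percent = double()))
  }
  if (stratify_by_level1) {
    strat_n <- table(sub$level1)
    out <- long |>
      dplyr::count(.data$level1, .data$chromosome, name = "count") |>
      dplyr::mutate(denominator = as.integer(strat_n[.data$level1]))
  } else {
    out <- long |>
      dplyr::count(.data$chromosome, name = "count") |>
      dplyr::mutate(denominator = nrow(classified))
  }
  out$percent <- rate(out$count, out$denominator)
  out[order(match(out$chromosome, .chrom_levels_mar)), , drop = FALSE]
}

#' Chromosome-pair tallies for translocations
#'
#' Unordered chromosome-pair counts for Robertsonian or reciprocal
#' translocations across a classified cohort. Three-way translocations
#' contribute each of their unordered pairs and are flagged via
#' `n_from_three_way`.
#'
#' @inheritParams category_rates
#' @param kind `"robertsonian"` or `"reciprocal_translocation"`.
#' @return A tibble with `chr_a`, `chr_b` (karyogram-ordered within pair),
#'   `count` and `n_from_three_way`, sorted by decreasing count.
#' @export
pair_counts <- function(classified,
                        kind = c("robertsonian", "reciprocal_translocation"),
                        karyotype = "karyotype") {
  kind <- match.arg(kind)
  label <- if (kind == "robertsonian") "robertsonian" else "translocation"
  .check_classified(classified, c("level1", "level2_all", karyotype))
  sub <- classified[.split_has(classified$level2_all, label), , drop = FALSE]
  empty <- tibble::tibble(chr_a = character(), chr_b = character(),
                          count = integer(), n_from_three_way = integer())
  if (nrow(sub) == 0) return(empty)
  uk <- unique(sub[[karyotype]])
  pairs_by_string <- lapply(uk, function(s) {
    abns <- all_abnormalities(parse_karyotype(s))
    abns <- abns[vapply(abns, function(a) a$kind ==
                          if (kind == "robertsonian") "robertsonian" else "reciprocal_translocation",
                        logical(1))]
    do.call(rbind, lapply(abns, function(a) {
      ch <- a$chromosomes
      if (length(ch) < 2) return(NULL)
      cmb <- utils::combn(ch, 2)
      data.frame(chr_a = cmb[1, ], chr_b = cmb[2, ],
                 three_way = length(ch) > 2)
    }))
  })
  idx <- match(sub[[karyotype]], uk)
  all_pairs <- do.call(rbind, pairs_by_string[idx])
  if (is.null(all_pairs) || nrow(all_pairs) == 0) return(empty)
  # canonical unordered orientation
  swap <- match(all_pairs$chr_a, .chrom_levels_mar) >
    match(all_pairs$chr_b, .chrom_levels_mar)
  tmp <- all_pairs$chr_a[swap]
  all_pairs$chr_a[swap] <- all_pairs$chr_b[swap]
  all_pairs$chr_b[swap] <- tmp
  out <- tibble::as_tibble(all_pairs) |>
    dplyr::group_by(.data$chr_a, .data$chr_b) |>
    dplyr::summarise(count = dplyr::n(),
                     n_from_three_way = sum(.data$three_way),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$chr_a, .data$chr_b)
  out$count <- as.integer(out$count)
  out$n_from_three_way <- as.integer(out$n_from_three_way)
  out
}

#' Unbalanced-result rate per indication group
#'
#' For each primary indication present in the cohort, the share of samples
#' whose karyotype is unbalanced (Level 4). The denominator is the number of
#' classified samples carrying that indication; groups absent from the
#' cohort yield no row.
#'
#' @param classified A cohort classified by [classify_cohort()] with an
#'   `indication` column (see [assign_indications()]).
#' @return A tibble with `indication`, `count`, `denominator`, `percent`,
#'   sorted by decreasing percent.
#' @export
unbalanced_by_indication <- function(classified) {
  .check_classified(classified, c("level1", "level4", "indication"))
  classified |>
    dplyr::group_by(.data$indication) |>
    dplyr::summarise(count = sum(.data$level4 == "unbalanced"),
                     denominator = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(count = as.integer(.data$count),
                  percent = rate(.data$count, .data$denominator)) |>
    dplyr::arrange(dplyr::desc(.data$percent))
}
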