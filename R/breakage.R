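# Counting of chromosome breakage events outside centromeric regions.
# A breakage event is any recorded breakpoint whose band designation is not
# "10" (p10/q10 denote the centromere); length-variant tokens carry no
# breakpoints and never contribute. Inversions therefore contribute two
# events, reciprocal translocations one per involved chromosome, interstitial
# deletions two and terminal deletions one, duplications two, additions one,
# whole-arm isochromosomes and Robertsonian translocations zero.

#' Breakage events of a single karyotype
#'
#' Tallies non-centromeric breakpoints over all abnormalities in all clones.
#' Identical abnormalities appearing in several clones of a mosaic are
#' counted once; bands designated "10" (the centromere) are excluded.
#'
#' @param k An `iscn_karyotype` or an ISCN string.
#' @return A list of class `breakage_summary` with `events` (tibble of
#'   `chromosome`, `arm`, `band`), `n_events` and `per_chromosome` (tibble of
#'   `chromosome`, `n_events` in karyogram order).
#' @export
#' @examples
#' extract_breakage("46,XY,inv(9)(p12q13)")     # 2 events on chromosome 9
#' extract_breakage("45,XX,rob(13;14)(q10;q10)") # 0 events
extract_breakage <- function(k) {
  k <- .as_karyotype(k)
  abns <- all_abnormalities(k)
  if (length(abns) > 0) {
    abns <- abns[!duplicated(vapply(abns, abn_signature, character(1)))]
  }
  rows <- list()
  for (a in abns) {
    for (b in a$breakpoints) {
      if (b$designation == "10") next
      rows[[length(rows) + 1]] <- b
    }
  }
  events <- tibble::tibble(
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    arm = vapply(rows, `[[`, character(1), "arm"),
    band = vapply(rows, `[[`, character(1), "designation")
  )
  per_chrom <- if (nrow(events) == 0) {
    tibble::tibble(chromosome = character(), n_events = integer())
  } else {
    tb <- table(events$chromosome)
    tibble::tibble(chromosome = chrom_sort(names(tb)),
                   n_events = as.integer(tb[chrom_sort(names(tb))]))
  }
  structure(list(events = events, n_events = nrow(events),
                 per_chromosome = per_chrom),
            class = "breakage_summary")
}

#' @export
print.breakage_summary <- function(x, ...) {
  cat(sprintf("<breakage_summary> %d non-centromeric breakage event(s)\n", x$n_events))
  if (x$n_events > 0) print(x$per_chromosome)
  invisible(x)
}

#' Cohort-level breakage summary
#'
#' Counts fetuses carrying at least one non-centromeric breakage event,
#' stratifies them by Level-1 class (the polymorphism stratum is the inv(9)
#' carriers, whose two pericentric breakpoints count), and aggregates event
#' totals per chromosome. The stratified fetus counts always sum to the
#' total.
#'
#' @param classified A cohort classified by [classify_cohort()] (columns
#'   `karyotype`, `level1`).
#' @param karyotype Name of the karyotype column.
#' @return A list with `n_fetuses`, `n_events`, `fetuses_by_level1` (tibble
#'   `level1`, `n_fetuses`) and `events_per_chromosome` (tibble `chromosome`,
#'   `n_events`).
#' @export
cohort_breakage <- function(classified, karyotype = "karyotype") {
  stopifnot(is.data.frame(classified),
            all(c(karyotype, "level1") %in% names(classified)))
  ok <- !is.na(classified$level1)
  ks <- classified[[karyotype]][ok]
  lev <- classified$level1[ok]
  # normal karyotypes carry no abnormality tokens, hence no breakpoints
  cand <- lev != "normal"
  uk <- unique(ks[cand])
  summaries <- lapply(uk, extract_breakage)
  n_ev_by_string <- vapply(summaries, `[[`, integer(1), "n_events")
  idx <- match(ks, uk)                      # NA for normal strings
  n_ev <- ifelse(is.na(idx), 0L, n_ev_by_string[idx])

  has_event <- n_ev > 0
  strata <- table(factor(lev[has_event], levels = .level1_levels))
  fetuses_by_level1 <- tibble::tibble(
    level1 = names(strata),
    n_fetuses = as.integer(strata)
  )

  per_chrom_all <- dplyr::bind_rows(lapply(seq_along(uk), function(i) {
    pc <- summaries[[i]]$per_chromosome
    if (nrow(pc) == 0) return(NULL)
    pc$n_events <- pc$n_events * sum(idx == i, na.rm = TRUE)
    pc
  }))
  events_per_chromosome <- if (is.null(per_chrom_all) || nrow(per_chrom_all) == 0) {
    tibble::tibble(chromosome = character(), n_events = integer())
  } else {
    agg <- stats::aggregate(n_events ~ chromosome, per_chrom_all, sum)
    ord <- order(match(agg$chromosome, .chrom_levels_mar))
    tibble::tibble(chromosome = agg$chromosome[ord],
                   n_events = as.integer(agg$n_events[ord]))
  }

  list(n_fetuses = sum(has_event),
       n_events = sum(n_ev),
       fetuses_by_level1 = fetuses_by_level1,
       events_per_chromosome = events_per_chromosome)
}
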