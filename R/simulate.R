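# Seeded synthetic-cohort generator. Emits one row per sample: a clinical
# screening record, an ISCN karyotype string (or NA for a failed culture)
# and the ground-truth four-level classification, with category frequencies
# parameterised by a CohortConfig whose defaults transcribe the published
# rates of a 38,636-sample amniocentesis series.

# ---- default frequency tables ----------------------------------------------

# Level-2 category mix within non-mosaic abnormal results. Aneuploidy,
# Robertsonian, inversion, deletion and isochromosome counts are printed in
# the source tables; the translocation/derivative split of the 218 combined
# cases and the small residual categories are documented plausible defaults.
.default_nonmosaic_mix <- c(
  aneuploidy = 1338, robertsonian = 97, translocation = 150, derivative = 37,
  inversion = 70, deletion = 64, duplication = 12, addition = 10,
  psu_dic = 6, isochromosome = 6, triploid = 15, hermaphroditism = 3
)

.default_mosaic_mix <- c(
  aneuploidy = 219, translocation = 25, derivative = 6, deletion = 8,
  isochromosome = 13, inversion = 2
)

# within-aneuploidy chromosome shares, separately for non-mosaic and mosaic
# carriers (the published mosaic/non-mosaic proportions)
.default_aneuploidy_chrom <- list(
  non_mosaic = c(`21` = 0.5209, X = 0.2900, `18` = 0.1517, `13` = 0.0195,
                 mar = 0.0164, Y = 0.0015),
  mosaic = c(X = 0.4612, `21` = 0.1461, mar = 0.1324, Y = 0.1142,
             `13` = 0.1096, `18` = 0.0365)
)

# the 11 observed Robertsonian pair types with their counts
.default_rob_pairs <- c(
  "13;14" = 47, "14;21" = 15, "21;21" = 14, "13;21" = 5, "14;22" = 4,
  "13;15" = 3, "15;21" = 3, "21;22" = 3, "14;15" = 2, "13;22" = 2,
  "15;22" = 1
)

# recurrent reciprocal-translocation pairs; the "other" mass is drawn
# uniformly over random distinct autosome pairs
.default_translocation_pairs <- c(
  "11;22" = 8, "2;10" = 5, "1;2" = 3, "3;7" = 3, "4;8" = 3, "7;14" = 3,
  other = 50
)

# non-mosaic inversions outside chromosome 9 (Y-led); mosaic inversions are
# the two chromosome-11 cases
.default_inversion_chrom <- c(
  Y = 23, `10` = 8, `1` = 7, `7` = 6, `2` = 5, `5` = 4, `3` = 3, `4` = 3,
  `6` = 3, `8` = 2, `11` = 2, `12` = 2, `16` = 2
)

.default_deletion_chrom <- c(
  `5` = 11, X = 11, `18` = 10, `4` = 6, `7` = 5, `13` = 5, `1` = 4,
  `11` = 4, `2` = 3, `9` = 3, `3` = 2, `6` = 2, `10` = 2, `15` = 2, `22` = 2
)

.default_iso_chrom <- c(X = 14, Y = 4, `12` = 1)

# chromosome shares within length polymorphisms (Y-led, then 15); the
# remainder spreads over the other qh-variant and satellited chromosomes
.default_lengthpoly_chrom <- c(
  Y = 0.1869, `15` = 0.1738, `9` = 0.10, `21` = 0.10, `1` = 0.09,
  `14` = 0.09, `16` = 0.09, `13` = 0.08, `22` = 0.0893
)

.band_pool <- c("11", "12", "13", "15", "21", "22", "23", "24", "25",
                "31", "32", "33")

#' Default per-year indication mix
#'
#' A year-by-category weight matrix emulating the published temporal trends:
#' serum-screening referrals decline while NIPT, increased-NT and ultrasound
#' referrals rise; advanced maternal age stays the dominant indication
#' throughout. Weights interpolate linearly between 2010 and 2024 endpoints
#' and are row-normalised.
#'
#' @param years Integer vector of cohort years.
#' @return A numeric matrix, one row per year (rownames), one column per
#'   category of [indication_categories()], rows summing to 1.
#' @export
default_indication_mix <- function(years = c(2010:2016, 2018:2024)) {
  start <- c(ultrasound_structural = 0.050, increased_NT = 0.015,
             high_risk_NIPT = 0.0005, high_risk_serum = 0.270,
             parent_chromosomal_abnormality = 0.012,
             prior_chromosomal_pregnancy = 0.010, monogenic_disease = 0.003,
             parent_intellectual_disability = 0.0008, cord_blood = 0.0002,
             adverse_history = 0.020, advanced_maternal_age = 0.600,
             others = 0.018)
  end <- c(ultrasound_structural = 0.170, increased_NT = 0.070,
           high_risk_NIPT = 0.105, high_risk_serum = 0.055,
           parent_chromosomal_abnormality = 0.012,
           prior_chromosomal_pregnancy = 0.012, monogenic_disease = 0.004,
           parent_intellectual_disability = 0.0008, cord_blood = 0.0002,
           adverse_history = 0.025, advanced_maternal_age = 0.520,
           others = 0.026)
  cats <- indication_categories()
  frac <- (years - 2010) / (2024 - 2010)
  m <- t(vapply(frac, function(f) {
    w <- (1 - f) * start[cats] + f * end[cats]
    w / sum(w)
  }, numeric(length(cats))))
  dimnames(m) <- list(as.character(years), cats)
  m
}

.norm_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p)) < 1e-12) stop("invalid weights for ", what)
  p / sum(p)
}

# ---- configuration ----------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' Frequency parameterisation of [generate_cohort()]. The defaults encode
#' the published structure of the emulated amniocentesis series: Level-1 mix
#' 4.68 / 0.71 / 1.70 / 92.91 percent (non-mosaic / mosaic / polymorphism /
#' normal), a 16-in-38,652 culture-failure rate, category, chromosome and
#' translocation-pair tables from the reported counts, and per-year
#' indication mixes following the reported temporal trends.
#'
#' @param n_samples Number of samples to generate.
#' @param seed Integer seed fixing the entire cohort.
#' @param level1_probs Named probability 4-vector over
#'   `non_mosaic`, `mosaic`, `polymorphism`, `normal`; must sum to 1.
#' @param failure_rate Probability a sample yields no karyotype.
#' @param nonmosaic_mix,mosaic_mix Named weights over Level-2 categories
#'   within the non-mosaic and mosaic strata.
#' @param aneuploidy_chrom List with `non_mosaic` and `mosaic` chromosome
#'   weight vectors for aneuploidies.
#' @param rob_pairs,translocation_pairs Named weights over `"a;b"` pairs
#'   (`translocation_pairs` may include an `other` mass drawn uniformly over
#'   random autosome pairs).
#' @param inversion_chrom,deletion_chrom,iso_chrom Chromosome weights for
#'   the respective categories.
#' @param p_inv9 Share of polymorphisms that are inv(9) (the published
#'   353/655).
#' @param lengthpoly_chrom Chromosome weights within length polymorphisms.
#' @param indication_mix Year-by-category matrix, see
#'   [default_indication_mix()].
#' @param years Calendar years to sample (uniformly).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 38636,
                          seed = 1L,
                          level1_probs = c(non_mosaic = 0.0468,
                                           mosaic = 0.0071,
                                           polymorphism = 0.0170,
                                           normal = 0.9291),
                          failure_rate = 16 / 38652,
                          nonmosaic_mix = .default_nonmosaic_mix,
                          mosaic_mix = .default_mosaic_mix,
                          aneuploidy_chrom = .default_aneuploidy_chrom,
                          rob_pairs = .default_rob_pairs,
                          translocation_pairs = .default_translocation_pairs,
                          inversion_chrom = .default_inversion_chrom,
                          deletion_chrom = .default_deletion_chrom,
                          iso_chrom = .default_iso_chrom,
                          p_inv9 = 353 / 655,
                          lengthpoly_chrom = .default_lengthpoly_chrom,
                          indication_mix = NULL,
                          years = c(2010:2016, 2018:2024)) {
  stopifnot(length(n_samples) == 1, n_samples >= 0,
            length(seed) == 1, is.finite(seed))
  req <- c("non_mosaic", "mosaic", "polymorphism", "normal")
  if (!setequal(names(level1_probs), req)) {
    stop("level1_probs must be named over: ", paste(req, collapse = ", "))
  }
  level1_probs <- level1_probs[req]
  if (abs(sum(level1_probs) - 1) > 1e-9 || any(level1_probs < 0)) {
    stop("level1_probs must be nonnegative and sum to 1")
  }
  stopifnot(failure_rate >= 0, failure_rate < 1,
            p_inv9 >= 0, p_inv9 <= 1)
  if (is.null(indication_mix)) indication_mix <- default_indication_mix(years)
  if (!all(as.character(years) %in% rownames(indication_mix))) {
    stop("indication_mix must have one row per year")
  }
  structure(list(
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    level1_probs = level1_probs, failure_rate = failure_rate,
    nonmosaic_mix = .norm_probs(nonmosaic_mix, "nonmosaic_mix"),
    mosaic_mix = .norm_probs(mosaic_mix, "mosaic_mix"),
    aneuploidy_chrom = lapply(aneuploidy_chrom, .norm_probs, what = "aneuploidy_chrom"),
    rob_pairs = .norm_probs(rob_pairs, "rob_pairs"),
    translocation_pairs = .norm_probs(translocation_pairs, "translocation_pairs"),
    inversion_chrom = .norm_probs(inversion_chrom, "inversion_chrom"),
    deletion_chrom = .norm_probs(deletion_chrom, "deletion_chrom"),
    iso_chrom = .norm_probs(iso_chrom, "iso_chrom"),
    p_inv9 = p_inv9,
    lengthpoly_chrom = .norm_probs(lengthpoly_chrom, "lengthpoly_chrom"),
    indication_mix = indication_mix, years = as.integer(years)
  ), class = "cohort_config")
}

# ---- karyotype string templates ---------------------------------------------

.pick <- function(x, prob = NULL) {
  if (length(x) == 1) x else sample(x, 1L, prob = prob)
}

.pick_name <- function(weights) .pick(names(weights), prob = unname(weights))

.rand_sex <- function() .pick(c("XX", "XY"))

.rand_band <- function() {
  paste0(.pick(c("p", "q")), .pick(.band_pool))
}

.cellcounts <- function() sample(3:30, 2, replace = TRUE)

.mosaicise <- function(abnormal_clone, normal_clone) {
  cc <- .cellcounts()
  sprintf("mos %s[%d]/%s[%d]", abnormal_clone, cc[1], normal_clone, cc[2])
}

.truth <- function(karyotype, level1, level2, level3, level4) {
  list(karyotype = karyotype,
       truth = list(level1 = level1, level2 = level2,
                    level3 = level3, level4 = level4))
}

.gen_aneuploidy <- function(mosaic, cfg) {
  w <- cfg$aneuploidy_chrom[[if (mosaic) "mosaic" else "non_mosaic"]]
  chr <- .pick_name(w)
  if (chr %in% c("13", "18", "21")) {
    sex <- .rand_sex()
    abn <- sprintf("47,%s,+%s", sex, chr)
    normal <- sprintf("46,%s", sex)
  } else if (chr == "mar") {
    sex <- .rand_sex()
    abn <- sprintf("47,%s,+mar", sex)
    normal <- sprintf("46,%s", sex)
  } else if (chr == "X") {
    form <- .pick(c("45,X", "47,XXX", "47,XXY"), prob = c(0.5, 0.3, 0.2))
    abn <- form
    normal <- if (form == "47,XXY") "46,XY" else "46,XX"
  } else {  # Y
    abn <- "47,XYY"
    normal <- "46,XY"
  }
  kar <- if (mosaic) .mosaicise(abn, normal) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "aneuploidy", chr, "unbalanced")
}

.gen_robertsonian <- function(mosaic, cfg) {
  pair <- strsplit(.pick_name(cfg$rob_pairs), ";", fixed = TRUE)[[1]]
  sex <- .rand_sex()
  head <- .pick(c("rob", "der"), prob = c(0.8, 0.2))
  abn <- sprintf("45,%s,%s(%s;%s)(q10;q10)", sex, head, pair[1], pair[2])
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "robertsonian", chrom_sort(unique(pair)), "balanced")
}

.rand_autosome_pair <- function() {
  sort(sample(1:22, 2))
}

.gen_translocation <- function(mosaic, cfg) {
  key <- .pick_name(cfg$translocation_pairs)
  pair <- if (key == "other") as.character(.rand_autosome_pair()) else
    strsplit(key, ";", fixed = TRUE)[[1]]
  sex <- .rand_sex()
  abn <- sprintf("46,%s,t(%s;%s)(%s;%s)", sex, pair[1], pair[2],
                 .rand_band(), .rand_band())
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "translocation", chrom_sort(pair), "balanced")
}

.gen_derivative <- function(mosaic, cfg) {
  pair <- as.character(.rand_autosome_pair())
  sex <- .rand_sex()
  abn <- sprintf("46,%s,der(%s)t(%s;%s)(%s;%s)", sex, pair[1], pair[1],
                 pair[2], .rand_band(), .rand_band())
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "derivative", chrom_sort(pair), "unbalanced")
}

.gen_inversion <- function(mosaic, cfg) {
  chr <- if (mosaic) "11" else .pick_name(cfg$inversion_chrom)
  if (chr == "Y") {
    sex <- "XY"
    abn <- sprintf("46,XY,inv(Y)(%s%s)", .pick(c("p11", "p11.2")),
                   .pick(c("q11", "q12")))
  } else {
    sex <- .rand_sex()
    abn <- sprintf("46,%s,inv(%s)(p%sq%s)", sex, chr,
                   .pick(c("11", "13", "21")), .pick(c("13", "21", "25")))
  }
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "inversion", chr, "balanced")
}

.gen_deletion <- function(mosaic, cfg) {
  chr <- .pick_name(cfg$deletion_chrom)
  if (chr == "X") {
    clone_sex <- "X"
  } else if (chr == "Y") {
    clone_sex <- "X"
  } else {
    clone_sex <- .rand_sex()
  }
  bands <- if (stats::runif(1) < 0.5) .rand_band() else {
    arm <- .pick(c("p", "q"))
    paste0(arm, .pick(c("11", "13", "14")), arm, .pick(c("21", "22", "31")))
  }
  abn <- sprintf("46,%s,del(%s)(%s)", clone_sex, chr, bands)
  normal <- if (clone_sex == "X") {
    if (chr == "Y") "46,XY" else "46,XX"
  } else sprintf("46,%s", clone_sex)
  kar <- if (mosaic) .mosaicise(abn, normal) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "deletion", chr, "unbalanced")
}

.gen_isochromosome <- function(mosaic, cfg) {
  chr <- .pick_name(cfg$iso_chrom)
  if (chr %in% c("X", "Y")) {
    abn <- sprintf("46,X,i(%s)(q10)", chr)
    normal <- if (chr == "Y") "46,XY" else "46,XX"
  } else {
    sex <- .rand_sex()
    abn <- sprintf("46,%s,i(%s)(%s10)", sex, chr, .pick(c("p", "q")))
    normal <- sprintf("46,%s", sex)
  }
  kar <- if (mosaic) .mosaicise(abn, normal) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "isochromosome", chr, "unbalanced")
}

.gen_duplication <- function(mosaic, cfg) {
  chr <- as.character(.pick(1:22))
  sex <- .rand_sex()
  arm <- .pick(c("p", "q"))
  abn <- sprintf("46,%s,dup(%s)(%s%s%s%s)", sex, chr, arm,
                 .pick(c("11", "13", "21")), arm, .pick(c("22", "31", "33")))
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "duplication", chr, "unbalanced")
}

.gen_addition <- function(mosaic, cfg) {
  chr <- as.character(.pick(1:22))
  sex <- .rand_sex()
  abn <- sprintf("46,%s,add(%s)(%s)", sex, chr, .rand_band())
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "addition", chr, "unbalanced")
}

.gen_psu_dic <- function(mosaic, cfg) {
  chr <- .pick(.acrocentrics)
  sex <- .rand_sex()
  band <- paste0("q", .pick(c("11", "12")))
  abn <- sprintf("45,%s,psu dic(%s;%s)(%s;%s)", sex, chr, chr, band, band)
  kar <- if (mosaic) .mosaicise(abn, sprintf("46,%s", sex)) else abn
  .truth(kar, if (mosaic) "mosaic" else "non_mosaic",
         "psu_dic", chr, "unbalanced")
}

.gen_triploid <- function(mosaic, cfg) {
  .truth(.pick(c("69,XXX", "69,XXY"), prob = c(0.6, 0.4)),
         "non_mosaic", "triploid", NA_character_, "unbalanced")
}

.gen_hermaphroditism <- function(mosaic, cfg) {
  .truth("46,XX/46,XY", "non_mosaic", "hermaphroditism",
         NA_character_, "unbalanced")
}

.gen_length_polymorphism <- function(cfg) {
  chr <- .pick_name(cfg$lengthpoly_chrom)
  if (chr == "Y") {
    tok <- .pick(c("Yqh+", "Yqh-"), prob = c(0.7, 0.3))
    sex <- "XY"
  } else if (chr %in% c("1", "9", "16")) {
    tok <- paste0(chr, "qh+")
    sex <- .rand_sex()
  } else {
    tok <- paste0(chr, .pick(c("ps+", "pstk+"), prob = c(0.7, 0.3)))
    sex <- .rand_sex()
  }
  .truth(sprintf("46,%s,%s", sex, tok), "polymorphism",
         "length_polymorphism", chr, "balanced")
}

.gen_inv9 <- function(cfg) {
  sex <- .pick(c("XN", "XX", "XY"), prob = c(1 / 3, 1 / 3, 1 / 3))
  bands <- .pick(c("p11q12", "p12q13", "p11q13"))
  .truth(sprintf("46,%s,inv(9)(%s)", sex, bands), "polymorphism",
         "inversion", "9", "balanced")
}

#' Draw one abnormal or polymorphic karyotype string
#'
#' Samples a syntactically valid ISCN string of the requested Level-2
#' category from the configured templates, together with its ground-truth
#' four-level labels. Uses the current R random-number state; call
#' `set.seed()` for reproducibility.
#'
#' @param category A Level-2 category: one of `"aneuploidy"`,
#'   `"robertsonian"`, `"translocation"`, `"derivative"`, `"inversion"`,
#'   `"deletion"`, `"duplication"`, `"addition"`, `"isochromosome"`,
#'   `"psu_dic"`, `"triploid"`, `"hermaphroditism"`,
#'   `"length_polymorphism"`. `"inversion"` with `mosaic = FALSE` draws a
#'   non-chromosome-9 inversion (inv(9) belongs to the polymorphism
#'   stratum).
#' @param mosaic Emit a two-clone mosaic (abnormal clone plus a normal
#'   clone, with cell counts). Ignored for triploid/hermaphroditism.
#' @param cfg A [cohort_config()] supplying the frequency tables.
#' @return A list with `karyotype` (string) and `truth` (list `level1`,
#'   `level2`, `level3`, `level4`).
#' @export
#' @examples
#' set.seed(1)
#' sample_abnormal_karyotype("robertsonian")
sample_abnormal_karyotype <- function(category, mosaic = FALSE,
                                      cfg = cohort_config()) {
  gen <- switch(category,
                aneuploidy = .gen_aneuploidy,
                robertsonian = .gen_robertsonian,
                translocation = .gen_translocation,
                derivative = .gen_derivative,
                inversion = .gen_inversion,
                deletion = .gen_deletion,
                duplication = .gen_duplication,
                addition = .gen_addition,
                isochromosome = .gen_isochromosome,
                psu_dic = .gen_psu_dic,
                triploid = .gen_triploid,
                hermaphroditism = .gen_hermaphroditism,
                length_polymorphism = function(mosaic, cfg) .gen_length_polymorphism(cfg),
                stop("no generator for category '", category, "'"))
  gen(mosaic, cfg)
}

.sample_polymorphism <- function(cfg) {
  if (stats::runif(1) < cfg$p_inv9) .gen_inv9(cfg) else .gen_length_polymorphism(cfg)
}

# ---- clinical record synthesis ----------------------------------------------

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ages: referrals for advanced maternal age sit above the 35-year cutoff;
# the remaining population is a two-component mixture straddling it so the
# age rule is exercised on both sides.
.gen_ages <- function(target) {
  n <- length(target)
  age <- numeric(n)
  ama <- target == "advanced_maternal_age"
  oth <- target == "others"
  rest <- !ama & !oth
  age[ama] <- .clip(stats::rnorm(sum(ama), 38, 2.5), 35, 52)
  age[oth] <- .clip(stats::rnorm(sum(oth), 28, 4), 18, 34.8)
  n_rest <- sum(rest)
  comp <- stats::runif(n_rest) < 0.3
  base <- .clip(stats::rnorm(n_rest, 29, 4), 18, 34.8)
  older <- .clip(stats::rnorm(n_rest, 37, 2), 35, 50)
  age[rest] <- ifelse(comp, older, base)
  round(age, 1)
}

.gen_clinical <- function(target, thresholds = screening_thresholds()) {
  n <- length(target)
  rec <- tibble::tibble(
    maternal_age_at_edd = .gen_ages(target),
    serum_t21_risk = NA_real_, serum_t18_risk = NA_real_,
    afp_mom = NA_real_, nt_mm = NA_real_,
    nipt_z_21 = NA_real_, nipt_z_18 = NA_real_, nipt_z_13 = NA_real_,
    ultrasound_structural = target == "ultrasound_structural",
    parent_chromosomal_abnormality = target == "parent_chromosomal_abnormality",
    prior_chromosomal_pregnancy = target == "prior_chromosomal_pregnancy",
    parent_intellectual_disability = target == "parent_intellectual_disability",
    monogenic_disease = target == "monogenic_disease",
    cord_blood_sample = target == "cord_blood",
    adverse_history = target == "adverse_history"
  )
  i <- which(target == "increased_NT")
  rec$nt_mm[i] <- round(stats::runif(length(i), 3.1, 6.5), 1)
  # screened-negative NT measurements for a slice of the remaining samples
  j <- which(target != "increased_NT" & stats::runif(n) < 0.3)
  rec$nt_mm[j] <- round(stats::runif(length(j), 0.8, 2.9), 1)
  i <- which(target == "high_risk_serum")
  which_analyte <- sample(3, length(i), replace = TRUE)
  rec$serum_t21_risk[i[which_analyte == 1]] <-
    1 / stats::runif(sum(which_analyte == 1), 20, 269)
  rec$serum_t18_risk[i[which_analyte == 2]] <-
    1 / stats::runif(sum(which_analyte == 2), 20, 349)
  rec$afp_mom[i[which_analyte == 3]] <-
    round(stats::runif(sum(which_analyte == 3), 2.6, 6), 2)
  i <- which(target == "high_risk_NIPT")
  which_tri <- sample(3, length(i), replace = TRUE)
  z <- round(stats::runif(length(i), 3.2, 20), 2)
  rec$nipt_z_21[i[which_tri == 1]] <- z[which_tri == 1]
  rec$nipt_z_18[i[which_tri == 2]] <- z[which_tri == 2]
  rec$nipt_z_13[i[which_tri == 3]] <- z[which_tri == 3]
  rec
}

# ---- cohort generation ------------------------------------------------------

#' Generate a seeded synthetic amniocentesis cohort
#'
#' Produces `cfg$n_samples` rows, each a clinical screening record plus an
#' ISCN karyotype string and its ground-truth four-level classification.
#' Identical configurations (including the seed) yield identical cohorts;
#' ground-truth labels equal `classify(parse_karyotype(karyotype))` by
#' construction. Failed cultures (probability `cfg$failure_rate`) carry `NA`
#' in the karyotype and truth columns.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble with columns `sample_id`, `year`, the clinical fields of
#'   [eligible_indications()], `indication_target` (the category the record
#'   was built to satisfy), `karyotype` and `truth_level1`,
#'   `truth_level2_primary`, `truth_level3`, `truth_level4`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 200, seed = 7))
#' table(cohort$truth_level1)
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples

  year <- if (n > 0) sample(cfg$years, n, replace = TRUE) else integer(0)
  target <- character(n)
  for (y in sort(unique(year))) {
    i <- which(year == y)
    w <- cfg$indication_mix[as.character(y), ]
    target[i] <- sample(colnames(cfg$indication_mix), length(i),
                        replace = TRUE, prob = w)
  }
  rec <- .gen_clinical(target)

  lev <- if (n > 0) {
    sample(names(cfg$level1_probs), n, replace = TRUE, prob = cfg$level1_probs)
  } else character(0)
  failed <- stats::runif(n) < cfg$failure_rate

  kar <- rep(NA_character_, n)
  t1 <- rep(NA_character_, n)
  t2 <- rep(NA_character_, n)
  t3 <- rep(NA_character_, n)
  t4 <- rep(NA_character_, n)

  i_norm <- which(lev == "normal")
  kar[i_norm] <- sample(c("46,XX", "46,XY"), length(i_norm), replace = TRUE)
  t1[i_norm] <- "normal"; t2[i_norm] <- "normal"
  t3[i_norm] <- "None"; t4[i_norm] <- "balanced"

  fill <- function(i, draw) {
    kar[i] <<- draw$karyotype
    t1[i] <<- draw$truth$level1
    t2[i] <<- draw$truth$level2
    t3[i] <<- .level3_string(draw$truth$level3)
    t4[i] <<- draw$truth$level4
  }
  for (i in which(lev == "polymorphism")) fill(i, .sample_polymorphism(cfg))

  i_nm <- which(lev == "non_mosaic")
  cat_nm <- if (length(i_nm) > 0) {
    sample(names(cfg$nonmosaic_mix), length(i_nm), replace = TRUE,
           prob = cfg$nonmosaic_mix)
  } else character(0)
  for (j in seq_along(i_nm)) {
    fill(i_nm[j], sample_abnormal_karyotype(cat_nm[j], mosaic = FALSE, cfg = cfg))
  }

  i_mo <- which(lev == "mosaic")
  cat_mo <- if (length(i_mo) > 0) {
    sample(names(cfg$mosaic_mix), length(i_mo), replace = TRUE,
           prob = cfg$mosaic_mix)
  } else character(0)
  for (j in seq_along(i_mo)) {
    fill(i_mo[j], sample_abnormal_karyotype(cat_mo[j], mosaic = TRUE, cfg = cfg))
  }

  kar[failed] <- NA_character_
  t1[failed] <- NA_character_; t2[failed] <- NA_character_
  t3[failed] <- NA_character_; t4[failed] <- NA_character_

  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%06d", seq_len(n)), year = year),
    rec,
    tibble::tibble(indication_target = target, karyotype = kar,
                   truth_level1 = t1, truth_level2_primary = t2,
                   truth_level3 = t3, truth_level4 = t4)
  )
}
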