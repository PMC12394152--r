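# Prenatal-diagnosis indication rules. Each sample's clinical screening
# record maps to the set of indication categories whose rule fires, and to a
# single primary category under a documented precedence.

#' The twelve prenatal-diagnosis indication categories
#'
#' Returned in the default precedence order used by [primary_indication()]:
#' ultrasound structural anomaly first, `others` last. `others` is the
#' fallback that fires only when no other rule does.
#'
#' @return Character vector of the 12 category names.
#' @export
indication_categories <- function() {
  c("ultrasound_structural", "increased_NT", "high_risk_NIPT",
    "high_risk_serum", "parent_chromosomal_abnormality",
    "prior_chromosomal_pregnancy", "monogenic_disease",
    "parent_intellectual_disability", "cord_blood", "adverse_history",
    "advanced_maternal_age", "others")
}

#' Screening thresholds for indication assignment
#'
#' Numeric cutoffs of the referral rules. Risk cutoffs are exceeded strictly
#' (a serum risk of exactly 1/270, an NT of exactly 3.0 mm or a Z-score of
#' exactly 3 does not fire); the age rule is inclusive ("at or beyond 35").
#'
#' @param t21_serum_risk Trisomy-21 serum risk cutoff (fraction; default 1/270).
#' @param t18_serum_risk Trisomy-18 serum risk cutoff (fraction; default 1/350).
#' @param afp_mom AFP neural-tube-defect cutoff in multiples of the median.
#' @param nt_mm Nuchal translucency cutoff in millimetres.
#' @param nipt_z NIPT trisomy Z-score cutoff.
#' @param advanced_age_years Advanced-maternal-age cutoff in years (inclusive).
#' @return A validated list of class `screening_thresholds`.
#' @export
screening_thresholds <- function(t21_serum_risk = 1 / 270,
                                 t18_serum_risk = 1 / 350,
                                 afp_mom = 2.5,
                                 nt_mm = 3.0,
                                 nipt_z = 3,
                                 advanced_age_years = 35) {
  th <- list(t21_serum_risk = t21_serum_risk, t18_serum_risk = t18_serum_risk,
             afp_mom = afp_mom, nt_mm = nt_mm, nipt_z = nipt_z,
             advanced_age_years = advanced_age_years)
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1)))) {
    stop("all thresholds must be single positive numbers")
  }
  if (t21_serum_risk >= 1 || t18_serum_risk >= 1) {
    stop("serum risk cutoffs must be fractions in (0, 1)")
  }
  structure(th, class = "screening_thresholds")
}

.num_col <- function(data, name) {
  if (name %in% names(data)) {
    x <- data[[name]]
    ifelse(is.na(x), -Inf, as.numeric(x))
  } else rep(-Inf, nrow(data))
}

.flag_col <- function(data, name) {
  if (name %in% names(data)) {
    x <- data[[name]]
    !is.na(x) & as.logical(x)
  } else rep(FALSE, nrow(data))
}

# logical n x 12 matrix of fired rules, one column per category
eligibility_matrix <- function(data, thresholds = screening_thresholds()) {
  th <- thresholds
  m <- cbind(
    ultrasound_structural = .flag_col(data, "ultrasound_structural"),
    increased_NT = .num_col(data, "nt_mm") > th$nt_mm,
    high_risk_NIPT = .num_col(data, "nipt_z_21") > th$nipt_z |
      .num_col(data, "nipt_z_18") > th$nipt_z |
      .num_col(data, "nipt_z_13") > th$nipt_z,
    high_risk_serum = .num_col(data, "serum_t21_risk") > th$t21_serum_risk |
      .num_col(data, "serum_t18_risk") > th$t18_serum_risk |
      .num_col(data, "afp_mom") > th$afp_mom,
    parent_chromosomal_abnormality = .flag_col(data, "parent_chromosomal_abnormality"),
    prior_chromosomal_pregnancy = .flag_col(data, "prior_chromosomal_pregnancy"),
    monogenic_disease = .flag_col(data, "monogenic_disease"),
    parent_intellectual_disability = .flag_col(data, "parent_intellectual_disability"),
    cord_blood = .flag_col(data, "cord_blood_sample"),
    adverse_history = .flag_col(data, "adverse_history"),
    advanced_maternal_age = .num_col(data, "maternal_age_at_edd") >= th$advanced_age_years,
    others = FALSE
  )
  m[, "others"] <- rowSums(m) == 0
  m
}

#' Indication categories eligible for one record
#'
#' Evaluates every referral rule on a single clinical record and returns all
#' categories that fire (in precedence order). `others` fires exactly when
#' nothing else does.
#'
#' @param record A named list or one-row data frame with any of the fields
#'   `maternal_age_at_edd`, `serum_t21_risk`, `serum_t18_risk`, `afp_mom`,
#'   `nt_mm`, `nipt_z_21`, `nipt_z_18`, `nipt_z_13` (numeric) and
#'   `ultrasound_structural`, `parent_chromosomal_abnormality`,
#'   `prior_chromosomal_pregnancy`, `parent_intellectual_disability`,
#'   `monogenic_disease`, `cord_blood_sample`, `adverse_history` (logical).
#'   Missing fields and `NA`s never fire.
#' @param thresholds A [screening_thresholds()] object.
#' @return Character vector of eligible categories (at least one).
#' @export
#' @examples
#' eligible_indications(list(maternal_age_at_edd = 36))
#' eligible_indications(list(maternal_age_at_edd = 30, nt_mm = 3.5))
eligible_indications <- function(record, thresholds = screening_thresholds()) {
  df <- tibble::as_tibble(record[lengths(record) == 1])
  m <- eligibility_matrix(df, thresholds)
  colnames(m)[m[1, ]]
}

#' Primary indication per sample
#'
#' Reduces each record's eligible category set to one reported indication
#' using a configurable precedence (default: the order of
#' [indication_categories()], structural ultrasound findings first,
#' advanced maternal age next-to-last, `others` last).
#'
#' @param data A data frame of clinical records (fields as in
#'   [eligible_indications()]).
#' @param thresholds A [screening_thresholds()] object.
#' @param precedence Character permutation of [indication_categories()].
#' @return Character vector, one category per row of `data`.
#' @export
primary_indication <- function(data, thresholds = screening_thresholds(),
                               precedence = indication_categories()) {
  if (!setequal(precedence, indication_categories())) {
    stop("`precedence` must be a permutation of indication_categories()")
  }
  m <- eligibility_matrix(data, thresholds)[, precedence, drop = FALSE]
  precedence[apply(m, 1, which.max)]
}

#' Append the primary indication to a cohort table
#'
#' @inheritParams primary_indication
#' @return `data` with a character column `indication` appended.
#' @export
assign_indications <- function(data, thresholds = screening_thresholds(),
                               precedence = indication_categories()) {
  data$indication <- primary_indication(data, thresholds, precedence)
  tibble::as_tibble(data)
}
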