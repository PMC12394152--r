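test_that("grammar-forced strings parse to the expected structures", {
  k <- parse_karyotype("46,XX")
  expect_length(k$clones, 1)
  expect_equal(k$clones[[1]]$modal_number, 46L)
  expect_equal(k$clones[[1]]$sex_designation, "XX")
  expect_length(k$clones[[1]]$abnormalities, 0)

  k <- parse_karyotype("mos 45,X[12]/46,XX[18]")
  expect_true(k$mos_prefix)
  expect_equal(vapply(k$clones, `[[`, integer(1), "cell_count"), c(12L, 18L))
  a <- k$clones[[1]]$abnormalities[[1]]
  expect_equal(a$kind, "numerical_loss")
  expect_equal(a$chromosomes, "X")

  k <- parse_karyotype("46,XN,inv(9)(p12q13)")
  a <- k$clones[[1]]$abnormalities[[1]]
  expect_equal(a$kind, "inversion")
  expect_equal(a$chromosomes, "9")
  expect_equal(vapply(a$breakpoints, function(b) paste0(b$arm, b$designation),
                      character(1)), c("p12", "q13"))

  k <- parse_karyotype("45,XY,rob(13;14)(q10;q10)")
  a <- k$clones[[1]]$abnormalities[[1]]
  expect_equal(a$kind, "robertsonian")
  expect_equal(a$chromosomes, c("13", "14"))
  expect_equal(vapply(a$breakpoints, `[[`, character(1), "designation"),
               c("10", "10"))
})

test_that("whitespace, case and notation variants normalise", {
  expect_true(karyotype_equal(parse_karyotype("46,XN,inv (9)(p12q13)"),
                              parse_karyotype("46,xn,INV(9)(P12Q13)")))
  expect_true(karyotype_equal(parse_karyotype("45,XX,psu dic(15;15)(q11;q11)"),
                              parse_karyotype("45,XX,psudic(15;15)(q11;q11)")))
  # der(a;b)(q10;q10) is the whole-arm centric-fusion spelling
  a <- parse_karyotype("45,XX,der(13;14)(q10;q10)")$clones[[1]]$abnormalities[[1]]
  expect_equal(a$kind, "robertsonian")
})

test_that("sex-chromosome headers imply the right numerical abnormalities", {
  kinds_of <- function(s) {
    vapply(parse_karyotype(s)$clones[[1]]$abnormalities, `[[`, character(1), "kind")
  }
  chr_of <- function(s) {
    unlist(lapply(parse_karyotype(s)$clones[[1]]$abnormalities, `[[`, "chromosomes"))
  }
  expect_equal(kinds_of("45,X"), "numerical_loss")
  expect_equal(chr_of("45,X"), "X")
  expect_equal(kinds_of("47,XXY"), "numerical_gain")
  expect_equal(chr_of("47,XXY"), "X")
  expect_equal(kinds_of("47,XYY"), "numerical_gain")
  expect_equal(chr_of("47,XYY"), "Y")
  # structural involvement of a sex chromosome suppresses the implication
  expect_equal(kinds_of("46,X,i(X)(q10)"), "isochromosome")
  # triploidy is carried by the modal number, not abnormality tokens
  expect_length(parse_karyotype("69,XXY")$clones[[1]]$abnormalities, 0)
})

test_that("malformed and unsupported strings fail with distinct conditions", {
  expect_error(parse_karyotype(""), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("46"), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("46,ZZ"), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("46,XX,blah(3)"), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("46,XX,+21[0]"), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("mos 46,XX"), class = "karyocohort_syntax_error")
  # modal number contradicting numerical-token arithmetic
  expect_error(parse_karyotype("46,XX,+21"), class = "karyocohort_syntax_error")
  expect_error(parse_karyotype("46,X"), class = "karyocohort_syntax_error")
  # valid ISCN outside the supported subset is flagged as such
  expect_error(parse_karyotype("46,XX,fra(X)(q27.3)"),
               class = "karyocohort_unsupported_notation")
  expect_error(parse_karyotype("46,XX,ins(2;5)(q13;q21q31)"),
               class = "karyocohort_unsupported_notation")
  expect_error(parse_karyotype("46,XX,r(15)"),
               class = "karyocohort_unsupported_notation")
})

test_that("clone count equals one plus the number of slash separators", {
  for (s in c("46,XY", "46,XX/46,XY", "mos 45,X[5]/46,XX[10]/47,XXX[3]")) {
    expect_length(parse_karyotype(s)$clones,
                  1L + lengths(regmatches(s, gregexpr("/", s, fixed = TRUE))))
  }
})

test_that("formatting is the identity on canonical strings and inverts parsing", {
  for (s in c("46,XX", "mos 45,X[12]/46,XX[18]", "47,XY,+mar",
              "46,XN,inv(9)(p12q13)", "45,XY,rob(13;14)(q10;q10)",
              "46,XX,del(5)(q13q33)", "46,XY,Yqh-", "46,XX,15ps+",
              "45,XX,psu dic(15;15)(q11;q11)",
              "46,XX,der(9)t(9;15)(q22;q24)", "69,XXY")) {
    expect_identical(format_karyotype(parse_karyotype(s)), s)
  }
})

test_that("parse-format round-trip holds on generated cohorts", {
  co <- generate_cohort(cohort_config(n_samples = 4000, seed = 42))
  strings <- unique(co$karyotype[!is.na(co$karyotype)])
  expect_gt(length(strings), 50)
  for (s in strings) {
    k <- parse_karyotype(s)
    expect_true(karyotype_equal(k, parse_karyotype(format_karyotype(k))),
                info = s)
  }
})

test_that("abnormality chromosomes stay within the legal label set", {
  co <- generate_cohort(cohort_config(n_samples = 2000, seed = 7))
  strings <- unique(co$karyotype[!is.na(co$karyotype)])
  legal <- c(as.character(1:22), "X", "Y", "mar")
  for (s in strings) {
    chrs <- unlist(lapply(parse_karyotype(s)$clones, function(cl) {
      lapply(cl$abnormalities, `[[`, "chromosomes")
    }))
    expect_true(all(chrs %in% legal), info = s)
  }
})
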