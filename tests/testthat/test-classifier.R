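test_that("level 1 separates normal, polymorphism, mosaic and non-mosaic", {
  expect_equal(classify_level1("46,XY"), "normal")
  expect_equal(classify_level1("46,XN,inv(9)(p12q13)"), "polymorphism")
  expect_equal(classify_level1("46,XY,Yqh+"), "polymorphism")
  expect_equal(classify_level1("mos 45,X[12]/46,XX[18]"), "mosaic")
  expect_equal(classify_level1("47,XX,+21"), "non_mosaic")
  # a polymorphism alongside a true abnormality is not a polymorphism result
  expect_equal(classify_level1("47,XY,+21,Yqh+"), "non_mosaic")
  # hermaphroditism is excluded from the mosaic class
  expect_equal(classify_level1("46,XX/46,XY"), "non_mosaic")
  # two clones identical up to cell count are one cell line
  expect_equal(classify_level1("46,XX[15]/46,XX[10]"), "normal")
})

test_that("level 2 collects labels and picks the primary by precedence", {
  expect_equal(classify_level2("45,XY,rob(13;14)(q10;q10)"),
               list(labels = "robertsonian", primary = "robertsonian"))
  expect_equal(classify_level2("46,XX/46,XY"),
               list(labels = "hermaphroditism", primary = "hermaphroditism"))
  l2 <- classify_level2("mos 47,XX,+21/46,XX,t(2;10)(q21;q22)")
  expect_setequal(l2$labels, c("aneuploidy", "translocation"))
  expect_equal(l2$primary, "aneuploidy")
  expect_equal(classify_level2("69,XXX")$primary, "triploid")
  # 46,XX/46,XY plus any other abnormality is mosaic, not hermaphroditism
  expect_equal(classify_level1("46,XX/46,XY/47,XX,+21"), "mosaic")
  expect_false("hermaphroditism" %in%
                 classify_level2("46,XX/46,XY/47,XX,+21")$labels)
})

test_that("level-2 primary follows the documented precedence for label pairs", {
  # enumeration oracle: generate a sample carrying each unordered pair of
  # instantiable labels via a two-clone mosaic and check the reported
  # primary is the earlier label in the precedence order
  reps <- list(
    aneuploidy = "47,XX,+21", robertsonian = "45,XX,rob(13;14)(q10;q10)",
    translocation = "46,XX,t(2;10)(q21;q22)",
    derivative = "46,XX,der(9)t(9;15)(q22;q24)",
    psu_dic = "45,XX,psu dic(15;15)(q11;q11)",
    isochromosome = "46,XX,i(12)(p10)", deletion = "46,XX,del(5)(q13q33)",
    duplication = "46,XX,dup(1)(q21q32)", addition = "46,XX,add(5)(p15)",
    inversion = "46,XX,inv(2)(p11q13)", length_polymorphism = "46,XX,1qh+"
  )
  precedence <- c("aneuploidy", "robertsonian", "translocation", "derivative",
                  "psu_dic", "isochromosome", "deletion", "duplication",
                  "addition", "inversion", "length_polymorphism")
  for (i in seq_along(precedence)) {
    for (j in seq_along(precedence)) {
      if (i >= j) next
      s <- paste0("mos ", reps[[precedence[i]]], "[10]/",
                  reps[[precedence[j]]], "[20]")
      l2 <- classify_level2(s)
      expect_equal(l2$primary, precedence[i], info = s)
      expect_setequal(l2$labels, c(precedence[i], precedence[j]))
    }
  }
})

test_that("level 3 reports involved chromosomes, with a None sentinel", {
  expect_equal(classify_level3("46,XX,t(11;22)(q23;q11)"), c("11", "22"))
  expect_equal(classify_level3("69,XXX"), NA_character_)
  expect_equal(classify_level3("46,XX/46,XY"), NA_character_)
  expect_equal(classify_level3("47,XY,+mar"), "mar")
  # union across clones, karyogram order
  expect_equal(classify_level3("mos 47,XX,+21/46,XX,t(2;10)(q21;q22)"),
               c("2", "10", "21"))
})

test_that("level 4 marks material-neutral results balanced", {
  expect_equal(classify_level4("45,XX,rob(13;14)(q10;q10)"), "balanced")
  expect_equal(classify_level4("46,XX,inv(2)(p11q13)"), "balanced")
  expect_equal(classify_level4("46,XX,t(11;22)(q23;q11)"), "balanced")
  expect_equal(classify_level4("46,XY"), "balanced")
  expect_equal(classify_level4("46,X,i(X)(q10)"), "unbalanced")
  expect_equal(classify_level4("47,XX,+21"), "unbalanced")
  expect_equal(classify_level4("46,XX,del(5)(p15)"), "unbalanced")
  expect_equal(classify_level4("69,XXY"), "unbalanced")
  expect_equal(classify_level4("46,XX/46,XY"), "unbalanced")
})

test_that("classify composes the four levels deterministically", {
  r <- classify("47,XX,+21")
  expect_s3_class(r, "classified_result")
  expect_equal(r$level1, "non_mosaic")
  expect_equal(r$level2, "aneuploidy")
  expect_equal(r$level3, "21")
  expect_equal(r$level4, "unbalanced")

  r <- classify("46,XN,inv(9)(p12q13)")
  expect_equal(unlist(r[c("level1", "level2_primary", "level3", "level4")]),
               c(level1 = "polymorphism", level2_primary = "inversion",
                 level3 = "9", level4 = "balanced"))

  r <- classify("mos 45,X[5]/46,XX[25]")
  expect_equal(unlist(r[c("level1", "level2_primary", "level3", "level4")]),
               c(level1 = "mosaic", level2_primary = "aneuploidy",
                 level3 = "X", level4 = "unbalanced"))

  expect_identical(classify("mos 45,X[5]/46,XX[25]"),
                   classify("mos 45,X[5]/46,XX[25]"))
})

test_that("None sentinel appears exactly for hermaphroditism, triploid, normal", {
  co <- generate_cohort(cohort_config(n_samples = 4000, seed = 5))
  cl <- classify_cohort(co[!is.na(co$karyotype), ])
  none <- cl$level3 == "None"
  sentinel_primary <- cl$level2_primary %in%
    c("hermaphroditism", "triploid", "normal")
  expect_equal(none, sentinel_primary)
})

test_that("polymorphism always implies balanced", {
  co <- generate_cohort(cohort_config(n_samples = 6000, seed = 9))
  cl <- classify_cohort(co[!is.na(co$karyotype), ])
  expect_true(all(cl$level4[cl$level1 == "polymorphism"] == "balanced"))
  expect_gt(sum(cl$level1 == "polymorphism"), 0)
})

test_that("classifier recovers generator ground truth at all four levels", {
  cl <- make_classified_cohort(5000, seed = 21)
  expect_equal(cl$level1, cl$truth_level1)
  expect_equal(cl$level2_primary, cl$truth_level2_primary)
  expect_equal(cl$level3, cl$truth_level3)
  expect_equal(cl$level4, cl$truth_level4)
})
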