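test_that("rate uses round-half-up to two decimals and rejects bad input", {
  expect_equal(rate(0, 100), 0)
  expect_equal(rate(1, 3), 33.33)
  expect_equal(rate(2, 3), 66.67)
  expect_equal(rate(1, 8), 12.5)      # exact half rounds up: 12.5, not 12.49
  expect_equal(rate(25, 2000), 1.25)
  expect_error(rate(1, 0), "positive")
  expect_error(rate(-1, 10), "count")
  expect_error(rate(11, 10), "count")
})

test_that("level-1 table partitions the cohort, overall and per year", {
  cl <- classify_strings(c("46,XY", "46,XN,inv(9)(p12q13)",
                           "mos 45,X[5]/46,XX[25]", "47,XX,+21"))
  tab <- level1_table(cl)
  expect_setequal(tab$level1, c("non_mosaic", "mosaic", "polymorphism", "normal"))
  expect_equal(tab$percent, rep(25, 4))
  expect_equal(sum(tab$count), unique(tab$denominator))

  cl <- classify_strings(rep("46,XX", 100))
  tab <- level1_table(cl)
  expect_equal(tab$percent[tab$level1 == "normal"], 100)
  expect_equal(tab$percent[tab$level1 != "normal"], rep(0, 3))

  cl <- make_classified_cohort(5000, seed = 77)
  cl$year <- cl$year  # by-year partition
  tab <- level1_table(cl, by_year = TRUE)
  sums <- tapply(tab$percent, tab$year, sum)
  expect_true(all(abs(sums - 100) <= 0.02))
  expect_true(all(tapply(tab$count, tab$year, sum) ==
                    tapply(tab$denominator, tab$year, unique)))
  expect_error(level1_table(cl[0, ]), "empty")
})

test_that("level-1 percentages recover the configured mix at scale", {
  cfg <- cohort_config(n_samples = 20000, seed = 101)
  cl <- make_classified_cohort(20000, seed = 101)
  tab <- level1_table(cl)
  n <- unique(tab$denominator)
  for (class in names(cfg$level1_probs)) {
    p <- cfg$level1_probs[[class]]
    tol <- 3 * sqrt(p * (1 - p) / n) * 100
    expect_lt(abs(tab$percent[tab$level1 == class] - 100 * p), tol)
  }
})

test_that("category rates count carriers per chromosome", {
  cl <- classify_strings(c("47,XX,+21", "47,XY,+21",
                           "mos 45,X[5]/46,XX[25]", "mos 45,X[9]/46,XX[20]",
                           "46,XY"))
  tab <- category_rates(cl, "aneuploidy")
  expect_equal(tab$count[tab$chromosome == "21"], 2L)
  expect_equal(tab$count[tab$chromosome == "X"], 2L)
  expect_equal(unique(tab$denominator), 5L)
  # within-stratum shares: all mosaic aneuploidies here involve X
  st <- category_rates(cl, "aneuploidy", stratify_by_level1 = TRUE)
  expect_equal(st$percent[st$level1 == "mosaic" & st$chromosome == "X"], 100)
  expect_equal(st$percent[st$level1 == "non_mosaic" & st$chromosome == "21"], 100)
  # empty subset: zero rows, no failure
  expect_equal(nrow(category_rates(cl, "deletion")), 0L)
  expect_error(category_rates(cl, "nonsense"), "unknown")
})

test_that("pair counts are unordered and include three-way pairs flagged", {
  cl <- classify_strings(c(rep("45,XX,rob(13;14)(q10;q10)", 3),
                           "46,XX,t(11;22)(q23;q11)",
                           "46,XY,t(22;11)(q11;q23)",
                           "46,XX,t(1;3;7)(p22;q21;q15)"))
  rb <- pair_counts(cl, "robertsonian")
  expect_equal(rb$count[rb$chr_a == "13" & rb$chr_b == "14"], 3L)
  rt <- pair_counts(cl, "reciprocal_translocation")
  expect_equal(rt$count[rt$chr_a == "11" & rt$chr_b == "22"], 2L)
  three <- rt[rt$n_from_three_way > 0, ]
  expect_equal(nrow(three), 3L)  # (1,3), (1,7), (3,7)
  expect_true(all(three$count == 1L))
})

test_that("pair counts equal a brute-force string scan on a synthetic cohort", {
  cl <- make_classified_cohort(8000, seed = 55)
  rb <- pair_counts(cl, "robertsonian")
  # oracle: scan raw strings for rob/der whole-arm tokens
  hits <- regmatches(cl$karyotype,
                     regexpr("(rob|der)\\(([0-9]+);([0-9]+)\\)", cl$karyotype))
  pairs <- t(vapply(hits, function(h) {
    ch <- strsplit(gsub("^(rob|der)\\(|\\)$", "", h), ";")[[1]]
    sort(as.integer(ch))
  }, integer(2)))
  oracle <- table(paste(pairs[, 1], pairs[, 2], sep = ";"))
  got <- stats::setNames(rb$count, paste(rb$chr_a, rb$chr_b, sep = ";"))
  expect_mapequal(as.list(got),
                  as.list(stats::setNames(as.integer(oracle), names(oracle))))
  expect_equal(sum(rb$count), length(hits))
})

test_that("tables are invariant under cohort row order", {
  cl <- make_classified_cohort(3000, seed = 8)
  perm <- cl[sample(nrow(cl)), ]
  expect_equal(level1_table(cl), level1_table(perm))
  expect_equal(category_rates(cl, "aneuploidy"),
               category_rates(perm, "aneuploidy"))
  expect_equal(pair_counts(cl, "robertsonian"),
               pair_counts(perm, "robertsonian"))
})

test_that("unbalanced-by-indication equals a brute-force cross-tab", {
  cl <- assign_indications(make_classified_cohort(6000, seed = 99))
  tab <- unbalanced_by_indication(cl)
  for (i in seq_len(nrow(tab))) {
    sub <- cl[cl$indication == tab$indication[i], ]
    expect_equal(tab$denominator[i], nrow(sub))
    expect_equal(tab$count[i], sum(sub$level4 == "unbalanced"))
    expect_equal(tab$percent[i], rate(tab$count[i], tab$denominator[i]))
  }
  expect_setequal(tab$indication, unique(cl$indication))

  # 10 NIPT-indicated samples, 4 unbalanced -> 40.00%
  toy <- classify_strings(c(rep("47,XX,+21", 4), rep("46,XY", 6)))
  toy$indication <- "high_risk_NIPT"
  expect_equal(unbalanced_by_indication(toy)$percent, 40)
})

test_that("every table's percent recomputes from count and denominator", {
  cl <- assign_indications(make_classified_cohort(4000, seed = 61))
  for (tab in list(level1_table(cl), category_rates(cl, "aneuploidy"),
                   unbalanced_by_indication(cl))) {
    expect_equal(tab$percent, rate(tab$count, tab$denominator))
  }
})
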