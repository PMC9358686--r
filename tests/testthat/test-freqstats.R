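make_cases_with_counts <- function(counts, n) {
  # deterministic clean cases realizing exact symptom counts
  tibble::tibble(
    case_id = sprintf("c%03d", seq_len(n)),
    symptoms = lapply(seq_len(n), function(i) {
      sort(names(counts)[counts >= i])
    }),
    herbs = rep(list("Jinyinhua"), n)
  )
}

test_that("frequency table counts cases per item with descending, tie-broken order", {
  cases <- make_cases_with_counts(c(`Thready pulse` = 116, `Dry eyes` = 38,
                                    `Fatigue` = 311), 311)
  ft <- frequency_table(cases, "symptoms")
  expect_equal(ft$count[ft$item == "Thready pulse"], 116L)
  expect_equal(round(ft$rate[ft$item == "Thready pulse"], 3), 0.373)
  expect_equal(ft$rate[ft$item == "Fatigue"], 1)

  # hand count with alphabetical tie-break: {A,B},{A},{B}
  cc <- tibble::tibble(case_id = c("1", "2", "3"), symptoms = rep(list("s"), 3),
                       herbs = list(c("A", "B"), "A", "B"))
  fh <- frequency_table(cc, "herbs")
  expect_equal(fh$item, c("A", "B"))
  expect_equal(fh$count, c(2L, 2L))
  expect_equal(fh$rate, c(2 / 3, 2 / 3))

  expect_error(frequency_table(cc[0, ], "herbs"), "at least one case")
})

test_that("item counts conserve total set sizes across cases", {
  for (seed in c(3, 14, 25)) {
    cases <- rand_clean_cases(seed)
    for (dom in c("herbs", "symptoms")) {
      ft <- frequency_table(cases, dom)
      expect_equal(sum(ft$count), sum(lengths(cases[[dom]])))
    }
  }
})

test_that("high-frequency filter is inclusive at the threshold and monotone", {
  tb <- tibble::tibble(item = c("keep", "edge", "drop"),
                       count = c(38L, 31L, 30L),
                       rate = c(38, 31.1, 30.8) / 311)
  kept <- filter_high_frequency(tb, 0.10)
  expect_setequal(kept$item, c("keep", "edge"))   # 12.22% and 10.0% retained
  expect_false("drop" %in% kept$item)             # 9.9% dropped
  expect_equal(filter_high_frequency(tb, 0), tb)  # identity at zero

  for (r in seq(0, 0.5, by = 0.05)) {
    expect_true(all(filter_high_frequency(tb, r + 0.05)$item %in%
                      filter_high_frequency(tb, r)$item))
  }
})

test_that("pain share is occurrence-weighted and sums to one", {
  d <- ra_dictionary()
  cases <- tibble::tibble(
    case_id = c("1", "2"),
    symptoms = list(c("Upper limb joint pain", "Poor sleep"), "Poor sleep"),
    herbs = rep(list("Jinyinhua"), 2))
  ps <- pain_share(cases, d)
  expect_equal(sum(ps$fraction[ps$kind == "pain"]), 1 / 3)
  expect_equal(sum(ps$fraction), 1)

  all_pain <- tibble::tibble(case_id = "1", symptoms = list("Polyarthralgia"),
                             herbs = list("X"))
  expect_equal(sum(pain_share(all_pain, d)$fraction[
    pain_share(all_pain, d)$kind == "pain"]), 1)

  no_pain <- tibble::tibble(case_id = "1", symptoms = list("Dry eyes"),
                            herbs = list("X"))
  expect_equal(sum(pain_share(no_pain, d)$fraction[
    pain_share(no_pain, d)$kind == "pain"]), 0)
})

test_that("category shares support both weightings and sum to 100", {
  mono <- ra_monographs()
  tb <- tibble::tibble(item = c("Jinyinhua", "Wugong"), count = c(30L, 10L),
                       rate = c(0.3, 0.1))
  by_freq <- category_shares(mono, tb, "frequency")
  expect_equal(by_freq$share_pct[by_freq$category == "Heat-clearing medicinal"], 75)
  by_count <- category_shares(mono, tb, "count")
  expect_equal(sort(by_count$share_pct), c(50, 50))

  one <- category_shares(mono, tb[1, ])
  expect_equal(one$share_pct, 100)

  expect_error(category_shares(mono, tibble::tibble(item = "NotAHerb",
                                                    count = 1L, rate = 1)),
               "NotAHerb")

  packaged <- tibble::tibble(item = mono$name, count = mono$count,
                             rate = mono$count / 311)
  for (w in c("frequency", "count")) {
    expect_lt(abs(sum(category_shares(mono, packaged, w)$share_pct) - 100), 0.5)
  }
})

test_that("packaged monographs reproduce the printed efficacy-category shares", {
  mono <- ra_monographs()
  tb <- tibble::tibble(item = mono$name, count = mono$count,
                       rate = mono$count / 311)
  sh <- category_shares(mono, tb, "frequency")
  printed <- c(`Tonifying and replenishing medicinal` = 21,
               `Wind-dampness dispelling medicinal` = 20,
               `Heat-clearing medicinal` = 17,
               `Dampness-draining diuretic medicinal` = 11,
               `Liver and wind-soothing medicine` = 9,
               `Exterior-releasing medicinal` = 9,
               `Blood-activating and stasis-dispelling medicinal` = 8,
               `Interior-warming medicinal` = 5)
  expect_setequal(sh$category, names(printed))
  expect_equal(round(sh$share_pct[match(names(printed), sh$category)]),
               unname(printed))
})

test_that("attribute edges enumerate property, flavor and meridian incidences", {
  mono <- ra_monographs()
  e_jyh <- attribute_edges(mono[mono$name == "Jinyinhua", ])
  expect_equal(nrow(e_jyh), 4)  # Cold; Sweet; Stomach, Lung
  expect_setequal(e_jyh$attribute, c("Cold", "Sweet", "Stomach", "Lung"))
  expect_equal(nrow(attribute_edges(mono[mono$name == "Wugong", ])), 3)
  expect_equal(nrow(attribute_edges(mono[0, ])), 0)

  edges <- attribute_edges(mono)
  expect_equal(nrow(edges),
               sum(1 + lengths(mono$flavors) + lengths(mono$meridians)))
  # deterministic ordering: herb, then class property < flavor < meridian
  expect_equal(edges, edges[order(edges$herb,
                                  factor(edges$attribute_class,
                                         c("property", "flavor", "meridian")),
                                  edges$attribute), ])

  sif <- tempfile(fileext = ".sif")
  write_sif(edges, sif)
  expect_equal(length(readLines(sif)), nrow(edges))
  unlink(sif)
})
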