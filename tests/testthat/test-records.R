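test_that("symptom and herb standardization follow the dictionary and its exceptions", {
  d <- ra_dictionary()
  expect_equal(standardize_symptom("Wrist pain", d), "Upper limb joint pain")
  expect_equal(standardize_symptom("Burnout", d), "Fatigue")
  expect_equal(standardize_symptom("Fatigue", d), "Fatigue")
  expect_equal(standardize_symptom("Lower extremity joint pain", d),
               "Joint pain of lower extremity")
  expect_equal(standardize_herb("Han Fangji", d), "Fangji")
  expect_equal(standardize_herb("Panax notoginseng powder", d), "Sanqi")
  # deliberately unmerged: distinct drugs and distinct plant parts
  expect_equal(standardize_herb("Chuanniuxi", d), "Chuanniuxi")
  expect_equal(standardize_herb("Niuxigen", d), "Niuxigen")
  expect_equal(standardize_herb("Jinyinhua", d), "Jinyinhua")
  expect_equal(standardize_herb("Rendongteng", d), "Rendongteng")
  # unknown terms pass through, optionally with a warning
  expect_equal(standardize_symptom("Mystery symptom", d), "Mystery symptom")
  expect_warning(standardize_herb("Mystery herb", d, warn_unmapped = TRUE),
                 "unmapped")
})

test_that("standardization is idempotent over the whole dictionary", {
  d <- ra_dictionary()
  once_s <- standardize_symptom(names(d$symptom_map), d)
  expect_equal(standardize_symptom(once_s, d), once_s)
  once_h <- standardize_herb(names(d$herb_map), d)
  expect_equal(standardize_herb(once_h, d), once_h)
})

test_that("multi-joint rule replaces multi-region pain and is idempotent", {
  d <- ra_dictionary()
  expect_setequal(
    apply_multi_joint_rule(
      c("Upper limb joint pain", "Lumbosacral pain", "Poor sleep"), d),
    c("Polyarthralgia", "Poor sleep"))
  expect_setequal(
    apply_multi_joint_rule(c("Upper limb joint pain", "Poor sleep"), d),
    c("Upper limb joint pain", "Poor sleep"))
  expect_equal(apply_multi_joint_rule(character(), d), character())
  # regional pain plus an existing Polyarthralgia collapses to one term
  expect_setequal(
    apply_multi_joint_rule(
      c("Upper limb joint pain", "Joint pain of lower extremity",
        "Polyarthralgia"), d),
    "Polyarthralgia")
  for (s in list(c("Upper limb joint pain", "Lumbosacral pain"),
                 c("Lumbosacral pain", "Dry eyes"),
                 c("Polyarthralgia"))) {
    once <- apply_multi_joint_rule(s, d)
    expect_setequal(apply_multi_joint_rule(once, d), once)
  }
})

test_that("eligibility screen applies every criterion with printed boundary semantics", {
  expect_true(screen_cases(make_raw_case())$eligible)

  boundary <- list(
    list(das28_before = 3.2, id = "das28_before"),  # strict lower bound
    list(das28_before = 5.1, id = "das28_before"),  # strict upper bound
    list(das28_after = 2.6, id = "das28_after"),
    list(haq_before = 0.99, id = "haq_before"),
    list(haq_after = 0.5, id = "haq_after"),
    list(wbc = 3.5, id = "wbc"),                    # <= 3.5 excluded
    list(alt_uln_ratio = 2.0, id = "alt_uln_ratio"),
    list(ast_uln_ratio = 2.0, id = "ast_uln_ratio"),
    list(age = 17L, id = "age"), list(age = 71L, id = "age"),
    list(duration = 5L, id = "duration"),
    list(vas_after = 6, id = "vas"),                # VAS must decrease
    list(consent = FALSE, id = "consent"),
    list(tcm_treated = FALSE, id = "tcm_treated")
  )
  for (b in boundary) {
    case <- do.call(make_raw_case, b[setdiff(names(b), "id")])
    res <- screen_cases(case)
    expect_false(res$eligible)
    expect_equal(res$failed_criteria[[1]], b$id)
  }
  # inclusive bounds that pass
  passing <- list(list(age = 18L), list(age = 70L), list(duration = 6L),
                  list(haq_before = 1.0), list(wbc = 3.51))
  for (p in passing) {
    expect_true(screen_cases(do.call(make_raw_case, p))$eligible)
  }
})

test_that("screening is a pure conjunction: fixing one failing field removes exactly its id", {
  bad <- make_raw_case(das28_before = 3.0, wbc = 3.0, consent = FALSE)
  res <- screen_cases(bad)
  expect_setequal(res$failed_criteria[[1]],
                  c("das28_before", "wbc", "consent"))
  fixed <- screen_cases(make_raw_case(das28_before = 3.0, wbc = 3.0))
  expect_setequal(fixed$failed_criteria[[1]], c("das28_before", "wbc"))
})

test_that("missing required fields reject the record as incomplete", {
  res <- screen_cases(make_raw_case(haq_after = NA_real_))
  expect_false(res$eligible)
  expect_equal(res$failed_criteria[[1]], "incomplete_record")
})

test_that("clean_cases standardizes, deduplicates and collapses multi-region pain", {
  d <- ra_dictionary()
  raw <- make_raw_case(
    symptoms = list(c("Wrist pain", "Knee joint pain", "Burnout", "Burnout")),
    herbs = list(c("Han Fangji", "Fangji")))
  cc <- clean_cases(raw, d)
  expect_setequal(cc$symptoms[[1]], c("Polyarthralgia", "Fatigue"))
  expect_equal(cc$herbs[[1]], "Fangji")

  # invariance to list order and duplication
  raw2 <- make_raw_case(
    symptoms = list(c("Burnout", "Knee joint pain", "Wrist pain")),
    herbs = list(c("Fangji", "Han Fangji", "Han Fangji")))
  expect_equal(clean_cases(raw2, d)[c("symptoms", "herbs")],
               cc[c("symptoms", "herbs")])

  expect_error(clean_cases(make_raw_case(herbs = list(character())), d),
               "degenerate_case")
})

test_that("case tables round-trip through CSV and JSON-lines", {
  cases <- dplyr::bind_rows(make_raw_case("c1"),
                            make_raw_case("c2", symptoms = list("Dry eyes"),
                                          herbs = list("Yiyiren")))
  for (ext in c(".csv", ".jsonl")) {
    path <- tempfile(fileext = ext)
    write_cases(cases, path)
    back <- read_cases(path)
    expect_equal(back$case_id, cases$case_id)
    expect_equal(back$symptoms, cases$symptoms)
    expect_equal(back$herbs, cases$herbs)
    expect_equal(back$das28_before, cases$das28_before)
    unlink(path)
  }
})
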