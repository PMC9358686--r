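# fixtures built in code: an eligible raw case, random transactions,
# and random clean-case tables used by the property suites

make_raw_case <- function(case_id = "c1", age = 45L, duration = 12L,
                          das28_before = 4.0, das28_after = 2.0,
                          haq_before = 1.2, haq_after = 0.3,
                          vas_before = 6, vas_after = 3,
                          alt_uln_ratio = 1.0, ast_uln_ratio = 1.0,
                          wbc = 5.0, consent = TRUE, tcm_treated = TRUE,
                          symptoms = list(c("Polyarthralgia", "Fatigue")),
                          herbs = list(c("Jinyinhua", "Wugong"))) {
  tibble::tibble(
    case_id = case_id, age = age, duration = duration,
    das28_before = das28_before, das28_after = das28_after,
    haq_before = haq_before, haq_after = haq_after,
    vas_before = vas_before, vas_after = vas_after,
    alt_uln_ratio = alt_uln_ratio, ast_uln_ratio = ast_uln_ratio,
    wbc = wbc, consent = consent, tcm_treated = tcm_treated,
    symptoms = symptoms, herbs = herbs
  )
}

# long transaction tibble over random subsets of LETTERS[1:n_items]
rand_transactions <- function(seed, n_items = 8, n_trans = 30,
                              p_item = 0.4) {
  withr::with_seed(seed, {
    items <- LETTERS[seq_len(n_items)]
    cls <- sample(c("herb", "symptom"), n_items, replace = TRUE)
    rows <- lapply(seq_len(n_trans), function(i) {
      keep <- runif(n_items) < p_item
      if (!any(keep)) keep[sample.int(n_items, 1)] <- TRUE
      tibble::tibble(case_id = sprintf("t%03d", i), item = items[keep],
                     class = cls[keep])
    })
    dplyr::bind_rows(rows)
  })
}

# clean-case tibble with random herb/symptom sets over small vocabularies
rand_clean_cases <- function(seed, n_cases = 20, herbs = LETTERS[1:6],
                             symptoms = letters[1:4]) {
  withr::with_seed(seed, {
    tibble::tibble(
      case_id = sprintf("c%03d", seq_len(n_cases)),
      symptoms = lapply(seq_len(n_cases), function(i) {
        sort(sample(symptoms, sample.int(length(symptoms), 1)))
      }),
      herbs = lapply(seq_len(n_cases), function(i) {
        sort(sample(herbs, sample.int(length(herbs), 1)))
      })
    )
  })
}

# transactions holding exactly the given itemsets (one per element)
transactions_of <- function(sets) {
  rows <- lapply(seq_along(sets), function(i) {
    if (length(sets[[i]]) == 0) return(NULL)
    tibble::tibble(case_id = sprintf("t%02d", i), item = sets[[i]],
                   class = "herb")
  })
  dplyr::bind_rows(rows)
}

rule_key <- function(rules) {
  if (nrow(rules) == 0) return(character(0))
  paste0(rules$lhs_label, " -> ", rules$rhs)
}

expect_same_rules <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  expect_setequal(rule_key(a), rule_key(b))
  if (nrow(a) > 0) {
    bb <- b[match(rule_key(a), rule_key(b)), ]
    expect_equal(a$support, bb$support, tolerance = tol)
    expect_equal(a$confidence, bb$confidence, tolerance = tol)
    expect_equal(a$lift, bb$lift, tolerance = tol)
    expect_equal(a$co_count, bb$co_count)
  }
}
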