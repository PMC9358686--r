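test_that("transactions restrict to the requested item classes", {
  cases <- tibble::tibble(
    case_id = c("c1", "c2"),
    symptoms = list("Polyarthralgia", "Dry eyes"),
    herbs = list(c("Jinyinhua", "Wugong"), character()))
  tr_both <- suppressWarnings(build_transactions(cases, "both"))
  expect_equal(nrow(tr_both[tr_both$case_id == "c1", ]), 3)
  expect_setequal(tr_both$class[tr_both$case_id == "c1"],
                  c("herb", "symptom"))
  tr_h <- suppressWarnings(build_transactions(cases, "herbs"))
  expect_equal(nrow(tr_h), 2)
  expect_warning(build_transactions(cases, "herbs"), "dropped")
  expect_false("c2" %in% tr_h$case_id)
})

test_that("level-wise search finds exactly the frequent itemsets", {
  tr <- transactions_of(list(c("A", "B"), c("A", "B"), "A", c("B", "C")))
  fi <- frequent_itemsets(tr, min_support = 0.5)
  expect_equal(setNames(fi$support, fi$label),
               c(A = 0.75, B = 0.75, `A;B` = 0.5))

  # no common item across all transactions at min_support 1
  tr2 <- transactions_of(list("A", "B"))
  expect_equal(nrow(frequent_itemsets(tr2, min_support = 1)), 0)

  expect_error(frequent_itemsets(tr[0, ], 0.5), "no transactions")
})

test_that("at vanishing support the search equals brute-force enumeration", {
  for (seed in c(2, 9, 31)) {
    tr <- rand_transactions(seed, n_items = 7, n_trans = 25)
    mat <- table(tr$case_id, tr$item) > 0
    items <- colnames(mat)
    fi <- frequent_itemsets(tr, min_support = 1e-9, max_size = 3)
    # enumerate all itemsets up to size 3 with count >= 1
    expected <- list()
    for (k in 1:3) {
      for (s in utils::combn(items, k, simplify = FALSE)) {
        cnt <- sum(rowSums(mat[, s, drop = FALSE]) == k)
        if (cnt >= 1) expected[[paste(s, collapse = ";")]] <- cnt
      }
    }
    expect_setequal(fi$label, names(expected))
    expect_equal(fi$count[match(names(expected), fi$label)],
                 as.integer(unlist(expected)))
  }
})

test_that("rule metrics match hand-enumerated values", {
  tr <- transactions_of(list(c("A", "B"), "A", "B", c("A", "B")))
  m <- rule_metrics(tr, "A", "B")
  expect_equal(m$support, 0.5)
  expect_equal(m$confidence, 2 / 3)
  expect_equal(m$lift, 8 / 9)
  expect_equal(m$co_count, 2L)

  # exact independence (the empty transaction is a case with another item)
  tr_ind <- transactions_of(list(c("A", "B"), "A", "B", "Z"))
  expect_equal(rule_metrics(tr_ind, "A", "B")$lift, 1)

  # co-occurrence in every transaction
  tr_all <- transactions_of(list(c("A", "B"), c("A", "B")))
  m_all <- rule_metrics(tr_all, "A", "B")
  expect_equal(m_all$confidence, 1)
  expect_equal(m_all$lift, 1)

  expect_error(rule_metrics(tr, "A", "A"), "disjoint")
  expect_error(rule_metrics(tr, "A", character()), "nonempty")
  expect_error(rule_metrics(tr, "A", "Q"), "absent")
})

test_that("disabled thresholds emit every co-occurring ordered pair", {
  tr <- transactions_of(list(c("A", "B"), c("B", "C")))
  r <- mine_rules(tr, 2, mining_thresholds(0, 0, 0, 1))
  expect_setequal(rule_key(r), c("A -> B", "B -> A", "B -> C", "C -> B"))

  one <- transactions_of(list(c("A", "B")))
  r1 <- brute_force_rules(one, 2, mining_thresholds(0, 0, 0, 1))
  expect_setequal(rule_key(r1), c("A -> B", "B -> A"))
  expect_true(all(r1$support == 1 & r1$confidence == 1 & r1$lift == 1))
})

test_that("miner and brute-force oracle agree on random datasets", {
  ths <- list(mining_thresholds(), mining_thresholds(0.05, 0.3, 1, 1),
              mining_thresholds(0.2, 0.6, 1.5, 2))
  for (seed in 1:40) {
    tr <- rand_transactions(seed, n_items = 5 + seed %% 8,
                            n_trans = 10 + (seed * 7) %% 50)
    th <- ths[[1 + seed %% length(ths)]]
    for (ord in c(2, 3)) {
      expect_same_rules(mine_rules(tr, ord, th),
                        brute_force_rules(tr, ord, th))
    }
  }
  expect_error(brute_force_rules(transactions_of(list(LETTERS[1:16]))),
               "guard")
})

test_that("support is anti-monotone and rule identities hold exactly", {
  for (seed in c(4, 18)) {
    tr <- rand_transactions(seed, n_items = 8, n_trans = 40)
    fi <- frequent_itemsets(tr, 0.05, max_size = 3)
    supp <- setNames(fi$support, fi$label)
    n <- attr(fi, "n_transactions")
    for (i in which(fi$size > 1)) {
      s <- fi$items[[i]]
      for (d in seq_along(s)) {
        sub <- paste(s[-d], collapse = ";")
        expect_gte(supp[[sub]], fi$support[i])
      }
    }
    r <- mine_rules(tr, 2, mining_thresholds(0.05, 0, 0, 1))
    expect_equal(r$co_count, as.integer(round(r$support * n)))
    # confidence * support(lhs) = support(lhs u rhs)
    supp1 <- setNames(fi$support[fi$size == 1], fi$label[fi$size == 1])
    expect_equal(r$confidence * unname(supp1[r$lhs_label]), r$support,
                 tolerance = 1e-12)
    # 1 -> 1 symmetry of support and lift
    fwd <- rule_key(r)
    rev <- paste(r$rhs, "->", r$lhs_label)
    present <- rev %in% fwd
    ridx <- match(rev[present], fwd)
    expect_equal(r$lift[present], r$lift[ridx])
    expect_equal(r$support[present], r$support[ridx])
  }
})

test_that("raising any threshold never adds a rule", {
  tr <- rand_transactions(5, n_items = 8, n_trans = 40)
  base <- mining_thresholds(0.05, 0.2, 0.8, 1)
  r0 <- mine_rules(tr, 2, base)
  tighter <- list(mining_thresholds(0.15, 0.2, 0.8, 1),
                  mining_thresholds(0.05, 0.5, 0.8, 1),
                  mining_thresholds(0.05, 0.2, 1.2, 1),
                  mining_thresholds(0.05, 0.2, 0.8, 5))
  for (th in tighter) {
    expect_true(all(rule_key(mine_rules(tr, 2, th)) %in% rule_key(r0)))
  }
})

test_that("planted associations are recovered and filtered RHS classes respected", {
  cases <- generate_cases(planted_config(n_cases = 2000, seed = 3))
  cc <- clean_cases(cases, ra_dictionary())
  r <- mine_rules(build_transactions(cc, "herbs"), 2)
  expect_true("Jinyinhua -> Wugong" %in% rule_key(r))
  got <- r[r$lhs_label == "Jinyinhua" & r$rhs == "Wugong", ]
  expect_lt(abs(got$lift - 1.64), 0.1)

  r3 <- mine_rules(build_transactions(cc, "both"), 3,
                   mining_thresholds(0.1, 0.5, 1), rhs_class = "symptom")
  expect_true(all(r3$rhs == "Polyarthralgia") || nrow(r3) == 0)
})
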