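#' Build transactions from clean cases
#'
#' Flattens each clean case into one transaction: the set of its canonical
#' items, each tagged as `herb` or `symptom`. Second-order herb-pair mining
#' uses `include = "herbs"`; third-order herb-symptom mining uses
#' `include = "both"`. Cases that yield an empty transaction under the flag
#' are dropped with a warning.
#'
#' @param cases Clean case tibble ([clean_cases()]).
#' @param include `"both"`, `"herbs"` or `"symptoms"`.
#' @return A long tibble with columns `case_id`, `item`, `class` — one row
#'   per item occurrence.
#' @export
build_transactions <- function(cases, include = c("both", "herbs", "symptoms")) {
  include <- match.arg(include)
  none <- rep(list(character()), nrow(cases))
  h <- if (include %in% c("both", "herbs")) cases$herbs else none
  s <- if (include %in% c("both", "symptoms")) cases$symptoms else none
  idx <- c(rep(seq_along(h), lengths(h)), rep(seq_along(s), lengths(s)))
  out <- tibble(
    case_id = cases$case_id[idx],
    item = c(unlist(h), unlist(s)),
    class = c(rep("herb", sum(lengths(h))),
              rep("symptom", sum(lengths(s))))
  )
  out <- out[order(idx, method = "radix"), ]
  dropped <- setdiff(cases$case_id, out$case_id)
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " case(s) dropped (empty under include='",
                include, "')"))
  }
  out
}

# long transaction tibble -> logical case x item matrix with a class map
transaction_matrix <- function(transactions) {
  if (nrow(transactions) == 0) abort("no transactions")
  cases <- unique(transactions$case_id)
  items <- sort(unique(transactions$item))
  mat <- matrix(FALSE, length(cases), length(items),
                dimnames = list(cases, items))
  mat[cbind(match(transactions$case_id, cases),
            match(transactions$item, items))] <- TRUE
  cls <- transactions[!duplicated(transactions$item), ]
  attr(mat, "item_class") <- setNames(cls$class, cls$item)
  mat
}

itemset_label <- function(items) paste(items, collapse = ";")

#' Mining thresholds
#'
#' The acceptance filter applied to candidate rules: minimum support and
#' confidence (proportions), minimum lift, and a minimum absolute
#' co-occurrence count. Defaults are the study's acceptance thresholds —
#' support 10%, confidence 50%, lift 1.2 — implemented inclusively
#' (`>=`), with rules co-occurring in fewer than one case eliminated.
#'
#' @param min_support,min_confidence Proportions in `[0, 1]`.
#' @param min_lift Nonnegative ratio (1 = independence).
#' @param min_count Minimum co-occurrence count (integer).
#' @return A `mining_thresholds` list.
#' @export
mining_thresholds <- function(min_support = 0.10, min_confidence = 0.50,
                              min_lift = 1.2, min_count = 1) {
  vals <- c(min_support, min_confidence, min_lift, min_count)
  if (any(vals < 0)) abort("thresholds must be nonnegative")
  if (min_support > 1 || min_confidence > 1) {
    abort("min_support and min_confidence are proportions in [0, 1]")
  }
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, min_count = as.integer(min_count)),
            class = "mining_thresholds")
}

#' Level-wise frequent itemset mining
#'
#' The classic Apriori search: size-k candidates are generated only by
#' joining frequent (k-1)-itemsets sharing a (k-2)-prefix and are pruned
#' when any (k-1)-subset is infrequent (anti-monotonicity of support), so
#' the returned sets are exactly the itemsets of size 1..`max_size` with
#' support at least `min_support` (and at least one occurrence).
#'
#' @param transactions Long transaction tibble ([build_transactions()]).
#' @param min_support Minimum support as a proportion.
#' @param max_size Largest itemset size to search.
#' @return A tibble with columns `items` (list of sorted character
#'   vectors), `label`, `size`, `count`, `support`, sorted by size, then
#'   support descending, then label.
#' @export
frequent_itemsets <- function(transactions, min_support = 0.10, max_size = 3) {
  mat <- transaction_matrix(transactions)
  n <- nrow(mat)
  if (min_support > 1) abort("min_support must be at most 1")

  res_items <- list(); res_count <- integer(); res_size <- integer()
  keep <- function(count) count >= 1 & count / n >= min_support

  counts1 <- colSums(mat)
  frequent <- as.list(colnames(mat)[keep(counts1)])
  counts_k <- as.integer(counts1[keep(counts1)])
  k <- 1
  while (length(frequent) > 0 && k <= max_size) {
    res_items <- c(res_items, frequent)
    res_count <- c(res_count, counts_k)
    res_size <- c(res_size, rep(k, length(frequent)))
    if (k == max_size) break
    cand <- apriori_candidates(frequent)
    if (length(cand) == 0) break
    counts <- vapply(cand, function(s) {
      sum(rowSums(mat[, s, drop = FALSE]) == length(s))
    }, numeric(1))
    sel <- keep(counts)
    frequent <- cand[sel]
    counts_k <- as.integer(counts[sel])
    k <- k + 1
  }

  out <- tibble(
    items = res_items,
    label = vapply(res_items, itemset_label, character(1)),
    size = res_size,
    count = res_count,
    support = res_count / n
  )
  out <- out[order(out$size, -out$support, out$label), ]
  attr(out, "n_transactions") <- n
  out
}

# join frequent k-itemsets sharing a (k-1)-prefix; prune by subset frequency
apriori_candidates <- function(frequent) {
  k <- length(frequent[[1]])
  labels <- vapply(frequent, itemset_label, character(1))
  frequent <- frequent[order(labels)]
  labels <- sort(labels)
  have <- new.env(parent = emptyenv())
  for (l in labels) assign(l, TRUE, envir = have)
  cand <- list()
  for (i in seq_along(frequent)) {
    for (j in seq_along(frequent)) {
      if (j <= i) next
      a <- frequent[[i]]; b <- frequent[[j]]
      if (k > 1 && !identical(a[-k], b[-k])) next
      s <- sort(union(a, b))
      if (length(s) != k + 1) next
      subsets_ok <- all(vapply(seq_along(s), function(d) {
        exists(itemset_label(s[-d]), envir = have, inherits = FALSE)
      }, logical(1)))
      if (subsets_ok) cand[[itemset_label(s)]] <- s
    }
  }
  unname(cand)
}

#' Support, confidence and lift of a single rule
#'
#' Direct computation from the transactions: support is the fraction of
#' transactions containing both sides, confidence divides by the fraction
#' containing the LHS, and lift divides confidence by the fraction
#' containing the RHS (1 = independence, above 1 = positive association).
#'
#' @param transactions Long transaction tibble.
#' @param lhs,rhs Disjoint nonempty character vectors of items.
#' @return A one-row tibble: `support`, `confidence`, `lift`, `co_count`.
#' @export
rule_metrics <- function(transactions, lhs, rhs) {
  lhs <- unique(as.character(lhs)); rhs <- unique(as.character(rhs))
  if (length(lhs) == 0 || length(rhs) == 0) abort("lhs and rhs must be nonempty")
  if (length(intersect(lhs, rhs)) > 0) abort("lhs and rhs must be disjoint")
  mat <- transaction_matrix(transactions)
  missing <- setdiff(c(lhs, rhs), colnames(mat))
  if (length(missing) > 0) {
    abort(paste0("item(s) absent from transactions: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(mat)
  has <- function(s) rowSums(mat[, s, drop = FALSE]) == length(s)
  n_lhs <- sum(has(lhs))
  if (n_lhs == 0) abort("undefined confidence: LHS never occurs")
  co <- sum(has(lhs) & has(rhs))
  support <- co / n
  confidence <- co / n_lhs
  tibble(support = support, confidence = confidence,
         lift = confidence / (sum(has(rhs)) / n), co_count = co)
}

#' Mine second- or third-order association rules
#'
#' Generates every rule with a single-item RHS and an LHS of one item
#' (`order = 2`) or two items (`order = 3`) from the frequent itemsets, and
#' keeps exactly those satisfying all thresholds: support >= `min_support`,
#' confidence >= `min_confidence`, lift >= `min_lift` and co-occurrence
#' count >= `min_count`. The search is complete — no qualifying rule is
#' omitted (property-tested against [brute_force_rules()]). Rules are
#' sorted by lift descending, then support descending, then
#' lexicographically.
#'
#' @param transactions Long transaction tibble.
#' @param order 2 (pair rules) or 3 (two-item LHS).
#' @param thresholds A [mining_thresholds()].
#' @param rhs_class Restrict the RHS item class: `"any"`, `"herb"` or
#'   `"symptom"`.
#' @return A `herb_rules` tibble: `lhs` (list), `lhs_label`, `rhs`,
#'   `support`, `confidence`, `lift`, `co_count`.
#' @export
mine_rules <- function(transactions, order = 2,
                       thresholds = mining_thresholds(),
                       rhs_class = c("any", "herb", "symptom")) {
  rhs_class <- match.arg(rhs_class)
  if (!order %in% c(2, 3)) abort("order must be 2 or 3")
  freq <- frequent_itemsets(transactions, thresholds$min_support,
                            max_size = order)
  n <- attr(freq, "n_transactions")
  cnt <- setNames(freq$count, freq$label)

  top <- freq$items[freq$size == order]
  rules <- list()
  for (s in top) {
    for (d in seq_along(s)) {
      rules[[length(rules) + 1]] <- list(lhs = s[-d], rhs = s[d], set = s)
    }
  }
  if (length(rules) == 0) return(finalize_rules(empty_rules(), n, thresholds, order))

  lhs_lab <- vapply(rules, function(r) itemset_label(r$lhs), character(1))
  set_lab <- vapply(rules, function(r) itemset_label(r$set), character(1))
  rhs <- vapply(rules, function(r) r$rhs, character(1))
  # metrics from integer counts, in the same expressions as the exhaustive
  # oracle, so boundary thresholds compare bit-identically on both routes
  out <- tibble(
    lhs = lapply(rules, function(r) r$lhs),
    lhs_label = lhs_lab,
    rhs = rhs,
    support = unname(cnt[set_lab]) / n,
    confidence = unname(cnt[set_lab] / cnt[lhs_lab]),
    lift = NA_real_,
    co_count = as.integer(unname(cnt[set_lab]))
  )
  out$lift <- out$confidence / (unname(cnt[rhs]) / n)
  out <- filter_rules(out, transactions, thresholds, rhs_class)
  finalize_rules(out, n, thresholds, order)
}

filter_rules <- function(out, transactions, thresholds, rhs_class) {
  if (rhs_class != "any") {
    cls <- transactions[!duplicated(transactions$item), ]
    item_class <- setNames(cls$class, cls$item)
    out <- out[item_class[out$rhs] == rhs_class, ]
  }
  out[out$support >= thresholds$min_support &
        out$confidence >= thresholds$min_confidence &
        out$lift >= thresholds$min_lift &
        out$co_count >= thresholds$min_count, ]
}

empty_rules <- function() {
  tibble(lhs = list(), lhs_label = character(), rhs = character(),
         support = double(), confidence = double(), lift = double(),
         co_count = integer())
}

finalize_rules <- function(out, n, thresholds, rule_order) {
  out <- out[order(-out$lift, -out$support, out$lhs_label, out$rhs), ]
  attr(out, "n_transactions") <- n
  attr(out, "thresholds") <- thresholds
  attr(out, "order") <- rule_order
  class(out) <- c("herb_rules", class(out))
  out
}

#' Exhaustive rule enumeration (oracle)
#'
#' Enumerates every (LHS, RHS) split of the required order directly —
#' no level-wise search, no pruning — and applies the same threshold filter
#' and ordering as [mine_rules()]. Used as an independent correctness
#' oracle; guarded to at most 15 distinct items.
#'
#' @inheritParams mine_rules
#' @return A `herb_rules` tibble identical in form to [mine_rules()].
#' @export
brute_force_rules <- function(transactions, order = 2,
                              thresholds = mining_thresholds(),
                              rhs_class = c("any", "herb", "symptom")) {
  rhs_class <- match.arg(rhs_class)
  if (!order %in% c(2, 3)) abort("order must be 2 or 3")
  mat <- transaction_matrix(transactions)
  items <- colnames(mat)
  if (length(items) > 15) abort("brute force guard: more than 15 distinct items")
  n <- nrow(mat)
  has <- function(s) rowSums(mat[, s, drop = FALSE]) == length(s)

  sets <- utils::combn(items, order, simplify = FALSE)
  rows <- list()
  for (s in sets) {
    s <- sort(s)
    co <- sum(has(s))
    for (d in seq_along(s)) {
      lhs <- s[-d]; rhs <- s[d]
      n_lhs <- sum(has(lhs))
      if (n_lhs == 0) next
      conf <- co / n_lhs
      lab <- itemset_label(lhs)
      rows[[length(rows) + 1]] <- tibble(
        lhs = list(lhs), lhs_label = lab, rhs = rhs,
        support = co / n, confidence = conf,
        lift = conf / (sum(has(rhs)) / n), co_count = as.integer(co)
      )
    }
  }
  out <- if (length(rows) == 0) empty_rules() else bind_rows(rows)
  out <- filter_rules(out, transactions, thresholds, rhs_class)
  finalize_rules(out, n, thresholds, order)
}
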