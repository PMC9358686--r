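#' Synthetic prescription dataset configuration
#'
#' The generator models co-prescription structure with a latent-class
#' mixture: each case draws a latent class by weight, then every vocabulary
#' item (herb or symptom) independently with its class-specific Bernoulli
#' probability. Within-class independence with between-class mixing yields
#' closed-form support/confidence/lift for any rule (see
#' [expected_rule_metrics()]), so planted associations can be recovered and
#' checked exactly. Clinical eligibility fields are drawn to pass the
#' screen, except for a configurable fraction of cases given one randomly
#' chosen failing criterion.
#'
#' @param n_cases Number of cases to generate.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate byte-identical datasets.
#' @param classes List of latent classes, each a `list(weight =, probs =)`
#'   where `probs` is a named numeric vector of Bernoulli probabilities over
#'   vocabulary items (items omitted from a class have probability 0).
#'   Weights must sum to 1.
#' @param vocab Tibble with columns `item` and `class` (`"herb"` or
#'   `"symptom"`) declaring the item vocabulary.
#' @param ineligible_fraction Probability that a case is made ineligible by
#'   planting one failing screening criterion.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_cases, seed, classes, vocab,
                         ineligible_fraction = 0) {
  if (n_cases < 0) abort("n_cases must be nonnegative")
  if (!all(c("item", "class") %in% names(vocab)) || nrow(vocab) == 0) {
    abort("vocab must be a nonempty tibble with columns item, class")
  }
  if (anyDuplicated(vocab$item)) abort("vocab items must be unique")
  if (!all(vocab$class %in% c("herb", "symptom"))) {
    abort("vocab class must be 'herb' or 'symptom'")
  }
  w <- vapply(classes, function(cl) cl$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) abort("class weights must sum to 1")
  for (cl in classes) {
    p <- cl$probs
    if (is.null(names(p)) || !all(names(p) %in% vocab$item)) {
      abort("class probs must be named with vocabulary items")
    }
    if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  }
  if (ineligible_fraction < 0 || ineligible_fraction > 1) {
    abort("ineligible_fraction must lie in [0, 1]")
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         classes = classes, vocab = as_tibble(vocab),
         ineligible_fraction = ineligible_fraction),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_cases, "cases,", length(x$classes),
      "latent class(es),", nrow(x$vocab), "items, seed", x$seed, "\n")
  invisible(x)
}

# class-probability matrix K x M over the full vocabulary
class_prob_matrix <- function(config) {
  items <- config$vocab$item
  P <- matrix(0, length(config$classes), length(items),
              dimnames = list(NULL, items))
  for (k in seq_along(config$classes)) {
    p <- config$classes[[k]]$probs
    P[k, names(p)] <- unname(p)
  }
  P
}

#' Default study-scale configuration
#'
#' A single-class configuration emulating the analyzed cohort: 311 eligible
#' cases over the 16 high-frequency herbs and 18 high-frequency symptoms of
#' the packaged monograph and symptom tables, each item at its observed
#' marginal rate (count/311). With a single class all items are independent,
#' so this config is also a null model for rule mining.
#'
#' @param n_cases Number of cases (default 311, the cohort size).
#' @param seed Integer seed.
#' @param ineligible_fraction See [synth_config()]; 0 by default so all
#'   generated cases pass the screen.
#' @return A [synth_config()].
#' @export
ra_config <- function(n_cases = 311, seed = 1, ineligible_fraction = 0) {
  mono <- ra_monographs()
  sym <- readr::read_csv(
    system.file("extdata", "ra_symptom_counts.csv", package = "herbminer",
                mustWork = TRUE),
    col_types = readr::cols(item = readr::col_character(),
                            count = readr::col_integer()))
  vocab <- bind_rows(
    tibble(item = mono$name, class = "herb"),
    tibble(item = sym$item, class = "symptom")
  )
  probs <- setNames(c(mono$count, sym$count) / 311, vocab$item)
  synth_config(n_cases, seed, list(list(weight = 1, probs = probs)),
               vocab, ineligible_fraction)
}

#' Two-class planted-association configuration
#'
#' Two equal-weight latent classes in which the herbs `a` and `b` are
#' prescribed with probability `p_high` in one class and `p_low` in the
#' other. With the defaults (0.9/0.1) the rule `a -> b` has closed-form
#' support 0.41, confidence 0.82 and lift 1.64, comfortably beyond the
#' default mining thresholds. An always-present base herb and base symptom
#' keep every case nonempty (their rules have lift 1 and are filtered), so
#' no case is redrawn and the closed-form metrics are exact.
#'
#' @param n_cases,seed See [synth_config()].
#' @param a,b Names of the planted herb pair.
#' @param p_high,p_low Within-class prescription probabilities.
#' @return A [synth_config()].
#' @export
planted_config <- function(n_cases = 2000, seed = 1,
                           a = "Jinyinhua", b = "Wugong",
                           p_high = 0.9, p_low = 0.1) {
  vocab <- tibble(
    item = c(a, b, "Gancao", "Polyarthralgia"),
    class = c("herb", "herb", "herb", "symptom")
  )
  probs <- function(p) setNames(c(p, p, 1, 1), vocab$item)
  synth_config(n_cases, seed,
               list(list(weight = 0.5, probs = probs(p_high)),
                    list(weight = 0.5, probs = probs(p_low))),
               vocab)
}

#' Matched-marginal independence configuration
#'
#' A single-class (hence fully independent) configuration over herbs with
#' marginal probabilities at most 0.5, used as a null control: at large n no
#' herb pair should pass the default support/confidence/lift filter. The
#' same always-present base items as [planted_config()] keep cases nonempty.
#'
#' @param n_cases,seed See [synth_config()].
#' @param probs Named vector of herb marginals (all <= 0.5).
#' @return A [synth_config()].
#' @export
independence_config <- function(n_cases = 20000, seed = 1,
                                probs = c(Jinyinhua = 0.5, Yiyiren = 0.45,
                                          Wugong = 0.4, Qingfengteng = 0.35,
                                          Chaobaishao = 0.3, Tusizi = 0.25,
                                          Baizhu = 0.2, Fuzi = 0.15)) {
  if (any(probs > 0.5)) abort("null-control marginals must be <= 0.5")
  vocab <- tibble(
    item = c(names(probs), "Gancao", "Polyarthralgia"),
    class = c(rep("herb", length(probs)), "herb", "symptom")
  )
  p <- setNames(c(unname(probs), 1, 1), vocab$item)
  synth_config(n_cases, seed, list(list(weight = 1, probs = p)), vocab)
}

#' Generate synthetic raw cases
#'
#' Draws `n_cases` raw case records from a [synth_config()]: a latent class
#' per case, items by class-specific Bernoulli draws, and clinical fields
#' eligible under [screen_cases()] except for a `ineligible_fraction` of
#' cases given one randomly chosen failing criterion. Cases drawing zero
#' herbs or zero symptoms are redrawn (at most 100 rounds). All randomness
#' comes from one stream seeded by `config$seed`; the global RNG state is
#' left untouched.
#'
#' @param config A [synth_config()].
#' @return A raw case tibble as read by [read_cases()].
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cases
  if (n == 0) return(empty_case_table())
  withr::with_seed(config$seed, generate_cases_impl(config, n))
}

generate_cases_impl <- function(config, n) {
  P <- class_prob_matrix(config)
  items <- colnames(P)
  is_herb <- config$vocab$class == "herb"
  w <- vapply(config$classes, function(cl) cl$weight, numeric(1))

  draw_items <- function(m) {
    cls <- sample.int(length(w), m, replace = TRUE, prob = w)
    (matrix(runif(m * length(items)), m) < P[cls, , drop = FALSE])
  }
  present <- draw_items(n)
  bad <- which(rowSums(present[, is_herb, drop = FALSE]) == 0 |
                 rowSums(present[, !is_herb, drop = FALSE]) == 0)
  attempts <- 0
  while (length(bad) > 0) {
    attempts <- attempts + 1
    if (attempts > 100) {
      abort("failed to draw a nonempty case within 100 attempts")
    }
    present[bad, ] <- draw_items(length(bad))
    bad <- bad[rowSums(present[bad, is_herb, drop = FALSE]) == 0 |
                 rowSums(present[bad, !is_herb, drop = FALSE]) == 0]
  }

  cases <- tibble(
    case_id = sprintf("case%05d", seq_len(n)),
    age = sample(18:70, n, replace = TRUE),
    duration = sample(6:240, n, replace = TRUE),
    das28_before = runif(n, 3.3, 5.0),
    das28_after = runif(n, 0.8, 2.5),
    haq_before = runif(n, 1.0, 2.5),
    haq_after = runif(n, 0.0, 0.45),
    vas_before = runif(n, 4, 9),
    vas_after = NA_real_,
    alt_uln_ratio = runif(n, 0.2, 1.8),
    ast_uln_ratio = runif(n, 0.2, 1.8),
    wbc = runif(n, 4.0, 9.5),
    consent = TRUE,
    tcm_treated = TRUE
  )
  cases$vas_after <- pmax(0, cases$vas_before - runif(n, 1, 3))

  flag <- runif(n) < config$ineligible_fraction
  if (any(flag)) {
    ids <- names(screen_criteria)
    pick <- sample(ids, sum(flag), replace = TRUE)
    rows <- which(flag)
    for (j in seq_along(rows)) {
      cases <- plant_failure(cases, rows[j], pick[j])
    }
  }

  cases$symptoms <- lapply(seq_len(n), function(i) items[present[i, ] & !is_herb])
  cases$herbs <- lapply(seq_len(n), function(i) items[present[i, ] & is_herb])
  cases
}

plant_failure <- function(cases, i, criterion) {
  switch(criterion,
    age = { cases$age[i] <- sample(c(10:17, 71:85), 1) },
    duration = { cases$duration[i] <- sample(0:5, 1) },
    das28_before = { cases$das28_before[i] <- runif(1, 2.0, 3.2) },
    das28_after = { cases$das28_after[i] <- runif(1, 2.6, 4.0) },
    haq_before = { cases$haq_before[i] <- runif(1, 0, 0.99) },
    haq_after = { cases$haq_after[i] <- runif(1, 0.5, 1.5) },
    vas = { cases$vas_after[i] <- cases$vas_before[i] + runif(1, 0, 2) },
    alt_uln_ratio = { cases$alt_uln_ratio[i] <- runif(1, 2, 4) },
    ast_uln_ratio = { cases$ast_uln_ratio[i] <- runif(1, 2, 4) },
    wbc = { cases$wbc[i] <- runif(1, 2, 3.5) },
    consent = { cases$consent[i] <- FALSE },
    tcm_treated = { cases$tcm_treated[i] <- FALSE }
  )
  cases
}

empty_case_table <- function() {
  tibble(
    case_id = character(), age = integer(), duration = integer(),
    das28_before = double(), das28_after = double(),
    haq_before = double(), haq_after = double(),
    vas_before = double(), vas_after = double(),
    alt_uln_ratio = double(), ast_uln_ratio = double(), wbc = double(),
    consent = logical(), tcm_treated = logical(),
    symptoms = list(), herbs = list()
  )
}

#' Closed-form rule metrics under a latent-class configuration
#'
#' Under within-class independence with between-class mixing, the
#' probability that an itemset S is present is `sum_c w_c prod_{i in S}
#' p_{c,i}`. Support of a rule is that probability for the union of sides;
#' confidence divides by the LHS probability; lift divides confidence by the
#' RHS probability. The empty itemset has probability 1 (empty product), so
#' an empty rule has support, confidence and lift all 1.
#'
#' @param config A [synth_config()].
#' @param lhs,rhs Character vectors of vocabulary items (either may be
#'   empty).
#' @return A one-row tibble with columns `support`, `confidence`, `lift`.
#' @examples
#' cfg <- planted_config()
#' expected_rule_metrics(cfg, "Jinyinhua", "Wugong")
#' @export
expected_rule_metrics <- function(config, lhs, rhs) {
  stopifnot(inherits(config, "synth_config"))
  lhs <- unique(as.character(lhs)); rhs <- unique(as.character(rhs))
  unknown <- setdiff(c(lhs, rhs), config$vocab$item)
  if (length(unknown) > 0) {
    abort(paste0("unknown item(s): ", paste(unknown, collapse = ", ")))
  }
  P <- class_prob_matrix(config)
  w <- vapply(config$classes, function(cl) cl$weight, numeric(1))
  pset <- function(s) {
    if (length(s) == 0) return(1)
    sum(w * apply(P[, s, drop = FALSE], 1, prod))
  }
  support <- pset(union(lhs, rhs))
  confidence <- support / pset(lhs)
  tibble(support = support, confidence = confidence,
         lift = confidence / pset(rhs))
}
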