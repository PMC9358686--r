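#' Case records
#'
#' A raw case table holds one patient visit per row: an identifier, the
#' clinical scores used for eligibility screening (DAS28, HAQ-DI and VAS
#' before/after treatment, liver-enzyme ratios as multiples of the upper
#' limit of normal, white blood cell count), consent and TCM-treatment flags,
#' and two list-columns `symptoms` and `herbs` holding the raw term lists as
#' recorded (duplicates and regional name variants allowed).
#'
#' @name case-records
#' @keywords internal
NULL

case_fields <- c(
  "case_id", "age", "duration",
  "das28_before", "das28_after", "haq_before", "haq_after",
  "vas_before", "vas_after", "alt_uln_ratio", "ast_uln_ratio", "wbc",
  "consent", "tcm_treated"
)

#' Read and write case records
#'
#' Cases are exchanged either as CSV (one row per case; the `symptoms` and
#' `herbs` lists are `;`-separated within a single field) or as JSON lines
#' (one object per line with the lists as arrays). Files are UTF-8.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`; the default guesses from the file
#'   extension.
#' @return `read_cases()` returns a tibble of raw cases with list-columns
#'   `symptoms` and `herbs`.
#' @export
read_cases <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      case_id = readr::col_character(),
      age = readr::col_integer(), duration = readr::col_integer(),
      consent = readr::col_logical(), tcm_treated = readr::col_logical(),
      symptoms = readr::col_character(), herbs = readr::col_character(),
      .default = readr::col_double()
    ))
    df$symptoms <- split_list_field(df$symptoms)
    df$herbs <- split_list_field(df$herbs)
    as_tibble(df)
  } else {
    rows <- lapply(readLines(path, encoding = "UTF-8", warn = FALSE), function(l) {
      x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      x$symptoms <- list(as.character(unlist(x$symptoms)))
      x$herbs <- list(as.character(unlist(x$herbs)))
      as_tibble(x[c(case_fields, "symptoms", "herbs")])
    })
    bind_rows(rows)
  }
}

split_list_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' @rdname read_cases
#' @param cases A case tibble (raw or cleaned) with list-columns `symptoms`
#'   and `herbs`.
#' @return `write_cases()` returns `path`, invisibly.
#' @export
write_cases <- function(cases, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    flat <- cases
    flat$symptoms <- map_chr(cases$symptoms, paste, collapse = ";")
    flat$herbs <- map_chr(cases$herbs, paste, collapse = ";")
    readr::write_csv(flat, path)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(cases))) {
      row <- as.list(cases[i, setdiff(names(cases), c("symptoms", "herbs"))])
      row <- lapply(row, function(v) if (is.list(v)) v[[1]] else v)
      row$symptoms <- cases$symptoms[[i]]
      row$herbs <- cases$herbs[[i]]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Standardize raw symptom and herb terms
#'
#' Maps raw terms onto the canonical vocabulary of a [term_dictionary()].
#' Unmapped terms pass through unchanged (the dictionary cannot be
#' exhaustive) and are reported once per call via a warning when
#' `warn_unmapped = TRUE`. Standardization is idempotent: canonical terms
#' map to themselves.
#'
#' @param terms Character vector of raw symptom terms.
#' @param dict A [term_dictionary()].
#' @param warn_unmapped Warn about terms absent from the dictionary?
#' @return Character vector of canonical terms, same length as the input.
#' @examples
#' d <- ra_dictionary()
#' standardize_symptom(c("Wrist pain", "Burnout", "Fatigue"), d)
#' standardize_herb(c("Han Fangji", "Chuanniuxi"), d)
#' @export
standardize_symptom <- function(terms, dict, warn_unmapped = FALSE) {
  standardize_terms(terms, dict$symptom_map, "symptom", warn_unmapped)
}

#' @rdname standardize_symptom
#' @param names Character vector of raw herb names.
#' @export
standardize_herb <- function(names, dict, warn_unmapped = FALSE) {
  standardize_terms(names, dict$herb_map, "herb", warn_unmapped)
}

standardize_terms <- function(x, map, what, warn_unmapped) {
  x <- as.character(x)
  hit <- x %in% names(map)
  if (warn_unmapped && any(!hit)) {
    warn(paste0("unmapped ", what, " term(s) passed through: ",
                paste(unique(x[!hit]), collapse = ", ")))
  }
  out <- x
  out[hit] <- unname(map[x[hit]])
  out
}

#' Collapse multi-region pain into a single multi-joint term
#'
#' If the canonical symptom set names pain in two or more distinct body
#' regions (per the dictionary's region labels), the regional pain terms are
#' replaced by the single canonical term `"Polyarthralgia"`; with fewer than
#' two regions the set is returned unchanged. The operation is idempotent.
#'
#' @param symptoms Character vector of canonical symptom terms (a set).
#' @param dict A [term_dictionary()].
#' @return Character vector of canonical symptom terms.
#' @examples
#' d <- ra_dictionary()
#' apply_multi_joint_rule(
#'   c("Upper limb joint pain", "Lumbosacral pain", "Poor sleep"), d)
#' @export
apply_multi_joint_rule <- function(symptoms, dict) {
  symptoms <- unique(as.character(symptoms))
  regional <- symptoms[symptoms %in% names(dict$pain_regions)]
  if (length(unique(dict$pain_regions[regional])) >= 2) {
    symptoms <- c(setdiff(symptoms, regional), "Polyarthralgia")
    symptoms <- unique(symptoms)
  }
  symptoms
}

# criterion predicates; each must hold for eligibility
screen_criteria <- list(
  age = function(d) d$age >= 18 & d$age <= 70,
  duration = function(d) d$duration >= 6,
  das28_before = function(d) d$das28_before > 3.2 & d$das28_before < 5.1,
  das28_after = function(d) d$das28_after < 2.6,
  haq_before = function(d) d$haq_before >= 1,
  haq_after = function(d) d$haq_after < 0.5,
  vas = function(d) d$vas_after < d$vas_before,
  alt_uln_ratio = function(d) d$alt_uln_ratio < 2,
  ast_uln_ratio = function(d) d$ast_uln_ratio < 2,
  wbc = function(d) d$wbc > 3.5,
  consent = function(d) d$consent,
  tcm_treated = function(d) d$tcm_treated
)

#' Eligibility screening of raw cases
#'
#' Applies the study's inclusion/exclusion screen to each case. A case is
#' eligible iff all of the following hold: age 18-70; disease duration of at
#' least 6 months; DAS28 strictly between 3.2 and 5.1 before treatment and
#' below 2.6 after; HAQ-DI at least 1 before and below 0.5 after; VAS
#' decreased after treatment; ALT and AST each below 2 times the upper limit
#' of normal; white blood cell count above 3.5 (x10^9/L); informed consent;
#' and TCM treatment received. Bounds are strict or inclusive exactly as
#' stated. A case with any required field missing fails with the single
#' criterion id `"incomplete_record"`.
#'
#' @param cases Raw case tibble (see [read_cases()]).
#' @return A tibble with columns `case_id`, `eligible` (logical) and
#'   `failed_criteria` (list of criterion ids; empty iff eligible).
#' @export
screen_cases <- function(cases) {
  check_case_columns(cases)
  n <- nrow(cases)
  complete <- rep(TRUE, n)
  for (f in case_fields) complete <- complete & !is.na(cases[[f]])
  fails <- matrix(FALSE, n, length(screen_criteria),
                  dimnames = list(NULL, names(screen_criteria)))
  for (id in names(screen_criteria)) {
    ok <- screen_criteria[[id]](cases)
    fails[, id] <- !is.na(ok) & !ok
  }
  failed <- lapply(seq_len(n), function(i) {
    if (!complete[i]) "incomplete_record" else colnames(fails)[fails[i, ]]
  })
  tibble(
    case_id = cases$case_id,
    eligible = lengths(failed) == 0,
    failed_criteria = failed
  )
}

check_case_columns <- function(cases) {
  missing <- setdiff(case_fields, names(cases))
  if (length(missing) > 0) {
    abort(paste0("case table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(cases)
}

#' Build clean transaction-ready cases
#'
#' Standardizes each case's raw symptom and herb lists, deduplicates them
#' into sets, and applies the multi-joint pain rule. The result is the
#' "transaction" unit consumed by the frequency, rule-mining and clustering
#' analyses. The output is invariant to the order and duplication of the raw
#' lists.
#'
#' @param cases Raw case tibble; normally the eligible subset after
#'   [screen_cases()].
#' @param dict A [term_dictionary()].
#' @param warn_unmapped Warn about unmapped raw terms?
#' @return A tibble with columns `case_id`, `symptoms`, `herbs`; the latter
#'   two are list-columns of sorted canonical sets.
#' @examples
#' d <- ra_dictionary()
#' raw <- tibble::tibble(
#'   case_id = "c1",
#'   symptoms = list(c("Wrist pain", "Knee joint pain", "Burnout", "Burnout")),
#'   herbs = list(c("Han Fangji", "Fangji")))
#' clean_cases(raw, d)
#' @export
clean_cases <- function(cases, dict, warn_unmapped = FALSE) {
  if (nrow(cases) == 0) abort("no cases to clean")
  symptoms <- lapply(cases$symptoms, function(s) {
    s <- unique(standardize_symptom(s, dict, warn_unmapped))
    sort(apply_multi_joint_rule(s, dict))
  })
  herbs <- lapply(cases$herbs, function(h) {
    sort(unique(standardize_herb(h, dict, warn_unmapped)))
  })
  empty <- lengths(symptoms) == 0 | lengths(herbs) == 0
  if (any(empty)) {
    abort(paste0("degenerate_case: empty symptom or herb set after cleaning: ",
                 paste(cases$case_id[empty], collapse = ", ")),
          class = "herbminer_degenerate_case")
  }
  tibble(case_id = cases$case_id, symptoms = symptoms, herbs = herbs)
}
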