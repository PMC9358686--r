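#' Terminology dictionaries for symptoms and herbs
#'
#' A term dictionary maps raw clinical terms to a canonical vocabulary. It
#' carries four components: a symptom map, a herb map, a region label for
#' each canonical regional-pain term (used by the multi-joint rule), and a
#' pain lexicon — the set of canonical symptoms counted as "pain" in the
#' pain/other proportion analysis.
#'
#' Both maps are functions: every raw term has exactly one canonical image,
#' and every canonical term maps to itself, so standardization is idempotent.
#'
#' @param symptom_map,herb_map Named character vectors, `raw -> canonical`.
#' @param pain_regions Named character vector mapping canonical regional-pain
#'   terms to a region label (`"upper_limb"`, `"lower_limb"`,
#'   `"lumbosacral"`).
#' @param pain_lexicon Character vector of canonical terms counted as pain
#'   symptoms. Must contain every name in `pain_regions`.
#'
#' @return An object of class `term_dictionary`.
#' @seealso [read_term_dictionary()], [ra_dictionary()]
#' @export
term_dictionary <- function(symptom_map, herb_map, pain_regions = character(),
                            pain_lexicon = character()) {
  symptom_map <- close_map(symptom_map, "symptom_map")
  herb_map <- close_map(herb_map, "herb_map")
  pain_regions <- as_named_chr(pain_regions, "pain_regions")
  pain_lexicon <- unique(as.character(pain_lexicon))
  missing_pain <- setdiff(names(pain_regions), pain_lexicon)
  if (length(missing_pain) > 0) {
    abort(paste0("pain_regions terms not in pain_lexicon: ",
                 paste(missing_pain, collapse = ", ")))
  }
  structure(
    list(symptom_map = symptom_map, herb_map = herb_map,
         pain_regions = pain_regions, pain_lexicon = pain_lexicon),
    class = "term_dictionary"
  )
}

# add identity entries for canonical images and check functionality
close_map <- function(map, what) {
  map <- as_named_chr(map, what)
  if (anyDuplicated(names(map))) {
    dup <- unique(names(map)[duplicated(names(map))])
    bad <- dup[vapply(dup, function(r) length(unique(map[names(map) == r])) > 1,
                      logical(1))]
    if (length(bad) > 0) {
      abort(paste0(what, ": raw term(s) with more than one canonical image: ",
                   paste(bad, collapse = ", ")))
    }
    map <- map[!duplicated(names(map))]
  }
  canon <- setdiff(unname(map), names(map))
  c(map, setNames(canon, canon))
}

as_named_chr <- function(x, what) {
  x <- unlist(x)
  if (length(x) == 0) return(setNames(character(), character()))
  if (is.null(names(x)) || any(names(x) == "")) {
    abort(paste0(what, " must be a fully named character vector"))
  }
  setNames(as.character(x), names(x))
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>\n")
  cat("  symptom terms:", length(x$symptom_map),
      "(", length(unique(x$symptom_map)), "canonical )\n")
  cat("  herb names:   ", length(x$herb_map),
      "(", length(unique(x$herb_map)), "canonical )\n")
  cat("  pain lexicon: ", paste(x$pain_lexicon, collapse = ", "), "\n")
  invisible(x)
}

#' Read a term dictionary from CSV
#'
#' The CSV has columns `raw`, `canonical`, `class` (`symptom` or `herb`),
#' and optional `region` and `is_pain` columns which are read off the rows
#' whose `raw` term is canonical (maps to itself).
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A [term_dictionary()].
#' @export
read_term_dictionary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    raw = readr::col_character(), canonical = readr::col_character(),
    class = readr::col_character(), region = readr::col_character(),
    is_pain = readr::col_logical()
  ))
  if (!all(df$class %in% c("symptom", "herb"))) {
    abort("dictionary class column must be 'symptom' or 'herb'")
  }
  sym <- df[df$class == "symptom", ]
  hrb <- df[df$class == "herb", ]
  regions <- sym[!is.na(sym$region), ]
  pain <- sym[!is.na(sym$is_pain) & sym$is_pain, ]
  term_dictionary(
    symptom_map = setNames(sym$canonical, sym$raw),
    herb_map = setNames(hrb$canonical, hrb$raw),
    pain_regions = setNames(regions$region, regions$canonical),
    pain_lexicon = unique(pain$canonical)
  )
}

#' Packaged rheumatoid-arthritis prescription dictionary
#'
#' The dictionary used throughout the package examples: pinyin herb names
#' standardized to their pharmacopeia form (regional name variants collapsed;
#' deliberately distinct drugs such as "Chuanniuxi"/"Niuxigen", and distinct
#' plant parts such as "Jinyinhua"/"Rendongteng", left unmerged), and English
#' symptom phrases with regional pains mapped to three body-region terms plus
#' the "Polyarthralgia" multi-joint term.
#'
#' @return A [term_dictionary()].
#' @export
ra_dictionary <- function() {
  read_term_dictionary(
    system.file("extdata", "ra_term_dictionary.csv", package = "herbminer",
                mustWork = TRUE)
  )
}
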