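#' Read a herb monograph table
#'
#' A monograph annotates each canonical herb with its thermal property, its
#' flavors, its meridian tropism, and one of the eight efficacy categories
#' used to classify high-frequency herbs. `flavors` and `meridians` are
#' `;`-separated within their CSV fields.
#'
#' @param path Path to a CSV with columns `name`, `property`, `flavors`,
#'   `meridians`, `category` (extra columns such as printed counts are kept).
#' @return A tibble with list-columns `flavors` and `meridians`.
#' @export
read_monographs <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), property = readr::col_character(),
    flavors = readr::col_character(), meridians = readr::col_character(),
    category = readr::col_character(), .default = readr::col_double()
  ))
  df$flavors <- split_list_field(df$flavors)
  df$meridians <- split_list_field(df$meridians)
  bad <- lengths(df$flavors) == 0 | lengths(df$meridians) == 0
  if (any(bad)) {
    abort(paste0("monograph(s) without flavor or meridian: ",
                 paste(df$name[bad], collapse = ", ")))
  }
  as_tibble(df)
}

#' Packaged high-frequency herb monographs
#'
#' The 16 herbs prescribed in more than 10% of the analyzed cohort, with
#' their pharmacopeia property/flavor/meridian annotation, efficacy
#' category, and observed prescription counts.
#'
#' @return A monograph tibble (see [read_monographs()]) with `count` and
#'   `rate_pct` columns.
#' @export
ra_monographs <- function() {
  read_monographs(
    system.file("extdata", "ra_monographs.csv", package = "herbminer",
                mustWork = TRUE)
  )
}

#' Item frequency table
#'
#' Counts, for every herb or symptom, the number of cases whose canonical
#' set contains it, and the corresponding rate (count / number of cases).
#' Rows are sorted by count descending with alphabetical tie-break.
#'
#' @param cases Clean case tibble (see [clean_cases()]).
#' @param domain `"herbs"` or `"symptoms"`.
#' @return A tibble with columns `item`, `count`, `rate`.
#' @export
frequency_table <- function(cases, domain = c("herbs", "symptoms")) {
  domain <- match.arg(domain)
  if (nrow(cases) == 0) abort("frequency_table needs at least one case")
  n <- nrow(cases)
  counts <- table(unlist(lapply(cases[[domain]], unique)))
  out <- tibble(item = names(counts), count = as.integer(counts))
  out$rate <- out$count / n
  out <- out[order(-out$count, out$item), ]
  attr(out, "n_cases") <- n
  out
}

#' High-frequency enrollment filter
#'
#' Keeps the items whose rate is at least `min_rate` (default 10%, the
#' study's enrollment threshold; implemented inclusively to avoid
#' floating-point equality artifacts at the boundary). Row order is
#' preserved.
#'
#' @param table A frequency tibble from [frequency_table()].
#' @param min_rate Minimum rate as a proportion.
#' @return The filtered frequency tibble (possibly empty).
#' @export
filter_high_frequency <- function(table, min_rate = 0.10) {
  out <- table[table$rate >= min_rate, ]
  attr(out, "n_cases") <- attr(table, "n_cases")
  out
}

#' Pain versus other symptom occurrence shares
#'
#' Classifies symptom occurrences (each case-symptom pair counts once) into
#' the dictionary's pain lexicon versus all other symptoms, and breaks the
#' pain share down by pain location. All fractions are of total symptom
#' occurrences, so the location rows sum to the pain share and the table
#' sums to 1.
#'
#' @param cases Clean case tibble.
#' @param dict A [term_dictionary()] with a nonempty pain lexicon.
#' @return A tibble with columns `term`, `kind` (`"pain"`/`"other"`),
#'   `occurrences`, `fraction`: one row per observed pain term plus one
#'   `"Other symptoms"` row.
#' @export
pain_share <- function(cases, dict) {
  if (length(dict$pain_lexicon) == 0) abort("pain lexicon is empty")
  occ <- unlist(lapply(cases$symptoms, unique))
  if (length(occ) == 0) abort("no symptom occurrences")
  total <- length(occ)
  pain_occ <- occ[occ %in% dict$pain_lexicon]
  by_loc <- table(pain_occ)
  out <- tibble(
    term = c(names(by_loc), "Other symptoms"),
    kind = c(rep("pain", length(by_loc)), "other"),
    occurrences = c(as.integer(by_loc), total - length(pain_occ))
  )
  out$fraction <- out$occurrences / total
  out[order(out$kind == "other", -out$occurrences, out$term), ]
}

#' Efficacy-category shares of high-frequency herbs
#'
#' Computes the percentage of each efficacy category among the table's
#' herbs. With `weighting = "frequency"` (default) each herb contributes
#' its prescription count, so the share is the category's fraction of all
#' high-frequency prescriptions; with `weighting = "count"` each herb
#' contributes 1.
#'
#' @param monographs Monograph tibble covering every herb in `table`.
#' @param table Frequency tibble of herbs ([frequency_table()] output).
#' @param weighting `"frequency"` or `"count"`.
#' @return A tibble with columns `category`, `n_herbs`, `weight`,
#'   `share_pct`, sorted by share descending; shares sum to 100.
#' @export
category_shares <- function(monographs, table,
                            weighting = c("frequency", "count")) {
  weighting <- match.arg(weighting)
  missing <- setdiff(table$item, monographs$name)
  if (length(missing) > 0) {
    abort(paste0("herb(s) without monograph: ", paste(missing, collapse = ", ")))
  }
  m <- monographs[match(table$item, monographs$name), ]
  w <- if (weighting == "frequency") table$count else rep(1L, nrow(table))
  agg <- tibble(category = m$category, w = w) |>
    group_by(.data$category) |>
    summarise(n_herbs = n(), weight = sum(.data$w), .groups = "drop")
  agg$share_pct <- 100 * agg$weight / sum(agg$weight)
  agg[order(-agg$share_pct, agg$category), ]
}

#' Herb-attribute network edges
#'
#' One edge per herb-attribute incidence over the three monograph attribute
#' classes (thermal property, flavors, meridian tropism), ordered by herb,
#' then attribute class (property, flavor, meridian), then attribute — the
#' edge list behind the herb-attribute network map.
#'
#' @param monographs Monograph tibble.
#' @return A tibble with columns `herb`, `attribute`, `attribute_class`.
#' @export
attribute_edges <- function(monographs) {
  if (nrow(monographs) == 0) {
    return(tibble(herb = character(), attribute = character(),
                  attribute_class = character()))
  }
  rows <- lapply(seq_len(nrow(monographs)), function(i) {
    m <- monographs[i, ]
    tibble(
      herb = m$name,
      attribute = c(m$property, sort(m$flavors[[1]]), sort(m$meridians[[1]])),
      attribute_class = c("property",
                          rep("flavor", length(m$flavors[[1]])),
                          rep("meridian", length(m$meridians[[1]])))
    )
  })
  out <- bind_rows(rows)
  cls <- factor(out$attribute_class, levels = c("property", "flavor", "meridian"))
  out[order(out$herb, cls, out$attribute), ]
}

#' Write an attribute edge list as SIF plus node attributes
#'
#' Writes `<herb>\t<class>\t<attribute>` lines (simple interaction format)
#' and a companion node-attribute CSV suitable for Cytoscape-style import.
#'
#' @param edges Output of [attribute_edges()].
#' @param sif_path,nodes_path Output file paths.
#' @return `sif_path`, invisibly.
#' @export
write_sif <- function(edges, sif_path, nodes_path = NULL) {
  writeLines(paste(edges$herb, edges$attribute_class, edges$attribute,
                   sep = "\t"), sif_path)
  if (!is.null(nodes_path)) {
    nodes <- bind_rows(
      tibble(node = unique(edges$herb), type = "herb"),
      tibble(node = unique(edges$attribute[edges$attribute_class == "property"]),
             type = "property"),
      tibble(node = unique(edges$attribute[edges$attribute_class == "flavor"]),
             type = "flavor"),
      tibble(node = unique(edges$attribute[edges$attribute_class == "meridian"]),
             type = "meridian")
    )
    readr::write_csv(nodes, nodes_path)
  }
  invisible(sif_path)
}
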