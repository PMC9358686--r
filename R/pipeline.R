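#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the inputs (case and
#' dictionary/monograph files, or a synthetic configuration), the mining
#' thresholds, the frequency-enrollment rate, the cluster settings, and the
#' seed. Either `cases_path` or `synth` must be provided.
#'
#' @param cases_path Optional path to a case CSV/JSON-lines file.
#' @param dictionary_path,monographs_path Optional paths; the packaged
#'   dictionary and monographs are used when `NULL`.
#' @param synth Optional [synth_config()] used when `cases_path` is `NULL`;
#'   defaults to [ra_config()] seeded with `seed`.
#' @param thresholds A [mining_thresholds()].
#' @param min_rate High-frequency enrollment rate (proportion).
#' @param cluster_min_count Strict occurrence bound for cluster enrollment.
#' @param k Number of cluster groups to report.
#' @param metric,linkage Clustering distance and linkage (see
#'   [herb_linkage()]).
#' @param seed Integer seed driving all randomness.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cases_path = NULL, dictionary_path = NULL,
                            monographs_path = NULL, synth = NULL,
                            thresholds = mining_thresholds(),
                            min_rate = 0.10, cluster_min_count = 50,
                            k = 3, metric = "euclidean", linkage = "complete",
                            seed = 1) {
  if (min_rate < 0 || min_rate > 1) abort("min_rate must lie in [0, 1]")
  if (k < 1) abort("k must be at least 1")
  if (cluster_min_count < 0) abort("cluster_min_count must be nonnegative")
  for (p in c(cases_path, dictionary_path, monographs_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("file not found: ", p))
  }
  if (is.null(cases_path) && is.null(synth)) synth <- ra_config(seed = seed)
  structure(
    list(cases_path = cases_path, dictionary_path = dictionary_path,
         monographs_path = monographs_path, synth = synth,
         thresholds = thresholds, min_rate = min_rate,
         cluster_min_count = cluster_min_count, k = k,
         metric = metric, linkage = linkage, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the [pipeline_config()] arguments; thresholds are
#' given under a `thresholds:` block (`min_support`, `min_confidence`,
#' `min_lift`, `min_count`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(mining_thresholds, y$thresholds %||% list())
  args <- y[intersect(names(y), c("cases_path", "dictionary_path",
                                  "monographs_path", "min_rate",
                                  "cluster_min_count", "k", "metric",
                                  "linkage", "seed"))]
  do.call(pipeline_config, c(args, list(thresholds = th)))
}

#' Run the full prescription-mining pipeline
#'
#' Executes the fixed stage order: screen, clean, frequency analysis with
#' the enrollment filter, pain/other proportions, efficacy-category shares
#' and attribute network edges, second-order herb-pair rule mining,
#' third-order herb-and-symptom rule mining, hierarchical co-prescription
#' clustering, then (optionally) writes the report bundle. Any stage error
#' aborts with the stage name; when writing fails, partially written files
#' are removed. All randomness derives from `config$seed`, so a given
#' configuration always yields a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report bundle files.
#' @return A `report_bundle` list: `screening` (per-criterion failure
#'   counts), `frequency_herbs`/`frequency_symptoms` (full and enrolled),
#'   `pain_share`, `category_shares`, `edges`, `rules_order2`,
#'   `rules_order3`, `dendrogram`, `groups`, `meta`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "herbminer_stage_error")
    })
    message(sprintf("[herbminer] %-12s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  dict <- stage("load", {
    if (is.null(config$dictionary_path)) ra_dictionary()
    else read_term_dictionary(config$dictionary_path)
  })
  monographs <- if (is.null(config$monographs_path)) ra_monographs()
                else read_monographs(config$monographs_path)
  raw <- stage("input", {
    if (!is.null(config$cases_path)) read_cases(config$cases_path)
    else generate_cases(config$synth)
  })

  screen <- stage("screen", screen_cases(raw))
  eligible <- raw[screen$eligible, ]
  if (nrow(eligible) == 0) {
    abort("pipeline stage 'screen' failed: no eligible cases",
          class = "herbminer_stage_error")
  }
  screening <- summarise_screen(screen)

  cases <- stage("clean", clean_cases(eligible, dict))
  freq_h <- stage("frequency", frequency_table(cases, "herbs"))
  freq_s <- frequency_table(cases, "symptoms")
  high_h <- filter_high_frequency(freq_h, config$min_rate)
  high_s <- filter_high_frequency(freq_s, config$min_rate)
  pain <- stage("proportion", pain_share(cases, dict))
  covered <- high_h[high_h$item %in% monographs$name, ]
  shares <- stage("classify", category_shares(monographs, covered))
  edges <- attribute_edges(monographs[monographs$name %in% covered$item, ])

  rules2 <- stage("mine2", mine_rules(build_transactions(cases, "herbs"),
                                      order = 2, thresholds = config$thresholds))
  rules3 <- stage("mine3", mine_rules(build_transactions(cases, "both"),
                                      order = 3, thresholds = config$thresholds))

  cluster <- stage("cluster", {
    inc <- build_incidence(cases, config$cluster_min_count)
    dend <- herb_linkage(inc, config$metric, config$linkage)
    list(dendrogram = dend,
         groups = cut_groups(dend, min(config$k, length(dend$leaves))))
  })

  bundle <- structure(list(
    screening = screening,
    frequency_herbs = freq_h, frequency_symptoms = freq_s,
    high_frequency_herbs = high_h, high_frequency_symptoms = high_s,
    pain_share = pain, category_shares = shares, edges = edges,
    rules_order2 = rules2, rules_order3 = rules3,
    dendrogram = cluster$dendrogram, groups = cluster$groups,
    meta = tibble(
      package_version = as.character(utils::packageVersion("herbminer")),
      seed = config$seed,
      n_input = nrow(raw), n_eligible = nrow(eligible),
      config_hash = config_hash(config))
  ), class = "report_bundle")

  if (!is.null(out_dir)) stage("write", write_bundle(bundle, out_dir))
  bundle
}

summarise_screen <- function(screen) {
  fails <- unlist(screen$failed_criteria)
  counts <- table(fails)
  bind_rows(
    tibble(criterion = "eligible", n = sum(screen$eligible)),
    tibble(criterion = "ineligible", n = sum(!screen$eligible)),
    tibble(criterion = names(counts), n = as.integer(counts))
  )
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
  }
  tryCatch({
    pct <- function(x) round(100 * x, 2)
    emit("screening_summary.csv", function(p) readr::write_csv(bundle$screening, p))
    for (nm in c("frequency_herbs", "frequency_symptoms",
                 "high_frequency_herbs", "high_frequency_symptoms")) {
      tb <- bundle[[nm]]
      local({
        out <- tibble(item = tb$item, count = tb$count, rate_percent = pct(tb$rate))
        emit(paste0(nm, ".csv"), function(p) readr::write_csv(out, p))
      })
    }
    emit("pain_share.csv", function(p) {
      out <- bundle$pain_share
      out$fraction <- round(out$fraction, 6)
      readr::write_csv(out, p)
    })
    emit("category_shares.csv", function(p) {
      out <- bundle$category_shares
      out$share_pct <- round(out$share_pct, 2)
      readr::write_csv(out, p)
    })
    emit("attribute_edges.sif", function(p) write_sif(bundle$edges, p))
    emit("attribute_nodes.csv", function(p) {
      write_sif(bundle$edges, tempfile(fileext = ".sif"), p)
    })
    emit("rules_order2.csv", function(p) readr::write_csv(bubble_table(bundle$rules_order2), p))
    emit("rules_order3.csv", function(p) readr::write_csv(bubble_table(bundle$rules_order3), p))
    emit("dendrogram.nwk", function(p) writeLines(to_newick(bundle$dendrogram), p))
    emit("cluster_groups.csv", function(p) readr::write_csv(bundle$groups, p))
    emit("manifest.json", function(p) {
      jsonlite::write_json(as.list(bundle$meta), p, auto_unbox = TRUE, digits = NA)
    })
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(out_dir)
}

#' Bubble-diagram table for association rules
#'
#' One row per rule in mining order, with confidence and support on the
#' percent scale (2 decimals) and lift rounded to 3 decimals — the layout
#' consumed by the rule bubble diagrams (x = confidence, y = LHS per RHS
#' panel, size = support, color = lift).
#'
#' @param rules A `herb_rules` tibble from [mine_rules()].
#' @return A tibble with columns `lhs`, `rhs`, `confidence`, `support`,
#'   `lift`.
#' @export
bubble_table <- function(rules) {
  tibble(
    lhs = rules$lhs_label,
    rhs = rules$rhs,
    confidence = round(100 * rules$confidence, 2),
    support = round(100 * rules$support, 2),
    lift = round(rules$lift, 3)
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  eligible cases: ",
      x$screening$n[x$screening$criterion == "eligible"], "\n")
  cat("  enrolled herbs/symptoms:", nrow(x$high_frequency_herbs), "/",
      nrow(x$high_frequency_symptoms), "\n")
  cat("  rules (order 2 / 3):", nrow(x$rules_order2), "/",
      nrow(x$rules_order3), "\n")
  cat("  cluster groups:", max(x$groups$group), "over",
      length(x$dendrogram$leaves), "herbs\n")
  invisible(x)
}
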