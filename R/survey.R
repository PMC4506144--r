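#' Load and link respondent and language tables
#'
#' Reads a respondent CSV/TSV, a language metadata CSV and a link table
#' mapping survey language names (optionally per country, for names like
#' "Arabic" that resolve differently by country) to language ids. Applies
#' the exclusion rules: rows without a savings answer, rows whose language
#' name cannot be resolved, and rows whose resolved language is missing
#' from the metadata are dropped, with a per-reason tally.
#'
#' @param respondents_file path to the respondent table (`respondent_id`,
#'   `saved`, `language_name`, `country`, `wave`, covariates). Delimiter
#'   inferred from the extension (`.tsv` = tab).
#' @param meta_file path to the language metadata table (`language_id`,
#'   `ftr`, `family`, `genus`, `area`, `latitude`, `longitude`, ...).
#' @param link_file path to the link table (`language_name`, `country`
#'   (may be `NA` for country-independent names), `language_id`).
#' @return list: `respondents` (with resolved `language_id`), `meta`,
#'   `tally` (named counts per drop reason), `n_input`, `n_retained`.
#' @export
load_dataset <- function(respondents_file, meta_file, link_file) {
  read_any <- function(path) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  resp <- read_any(respondents_file)
  meta <- read_any(meta_file)
  link <- read_any(link_file)
  if (anyDuplicated(resp$respondent_id)) stop("duplicate respondent ids")
  n_input <- nrow(resp)
  tally <- c(missing_savings = 0L, unlinked_language = 0L,
             missing_metadata = 0L)

  ok_saved <- !is.na(resp$saved) & resp$saved %in% c(0, 1)
  tally["missing_savings"] <- sum(!ok_saved)
  resp <- resp[ok_saved, , drop = FALSE]

  # country-specific link rows take precedence over generic ones
  resolve <- function(name, country) {
    hit <- link$language_id[link$language_name == name &
                              !is.na(link$country) & link$country == country]
    if (length(hit)) return(hit[1])
    hit <- link$language_id[link$language_name == name & is.na(link$country)]
    if (length(hit)) hit[1] else NA_character_
  }
  resp$language_id <- mapply(resolve, resp$language_name, resp$country,
                             USE.NAMES = FALSE)
  ok_link <- !is.na(resp$language_id)
  tally["unlinked_language"] <- sum(!ok_link)
  resp <- resp[ok_link, , drop = FALSE]

  ok_meta <- resp$language_id %in% meta$language_id
  tally["missing_metadata"] <- sum(!ok_meta)
  resp <- resp[ok_meta, , drop = FALSE]

  list(respondents = resp, meta = meta, tally = tally,
       n_input = n_input, n_retained = nrow(resp))
}

#' Descriptive summaries of a linked survey dataset
#'
#' Computes the dataset-level quantities used to characterise the survey:
#' saving proportion, share of strong-FTR speakers, the strong/weak
#' variance ratio of the binary outcome (population variance, denominator
#' n), mean number of languages per country, and counts of countries,
#' areas and families whose retained respondents show no FTR variation.
#'
#' @param respondents linked respondent table (with `language_id`).
#' @param meta language metadata (with `ftr` in `{"strong","weak"}`).
#' @param waves optional wave filter (e.g. `3:5`).
#' @return list of summary fields; `variance_ratio` is `NA` when either
#'   class has zero variance.
#' @export
summarize_dataset <- function(respondents, meta, waves = NULL) {
  if (!is.null(waves)) {
    respondents <- respondents[respondents$wave %in% waves, , drop = FALSE]
  }
  if (nrow(respondents) == 0) stop("empty selection")
  ftr <- meta$ftr[match(respondents$language_id, meta$language_id)]
  pvar <- function(v) mean((v - mean(v))^2)
  v_strong <- if (any(ftr == "strong")) {
    pvar(respondents$saved[ftr == "strong"])
  } else {
    NA_real_
  }
  v_weak <- if (any(ftr == "weak")) {
    pvar(respondents$saved[ftr == "weak"])
  } else {
    NA_real_
  }
  variance_ratio <- if (isTRUE(v_weak > 0)) v_strong / v_weak else NA_real_

  langs_per_country <- tapply(respondents$language_id, respondents$country,
                              function(v) length(unique(v)))
  no_variation <- function(group) {
    g <- tapply(ftr, respondents[[group]],
                function(v) length(unique(v)) == 1)
    sum(g)
  }
  counts <- list()
  for (g in c("country", "area", "family")) {
    grp <- if (g %in% names(respondents)) g else NULL
    if (is.null(grp) && g %in% names(meta)) {
      respondents[[g]] <- meta[[g]][match(respondents$language_id,
                                          meta$language_id)]
      grp <- g
    }
    counts[[g]] <- if (is.null(grp)) NA_integer_ else no_variation(g)
  }
  list(
    n_rows = nrow(respondents),
    prop_saving = mean(respondents$saved),
    prop_strong_ftr_speakers = mean(ftr == "strong"),
    variance_ratio_strong_weak = variance_ratio,
    mean_languages_per_country = mean(langs_per_country),
    n_countries = length(unique(respondents$country)),
    n_countries_no_ftr_variation = counts$country,
    n_areas_no_ftr_variation = counts$area,
    n_families_no_ftr_variation = counts$family
  )
}

#' Write a scenario's tables to disk
#'
#' Writes respondents and language metadata as CSV and the tree as Newick,
#' so a simulated scenario round-trips through the same file formats real
#' data arrives in.
#'
#' @param scenario list from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    respondents = file.path(dir, "respondents.csv"),
    meta = file.path(dir, "language_meta.csv"),
    tree = file.path(dir, "tree.nwk")
  )
  utils::write.csv(scenario$respondents, paths["respondents"],
                   row.names = FALSE)
  utils::write.csv(scenario$meta, paths["meta"], row.names = FALSE)
  ape::write.tree(scenario$tree, paths["tree"])
  invisible(paths)
}
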