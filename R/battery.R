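#' Default battery configuration
#'
#' Method toggles, permutation counts and significance level for
#' [run_battery()]. Any element can be overridden through the `config`
#' argument.
#'
#' @return named list of defaults.
#' @export
battery_defaults <- function() {
  list(
    alpha = 0.05,
    n_perm = 499,
    n_reps_indep = 1000,
    glmm_slopes = TRUE,
    methods = c("naive_logistic", "mixed_effects", "matched_regression",
                "independent_samples", "partial_mantel",
                "stratified_mantel", "moran", "pgls")
  )
}

battery_row <- function(method, aggregated, controls, statistic, p, alpha) {
  data.frame(method = method, aggregated = aggregated, controls = controls,
             statistic = statistic, p = p, robust = is.finite(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Run the full robustness battery on one dataset
#'
#' Orchestrates the stages in dependency order: matched regression and
#' residualisation first (the aggregate methods consume the residuals),
#' then the tree, then the comparative, spatial and resampling tests. Each
#' enabled method contributes one row to the report: method name, whether
#' it aggregates the data, which non-independence controls it applies, its
#' headline statistic and p-value, and a robust flag at the stated alpha
#' (robust = the trait effect survives that method's controls).
#'
#' @param scenario list with `respondents`, `meta`, `tree`, `coords`,
#'   `classification` — either from [simulate_scenario()] or assembled
#'   from loaded data.
#' @param config list overriding [battery_defaults()].
#' @param seed integer seed governing every stochastic stage.
#' @return data.frame (`BatteryReport`), one row per enabled method, with
#'   attributes `alpha`, `seed`, and `details` (the underlying fit
#'   objects).
#' @export
run_battery <- function(scenario, config = list(), seed = 1) {
  cfg <- utils::modifyList(battery_defaults(), config)
  methods <- cfg$methods
  rows <- list()
  details <- list()
  resp <- scenario$respondents
  meta <- scenario$meta
  tree <- scenario$tree
  if (length(methods) == 0) {
    out <- battery_row(character(), logical(), character(), numeric(),
                       numeric(), cfg$alpha)[0, ]
    attr(out, "alpha") <- cfg$alpha
    attr(out, "seed") <- seed
    return(out)
  }
  seeds <- derive_seeds(seed, 4)

  needs_residuals <- any(methods %in% c("independent_samples",
                                        "partial_mantel",
                                        "stratified_mantel", "moran",
                                        "pgls", "matched_regression"))
  res_tab <- NULL
  if (needs_residuals) {
    matched <- fit_binned_logistic(
      resp, bin_vars = c("country", "family", "sex_female"),
      predictors = c("weak_ftr", "employed", "trust"),
      cluster = "family"
    )
    details$matched <- matched
    # residual trait comes from the nuisance-only regression: a model that
    # includes the group trait has residuals orthogonal to it by the score
    # equation, which would empty the aggregate stages of their signal
    nuisance <- fit_binned_logistic(
      resp, bin_vars = c("country", "family", "sex_female"),
      predictors = c("employed", "trust"),
      cluster = "family"
    )
    res_tab <- language_residuals(nuisance, min_n = 1)
    details$residual_fit <- nuisance
  }

  if ("naive_logistic" %in% methods) {
    fit <- stats::glm(saved ~ weak_ftr, data = resp,
                      family = stats::binomial())
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <- battery_row(
      "naive_logistic", FALSE, "none", sm["weak_ftr", "z value"],
      sm["weak_ftr", "Pr(>|z|)"], cfg$alpha)
    details$naive <- fit
  }

  if ("mixed_effects" %in% methods) {
    slope <- if (isTRUE(cfg$glmm_slopes)) "weak_ftr" else NULL
    full <- fit_logistic_glmm(
      resp, fixed = "weak_ftr",
      random = list(country = slope, family = slope, area = slope))
    null <- fit_logistic_glmm(
      resp, fixed = character(),
      random = list(country = slope, family = slope, area = slope))
    lrt <- likelihood_ratio_test(full, null)
    rows[[length(rows) + 1]] <- battery_row(
      "mixed_effects", FALSE, "family+area+country", lrt$statistic, lrt$p,
      cfg$alpha)
    details$glmm <- full
  }

  if ("matched_regression" %in% methods) {
    cf <- details$matched$coefficients
    i <- match("weak_ftr", cf$term)
    rows[[length(rows) + 1]] <- battery_row(
      "matched_regression", FALSE, "family+country", cf$z[i], cf$p[i],
      cfg$alpha)
  }

  if ("independent_samples" %in% methods) {
    ind <- independent_family_samples(res_tab, meta,
                                      n_reps = cfg$n_reps_indep,
                                      seed = seeds[1])
    # two-sided evidence scale: robust when strong-lower in > 1 - alpha/2
    p_eq <- 2 * min(ind$prop_strong_lower, 1 - ind$prop_strong_lower)
    rows[[length(rows) + 1]] <- battery_row(
      "independent_samples", TRUE, "family", ind$prop_strong_lower, p_eq,
      cfg$alpha)
    details$independent <- ind
  }

  if (any(methods %in% c("partial_mantel", "stratified_mantel"))) {
    common <- res_tab$language_id
    res_v <- stats::setNames(res_tab$residual, res_tab$language_id)
    m <- meta[match(common, meta$language_id), ]
    sav_d <- as.matrix(stats::dist(res_v[common]))
    ftr_d <- outer(m$ftr, m$ftr, `!=`) * 1
    dimnames(ftr_d) <- list(common, common)
    phylo_d <- patristic_matrix(tree)[common, common]
    geo_d <- geodesic_matrix(
      data.frame(language_id = common, latitude = m$latitude,
                 longitude = m$longitude))
    if ("partial_mantel" %in% methods) {
      pm <- partial_mantel(sav_d, ftr_d, list(phylo_d, geo_d),
                           n_perm = cfg$n_perm, seed = seeds[2])
      rows[[length(rows) + 1]] <- battery_row(
        "partial_mantel", TRUE, "phylo+geo", pm$r, pm$p, cfg$alpha)
      details$partial_mantel <- pm
    }
    if ("stratified_mantel" %in% methods) {
      strata <- stats::setNames(m$family, common)
      sm <- tryCatch(
        stratified_mantel(sav_d, ftr_d, strata,
                          controls = list(phylo_d, geo_d),
                          method = "kendall", n_perm = cfg$n_perm,
                          seed = seeds[3]),
        error = function(e) NULL)
      if (!is.null(sm)) {
        rows[[length(rows) + 1]] <- battery_row(
          "stratified_mantel", TRUE, "family+phylo+geo", sm$r, sm$p,
          cfg$alpha)
        details$stratified_mantel <- sm
      }
    }
  }

  if ("moran" %in% methods) {
    res_v <- stats::setNames(res_tab$residual, res_tab$language_id)
    mo <- morans_i(res_v, scenario$coords)
    rows[[length(rows) + 1]] <- battery_row(
      "moran", TRUE, "geo", mo$observed, mo$p, cfg$alpha)
    details$moran <- mo
  }

  if ("pgls" %in% methods) {
    res_v <- stats::setNames(res_tab$residual, res_tab$language_id)
    xv <- stats::setNames(as.integer(meta$ftr == "weak"), meta$language_id)
    keep <- intersect(tree$tip.label, names(res_v))
    tr <- if (length(keep) < length(tree$tip.label)) {
      ape::keep.tip(tree, keep)
    } else {
      tree
    }
    pf <- pgls(tr, res_v, xv, cov_model = "pagel")
    rows[[length(rows) + 1]] <- battery_row(
      "pgls", TRUE, "phylo", pf$coefficients$t[2], pf$coefficients$p[2],
      cfg$alpha)
    details$pgls <- pf
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- cfg$alpha
  attr(out, "seed") <- seed
  attr(out, "details") <- details
  out
}

#' Write a battery report as CSV and JSON
#'
#' @param report data.frame from [run_battery()].
#' @param path_prefix output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_battery_report <- function(report, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(
    list(alpha = attr(report, "alpha"), seed = attr(report, "seed"),
         rows = report),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
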