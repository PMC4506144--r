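#' Regression on matched samples (binned logistic regression)
#'
#' Splits the data into bins where every respondent is identical on all
#' `bin_vars` (fully interacted), drops uninformative bins (fewer than two
#' respondents or no outcome variation), and estimates the predictor
#' effects within bins. Two estimators:
#' \describe{
#'   \item{`"fixed"`}{ordinary logistic regression with a dummy per bin
#'     (the default); with a single bin the predictor coefficient is
#'     exactly the table's log odds ratio.}
#'   \item{`"conditional"`}{exact conditional logistic regression
#'     ([survival::clogit()]), conditioning on the number of successes per
#'     bin.}
#' }
#' Cluster-robust standard errors (sandwich estimator) are reported when
#' `cluster` names a grouping column (e.g. language family or country).
#'
#' @param data respondent-level data.frame with a 0/1 outcome.
#' @param bin_vars character vector of matching variables.
#' @param predictors character vector of predictor columns.
#' @param cluster optional column name for cluster-robust SEs.
#' @param outcome outcome column name (default `"saved"`).
#' @param method `"fixed"` or `"conditional"`.
#' @importFrom survival strata clogit Surv coxph coxph.control
#' @return object of class `"matched_fit"`: `coefficients` (log-odds scale
#'   with `odds_ratio`), `logLik`, `aic`, `bic`, `n_bins_informative`,
#'   `n_retained`, per-respondent response residuals in `$residuals`
#'   (fixed method), and the retained data in `$data`.
#' @export
fit_binned_logistic <- function(data, bin_vars, predictors, cluster = NULL,
                                outcome = "saved",
                                method = c("fixed", "conditional")) {
  method <- match.arg(method)
  stopifnot(outcome %in% names(data), all(bin_vars %in% names(data)),
            all(predictors %in% names(data)))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  bin <- interaction(data[bin_vars], drop = TRUE, sep = ":")
  keep_bin <- tapply(y, bin, function(v) length(v) >= 2 && var(v) > 0)
  informative <- names(keep_bin)[keep_bin]
  if (length(informative) == 0) stop("no informative bins")
  keep <- bin %in% informative
  dat <- data[keep, , drop = FALSE]
  dat$.bin <- droplevels(bin[keep])
  for (p in predictors) {
    if (all(tapply(dat[[p]], dat$.bin, function(v) var(as.numeric(factor(v)))) == 0)) {
      stop("predictor constant within every bin: ", p)
    }
  }
  pred_rhs <- paste(predictors, collapse = " + ")

  if (method == "fixed") {
    bin_term <- if (nlevels(dat$.bin) > 1) "+ .bin" else ""
    form <- stats::as.formula(paste(outcome, "~", pred_rhs, bin_term))
    fit <- stats::glm(form, data = dat, family = stats::binomial())
    vc <- if (is.null(cluster)) stats::vcov(fit) else
      sandwich::vcovCL(fit, cluster = dat[[cluster]])
    est <- stats::coef(fit)
    rows <- which(!grepl("^\\.bin", names(est)) &
                    names(est) != "(Intercept)")
    se <- sqrt(diag(vc))[rows]
    coefs <- data.frame(term = names(est)[rows], estimate = est[rows],
                        se = se, odds_ratio = exp(est[rows]),
                        z = est[rows] / se,
                        p = 2 * stats::pnorm(-abs(est[rows] / se)),
                        row.names = NULL, stringsAsFactors = FALSE)
    resid <- dat[[outcome]] - stats::fitted(fit)
    ll <- as.numeric(stats::logLik(fit))
    k <- length(est)
  } else {
    form <- stats::as.formula(paste(outcome, "~", pred_rhs,
                                    "+ strata(.bin)"))
    fit <- survival::clogit(form, data = dat, method = "exact")
    sm <- summary(fit)$coefficients
    est <- sm[, "coef"]
    vc <- if (is.null(cluster)) stats::vcov(fit) else
      sandwich::vcovCL(fit, cluster = dat[[cluster]])
    se <- sqrt(diag(vc))
    coefs <- data.frame(term = rownames(sm), estimate = est, se = se,
                        odds_ratio = exp(est), z = est / se,
                        p = 2 * stats::pnorm(-abs(est / se)),
                        row.names = NULL, stringsAsFactors = FALSE)
    resid <- NULL
    ll <- fit$loglik[2]
    k <- length(est)
  }
  n <- nrow(dat)
  structure(list(coefficients = coefs, logLik = ll,
                 aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k,
                 n_bins_informative = length(informative),
                 n_retained = n, n_dropped = nrow(data) - n,
                 method = method, residuals = resid, data = dat,
                 fit = fit),
            class = "matched_fit")
}

#' @export
print.matched_fit <- function(x, ...) {
  cat(sprintf("Matched-sample %s logistic regression: %d informative bins, %d respondents (%d dropped)\n",
              x$method, x$n_bins_informative, x$n_retained, x$n_dropped))
  print(x$coefficients, digits = 4)
  cat(sprintf("  logLik = %.2f, AIC = %.2f, BIC = %.2f\n", x$logLik, x$aic,
              x$bic))
  invisible(x)
}

#' Aggregate model residuals per language
#'
#' Response-scale residuals (observed minus fitted probability) from a
#' matched fit, averaged per language. These residualised savings values
#' carry the variation in the outcome not explained by the matching
#' variables, and serve as the per-language trait for all aggregate
#' (Mantel, PGLS, independent-sample) analyses.
#'
#' @param fit a `"matched_fit"` from the `"fixed"` method (which carries
#'   respondent residuals).
#' @param min_n languages with fewer retained respondents are flagged.
#' @return data.frame: `language_id`, `residual` (mean), `n`, `flagged`.
#' @export
language_residuals <- function(fit, min_n = 5) {
  if (is.null(fit$residuals)) {
    stop("fit carries no respondent residuals (use method = 'fixed')")
  }
  dat <- fit$data
  if (!"language_id" %in% names(dat)) stop("data lacks language_id")
  agg <- stats::aggregate(fit$residuals,
                          by = list(language_id = dat$language_id),
                          FUN = mean)
  cnt <- table(dat$language_id)
  out <- data.frame(language_id = agg$language_id, residual = agg$x,
                    n = as.integer(cnt[agg$language_id]),
                    stringsAsFactors = FALSE)
  out$flagged <- out$n < min_n
  out[order(out$language_id), ]
}

#' Serendipity scan over alternative linguistic features
#'
#' Refits the matched regression once per linguistic feature, identical in
#' structure except for the swapped feature, and ranks the features by BIC
#' (AIC as cross-check). A feature that outranks most alternatives is
#' unlikely to owe its fit to chance alone.
#'
#' @param data respondent-level data.frame with `language_id`.
#' @param feature_table data.frame: `language_id` plus one column per
#'   linguistic feature (values per language).
#' @param base_predictors predictors included in every regression.
#' @param bin_vars matching variables, as [fit_binned_logistic()].
#' @param cluster,outcome as [fit_binned_logistic()].
#' @return data.frame sorted by BIC: `feature`, `estimate`, `p`, `aic`,
#'   `bic`, `rank`, `converged`; attribute `"n_failed"` counts
#'   non-converged fits (excluded from the ranking).
#' @export
serendipity_scan <- function(data, feature_table, base_predictors = character(),
                             bin_vars, cluster = NULL, outcome = "saved") {
  stopifnot("language_id" %in% names(feature_table))
  features <- setdiff(names(feature_table), "language_id")
  if (length(features) < 1) stop("feature table has no feature columns")
  rows <- lapply(features, function(f) {
    data$.feature <- feature_table[[f]][match(data$language_id,
                                              feature_table$language_id)]
    fit <- tryCatch(
      fit_binned_logistic(data, bin_vars,
                          c(".feature", base_predictors),
                          cluster = cluster, outcome = outcome),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || !isTRUE(fit$fit$converged)) {
      data.frame(feature = f, estimate = NA_real_, p = NA_real_,
                 aic = NA_real_, bic = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      i <- match(".feature", fit$coefficients$term)
      data.frame(feature = f, estimate = fit$coefficients$estimate[i],
                 p = fit$coefficients$p[i], aic = fit$aic, bic = fit$bic,
                 converged = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  n_failed <- sum(!out$converged)
  if (all(!out$converged)) stop("all feature fits failed")
  out <- out[order(out$bic), ]
  out$rank <- NA_integer_
  out$rank[out$converged] <- seq_len(sum(out$converged))
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
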