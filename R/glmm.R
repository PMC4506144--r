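#' Fit a logistic mixed-effects model with crossed random effects
#'
#' Laplace-approximate ML fit of a binomial GLMM via [lme4::glmer()]. Random
#' terms are given as a named list: each name is a grouping factor (e.g.
#' `country`, `family`, `area`), each value is `NULL` for a random intercept
#' only, or the name of a fixed term to give that factor a correlated
#' random slope (at most one slope term per factor).
#'
#' @param data respondent-level data.frame; the outcome must be 0/1.
#' @param outcome name of the binary outcome column (default `"saved"`).
#' @param fixed character vector of fixed-effect column names (may be
#'   empty for an intercept-only model).
#' @param random named list of random terms, e.g.
#'   `list(country = "weak_ftr", family = "weak_ftr", area = NULL)`.
#' @param correlated if `FALSE`, intercepts and slopes within a factor are
#'   uncorrelated (`||` syntax).
#' @param control optional [lme4::glmerControl()]; defaults to bobyqa.
#' @return object of class `"glmm_fit"`: `beta` (fixed estimates with SEs),
#'   `varcomp` (random-effect SDs/correlations), `logLik`, `converged`,
#'   `singular`, the `formula`, and the underlying `merMod` in `$fit`.
#' @export
fit_logistic_glmm <- function(data, outcome = "saved", fixed = character(),
                              random = list(), correlated = TRUE,
                              control = NULL) {
  stopifnot(outcome %in% names(data))
  yv <- data[[outcome]]
  if (!all(yv %in% c(0, 1))) stop("outcome must be binary 0/1")
  for (g in names(random)) {
    if (!g %in% names(data)) stop("grouping factor absent: ", g)
    if (length(unique(data[[g]])) < 2) {
      stop("grouping factor '", g, "' needs >= 2 levels")
    }
  }
  fx <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  bar <- if (correlated) "|" else "||"
  rnd <- vapply(names(random), function(g) {
    slope <- random[[g]]
    inner <- if (is.null(slope)) "1" else paste("1 +", slope)
    sprintf("(%s %s %s)", inner, bar, g)
  }, character(1))
  rhs <- paste(c(fx, rnd), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  if (is.null(control)) {
    control <- lme4::glmerControl(optimizer = "bobyqa",
                                  check.conv.singular = "ignore")
  }
  if (length(random) == 0) {
    # degenerate spec: plain logistic regression
    fit <- stats::glm(form, data = data, family = stats::binomial())
    sm <- summary(fit)$coefficients
    beta <- data.frame(term = rownames(sm), estimate = sm[, 1],
                       se = sm[, 2], row.names = NULL,
                       stringsAsFactors = FALSE)
    return(structure(list(beta = beta, varcomp = NULL,
                          logLik = as.numeric(stats::logLik(fit)),
                          converged = fit$converged, singular = FALSE,
                          formula = form, fit = fit, n = nrow(data)),
                     class = "glmm_fit"))
  }
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(form, data = data, family = stats::binomial(),
                control = control),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  beta <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4) == 0 &&
    !any(grepl("failed to converge", msgs))
  structure(list(beta = beta, varcomp = vc,
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = conv, singular = lme4::isSingular(fit),
                 messages = msgs, formula = form, fit = fit,
                 n = nrow(data)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Logistic GLMM:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, logLik = %.2f, converged = %s%s\n", x$n, x$logLik,
              x$converged, if (isTRUE(x$singular)) " (singular)" else ""))
  print(transform(x$beta, odds_ratio = exp(estimate)), digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested GLMM fits
#'
#' `chi^2 = 2 (LL_full - LL_null)` compared to a chi-squared distribution
#' with df equal to the difference in parameter counts.
#'
#' @param full,null `"glmm_fit"` objects; `null` must be nested in `full`.
#' @return list: `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  df_full <- n_params(full)
  df_null <- n_params(null)
  if (df_full < df_null) stop("models not nested: full has fewer parameters")
  stat <- 2 * (full$logLik - null$logLik)
  if (stat < -1e-6) {
    stop("negative likelihood-ratio statistic: optimizer failure suspected")
  }
  stat <- max(stat, 0)
  df <- df_full - df_null
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

n_params <- function(fit) {
  nb <- nrow(fit$beta)
  nv <- if (is.null(fit$varcomp)) 0 else nrow(fit$varcomp)
  nb + nv
}

#' Wald z test for a fixed effect
#'
#' `z = estimate / SE` with a two-sided normal p-value. `z^2` is the
#' single-df Wald chi-squared for the same term.
#'
#' @param fit a `"glmm_fit"`.
#' @param term fixed-effect term name.
#' @return list: `statistic` (z), `df = 1`, `p`.
#' @export
wald_test <- function(fit, term) {
  row <- match(term, fit$beta$term)
  if (is.na(row)) stop("term not in fit: ", term)
  se <- fit$beta$se[row]
  if (!is.finite(se) || se <= 0) stop("standard error unavailable for ", term)
  z <- fit$beta$estimate[row] / se
  list(statistic = z, df = 1, p = 2 * stats::pnorm(-abs(z)))
}

#' Extract random-effect estimates (BLUPs)
#'
#' One row per group level per random term, with conditional standard
#' deviations, sorted by grouping factor and level for reproducibility.
#' Also reports, per grouping factor with a slope, the correlation between
#' intercept and slope BLUPs.
#'
#' @param fit a `"glmm_fit"` with random terms.
#' @return data.frame: `group_factor`, `level`, `term`, `estimate`, `se`;
#'   attribute `"blup_correlations"` holds per-factor intercept/slope
#'   correlations.
#' @export
extract_random_effects <- function(fit) {
  if (is.null(fit$varcomp)) stop("fit has no random effects")
  re <- lme4::ranef(fit$fit, condVar = TRUE)
  out <- list()
  cors <- list()
  for (g in names(re)) {
    df <- re[[g]]
    pv <- attr(df, "postVar")
    for (j in seq_len(ncol(df))) {
      out[[length(out) + 1]] <- data.frame(
        group_factor = g, level = rownames(df), term = colnames(df)[j],
        estimate = df[, j], se = sqrt(pv[j, j, ]),
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
    if (ncol(df) >= 2 && stats::sd(df[, 1]) > 0 && stats::sd(df[, 2]) > 0) {
      cors[[g]] <- stats::cor(df[, 1], df[, 2])
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group_factor, res$term, res$level), ]
  rownames(res) <- NULL
  attr(res, "blup_correlations") <- cors
  res
}
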