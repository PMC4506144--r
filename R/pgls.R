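# GLS machinery shared by the signal statistics and PGLS ------------------

# log-likelihood and estimates of y ~ X under covariance structure V
# (V up to a scalar: sigma2 is profiled out by ML)
gls_fit <- function(y, x, v) {
  n <- length(y)
  cv <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  # whiten
  yt <- backsolve(cv, y, transpose = TRUE)
  xt <- backsolve(cv, x, transpose = TRUE)
  qr_x <- qr(xt)
  beta <- qr.coef(qr_x, yt)
  res <- yt - xt %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(cv)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  p <- ncol(x)
  sigma2_reml <- rss / (n - p)
  xtxi <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtxi) * sigma2_reml)
  list(beta = as.numeric(beta), se = se, logLik = ll, sigma2 = sigma2_ml,
       df = n - p, rss = rss, vcov = xtxi * sigma2_reml)
}

pagel_v <- function(v_bm, lam) {
  v <- v_bm * lam
  diag(v) <- diag(v_bm)
  v
}

# upper bound on lambda keeping V(lambda) positive definite on an
# ultrametric tree: total depth over deepest internal node height
lambda_max <- function(v_bm) {
  off <- v_bm
  diag(off) <- 0
  mx <- max(off)
  if (mx <= 0) return(1)
  max(1, min(diag(v_bm)) / mx)
}

#' Pagel's lambda phylogenetic signal for a continuous trait
#'
#' Maximum-likelihood estimate of the branch-length scaling parameter
#' lambda: the off-diagonal entries of the Brownian-motion covariance matrix
#' are multiplied by lambda and the GLS likelihood of an intercept-only
#' model is maximised over lambda by bounded optimisation. Likelihood-ratio
#' tests compare the estimate against lambda = 0 (no signal) and lambda = 1
#' (Brownian motion).
#'
#' @param tree a `"phylo"` object.
#' @param trait named continuous vector per tip.
#' @return a `"signal_result"` list: `statistic = "lambda"`, `estimate`,
#'   `logLik`, `logLik0`, `logLik1`, `p_vs_random`, `p_vs_BM`.
#' @export
pagel_lambda <- function(tree, trait) {
  tips <- tree$tip.label
  if (length(tips) < 4) stop("need at least 4 tips")
  y <- as.numeric(trait[tips])
  if (anyNA(y)) stop("missing trait values")
  if (stats::sd(y) == 0) stop("constant trait")
  v_bm <- ape::vcv(tree)
  x <- matrix(1, length(y), 1)
  lmax <- lambda_max(v_bm)
  ll_at <- function(lam) {
    f <- gls_fit(y, x, pagel_v(v_bm, lam))
    if (is.null(f)) -Inf else f$logLik
  }
  opt <- stats::optimize(ll_at, c(0, lmax), maximum = TRUE, tol = 1e-8)
  # guard the boundary: optimize can miss maxima at the interval ends
  cand <- c(opt$maximum, 0, 1, lmax)
  lls <- vapply(cand, ll_at, numeric(1))
  est <- cand[which.max(lls)]
  ll <- max(lls)
  ll0 <- ll_at(0)
  ll1 <- ll_at(1)
  structure(list(
    statistic = "lambda", estimate = est, logLik = ll,
    logLik0 = ll0, logLik1 = ll1,
    p_vs_random = stats::pchisq(2 * (ll - ll0), 1, lower.tail = FALSE),
    p_vs_BM = stats::pchisq(2 * (ll - ll1), 1, lower.tail = FALSE),
    n = length(y)
  ), class = "signal_result")
}

# sum over edges of |node value - parent value| with ancestral node values
# estimated as the unweighted mean of child values (polytomies averaged);
# vectorised over columns of a tips x m matrix
d_statistic <- function(tree, tip_matrix) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  m <- ncol(tip_matrix)
  vals <- matrix(0, n_all, m)
  vals[seq_len(n_tip), ] <- tip_matrix
  children <- split(tree$edge[, 2], tree$edge[, 1])
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    if (done[parent]) next
    kids <- children[[as.character(parent)]]
    if (all(done[kids])) {
      vals[parent, ] <- colMeans(vals[kids, , drop = FALSE])
      done[parent] <- TRUE
    }
  }
  while (!all(done)) {
    for (parent in which(!done)) {
      kids <- children[[as.character(parent)]]
      if (all(done[kids])) {
        vals[parent, ] <- colMeans(vals[kids, , drop = FALSE])
        done[parent] <- TRUE
      }
    }
  }
  colSums(abs(vals[tree$edge[, 2], , drop = FALSE] -
                vals[tree$edge[, 1], , drop = FALSE]))
}

#' Fritz-Purvis D phylogenetic signal for a binary trait
#'
#' Computes the observed sum of sister-clade differences `d_obs` (ancestral
#' values by equal-weight averaging, polytomies averaged over children) and
#' scales it between its expectations under two simulated nulls:
#' tip-shuffling (no signal; D = 1) and threshold Brownian motion with the
#' observed prevalence (clumped signal; D = 0):
#' `D = (d_obs - mean d_BM) / (mean d_random - mean d_BM)`.
#'
#' @param tree a `"phylo"` object.
#' @param trait named 0/1 vector per tip; both states must be present.
#' @param n_sim simulations per null (>= 200).
#' @param seed integer RNG seed.
#' @return a `"signal_result"` list: `statistic = "D"`, `estimate`,
#'   `d_obs`, `p_vs_random` (tail P(d_random <= d_obs)), `p_vs_BM`
#'   (tail P(d_BM >= d_obs)), `n_sim`.
#' @export
fritz_purvis_d <- function(tree, trait, n_sim = 1000, seed = 1) {
  tips <- tree$tip.label
  x <- as.numeric(trait[tips])
  if (anyNA(x)) stop("missing trait values")
  k <- sum(x)
  n <- length(x)
  if (k == 0 || k == n) stop("monomorphic trait: D undefined")
  if (n_sim < 200) stop("n_sim must be >= 200")
  d_obs <- d_statistic(tree, matrix(x, ncol = 1))
  v_bm <- ape::vcv(tree)
  cv <- chol(v_bm)
  sims <- withr_seed(seed, {
    shuf <- vapply(seq_len(n_sim), function(i) x[sample.int(n)],
                   numeric(n))
    liab <- t(matrix(stats::rnorm(n_sim * n), n_sim, n) %*% cv)
    # threshold each liability column at the observed prevalence
    bm <- apply(liab, 2, function(z) as.numeric(rank(z, ties.method = "first") > n - k))
    list(shuf = shuf, bm = bm)
  })
  d_rand <- d_statistic(tree, sims$shuf)
  d_bm <- d_statistic(tree, sims$bm)
  scale <- mean(d_rand) - mean(d_bm)
  est <- if (scale == 0) NA_real_ else (d_obs - mean(d_bm)) / scale
  structure(list(
    statistic = "D", estimate = est, d_obs = d_obs,
    mean_d_random = mean(d_rand), mean_d_BM = mean(d_bm),
    p_vs_random = mean(d_rand <= d_obs),
    p_vs_BM = mean(d_bm >= d_obs),
    n_sim = n_sim, n = n
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (x$statistic == "lambda") {
    cat(sprintf("Pagel's lambda = %.4f (logLik %.2f; vs lambda=0 p = %.3g; vs lambda=1 p = %.3g)\n",
                x$estimate, x$logLik, x$p_vs_random, x$p_vs_BM))
  } else {
    cat(sprintf("Fritz-Purvis D = %.4f (d_obs = %.2f; vs random p = %.3g; vs BM p = %.3g; %d sims)\n",
                x$estimate, x$d_obs, x$p_vs_random, x$p_vs_BM, x$n_sim))
  }
  invisible(x)
}

pgls_covariance <- function(tree, cov_model, par) {
  v_bm <- ape::vcv(tree)
  switch(cov_model,
    BM = v_bm,
    pagel = pagel_v(v_bm, par),
    OU = exp(-par * patristic_matrix(tree)) * max(v_bm),
    grafen = ape::vcv(grafen_rescale(tree, par,
                                     total_depth = max(v_bm))),
    stop("unknown covariance model: ", cov_model)
  )
}

#' Phylogenetic generalised least squares regression
#'
#' GLS regression of a continuous tip trait on predictors with error
#' covariance given by one of four models: `"BM"` (Brownian motion, shared
#' path lengths), `"pagel"` (off-diagonals scaled by lambda), `"OU"`
#' (stationary Ornstein-Uhlenbeck, `exp(-alpha d)`), or `"grafen"`
#' (Grafen-rescaled heights raised to rho). The model parameter is profiled
#' by maximum likelihood unless fixed.
#'
#' @param tree a `"phylo"` object.
#' @param y named response per tip.
#' @param x predictor: named vector, or data.frame/matrix with rownames =
#'   tip labels.
#' @param cov_model `"BM"`, `"pagel"`, `"OU"` or `"grafen"`.
#' @param param fixed covariance parameter (lambda, alpha or rho); `NULL`
#'   (default) profiles it by ML. Ignored for `"BM"`.
#' @return object of class `"pgls_fit"`: `coefficients` table (estimate,
#'   SE, t, p, CI), `logLik`, `param`, `cov_model`, `df`, `n`.
#' @export
pgls <- function(tree, y, x, cov_model = "pagel", param = NULL) {
  tips <- tree$tip.label
  yv <- as.numeric(y[tips])
  if (anyNA(yv)) stop("response missing for some tips")
  if (is.null(dim(x))) {
    xm <- matrix(as.numeric(x[tips]), ncol = 1,
                 dimnames = list(tips, "x"))
  } else {
    xm <- as.matrix(x)[tips, , drop = FALSE]
    storage.mode(xm) <- "double"
  }
  if (anyNA(xm)) stop("predictors missing for some tips")
  design <- cbind(`(Intercept)` = 1, xm)
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design")
  n <- length(yv)

  fit_at <- function(par) {
    v <- pgls_covariance(tree, cov_model, par)
    gls_fit(yv, design, v)
  }
  if (cov_model == "BM") {
    param_hat <- NA_real_
    fit <- gls_fit(yv, design, pgls_covariance(tree, "BM", NULL))
  } else if (!is.null(param)) {
    param_hat <- param
    fit <- fit_at(param)
  } else {
    bounds <- switch(cov_model,
      pagel = c(0, lambda_max(ape::vcv(tree))),
      OU = log(c(1e-2, 1e2) / max(patristic_matrix(tree))),
      grafen = log(c(0.01, 10))
    )
    obj <- function(p) {
      par <- if (cov_model == "pagel") p else exp(p)
      f <- fit_at(par)
      if (is.null(f)) Inf else -f$logLik
    }
    opt <- stats::optimize(obj, bounds, tol = 1e-8)
    param_hat <- if (cov_model == "pagel") opt$minimum else exp(opt$minimum)
    if (cov_model == "pagel") {
      # check the boundary values too
      cand <- c(param_hat, 0, 1)
      vals <- vapply(cand, obj, numeric(1))
      param_hat <- cand[which.min(vals)]
    }
    fit <- fit_at(param_hat)
  }
  if (is.null(fit)) stop("covariance matrix not positive definite")
  tval <- fit$beta / fit$se
  pval <- 2 * stats::pt(-abs(tval), fit$df)
  ci <- cbind(fit$beta - stats::qt(0.975, fit$df) * fit$se,
              fit$beta + stats::qt(0.975, fit$df) * fit$se)
  coefs <- data.frame(
    term = colnames(design), estimate = fit$beta, se = fit$se,
    t = tval, df = fit$df, p = pval,
    ci_low = ci[, 1], ci_high = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, logLik = fit$logLik,
                 sigma2 = fit$sigma2, cov_model = cov_model,
                 param = param_hat, df = fit$df, n = n,
                 vcov = fit$vcov,
                 tree = tree, y = yv, x = xm),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s covariance%s): logLik = %.2f, n = %d\n",
              x$cov_model,
              if (is.na(x$param)) "" else sprintf(", param = %.4f", x$param),
              x$logLik, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Coefficient extraction for PGLS fits
#' @param object a `"pgls_fit"`.
#' @param ... unused.
#' @export
coef.pgls_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = nrow(object$coefficients) + 1 +
              as.integer(object$cov_model != "BM"), class = "logLik")
}

#' Influence diagnostics for a PGLS fit
#'
#' Refits the model leaving out each tip in turn. The dfbeta for a tip is
#' the change in the focal coefficient scaled by the full-model standard
#' error; tips with `|dfbeta| > cutoff` (default `2/sqrt(n)`) are flagged.
#'
#' @param tree,y,x,cov_model,param as [pgls()].
#' @param term which coefficient to track (default: the first predictor).
#' @param cutoff flagging threshold; default `2/sqrt(n)`.
#' @return list: `dfbeta` data.frame per tip (with leave-one-out
#'   coefficient and p), `cutoff`, `flagged`, `max_loo_p`.
#' @export
pgls_influence <- function(tree, y, x, cov_model = "pagel", param = NULL,
                           term = NULL, cutoff = NULL) {
  n <- length(tree$tip.label)
  if (n < 10) stop("need at least 10 tips")
  full <- pgls(tree, y, x, cov_model, param)
  if (is.null(term)) term <- full$coefficients$term[2]
  row <- match(term, full$coefficients$term)
  b_full <- full$coefficients$estimate[row]
  se_full <- full$coefficients$se[row]
  if (is.null(cutoff)) cutoff <- 2 / sqrt(n)
  out <- data.frame(language_id = tree$tip.label, dfbeta = NA_real_,
                    loo_estimate = NA_real_, loo_p = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tip <- tree$tip.label[i]
    sub_tree <- ape::drop.tip(tree, tip)
    res <- tryCatch(
      pgls(sub_tree, y, x, cov_model, param),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      r2 <- match(term, res$coefficients$term)
      out$loo_estimate[i] <- res$coefficients$estimate[r2]
      out$loo_p[i] <- res$coefficients$p[r2]
      out$dfbeta[i] <- (b_full - out$loo_estimate[i]) / se_full
      out$converged[i] <- TRUE
    }
  }
  flagged <- out$language_id[out$converged & abs(out$dfbeta) > cutoff]
  list(dfbeta = out, cutoff = cutoff, flagged = flagged,
       max_loo_p = max(out$loo_p, na.rm = TRUE), term = term,
       full = full)
}

#' Sweep PGLS over branch length and depth assumptions
#'
#' Rebuilds the tree from the classification at every combination of
#' within-family depth, root depth and (optionally) Grafen's rho, refits the
#' PGLS at each grid point, and reports coefficient, p and log-likelihood
#' per point together with the best-fitting point.
#'
#' @param classification classification table for [build_tree()].
#' @param y,x named tip vectors as [pgls()].
#' @param family_depth_grid,root_depth_grid numeric grids in years.
#' @param rho_grid optional grid of Grafen exponents; when supplied the
#'   built tree is Grafen-rescaled before fitting (rho sweep rows have
#'   `rho` set).
#' @param cov_model,param as [pgls()].
#' @return data.frame, one row per grid point, with attribute `"best"`
#'   giving the row index with maximal log-likelihood.
#' @export
branch_length_sweep <- function(classification, y, x,
                                family_depth_grid = 6000,
                                root_depth_grid = 60000,
                                rho_grid = NULL,
                                cov_model = "pagel", param = NULL) {
  stopifnot(length(family_depth_grid) >= 1, length(root_depth_grid) >= 1)
  grid <- expand.grid(family_depth = family_depth_grid,
                      root_depth = root_depth_grid,
                      rho = if (is.null(rho_grid)) NA_real_ else rho_grid)
  grid <- grid[grid$family_depth <= grid$root_depth, , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- build_tree(classification,
                     family_depth = max(grid$family_depth[i], 1),
                     root_depth = grid$root_depth[i])
    if (!is.na(grid$rho[i])) {
      tr <- grafen_rescale(tr, grid$rho[i], total_depth = grid$root_depth[i])
    }
    f <- tryCatch(pgls(tr, y, x, cov_model, param), error = function(e) NULL)
    if (is.null(f)) {
      data.frame(estimate = NA_real_, p = NA_real_, logLik = NA_real_,
                 param = NA_real_)
    } else {
      data.frame(estimate = f$coefficients$estimate[2],
                 p = f$coefficients$p[2], logLik = f$logLik,
                 param = f$param)
    }
  })
  out <- cbind(grid, do.call(rbind, res))
  rownames(out) <- NULL
  attr(out, "best") <- if (all(is.na(out$logLik))) NA_integer_ else
    which.max(out$logLik)
  out
}
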