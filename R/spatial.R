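#' Great-circle distance matrix between languages
#'
#' Haversine distances (km, sphere radius 6371 km) between language
#' locations. If a waypoint routing graph is supplied, pairs on different
#' continents are routed through the graph: the distance is the minimum over
#' entry/exit waypoints of direct legs plus the shortest waypoint path.
#' Routed distances are never shorter than the direct great circle.
#'
#' @param coords data.frame with `language_id`, `latitude`, `longitude`, and
#'   (when routing) `continent`.
#' @param waypoints optional list with `nodes` (data.frame `id`, `latitude`,
#'   `longitude`) and `edges` (data.frame `from`, `to`); edge weights are
#'   great-circle distances between the nodes.
#' @return symmetric km matrix with zero diagonal, dimnames = language ids.
#' @export
geodesic_matrix <- function(coords, waypoints = NULL) {
  stopifnot(all(c("language_id", "latitude", "longitude") %in% names(coords)))
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180)) {
    stop("invalid coordinates")
  }
  p <- as.matrix(coords[, c("longitude", "latitude")])
  r_m <- 6371 * 1000
  d <- geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = r_m)
  }) / 1000
  dimnames(d) <- list(coords$language_id, coords$language_id)

  if (!is.null(waypoints)) {
    if (!"continent" %in% names(coords)) {
      stop("waypoint routing needs a continent column")
    }
    wp <- waypoints$nodes
    wq <- as.matrix(wp[, c("longitude", "latitude")])
    n_w <- nrow(wp)
    # waypoint graph shortest paths (Floyd-Warshall; graphs are small)
    g <- matrix(Inf, n_w, n_w, dimnames = list(wp$id, wp$id))
    diag(g) <- 0
    for (e in seq_len(nrow(waypoints$edges))) {
      i <- match(waypoints$edges$from[e], wp$id)
      j <- match(waypoints$edges$to[e], wp$id)
      w <- geosphere::distHaversine(wq[i, ], wq[j, ], r = r_m) / 1000
      g[i, j] <- min(g[i, j], w)
      g[j, i] <- min(g[j, i], w)
    }
    for (k in seq_len(n_w)) {
      g <- pmin(g, outer(g[, k], g[k, ], `+`))
    }
    # language -> waypoint legs
    lw <- matrix(0, nrow(coords), n_w)
    for (j in seq_len(n_w)) {
      lw[, j] <- geosphere::distHaversine(p, wq[j, ], r = r_m) / 1000
    }
    cont <- coords$continent
    for (i in seq_len(nrow(coords) - 1)) {
      for (j in seq(i + 1, nrow(coords))) {
        if (cont[i] != cont[j]) {
          routed <- min(outer(lw[i, ], lw[j, ], `+`) + g)
          d[i, j] <- d[j, i] <- max(routed, d[i, j])
        }
      }
    }
  }
  d
}

# off-diagonal vectorisation helpers -------------------------------------

lower_vec <- function(m) m[lower.tri(m)]

check_same_labels <- function(a, b) {
  la <- rownames(a)
  lb <- rownames(b)
  if (is.null(la) || is.null(lb) || !identical(la, lb)) {
    stop("distance matrices must share identical labels in identical order")
  }
}

matrix_cor <- function(a, b, method) {
  stats::cor(lower_vec(a), lower_vec(b), method = method)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# permutations restricted to strata; returns a matrix of permutation rows
all_strata_perms <- function(strata) {
  groups <- split(seq_along(strata), strata)
  per_group <- lapply(groups, function(idx) {
    if (length(idx) == 1) return(matrix(idx, 1, 1))
    p <- all_perms(length(idx))
    matrix(idx[p], nrow(p), ncol(p))
  })
  grid <- expand.grid(lapply(per_group, function(m) seq_len(nrow(m))))
  out <- matrix(NA_integer_, nrow(grid), length(strata))
  for (r in seq_len(nrow(grid))) {
    for (gi in seq_along(per_group)) {
      out[r, groups[[gi]]] <- per_group[[gi]][grid[r, gi], ]
    }
  }
  out
}

random_strata_perm <- function(strata) {
  idx <- seq_along(strata)
  for (g in split(seq_along(strata), strata)) {
    if (length(g) > 1) idx[g] <- g[sample.int(length(g))]
  }
  idx
}

mantel_engine <- function(stat_fun, n, n_perm, seed, strata = NULL,
                          exhaustive_limit = 1e5) {
  r_obs <- suppressWarnings(stat_fun(seq_len(n)))
  if (!is.finite(r_obs)) stop("correlation undefined (constant matrix?)")
  n_space <- if (is.null(strata)) {
    lfactorial(n)
  } else {
    sum(vapply(split(seq_len(n), strata), function(g) lfactorial(length(g)),
               numeric(1)))
  }
  exhaustive <- n_space <= log(exhaustive_limit) && n_space <= log(n_perm + 1)
  if (exhaustive) {
    perms <- if (is.null(strata)) all_perms(n) else all_strata_perms(strata)
    r_perm <- apply(perms, 1, stat_fun)
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_used <- nrow(perms)
  } else {
    r_perm <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- if (is.null(strata)) sample.int(n) else random_strata_perm(strata)
        stat_fun(idx)
      }, numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive,
       r_perm = r_perm)
}

mantel_result <- function(r, p, n_perm, scope, method, exhaustive,
                          ci = c(NA_real_, NA_real_)) {
  structure(list(r = r, p = p, ci_low = ci[1], ci_high = ci[2],
                 n_perm = n_perm, scope = scope, method = method,
                 exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test (%s): r = %.4f, p = %.4g (%d permutations%s)\n",
              x$scope, x$method, x$r, x$p, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

boot_ci <- function(a, b, method, n_boot, seed) {
  n <- nrow(a)
  withr_seed(seed + 1L, {
    rs <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      suppressWarnings(matrix_cor(a[idx, idx], b[idx, idx], method))
    }, numeric(1))
    stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the off-diagonal entries of two labelled distance matrices and
#' assesses significance by permuting the labels of the second matrix. The
#' default p-value is two-sided on `|r|`:
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm)`. When the permutation
#' space is small enough the test enumerates it exhaustively.
#'
#' @param a,b labelled symmetric distance matrices with identical labels.
#' @param method correlation: `"spearman"` (default), `"pearson"`,
#'   `"kendall"`.
#' @param n_perm number of random permutations (>= 99).
#' @param seed integer RNG seed.
#' @param ci compute a percentile bootstrap CI over label resampling.
#' @param n_boot bootstrap draws for the CI.
#' @return a `"mantel_result"`: `r`, `p`, `ci_low`/`ci_high`, `n_perm`,
#'   `scope`, `method`.
#' @export
mantel_test <- function(a, b, method = "spearman", n_perm = 999, seed = 1,
                        ci = FALSE, n_boot = 1000) {
  check_same_labels(a, b)
  if (n_perm < 99) stop("n_perm must be >= 99")
  n <- nrow(a)
  stat <- function(idx) matrix_cor(a, b[idx, idx], method)
  eng <- mantel_engine(stat, n, n_perm, seed)
  ci_v <- if (ci) boot_ci(a, b, method, n_boot, seed) else c(NA_real_, NA_real_)
  mantel_result(eng$r, eng$p, eng$n_perm, "simple", method, eng$exhaustive,
                ci_v)
}

# residualize matrix entries on control matrices (Smouse-Long-Sokal);
# operates on the off-diagonal vector and reshapes back to a matrix
residual_matrix <- function(m, controls, rank_transform) {
  v <- lower_vec(m)
  if (rank_transform) v <- rank(v)
  x <- do.call(cbind, lapply(controls, function(cm) {
    w <- lower_vec(cm)
    if (rank_transform) rank(w) else w
  }))
  res <- stats::lm.fit(cbind(1, x), v)$residuals
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  out[lower.tri(out)] <- res
  out + t(out)
}

#' Partial Mantel test
#'
#' Residualises both focal matrices on one or more control distance matrices
#' (entrywise regression of the off-diagonal vectors), then runs a Mantel
#' permutation test on the residual matrices. For `method = "spearman"` the
#' vectors are rank-transformed before residualisation.
#'
#' @inheritParams mantel_test
#' @param controls list of control distance matrices (same labels).
#' @return a `"mantel_result"` with scope `"partial"`.
#' @export
partial_mantel <- function(a, b, controls, method = "spearman",
                           n_perm = 999, seed = 1, ci = FALSE,
                           n_boot = 1000) {
  if (!is.list(controls) || length(controls) < 1) {
    stop("need at least one control matrix")
  }
  check_same_labels(a, b)
  for (cm in controls) check_same_labels(a, cm)
  if (n_perm < 99) stop("n_perm must be >= 99")
  rank_tf <- method == "spearman"
  for (cm in controls) {
    if (abs(matrix_cor(a, cm, method)) > 1 - 1e-10 ||
        abs(matrix_cor(b, cm, method)) > 1 - 1e-10) {
      stop("control matrix collinear with a focal matrix")
    }
  }
  ra <- residual_matrix(a, controls, rank_tf)
  rb <- residual_matrix(b, controls, rank_tf)
  inner_method <- if (rank_tf) "pearson" else method
  n <- nrow(a)
  stat <- function(idx) matrix_cor(ra, rb[idx, idx], inner_method)
  eng <- mantel_engine(stat, n, n_perm, seed)
  ci_v <- if (ci) boot_ci(ra, rb, inner_method, n_boot, seed) else
    c(NA_real_, NA_real_)
  mantel_result(eng$r, eng$p, eng$n_perm, "partial", method, eng$exhaustive,
                ci_v)
}

#' Stratified Mantel test
#'
#' As [mantel_test()] but label permutations are restricted to occur within
#' the given strata (typically language families), so languages are only
#' ever exchanged with members of their own family. Singleton strata are
#' fixed points. Optionally residualises on control matrices first, giving a
#' stratified partial test.
#'
#' @inheritParams mantel_test
#' @param strata named vector (names = labels) assigning each label to a
#'   stratum.
#' @param controls optional list of control matrices, as [partial_mantel()].
#' @return a `"mantel_result"` with scope `"stratified"`.
#' @export
stratified_mantel <- function(a, b, strata, method = "kendall",
                              controls = NULL, n_perm = 999, seed = 1) {
  check_same_labels(a, b)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!all(rownames(a) %in% names(strata))) {
    stop("every label needs a stratum")
  }
  s <- as.character(strata[rownames(a)])
  if (all(table(s) == 1)) stop("all strata are singletons: nothing to permute")
  if (!is.null(controls)) {
    rank_tf <- method == "spearman"
    a <- residual_matrix(a, controls, rank_tf)
    b <- residual_matrix(b, controls, rank_tf)
    if (rank_tf) method <- "pearson"
  }
  n <- nrow(a)
  stat <- function(idx) matrix_cor(a, b[idx, idx], method)
  eng <- mantel_engine(stat, n, n_perm, seed, strata = s)
  mantel_result(eng$r, eng$p, eng$n_perm, "stratified", method,
                eng$exhaustive)
}

#' Moran's I spatial autocorrelation
#'
#' Inverse-distance weights (self-weight zero), row-standardised, with the
#' analytic null expectation `-1/(n-1)` and a normal-approximation p-value
#' (delegates the moment computation to [ape::Moran.I()]).
#'
#' @param values named numeric vector per language.
#' @param coords data.frame with `language_id`, `latitude`, `longitude`
#'   covering the names of `values`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list: `observed`, `expected`, `sd`, `p`, `n`, `weights`.
#' @export
morans_i <- function(values, coords, alternative = "two.sided") {
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by language id")
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  coords <- coords[match(ids, coords$language_id), ]
  d <- geodesic_matrix(coords)
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- max(w[is.finite(w)]) # coincident points
  w <- w / rowSums(w)
  m <- ape::Moran.I(as.numeric(values), weight = w, scaled = FALSE,
                    alternative = alternative)
  list(observed = m$observed, expected = m$expected, sd = m$sd,
       p = m$p.value, n = length(values), weights = w)
}

# Gaussian-kernel GWR internals ------------------------------------------

gwr_at_bandwidth <- function(y, x, d, bw) {
  n <- length(y)
  xm <- cbind(1, x)
  p <- ncol(xm)
  coefs <- matrix(NA_real_, n, p)
  s_diag <- numeric(n)
  fitted <- numeric(n)
  smat <- matrix(0, n, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    w <- exp(-0.5 * (d[i, ] / bw)^2)
    xtw <- t(xm * w)
    xtx <- xtw %*% xm
    inv <- tryCatch(solve(xtx), error = function(e) NULL)
    if (is.null(inv)) {
      ok[i] <- FALSE
      next
    }
    si <- xm[i, , drop = FALSE] %*% inv %*% xtw
    smat[i, ] <- si
    s_diag[i] <- si[i]
    coefs[i, ] <- inv %*% xtw %*% y
    fitted[i] <- si %*% y
  }
  list(coefs = coefs, fitted = fitted, smat = smat, ok = ok)
}

gwr_aicc <- function(y, x, d, bw) {
  fit <- gwr_at_bandwidth(y, x, d, bw)
  if (any(!fit$ok)) return(Inf)
  n <- length(y)
  rss <- sum((y - fit$fitted)^2)
  tr_s <- sum(diag(fit$smat))
  if (n - 2 - tr_s <= 0) return(Inf)
  n * log(rss / n) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
}

#' Geographically weighted regression
#'
#' Locally weighted least squares at every site with a Gaussian kernel on
#' great-circle distance. The bandwidth (km) is chosen by minimising the
#' corrected AIC when not supplied. Reports local coefficients, the global
#' OLS coefficient, AICc, residual sum of squares, a quasi-global R-squared,
#' and an F comparison of the GWR and OLS residual variances.
#'
#' @param y response per language (named vector).
#' @param x single predictor per language (named vector, same names).
#' @param coords data.frame with `language_id`, `latitude`, `longitude`.
#' @param bandwidth optional fixed kernel bandwidth in km.
#' @return object of class `"gwr_fit"`.
#' @export
gwr <- function(y, x, coords, bandwidth = NULL) {
  ids <- names(y)
  stopifnot(!is.null(ids), identical(ids, names(x)))
  if (length(y) < 10) stop("need at least 10 sites")
  coords <- coords[match(ids, coords$language_id), ]
  d <- geodesic_matrix(coords)
  if (is.null(bandwidth)) {
    lo <- stats::quantile(d[d > 0], 0.05)
    hi <- max(d)
    opt <- stats::optimize(function(b) gwr_aicc(y, x, d, b), c(lo, hi))
    bandwidth <- opt$minimum
  }
  fit <- gwr_at_bandwidth(y, x, d, bandwidth)
  n <- length(y)
  rss <- sum((y - fit$fitted)^2, na.rm = TRUE)
  tr_s <- sum(diag(fit$smat))
  ols <- stats::lm(y ~ x)
  rss_ols <- sum(stats::residuals(ols)^2)
  edf_gwr <- n - 2 * tr_s + sum(fit$smat^2) # effective residual df
  df_ols <- n - 2
  f_stat <- (rss / edf_gwr) / (rss_ols / df_ols)
  p_f <- stats::pf(f_stat, edf_gwr, df_ols)
  aicc <- gwr_aicc(y, x, d, bandwidth)
  structure(list(
    bandwidth = bandwidth,
    local_coefficients = data.frame(language_id = ids,
                                    intercept = fit$coefs[, 1],
                                    slope = fit$coefs[, 2]),
    global_coefficient = unname(stats::coef(ols)[2]),
    aicc = aicc, rss = rss, rss_ols = rss_ols,
    quasi_r2 = 1 - rss / sum((y - mean(y))^2),
    f_statistic = f_stat, f_df1 = edf_gwr, f_df2 = df_ols, f_p = p_f,
    effective_parameters = tr_s, n = n,
    failed_sites = ids[!fit$ok]
  ), class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf(paste0("GWR: bandwidth = %.1f km, global coefficient = %.4f,",
                     " AICc = %.2f\n  RSS = %.2f (OLS %.2f), quasi-R2 = %.3f,",
                     " F = %.4f (df %.1f, %d), p = %.3g\n"),
              x$bandwidth, x$global_coefficient, x$aicc, x$rss, x$rss_ols,
              x$quasi_r2, x$f_statistic, x$f_df1, x$f_df2, x$f_p))
  invisible(x)
}
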