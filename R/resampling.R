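#' Independent-family Monte-Carlo comparison of trait classes
#'
#' Per replicate, draws one strong-FTR language from every family that has
#' at least one, and one weak-FTR language from every family that has at
#' least one (families lacking a class are skipped for that class, or the
#' replicate restricted to families with both classes when
#' `require_both = TRUE`). The two sample means of the residualised savings
#' trait are compared; the reported proportion is the fraction of
#' replicates in which the strong-FTR mean is strictly lower (ties count
#' as failures).
#'
#' @param residuals data.frame with `language_id` and `residual` (as
#'   [language_residuals()]), or a named numeric vector.
#' @param meta language metadata with `language_id`, `ftr`, `family`.
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed integer RNG seed.
#' @param require_both restrict to families containing both classes.
#' @return list: `prop_strong_lower`, `n_reps`, `n_families_strong`,
#'   `n_families_weak`.
#' @export
independent_family_samples <- function(residuals, meta, n_reps = 10000,
                                       seed = 1, require_both = FALSE) {
  if (is.data.frame(residuals)) {
    res <- stats::setNames(residuals$residual, residuals$language_id)
  } else {
    res <- residuals
  }
  meta <- meta[meta$language_id %in% names(res), , drop = FALSE]
  strong <- split(meta$language_id[meta$ftr == "strong"],
                  meta$family[meta$ftr == "strong"])
  weak <- split(meta$language_id[meta$ftr == "weak"],
                meta$family[meta$ftr == "weak"])
  if (require_both) {
    fams <- intersect(names(strong), names(weak))
    strong <- strong[fams]
    weak <- weak[fams]
  }
  if (length(strong) == 0 || length(weak) == 0) {
    stop("a trait class is absent from every family")
  }
  if (length(strong) < 2 || length(weak) < 2) {
    stop("need >= 2 families containing each class")
  }
  pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)
  lower <- withr_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      m_s <- mean(res[vapply(strong, pick1, character(1))])
      m_w <- mean(res[vapply(weak, pick1, character(1))])
      m_s < m_w
    }, logical(1))
  })
  list(prop_strong_lower = mean(lower), n_reps = n_reps,
       n_families_strong = length(strong), n_families_weak = length(weak))
}

# deduplicated permutations, global or within-family
draw_permutations <- function(values, families, scope, n_perm, seed) {
  n <- length(values)
  withr_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", n_perm)
    got <- 0L
    attempts <- 0L
    max_attempts <- n_perm * 50L
    while (got < n_perm && attempts < max_attempts) {
      attempts <- attempts + 1L
      idx <- if (scope == "global") {
        sample.int(n)
      } else {
        random_strata_perm(families)
      }
      key <- paste(values[idx], collapse = "\r")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- idx
    }
    out[seq_len(got)]
  })
}

#' Permutation test around the PGLS fit
#'
#' Refits the PGLS after randomly re-assigning the trait (`ftr`), the
#' response (`savings`), or both, without replacement, either globally or
#' only within language families. Permutations are deduplicated on the
#' permuted value sequence. Reports the fraction of converged permutations
#' with a larger absolute coefficient, the fraction with a coefficient both
#' negative and lower than observed, and the median distance of the
#' stronger permutations from the original data (Hamming count for the
#' binary trait, mean absolute relative difference for the response).
#'
#' @param tree,y,x,cov_model,param as [pgls()]; `x` a named binary vector.
#' @param permute which variable(s) to permute: `"ftr"`, `"savings"`,
#'   `"both"`.
#' @param scope `"global"` or `"within_family"`.
#' @param families named vector (tip label -> family); required for
#'   within-family scope.
#' @param n_perm number of unique permutations (>= 99).
#' @param seed integer RNG seed.
#' @return a `"permutation_summary"` list.
#' @export
permute_trait_test <- function(tree, y, x, cov_model = "pagel",
                               param = NULL,
                               permute = c("ftr", "savings", "both"),
                               scope = c("global", "within_family"),
                               families = NULL, n_perm = 999, seed = 1) {
  permute <- match.arg(permute)
  scope <- match.arg(scope)
  if (n_perm < 99) stop("n_perm must be >= 99")
  tips <- tree$tip.label
  xv <- x[tips]
  yv <- y[tips]
  if (length(unique(xv)) == 1 && permute %in% c("ftr", "both")) {
    warning("trait is constant: all permutations identical")
    return(structure(list(n_perm = 0L, n_converged = 0L,
                          prop_abs_stronger = 0, prop_signed_stronger = 0,
                          scope = scope, permuted = permute,
                          median_changes = NA_real_),
                     class = "permutation_summary"))
  }
  fam <- if (scope == "within_family") {
    if (is.null(families)) stop("within_family scope needs families")
    as.character(families[tips])
  } else {
    NULL
  }
  base <- pgls(tree, yv, xv, cov_model, param)
  b_obs <- base$coefficients$estimate[2]
  seeds <- derive_seeds(seed, 2)
  perm_x <- if (permute %in% c("ftr", "both")) {
    draw_permutations(xv, fam, scope, n_perm, seeds[1])
  } else {
    NULL
  }
  perm_y <- if (permute %in% c("savings", "both")) {
    draw_permutations(yv, fam, scope, n_perm, seeds[2])
  } else {
    NULL
  }
  n_eff <- max(length(perm_x), length(perm_y))
  b_perm <- rep(NA_real_, n_eff)
  changes <- rep(NA_real_, n_eff)
  for (i in seq_len(n_eff)) {
    xi <- if (is.null(perm_x)) xv else {
      v <- xv[perm_x[[i]]]
      names(v) <- tips
      v
    }
    yi <- if (is.null(perm_y)) yv else {
      v <- yv[perm_y[[i]]]
      names(v) <- tips
      v
    }
    f <- tryCatch(pgls(tree, yi, xi, cov_model, param),
                  error = function(e) NULL)
    if (!is.null(f)) b_perm[i] <- f$coefficients$estimate[2]
    changes[i] <- if (permute == "savings") {
      mean(abs(yi - yv) / pmax(abs(yv), .Machine$double.eps))
    } else {
      sum(xi != xv)
    }
  }
  conv <- is.finite(b_perm)
  stronger <- conv & abs(b_perm) > abs(b_obs)
  structure(list(
    n_perm = n_eff, n_converged = sum(conv),
    prop_abs_stronger = if (any(conv)) mean(abs(b_perm[conv]) > abs(b_obs)) else 0,
    prop_signed_stronger = if (any(conv)) {
      mean(b_perm[conv] < 0 & b_perm[conv] < b_obs)
    } else {
      0
    },
    scope = scope, permuted = permute,
    median_changes = if (any(stronger)) stats::median(changes[stronger])
                     else NA_real_,
    observed = b_obs
  ), class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(paste0("Permutation test (%s, %s scope): %d/%d converged\n",
                     "  |coef| stronger: %.3f, negative & lower: %.3f",
                     " (observed %.4f)\n"),
              x$permuted, x$scope, x$n_converged, x$n_perm,
              x$prop_abs_stronger, x$prop_signed_stronger,
              if (is.null(x$observed)) NA_real_ else x$observed))
  invisible(x)
}
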