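# Independent oracles and fixture builders used across the suite.

# small fixed classification: 3 families x 2 genera x 2 languages
fixture_classification <- function() {
  data.frame(
    family = rep(c("F1", "F2", "F3"), each = 4),
    genus = rep(sprintf("g%d", 1:6), each = 2),
    language_id = sprintf("L%02d", 1:12),
    stringsAsFactors = FALSE
  )
}

# brute-force parsimony: minimise changes over every internal labelling
oracle_parsimony <- function(tree, trait) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  states <- sort(unique(as.numeric(trait)))
  tip_state <- as.numeric(trait[tree$tip.label])
  grids <- rev(expand.grid(rep(list(states), n_node)))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    lab <- c(tip_state, as.numeric(grids[r, ]))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute-force path-sum patristic distance via node paths
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      path <- ape::nodepath(tree, i, j)
      # sum edge lengths along the path (exclude the MRCA's stem)
      mrca <- ape::getMRCA(tree, c(i, j))
      d <- sum(elen[setdiff(path, mrca)])
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

# exhaustive Mantel p-value: proportion of all label permutations of b
# whose |correlation| is at least the observed one
oracle_mantel_exhaustive <- function(a, b, method = "spearman",
                                     strata = NULL) {
  n <- nrow(a)
  va <- a[lower.tri(a)]
  r_obs <- stats::cor(va, b[lower.tri(b)], method = method)
  perms <- if (is.null(strata)) {
    m <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    m[apply(m, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
  } else {
    groups <- split(seq_len(n), strata)
    base <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    base <- base[apply(base, 1, function(r) !anyDuplicated(r)), ,
                 drop = FALSE]
    ok <- apply(base, 1, function(r) {
      all(vapply(groups, function(g) setequal(r[g], g), logical(1)))
    })
    base[ok, , drop = FALSE]
  }
  rs <- apply(perms, 1, function(idx) {
    stats::cor(va, b[idx, idx][lower.tri(b)], method = method)
  })
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12),
       n_perm = nrow(perms))
}

# exhaustive conditional log-likelihood of a binned logistic model:
# within each bin, condition on the number of successes and enumerate the
# outcome arrangements
oracle_conditional_loglik <- function(y, x, bin, beta) {
  ll <- 0
  for (b in unique(bin)) {
    idx <- which(bin == b)
    yb <- y[idx]
    xb <- x[idx, , drop = FALSE]
    k <- sum(yb)
    if (k == 0 || k == length(yb)) next
    eta <- as.numeric(xb %*% beta)
    num <- sum(eta[yb == 1])
    sets <- utils::combn(length(yb), k)
    denom <- log(sum(apply(sets, 2, function(s) exp(sum(eta[s])))))
    ll <- ll + num - denom
  }
  ll
}

# closed-form GLS estimates by direct matrix inversion
oracle_gls <- function(y, x, v) {
  vi <- solve(v)
  xtvx <- t(x) %*% vi %*% x
  beta <- solve(xtvx, t(x) %*% vi %*% y)
  res <- y - x %*% beta
  n <- length(y)
  p <- ncol(x)
  sigma2 <- as.numeric(t(res) %*% vi %*% res) / (n - p)
  se <- sqrt(diag(solve(xtvx)) * sigma2)
  list(beta = as.numeric(beta), se = se)
}

# small labelled distance matrix from a seeded point configuration
random_distance_matrix <- function(n, seed, labels = sprintf("t%d", 1:n)) {
  set.seed(seed)
  pts <- matrix(rnorm(2 * n), n, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(labels, labels)
  d
}

# scenario small enough for fast GLMM fits
small_glmm_scenario <- function(seed, beta_ftr = 0.4, sd = 0.3,
                                n_per_language = 60) {
  cls <- simulate_taxonomy(n_families = 6, genera_per_family = 2,
                           languages_per_genus = 2, seed = seed)
  tree <- build_tree(cls)
  ftr <- simulate_binary_trait(tree, "mk2", q01 = 5e-5, q10 = 5e-5,
                               seed = seed + 1)
  if (length(unique(ftr)) == 1) ftr[seq_len(12)] <- rep(0:1, 6)
  coords <- simulate_coordinates(tree, 5000, seed = seed + 2)
  meta <- simulate_language_meta(cls, tree, ftr, coords, n_areas = 3,
                                 n_countries = 8, seed = seed + 3)
  resp <- simulate_respondents(meta, beta_ftr = beta_ftr, intercept = -0.5,
                               sd_country = sd, sd_family = sd,
                               sd_area = sd,
                               n_per_language = n_per_language,
                               seed = seed + 4)
  list(meta = meta, respondents = resp, tree = tree, coords = coords,
       classification = cls, ftr = ftr)
}
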