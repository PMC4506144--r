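test_that("PGLS with lambda fixed at 0 reproduces OLS exactly", {
  set.seed(1)
  tr <- ape::rcoal(20) # ultrametric: lambda = 0 gives an identity-like V
  x <- setNames(rnorm(20), tr$tip.label)
  y <- setNames(0.5 * x + rnorm(20), tr$tip.label)
  fit <- pgls(tr, y, x, cov_model = "pagel", param = 0)
  ols <- summary(lm(y[tr$tip.label] ~ x[tr$tip.label]))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ols[, 1]),
               tolerance = 1e-6)
  expect_equal(fit$coefficients$se, unname(ols[, 2]), tolerance = 1e-6)
  expect_equal(fit$coefficients$t, unname(ols[, 3]), tolerance = 1e-6)
})

test_that("PGLS with fixed covariance equals closed-form GLS on small trees", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    y <- setNames(rnorm(n), tr$tip.label)
    for (spec in list(list(m = "BM", p = NULL), list(m = "pagel", p = 0.6),
                      list(m = "OU", p = 0.8),
                      list(m = "grafen", p = 0.5))) {
      fit <- pgls(tr, y, x, cov_model = spec$m, param = spec$p)
      v <- galton:::pgls_covariance(tr, spec$m, spec$p)
      orc <- oracle_gls(y[tr$tip.label],
                        cbind(1, x[tr$tip.label]), v)
      expect_equal(fit$coefficients$estimate, orc$beta, tolerance = 1e-6)
      expect_equal(fit$coefficients$se, orc$se, tolerance = 1e-6)
    }
  }
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(5)
  tr <- ape::rcoal(25)
  tr$edge.length <- tr$edge.length * 10
  x <- setNames(rnorm(25), tr$tip.label)
  y <- setNames(0.4 * x + rnorm(25), tr$tip.label)
  dat <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                    spp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corBrownian(1, tr, form = ~ spp),
                   method = "ML")
  fit <- pgls(tr, y, x, cov_model = "BM")
  expect_equal(unname(coef(fit)["x"]), unname(coef(ref)["x"]),
               tolerance = 1e-8)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("lambda estimation: destroyed signal near 0, BM signal near 1", {
  cls <- simulate_taxonomy(10, 2, 3, seed = 71)
  tr <- build_tree(cls)
  y_bm <- simulate_continuous_trait(tr, "BM", sigma2 = 1 / 60000,
                                    n_replicates = 1, seed = 72)[1, ]
  sig <- pagel_lambda(tr, y_bm)
  expect_gt(sig$estimate, 0.6)
  set.seed(73)
  lams <- vapply(1:20, function(i) {
    shuffled <- setNames(sample(y_bm), names(y_bm))
    pagel_lambda(tr, shuffled)$estimate
  }, numeric(1))
  expect_lt(median(lams), 0.1)
  expect_error(pagel_lambda(tr, setNames(rep(1, length(tr$tip.label)),
                                         tr$tip.label)),
               "constant")
})

test_that("lambda agrees with phytools::phylosig", {
  skip_if_not_installed("phytools")
  cls <- simulate_taxonomy(8, 2, 3, seed = 74)
  tr <- ape::multi2di(build_tree(cls))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  y <- simulate_continuous_trait(tr, "pagel_lambda", sigma2 = 1 / 60000,
                                 lam = 0.6, n_replicates = 1,
                                 seed = 75)[1, ]
  ours <- pagel_lambda(tr, y)
  ref <- phytools::phylosig(tr, y[tr$tip.label], method = "lambda")
  expect_equal(ours$estimate, ref$lambda, tolerance = 0.02)
  expect_equal(ours$logLik, ref$logL, tolerance = 0.05)
})

test_that("signal statistics are invariant to tip-storage order", {
  cls <- simulate_taxonomy(6, 2, 2, seed = 81)
  tr <- build_tree(cls)
  y <- simulate_continuous_trait(tr, "BM", sigma2 = 1 / 60000,
                                 n_replicates = 1, seed = 82)[1, ]
  b <- simulate_binary_trait(tr, "threshold", sigma2 = 1 / 60000, seed = 83)
  perm <- sample(names(y))
  expect_equal(pagel_lambda(tr, y)$estimate,
               pagel_lambda(tr, y[perm])$estimate, tolerance = 1e-8)
  expect_equal(fritz_purvis_d(tr, b, n_sim = 200, seed = 9)$estimate,
               fritz_purvis_d(tr, b[perm], n_sim = 200, seed = 9)$estimate,
               tolerance = 1e-12)
})

test_that("Fritz-Purvis D anchors: shuffled traits near 1, threshold-BM near 0", {
  cls <- simulate_taxonomy(10, 2, 3, seed = 91)
  tr <- build_tree(cls)
  base <- simulate_binary_trait(tr, "threshold", sigma2 = 1 / 60000,
                                seed = 92)
  set.seed(93)
  d_shuf <- vapply(1:15, function(i) {
    shuffled <- setNames(sample(base), names(base))
    fritz_purvis_d(tr, shuffled, n_sim = 400, seed = i)$estimate
  }, numeric(1))
  expect_equal(mean(d_shuf), 1, tolerance = 0.25)
  d_bm <- vapply(1:15, function(i) {
    b <- simulate_binary_trait(tr, "threshold", sigma2 = 1 / 60000,
                               seed = 200 + i)
    if (length(unique(b)) == 1) return(NA_real_)
    fritz_purvis_d(tr, b, n_sim = 400, seed = i)$estimate
  }, numeric(1))
  expect_equal(mean(d_bm, na.rm = TRUE), 0, tolerance = 0.25)
  expect_error(fritz_purvis_d(tr, setNames(rep(1, length(base)),
                                           names(base)), n_sim = 200),
               "monomorphic")
})

test_that("influence diagnostics: symmetry on exchangeable tips and definitional dfbeta", {
  # star-like tree: all tips exchangeable
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:12), collapse = ","), ");"))
  x <- setNames(rep(c(0, 1), 6), star$tip.label)
  y <- setNames(rep(c(0.2, 0.9), 6), star$tip.label)
  y <- y + rep(c(-0.01, 0.01), each = 6) # break exact ties mildly
  inf <- pgls_influence(star, y, x, cov_model = "BM")
  # dfbeta recomputed by explicit refit equals the reported value
  i <- 3
  full <- pgls(star, y, x, cov_model = "BM")
  sub <- pgls(ape::drop.tip(star, star$tip.label[i]), y, x,
              cov_model = "BM")
  manual <- (full$coefficients$estimate[2] - sub$coefficients$estimate[2]) /
    full$coefficients$se[2]
  expect_equal(inf$dfbeta$dfbeta[i], manual, tolerance = 1e-10)
  expect_equal(inf$cutoff, 2 / sqrt(12))
  expect_true(all(inf$dfbeta$converged))

  # a planted outlier is flagged
  cls <- simulate_taxonomy(8, 2, 2, seed = 95)
  tr <- build_tree(cls)
  n <- length(tr$tip.label)
  xx <- setNames(rep(c(0, 1), length.out = n), tr$tip.label)
  set.seed(96)
  yy <- setNames(0.3 * xx + rnorm(n, 0, 0.2), tr$tip.label)
  yy[5] <- yy[5] + 5
  inf2 <- pgls_influence(tr, yy, xx, cov_model = "pagel")
  expect_true(tr$tip.label[5] %in% inf2$flagged)
})

test_that("branch-length sweep: one-point grid equals a single fit, best point self-consistent", {
  cls <- fixture_classification()
  tr <- build_tree(cls)
  xv <- setNames(rep(c(0, 1), 6), tr$tip.label)
  yv <- simulate_continuous_trait(tr, "BM", sigma2 = 1 / 60000,
                                  n_replicates = 1, seed = 97)[1, ] +
    0.4 * xv
  single <- branch_length_sweep(cls, yv, xv, 6000, 60000,
                                cov_model = "pagel")
  direct <- pgls(tr, yv, xv, cov_model = "pagel")
  expect_equal(nrow(single), 1)
  expect_equal(single$estimate, direct$coefficients$estimate[2],
               tolerance = 1e-10)
  expect_equal(single$logLik, direct$logLik, tolerance = 1e-10)

  grid <- branch_length_sweep(cls, yv, xv,
                              family_depth_grid = c(3000, 6000, 12000),
                              root_depth_grid = c(30000, 60000),
                              cov_model = "pagel")
  expect_equal(nrow(grid), 6)
  expect_true(is.finite(attr(grid, "best")))
  # rho sweep rows carry the exponent
  rg <- branch_length_sweep(cls, yv, xv, 6000, 60000,
                            rho_grid = c(0.15, 1), cov_model = "pagel")
  expect_equal(rg$rho, c(0.15, 1))
  expect_true(all(is.finite(rg$logLik)))
})
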