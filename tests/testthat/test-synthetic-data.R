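test_that("taxonomy generator honours counts, ranges and seeds", {
  cls <- simulate_taxonomy(3, 2, 2, seed = 1)
  expect_equal(nrow(cls), 12)
  expect_equal(length(unique(cls$family)), 3)
  expect_equal(anyDuplicated(cls$language_id), 0)

  single <- simulate_taxonomy(1, 1, 1, seed = 1)
  expect_equal(nrow(single), 1)

  rng <- simulate_taxonomy(10, c(1, 3), c(2, 4), seed = 5)
  gen_per_fam <- tapply(rng$genus, rng$family,
                        function(v) length(unique(v)))
  expect_true(all(gen_per_fam >= 1 & gen_per_fam <= 3))
  lang_per_gen <- table(rng$genus)
  expect_true(all(lang_per_gen >= 2 & lang_per_gen <= 4))

  expect_identical(simulate_taxonomy(5, c(1, 3), c(1, 4), seed = 9),
                   simulate_taxonomy(5, c(1, 3), c(1, 4), seed = 9))
})

test_that("continuous trait replicates reproduce the model covariance", {
  cls <- fixture_classification()
  tr <- build_tree(cls)
  # zero rate: every tip equals the root state
  flat <- simulate_continuous_trait(tr, "BM", sigma2 = 0, root_state = 3,
                                    n_replicates = 5, seed = 1)
  expect_true(all(flat == 3))

  # BM: Var(tip) ~ depth, Cov ~ shared path length (Monte Carlo)
  sig2 <- 1 / 60000
  x <- simulate_continuous_trait(tr, "BM", sigma2 = sig2,
                                 n_replicates = 10000, seed = 2)
  v <- cov(x)
  expect_equal(v["L01", "L01"], sig2 * 60000, tolerance = 0.05)
  expect_equal(v["L01", "L02"], sig2 * (60000 - 3000), tolerance = 0.08)
  expect_equal(v["L01", "L05"], 0, tolerance = 0.05)

  # lambda = 0 removes off-diagonal covariance
  x0 <- simulate_continuous_trait(tr, "pagel_lambda", sigma2 = sig2,
                                  lam = 0, n_replicates = 10000, seed = 3)
  v0 <- cov(x0)
  off <- v0[lower.tri(v0)]
  expect_lt(max(abs(off)), 0.05)

  expect_error(simulate_continuous_trait(tr, "OU", alpha = 0), "alpha")
})

test_that("binary trait generator is deterministic and rate-monotone", {
  cls <- fixture_classification()
  tr <- build_tree(cls)
  frozen <- simulate_binary_trait(tr, "mk2", q01 = 0, q10 = 0,
                                  root_state = 1, seed = 1)
  expect_true(all(frozen == 1))
  expect_identical(simulate_binary_trait(tr, "mk2", q01 = 2e-5, q10 = 2e-5,
                                         seed = 4),
                   simulate_binary_trait(tr, "mk2", q01 = 2e-5, q10 = 2e-5,
                                         seed = 4))
  # higher rates imply more parsimony changes (median over replicates)
  score_at <- function(q, seeds) {
    vapply(seeds, function(s) {
      tra <- simulate_binary_trait(tr, "mk2", q01 = q, q10 = q, seed = s)
      fitch_parsimony(tr, tra)
    }, integer(1))
  }
  lo <- median(score_at(2e-6, 1:40))
  hi <- median(score_at(5e-5, 1:40))
  expect_gt(hi, lo)
  expect_error(simulate_binary_trait(tr, "mk2", q01 = -1), "non-negative")
})

test_that("respondent simulator matches its analytic marginal probability", {
  cls <- fixture_classification()
  tr <- build_tree(cls)
  ftr <- setNames(rep(c(0L, 1L), 6), tr$tip.label)
  coords <- simulate_coordinates(tr, 3000, seed = 1)
  meta <- simulate_language_meta(cls, tr, ftr, coords, n_areas = 2,
                                 n_countries = 4, seed = 1)
  # all effects zero: pooled saving proportion 0.5
  flat <- simulate_respondents(meta, n_per_language = 400, seed = 2)
  expect_equal(mean(flat$saved), 0.5, tolerance = 0.02)
  expect_equal(nrow(flat), 12 * 400)

  # no slopes: marginal P(save) is the logit-normal average
  b0 <- -0.8
  sds <- c(0.6, 0.4, 0.3)
  props <- vapply(1:15, function(s) {
    mean(simulate_respondents(meta, intercept = b0, sd_country = sds[1],
                              sd_family = sds[2], sd_area = sds[3],
                              n_per_language = 400, seed = s)$saved)
  }, numeric(1))
  s_tot <- sqrt(sum(sds^2))
  analytic <- integrate(function(z) plogis(b0 + s_tot * z) * dnorm(z),
                        -Inf, Inf)$value
  # averaged over replicate group-effect draws to tame group-level noise
  expect_equal(mean(props), analytic, tolerance = 0.05)

  # large family SD: between-family variance dominates
  sim2 <- simulate_respondents(meta, sd_family = 2, n_per_language = 300,
                               seed = 4)
  p_lang <- tapply(sim2$saved, sim2$language_id, mean)
  fam <- meta$family[match(names(p_lang), meta$language_id)]
  between <- var(tapply(p_lang, fam, mean))
  within <- mean(tapply(p_lang, fam, var))
  expect_gt(between, within)

  expect_error(simulate_respondents(meta[, -2]), "columns")
})

test_that("coordinates respect clamping, heritability and zero dispersal", {
  cls <- fixture_classification()
  tr <- build_tree(cls)
  fixed <- simulate_coordinates(tr, 0, root_location = c(10, 20), seed = 1)
  expect_true(all(fixed$latitude == 10 & fixed$longitude == 20))

  co <- simulate_coordinates(tr, 8000, seed = 2)
  expect_true(all(co$latitude >= -90 & co$latitude <= 90))
  expect_true(all(co$longitude >= -180 & co$longitude <= 180))

  # relatives closer in expectation: within-family pairs vs cross-family
  d <- geodesic_matrix(co)
  fam <- cls$family[match(rownames(d), cls$language_id)]
  same <- outer(fam, fam, `==`) & upper.tri(d)
  diff <- !outer(fam, fam, `==`) & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("inherited traits on simulated coordinates show spatial clustering", {
  # pipeline property: a trait that diffuses down the tree plus Brownian
  # dispersal of locations yields positive Moran's I in most replicates
  cls <- simulate_taxonomy(10, 2, 3, seed = 8)
  tr <- build_tree(cls)
  hits <- vapply(1:10, function(s) {
    y <- simulate_continuous_trait(tr, "BM", sigma2 = 1 / 60000,
                                   n_replicates = 1, seed = s)[1, ]
    co <- simulate_coordinates(tr, 9000, seed = s + 100)
    m <- morans_i(y, co)
    m$observed > m$expected & m$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("scenario simulation is reproducible and writes round-trippable files", {
  sc1 <- simulate_scenario(n_families = 5, n_per_language = 20, seed = 11)
  sc2 <- simulate_scenario(n_families = 5, n_per_language = 20, seed = 11)
  expect_identical(sc1$respondents, sc2$respondents)
  expect_identical(sc1$ftr, sc2$ftr)

  dir <- withr::local_tempdir()
  paths <- write_scenario(sc1, dir)
  back <- read.csv(paths["respondents"])
  expect_equal(nrow(back), nrow(sc1$respondents))
  expect_equal(back$saved, sc1$respondents$saved)
  tr <- ape::read.tree(paths["tree"])
  expect_setequal(tr$tip.label, sc1$tree$tip.label)

  # YAML scenario round trip
  yml <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(n_families = 5, n_per_language = 20, seed = 11), yml)
  sc3 <- read_scenario(yml)
  expect_identical(sc3$respondents$saved, sc1$respondents$saved)
})
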