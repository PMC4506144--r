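test_that("geodesic distances: zero, antipodal, and waypoint routing bounds", {
  co <- data.frame(language_id = c("a", "b", "c"),
                   latitude = c(0, 0, 10), longitude = c(0, 180, 10))
  d <- geodesic_matrix(co)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_error(geodesic_matrix(data.frame(language_id = "x",
                                          latitude = 95, longitude = 0)),
               "invalid")

  # routed cross-continent distance is never below the direct great circle
  co2 <- data.frame(language_id = c("p", "q"),
                    latitude = c(10, -10), longitude = c(0, 100),
                    continent = c("C1", "C2"))
  wps <- list(
    nodes = data.frame(id = c("w1", "w2"), latitude = c(40, 30),
                       longitude = c(30, 70)),
    edges = data.frame(from = "w1", to = "w2")
  )
  direct <- geodesic_matrix(co2[, 1:3])["p", "q"]
  routed <- geodesic_matrix(co2, waypoints = wps)["p", "q"]
  expect_gte(routed, direct - 1e-9)
})

test_that("Mantel test: identity, determinism and p-value floor", {
  a <- random_distance_matrix(10, 1)
  m <- mantel_test(a, a, method = "pearson", n_perm = 199, seed = 3)
  expect_equal(m$r, 1)
  expect_gte(m$p, 1 / (m$n_perm + 1))
  m2 <- mantel_test(a, a, method = "pearson", n_perm = 199, seed = 3)
  expect_identical(m$p, m2$p)
  # spearman r = 1 for identical matrices without ties
  ms <- mantel_test(a, a, method = "spearman", n_perm = 199, seed = 3)
  expect_equal(ms$r, 1)
  expect_error(mantel_test(a, a, n_perm = 50), ">= 99")
  const <- a
  const[] <- 1
  diag(const) <- 0
  expect_error(mantel_test(a, const, n_perm = 199), "undefined")
})

test_that("simple and partial Mantel p-values match exhaustive enumeration on 5 labels", {
  a <- random_distance_matrix(5, 11)
  b <- random_distance_matrix(5, 12, labels = rownames(a))
  cmat <- random_distance_matrix(5, 13, labels = rownames(a))
  for (method in c("pearson", "spearman")) {
    got <- mantel_test(a, b, method = method, n_perm = 999)
    orc <- oracle_mantel_exhaustive(a, b, method = method)
    expect_true(got$exhaustive)
    expect_equal(got$r, orc$r, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  # partial: enumeration over the residual matrices
  gp <- partial_mantel(a, b, list(cmat), method = "pearson", n_perm = 999)
  ra <- a - 0
  # rebuild the residual matrices exactly as the implementation defines them
  resid_m <- function(m, ctrl) {
    v <- m[lower.tri(m)]
    x <- ctrl[lower.tri(ctrl)]
    r <- lm.fit(cbind(1, x), v)$residuals
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    out[lower.tri(out)] <- r
    out + t(out)
  }
  orc_p <- oracle_mantel_exhaustive(resid_m(a, cmat), resid_m(b, cmat),
                                    method = "pearson")
  expect_equal(gp$r, orc_p$r, tolerance = 1e-12)
  expect_equal(gp$p, orc_p$p, tolerance = 1e-12)
})

test_that("partial Mantel reduces to simple Mantel under an irrelevant control", {
  a <- random_distance_matrix(25, 21)
  b0 <- random_distance_matrix(25, 22, labels = rownames(a))
  b <- 0.7 * a + 0.3 * b0 # correlated focal pair
  ctrl <- random_distance_matrix(25, 23, labels = rownames(a))
  ctrl[] <- 5 + 0.01 * ctrl
  diag(ctrl) <- 0
  simple <- mantel_test(a, b, method = "pearson", n_perm = 199, seed = 1)
  part <- partial_mantel(a, b, list(ctrl), method = "pearson",
                         n_perm = 199, seed = 1)
  expect_equal(part$r, simple$r, tolerance = 0.05)
  expect_error(partial_mantel(a, b, list(a), n_perm = 199), "collinear")
})

test_that("stratified Mantel matches exhaustive within-stratum enumeration", {
  a <- random_distance_matrix(6, 31)
  b <- random_distance_matrix(6, 32, labels = rownames(a))
  strata <- setNames(c("s1", "s1", "s1", "s2", "s2", "s3"), rownames(a))
  got <- stratified_mantel(a, b, strata, method = "pearson", n_perm = 999)
  orc <- oracle_mantel_exhaustive(a, b, method = "pearson",
                                  strata = strata[rownames(a)])
  expect_true(got$exhaustive)
  expect_equal(got$n_perm, orc$n_perm) # 3! x 2! x 1! = 12
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_error(
    stratified_mantel(a, b, setNames(paste0("s", 1:6), rownames(a)),
                      n_perm = 999),
    "singleton")
})

test_that("single stratum reproduces the global Mantel under the same scheme", {
  a <- random_distance_matrix(5, 41)
  b <- random_distance_matrix(5, 42, labels = rownames(a))
  one <- setNames(rep("s", 5), rownames(a))
  g1 <- stratified_mantel(a, b, one, method = "pearson", n_perm = 999)
  g2 <- mantel_test(a, b, method = "pearson", n_perm = 999)
  expect_equal(g1$r, g2$r)
  expect_equal(g1$p, g2$p) # both exhaustive over the same 120 permutations
})

test_that("Moran's I: exact expectation, clustering detection, errors", {
  set.seed(51)
  n <- 95
  co <- data.frame(language_id = sprintf("L%02d", 1:n),
                   latitude = runif(n, -60, 60),
                   longitude = runif(n, -170, 170))
  vals <- setNames(rnorm(n), co$language_id)
  m <- morans_i(vals, co)
  expect_identical(m$expected, -1 / (n - 1))
  expect_equal(unname(rowSums(m$weights)), rep(1, n), tolerance = 1e-12)

  # perfectly location-driven values cluster
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    co2 <- data.frame(language_id = sprintf("L%02d", 1:40),
                      latitude = runif(40, -60, 60),
                      longitude = runif(40, -170, 170))
    v <- setNames(co2$latitude / 10 + rnorm(40, 0, 0.3), co2$language_id)
    mm <- morans_i(v, co2)
    mm$observed > 0 && mm$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(morans_i(setNames(rep(1, 10), sprintf("L%02d", 1:10)), co),
               "constant")
})

test_that("GWR flattens to OLS at huge bandwidth and finds regional slopes", {
  set.seed(61)
  n <- 40
  co <- data.frame(language_id = sprintf("L%02d", 1:n),
                   latitude = runif(n, -40, 40),
                   longitude = c(runif(n / 2, -120, -60),
                                 runif(n / 2, 60, 120)))
  x <- setNames(rnorm(n), co$language_id)
  y <- setNames(0.8 * x + rnorm(n, 0, 0.2), co$language_id)
  flat <- gwr(y, x, co, bandwidth = 1e7)
  ols <- coef(lm(y ~ x))
  expect_equal(flat$local_coefficients$slope,
               rep(unname(ols[2]), n), tolerance = 1e-3)
  expect_equal(flat$global_coefficient, unname(ols[2]), tolerance = 1e-10)

  # opposite slopes in the two hemispheres are recovered locally
  west <- co$longitude < 0
  y2 <- setNames(ifelse(west, -1, 1) * x + rnorm(n, 0, 0.1),
                 co$language_id)
  fit <- gwr(y2, x, co, bandwidth = 2000)
  sl <- fit$local_coefficients$slope
  expect_true(all(sl[west] < 0))
  expect_true(all(sl[!west] > 0))
  expect_lt(fit$rss, fit$rss_ols)

  # automatic bandwidth selection lands between the extremes
  auto <- gwr(y2, x, co)
  expect_gt(auto$bandwidth, 0)
  expect_lt(auto$aicc, gwr(y2, x, co, bandwidth = 1e7)$aicc)
  expect_error(gwr(y[1:5], x[1:5], co[1:5, ]), "10 sites")
})

test_that("Mantel agrees with vegan on a realistic pair", {
  skip_if_not_installed("vegan")
  a <- random_distance_matrix(30, 71)
  b0 <- random_distance_matrix(30, 72, labels = rownames(a))
  b <- 0.5 * a + 0.5 * b0
  got <- mantel_test(a, b, method = "pearson", n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), method = "pearson",
                       permutations = 999)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-10)
  # one-sided vegan p and two-sided |r| p agree for a clearly positive r
  expect_lt(abs(got$p - ref$signif), 0.02)
})
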