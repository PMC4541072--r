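test_that("standardization is exact, invertible, and rejects constants", {
  tab <- synthesize_feature_table(population_spec(blob_profiles(), 4, 3,
                                                  seed = 1))
  z <- standardize_features(tab)
  zm <- as.matrix(z[, vars10])
  expect_true(all(abs(colMeans(zm)) < 1e-10))
  expect_true(all(abs(apply(zm, 2, sd) - 1) < 1e-10))
  back <- unstandardize_features(z)
  expect_equal(as.matrix(back[, vars10]), as.matrix(tab[, vars10]),
               tolerance = 1e-8)

  bad <- tab
  bad$wiener_entropy <- 0.5
  expect_error(standardize_features(bad), "wiener_entropy")
})

test_that("log-likelihood distance matches direct formula evaluation", {
  # independent oracle: direct xi computation on a 4-row, 2-variable example
  a <- matrix(c(0, 0.5, 1, 1.2), 2, 2)
  b <- matrix(c(4, 4.6, 5, 5.5), 2, 2)
  sds <- c(2, 2.5)
  xi <- function(m) {
    wv <- apply(m, 2, function(col) mean(col^2) - mean(col)^2)
    -nrow(m) * sum(0.5 * log(sds^2 + wv))
  }
  expect_equal(loglik_distance(a, b, sds), xi(a) + xi(b) - xi(rbind(a, b)),
               tolerance = 1e-12)

  # two singletons at the same point merge at zero cost
  p <- matrix(c(1, 2), 1, 2)
  expect_equal(loglik_distance(p, p, sds), 0)

  # moving clusters apart strictly increases the distance
  d_at <- vapply(c(1, 2, 4, 8), function(off)
    loglik_distance(a, b + off, sds), numeric(1))
  expect_true(all(diff(d_at) > 0))
})

test_that("BIC-guided merging recovers planted structure", {
  # two point masses: k = 2 and BIC(2) < BIC(1), checked against the
  # direct BIC formula
  x <- data.frame(v1 = rep(c(0, 20), each = 10),
                  v2 = rep(c(0, 20), each = 10))
  sol <- fit_twostep(x, k_max = 5, variables = c("v1", "v2"))
  expect_equal(sol$k, 2)
  expect_lt(sol$bic_trace[2], sol$bic_trace[1])
  # oracle: standardized two-point data, within-var 0 at k=2, overall
  # biased var at k=1
  n <- 20; V <- 2
  z_var <- var(rep(c(0, 20), each = 10)) # = sd^2 -> standardized var 1
  bic1 <- n * V * log(1 + (n - 1) / n) + 2 * 1 * V * log(n)
  bic2 <- 0 + 2 * 2 * V * log(n)
  expect_equal(unname(sol$bic_trace[1]), bic1, tolerance = 1e-8)
  expect_equal(unname(sol$bic_trace[2]), bic2, tolerance = 1e-8)

  expect_equal(fit_twostep(data.frame(v1 = rep(1, 8)), k_max = 4,
                           variables = "v1")$k, 1)
})

test_that("well-separated mixtures are recovered with correct assignments", {
  tab <- synthesize_feature_table(
    population_spec(blob_profiles(sep = 10), 10, 4, seed = 42))
  sol <- fit_twostep(tab)
  expect_equal(sol$k, 4)
  ct <- cluster_context_crosstab(sol, tab)
  expect_gte(sum(apply(ct, 1, max)) / sum(ct), 0.95)
})

test_that("cluster labels are invariant under row shuffling", {
  tab <- synthesize_feature_table(
    population_spec(blob_profiles(), 8, 4, seed = 3))
  sol1 <- fit_twostep(tab)
  perm <- withr::with_seed(9, sample(nrow(tab)))
  sol2 <- fit_twostep(tab[perm, ])
  expect_equal(sol2$k, sol1$k)
  expect_true(same_partition(sol1$labels[perm], sol2$labels))
})

test_that("silhouette matches hand computation and conventions", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  # by hand: a = 1, b = (10 + sqrt(101)) / 2 for every point
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_sc(x, lab), (b - 1) / b, tolerance = 1e-12)
  expect_lt(abs(silhouette_sc(x, lab) - 0.900), 0.001)

  same <- matrix(1, 4, 2)
  expect_equal(silhouette_sc(same, c(1, 1, 2, 2)), 0)
  far <- rbind(c(0, 0), c(0, 1e-9), c(1e6, 0), c(1e6, 1e-9))
  expect_gt(silhouette_sc(far, c(1, 1, 2, 2)), 0.999)
  expect_error(silhouette_sc(x, rep(1, 4)), "2 clusters")
})

test_that("silhouette agrees with the cluster package on generated data", {
  skip_if_not_installed("cluster")
  tab <- synthesize_feature_table(
    population_spec(blob_profiles(sep = 3), 6, 4, seed = 8))
  z <- as.matrix(standardize_features(tab)[, vars10])
  lab <- withr::with_seed(2, sample(1:3, nrow(z), replace = TRUE))
  ref <- mean(cluster::silhouette(lab, dist(z))[, "sil_width"])
  expect_equal(silhouette_sc(z, lab), ref, tolerance = 1e-10)
})

test_that("single-population data yields no spurious strong clustering", {
  for (s in 1:5) {
    tab <- synthesize_feature_table(
      population_spec(list(single_profile()), 10, 4, seed = 800 + s))
    sol <- fit_twostep(tab)
    expect_true(sol$k <= 2)
    if (sol$k == 2) expect_lt(sol$silhouette_sc, 0.3)
  }
})

test_that("cluster-context crosstab conserves counts and purity", {
  tab <- synthesize_feature_table(
    population_spec(blob_profiles(sep = 10), 8, 4, seed = 13))
  sol <- fit_twostep(tab)
  ct <- cluster_context_crosstab(sol, tab)
  expect_equal(sum(ct), nrow(tab))
  expect_equal(unname(colSums(ct)),
               unname(as.vector(table(tab$context))))
  # context-pure generation: permuted-diagonal structure
  expect_true(all(apply(ct, 1, function(r) sum(r > 0)) == 1))
})

test_that("k_max above the row count is reduced with a warning", {
  tab <- synthesize_feature_table(
    population_spec(blob_profiles()[1:2], 2, 3, seed = 4))
  expect_warning(sol <- fit_twostep(tab, k_max = 50), "k_max")
  expect_true(sol$k <= nrow(tab))
})
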