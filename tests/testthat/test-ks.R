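test_that("ecdf_eval counts proportions with the weak-inequality convention", {
  expect_equal(ecdf_eval(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(ecdf_eval(c(1, 2, 3, 4), 0.5), 0)
  expect_equal(ecdf_eval(c(1, 2, 3, 4), 4), 1)
  expect_equal(ecdf_eval(c(1, 1, 2), 1), 2 / 3)  # ties counted weakly
  expect_error(ecdf_eval(numeric(0), 1), "empty")
  # monotone, bounded
  set.seed(3)
  s <- rnorm(50)
  t <- sort(rnorm(40))
  v <- ecdf_eval(s, t)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) >= 0))
})

test_that("kolmogorov_cdf matches frozen reference values and is a CDF", {
  expect_equal(kolmogorov_cdf(-1), 0)
  expect_equal(kolmogorov_cdf(0), 0)
  expect_equal(kolmogorov_cdf(10), 1)
  # frozen from scipy.special.kolmogorov
  expect_equal(kolmogorov_cdf(1.3258), 0.94053517904815, tolerance = 1e-9)
  x <- seq(0.01, 3, by = 0.01)
  v <- kolmogorov_cdf(x)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("ks_critical_value inverts the Kolmogorov CDF", {
  # frozen from scipy.special.kolmogi
  expect_equal(ks_critical_value(0.05), 1.3580986393225507, tolerance = 1e-7)
  expect_equal(ks_critical_value(0.01), 1.6276236115189504, tolerance = 1e-7)
  expect_equal(ks_critical_value(1 - kolmogorov_cdf(1.3258)), 1.3258,
               tolerance = 1e-8)
  expect_true(ks_critical_value(0.01) > ks_critical_value(0.05))
  expect_true(ks_critical_value(0.05) > ks_critical_value(0.10))
  expect_error(ks_critical_value(0), "alpha")
  expect_error(ks_critical_value(1.2), "alpha")
})

test_that("ks_config ties the threshold to its significance level", {
  cfg <- ks_config()
  expect_equal(cfg$ca, 1.3258)
  expect_equal(cfg$alpha, 1 - 0.94053517904815, tolerance = 1e-9)
  expect_error(ks_config(ca = -1), "positive")
})

test_that("scaled_ks_distance applies the two-sample factor", {
  x <- 1:16
  z <- c(1:8, 1000 + 1:8)
  expect_equal(scaled_ks_distance(x, z, mean(z)), sqrt(8) * 0.5)
  expect_equal(scaled_ks_distance(x, x, c(0, 5, 20)), rep(0, 3))
  # invariance under a common location shift
  expect_equal(scaled_ks_distance(x + 3, z + 3, mean(z) + 3),
               scaled_ks_distance(x, z, mean(z)))
  expect_error(scaled_ks_distance(numeric(0), z, 1), "empty")
})

test_that("node_rs evaluates probes from the tree and thresholds at Ca", {
  x <- 1:16
  z <- c(1:8, 1000 + 1:8)
  tr <- haar_trees(z)
  root <- node_rs(x, z, tr$tca, 4, 1)
  expect_equal(root$probe_main, mean(z))
  expect_equal(root$probe_alt, 4.5)  # left-half-block mean
  expect_equal(root$d_alt, 0)        # both e.c.d.f.s agree at 4.5
  expect_equal(root$rs, sqrt(8) * 0.5, tolerance = 1e-12)

  # identical series: no distance anywhere
  tr_x <- haar_trees(as.numeric(x))
  expect_equal(node_rs(x, x, tr_x$tca, 4, 1)$rs, 0)

  # n = 8 with the same relative shift: scale factor caps the distance at
  # 1.0 < Ca, so the node statistic stays zero
  x8 <- 1:8
  z8 <- c(1:4, 1000 + 1:4)
  tr8 <- haar_trees(z8)
  r8 <- node_rs(x8, z8, tr8$tca, 3, 1)
  expect_equal(max(r8$d_main, r8$d_alt), 1.0)
  expect_equal(r8$rs, 0)

  # level-0 probes coincide, so leaves never carry a node statistic
  leaf <- node_rs(x, z, tr$tca, 0, 9)
  expect_equal(leaf$probe_alt, leaf$probe_main)
  expect_equal(leaf$rs, 0)

  expect_error(node_rs(x, z, tr$tca, 5, 1), "level")
})

test_that("node_rs is invariant under common location shifts", {
  set.seed(13)
  x <- rnorm(32)
  z <- c(rnorm(20), rnorm(12, mean = 3))
  tr <- haar_trees(z)
  tr_s <- haar_trees(z + 7)
  for (lev in c(4, 3, 2)) {
    for (j in c(1, 2)) {
      a <- node_rs(x, z, tr$tca, lev, j)
      b <- node_rs(x + 7, z + 7, tr_s$tca, lev, j)
      expect_equal(a$rs, b$rs, tolerance = 1e-8)
    }
  }
})

test_that("ks_global_test matches the brute-force supremum", {
  g <- ks_global_test(rep(0, 8), c(rep(0, 4), rep(10, 4)))
  expect_equal(g$statistic, 1.0)
  expect_false(g$reject)
  expect_equal(ks_global_test(1:10, 1:10)$statistic, 0)
  set.seed(17)
  for (r in 1:10) {
    n <- sample(c(8, 16, 33, 64), 1)
    x <- rnorm(n)
    z <- rnorm(n, mean = rnorm(1))
    expect_equal(ks_global_test(x, z)$statistic, oracle_ks_global(x, z),
                 tolerance = 1e-12)
  }
})

test_that("ks_global_test holds its nominal size under the null", {
  rej <- vapply(1:1000, function(r) {
    cfg <- sim_config(256, 128, 0, 1, seed = 3, reps = 1)
    p <- gen_pair(cfg, r)
    ks_global_test(p$x, p$z, alpha = 0.05)$reject
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
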