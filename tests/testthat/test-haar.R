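test_that("haar_step computes orthonormal pair averages and differences", {
  s <- haar_step(c(1, 2, 3, 4))
  expect_equal(s$trend, c(2.12132034355964, 4.94974746830583))
  expect_equal(s$fluct, c(-0.707106781186547, -0.707106781186547))

  const <- haar_step(rep(3.5, 8))
  expect_equal(const$fluct, rep(0, 4))
  expect_equal(const$trend, rep(3.5 * sqrt(2), 4))

  # energy conservation: 30 = 29 + 1
  expect_equal(sum(s$trend^2) + sum(s$fluct^2), 30)
  expect_equal(sum(s$trend^2), 29)

  expect_error(haar_step(c(1, 2, 3)), "length 3")
  expect_error(haar_step(c(1, NA, 3, 4)), "non-finite")
})

test_that("haar_multilevel cascades haar_step and conserves energy", {
  d <- haar_multilevel(c(1, 2, 3, 4), depth = 2)
  expect_equal(d$trend[[2]], 5)
  expect_equal(d$fluct[[2]], -2)
  expect_equal(5^2 + (-2)^2 + sum(d$fluct[[1]]^2), 30)

  s <- haar_step(c(1, 2, 3, 4))
  d1 <- haar_multilevel(c(1, 2, 3, 4), depth = 1)
  expect_equal(d1$trend[[1]], s$trend)
  expect_equal(d1$fluct[[1]], s$fluct)

  expect_error(haar_multilevel(1:4, depth = 3), "depth")
  expect_error(haar_multilevel(1:12, depth = 3), "not divisible")

  # every level's length halves, and energy is conserved at every level
  set.seed(11)
  z <- rnorm(64)
  d <- haar_multilevel(z, depth = 6)
  for (i in 1:6) {
    expect_length(d$trend[[i]], 64 / 2^i)
    expect_length(d$fluct[[i]], 64 / 2^i)
    energy <- sum(d$trend[[i]]^2) +
      sum(vapply(1:i, function(j) sum(d$fluct[[j]]^2), numeric(1)))
    expect_equal(energy, sum(z^2), tolerance = 1e-9)
  }
})

test_that("coefficients agree with the explicit basis-vector oracle", {
  set.seed(7)
  for (n in c(8, 32, 128)) {
    z <- rnorm(n)
    d <- haar_multilevel(z)
    for (lev in seq_len(d$depth)) {
      o <- oracle_haar_level(z, lev)
      expect_equal(d$trend[[lev]], o$trend, tolerance = 1e-12)
      expect_equal(d$fluct[[lev]], o$fluct, tolerance = 1e-12)
    }
  }
})

test_that("coefficients match an independent wavelet implementation", {
  # Frozen from PyWavelets 1.9 wavedec(x, "haar", level = 3), which uses
  # the same orthonormal left-minus-right convention.
  x <- c(0.5, -1.25, 2.0, 3.5, -0.75, 1.0, 4.25, -2.0)
  d <- haar_multilevel(x, depth = 3)
  expect_equal(d$trend[[3]], 2.563262081801, tolerance = 1e-10)
  expect_equal(d$fluct[[3]], 0.795495128835, tolerance = 1e-10)
  expect_equal(d$fluct[[2]], c(-3.125, -1.0), tolerance = 1e-10)
  expect_equal(d$fluct[[1]],
               c(1.237436867076, -1.06066017178,
                 -1.237436867076, 4.419417382416),
               tolerance = 1e-10)
})

test_that("haar_reconstruct inverts the decomposition", {
  expect_equal(haar_reconstruct(haar_multilevel(c(1, 2, 3, 4), 2)),
               c(1, 2, 3, 4))
  set.seed(21)
  z <- rnorm(64)
  expect_equal(haar_reconstruct(haar_multilevel(z)), z, tolerance = 1e-9)
  zero <- haar_multilevel(rep(0, 16))
  expect_equal(haar_reconstruct(zero), rep(0, 16))
  bad <- haar_multilevel(1:8)
  bad$fluct[[1]] <- bad$fluct[[1]][1:2]
  expect_error(haar_reconstruct(bad), "inconsistent")
})

test_that("haar_trees builds both trees with sample leaves", {
  tr <- haar_trees(c(1, 2, 3, 4))
  expect_equal(tree_node(tr$tca, 2, 1), 5)
  expect_equal(tr$tca$levels[[2]], c(2.12132034355964, 4.94974746830583))
  expect_equal(tr$tca$levels[[1]], c(1, 2, 3, 4))
  expect_equal(tree_node(tr$tcd, 2, 1), -2)
  expect_equal(tree_block(tr$tca, 2, 1), c(1, 4))
  expect_error(haar_trees(1:12), "power-of-two")
  expect_error(tree_node(tr$tca, 3, 1), "level")
  expect_error(tree_node(tr$tca, 1, 5), "position")
})

test_that("tree recurrences hold node by node", {
  set.seed(5)
  z <- rnorm(32)
  tr <- haar_trees(z)
  for (lev in 1:5) {
    for (j in seq_len(32 / 2^lev)) {
      a_left <- tree_node(tr$tca, lev - 1, 2 * j - 1)
      a_right <- tree_node(tr$tca, lev - 1, 2 * j)
      expect_equal(tree_node(tr$tca, lev, j), (a_left + a_right) / sqrt(2))
      expect_equal(tree_node(tr$tcd, lev, j), (a_left - a_right) / sqrt(2))
    }
  }
})

test_that("blocks partition the index range at every level", {
  tr <- haar_trees(rnorm(64))
  for (lev in 0:6) {
    blocks <- lapply(seq_len(64 / 2^lev), function(j) {
      b <- tree_block(tr$tca, lev, j)
      b[1]:b[2]
    })
    expect_equal(sort(unlist(blocks)), 1:64)
  }
})

test_that("block_mean recovers arithmetic means exactly", {
  tr <- haar_trees(c(1, 2, 3, 4))
  expect_equal(block_mean(tr$tca, 2, 1), 2.5)
  expect_equal(block_mean(tr$tca, 1, 1), 1.5)
  expect_equal(block_mean(tr$tca, 0, 3), 3)
  set.seed(9)
  z <- rnorm(32)
  tr <- haar_trees(z)
  for (lev in 0:5) {
    for (j in seq_len(32 / 2^lev)) {
      b <- tree_block(tr$tca, lev, j)
      expect_equal(block_mean(tr$tca, lev, j), mean(z[b[1]:b[2]]),
                   tolerance = 1e-12)
    }
  }
  expect_error(block_mean(tr$tcd, 1, 1), "approximation")
})
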