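test_that("match is exactly symmetric and 100% under similarity transforms", {
  a <- make_hex_lattice(100, 0.1, 6, 6, seed = 3)
  b <- similarity_transform(a, angle = 0.7, scale = 0.072, shift = c(5, -3))
  expect_equal(tiling_match(a, b)$fraction, 100)
  # symmetry, exactly
  a2 <- random_pattern(25, seed = 9)
  b2 <- random_pattern(25, seed = 10)
  expect_identical(tiling_match(a2, b2)$fraction,
                   tiling_match(b2, a2)$fraction)
  # similarity transform of either side leaves the fraction unchanged
  m0 <- tiling_match(a2, b2)$fraction
  expect_equal(tiling_match(similarity_transform(a2, 1.1, 3, c(7, 7)),
                            b2)$fraction, m0)
})

test_that("id pairing is enforced and fractions agree with a brute-force count", {
  a <- random_pattern(6, seed = 1)
  bad <- tiling_pattern(7:12, a$x, a$y)
  expect_error(tiling_match(a, bad), "id set")

  # displace single points and compare against the oracle's edge sets
  for (s in 1:5) {
    a <- random_pattern(6, seed = 300 + s, scale = 10)
    b <- a
    b$x[3] <- b$x[3] + 4
    b$y[3] <- b$y[3] - 2
    ka <- oracle_edge_keys(bruteforce_delaunay_edges(a$x, a$y))
    kb <- oracle_edge_keys(bruteforce_delaunay_edges(b$x, b$y))
    want <- 100 * length(intersect(ka, kb)) / mean(c(length(ka), length(kb)))
    expect_equal(tiling_match(a, b)$fraction, want)
  }
})

test_that("match bookkeeping is internally consistent", {
  a <- make_hex_lattice(100, 0.1, 5, 5, seed = 21)
  b <- project_axons(
    make_hex_lattice(7.2, 0.1, 5, 5, seed = 21, unit = "deg",
                     space = "visual"), sigma = 40, seed = 22)
  m <- tiling_match(a, b)
  expect_equal(nrow(m$common_edges) + nrow(m$unique_a), m$n_edges_a)
  expect_equal(nrow(m$common_edges) + nrow(m$unique_b), m$n_edges_b)
  expect_equal(m$fraction,
               100 * nrow(m$common_edges) / mean(c(m$n_edges_a, m$n_edges_b)))
  expect_gte(m$fraction, 0)
  expect_lte(m$fraction, 200 * min(m$n_edges_a, m$n_edges_b) /
               (m$n_edges_a + m$n_edges_b))
})

test_that("permutation null is deterministic, below the true match, and stable", {
  rf <- make_hex_lattice(7.2, 0.1, 5, 5, seed = 5, unit = "deg",
                         space = "visual")
  ax <- project_axons(rf, sigma = 20, seed = 6)
  n1 <- bootstrap_chance(rf, ax, repetitions = 500, seed = 77)
  n2 <- bootstrap_chance(rf, ax, repetitions = 500, seed = 77)
  expect_identical(n1$null, n2$null)
  expect_lt(n1$threshold, tiling_match(rf, ax)$fraction)
  expect_error(bootstrap_chance(rf, ax, repetitions = 50), ">= 100")

  # mean null match is stable across seeds (SD of means < 1 percentage point)
  means <- vapply(1:20, function(s)
    mean(bootstrap_chance(rf, ax, repetitions = 200, seed = s)$null),
    numeric(1))
  expect_lt(sd(means), 1)
})
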