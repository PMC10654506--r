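test_that("zero-jitter projection is a pure similarity transform", {
  rf <- make_hex_lattice(7.2, 0.1, 6, 6, seed = 2, unit = "deg",
                         space = "visual")
  ax <- project_axons(rf, L_axon = 100, L_rf = 7.2, sigma = 0)
  expect_equal(tiling_match(rf, ax)$fraction, 100)
  # explicit scale factor: (7.2, 0) deg -> (100, 0) um
  one <- tiling_pattern(1, 7.2, 0, unit = "deg", space = "visual")
  got <- project_axons(one, sigma = 0)
  expect_equal(c(got$x, got$y), c(100, 0))
  # all pairwise distance ratios preserved
  d_rf <- dist(cbind(rf$x, rf$y))
  d_ax <- dist(cbind(ax$x, ax$y))
  expect_equal(as.numeric(d_ax / d_rf), rep(100 / 7.2, length(d_rf)),
               tolerance = 1e-9)
  expect_error(project_axons(make_hex_lattice(100, 0.1, 3, 3), sigma = 0),
               "degrees")
  expect_error(project_axons(rf, sigma = -1), "sigma")
})

test_that("large projection jitter degrades the match toward chance", {
  rf <- make_hex_lattice(7.2, 0.1, 5, 5, seed = 31, unit = "deg",
                         space = "visual")
  ax0 <- project_axons(rf, sigma = 100, seed = 32)
  band <- bootstrap_chance(rf, ax0, repetitions = 2000, seed = 33)
  sim_median <- function(sigma) {
    median(vapply(1:200, function(r) {
      rfp <- make_hex_lattice(7.2, 0.1, 5, 5, seed = derive_seed(r, "rf"),
                              unit = "deg", space = "visual")
      axp <- project_axons(rfp, sigma = sigma, seed = derive_seed(r, "ax"))
      tiling_match(rfp, axp)$fraction
    }, numeric(1)))
  }
  # at sigma = L the match is heavily degraded but local correspondence is
  # still detectable above the permutation chance level
  m100 <- sim_median(100)
  expect_lt(m100, 60)
  expect_gt(m100, band$threshold)
  # at sigma = 3 L the correspondence has collapsed into the chance band
  m300 <- sim_median(300)
  expect_lt(m300, band$threshold)
  expect_gt(m300, quantile(band$null, 0.005))
})

test_that("convergence draws select brute-force nearest axons with unit weights", {
  soma <- make_hex_lattice(56, 0.1, 7, 7, seed = 51)
  axon <- make_hex_lattice(100, 0.1, 7, 7, seed = 52)
  conn <- draw_convergence(soma, axon, lambda_mean = 5.5, seed = 53)
  expect_length(conn, nrow(soma))
  for (rec in conn) {
    expect_gte(length(rec$axon_ids), 1)
    expect_equal(sum(rec$weights), 1, tolerance = 1e-9)
    expect_true(all(rec$weights >= 0))
    i <- match(rec$sc_id, soma$id)
    d <- sqrt((axon$x - soma$x[i])^2 + (axon$y - soma$y[i])^2)
    top_k <- axon$id[order(d)[seq_along(rec$axon_ids)]]
    expect_setequal(rec$axon_ids, top_k)
  }
  expect_error(draw_convergence(soma, axon, lambda_mean = 0.5), "lambda")
})

test_that("zero-truncated Poisson draws have the closed-form mean", {
  lam <- 5.5
  soma <- tiling_pattern(1:10000, rnorm(10000), rnorm(10000))
  axon <- make_hex_lattice(100, 0.1, 9, 9, seed = 1)
  conn <- draw_convergence(soma, axon, lambda_mean = lam, seed = 7)
  k <- vapply(conn, function(r) length(r$axon_ids), numeric(1))
  want <- lam / (1 - exp(-lam))
  expect_lt(abs(mean(k) - want) / want, 0.02)
  expect_gte(min(k), 1)
})

test_that("equidistant axons get equal weights and SC RFs are weighted averages", {
  soma <- tiling_pattern("s1", 0, 0, unit = "um", space = "sc")
  axon <- tiling_pattern(c("a1", "a2"), c(-50, 50), c(0, 0),
                         unit = "um", space = "sc")
  conn <- draw_convergence(soma, axon, lambda_mean = 10, seed = 3)
  expect_equal(conn[[1]]$weights, c(0.5, 0.5), tolerance = 1e-9)

  rfs <- tiling_pattern(c("a1", "a2"), c(0, 4), c(0, 0),
                        unit = "deg", space = "visual")
  sc_rf <- compute_sc_rfs(conn, rfs)
  expect_equal(c(sc_rf$x, sc_rf$y), c(2, 0), tolerance = 1e-9)
  # k = 1 copies the input RF center
  conn1 <- structure(list(list(sc_id = "s1", axon_ids = "a2", weights = 1)),
                     class = "connectivity_set")
  expect_equal(compute_sc_rfs(conn1, rfs)$x, 4)
  # missing RF for a connected axon is a consistency error
  connx <- structure(list(list(sc_id = "s1", axon_ids = "zz", weights = 1)),
                     class = "connectivity_set")
  expect_error(compute_sc_rfs(connx, rfs), "absent")
})

test_that("higher convergence pulls SC RFs toward the retinotopic ideal", {
  # median distance between SC RF centers and the ideal retinotopic position
  # decreases monotonically over lambda in {1, 3, 5.5, 8, 10} at sigma = 27
  lam_grid <- c(1, 3, 5.5, 8, 10)
  med_dist <- vapply(seq_along(lam_grid), function(li) {
    cfg <- sim_config(sigma = 27, lambda_mean = lam_grid[li])
    d <- vapply(1:200, function(r) {
      g <- simulate_retinocollicular(cfg, seed = derive_seed(r, paste0("m", li)))
      keep <- match(interior_ids(g$sc_soma), g$sc_soma$id)
      ideal_x <- g$sc_soma$x[keep] * cfg$L_rf / cfg$L_axon
      ideal_y <- g$sc_soma$y[keep] * cfg$L_rf / cfg$L_axon
      median(sqrt((g$sc_rf$x[keep] - ideal_x)^2 +
                    (g$sc_rf$y[keep] - ideal_y)^2))
    }, numeric(1))
    median(d)
  }, numeric(1))
  expect_true(all(diff(med_dist) < 0))
})

test_that("the full simulation is reproducible and structurally consistent", {
  cfg <- sim_config(sigma = 27, lambda_mean = 5.5, seed = 9)
  g1 <- simulate_retinocollicular(cfg)
  g2 <- simulate_retinocollicular(cfg)
  expect_identical(g1$axon$x, g2$axon$x)
  expect_identical(g1$sc_rf$x, g2$sc_rf$x)
  expect_identical(g1$rgc_rf$id, g1$axon$id)
  expect_identical(g1$sc_soma$id, g1$sc_rf$id)
  all_axon_ids <- unique(unlist(lapply(g1$connectivity, `[[`, "axon_ids")))
  expect_true(all(all_axon_ids %in% g1$axon$id))
  expect_error(sim_config(lambda_mean = 0.2), "lambda_mean")
  expect_error(sim_config(L_axon = -1), "spacings")
})
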