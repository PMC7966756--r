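test_that("network edges use a closed-interval cutoff", {
  w <- water_set(rbind(c(0, 0, 0), c(3.70, 0, 0)))
  expect_equal(nrow(build_network(w, 3.7)$edges), 1L)
  w2 <- water_set(rbind(c(0, 0, 0), c(3.71, 0, 0)))
  expect_equal(nrow(build_network(w2, 3.7)$edges), 0L)
})

test_that("a noise-free zigzag yields a single chain with exact statistics", {
  z <- gen_zigzag(12, spacing = 2.86, angle = 116, noise_sigma = 0)
  net <- build_network(z$waters, 3.7)
  expect_equal(nrow(net$edges), 11L)
  st <- network_stats(net)
  expect_equal(st$component_sizes, 12L)
  expect_equal(st$mean_distance, 2.86, tolerance = 1e-12)
  expect_equal(st$mean_angle, 116, tolerance = 1e-9)
  expect_equal(st$n_branches, 0L)
})

test_that("three collinear waters give a single 180-degree angle", {
  w <- water_set(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  st <- network_stats(build_network(w, 2.5))
  expect_equal(st$angles, 180)
})

test_that("edge sets are nested as the cutoff grows", {
  for (seed in 1:5) {
    set.seed(seed)
    w <- water_set(matrix(rnorm(30, sd = 3), 10))
    prev <- character(0)
    for (cutoff in c(2, 3, 4.5, 7)) {
      e <- build_network(w, cutoff)$edges
      keys <- paste(e$from, e$to)
      expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})

test_that("non-finite water coordinates are rejected by name", {
  w <- water_set(rbind(c(0, 0, 0), c(1, 0, 0)))
  w$x[2] <- Inf
  expect_error(build_network(w), "W2")
})

test_that("a planted collinear trough is recovered exactly", {
  tr <- gen_zigzag(6, spacing = 4.6, angle = 180, noise_sigma = 0)
  res <- find_linear_trough(tr$waters, line_tolerance = 1.0)
  expect_true(res$found)
  expect_equal(length(res$water_id), 6L)
  expect_equal(res$mean_interval, 4.6, tolerance = 1e-9)
  expect_equal(res$residual, 0, tolerance = 1e-9)
  expect_equal(res$span, 5 * 4.6, tolerance = 1e-9)
})

test_that("off-line decoys are excluded at the stated tolerance", {
  tr <- gen_zigzag(6, spacing = 4.6, angle = 180, noise_sigma = 0)
  decoy <- water_set(rbind(as.matrix(tr$waters[, c("x", "y", "z")]),
                           c(11.5, 2, 0)))  # 2 Angstrom perpendicular residual
  res <- find_linear_trough(decoy, line_tolerance = 1.0)
  expect_equal(length(res$water_id), 6L)
  expect_false("W7" %in% res$water_id)
  expect_equal(sort(res$water_id), oracle_trough_ids(decoy, 1.0))
})

test_that("the trough search agrees with exhaustive enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:9, 1)
    base <- cbind(seq(0, by = 3.5, length.out = n), 0, 0)
    X <- base + matrix(rnorm(3 * n, sd = 0.8), n)
    w <- water_set(X)
    got <- find_linear_trough(w, line_tolerance = 0.8)
    want <- oracle_trough_ids(w, 0.8)
    if (length(want)) {
      expect_equal(sort(got$water_id), want)
    } else {
      expect_false(got$found)
    }
  }
})

test_that("too few collinear waters give a no-trough result, not an error", {
  w <- water_set(rbind(c(0, 0, 0), c(5, 5, 0), c(0, 5, 5)))
  res <- find_linear_trough(w, line_tolerance = 0.1)
  expect_false(res$found)
  expect_equal(length(res$water_id), 0L)
})

test_that("anchored candidate pools are restricted to side-chain contacts", {
  # trough waters parked 2.5 Angstrom from the CB atoms of residues 2..7,
  # plus a far-away water that must not enter the pool
  s <- gen_toy_structure(8)
  cb <- s$atoms[s$atoms$elety == "CB" & s$atoms$resno %in% 2:7, ]
  line <- cbind(cb$x, cb$y - 2.5, cb$z)
  w <- water_set(rbind(line, c(0, 40, 40)))
  res <- find_linear_trough(w, structure = s, anchor_residues = 2:7,
                            line_tolerance = 1.0)
  expect_true(res$found)
  expect_equal(length(res$water_id), 6L)
  expect_false("W7" %in% res$water_id)
  # the scaffold wiggle perturbs the planted line slightly
  expect_equal(res$mean_interval, 3.8, tolerance = 0.05)
})

test_that("a planted decagon ring is recovered closed with exact geometry", {
  rg <- gen_ring(10, edge = 2.74, carbon_dist = 3.4, noise_sigma = 0)
  res <- find_hydration_ring(rg$waters, rg$carbons, ring_cutoff = 3.5)
  expect_true(res$ring_closure)
  expect_equal(length(res$water_id), 10L)
  expect_equal(res$mean_adjacent, 2.74, tolerance = 1e-9)
  expect_equal(res$mean_carbon_dist, 3.4, tolerance = 1e-6)
})

test_that("removing a ring vertex yields an open chain of nine", {
  rg <- gen_ring(10, edge = 2.74, noise_sigma = 0)
  w <- rg$waters[-3, , drop = FALSE]
  res <- find_hydration_ring(w, rg$carbons, ring_cutoff = 3.5)
  expect_false(res$ring_closure)
  expect_equal(length(res$water_id), 9L)
})

test_that("ring search honours the side-chain contact cutoff", {
  rg <- gen_ring(10, edge = 2.74, noise_sigma = 0)
  far <- water_set(rbind(as.matrix(rg$waters[, c("x", "y", "z")]),
                         c(20, 20, 20)))
  res <- find_hydration_ring(far, rg$carbons, ring_cutoff = 3.5,
                             contact_cutoff = 4.5)
  expect_equal(length(res$water_id), 10L)
  expect_false("W11" %in% res$water_id)
})
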