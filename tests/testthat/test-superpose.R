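test_that("identical point sets superpose with identity and zero RMSD", {
  set.seed(1)
  P <- matrix(rnorm(12), 4)
  fit <- kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("planted rigid transforms are recovered to 1e-6", {
  for (seed in 1:20) {
    set.seed(seed)
    P <- matrix(rnorm(3 * 8, sd = 3), 8)
    R0 <- icebound:::random_rotation()
    t0 <- runif(3, -5, 5)
    Q <- P %*% t(R0) + matrix(t0, 8, 3, byrow = TRUE)
    fit <- kabsch(P, Q)
    expect_lt(max(abs(fit$rotation - R0)), 1e-6)
    expect_lt(max(abs(fit$translation - t0)), 1e-6)
    expect_lt(fit$rmsd, 1e-6)
    # the returned rotation is proper orthogonal
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
})

test_that("kabsch matches the rotation-grid oracle on 4-point sets", {
  for (seed in 1:3) {
    set.seed(seed)
    P <- matrix(rnorm(12, sd = 2), 4)
    Q <- matrix(rnorm(12, sd = 2), 4)
    expect_equal(kabsch(P, Q)$rmsd, oracle_rmsd(P, Q), tolerance = 1e-4)
  }
})

test_that("RMSD is invariant under rigid motion of both sets", {
  set.seed(2)
  P <- matrix(rnorm(15), 5)
  Q <- matrix(rnorm(15), 5)
  base <- kabsch(P, Q)$rmsd
  for (seed in 1:5) {
    set.seed(seed)
    R0 <- icebound:::random_rotation()
    t0 <- runif(3, -10, 10)
    move <- function(X) X %*% t(R0) + matrix(t0, nrow(X), 3, byrow = TRUE)
    expect_equal(kabsch(move(P), move(Q))$rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate inputs raise a degeneracy error", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate|collinear")
  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3 point")
})

test_that("docking a patch subset onto its own patch gives zero RMSD", {
  patch <- extract_plane_patch(build_ice_lattice(extent = 4), "basal", 1.0, 12)
  sub <- patch$oxygens[c(3, 5, 8, 11, 14, 17, 20, 23, 26, 29, 31), ]
  fit <- dock_waters_to_plane(water_set(sub), patch, n_starts = 20, seed = 3)
  expect_lt(fit$rmsd, 1e-8)
  expect_true(fit$converged)
  # correspondence is injective
  expect_equal(anyDuplicated(fit$correspondence), 0L)
})

test_that("docking recovers planted transforms and tracks the noise level", {
  patch <- extract_plane_patch(build_ice_lattice(extent = 4), "basal", 1.0, 12)
  # noise-free: exact recovery regardless of the planted orientation
  pm0 <- gen_transformed_patch(patch, 11, noise_sigma = 0, seed = 11)
  fit0 <- dock_waters_to_plane(pm0$waters, patch, n_starts = 24, seed = 1)
  expect_lt(fit0$rmsd, 1e-6)
  # sigma = 0.2: RMSD close to the 3D noise scale sigma * sqrt(3), with a
  # band wide enough for the 11-point fit's absorbed degrees of freedom
  sigma <- 0.2
  rmsds <- vapply(1:50, function(s) {
    pm <- gen_transformed_patch(patch, 11, noise_sigma = sigma, seed = s)
    dock_waters_to_plane(pm$waters, patch, n_starts = 12, seed = 1)$rmsd
  }, numeric(1))
  expect_gt(mean(rmsds), 0.5 * sigma)
  expect_lt(mean(rmsds), 2 * sigma * sqrt(3))
})

test_that("the docked RMSD equals a kabsch refit of its own correspondence", {
  patch <- extract_plane_patch(build_ice_lattice(extent = 4), "basal", 1.0, 12)
  pm <- gen_transformed_patch(patch, 9, noise_sigma = 0.3, seed = 4)
  fit <- dock_waters_to_plane(pm$waters, patch, n_starts = 12, seed = 2)
  refit <- kabsch(as.matrix(pm$waters[, c("x", "y", "z")]), patch$oxygens,
                  pairing = cbind(seq_along(fit$correspondence),
                                  unname(fit$correspondence)))
  expect_equal(fit$rmsd, refit$rmsd, tolerance = 1e-9)
})

test_that("more starts never worsen the docked RMSD", {
  patch <- extract_plane_patch(build_ice_lattice(extent = 4), "prism1", 1.0, 12)
  pm <- gen_transformed_patch(patch, 10, noise_sigma = 0.4, seed = 9)
  r4 <- dock_waters_to_plane(pm$waters, patch, n_starts = 4, seed = 5)$rmsd
  r12 <- dock_waters_to_plane(pm$waters, patch, n_starts = 12, seed = 5)$rmsd
  r24 <- dock_waters_to_plane(pm$waters, patch, n_starts = 24, seed = 5)$rmsd
  expect_lte(r12, r4 + 1e-12)
  expect_lte(r24, r12 + 1e-12)
})

test_that("docking refuses a patch smaller than the water set", {
  patch <- extract_plane_patch(build_ice_lattice(extent = 2), "basal", 1.0, 3)
  big <- water_set(matrix(rnorm(3 * (nrow(patch$oxygens) + 1)),
                          nrow(patch$oxygens) + 1))
  expect_error(dock_waters_to_plane(big, patch), "fewer oxygens")
})

test_that("calpha RMSD is zero against itself and scales with perturbation", {
  s <- gen_toy_structure(200, cell = c(800, 40, 40))
  expect_equal(as.numeric(calpha_rmsd(s, s)), 0, tolerance = 1e-10)
  sigma <- 0.1
  set.seed(6)
  s2 <- s
  idx <- which(s2$atoms$elety == "CA")
  s2$atoms[idx, c("x", "y", "z")] <- s2$atoms[idx, c("x", "y", "z")] +
    matrix(rnorm(3 * length(idx), 0, sigma), length(idx))
  r <- as.numeric(calpha_rmsd(s, s2))
  expect_equal(r, sigma * sqrt(3), tolerance = 0.15)
  expect_error(calpha_rmsd(s, gen_toy_structure(2)), "3 common")
})
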