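# Independent oracles used to check the package's implementations.

# Brute-force superposition RMSD: given a rotation, the optimal translation
# matches centroids; search rotations on an Euler-angle grid, then polish
# with Nelder-Mead. Independent of the closed-form Kabsch path.
oracle_rmsd <- function(P, Q, grid_step = 30) {
  euler_rot <- function(a, b, g) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(g)
  }
  rmsd_of <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    Pr <- P %*% t(R)
    off <- colMeans(Q) - colMeans(Pr)
    sqrt(mean(rowSums((sweep(Pr, 2, -off) - Q)^2)))
  }
  best <- NULL
  for (a in seq(0, 2 * pi, by = grid_step * pi / 180)) {
    for (b in seq(0, pi, by = grid_step * pi / 180)) {
      for (g in seq(0, 2 * pi, by = grid_step * pi / 180)) {
        v <- rmsd_of(c(a, b, g))
        if (is.null(best) || v < best$value) best <- list(par = c(a, b, g), value = v)
      }
    }
  }
  opt <- stats::optim(best$par, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Brute-force symmetry expansion count: apply every operator and every
# neighbour-cell translation directly, keep images within `radius` of the
# probe points, drop near-duplicates sequentially.
oracle_symmetry_images <- function(wxyz, cell, ops, probe, radius,
                                   existing, dedup_tol = 0.1) {
  ca <- cos(cell[4:6] * pi / 180)
  sg <- sin(cell[6] * pi / 180)
  v <- sqrt(1 - sum(ca^2) + 2 * prod(ca))
  M <- matrix(c(cell[1], cell[2] * ca[3], cell[3] * ca[2],
                0, cell[2] * sg, cell[3] * (ca[1] - ca[2] * ca[3]) / sg,
                0, 0, cell[3] * v / sg), 3, byrow = TRUE)
  Minv <- solve(M)
  frac <- t(Minv %*% t(wxyz))
  kept <- existing
  count <- 0L
  for (i in seq_along(ops)) {
    for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
      if (i == 1L && n1 == 0 && n2 == 0 && n3 == 0) next
      g <- frac %*% t(ops[[i]]$R)
      g <- sweep(g, 2, ops[[i]]$t + c(n1, n2, n3), "+")
      img <- t(M %*% t(g))
      for (r in seq_len(nrow(img))) {
        dprobe <- min(sqrt(rowSums(sweep(probe, 2, img[r, ])^2)))
        if (dprobe > radius + 1e-9) next
        ddup <- min(sqrt(rowSums(sweep(kept, 2, img[r, ])^2)))
        if (ddup < dedup_tol) next
        kept <- rbind(kept, img[r, ])
        count <- count + 1L
      }
    }
  }
  count
}

# Exhaustive largest near-collinear subset: enumerate every subset of size
# >= 3, fit a line by PCA, keep those within tolerance; prefer larger size,
# then smaller total residual.
oracle_trough_ids <- function(waters, tol) {
  X <- as.matrix(waters[, c("x", "y", "z")])
  n <- nrow(X)
  best <- NULL
  for (k in n:3) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      Xc <- scale(X[sub, , drop = FALSE], scale = FALSE)
      pc <- prcomp(Xc, center = FALSE)
      perp <- sqrt(pmax(0, rowSums(Xc^2) - (Xc %*% pc$rotation[, 1])^2))
      if (max(perp) <= tol + 1e-9) {
        cand <- list(sub = sub, total = sum(perp))
        if (is.null(best) || cand$total < best$total - 1e-12) best <- cand
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) character(0) else sort(waters$water_id[best$sub])
}

# A toy crystal whose IBS-like first residues have a planted zigzag of
# waters nearby; reused across structure/pipeline tests.
make_motif_structure <- function(noise = 0, seed = 1) {
  z <- gen_zigzag(12, 2.86, 116, noise_sigma = noise, seed = seed)
  w <- z$waters
  # park the motif 3 Angstrom above the scaffold CA row of residues 2..5
  w[, c("x", "y", "z")] <- sweep(as.matrix(w[, c("x", "y", "z")]), 2,
                                 c(8, 10, 13), "+")
  list(zigzag = z,
       structure = gen_toy_structure(10, planted_waters = w,
                                     cell = c(60, 50, 55)))
}
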