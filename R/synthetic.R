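# Seeded generators for every input the pipeline consumes, each carrying its
# planted ground truth so analysis stages can be tested for parameter
# recovery. Noise is isotropic Gaussian in Cartesian coordinates (the
# B-factor-style positional uncertainty of crystallographic waters);
# regeneration with the same seed is bit-identical.

.planted_motif <- function(kind, truth, waters, extra = list()) {
  structure(c(list(kind = kind, truth = truth, waters = waters), extra),
            class = "planted_motif")
}

#' @export
print.planted_motif <- function(x, ...) {
  cat("<planted_motif> ", x$kind, " (", nrow(x$waters), " waters)\n", sep = "")
  invisible(x)
}

#' Generate a planar zigzag water chain
#'
#' A chain of `n_waters` oxygens with constant spacing and alternating turn
#' direction so every interior angle equals `angle`, plus isotropic Gaussian
#' noise. The defaults mirror the zigzag bound-water motif of AFP
#' ice-binding sites (spacing ~2.86 Angstrom, angle ~116 degrees);
#' `angle = 180` degenerates to a straight line, which is how trough
#' fixtures are planted.
#'
#' @param n_waters Number of waters (>= 3).
#' @param spacing Consecutive O-O distance in Angstrom (> 0).
#' @param angle Interior angle in degrees.
#' @param noise_sigma Per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed.
#' @return A `"planted_motif"` with `waters` ([water_set()]) and `truth`
#'   (`spacing`, `angle`, `noise_sigma`, `seed`).
#' @export
gen_zigzag <- function(n_waters = 12, spacing = 2.86, angle = 116,
                       noise_sigma = 0, seed = 1) {
  if (spacing <= 0) stop("spacing must be positive")
  if (n_waters < 3) stop("need at least 3 waters")
  delta <- (180 - angle) / 2 * pi / 180
  pts <- matrix(0, n_waters, 3)
  for (k in 2:n_waters) {
    phi <- if (k %% 2 == 0) delta else -delta
    pts[k, ] <- pts[k - 1, ] + spacing * c(cos(phi), sin(phi), 0)
  }
  pts <- with_seed(seed, pts + matrix(stats::rnorm(3 * n_waters, 0, noise_sigma),
                                      n_waters, 3))
  .planted_motif("zigzag",
                 list(spacing = spacing, angle = angle,
                      noise_sigma = noise_sigma, seed = seed),
                 water_set(pts))
}

#' Generate a hydration ring with its side-chain carbons
#'
#' Waters on a regular polygon of the given edge length surrounding a
#' benzene-like carbon hexagon, offset out of the water plane so the mean
#' water-to-nearest-carbon distance equals `carbon_dist` (solved
#' numerically). Defaults mirror the ten-water hydrophobic hydration ring
#' around an IBS phenylalanine (edge ~2.74, carbon distance ~3.4 Angstrom).
#'
#' @param n_waters Ring size (>= 4).
#' @param edge Adjacent water-water distance in Angstrom.
#' @param carbon_dist Target mean water-to-nearest-carbon distance.
#' @param noise_sigma Per-coordinate Gaussian noise sd applied to the waters.
#' @param seed RNG seed.
#' @return A `"planted_motif"` with `waters`, `carbons` (6 x 3 matrix) and
#'   `truth`.
#' @export
gen_ring <- function(n_waters = 10, edge = 2.74, carbon_dist = 3.4,
                     noise_sigma = 0, seed = 1) {
  if (n_waters < 4) stop("need at least 4 waters for a ring")
  radius <- edge / (2 * sin(pi / n_waters))
  th_w <- 2 * pi * (seq_len(n_waters) - 1) / n_waters
  waters0 <- cbind(radius * cos(th_w), radius * sin(th_w), 0)
  r_c <- 1.39  # aromatic ring radius
  th_c <- 2 * pi * (0:5) / 6
  mean_nc <- function(h) {
    carb <- cbind(r_c * cos(th_c), r_c * sin(th_c), h)
    mean(apply(pairwise_dist(waters0, carb), 1, min))
  }
  coplanar <- mean_nc(0)
  h <- if (carbon_dist <= coplanar) 0 else {
    stats::uniroot(function(h) mean_nc(h) - carbon_dist, c(0, 10),
                   tol = 1e-10)$root
  }
  carbons <- cbind(r_c * cos(th_c), r_c * sin(th_c), h)
  pts <- with_seed(seed, waters0 + matrix(stats::rnorm(3 * n_waters, 0, noise_sigma),
                                          n_waters, 3))
  .planted_motif("ring",
                 list(edge = edge, carbon_dist = carbon_dist,
                      noise_sigma = noise_sigma, seed = seed, offset = h),
                 water_set(pts), extra = list(carbons = carbons))
}

#' Generate a rigidly transformed, noised subset of an ice-plane patch
#'
#' Selects a spatially compact subset of patch oxygens, applies a rigid
#' transform (random proper rotation and translation unless given) and adds
#' isotropic Gaussian noise - the planted-truth fixture for docking
#' recovery tests.
#'
#' @param patch An [extract_plane_patch()] result.
#' @param subset_size Number of oxygens to take (<= patch size).
#' @param rotation Optional 3 x 3 proper rotation; random when `NULL`.
#' @param translation Optional length-3 translation; random (within +/- 10
#'   Angstrom) when `NULL`.
#' @param noise_sigma Per-coordinate Gaussian noise sd in Angstrom.
#' @param seed RNG seed.
#' @return A `"planted_motif"` whose `truth` records `rotation`,
#'   `translation`, `subset` (patch row indices) and `noise_sigma`.
#' @export
gen_transformed_patch <- function(patch, subset_size = 11, rotation = NULL,
                                  translation = NULL, noise_sigma = 0,
                                  seed = 1) {
  oxy <- if (inherits(patch, "ice_plane_patch")) patch$oxygens else
    as_xyz_matrix(patch)
  if (subset_size > nrow(oxy)) stop("subset larger than the patch")
  out <- with_seed(seed, {
    seedpt <- sample.int(nrow(oxy), 1)
    ord <- order(pairwise_dist(oxy[seedpt, , drop = FALSE], oxy)[1, ])
    subset <- sort(ord[seq_len(subset_size)])
    R <- rotation %||% random_rotation()
    t_vec <- translation %||% stats::runif(3, -10, 10)
    pts <- oxy[subset, , drop = FALSE] %*% t(R) +
      matrix(t_vec, subset_size, 3, byrow = TRUE)
    pts <- pts + matrix(stats::rnorm(3 * subset_size, 0, noise_sigma),
                        subset_size, 3)
    list(subset = subset, R = R, t = t_vec, pts = pts)
  })
  .planted_motif("lattice_patch",
                 list(rotation = out$R, translation = out$t,
                      subset = out$subset, noise_sigma = noise_sigma,
                      seed = seed),
                 water_set(out$pts))
}

#' Generate a two-state CD melting trace
#'
#' A logistic (two-state) transition between folded and unfolded ellipticity
#' baselines with planted midpoint `t_m` and slope `width`, plus Gaussian
#' noise, sampled on the given temperature grid (default 0.2 degrees C steps
#' from 20 to 60, the standard scan).
#'
#' @param t_m Planted midpoint in degrees C (must lie within the grid).
#' @param width Logistic width parameter in degrees C.
#' @param theta_folded,theta_unfolded Ellipticity baselines (arbitrary CD
#'   units).
#' @param noise_sigma Gaussian noise sd in the same units.
#' @param grid Temperature grid in degrees C.
#' @param t_low,t_high Reference temperatures stored on the trace.
#' @param seed RNG seed.
#' @return A [melt_trace()] with the planted parameters in attribute
#'   `"truth"`.
#' @export
gen_cd_trace <- function(t_m = 47.5, width = 2.0, theta_folded = -20,
                         theta_unfolded = -4, noise_sigma = 0,
                         grid = seq(20, 60, by = 0.2), t_low = min(grid),
                         t_high = max(grid), seed = 1) {
  if (t_m < min(grid) || t_m > max(grid)) stop("grid must span t_m")
  f <- 1 / (1 + exp(-(grid - t_m) / width))
  theta <- theta_folded + (theta_unfolded - theta_folded) * f
  theta <- with_seed(seed, theta + stats::rnorm(length(grid), 0, noise_sigma))
  tr <- melt_trace(grid, theta, t_low = t_low, t_high = t_high)
  attr(tr, "truth") <- list(t_m = t_m, width = width, noise_sigma = noise_sigma,
                            seed = seed)
  tr
}

#' Generate telegraph-process hydrogen-bond occupancy series
#'
#' Two-state Markov (random telegraph) occupancy per bond: bonded runs have
#' geometric length with mean `mean_lifetime / dt` frames, unbonded gaps a
#' geometric length with mean `mean_gap` frames. Region labels are attached
#' through per-bond residue positions.
#'
#' @param mean_lifetime Planted mean bonded lifetime in ps; scalar or one
#'   value per bond (recycled). Must be >= `dt`.
#' @param dt Frame interval in ps.
#' @param n_frames Series length.
#' @param n_bonds Number of independent bond series.
#' @param residue_positions Integer positions (length `n_bonds`, recycled)
#'   used by [region_residence()]; defaults to alternating positions 20
#'   (inside the default IBS ranges) and 60 (outside).
#' @param mean_gap Mean unbonded gap in frames.
#' @param seed RNG seed.
#' @return An [hbond_event_table()] with the planted parameters in attribute
#'   `"truth"`.
#' @export
gen_telegraph_hbonds <- function(mean_lifetime = 80, dt = 1, n_frames = 2000,
                                 n_bonds = 20, residue_positions = NULL,
                                 mean_gap = 5, seed = 1) {
  ml <- rep_len(mean_lifetime, n_bonds)
  if (any(ml < dt)) stop("mean_lifetime must be >= dt")
  pos <- as.integer(rep_len(residue_positions %||% c(20L, 60L), n_bonds))
  p_off <- dt / ml
  p_on <- 1 / mean_gap
  occ <- with_seed(seed, {
    m <- matrix(FALSE, n_frames, n_bonds)
    for (b in seq_len(n_bonds)) {
      # alternate geometric gap/run segments, starting unbonded so the first
      # run's formation is observed; segments drawn in batches for speed
      lens <- integer(0)
      total <- 0L
      while (total < n_frames) {
        k <- max(16L, ceiling(2 * (n_frames - total) / (mean_gap + ml[b] / dt)))
        gaps <- stats::rgeom(k, p_on) + 1L
        runs <- stats::rgeom(k, p_off[b]) + 1L
        batch <- as.integer(rbind(gaps, runs))
        lens <- c(lens, batch)
        total <- total + sum(batch)
      }
      s <- inverse.rle(list(
        lengths = lens,
        values = rep_len(c(FALSE, TRUE), length(lens))
      ))
      m[, b] <- s[seq_len(n_frames)]
    }
    m
  })
  tab <- hbond_event_table(occ, dt,
                           data.frame(residue = pos,
                                      water_id = paste0("w", seq_len(n_bonds)),
                                      stringsAsFactors = FALSE))
  attr(tab, "truth") <- list(mean_lifetime = ml, dt = dt, mean_gap = mean_gap,
                             seed = seed)
  tab
}

#' Generate a writable toy crystal structure
#'
#' A parseable miniature crystal: a poly-alanine scaffold in an extended
#' conformation, planted waters as HOH records, a unit cell and a space
#' group. The result round-trips through [write_structure()] /
#' [read_structure()] and supports symmetry expansion, so the whole
#' structure pipeline is testable without any deposited file. The file and
#' object are synthetic stand-ins, not models of any real protein.
#'
#' @param n_residues Scaffold length (alanines along x, 3.8 Angstrom per
#'   residue, starting at `scaffold_origin`).
#' @param planted_waters A [water_set()], `"planted_motif"`, or list of
#'   either; water coordinates are used as given.
#' @param cell Unit cell (a, b, c, alpha, beta, gamma).
#' @param space_group Space group name (default `"P 21 21 21"`).
#' @param scaffold_origin Cartesian origin of the first residue.
#' @param path Optional output PDB path; written when non-`NULL`.
#' @return The [crystal_structure()] (with the path in `$path` when written).
#' @export
gen_toy_structure <- function(n_residues = 10, planted_waters = NULL,
                              cell = c(40, 50, 60, 90, 90, 90),
                              space_group = "P 21 21 21",
                              scaffold_origin = c(5, 10, 10), path = NULL) {
  res <- list()
  for (i in seq_len(n_residues)) {
    # extended chain along x with a small deterministic wiggle so the Calpha
    # trace is never exactly collinear (superposition would be degenerate)
    ca <- scaffold_origin +
      c(3.8 * (i - 1), 0.3 * sin(0.9 * i), 0.3 * cos(1.3 * i))
    res[[i]] <- data.frame(
      elety = c("N", "CA", "C", "O", "CB"),
      resid = "ALA", chain = "A", resno = i,
      x = ca[1] + c(-1.2, 0, 1.2, 1.6, 0),
      y = ca[2] + c(0.8, 0, 0.8, 1.9, -1.0),
      z = ca[3] + c(0, 0, 0, 0, 1.2),
      o = 1, b = 10, elesy = c("N", "C", "C", "O", "C"),
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, res)
  if (!is.null(planted_waters)) {
    if (inherits(planted_waters, "planted_motif") ||
        inherits(planted_waters, "water_set")) {
      planted_waters <- list(planted_waters)
    }
    wxyz <- do.call(rbind, lapply(planted_waters, function(w) {
      if (inherits(w, "planted_motif")) w <- w$waters
      as_xyz_matrix(w)
    }))
    atoms <- rbind(atoms, data.frame(
      elety = "O", resid = "HOH", chain = "S",
      resno = 1000 + seq_len(nrow(wxyz)),
      x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
      o = 1, b = 20, elesy = "O", stringsAsFactors = FALSE
    ))
  }
  s <- crystal_structure(atoms, cell = cell, space_group = space_group,
                         id = "toy")
  if (!is.null(path)) {
    write_structure(s, path)
    s$path <- path
  }
  s
}
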