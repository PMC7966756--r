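# Ideal hexagonal ice (ice Ih) oxygen sublattice and crystallographic plane
# patches. Hydrogens (and proton disorder) are deliberately absent: bound
# waters in deposited structures are oxygens, so all comparisons are O-O.

#' Build an ideal ice Ih oxygen lattice
#'
#' Generates the oxygen sublattice of hexagonal ice: a wurtzite-type
#' arrangement with four oxygens per hexagonal cell (space group P6_3/mmc,
#' oxygens on the 4f sites with the ideal internal coordinate z = 1/16, which
#' makes all four nearest-neighbour O-O distances equal - 2.76 Angstrom for
#' the default constants). The defaults `a_ice` = 4.52, `c_ice` = 7.36
#' Angstrom are the ice Ih lattice constants near 0 degrees C.
#'
#' @param a_ice,c_ice Hexagonal lattice constants in Angstrom.
#' @param extent Integer number of unit-cell repeats along each axis.
#' @return An object of class `"ice_lattice"` with the Cartesian oxygen
#'   positions (`oxygens`, deterministic ordering), the cell vectors and the
#'   generating parameters.
#' @examples
#' ice <- build_ice_lattice(extent = 2)
#' nrow(ice$oxygens)  # 4 oxygens per cell
#' @export
build_ice_lattice <- function(a_ice = 4.52, c_ice = 7.36, extent = 3) {
  if (a_ice <= 0 || c_ice <= 0) stop("lattice constants must be positive")
  extent <- as.integer(extent)
  if (extent < 1) stop("extent must be >= 1")
  a1 <- c(a_ice, 0, 0)
  a2 <- c(-a_ice / 2, a_ice * sqrt(3) / 2, 0)
  a3 <- c(0, 0, c_ice)
  z0 <- 1 / 16
  basis <- rbind(
    c(1 / 3, 2 / 3, z0),
    c(2 / 3, 1 / 3, z0 + 1 / 2),
    c(2 / 3, 1 / 3, 1 - z0),
    c(1 / 3, 2 / 3, 1 / 2 - z0)
  )
  cells <- expand.grid(k = 0:(extent - 1), j = 0:(extent - 1), i = 0:(extent - 1))
  cells <- as.matrix(cells[, c("i", "j", "k")])
  frac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sweep(basis, 2, cells[r, ], "+")
  }))
  A <- rbind(a1, a2, a3)  # rows are lattice vectors
  oxy <- frac %*% A
  dimnames(oxy) <- NULL
  structure(
    list(a_ice = a_ice, c_ice = c_ice, extent = extent,
         oxygens = oxy, cell_vectors = A),
    class = "ice_lattice"
  )
}

#' @export
print.ice_lattice <- function(x, ...) {
  cat(sprintf("<ice_lattice> a=%.2f c=%.2f extent=%d (%d oxygens)\n",
              x$a_ice, x$c_ice, x$extent, nrow(x$oxygens)))
  invisible(x)
}

# Plane normals and shortest in-plane lattice vectors for the three
# low-index faces of hexagonal ice, in the Cartesian frame of
# build_ice_lattice (a1 along x, c along z).
.plane_geometry <- function(plane_id, a_ice, c_ice) {
  switch(plane_id,
    basal = list(
      normal = c(0, 0, 1),
      e1 = c(1, 0, 0), e2 = c(0, 1, 0)
    ),
    prism1 = list(  # {10-10}: contains c and the a2 lattice vector
      normal = c(sqrt(3) / 2, 1 / 2, 0),
      e1 = c(-1 / 2, sqrt(3) / 2, 0), e2 = c(0, 0, 1)
    ),
    prism2 = list(  # {11-20}: contains c and the (a1 - a2) lattice vector
      normal = c(1 / 2, sqrt(3) / 2, 0),
      e1 = c(sqrt(3) / 2, -1 / 2, 0), e2 = c(0, 0, 1)
    ),
    stop("plane_id must be one of 'basal', 'prism1', 'prism2'")
  )
}

#' Extract a crystallographic plane patch from an ice lattice
#'
#' Slices the oxygen lattice along one of the low-index faces of hexagonal
#' ice: `basal` (0001), `prism1` (10-10) or `prism2` (11-20). The patch is
#' the slab of oxygens within `thickness` of the best-populated plane offset
#' near the lattice center (for the basal face this is the puckered bilayer
#' whose chair-ring arrangement the bound waters are compared against).
#'
#' @param lattice An [build_ice_lattice()] result.
#' @param plane_id `"basal"`, `"prism1"` or `"prism2"`.
#' @param thickness Keep oxygens with |signed distance - offset| <=
#'   `thickness` (Angstrom); 1.0 captures one puckered bilayer.
#' @param min_count Fail unless the patch holds at least this many oxygens.
#' @return An object of class `"ice_plane_patch"`: `oxygens` (Cartesian),
#'   `plane_id`, `thickness`, in-plane unit basis `e1`/`e2` and `normal`.
#' @export
extract_plane_patch <- function(lattice, plane_id = c("basal", "prism1", "prism2"),
                                thickness = 1.0, min_count = 12L) {
  stopifnot(inherits(lattice, "ice_lattice"))
  plane_id <- match.arg(plane_id)
  if (thickness < 0) stop("thickness must be >= 0")
  geo <- .plane_geometry(plane_id, lattice$a_ice, lattice$c_ice)
  oxy <- lattice$oxygens
  d <- as.numeric(oxy %*% geo$normal)
  # candidate offsets: distinct (rounded) layer positions; pick the offset
  # whose slab holds the most oxygens, ties toward the lattice center
  layers <- sort(unique(round(d, 4)))
  counts <- vapply(layers, function(l) sum(abs(d - l) <= thickness + 1e-9), integer(1))
  center <- stats::median(d)
  best <- which(counts == max(counts))
  offset <- layers[best[which.min(abs(layers[best] - center))]]
  keep <- abs(d - offset) <= thickness + 1e-9
  if (sum(keep) < min_count) {
    stop("plane patch holds only ", sum(keep), " oxygens (need ", min_count,
         "); rebuild the lattice with a larger extent")
  }
  oxy <- oxy[keep, , drop = FALSE]
  structure(
    list(plane_id = plane_id, thickness = thickness, offset = offset,
         oxygens = oxy, e1 = geo$e1, e2 = geo$e2, normal = geo$normal,
         a_ice = lattice$a_ice, c_ice = lattice$c_ice),
    class = "ice_plane_patch"
  )
}

#' @export
print.ice_plane_patch <- function(x, ...) {
  cat(sprintf("<ice_plane_patch> %s plane, %d oxygens, thickness %.2f\n",
              x$plane_id, nrow(x$oxygens), x$thickness))
  invisible(x)
}

#' Characteristic repeat spacings of a plane patch
#'
#' Returns the distinct repeat distances of the patch: the lengths of the
#' translation vectors that map the patch onto itself (detected from the
#' generated points, so finite-patch edges are tolerated) together with the
#' nearest-neighbour O-O distance. These are the values compared against
#' measured water-water intervals on an ice-binding site - e.g. the prism
#' face of the default lattice repeats at ~4.5 and ~14.7 Angstrom (2 c).
#'
#' @param patch An [extract_plane_patch()] result.
#' @param max_spacing Ignore repeats longer than this (Angstrom).
#' @param digits Spacings are deduplicated after rounding to this many
#'   decimals (default 2, i.e. 0.01 Angstrom).
#' @return Sorted numeric vector of distinct spacings in Angstrom.
#' @export
characteristic_spacings <- function(patch, max_spacing = 16, digits = 2) {
  stopifnot(inherits(patch, "ice_plane_patch"))
  oxy <- patch$oxygens
  if (nrow(oxy) < 3) stop("patch must contain at least 3 oxygens")
  tol <- 1e-3
  centroid <- colMeans(oxy)
  ref <- which.min(rowSums(sweep(oxy, 2, centroid)^2))
  diffs <- sweep(oxy, 2, oxy[ref, ])
  lens <- sqrt(rowSums(diffs^2))
  cand <- which(lens > 0.5 & lens <= max_spacing)
  # bounding box of the patch, shrunk so edge effects don't veto a period
  lo <- apply(oxy, 2, min) + 0.1
  hi <- apply(oxy, 2, max) - 0.1
  spacings <- numeric(0)
  for (k in cand) {
    t_vec <- diffs[k, ]
    mapped <- sweep(oxy, 2, t_vec, "+")
    dmin <- apply(pairwise_dist(mapped, oxy), 1, min)
    inside <- rowSums(sweep(mapped, 2, lo, ">=") & sweep(mapped, 2, hi, "<=")) == 3
    hits <- dmin < tol
    if (sum(hits) >= 3 && all(hits[inside])) {
      spacings <- c(spacings, lens[k])
    }
  }
  d <- pairwise_dist(oxy)
  nn <- min(d[d > tol])
  out <- sort(unique(round(c(nn, spacings), digits)))
  out[out <= max_spacing]
}

#' Export a plane patch (or lattice) as a PDB of water oxygens
#'
#' @param x An `ice_plane_patch` or `ice_lattice`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_ice_pdb <- function(x, path) {
  oxy <- if (inherits(x, "ice_plane_patch") || inherits(x, "ice_lattice")) {
    x$oxygens
  } else {
    as_xyz_matrix(x)
  }
  atoms <- data.frame(
    elety = "O", resid = "HOH", chain = "W", resno = seq_len(nrow(oxy)),
    x = oxy[, 1], y = oxy[, 2], z = oxy[, 3], o = 1, b = 0, elesy = "O",
    stringsAsFactors = FALSE
  )
  write_structure(crystal_structure(atoms, id = "ice"), path)
}
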