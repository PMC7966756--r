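#' @importFrom stats setNames
NULL

# Residue names accepted as crystallographic water. Deposited structures carry
# oxygen-only waters, so all water geometry in this package is oxygen geometry.
WATER_RESNAMES <- c("HOH", "WAT", "H2O")

# Built-in symmetry operator tables (rotation part + fractional translation).
# P 21 21 21 is the orthorhombic group of the reference AFP crystals; P 1 is
# the identity-only group used by the synthetic fixtures.
.builtin_symops <- function() {
  list(
    "P1" = list(list(R = diag(3), t = c(0, 0, 0))),
    "P212121" = list(
      list(R = diag(3), t = c(0, 0, 0)),
      list(R = diag(c(1, -1, -1)), t = c(1 / 2, 1 / 2, 0)),
      list(R = diag(c(-1, 1, -1)), t = c(0, 1 / 2, 1 / 2)),
      list(R = diag(c(-1, -1, 1)), t = c(1 / 2, 0, 1 / 2))
    )
  )
}

.normalize_sg <- function(name) {
  gsub("[^A-Z0-9-]", "", toupper(name %||% ""))
}

#' Symmetry operators for a space group
#'
#' Returns the list of crystallographic symmetry operators (3x3 rotation part
#' plus fractional translation) for a supported space group. Built-in tables
#' cover `P 1` and `P 21 21 21`; other groups must supply operators through the
#' file header (`REMARK 290` in PDB).
#'
#' @param space_group Space group name (Hermann-Mauguin, spacing ignored).
#' @return List of operators, each `list(R = <3x3>, t = <length-3>)`.
#' @export
sym_ops <- function(space_group) {
  tab <- .builtin_symops()
  key <- .normalize_sg(space_group)
  if (!key %in% names(tab)) {
    stop(
      "no built-in operators for space group '", space_group,
      "'; supported built-ins: P 1, P 21 21 21 ",
      "(or supply operators via the PDB REMARK 290 header)"
    )
  }
  tab[[key]]
}

#' Construct a crystal structure object
#'
#' The central container of the package: an atom table plus unit-cell and
#' space-group metadata. Most users will obtain one from [read_structure()] or
#' [gen_toy_structure()] rather than calling this directly.
#'
#' @param atoms Data frame with columns `elety` (atom name), `resid` (residue
#'   name), `chain`, `resno` (integer author numbering), `alt`, `x`, `y`, `z`,
#'   `o` (occupancy), `b` (B-factor), `elesy` (element). A `sym` column tags
#'   symmetry copies (`"1_555"` for original atoms) and a logical `water`
#'   column flags water residues; both are derived when absent.
#' @param cell Unit cell as numeric of length 6 (`a`, `b`, `c` in Angstrom,
#'   `alpha`, `beta`, `gamma` in degrees) or `NULL` when unknown.
#' @param space_group Space group name, e.g. `"P 21 21 21"`.
#' @param symops Optional operator list as returned by [sym_ops()]; looked up
#'   from `space_group` when `NULL` and the group is a built-in.
#' @param id Identifier string carried through reports.
#' @return An object of class `"crystal_structure"`.
#' @export
crystal_structure <- function(atoms, cell = NULL, space_group = "P 1",
                              symops = NULL, id = "structure") {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$alt)) atoms$alt <- NA_character_
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  if (is.null(atoms$sym)) atoms$sym <- "1_555"
  if (is.null(atoms$water)) atoms$water <- atoms$resid %in% WATER_RESNAMES
  assert_finite_coords(as_xyz_matrix(atoms), paste(atoms$chain, atoms$resno, atoms$elety))
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancies must lie in [0, 1]")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$alt, atoms$sym)
  if (anyDuplicated(key)) {
    stop("duplicate atoms (chain/residue/atom-name/altloc/symmetry must be unique)")
  }
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) == 3) cell <- c(cell, 90, 90, 90)
    if (length(cell) != 6) stop("cell must have 6 parameters (a, b, c, alpha, beta, gamma)")
    names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
    if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
    if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) stop("cell angles must lie in (0, 180)")
  }
  if (is.null(symops) && .normalize_sg(space_group) %in% names(.builtin_symops())) {
    symops <- sym_ops(space_group)
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, cell = cell, space_group = space_group,
         symops = symops, id = id),
    class = "crystal_structure"
  )
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure> ", x$id, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), " (", sum(x$atoms$water), " water)\n", sep = "")
  if (!is.null(x$cell)) {
    cat(sprintf("  cell:  a=%.2f b=%.2f c=%.2f  %s\n",
                x$cell["a"], x$cell["b"], x$cell["c"], x$space_group))
  }
  invisible(x)
}

# Fractional -> Cartesian orthogonalization matrix (a along x convention).
orth_matrix <- function(cell) {
  ca <- cos(cell["alpha"] * pi / 180)
  cb <- cos(cell["beta"] * pi / 180)
  cg <- cos(cell["gamma"] * pi / 180)
  sg <- sin(cell["gamma"] * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  m <- matrix(c(
    cell["a"], cell["b"] * cg, cell["c"] * cb,
    0, cell["b"] * sg, cell["c"] * (ca - cb * cg) / sg,
    0, 0, cell["c"] * v / sg
  ), nrow = 3, byrow = TRUE)
  unname(m)
}

frac_matrix <- function(cell) solve(orth_matrix(cell))

# ---------------------------------------------------------------------------
# Reading / writing

.parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(list(cell = NULL, space_group = "P 1"))
  cl <- cl[1]
  cell <- as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)
  ))
  sg <- trimws(substr(cl, 56, 66))
  if (!nzchar(sg)) sg <- "P 1"
  list(cell = cell, space_group = sg)
}

.parse_remark290 <- function(lines) {
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (!length(sm)) return(NULL)
  fields <- lapply(strsplit(trimws(sub("^REMARK 290", "", sm)), "\\s+"), function(f) {
    list(row = as.integer(substr(f[1], 6, 6)), op = as.integer(f[2]),
         vals = as.numeric(f[3:6]))
  })
  nops <- max(vapply(fields, function(f) f$op, integer(1)))
  ops <- replicate(nops, list(R = matrix(0, 3, 3), t = numeric(3)), simplify = FALSE)
  for (f in fields) {
    ops[[f$op]]$R[f$row, ] <- f$vals[1:3]
    ops[[f$op]]$t[f$row] <- f$vals[4]
  }
  ops
}

.collapse_altloc <- function(atoms) {
  has_alt <- !is.na(atoms$alt) & nzchar(atoms$alt)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, atoms$sym)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    # keep the highest-occupancy conformer; ties broken by altloc letter ('A' wins)
    ord <- order(-atoms$o[idx], atoms$alt[idx], na.last = TRUE)
    keep[idx[-ord[1]]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

.cif_field <- function(lines, tag) {
  ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
  if (!length(ln)) return(NA_character_)
  val <- trimws(sub(paste0("^", tag), "", ln[1]))
  gsub("^['\"]|['\"]$", "", val)
}

#' Read a crystal structure from PDB or mmCIF
#'
#' Atom records are read through bio3d; the unit cell, space-group name and
#' any `REMARK 290` symmetry operators are taken from the file header.
#' Alternate locations are collapsed to a single conformer per atom (highest
#' occupancy, ties resolved toward altloc `A`), and water residues
#' (HOH/WAT/H2O) are flagged.
#'
#' @param path Path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A [crystal_structure()].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' gen_toy_structure(n_residues = 5, path = pdb)
#' s <- read_structure(pdb)
#' s$cell
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    pdb <- tryCatch(
      bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
      error = function(e) stop("failed to parse PDB file '", path, "': ",
                               conditionMessage(e))
    )
    hdr <- .parse_cryst1(lines)
    cell <- hdr$cell
    sg <- hdr$space_group
    symops <- .parse_remark290(lines)
  } else {
    pdb <- tryCatch(
      bio3d::read.cif(path, verbose = FALSE),
      error = function(e) stop("failed to parse mmCIF file '", path, "': ",
                               conditionMessage(e))
    )
    cellv <- suppressWarnings(as.numeric(c(
      .cif_field(lines, "_cell.length_a"), .cif_field(lines, "_cell.length_b"),
      .cif_field(lines, "_cell.length_c"), .cif_field(lines, "_cell.angle_alpha"),
      .cif_field(lines, "_cell.angle_beta"), .cif_field(lines, "_cell.angle_gamma")
    )))
    cell <- if (all(is.finite(cellv))) cellv else NULL
    sg <- .cif_field(lines, "_symmetry.space_group_name_H-M")
    if (is.na(sg)) sg <- "P 1"
    symops <- NULL
  }
  a <- pdb$atom
  atoms <- data.frame(
    elety = a$elety, resid = a$resid, chain = a$chain,
    resno = as.integer(a$resno), alt = a$alt,
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elesy = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                   substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    stringsAsFactors = FALSE
  )
  atoms <- .collapse_altloc(atoms)
  atoms$alt <- NA_character_
  if (is.null(symops)) {
    symops <- tryCatch(sym_ops(sg), error = function(e) NULL)
  }
  crystal_structure(atoms, cell = cell, space_group = sg, symops = symops,
                    id = sub("\\.[^.]+$", "", basename(path)))
}

#' Write a crystal structure as PDB
#'
#' Writes fixed-width PDB atom records through bio3d plus a `CRYST1` header
#' when the unit cell is known, so [read_structure()] round-trips cell and
#' space-group metadata.
#'
#' @param structure A [crystal_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  a <- structure$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    type = ifelse(a$water, "HETATM", "ATOM"),
    xyz = as.numeric(t(as_xyz_matrix(a))),
    resno = a$resno, resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    elety = a$elety, o = a$o, b = a$b, elesy = a$elesy
  )
  body <- readLines(tmp, warn = FALSE)
  header <- character(0)
  if (!is.null(structure$cell)) {
    header <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      structure$cell["a"], structure$cell["b"], structure$cell["c"],
      structure$cell["alpha"], structure$cell["beta"], structure$cell["gamma"],
      structure$space_group, length(structure$symops %||% list(1))
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selections and regions

#' Define named residue-position regions
#'
#' @param ... Named numeric vectors of inclusive range pairs, e.g.
#'   `ibs = c(19, 25, 38, 45)` for residues 19-25 and 38-45.
#' @return A `"region_definition"`: named list of two-column `from`/`to`
#'   matrices.
#' @seealso [ibs_regions()] for the default AFP ice-binding-site ranges.
#' @export
region_definition <- function(...) {
  args <- list(...)
  if (!length(args) || is.null(names(args)) || any(!nzchar(names(args)))) {
    stop("regions must be named")
  }
  out <- lapply(args, function(v) {
    v <- as.integer(v)
    if (length(v) %% 2 != 0) stop("each region needs from/to pairs")
    m <- matrix(v, ncol = 2, byrow = TRUE)
    colnames(m) <- c("from", "to")
    if (any(m < 1)) stop("residue positions must be >= 1")
    if (any(m[, 2] < m[, 1])) stop("range end before start")
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("ranges within a region must not overlap")
    }
    m
  })
  structure(out, class = "region_definition")
}

#' Default ice-binding-site residue ranges
#'
#' Residue positions of the compound ice-binding site (loop plus beta-sheet
#' sub-sites) of the 223-residue beta-helical fungal AFP scaffold.
#'
#' @return A [region_definition()] with a single `IBS` region covering
#'   positions 19-25, 38-45, 123-129, 147-153, 174-180, 192-198 and 210-216.
#' @export
ibs_regions <- function() {
  region_definition(IBS = c(19, 25, 38, 45, 123, 129, 147, 153,
                            174, 180, 192, 198, 210, 216))
}

.positions_in <- function(resno, ranges) {
  hit <- rep(FALSE, length(resno))
  for (r in seq_len(nrow(ranges))) {
    hit <- hit | (resno >= ranges[r, 1] & resno <= ranges[r, 2])
  }
  hit
}

# Atoms of `structure` whose residue number falls in any range of `regions`.
atoms_in_regions <- function(structure, regions, chain = NULL, protein_only = TRUE) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (protein_only) a <- a[!a$water, , drop = FALSE]
  hit <- rep(FALSE, nrow(a))
  for (m in unclass(regions)) hit <- hit | .positions_in(a$resno, m)
  a[hit, , drop = FALSE]
}

#' Construct a water set
#'
#' An ordered set of water oxygen positions with unique identifiers; the
#' common currency of the network, docking and synthetic-data modules.
#'
#' @param xyz n x 3 matrix (or data frame with `x`, `y`, `z`) of oxygen
#'   positions in Angstrom.
#' @param ids Character identifiers, unique; defaults to `W1..Wn`.
#' @return A data frame of class `"water_set"` with columns `water_id`, `x`,
#'   `y`, `z`.
#' @export
water_set <- function(xyz, ids = NULL) {
  m <- as_xyz_matrix(xyz)
  if (is.null(ids)) ids <- paste0("W", seq_len(nrow(m)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("water ids must be unique")
  assert_finite_coords(m, ids)
  out <- data.frame(water_id = ids, x = m[, 1], y = m[, 2], z = m[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("water_set", "data.frame")
  out
}

#' All water oxygens of a structure as a water set
#'
#' @param structure A [crystal_structure()].
#' @return A [water_set()] ordered by chain, residue number and symmetry tag;
#'   ids are `chain.resno.symtag`.
#' @export
waters_of <- function(structure) {
  a <- structure$atoms
  w <- a[a$water & a$elesy == "O", , drop = FALSE]
  w <- w[order(w$chain, w$resno, w$sym), , drop = FALSE]
  water_set(w[, c("x", "y", "z")],
            ids = sprintf("%s.%d.%s", ifelse(is.na(w$chain), "_", w$chain),
                          w$resno, w$sym))
}

#' Select waters near named residues
#'
#' Returns the waters whose oxygen lies within `cutoff` of any atom of the
#' residues named by `regions` - the operational definition of "waters on the
#' ice-binding site". The cutoff behind the reference structures' reported
#' IBS-water count is not fixed by convention, so it is a parameter
#' (default 4.0 Angstrom, any-atom distance).
#'
#' @param structure A [crystal_structure()] (symmetry-expanded copies count).
#' @param regions A [region_definition()].
#' @param cutoff Any-atom distance cutoff in Angstrom (> 0 returns waters,
#'   0 returns an empty set).
#' @param chain Optional chain filter applied to the protein atoms.
#' @return A [water_set()], deterministically ordered (chain, residue number,
#'   symmetry tag); empty with a warning when nothing is within reach.
#' @export
select_waters_near <- function(structure, regions, cutoff = 4.0, chain = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (cutoff < 0) stop("cutoff must be >= 0")
  prot <- atoms_in_regions(structure, regions, chain = chain)
  if (!nrow(prot)) stop("no protein atoms in the requested regions")
  w <- waters_of(structure)
  if (!nrow(w) || cutoff == 0) {
    warning("no waters within ", cutoff, " Angstrom of the selection")
    return(w[integer(0), , drop = FALSE])
  }
  d <- pairwise_dist(w, as_xyz_matrix(prot))
  keep <- apply(d, 1, min) <= cutoff + 1e-9
  if (!any(keep)) {
    warning("no waters within ", cutoff, " Angstrom of the selection")
  }
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand crystallographic symmetry around a selection
#'
#' Applies the space-group operators plus +/-1 unit-cell translations to the
#' structure's waters and keeps every image that falls within `radius` of the
#' center selection, so the ice-binding site is surrounded by all
#' crystallographically equivalent waters (as done when surveying bound-water
#' networks across crystals in different space groups). Images closer than
#' `dedup_tol` to an existing atom are dropped; added copies carry a
#' `op_lmn`-style symmetry tag (operator index, shifted cell translations).
#'
#' @param structure A [crystal_structure()] with unit cell and operators.
#' @param center A [water_set()], an n x 3 coordinate matrix, or a
#'   [region_definition()] naming protein residues to center on.
#' @param radius Keep images within this distance (Angstrom) of the center.
#' @param chain Chain filter used when `center` is a region definition.
#' @param dedup_tol Images within this distance of an existing atom are
#'   considered duplicates (default 0.1 Angstrom).
#' @return A new [crystal_structure()] containing the original atoms plus the
#'   tagged water images.
#' @export
expand_symmetry <- function(structure, center, radius = 6.0, chain = NULL,
                            dedup_tol = 0.1) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.null(structure$cell)) {
    stop("unit cell required for symmetry expansion but absent from the structure")
  }
  ops <- structure$symops
  if (is.null(ops)) {
    stop(
      "no symmetry operators for space group '", structure$space_group,
      "'; supported built-ins: P 1, P 21 21 21 ",
      "(or supply operators via the PDB REMARK 290 header)"
    )
  }
  cen <- if (inherits(center, "region_definition")) {
    as_xyz_matrix(atoms_in_regions(structure, center, chain = chain))
  } else {
    as_xyz_matrix(center)
  }
  if (!nrow(cen)) stop("empty center selection")
  a <- structure$atoms
  wat <- a[a$water, , drop = FALSE]
  if (!nrow(wat)) return(structure)
  M <- orth_matrix(structure$cell)
  Minv <- frac_matrix(structure$cell)
  frac <- t(Minv %*% t(as_xyz_matrix(wat)))
  existing <- as_xyz_matrix(a)
  shifts <- as.matrix(expand.grid(n1 = -1:1, n2 = -1:1, n3 = -1:1))
  added <- list()
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    base <- frac %*% t(op$R)
    base <- sweep(base, 2, op$t, "+")
    for (s in seq_len(nrow(shifts))) {
      n <- shifts[s, ]
      if (i == 1L && all(n == 0)) next  # the original copy itself
      img <- t(M %*% t(sweep(base, 2, n, "+")))
      dmin <- apply(pairwise_dist(img, cen), 1, min)
      keep <- which(dmin <= radius + 1e-9)
      if (!length(keep)) next
      dup <- apply(pairwise_dist(img[keep, , drop = FALSE], existing), 1, min) < dedup_tol
      keep <- keep[!dup]
      if (!length(keep)) next
      copies <- wat[keep, , drop = FALSE]
      copies[, c("x", "y", "z")] <- img[keep, , drop = FALSE]
      copies$sym <- sprintf("%d_%d%d%d", i, n[1] + 5, n[2] + 5, n[3] + 5)
      existing <- rbind(existing, img[keep, , drop = FALSE])
      added[[length(added) + 1L]] <- copies
    }
  }
  if (length(added)) a <- rbind(a, do.call(rbind, added))
  rownames(a) <- NULL
  crystal_structure(a, cell = structure$cell, space_group = structure$space_group,
                    symops = structure$symops, id = structure$id)
}
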