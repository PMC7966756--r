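# Rigid-body superposition: closed-form Kabsch fits, correspondence-search
# docking of bound-water sets onto ice-plane patches (multi-start iterative
# closest point with exact injective assignment), and Calpha structure
# comparison.

.superposition_result <- function(rotation, translation, rmsd, n_pairs,
                                  correspondence = NULL, converged = TRUE,
                                  n_starts = NA_integer_, seed = NA_integer_) {
  structure(
    list(rotation = rotation, translation = translation, rmsd = rmsd,
         n_pairs = n_pairs, correspondence = correspondence,
         converged = converged, n_starts = n_starts, seed = seed),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD %.4f Angstrom%s\n",
              x$n_pairs, x$rmsd, if (isTRUE(x$converged)) "" else " (unconverged)"))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' root-mean-squared deviation between `R p_i + t` and `q_i` over the given
#' pairing. Reflections are excluded (det(R) = +1): the handedness of a water
#' motif is physically meaningful.
#'
#' @param P,Q n x 3 coordinate matrices (or [water_set()]s).
#' @param pairing Two-column index matrix pairing rows of `P` with rows of
#'   `Q`; defaults to row-by-row.
#' @return A `"superposition_result"` with `rotation`, `translation`, `rmsd`
#'   and `n_pairs`. The fitted transform maps `P` onto `Q`.
#' @examples
#' P <- matrix(rnorm(12), 4)
#' fit <- kabsch(P, P)
#' fit$rmsd  # 0
#' @export
kabsch <- function(P, Q, pairing = NULL) {
  P <- as_xyz_matrix(P)
  Q <- as_xyz_matrix(Q)
  if (is.null(pairing)) {
    if (nrow(P) != nrow(Q)) stop("P and Q differ in size; supply a pairing")
    pairing <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
  }
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3) stop("need at least 3 point pairs")
  Pp <- P[pairing[, 1], , drop = FALSE]
  Qp <- Q[pairing[, 2], , drop = FALSE]
  cp <- colMeans(Pp)
  cq <- colMeans(Qp)
  Pc <- sweep(Pp, 2, cp)
  Qc <- sweep(Qp, 2, cq)
  sv <- svd(crossprod(Pc, Qc))  # H = Pc^T Qc
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate (collinear or coincident) point set; rotation ill-defined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)
  resid <- Qp - (Pp %*% t(R) + matrix(t_vec, nrow(Pp), 3, byrow = TRUE))
  rmsd <- sqrt(mean(rowSums(resid^2)))
  .superposition_result(R, t_vec, rmsd, nrow(pairing))
}

# Apply a superposition's rigid transform to coordinates.
#' Apply a fitted rigid transform
#' @param fit A `"superposition_result"`.
#' @param X n x 3 coordinates (or [water_set()]).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, X) {
  X <- as_xyz_matrix(X)
  X %*% t(fit$rotation) + matrix(fit$translation, nrow(X), 3, byrow = TRUE)
}

# Best-fit plane normal of a point set (smallest principal axis).
.plane_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}

#' Dock a bound-water set onto an ice-plane patch
#'
#' Multi-start iterative closest point (ICP) registration: from each starting
#' orientation the algorithm alternates (a) the optimal injective assignment
#' of each water to a distinct lattice oxygen (exact bipartite assignment on
#' the distance matrix, Hungarian method) and (b) a Kabsch fit on that
#' assignment, until the RMSD change drops below `tol`. Starts combine
#' orientations that align the waters' best-fit plane with the patch plane
#' (both signs, several in-plane angles) with uniformly random orientations.
#' The global best over all starts is returned; the run is deterministic
#' given `seed`.
#'
#' @param waters A [water_set()] (or n x 3 matrix) of bound-water oxygens.
#' @param patch An [extract_plane_patch()] result (its oxygen count must be
#'   at least the water count).
#' @param n_starts Total number of starting orientations (default 64).
#' @param tol Convergence threshold on the RMSD change (Angstrom).
#' @param max_iter Maximum ICP iterations per start.
#' @param seed RNG seed for the random starts (recorded in the result).
#' @return A `"superposition_result"`; `correspondence` maps each water
#'   (named by id when available) to a patch oxygen index, and `converged`
#'   reports whether the best start converged within `max_iter`.
#' @export
dock_waters_to_plane <- function(waters, patch, n_starts = 64, tol = 1e-6,
                                 max_iter = 100, seed = 1) {
  W <- as_xyz_matrix(waters)
  ids <- if (inherits(waters, "water_set")) waters$water_id else
    paste0("W", seq_len(nrow(W)))
  L <- if (inherits(patch, "ice_plane_patch")) patch$oxygens else
    as_xyz_matrix(patch)
  if (nrow(L) < nrow(W)) {
    stop("patch holds fewer oxygens (", nrow(L), ") than waters (", nrow(W), ")")
  }
  if (nrow(W) < 3) stop("need at least 3 waters to dock")
  n_normal <- c(0, 0, 1)
  if (inherits(patch, "ice_plane_patch")) n_normal <- patch$normal
  w_normal <- .plane_normal(W)
  cw <- colMeans(W)
  cl <- colMeans(L)

  # plane-aligned seeds: both normal signs crossed with in-plane angles fine
  # enough (15 degrees) that some start lands in the basin of the correct
  # lattice registration, then random orientations up to n_starts
  starts <- list()
  angles <- seq(0, 345, by = 15)
  for (sgn in c(1, -1)) {
    base <- rotation_between(sgn * w_normal, n_normal)
    for (ang in angles) {
      starts[[length(starts) + 1L]] <- rotation_about_axis(n_normal, ang) %*% base
    }
  }
  n_random <- max(0L, as.integer(n_starts) - length(starts))
  rand <- with_seed(seed, replicate(n_random, random_rotation(), simplify = FALSE))
  starts <- c(starts[seq_len(min(length(starts), n_starts))], rand)
  # in-plane registration offsets tried from every start (the hexagonal
  # lattice has shift-equivalent near-minima about one bond apart)
  e1 <- if (inherits(patch, "ice_plane_patch")) patch$e1 else c(1, 0, 0)
  e2 <- if (inherits(patch, "ice_plane_patch")) patch$e2 else c(0, 1, 0)
  offsets <- list(c(0, 0, 0), 1.4 * e1, -1.4 * e1, 1.4 * e2, -1.4 * e2)

  run_icp <- function(R0, off) {
    R <- R0
    t_vec <- as.numeric(cl - R %*% cw) + off
    prev <- Inf
    conv <- FALSE
    corr <- NULL
    for (it in seq_len(max_iter)) {
      Wt <- W %*% t(R) + matrix(t_vec, nrow(W), 3, byrow = TRUE)
      D <- pairwise_dist(Wt, L)
      corr <- as.integer(clue::solve_LSAP(D))
      fit <- kabsch(W, L, pairing = cbind(seq_len(nrow(W)), corr))
      R <- fit$rotation
      t_vec <- fit$translation
      if (abs(prev - fit$rmsd) < tol) {
        conv <- TRUE
        prev <- fit$rmsd
        break
      }
      prev <- fit$rmsd
    }
    list(rmsd = prev, R = R, t = t_vec, corr = corr, converged = conv)
  }

  best <- NULL
  for (st in starts) {
    for (off in offsets) {
      res <- run_icp(st, off)
      if (is.null(best) || res$rmsd < best$rmsd) best <- res
    }
  }
  if (!best$converged) {
    warning("ICP did not converge within ", max_iter,
            " iterations; returning best solution so far")
  }
  out <- .superposition_result(best$R, best$t, best$rmsd, nrow(W),
                               correspondence = stats::setNames(best$corr, ids),
                               converged = best$converged,
                               n_starts = length(starts), seed = seed)
  out
}

#' Calpha RMSD between two structures
#'
#' Pairs Calpha atoms of the given chains by author residue number, performs
#' a Kabsch fit and returns the RMSD - the standard whole-fold comparison
#' between closely related structures.
#'
#' @param structA,structB [crystal_structure()]s sharing residue numbering.
#' @param chains Length-2 character vector: the chain of `structA` and the
#'   chain of `structB` (default both `"A"`).
#' @return RMSD in Angstrom (numeric scalar) with the underlying
#'   `"superposition_result"` attached as attribute `fit`.
#' @export
calpha_rmsd <- function(structA, structB, chains = c("A", "A")) {
  get_ca <- function(s, ch) {
    a <- s$atoms
    a <- a[!a$water & a$elety == "CA" & a$chain %in% ch, , drop = FALSE]
    a[!duplicated(a$resno), , drop = FALSE]
  }
  ca1 <- get_ca(structA, chains[1])
  ca2 <- get_ca(structB, chains[2])
  common <- intersect(ca1$resno, ca2$resno)
  if (length(common) < 3) stop("fewer than 3 common Calpha residues")
  ca1 <- ca1[match(common, ca1$resno), , drop = FALSE]
  ca2 <- ca2[match(common, ca2$resno), , drop = FALSE]
  fit <- kabsch(as_xyz_matrix(ca1), as_xyz_matrix(ca2))
  out <- fit$rmsd
  attr(out, "fit") <- fit
  out
}
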