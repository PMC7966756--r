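# Proximity networks over bound waters and the three hydration motifs of
# beta-helical AFP ice-binding sites: zigzag chains (distance/angle
# statistics), linear troughs along hydrophobic grooves, and ring-like
# hydration shells around a hydrophobic side chain.

#' Build a water proximity network
#'
#' Connects every pair of waters within `cutoff` (closed interval; the
#' conventional display cutoff for proximal bound waters is 3.7 Angstrom).
#'
#' @param waters A [water_set()] with at least 2 waters.
#' @param cutoff Edge distance cutoff in Angstrom.
#' @return A `"water_network"`: `nodes` (the water set), `edges` (data frame
#'   `i`, `j`, `from`, `to`, `dist`, deterministic order), `cutoff`.
#' @export
build_network <- function(waters, cutoff = 3.7) {
  stopifnot(inherits(waters, "water_set") || is.matrix(waters))
  if (!inherits(waters, "water_set")) waters <- water_set(waters)
  if (nrow(waters) < 2) stop("need at least 2 waters")
  assert_finite_coords(as_xyz_matrix(waters), waters$water_id)
  d <- pairwise_dist(waters)
  idx <- which(upper.tri(d) & d <= cutoff + 1e-9, arr.ind = TRUE)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    from = waters$water_id[idx[, 1]], to = waters$water_id[idx[, 2]],
    dist = d[idx], stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = waters, edges = edges, cutoff = cutoff),
            class = "water_network")
}

#' @export
print.water_network <- function(x, ...) {
  cat(sprintf("<water_network> %d waters, %d edges (cutoff %.2f Angstrom)\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

.network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$water_id)
  )
}

#' Distance and angle statistics of a water network
#'
#' Edge distances plus the angle at the middle water of every connected
#' triple i-j-k (both edges present, angle measured at j) - the statistics
#' by which a zigzag bound-water chain is compared with an ice plane.
#'
#' @param net A [build_network()] result with at least one edge.
#' @return A `"network_stats"` list: `distances`, `angles` (degrees),
#'   `mean_distance`, `mean_angle`, ranges, `component_sizes` and
#'   `n_branches` (waters with 3 or more neighbours).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "water_network"))
  if (!nrow(net$edges)) stop("network has no edges")
  xyz <- as_xyz_matrix(net$nodes)
  nbrs <- lapply(seq_len(nrow(net$nodes)), function(v) {
    sort(unique(c(net$edges$j[net$edges$i == v], net$edges$i[net$edges$j == v])))
  })
  angles <- numeric(0)
  for (j in seq_along(nbrs)) {
    nb <- nbrs[[j]]
    if (length(nb) < 2) next
    for (p in utils::combn(length(nb), 2, simplify = FALSE)) {
      angles <- c(angles, triplet_angle(xyz[nb[p[1]], ], xyz[j, ], xyz[nb[p[2]], ]))
    }
  }
  comp <- igraph::components(.network_igraph(net))
  structure(
    list(
      distances = net$edges$dist,
      angles = angles,
      mean_distance = mean(net$edges$dist),
      distance_range = range(net$edges$dist),
      mean_angle = if (length(angles)) mean(angles) else NA_real_,
      angle_range = if (length(angles)) range(angles) else c(NA_real_, NA_real_),
      component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
      n_branches = sum(lengths(nbrs) >= 3)
    ),
    class = "network_stats"
  )
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "<network_stats> %d edges: %.2f-%.2f Angstrom (mean %.2f); %d angles: %.0f-%.0f deg (mean %.0f)\n",
    length(x$distances), x$distance_range[1], x$distance_range[2], x$mean_distance,
    length(x$angles), x$angle_range[1], x$angle_range[2], x$mean_angle
  ))
  invisible(x)
}

# Total-least-squares line fit: centroid + principal direction;
# returns perpendicular residuals and projections.
.tls_line <- function(X) {
  c0 <- colMeans(X)
  Xc <- sweep(X, 2, c0)
  sv <- svd(Xc)
  dir <- sv$v[, 1]
  proj <- as.numeric(Xc %*% dir)
  perp <- sqrt(pmax(0, rowSums(Xc^2) - proj^2))
  list(center = c0, direction = dir, projection = proj, residual = perp)
}

# Side-chain atoms of the named residues (backbone N/CA/C/O and hydrogens
# excluded).
.sidechain_atoms <- function(structure, resno, chain = NULL, carbon_only = FALSE) {
  a <- structure$atoms
  a <- a[!a$water & a$resno %in% resno, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[!a$elety %in% c("N", "CA", "C", "O", "OXT") & a$elesy != "H", , drop = FALSE]
  if (carbon_only) a <- a[a$elesy == "C", , drop = FALSE]
  a
}

#' Find the largest near-collinear water trough
#'
#' Searches for the largest subset of candidate waters (size >= 3) whose
#' perpendicular residuals from a total-least-squares line all stay within
#' `line_tolerance` - the "trough" motif of waters trapped in single file
#' along inward-facing hydrophobic residues. For up to `exact_max` candidates
#' the search enumerates subsets exactly; above that a pair-seeded consensus
#' search with TLS refinement is used. Ties (equal size) are resolved toward
#' the smallest total residual, then lexicographic water ids.
#'
#' @param waters A [water_set()] of candidate waters, or a larger set to be
#'   restricted via `structure`/`anchor_residues`.
#' @param structure Optional [crystal_structure()]; when given together with
#'   `anchor_residues`, candidates are the waters within `contact_cutoff` of
#'   any side-chain atom of the anchors.
#' @param anchor_residues Integer residue numbers of the trough-lining
#'   residues.
#' @param chain Chain of the anchor residues.
#' @param line_tolerance Maximum perpendicular residual in Angstrom
#'   (default 1.0).
#' @param contact_cutoff Water-to-side-chain cutoff defining the candidate
#'   pool (default 3.5 Angstrom).
#' @param exact_max Exhaustive search up to this many candidates (default 12).
#' @return A `"linear_trough"`: ordered `water_id`s, consecutive `intervals`,
#'   `mean_interval`, `span`, `residual` (max perpendicular), fitted `line`,
#'   and `found` (`FALSE` when no subset of size >= 3 fits, not an error).
#' @export
find_linear_trough <- function(waters, structure = NULL, anchor_residues = NULL,
                               chain = NULL, line_tolerance = 1.0,
                               contact_cutoff = 3.5, exact_max = 12) {
  stopifnot(inherits(waters, "water_set"))
  if (!is.null(structure) && !is.null(anchor_residues)) {
    sc <- .sidechain_atoms(structure, anchor_residues, chain = chain)
    if (!nrow(sc)) stop("anchor residues have no side-chain atoms")
    d <- pairwise_dist(waters, as_xyz_matrix(sc))
    waters <- waters[apply(d, 1, min) <= contact_cutoff + 1e-9, , drop = FALSE]
  }
  n <- nrow(waters)
  empty <- structure(
    list(water_id = character(0), intervals = numeric(0),
         mean_interval = NA_real_, span = NA_real_, residual = NA_real_,
         line = NULL, found = FALSE),
    class = "linear_trough"
  )
  if (n < 3) return(empty)
  X <- as_xyz_matrix(waters)

  fits <- function(sub) {
    f <- .tls_line(X[sub, , drop = FALSE])
    if (max(f$residual) <= line_tolerance + 1e-9) f else NULL
  }

  best <- NULL
  best_sub <- NULL
  consider <- function(sub) {
    f <- fits(sub)
    if (is.null(f)) return(invisible(NULL))
    better <- is.null(best) ||
      length(sub) > length(best_sub) ||
      (length(sub) == length(best_sub) &&
         (sum(f$residual) < sum(best$residual) - 1e-12 ||
            (abs(sum(f$residual) - sum(best$residual)) <= 1e-12 &&
               paste(sort(waters$water_id[sub]), collapse = ",") <
                 paste(sort(waters$water_id[best_sub]), collapse = ","))))
    if (better) {
      best <<- f
      best_sub <<- sub
    }
    invisible(NULL)
  }

  if (n <= exact_max) {
    for (k in n:3) {
      for (sub in utils::combn(n, k, simplify = FALSE)) consider(sub)
      if (!is.null(best)) break  # larger subsets already impossible
    }
  } else {
    # consensus search: each pair seeds a line; collect inliers, refine by TLS
    for (p in utils::combn(n, 2, simplify = FALSE)) {
      dir <- X[p[2], ] - X[p[1], ]
      len <- sqrt(sum(dir^2))
      if (len < 1e-9) next
      dir <- dir / len
      rel <- sweep(X, 2, X[p[1], ])
      proj <- as.numeric(rel %*% dir)
      perp <- sqrt(pmax(0, rowSums(rel^2) - proj^2))
      inl <- which(perp <= line_tolerance + 1e-9)
      if (length(inl) < 3) next
      # refine: TLS on inliers, re-collect, once more
      for (it in 1:2) {
        f <- .tls_line(X[inl, , drop = FALSE])
        relc <- sweep(X, 2, f$center)
        proj <- as.numeric(relc %*% f$direction)
        perp <- sqrt(pmax(0, rowSums(relc^2) - proj^2))
        inl <- which(perp <= line_tolerance + 1e-9)
        if (length(inl) < 3) break
      }
      if (length(inl) >= 3) consider(inl)
    }
  }
  if (is.null(best)) return(empty)
  ord <- best_sub[order(best$projection)]
  proj_sorted <- sort(best$projection)
  intervals <- diff(proj_sorted)
  structure(
    list(water_id = waters$water_id[ord], intervals = intervals,
         mean_interval = mean(intervals),
         span = max(best$projection) - min(best$projection),
         residual = max(best$residual),
         line = list(center = best$center, direction = best$direction),
         found = TRUE),
    class = "linear_trough"
  )
}

#' @export
print.linear_trough <- function(x, ...) {
  if (!x$found) {
    cat("<linear_trough> no trough found\n")
  } else {
    cat(sprintf(
      "<linear_trough> %d waters, mean interval %.2f Angstrom, span %.2f, max residual %.2f\n",
      length(x$water_id), x$mean_interval, x$span, x$residual
    ))
  }
  invisible(x)
}

# Exact longest simple cycle (>= min_len nodes) in an adjacency matrix via
# DFS with a canonical smallest-start rule; n is small (<= exact_max).
# Equal-length cycles resolve toward the smallest total edge length, then the
# lexicographically smallest id sequence.
.longest_cycle <- function(adj, d = NULL, ids = NULL, min_len = 4) {
  n <- nrow(adj)
  if (is.null(d)) d <- matrix(1, n, n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  best <- NULL
  best_len <- Inf
  path <- integer(0)
  visit <- function(v, start) {
    path[length(path) + 1L] <<- v
    for (w in which(adj[v, ])) {
      if (w == start && length(path) >= min_len) {
        tot <- sum(d[cbind(path, c(path[-1], start))])
        better <- is.null(best) || length(path) > length(best) ||
          (length(path) == length(best) &&
             (tot < best_len - 1e-12 ||
                (abs(tot - best_len) <= 1e-12 &&
                   paste(sort(ids[path]), collapse = ",") <
                     paste(sort(ids[best]), collapse = ","))))
        if (better) {
          best <<- path
          best_len <<- tot
        }
      } else if (w > start && !(w %in% path)) {
        visit(w, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) {
    path <- integer(0)
    visit(s, s)
  }
  best
}

# Exact longest simple path via DFS.
.longest_path <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  path <- integer(0)
  visit <- function(v) {
    path[length(path) + 1L] <<- v
    if (length(path) > length(best)) best <<- path
    for (w in which(adj[v, ])) if (!(w %in% path)) visit(w)
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) {
    path <- integer(0)
    visit(s)
  }
  best
}

#' Find the hydration ring around a hydrophobic side chain
#'
#' Restricts the waters to those within `contact_cutoff` of the side-chain
#' carbon atoms of the given residue, connects waters within `ring_cutoff`
#' (default 3.5 Angstrom) and searches for the largest simple cycle - the
#' ring-like hydrophobic hydration motif. The cycle search is exact for up to
#' `exact_max` candidate waters (the relevant structural scale); above that a
#' greedy search is used with a warning. When no cycle of length >= 4 exists,
#' the longest open chain is returned with `ring_closure = FALSE`.
#'
#' @param waters A [water_set()].
#' @param structure A [crystal_structure()], or an n x 3 matrix of side-chain
#'   carbon coordinates (in which case `residue` is ignored).
#' @param residue List with `chain` and `resno` selecting the residue.
#' @param ring_cutoff Water-water connectivity cutoff (Angstrom).
#' @param contact_cutoff Water-to-carbon cutoff defining the candidate pool
#'   (default 4.5 Angstrom).
#' @param exact_max Exact cycle enumeration up to this many candidates.
#' @return A `"hydration_ring"`: cyclic `water_id` sequence (or open chain),
#'   `adjacent_dists`, `mean_adjacent`, `mean_carbon_dist` (mean distance of
#'   ring waters to their nearest side-chain carbon), `ring_closure`.
#' @export
find_hydration_ring <- function(waters, structure, residue = NULL,
                                ring_cutoff = 3.5, contact_cutoff = 4.5,
                                exact_max = 15) {
  stopifnot(inherits(waters, "water_set"))
  carbons <- if (inherits(structure, "crystal_structure")) {
    if (is.null(residue)) stop("residue must be given with a structure")
    sc <- .sidechain_atoms(structure, residue$resno, chain = residue$chain,
                           carbon_only = TRUE)
    if (!nrow(sc)) stop("residue has no side-chain carbon atoms")
    as_xyz_matrix(sc)
  } else {
    as_xyz_matrix(structure)
  }
  dcarb <- pairwise_dist(waters, carbons)
  nearest_carbon <- apply(dcarb, 1, min)
  cand <- which(nearest_carbon <= contact_cutoff + 1e-9)
  empty <- structure(
    list(water_id = character(0), adjacent_dists = numeric(0),
         mean_adjacent = NA_real_, mean_carbon_dist = NA_real_,
         ring_closure = FALSE),
    class = "hydration_ring"
  )
  if (length(cand) < 3) return(empty)
  W <- waters[cand, , drop = FALSE]
  d <- pairwise_dist(W)
  adj <- d <= ring_cutoff + 1e-9
  diag(adj) <- FALSE
  cyc <- NULL
  if (length(cand) <= exact_max) {
    cyc <- .longest_cycle(adj, d = d, ids = W$water_id)
  } else {
    warning("more than ", exact_max,
            " candidate waters; using greedy cycle search")
    # greedy: walk to nearest unvisited neighbour, close when possible
    ord <- order(nearest_carbon[cand])
    start <- ord[1]
    pathg <- start
    repeat {
      nb <- which(adj[pathg[length(pathg)], ])
      nb <- setdiff(nb, pathg)
      if (!length(nb)) break
      pathg <- c(pathg, nb[which.min(d[pathg[length(pathg)], nb])])
    }
    if (length(pathg) >= 4 && adj[pathg[length(pathg)], pathg[1]]) cyc <- pathg
  }
  if (!is.null(cyc)) {
    ids <- W$water_id[cyc]
    dd <- d[cbind(cyc, c(cyc[-1], cyc[1]))]
    return(structure(
      list(water_id = ids, adjacent_dists = dd, mean_adjacent = mean(dd),
           mean_carbon_dist = mean(nearest_carbon[cand][cyc]),
           ring_closure = TRUE),
      class = "hydration_ring"
    ))
  }
  chain_idx <- if (length(cand) <= exact_max) .longest_path(adj) else
    seq_along(cand)
  if (length(chain_idx) < 2) return(empty)
  ids <- W$water_id[chain_idx]
  dd <- d[cbind(chain_idx[-length(chain_idx)], chain_idx[-1])]
  structure(
    list(water_id = ids, adjacent_dists = dd, mean_adjacent = mean(dd),
         mean_carbon_dist = mean(nearest_carbon[cand][chain_idx]),
         ring_closure = FALSE),
    class = "hydration_ring"
  )
}

#' @export
print.hydration_ring <- function(x, ...) {
  if (!length(x$water_id)) {
    cat("<hydration_ring> none found\n")
  } else {
    cat(sprintf(
      "<hydration_ring> %d waters (%s), mean adjacent %.2f Angstrom, mean carbon distance %.2f\n",
      length(x$water_id), if (x$ring_closure) "closed ring" else "open chain",
      x$mean_adjacent, x$mean_carbon_dist
    ))
  }
  invisible(x)
}
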