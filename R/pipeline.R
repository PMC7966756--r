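# Orchestration: structure -> symmetry expansion -> IBS water selection ->
# motif extraction -> ice-plane docking -> report, plus multi-structure
# comparison. Each stage is recorded in the report; independent stages
# continue past a failed one.

#' Build a validated analysis configuration
#'
#' @param structure Path to a PDB/mmCIF file or a [crystal_structure()].
#' @param chain Chain analysed (default `"A"`).
#' @param ibs [region_definition()] of the ice-binding site (default
#'   [ibs_regions()]).
#' @param water_cutoff Any-atom cutoff (Angstrom) defining "waters on the
#'   IBS" (default 4.0).
#' @param network_cutoff Water-water proximity cutoff for the network
#'   (default 3.7).
#' @param ring_cutoff Water-water cutoff for the hydration ring (default 3.5).
#' @param trough_tolerance Collinearity tolerance for the trough (default 1.0).
#' @param trough_anchors Residue numbers lining the trough (default the
#'   inward-facing hydrophobic positions 22, 213, 195, 177, 150, 126).
#' @param ring_residue List with `chain`/`resno` of the hydrophobic residue
#'   to survey for a hydration ring (default residue 43).
#' @param expand_radius Radius for symmetry expansion around the IBS.
#' @param dock_n Number of loop waters sampled for ice-plane docking
#'   (default 11).
#' @param loop_ranges Residue ranges of the IBS loop sub-site whose waters
#'   are docked (default 19-25 and 38-45).
#' @param lattice List of ice lattice parameters `a_ice`, `c_ice`, `extent`.
#' @param planes Ice planes to dock against.
#' @param dock List of docking parameters `n_starts`, `tol`, `max_iter`.
#' @param comparator Optional second structure (path or object) for Calpha
#'   RMSD.
#' @param seed Seed controlling every stochastic stage.
#' @return A validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(structure, chain = "A", ibs = ibs_regions(),
                            water_cutoff = 4.0, network_cutoff = 3.7,
                            ring_cutoff = 3.5, trough_tolerance = 1.0,
                            trough_anchors = c(22, 213, 195, 177, 150, 126),
                            ring_residue = list(chain = chain, resno = 43),
                            expand_radius = 6.0, dock_n = 11,
                            loop_ranges = c(19, 25, 38, 45),
                            lattice = list(a_ice = 4.52, c_ice = 7.36, extent = 4),
                            planes = c("basal", "prism1", "prism2"),
                            dock = list(n_starts = 64, tol = 1e-6, max_iter = 100),
                            comparator = NULL, seed = 1) {
  if (is.character(structure) && !file.exists(structure)) {
    stop("structure file not found: ", structure)
  }
  if (!is.character(structure) && !inherits(structure, "crystal_structure")) {
    stop("structure must be a file path or a crystal_structure")
  }
  cuts <- c(water_cutoff, network_cutoff, ring_cutoff, trough_tolerance,
            expand_radius)
  if (any(cuts <= 0)) stop("all cutoffs must be positive")
  if (!inherits(ibs, "region_definition")) stop("ibs must be a region_definition")
  planes <- match.arg(planes, c("basal", "prism1", "prism2"), several.ok = TRUE)
  structure(
    list(structure = structure, chain = chain, ibs = ibs,
         water_cutoff = water_cutoff, network_cutoff = network_cutoff,
         ring_cutoff = ring_cutoff, trough_tolerance = trough_tolerance,
         trough_anchors = trough_anchors, ring_residue = ring_residue,
         expand_radius = expand_radius, dock_n = dock_n,
         loop_ranges = loop_ranges, lattice = lattice, planes = planes,
         dock = dock, comparator = comparator, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

.load_structure <- function(x) {
  if (inherits(x, "crystal_structure")) x else read_structure(x)
}

#' Run the full ice-binding-site hydration analysis
#'
#' Executes the stages in order: load structure, expand crystallographic
#' symmetry around the IBS, select IBS waters, build the proximity network
#' and its statistics, find the linear trough and the hydration ring, build
#' the ideal ice lattice and dock the loop waters onto each requested plane,
#' and (optionally) compute the Calpha RMSD against a comparator structure.
#' A failed stage is recorded as `list(error = <message>)` and independent
#' stages still run; the whole run is deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return A list of class `"analysis_report"`; see [write_report()] for
#'   JSON serialization.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(schema = "icebound-report/1",
                 id = NULL, seed = config$seed,
                 version = as.character(utils::packageVersion("icebound")))
  stage <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }
  s <- stage(.load_structure(config$structure))
  if (!is.null(s$error)) {
    report$structure <- s
    class(report) <- "analysis_report"
    return(report)
  }
  report$id <- s$id
  report$n_atoms <- nrow(s$atoms)
  report$n_waters_total <- sum(s$atoms$water & s$atoms$elesy == "O")
  if (!is.null(s$cell)) {
    report$cell <- unname(s$cell)
    report$space_group <- s$space_group
  }

  expanded <- stage(expand_symmetry(s, config$ibs, radius = config$expand_radius,
                                    chain = config$chain))
  if (!is.null(expanded$error)) {
    report$symmetry_expansion <- expanded
    expanded <- s  # continue on the unexpanded structure
  } else {
    report$symmetry_expansion <- list(
      n_added = nrow(expanded$atoms) - nrow(s$atoms)
    )
  }

  wat <- stage(select_waters_near(expanded, config$ibs,
                                  cutoff = config$water_cutoff,
                                  chain = config$chain))
  if (!is.null(wat$error)) {
    report$ibs_waters <- wat
    class(report) <- "analysis_report"
    return(report)
  }
  report$ibs_waters <- list(n = nrow(wat), cutoff = config$water_cutoff,
                            ids = wat$water_id)

  report$network <- stage({
    net <- build_network(wat, cutoff = config$network_cutoff)
    st <- network_stats(net)
    list(n_edges = nrow(net$edges),
         mean_distance = st$mean_distance,
         distance_range = st$distance_range,
         mean_angle = st$mean_angle, angle_range = st$angle_range,
         component_sizes = st$component_sizes, n_branches = st$n_branches)
  })

  report$trough <- stage({
    tr <- find_linear_trough(wat, structure = expanded,
                             anchor_residues = config$trough_anchors,
                             chain = config$chain,
                             line_tolerance = config$trough_tolerance)
    list(found = tr$found, n = length(tr$water_id), water_id = tr$water_id,
         mean_interval = tr$mean_interval, span = tr$span,
         residual = tr$residual)
  })

  report$ring <- stage({
    rg <- find_hydration_ring(wat, expanded, residue = config$ring_residue,
                              ring_cutoff = config$ring_cutoff)
    list(n = length(rg$water_id), ring_closure = rg$ring_closure,
         water_id = rg$water_id, mean_adjacent = rg$mean_adjacent,
         mean_carbon_dist = rg$mean_carbon_dist)
  })

  report$docking <- stage({
    lat <- build_ice_lattice(config$lattice$a_ice, config$lattice$c_ice,
                             config$lattice$extent)
    loop <- region_definition(loop = config$loop_ranges)
    lw <- select_waters_near(expanded, loop, cutoff = config$water_cutoff,
                             chain = config$chain)
    if (nrow(lw) > config$dock_n) {
      # nearest dock_n waters to the loop atoms, deterministically
      la <- atoms_in_regions(expanded, loop, chain = config$chain)
      dmin <- apply(pairwise_dist(lw, as_xyz_matrix(la)), 1, min)
      lw <- lw[order(dmin, lw$water_id)[seq_len(config$dock_n)], , drop = FALSE]
    }
    per_plane <- list()
    for (pl in config$planes) {
      per_plane[[pl]] <- tryCatch({
        patch <- extract_plane_patch(lat, pl, min_count = max(12, nrow(lw)))
        fit <- dock_waters_to_plane(lw, patch,
                                    n_starts = config$dock$n_starts,
                                    tol = config$dock$tol,
                                    max_iter = config$dock$max_iter,
                                    seed = config$seed)
        list(rmsd = fit$rmsd, n = fit$n_pairs, converged = fit$converged,
             correspondence = unname(fit$correspondence),
             water_id = names(fit$correspondence))
      }, error = function(e) list(error = conditionMessage(e)))
    }
    list(n_waters = nrow(lw), water_id = lw$water_id, planes = per_plane)
  })

  if (!is.null(config$comparator)) {
    report$comparison <- stage({
      cmp <- .load_structure(config$comparator)
      r <- calpha_rmsd(s, cmp, chains = c(config$chain, config$chain))
      list(comparator = cmp$id, calpha_rmsd = as.numeric(r))
    })
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", x$id %||% "?", "\n", sep = "")
  cat("  waters total:", x$n_waters_total %||% NA, "  on IBS:",
      x$ibs_waters$n %||% NA, "\n")
  if (is.null(x$network$error)) {
    cat(sprintf("  network: mean distance %.2f, mean angle %.0f\n",
                x$network$mean_distance, x$network$mean_angle))
  }
  if (isTRUE(x$trough$found)) {
    cat(sprintf("  trough: %d waters, mean interval %.2f\n",
                x$trough$n, x$trough$mean_interval))
  }
  if (!is.null(x$docking$planes)) {
    for (pl in names(x$docking$planes)) {
      p <- x$docking$planes[[pl]]
      if (is.null(p$error)) cat(sprintf("  dock %s: RMSD %.2f\n", pl, p$rmsd))
    }
  }
  invisible(x)
}

#' Serialize an analysis report as JSON
#'
#' Deterministic (fixed precision) JSON so identical runs produce identical
#' bytes.
#'
#' @param report An [run_analysis()] report (or any list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Compare bound-water structures across related crystals
#'
#' For every pair of structures: the Calpha RMSD (chains paired by residue
#' number) and the fraction of waters at corresponding positions - waters of
#' one structure that land within `shared_cutoff` of a water of the other
#' after the Calpha superposition is applied (the operational reading of
#' "waters in corresponding positions").
#'
#' @param structures List (>= 2) of [crystal_structure()]s or file paths.
#' @param chain Chain used for all structures.
#' @param shared_cutoff Distance defining a shared water (default 1.0
#'   Angstrom).
#' @return A list of class `"structure_comparison"`: `calpha_rmsd` matrix and
#'   `shared_water_fraction` matrix (fraction of the row structure's waters
#'   shared with the column structure).
#' @export
compare_structures <- function(structures, chain = "A", shared_cutoff = 1.0) {
  if (length(structures) < 2) stop("need at least 2 structures")
  structures <- lapply(structures, .load_structure)
  ids <- vapply(structures, function(s) s$id, character(1))
  ids <- make.unique(ids)
  n <- length(structures)
  rms <- matrix(0, n, n, dimnames = list(ids, ids))
  shared <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- calpha_rmsd(structures[[i]], structures[[j]], chains = c(chain, chain))
      rms[i, j] <- as.numeric(r)
      wi <- waters_of(structures[[i]])
      wj <- waters_of(structures[[j]])
      if (nrow(wi) && nrow(wj)) {
        moved <- apply_transform(attr(r, "fit"), wi)
        dmin <- apply(pairwise_dist(moved, wj), 1, min)
        shared[i, j] <- mean(dmin <= shared_cutoff + 1e-9)
      } else {
        shared[i, j] <- NA_real_
      }
    }
  }
  structure(list(ids = ids, calpha_rmsd = rms, shared_water_fraction = shared),
            class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat("<structure_comparison>\nCalpha RMSD (Angstrom):\n")
  print(round(x$calpha_rmsd, 3))
  cat("shared water fraction:\n")
  print(round(x$shared_water_fraction, 3))
  invisible(x)
}
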