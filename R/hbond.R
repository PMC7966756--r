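# Protein-water hydrogen-bond detection on trajectory frames and the
# forward-lifetime residence-time statistic, aggregated by surface region
# (IBS vs non-IBS vs whole surface). The MD engine itself is out of scope:
# inputs are small multi-frame coordinate sets or precomputed event tables.

#' Construct a hydrogen-bond event table
#'
#' @param occupancy Logical (or 0/1) matrix, frames in rows, one column per
#'   protein-residue/water bond.
#' @param dt Frame interval in picoseconds.
#' @param bonds Data frame with one row per column of `occupancy`: `residue`
#'   (1-based protein position) and `water_id`.
#' @return An object of class `"hbond_event_table"`.
#' @export
hbond_event_table <- function(occupancy, dt, bonds) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "logical"
  if (dt <= 0) stop("dt must be positive")
  stopifnot(is.data.frame(bonds), all(c("residue", "water_id") %in% names(bonds)))
  if (nrow(bonds) != ncol(occupancy)) {
    stop("bonds must describe every occupancy column")
  }
  if (any(bonds$residue < 1)) stop("residue positions must be >= 1")
  structure(list(occupancy = occupancy, dt = dt,
                 bonds = data.frame(residue = as.integer(bonds$residue),
                                    water_id = as.character(bonds$water_id),
                                    stringsAsFactors = FALSE)),
            class = "hbond_event_table")
}

#' @export
print.hbond_event_table <- function(x, ...) {
  cat(sprintf("<hbond_event_table> %d frames x %d bonds (dt = %g ps)\n",
              nrow(x$occupancy), ncol(x$occupancy), x$dt))
  invisible(x)
}

#' Read/write hydrogen-bond event tables as CSV
#'
#' Long format: columns `frame`, `residue`, `water_id`, `bonded` (0/1).
#' @param path CSV path.
#' @param dt Frame interval in ps (stored in a `# dt=` comment on write,
#'   parsed back on read; can be overridden).
#' @return [hbond_event_table()] (read) or `path` invisibly (write).
#' @export
read_hbond_events <- function(path, dt = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(dt) && grepl("^# *dt=", first)) {
    dt <- as.numeric(sub("^# *dt=", "", first))
  }
  if (is.null(dt)) stop("dt not given and not recorded in the file")
  tab <- utils::read.csv(path, comment.char = "#")
  key <- paste(tab$residue, tab$water_id, sep = "|")
  bonds <- unique(data.frame(residue = tab$residue, water_id = tab$water_id,
                             key = key, stringsAsFactors = FALSE))
  frames <- sort(unique(tab$frame))
  occ <- matrix(FALSE, length(frames), nrow(bonds))
  occ[cbind(match(tab$frame, frames), match(key, bonds$key))] <- tab$bonded > 0
  hbond_event_table(occ, dt, bonds[, c("residue", "water_id")])
}

#' @rdname read_hbond_events
#' @param table An [hbond_event_table()].
#' @export
write_hbond_events <- function(table, path) {
  stopifnot(inherits(table, "hbond_event_table"))
  nf <- nrow(table$occupancy)
  nb <- ncol(table$occupancy)
  long <- data.frame(
    frame = rep(seq_len(nf), nb),
    residue = rep(table$bonds$residue, each = nf),
    water_id = rep(table$bonds$water_id, each = nf),
    bonded = as.integer(table$occupancy)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%g", table$dt), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect protein-water hydrogen bonds per frame
#'
#' A bond between a protein donor/acceptor heavy atom (N or O of a non-water
#' residue) and a water oxygen is present in a frame when their distance is
#' at most `d_cut` and - when hydrogens are present on the donor - the
#' hydrogen-donor-acceptor angle is at most `angle_cut` degrees from linear.
#' Without hydrogens (the usual case for crystallographic or coarse input)
#' the distance criterion alone is applied.
#'
#' @param frames List of n_atoms x 3 coordinate matrices, one per frame, all
#'   sharing the atom ordering of `atoms`.
#' @param atoms Data frame describing the shared atom ordering: columns
#'   `elety`, `resid`, `resno`, `elesy` (as in a [crystal_structure()] atom
#'   table; a crystal_structure may be passed directly).
#' @param d_cut Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_cut Hydrogen-donor-acceptor angle cutoff in degrees
#'   (default 30).
#' @param dt Frame interval in picoseconds.
#' @return An [hbond_event_table()] keyed by (protein residue position,
#'   water id); only pairs bonded in at least one frame are kept.
#' @export
detect_hbonds <- function(frames, atoms, d_cut = 3.5, angle_cut = 30, dt = 1) {
  if (inherits(atoms, "crystal_structure")) atoms <- atoms$atoms
  if (!length(frames)) stop("no frames supplied")
  frames <- lapply(frames, as_xyz_matrix)
  n_atoms <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, integer(1)) != n_atoms)) {
    stop("frames differ in atom count")
  }
  if (nrow(atoms) != n_atoms) stop("atoms table does not match the frames")
  is_water <- atoms$resid %in% WATER_RESNAMES
  polar <- which(!is_water & atoms$elesy %in% c("N", "O"))
  wox <- which(is_water & atoms$elesy == "O")
  if (!length(polar) || !length(wox)) stop("no polar protein atoms or no waters")
  hyd <- which(!is_water & atoms$elesy == "H")
  water_ids <- paste0("w", atoms$resno[wox])
  keys <- character(0)
  occ_list <- list()
  bond_res <- integer(0)
  bond_wat <- character(0)
  for (fi in seq_along(frames)) {
    X <- frames[[fi]]
    D <- pairwise_dist(X[polar, , drop = FALSE], X[wox, , drop = FALSE])
    hits <- which(D <= d_cut + 1e-9, arr.ind = TRUE)
    if (nrow(hits) && length(hyd)) {
      ok <- logical(nrow(hits))
      Dh <- pairwise_dist(X[hyd, , drop = FALSE], X[polar, , drop = FALSE])
      for (r in seq_len(nrow(hits))) {
        dnr <- polar[hits[r, 1]]
        acc <- wox[hits[r, 2]]
        # hydrogens covalently attached to this donor (within 1.25 Angstrom)
        hs <- hyd[Dh[, hits[r, 1]] <= 1.25]
        if (!length(hs)) {
          ok[r] <- TRUE  # donor carries no modeled hydrogen: distance-only
        } else {
          angs <- vapply(hs, function(h) {
            triplet_angle(X[h, ], X[dnr, ], X[acc, ])
          }, numeric(1))
          # deviation from linearity at the donor: H-D-A angle <= angle_cut
          ok[r] <- any(angs <= angle_cut + 1e-9)
        }
      }
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits)) {
      res <- atoms$resno[polar[hits[, 1]]]
      wat <- water_ids[hits[, 2]]
      pk <- unique(data.frame(res = res, wat = wat, stringsAsFactors = FALSE))
      for (r in seq_len(nrow(pk))) {
        k <- paste(pk$res[r], pk$wat[r], sep = "|")
        if (!k %in% keys) {
          keys <- c(keys, k)
          occ_list[[k]] <- logical(length(frames))
          bond_res <- c(bond_res, pk$res[r])
          bond_wat <- c(bond_wat, pk$wat[r])
        }
        occ_list[[k]][fi] <- TRUE
      }
    }
  }
  if (!length(keys)) stop("no hydrogen bonds detected in any frame")
  occ <- do.call(cbind, occ_list[keys])
  hbond_event_table(occ, dt, data.frame(residue = bond_res, water_id = bond_wat,
                                        stringsAsFactors = FALSE))
}

# Completed bonded runs (in frames) of one logical series; runs touching
# either trajectory end are truncated (formation or break unobserved).
.bond_runs <- function(series) {
  r <- rle(as.logical(series))
  on <- which(r$values)
  if (!length(on)) {
    return(list(completed = integer(0), truncated = integer(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  trunc <- starts[on] == 1 | ends[on] == length(series)
  list(completed = r$lengths[on][!trunc], truncated = r$lengths[on][trunc])
}

#' Forward lifetime of hydrogen bonds
#'
#' The forward lifetime is the duration of a maximal contiguous bonded run,
#' measured from formation to first break: a run of k frames lasts k * dt
#' picoseconds. Runs truncated by the trajectory ends are excluded by default
#' (their formation or break is unobserved) and can be included with
#' `include_truncated = TRUE`. One-frame interruptions count as real breaks
#' unless `grace` > 0, in which case gaps of at most `grace` frames are
#' bridged.
#'
#' @param table An [hbond_event_table()].
#' @param include_truncated Include end-truncated runs (default `FALSE`).
#' @param grace Bridge unbonded gaps of at most this many frames (default 0).
#' @return A list of class `"residence_estimate"`: `mean_lifetime` (ps,
#'   pooled over all runs), `n_runs`, `per_bond` mean lifetimes,
#'   `n_truncated`, and `truncated_only` flagging series that never complete
#'   a run. Errors when no frame is bonded.
#' @export
forward_lifetime <- function(table, include_truncated = FALSE, grace = 0) {
  stopifnot(inherits(table, "hbond_event_table"))
  occ <- table$occupancy
  if (!any(occ)) stop("no bonded frames in the event table")
  if (grace > 0) {
    occ <- apply(occ, 2, function(s) {
      r <- rle(as.logical(s))
      gaps <- which(!r$values & r$lengths <= grace)
      gaps <- gaps[gaps > 1 & gaps < length(r$values)]
      r$values[gaps] <- TRUE
      inverse.rle(r)
    })
    occ <- matrix(occ, nrow = nrow(table$occupancy))
  }
  runs <- apply(occ, 2, .bond_runs, simplify = FALSE)
  lifetimes <- lapply(runs, function(r) {
    if (include_truncated) c(r$completed, r$truncated) else r$completed
  })
  pooled <- unlist(lifetimes)
  n_trunc <- sum(vapply(runs, function(r) length(r$truncated), integer(1)))
  truncated_only <- length(pooled) == 0
  if (truncated_only) {
    warning("every bonded run touches a trajectory end; no completed ",
            "forward lifetimes (set include_truncated = TRUE to use them)")
  }
  structure(
    list(
      mean_lifetime = if (truncated_only) NA_real_ else mean(pooled) * table$dt,
      n_runs = length(pooled),
      per_bond = vapply(lifetimes, function(l) {
        if (length(l)) mean(l) * table$dt else NA_real_
      }, numeric(1)),
      n_truncated = n_trunc,
      truncated_only = truncated_only,
      dt = table$dt
    ),
    class = "residence_estimate"
  )
}

#' @export
print.residence_estimate <- function(x, ...) {
  cat(sprintf("<residence_estimate> mean forward lifetime %.2f ps over %d runs\n",
              x$mean_lifetime, x$n_runs))
  invisible(x)
}

#' Water residence time by surface region
#'
#' Pools hydrogen-bond forward lifetimes by surface region: bonds whose
#' protein residue position falls in a named region (e.g. the ice-binding
#' site ranges of [ibs_regions()]) versus all remaining positions
#' (`non-<name>`), plus the whole surface. Regions with no completed runs are
#' reported absent rather than zero.
#'
#' @param table An [hbond_event_table()].
#' @param regions A [region_definition()] (default [ibs_regions()]).
#' @param n_residues Protein length; bond positions beyond it raise an error.
#' @param ... Passed to [forward_lifetime()].
#' @return A `"residence_result"`: named list `lifetimes` (ps per region,
#'   including `whole`), `n_runs` per region.
#' @export
region_residence <- function(table, regions = ibs_regions(), n_residues = 223,
                             ...) {
  stopifnot(inherits(table, "hbond_event_table"))
  pos <- table$bonds$residue
  bad <- pos[pos > n_residues | pos < 1]
  if (length(bad)) {
    stop("bond residue position outside the sequence: ", paste(unique(bad), collapse = ", "))
  }
  groups <- list()
  assigned <- rep(FALSE, length(pos))
  for (nm in names(regions)) {
    inr <- .positions_in(pos, regions[[nm]])
    groups[[nm]] <- which(inr)
    assigned <- assigned | inr
  }
  if (length(regions) == 1) {
    groups[[paste0("non-", names(regions)[1])]] <- which(!assigned)
  } else if (any(!assigned)) {
    groups[["other"]] <- which(!assigned)
  }
  groups[["whole"]] <- seq_along(pos)
  lifetimes <- list()
  n_runs <- list()
  for (nm in names(groups)) {
    idx <- groups[[nm]]
    if (!length(idx)) next
    sub <- hbond_event_table(table$occupancy[, idx, drop = FALSE], table$dt,
                             table$bonds[idx, , drop = FALSE])
    est <- tryCatch(suppressWarnings(forward_lifetime(sub, ...)),
                    error = function(e) NULL)
    if (is.null(est) || est$truncated_only) next
    lifetimes[[nm]] <- est$mean_lifetime
    n_runs[[nm]] <- est$n_runs
  }
  structure(list(lifetimes = unlist(lifetimes), n_runs = unlist(n_runs)),
            class = "residence_result")
}

#' @export
print.residence_result <- function(x, ...) {
  cat("<residence_result> mean forward lifetime (ps):\n")
  for (nm in names(x$lifetimes)) {
    cat(sprintf("  %-10s %8.2f  (%d runs)\n", nm, x$lifetimes[[nm]], x$n_runs[[nm]]))
  }
  invisible(x)
}
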