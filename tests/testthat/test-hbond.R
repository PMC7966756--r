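# small helper: frames around one protein N donor (with optional hydrogen)
# and one water oxygen
.one_bond_frames <- function(water_positions, with_h = FALSE) {
  atoms <- data.frame(
    elety = c("N", if (with_h) "H", "OW"),
    resid = c("ALA", if (with_h) "ALA", "HOH"),
    resno = c(1L, if (with_h) 1L, 101L),
    chain = "A",
    elesy = c("N", if (with_h) "H", "O"),
    stringsAsFactors = FALSE
  )
  frames <- lapply(water_positions, function(p) {
    rbind(c(0, 0, 0), if (with_h) c(1.0, 0, 0), p)
  })
  list(frames = frames, atoms = atoms)
}

test_that("the distance criterion gates bond detection at the cutoff", {
  near <- .one_bond_frames(list(c(2.8, 0, 0)))
  tab <- detect_hbonds(near$frames, near$atoms, d_cut = 3.5, dt = 1)
  expect_true(all(tab$occupancy))
  far <- .one_bond_frames(list(c(3.6, 0, 0)))
  expect_error(detect_hbonds(far$frames, far$atoms, d_cut = 3.5, dt = 1),
               "no hydrogen bonds")
})

test_that("the hydrogen-donor-acceptor angle criterion applies when hydrogens exist", {
  # water along +x: H at (1,0,0) makes a 0-degree H-D-A angle -> bonded
  lin <- .one_bond_frames(list(c(2.8, 0, 0)), with_h = TRUE)
  expect_true(all(detect_hbonds(lin$frames, lin$atoms, dt = 1)$occupancy))
  # water along +y: angle is 90 degrees -> rejected at 30-degree cutoff
  bent <- .one_bond_frames(list(c(0, 2.8, 0)), with_h = TRUE)
  expect_error(detect_hbonds(bent$frames, bent$atoms, dt = 1),
               "no hydrogen bonds")
})

test_that("a water crossing the cutoff between frames gives occupancy 1,0", {
  two <- .one_bond_frames(list(c(2.8, 0, 0), c(4.5, 0, 0)))
  tab <- detect_hbonds(two$frames, two$atoms, dt = 1)
  expect_equal(as.logical(tab$occupancy), c(TRUE, FALSE))
})

test_that("forward lifetimes count completed runs only, by hand", {
  occ <- matrix(c(0, 1, 1, 0, 1, 0), ncol = 1)
  tab <- hbond_event_table(occ, dt = 1,
                           data.frame(residue = 1, water_id = "w1"))
  est <- forward_lifetime(tab)
  expect_equal(est$n_runs, 2L)
  expect_equal(est$mean_lifetime, 1.5)
  # dt scales lifetimes linearly
  tab2 <- hbond_event_table(occ, dt = 2.5,
                            data.frame(residue = 1, water_id = "w1"))
  expect_equal(forward_lifetime(tab2)$mean_lifetime, 3.75)
})

test_that("runs truncated by the trajectory ends are excluded unless asked", {
  occ <- matrix(rep(1, 10), ncol = 1)
  tab <- hbond_event_table(occ, dt = 1,
                           data.frame(residue = 1, water_id = "w1"))
  expect_warning(est <- forward_lifetime(tab), "trajectory end")
  expect_true(est$truncated_only)
  expect_true(is.na(est$mean_lifetime))
  est2 <- forward_lifetime(tab, include_truncated = TRUE)
  expect_equal(est2$mean_lifetime, 10)
  empty <- hbond_event_table(matrix(0, 5, 1), dt = 1,
                             data.frame(residue = 1, water_id = "w1"))
  expect_error(forward_lifetime(empty), "no bonded frames")
})

test_that("a grace period bridges short interruptions when requested", {
  occ <- matrix(c(0, 1, 1, 0, 1, 1, 0, 0), ncol = 1)
  tab <- hbond_event_table(occ, dt = 1,
                           data.frame(residue = 1, water_id = "w1"))
  expect_equal(forward_lifetime(tab)$mean_lifetime, 2)        # runs 2, 2
  expect_equal(forward_lifetime(tab, grace = 1)$mean_lifetime, 5)  # bridged
})

test_that("lifetimes are invariant to concatenating independent series", {
  t1 <- gen_telegraph_hbonds(12, 1, n_frames = 400, n_bonds = 1, seed = 1)
  t2 <- gen_telegraph_hbonds(12, 1, n_frames = 400, n_bonds = 1, seed = 2)
  # pad each series with an unbonded frame so boundary runs stay truncated
  s1 <- c(t1$occupancy[, 1], FALSE)
  s2 <- c(t2$occupancy[, 1], FALSE)
  joint <- hbond_event_table(matrix(c(s1, s2), ncol = 1), 1,
                             data.frame(residue = 1, water_id = "w1"))
  separate <- c(forward_lifetime(hbond_event_table(matrix(s1), 1, t1$bonds))$per_bond,
                forward_lifetime(hbond_event_table(matrix(s2), 1, t2$bonds))$per_bond)
  n1 <- forward_lifetime(hbond_event_table(matrix(s1), 1, t1$bonds))$n_runs
  n2 <- forward_lifetime(hbond_event_table(matrix(s2), 1, t2$bonds))$n_runs
  expect_equal(forward_lifetime(joint)$mean_lifetime,
               sum(separate * c(n1, n2)) / (n1 + n2))
})

test_that("telegraph lifetimes are recovered and converge as n^(-1/2)", {
  # single-seed recovery at moderate size
  tab <- gen_telegraph_hbonds(15, 1, n_frames = 4000, n_bonds = 25, seed = 5)
  est <- forward_lifetime(tab)
  expect_gt(est$n_runs, 2000)
  expect_lt(abs(est$mean_lifetime - 15) / 15, 0.05)
  # sd of the estimate shrinks like one over the square root of the run count
  sds <- vapply(c(100, 1000, 10000), function(n_target) {
    ests <- vapply(1:12, function(s) {
      tb <- gen_telegraph_hbonds(10, 1, n_frames = ceiling(n_target * 15.5),
                                 n_bonds = 1, seed = 1000 * n_target + s)
      forward_lifetime(tb)$mean_lifetime
    }, numeric(1))
    stats::sd(ests)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(c(100, 1000, 10000))))[2]
  expect_lt(abs(slope + 0.5), 0.2)
})

test_that("p_break = 1 forces every completed run to one frame", {
  tab <- gen_telegraph_hbonds(mean_lifetime = 1, dt = 1, n_frames = 500,
                              n_bonds = 5, seed = 3)
  est <- forward_lifetime(tab)
  expect_equal(est$mean_lifetime, 1)
})

test_that("region pooling recovers planted contrasts and the weighted mean", {
  tab <- gen_telegraph_hbonds(c(80, 68), 1, n_frames = 60000, n_bonds = 28,
                              residue_positions = c(20L, 60L), seed = 7)
  rr <- region_residence(tab)
  expect_lt(abs(rr$lifetimes[["IBS"]] - 80) / 80, 0.03)
  expect_lt(abs(rr$lifetimes[["non-IBS"]] - 68) / 68, 0.03)
  # whole-surface value sits between the two regional values
  expect_gt(rr$lifetimes[["whole"]], min(rr$lifetimes[c("IBS", "non-IBS")]))
  expect_lt(rr$lifetimes[["whole"]], max(rr$lifetimes[c("IBS", "non-IBS")]))
  # and equals their run-count weighted mean
  expect_equal(
    rr$lifetimes[["whole"]],
    sum(rr$lifetimes[c("IBS", "non-IBS")] * rr$n_runs[c("IBS", "non-IBS")]) /
      sum(rr$n_runs[c("IBS", "non-IBS")]),
    tolerance = 1e-9
  )
})

test_that("all-IBS tables give IBS equal to whole; empty regions are absent", {
  tab <- gen_telegraph_hbonds(30, 1, n_frames = 2000, n_bonds = 10,
                              residue_positions = 20L, seed = 2)
  rr <- region_residence(tab)
  expect_equal(rr$lifetimes[["IBS"]], rr$lifetimes[["whole"]])
  expect_false("non-IBS" %in% names(rr$lifetimes))
  bad <- gen_telegraph_hbonds(30, 1, n_frames = 100, n_bonds = 2,
                              residue_positions = 300L, seed = 2)
  expect_error(region_residence(bad), "300")
})

test_that("event tables round-trip through CSV", {
  tab <- gen_telegraph_hbonds(c(9, 7), 1.5, n_frames = 120, n_bonds = 4, seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  write_hbond_events(tab, p)
  tab2 <- read_hbond_events(p)
  expect_equal(tab2$dt, 1.5)
  expect_equal(tab2$occupancy, tab$occupancy, ignore_attr = TRUE)
  expect_equal(tab2$bonds$residue, tab$bonds$residue)
})
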