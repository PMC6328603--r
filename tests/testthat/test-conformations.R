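test_that("dihedral of a planar trans arrangement is 180 degrees", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0); p4 <- c(1, -1, 0)
  expect_equal(abs(dihedral_angle(p1, p2, p3, p4)), 180)
  # cis arrangement is 0
  expect_equal(dihedral_angle(c(0, 1, 0), p2, p3, c(1, 1, 0)), 0)
})

test_that("dihedrals match an independent vector-algebra oracle", {
  # hand-built configuration
  p <- list(c(1.2, 0.3, -0.5), c(0, 0, 0), c(1.5, 0.1, 0.2),
            c(2.0, 1.4, 1.1))
  expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
               oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               tolerance = 1e-9)
  set.seed(21)
  for (i in 1:25) {
    q <- lapply(1:4, function(j) stats::rnorm(3))
    expect_equal(dihedral_angle(q[[1]], q[[2]], q[[3]], q[[4]]),
                 oracle_dihedral(q[[1]], q[[2]], q[[3]], q[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("backbone phi/psi agree with an independent structure program", {
  tt <- gen_toy_trajectory(n_frames = 1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_minipdb(tt$traj$atoms, tt$traj$frames[[1]], p)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(p, verbose = FALSE))
  dih <- compute_dihedrals(tt$traj, resno = 64:66)
  d65 <- dih[dih$resno == 65 & dih$frame == 1, ]
  i65 <- grep("\\b65\\b", rownames(tor$tbl))
  expect_equal(d65$phi, unname(tor$tbl[i65, "phi"]), tolerance = 1e-4)
  expect_equal(d65$psi, unname(tor$tbl[i65, "psi"]), tolerance = 1e-4)
  # chain termini are NA-flagged, not fabricated
  d64 <- dih[dih$resno == 64 & dih$frame == 1, ]
  expect_true(is.na(d64$phi))
  expect_false(is.na(d64$psi))
  expect_match(attr(dih, "flags")[["A:64:phi"]], "terminus")
})

test_that("state classification is wrap-aware interval membership", {
  win <- state_windows(c(`76` = 120), halfwidth = 60)
  mk <- function(psi) {
    d <- data.frame(chain = "A", resno = 76L, frame = seq_along(psi),
                    phi = 0, psi = psi)
    class(d) <- c("dihedral_series", "data.frame")
    d
  }
  # windows: inwards psi in [60, 180], outwards in [-120, 0] (inclusive)
  lab <- classify_states(mk(c(120, -60, 30, 175, -115, -179, 60, 0.01)), win)
  expect_equal(as.character(lab$label),
               c("inwards", "outwards", "other", "inwards", "outwards",
                 "other", "inwards", "other"))
  # an angle at the inwards centre + 180 lands in the outwards window
  expect_equal(as.character(classify_states(mk(-60), win)$label), "outwards")
  # windows must not overlap, and every classified residue needs a window
  expect_error(state_windows(c(`76` = 120), halfwidth = 95), "overlap")
  expect_error(classify_states(mk(0), state_windows(c(`78` = 100))),
               "no state windows")
  # identical inputs give identical labels (pure function)
  d <- mk(stats::runif(50, -180, 180))
  expect_identical(classify_states(d, win)$label,
                   classify_states(d, win)$label)
})

test_that("classification matches a brute-force membership loop", {
  g <- gen_two_state_dihedrals(n_frames = 10000, seed = 13)
  got <- as.character(classify_states(g$dihedrals, g$windows)$label)
  want <- oracle_classify(g$dihedrals$psi, center_in = 120, halfwidth = 60)
  expect_identical(got, want)
})

test_that("state populations sum to one and transitions count label changes", {
  mk_assign <- function(labels) {
    d <- data.frame(chain = "A", resno = 76L, frame = seq_along(labels),
                    label = factor(labels, levels = c("inwards", "outwards",
                                                      "other")))
    class(d) <- c("state_assignment", "data.frame")
    d
  }
  allin <- state_populations(mk_assign(rep("inwards", 10)))
  expect_equal(allin$populations$p_inwards, 1)
  expect_equal(allin$populations$p_outwards, 0)
  expect_equal(allin$transitions$transitions, 0L)
  alt <- state_populations(mk_assign(rep(c("inwards", "outwards"), 5)))
  expect_equal(alt$transitions$transitions, 9L)
  expect_equal(alt$populations$p_inwards + alt$populations$p_outwards +
                 alt$populations$p_other, 1)
})

test_that("planted Markov populations are recovered within Markov-aware SE", {
  switch_rate <- 0.25
  n <- 10000
  lambda <- 1 - switch_rate           # lag-1 autocorrelation of the chain
  n_eff <- n * (1 - lambda) / (1 + lambda)
  for (p_in in c(0.5, 0.6, 0.9)) {
    for (seed in 1:20) {
      g <- gen_two_state_dihedrals(n_frames = n, p_in = p_in,
                                   switch_rate = switch_rate, seed = seed)
      p_hat <- mean(g$labels$label == "inwards")
      expect_lt(abs(p_hat - p_in), 3 * sqrt(p_in * (1 - p_in) / n_eff))
    }
  }
})

test_that("hydrogen bonds satisfy distance and angle criteria", {
  # static donor-hydrogen-acceptor at 2.9 A and ~165 degrees
  mk_traj <- function(acc_xyz) {
    atoms <- data.frame(chain = "A", resno = c(67L, 67L, 80L),
                        resid = c("TRP", "TRP", "ASP"),
                        elety = c("NE1", "HE1", "OD1"))
    h <- c(0.98, 0, 0)
    sf_trajectory(atoms, list(rbind(c(0, 0, 0), h, acc_xyz)))
  }
  ang <- 165 * pi / 180
  acc <- c(0.98, 0, 0) + 1.95 * c(-cos(ang), sin(ang), 0)  # D-H...A = 165 deg
  tr <- mk_traj(acc)
  expect_equal(hbond_occupancy(tr, 1, 3, 2)$occupancy, 1.0)
  expect_equal(hbond_occupancy(mk_traj(c(10, 0, 0)), 1, 3, 2)$occupancy, 0)
  # tight angle criterion rejects a bent geometry at short distance
  bent <- c(0.98, 1.0, 0)
  expect_equal(hbond_occupancy(mk_traj(bent), 1, 3, 2,
                               hbond_criteria(min_angle = 150))$occupancy, 0)
  expect_error(hbond_occupancy(tr, integer(0), 3), "empty donor")
})

test_that("scripted bond-breaking matches brute-force per-frame evaluation", {
  tt <- gen_toy_trajectory(n_frames = 12, hbond_break_frame = 7,
                           jitter_sd = 0.02, seed = 5)
  don <- select_atoms(tt$traj, resno = 67, elety = "NE1")
  acc <- select_atoms(tt$traj, resno = 80, elety = c("OD1", "OD2"))
  hyd <- select_atoms(tt$traj, resno = 67, elety = "HE1")
  got <- hbond_occupancy(tt$traj, don, acc, hyd)
  want <- oracle_hbond_frames(tt$traj, don, acc, hyd, 3.5, 120)
  expect_identical(got$per_frame, want)
  expect_identical(got$per_frame, tt$truth$hbond_present)
})

test_that("D80 rotamers bin by carboxylate-indole distance", {
  tt <- gen_toy_trajectory(n_frames = 10, hbond_break_frame = 6)
  rot <- classify_d80_rotamer(tt$traj)
  expect_equal(as.character(rot$label), tt$truth$rotamer)
  # sweep a synthetic distance ladder across both thresholds
  atoms <- data.frame(chain = "A", resno = c(67L, 80L, 80L),
                      resid = c("TRP", "ASP", "ASP"),
                      elety = c("NE1", "OD1", "OD2"))
  dists <- c(2.0, 3.5, 4.0, 6.4, 6.5, 9.0)
  frames <- lapply(dists, function(d)
    rbind(c(0, 0, 0), c(d, 0, 0), c(d + 0.8, 0.5, 0)))
  rot2 <- classify_d80_rotamer(sf_trajectory(atoms, frames))
  want <- vapply(dists, function(d)
    if (d <= 3.5) "down" else if (d >= 6.5) "up" else "middle", character(1))
  expect_equal(as.character(rot2$label), want)
  expect_error(classify_d80_rotamer(tt$traj, d_down = 7, d_up = 3), "d_down")
})

test_that("water census counts cavity waters and exchange events", {
  tt0 <- gen_toy_trajectory(n_frames = 6)
  w0 <- water_cavity_census(tt0$traj)
  expect_true(all(w0$counts$count == 1))   # one resident cavity water
  expect_equal(w0$total_events, 0L)
  tt <- gen_toy_trajectory(n_frames = 9, water_swap_frame = 4)
  w <- water_cavity_census(tt$traj)
  expect_equal(w$total_events, 2L)         # one exit + one entry at frame 4
  expect_equal(w$total_events, oracle_water_events(tt$traj))
  expect_true(all(w$counts$count == 1))    # identity changed, count did not
  # no waters at all: zero counts, zero events
  dry_idx <- tt0$traj$atoms$resid != "HOH"
  dry <- sf_trajectory(tt0$traj$atoms[dry_idx, ],
                       lapply(tt0$traj$frames, function(m) m[dry_idx, ]))
  wd <- water_cavity_census(dry)
  expect_true(all(wd$counts$count == 0))
  expect_equal(wd$total_events, 0L)
})

test_that("superposition recovers rigid motions exactly", {
  s <- gen_filter_structure()
  expect_equal(superpose_and_rmsd(s, s)$rmsd, 0)
  moved <- rigid_transform(s, random_rotation(seed = 3), c(11, -4, 7))
  expect_lt(superpose_and_rmsd(moved, s)$rmsd, 1e-9)
  # symmetric in the argument order
  s2 <- gen_filter_structure(perturb_sd = 0.2, seed = 8)
  expect_equal(superpose_and_rmsd(s2, s)$rmsd,
               superpose_and_rmsd(s, s2)$rmsd, tolerance = 1e-9)
  # mismatched selections refuse to superpose
  s3 <- s; s3$atoms$elety[1] <- "XX"
  expect_error(superpose_and_rmsd(s3, s), "identical atom lists")
})

test_that("RMSD matches rotation-search and bio3d oracles", {
  set.seed(31)
  for (i in 1:3) {
    X <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    Y <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    atoms <- data.frame(chain = "A", resno = 1:4, resid = "GLY",
                        elety = "CA")
    r <- superpose_and_rmsd(sf_structure(atoms, X), sf_structure(atoms, Y))
    expect_equal(r$rmsd, oracle_rmsd(X, Y), tolerance = 1e-6)
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.numeric(t(Y)), as.numeric(t(X))))
    expect_equal(r$rmsd, sqrt(mean(colSums(
      (matrix(fitted, 3) - t(Y))^2))), tolerance = 1e-6)
  }
})

test_that("geometric analyses are invariant under global rigid motion", {
  tt <- gen_toy_trajectory(n_frames = 8, hbond_break_frame = 5,
                           water_swap_frame = 3)
  R <- random_rotation(seed = 17); tr <- c(-30, 12, 55)
  moved <- rigid_transform(tt$traj, R, tr)
  # dihedrals
  d0 <- compute_dihedrals(tt$traj, resno = 65)
  d1 <- compute_dihedrals(moved, resno = 65)
  expect_equal(d1$psi, d0$psi, tolerance = 1e-9)
  expect_equal(d1$phi, d0$phi, tolerance = 1e-9)
  # hydrogen bonds
  don <- select_atoms(tt$traj, resno = 67, elety = "NE1")
  acc <- select_atoms(tt$traj, resno = 80, elety = c("OD1", "OD2"))
  expect_identical(hbond_occupancy(moved, don, acc)$per_frame,
                   hbond_occupancy(tt$traj, don, acc)$per_frame)
  # rotamers and water census
  expect_identical(classify_d80_rotamer(moved)$label,
                   classify_d80_rotamer(tt$traj)$label)
  expect_identical(water_cavity_census(moved)$total_events,
                   water_cavity_census(tt$traj)$total_events)
  # post-superposition RMSD
  s <- gen_filter_structure(); s2 <- gen_filter_structure(perturb_sd = 0.1,
                                                          seed = 2)
  expect_equal(superpose_and_rmsd(rigid_transform(s2, R, tr), s)$rmsd,
               superpose_and_rmsd(s2, s)$rmsd, tolerance = 1e-9)
})
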