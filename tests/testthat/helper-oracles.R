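# Independent brute-force oracles used to cross-check the implementation.
# Each one is a deliberately different route to the same quantity.

# exhaustive grid search for the mono-exponential rate, amplitude profiled
# out in closed form: I0(R) = sum(y e^{-Rt}) / sum(e^{-2Rt})
oracle_grid_rate <- function(t, y, r_max = 1, step = 1e-5) {
  R <- seq(0, r_max, by = step)
  E <- exp(-outer(R, t))
  num <- as.numeric(E %*% y)
  den <- rowSums(E * E)
  sse <- sum(y^2) - num^2 / den
  R[which.min(sse)]
}

# dihedral via plane normals + triple-product sign (different formula from
# the atan2 route in the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# plain loop membership classification on the circle
oracle_classify <- function(psi, center_in, halfwidth) {
  circ <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  center_out <- ((center_in + 180 + 180) %% 360) - 180
  vapply(psi, function(p) {
    if (is.na(p)) return("other")
    if (circ(p, center_in) <= halfwidth) "inwards"
    else if (circ(p, center_out) <= halfwidth) "outwards"
    else "other"
  }, character(1))
}

# per-frame hydrogen-bond evaluation, loop form
oracle_hbond_frames <- function(traj, donors, acceptors, hydrogens,
                                max_dist, min_angle) {
  vapply(traj$frames, function(m) {
    ok <- FALSE
    for (i in seq_along(donors)) for (j in seq_along(acceptors)) {
      d <- sqrt(sum((m[donors[i], ] - m[acceptors[j], ])^2))
      if (d > max_dist) next
      if (is.null(hydrogens)) { ok <- TRUE; break }
      h <- m[hydrogens[i], ]
      v1 <- m[donors[i], ] - h; v2 <- m[acceptors[j], ] - h
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= min_angle) { ok <- TRUE; break }
    }
    ok
  }, logical(1))
}

# water-exchange events by explicit set differences on water identities
oracle_water_events <- function(traj, anchor_resno = c(67, 71, 80),
                                radius = 5.0) {
  a <- traj$atoms
  wat <- which(a$resid == "HOH" & a$elety == "O")
  backbone <- c("N", "CA", "C", "O", "H", "HA", "HN")
  anch <- which(a$resno %in% anchor_resno & a$resid != "HOH" &
                  !(a$elety %in% backbone) & !startsWith(a$elety, "H"))
  sets <- lapply(traj$frames, function(m) {
    cen <- colMeans(m[anch, , drop = FALSE])
    wat[vapply(wat, function(w) sqrt(sum((m[w, ] - cen)^2)) <= radius,
               logical(1))]
  })
  ev <- 0L
  for (f in seq_along(sets)[-1])
    ev <- ev + length(setdiff(sets[[f]], sets[[f - 1]])) +
      length(setdiff(sets[[f - 1]], sets[[f]]))
  ev
}

# RMSD by numerical search over rotations (multi-start quasi-Newton on Euler
# angles), independent of the SVD route
oracle_rmsd <- function(X, Y, n_starts = 25, seed = 99) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rotmat <- function(e) {
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cz <- cos(e[3]); sz <- sin(e[3])
    matrix(c(cy * cz, -cy * sz, sy,
             cx * sz + sx * sy * cz, cx * cz - sx * sy * sz, -sx * cy,
             sx * sz - cx * sy * cz, sx * cz + cx * sy * sz, cx * cy),
           3, 3, byrow = TRUE)
  }
  f <- function(e) sqrt(mean(rowSums((Xc %*% t(rotmat(e)) - Yc)^2)))
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    e0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(e0, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
    if (o$value < best) best <- o$value
  }
  best
}

# minimal fixed-column PDB writer for reader tests (fixture generation only)
write_minipdb <- function(atoms, frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- frames[[k]]
    for (i in seq_len(nrow(atoms))) {
      name4 <- if (nchar(atoms$elety[i]) < 4L)
        sprintf(" %-3s", atoms$elety[i]) else atoms$elety[i]
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, name4, atoms$resid[i], atoms$chain[i], atoms$resno[i],
        m[i, 1], m[i, 2], m[i, 3]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

star_fixture <- function(variant) {
  system.file("extdata", sprintf("synthetic_shifts_%s.str", variant),
              package = "filterdyn")
}
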