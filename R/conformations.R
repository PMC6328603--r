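#' Dihedral angle of four points
#'
#' Signed torsion in degrees on (-180, 180], IUPAC convention (cis = 0,
#' trans = 180).
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap-aware angular difference a - b on (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Backbone phi/psi dihedrals over a trajectory
#'
#' Computes IUPAC phi (C[i-1], N, CA, C) and psi (N, CA, C, N[i+1]) per
#' frame for the requested residues of every chain. Chain termini or missing
#' backbone atoms yield `NA` angles with the reason recorded in the
#' `flags` attribute; angles are never fabricated.
#'
#' @param traj an [sf_trajectory()].
#' @param resno residues to analyse (NULL = all).
#' @param chains chains to analyse (NULL = all).
#' @return A `dihedral_series` data frame with columns `chain`, `resno`,
#'   `frame`, `phi`, `psi` (degrees on (-180, 180]).
#' @export
compute_dihedrals <- function(traj, resno = NULL, chains = NULL) {
  a <- traj$atoms
  if (is.null(chains)) chains <- unique(a$chain)
  rows <- list(); flags <- character()
  idx_of <- function(ch, rn, el) {
    i <- which(a$chain == ch & a$resno == rn & a$elety == el)
    if (length(i) == 1L) i else NA_integer_
  }
  nf <- length(traj$frames)
  for (ch in chains) {
    res_here <- sort(unique(a$resno[a$chain == ch]))
    if (!is.null(resno)) res_here <- intersect(res_here, resno)
    for (rn in res_here) {
      iN <- idx_of(ch, rn, "N"); iCA <- idx_of(ch, rn, "CA")
      iC <- idx_of(ch, rn, "C")
      iCp <- idx_of(ch, rn - 1L, "C")   # previous residue C (for phi)
      iNn <- idx_of(ch, rn + 1L, "N")   # next residue N (for psi)
      if (is.na(iN) || is.na(iCA) || is.na(iC)) {
        flags[paste0(ch, ":", rn)] <- "missing backbone atom"
        next
      }
      phi <- rep(NA_real_, nf); psi <- rep(NA_real_, nf)
      for (f in seq_len(nf)) {
        m <- traj$frames[[f]]
        if (!is.na(iCp))
          phi[f] <- dihedral_angle(m[iCp, ], m[iN, ], m[iCA, ], m[iC, ])
        if (!is.na(iNn))
          psi[f] <- dihedral_angle(m[iN, ], m[iCA, ], m[iC, ], m[iNn, ])
      }
      if (is.na(iCp)) flags[paste0(ch, ":", rn, ":phi")] <- "chain N-terminus"
      if (is.na(iNn)) flags[paste0(ch, ":", rn, ":psi")] <- "chain C-terminus"
      rows[[paste(ch, rn)]] <- data.frame(chain = ch, resno = rn,
                                          frame = seq_len(nf),
                                          phi = phi, psi = psi,
                                          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), frame = integer(),
               phi = numeric(), psi = numeric())
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  class(out) <- c("dihedral_series", "data.frame")
  out
}

#' Define inwards/outwards angular windows on psi
#'
#' For each classified residue the inwards window is centred on a reference
#' psi value (typically the conductive crystal-structure value for that
#' residue) and the outwards window on its antipode (the carbonyl-flipped
#' peptide plane). Window half-widths below 90 degrees guarantee the two
#' windows are disjoint; psi values outside both are labelled `other`.
#'
#' @param centers named numeric vector: inwards psi centre (degrees) per
#'   residue number.
#' @param halfwidth window half-width in degrees, 0 < halfwidth < 90.
#' @param outwards_centers optional named vector overriding the antipodal
#'   default.
#' @return A `state_windows` data frame with columns `resno`, `state`,
#'   `center`, `halfwidth`.
#' @export
state_windows <- function(centers, halfwidth = 60, outwards_centers = NULL) {
  if (is.null(names(centers)) || any(!nzchar(names(centers))))
    stop("centers must be a named vector (names = residue numbers)")
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  resno <- as.integer(names(centers))
  outc <- if (is.null(outwards_centers))
    ang_diff(centers + 180, 0) else outwards_centers[names(centers)]
  out <- rbind(
    data.frame(resno = resno, state = "inwards", center = as.numeric(centers),
               halfwidth = halfwidth),
    data.frame(resno = resno, state = "outwards", center = as.numeric(outc),
               halfwidth = halfwidth))
  # overlap check per residue (wrap-aware)
  for (rn in resno) {
    w <- out[out$resno == rn, ]
    sep <- abs(ang_diff(w$center[1], w$center[2]))
    if (sep < sum(w$halfwidth))
      stop("inwards/outwards windows overlap for residue ", rn,
           " (centres ", sep, " deg apart, half-widths sum to ",
           sum(w$halfwidth), ")")
  }
  class(out) <- c("state_windows", "data.frame")
  out
}

#' Classify carbonyl inwards/outwards states from psi dihedrals
#'
#' Pure wrap-aware interval membership: a frame is `inwards` when the
#' residue's psi lies within the inwards window, `outwards` within the
#' outwards window, and `other` otherwise (including undefined angles).
#' Classification uses psi of the residue contributing the carbonyl, which
#' is where a peptide-plane flip registers.
#'
#' @param dihedrals a `dihedral_series` from [compute_dihedrals()] (or a
#'   synthetic generator).
#' @param windows a [state_windows()] covering every classified residue.
#' @return A `state_assignment` data frame with columns `chain`, `resno`,
#'   `frame`, `label` and attribute `provenance`.
#' @export
classify_states <- function(dihedrals, windows) {
  need <- unique(dihedrals$resno)
  have <- unique(windows$resno)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("no state windows defined for residue(s): ",
         paste(miss, collapse = ", "))
  lab <- rep("other", nrow(dihedrals))
  for (st in c("inwards", "outwards")) {
    w <- windows[windows$state == st, ]
    ci <- w$center[match(dihedrals$resno, w$resno)]
    hw <- w$halfwidth[match(dihedrals$resno, w$resno)]
    hit <- !is.na(dihedrals$psi) & abs(ang_diff(dihedrals$psi, ci)) <= hw
    lab[hit] <- st
  }
  out <- data.frame(chain = dihedrals$chain, resno = dihedrals$resno,
                    frame = dihedrals$frame,
                    label = factor(lab, levels = c("inwards", "outwards",
                                                   "other")),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- windows
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' State populations and transition counts
#'
#' Per-residue (optionally per-chain) fractions of frames in each label,
#' summing to 1, plus the number of label changes between consecutive frames
#' of each (chain, residue) series.
#'
#' @param assign a `state_assignment`.
#' @param by grouping columns, `"resno"` (default, chains pooled) or
#'   `c("chain", "resno")`.
#' @return list with `populations` (data frame of fractions and `n_frames`)
#'   and `transitions` (data frame per chain/residue series).
#' @export
state_populations <- function(assign, by = "resno") {
  stopifnot(nrow(assign) > 0L)
  levs <- levels(assign$label)
  grp <- interaction(assign[by], drop = TRUE, sep = ":")
  tab <- table(grp, assign$label)
  frac <- sweep(tab, 1L, rowSums(tab), "/")
  keys <- do.call(rbind, strsplit(rownames(tab), ":", fixed = TRUE))
  pops <- data.frame(keys, stringsAsFactors = FALSE)
  names(pops) <- by
  if ("resno" %in% by) pops$resno <- as.integer(pops$resno)
  for (l in levs) pops[[paste0("p_", l)]] <- as.numeric(frac[, l])
  pops$n_frames <- as.integer(rowSums(tab))
  # transitions per (chain, resno) series in frame order
  sgrp <- interaction(assign$chain, assign$resno, drop = TRUE, sep = ":")
  trans <- lapply(split(assign, sgrp), function(d) {
    d <- d[order(d$frame), ]
    data.frame(chain = d$chain[1], resno = d$resno[1],
               transitions = sum(d$label[-1] != d$label[-nrow(d)]),
               stringsAsFactors = FALSE)
  })
  trans <- do.call(rbind, trans)
  rownames(trans) <- NULL
  list(populations = pops, transitions = trans)
}

#' Hydrogen-bond geometric criteria
#'
#' @param max_dist maximum donor-acceptor heavy-atom distance in Angstrom.
#' @param min_angle minimum D-H...A angle in degrees (applied only when
#'   hydrogen positions are supplied).
#' @param hydrogen_optional when TRUE (default) the bond is judged on
#'   distance alone if no hydrogens are given.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_dist = 3.5, min_angle = 120,
                           hydrogen_optional = TRUE) {
  if (max_dist <= 0) stop("max_dist must be > 0")
  if (min_angle < 0 || min_angle > 180)
    stop("min_angle must be in [0, 180]")
  structure(list(max_dist = max_dist, min_angle = min_angle,
                 hydrogen_optional = hydrogen_optional),
            class = "hbond_criteria")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A frame satisfies the bond when any donor/acceptor combination meets the
#' distance criterion (and, when hydrogen indices are given, the D-H...A
#' angle criterion for the hydrogen attached to that donor). Occupancy is the
#' fraction of satisfied frames.
#'
#' @param traj an [sf_trajectory()].
#' @param donors,acceptors integer atom indices (see [select_atoms()]).
#' @param hydrogens optional integer indices parallel to `donors` (the
#'   hydrogen bound to each donor), or NULL for distance-only evaluation.
#' @param criteria an [hbond_criteria()].
#' @return list with `occupancy` (fraction) and `per_frame` (logical vector).
#' @export
hbond_occupancy <- function(traj, donors, acceptors, hydrogens = NULL,
                            criteria = hbond_criteria()) {
  if (length(donors) == 0L) stop("empty donor selection")
  if (length(acceptors) == 0L) stop("empty acceptor selection")
  if (!is.null(hydrogens) && length(hydrogens) != length(donors))
    stop("hydrogens must parallel donors")
  per_frame <- vapply(traj$frames, function(m) {
    for (di in seq_along(donors)) {
      d <- m[donors[di], ]
      for (ai in seq_along(acceptors)) {
        acc <- m[acceptors[ai], ]
        if (sqrt(sum((d - acc)^2)) <= criteria$max_dist) {
          if (is.null(hydrogens)) {
            if (criteria$hydrogen_optional) return(TRUE) else next
          } else {
            h <- m[hydrogens[di], ]
            v1 <- d - h; v2 <- acc - h
            cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
            if (ang >= criteria$min_angle) return(TRUE)
          }
        }
      }
    }
    FALSE
  }, logical(1))
  list(occupancy = mean(per_frame), per_frame = per_frame)
}

#' Classify the D80 side-chain rotamer relative to W67
#'
#' The down configuration is defined functionally: the aspartate carboxylate
#' close enough to the tryptophan indole nitrogen to hydrogen-bond. Per chain
#' and frame, the minimum distance between the D80 carboxylate oxygens and
#' W67 Ne1 is binned into down (<= `d_down`), up (>= `d_up`) and middle.
#'
#' @param traj an [sf_trajectory()].
#' @param asp_resno,trp_resno residue numbers of the aspartate and
#'   tryptophan (defaults 80 and 67).
#' @param d_down,d_up distance thresholds in Angstrom.
#' @return A `state_assignment` data frame with labels down/middle/up; chains
#'   missing the required atoms are skipped and listed in `flags`.
#' @export
classify_d80_rotamer <- function(traj, asp_resno = 80, trp_resno = 67,
                                 d_down = 3.5, d_up = 6.5) {
  if (d_down >= d_up) stop("need d_down < d_up")
  a <- traj$atoms
  rows <- list(); flags <- character()
  for (ch in unique(a$chain)) {
    ox <- which(a$chain == ch & a$resno == asp_resno &
                  a$elety %in% c("OD1", "OD2"))
    ne <- which(a$chain == ch & a$resno == trp_resno & a$elety == "NE1")
    if (length(ox) == 0L || length(ne) != 1L) {
      flags[ch] <- "missing D80 carboxylate or W67 NE1"
      next
    }
    lab <- vapply(traj$frames, function(m) {
      dmin <- min(sqrt(rowSums((m[ox, , drop = FALSE] -
                                  matrix(m[ne, ], length(ox), 3,
                                         byrow = TRUE))^2)))
      if (dmin <= d_down) "down" else if (dmin >= d_up) "up" else "middle"
    }, character(1))
    rows[[ch]] <- data.frame(chain = ch, resno = asp_resno,
                             frame = seq_along(traj$frames),
                             label = factor(lab, levels = c("down", "middle",
                                                            "up")),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  attr(out, "provenance") <- c(d_down = d_down, d_up = d_up)
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' Buried-water census behind the selectivity filter
#'
#' Counts, per subunit and frame, the water oxygens within `radius` of the
#' centroid of the anchor side chains (by default residues 67, 71 and 80 -
#' the hydrogen-bond triad enclosing the crystallographic buried-water site).
#' An exchange event is a change in the identity set of in-cavity waters
#' between consecutive frames; each entry and each exit counts once.
#'
#' @param traj an [sf_trajectory()].
#' @param anchor_resno residues whose side-chain heavy atoms define the
#'   cavity centroid.
#' @param radius inclusion radius in Angstrom.
#' @param water_resid residue names identifying water.
#' @return list with `counts` (data frame chain x frame), `events` (named
#'   per-chain totals) and `total_events`.
#' @export
water_cavity_census <- function(traj, anchor_resno = c(67, 71, 80),
                                radius = 5.0,
                                water_resid = c("HOH", "WAT", "TIP3", "SOL")) {
  if (radius <= 0) stop("radius must be > 0")
  a <- traj$atoms
  wat <- which(a$resid %in% water_resid & a$elety %in% c("O", "OH2", "OW"))
  backbone <- c("N", "CA", "C", "O", "H", "HA", "HN")
  chains <- setdiff(unique(a$chain[a$resno %in% anchor_resno &
                                     !(a$resid %in% water_resid)]), NA)
  counts <- list(); events <- stats::setNames(integer(length(chains)), chains)
  for (ch in chains) {
    anch <- which(a$chain == ch & a$resno %in% anchor_resno &
                    !(a$elety %in% backbone) & !startsWith(a$elety, "H"))
    if (length(anch) == 0L)
      stop("no side-chain anchor atoms resolved for chain ", ch)
    prev <- integer()
    cnt <- integer(length(traj$frames))
    for (f in seq_along(traj$frames)) {
      m <- traj$frames[[f]]
      cen <- colMeans(m[anch, , drop = FALSE])
      if (length(wat)) {
        dw <- sqrt(rowSums((m[wat, , drop = FALSE] -
                              matrix(cen, length(wat), 3, byrow = TRUE))^2))
        inside <- wat[dw <= radius]
      } else inside <- integer()
      cnt[f] <- length(inside)
      if (f > 1L)
        events[ch] <- events[ch] + length(setdiff(inside, prev)) +
          length(setdiff(prev, inside))
      prev <- inside
    }
    counts[[ch]] <- data.frame(chain = ch, frame = seq_along(cnt),
                               count = cnt, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  list(counts = counts, events = events, total_events = sum(events))
}

#' Optimal superposition and RMSD of two structures
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `ref` over a common
#' atom selection, returning the RMSD after the optimal rotation and
#' translation. The selection must resolve identical ordered atom lists in
#' both structures.
#'
#' @param mobile,ref [sf_structure()] objects.
#' @param resno,elety,chain selection filters applied to both structures
#'   (see [select_atoms()]); NULL selects everything.
#' @return object of class `superposition`: list with `rmsd` (Angstrom),
#'   `rotation`, `translation` and `n_atoms`.
#' @export
superpose_and_rmsd <- function(mobile, ref, resno = NULL, elety = NULL,
                               chain = NULL) {
  im <- select_atoms(mobile, resno = resno, elety = elety, chain = chain)
  ir <- select_atoms(ref, resno = resno, elety = elety, chain = chain)
  km <- paste(mobile$atoms$chain[im], mobile$atoms$resno[im],
              mobile$atoms$elety[im])
  kr <- paste(ref$atoms$chain[ir], ref$atoms$resno[ir], ref$atoms$elety[ir])
  if (!identical(km, kr)) {
    miss <- c(setdiff(kr, km), setdiff(km, kr))
    stop("selection does not resolve identical atom lists; mismatched: ",
         paste(utils::head(miss, 5L), collapse = "; "))
  }
  X <- mobile$xyz[im, , drop = FALSE]  # mobile
  Y <- ref$xyz[ir, , drop = FALSE]     # reference
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  S <- svd(crossprod(Xc, Yc))          # t(Xc) %*% Yc
  d <- sign(det(S$u %*% t(S$v)))
  D <- diag(c(1, 1, d))
  R <- S$u %*% D %*% t(S$v)            # rotation applied as Xc %*% R
  Xfit <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((Xfit - Yc)^2)))
  structure(list(rmsd = rmsd, rotation = R,
                 translation = cy - as.numeric(cx %*% R),
                 n_atoms = nrow(X)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.4f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}
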