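#' Construct a structure (one coordinate set)
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`
#'   (3-letter residue name) and `elety` (atom name).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `sf_structure`.
#' @export
sf_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom identity within a chain/residue: ",
         key[duplicated(key)][1L])
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "sf_structure")
}

#' @export
print.sf_structure <- function(x, ...) {
  cat("<sf_structure>", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues, chains:",
      paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Construct a trajectory ensemble
#'
#' @param atoms topology atom table (see [sf_structure()]).
#' @param frames list of coordinate matrices (n_atoms x 3), one per frame.
#' @param times optional frame times (ns), strictly increasing.
#' @param t0_production logical; whether a t = 0 frame counts as a production
#'   frame for snapshot extraction (default `FALSE`: the run starts at the
#'   first stride).
#' @return object of class `sf_trajectory`.
#' @export
sf_trajectory <- function(atoms, frames, times = NULL, t0_production = FALSE) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  na <- nrow(atoms)
  for (k in seq_along(frames)) {
    frames[[k]] <- as.matrix(frames[[k]])
    if (nrow(frames[[k]]) != na || ncol(frames[[k]]) != 3L)
      stop("frame ", k, " has wrong atom count (", nrow(frames[[k]]),
           " vs topology ", na, ")")
  }
  if (!is.null(times)) {
    if (length(times) != length(frames))
      stop("frame_times length must equal number of frames")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, frames = frames, times = times,
                 t0_production = isTRUE(t0_production)),
            class = "sf_trajectory")
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat("<sf_trajectory>", length(x$frames), "frames,", nrow(x$atoms), "atoms")
  if (!is.null(x$times))
    cat(", t = ", x$times[1], "..", x$times[length(x$times)], " ns", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Chain, residue and atom naming are preserved verbatim. For multi-model
#' files the first model is returned; use [read_trajectory()] to map models
#' to frames.
#'
#' @param path PDB file.
#' @return An [sf_structure()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, stringsAsFactors = FALSE)
  sf_structure(atoms, cbind(at$x, at$y, at$z))
}

#' Read a multi-model PDB as a trajectory ensemble
#'
#' Models map to frames in file order. Frame times, when known, can be
#' supplied; otherwise use `stride_ns` metadata in
#' [extract_monomer_snapshots()].
#'
#' @param path multi-model PDB file.
#' @param times optional frame times in ns.
#' @param t0_production see [sf_trajectory()].
#' @return An [sf_trajectory()].
#' @export
read_trajectory <- function(path, times = NULL, t0_production = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, stringsAsFactors = FALSE)
  nm <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nm), function(k)
    matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE))
  sf_trajectory(atoms, frames, times = times, t0_production = t0_production)
}

#' Extract per-subunit snapshots from a trajectory
#'
#' Subsamples frames at a fixed stride and splits every retained frame into
#' one structure per subunit (chain). A 1-us tetramer trajectory sampled
#' every 10 ns yields 100 frames x 4 subunits = 400 monomer structures.
#' A frame at t = 0 is retained only when the trajectory marks it as a
#' production frame (`t0_production`).
#'
#' @param traj an [sf_trajectory()] with frame times (ns) or uniform spacing
#'   given via `frame_spacing_ns`.
#' @param stride_ns sampling interval in ns; must be >= the frame spacing.
#' @param n_subunits number of subunits; defaults to the number of chains.
#' @param frame_spacing_ns frame spacing when `traj$times` is absent.
#' @return list of [sf_structure()] objects, length
#'   `retained_frames * n_subunits`.
#' @export
extract_monomer_snapshots <- function(traj, stride_ns, n_subunits = NULL,
                                      frame_spacing_ns = NULL) {
  times <- traj$times
  if (is.null(times)) {
    if (is.null(frame_spacing_ns))
      stop("trajectory has no frame times; supply frame_spacing_ns")
    times <- (seq_along(traj$frames) - 1L) * frame_spacing_ns
  }
  spacing <- if (length(times) > 1L) min(diff(times)) else stride_ns
  if (stride_ns < spacing - 1e-9)
    stop("stride (", stride_ns, " ns) is smaller than the frame spacing (",
         spacing, " ns)")
  tol <- 1e-6 * max(stride_ns, 1)
  on_grid <- abs(times / stride_ns - round(times / stride_ns)) < tol
  keep <- on_grid & (times > tol | traj$t0_production)
  chains <- unique(traj$atoms$chain)
  if (is.null(n_subunits)) n_subunits <- length(chains)
  if (n_subunits != length(chains))
    stop("n_subunits (", n_subunits, ") does not match chains in topology (",
         length(chains), ")")
  out <- vector("list", sum(keep) * n_subunits)
  i <- 0L
  for (f in which(keep)) {
    for (ch in chains) {
      sel <- traj$atoms$chain == ch
      i <- i + 1L
      out[[i]] <- sf_structure(traj$atoms[sel, , drop = FALSE],
                               traj$frames[[f]][sel, , drop = FALSE])
    }
  }
  out
}

#' Select atom indices in a structure or trajectory
#'
#' @param x an [sf_structure()] or [sf_trajectory()].
#' @param resno residue numbers to keep (NULL = all).
#' @param elety atom names to keep (NULL = all).
#' @param chain chains to keep (NULL = all).
#' @param resid residue names to keep (NULL = all).
#' @return integer atom indices.
#' @export
select_atoms <- function(x, resno = NULL, elety = NULL, chain = NULL,
                         resid = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  which(keep)
}

#' Apply a rigid motion to a structure or trajectory
#'
#' Used mostly to verify invariance of geometric analyses: rotates by `R` and
#' then translates by `t` every coordinate (every frame for a trajectory).
#'
#' @param x an [sf_structure()] or [sf_trajectory()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector.
#' @return object of the same class.
#' @export
rigid_transform <- function(x, R = diag(3), t = c(0, 0, 0)) {
  mv <- function(m) sweep(m %*% t(R), 2L, -t)
  if (inherits(x, "sf_structure")) {
    x$xyz <- mv(x$xyz)
  } else if (inherits(x, "sf_trajectory")) {
    x$frames <- lapply(x$frames, mv)
  } else stop("unsupported object")
  x
}

#' Random rotation matrix (uniform over SO(3))
#' @param seed optional integer seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
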