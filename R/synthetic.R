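#' @name synthetic
#' @title Seeded synthetic-data generators with planted ground truth
#' @description Every input stream of the pipeline has a generator that emits
#'   data with known (planted) parameters, so each stage is testable end to
#'   end without external files. One integer seed governs each generator; a
#'   multiplicative counter-based splitting rule derives independent
#'   sub-streams, so the same spec always yields bit-identical output.
#'   The default synthetic system uses the landmark residue numbering of the
#'   channel (hydrogen-bond triad 67/71/80, filter 74-80), so tests can speak
#'   the same residue vocabulary as real data.
NULL

# counter-based seed splitting; stays below 2^31
split_seed <- function(seed, stream) {
  as.integer(((seed %% 2147483647) * 16807 + stream * 2654435) %% 2147483647)
}

# landmark residues of the synthetic channel
default_residues <- function() {
  data.frame(
    resno = c(64L, 67L, 69L, 70L, 71L, 74L, 76L, 78L, 79L, 80L, 82L),
    resname = c("ARG", "TRP", "SER", "VAL", "GLU", "THR", "VAL", "TYR",
                "GLY", "ASP", "TYR"),
    stringsAsFactors = FALSE)
}

# deterministic, plausible base shifts (ppm) per residue/atom
base_shift <- function(resno, resname, atom) {
  switch(atom,
         H = 8.0 + 0.04 * ((resno * 7) %% 11) / 10,
         N = 116 + (resno * 13) %% 9,
         C = 174 + ((resno * 5) %% 7) / 2,
         CA = if (resname == "GLY") 45.2 else 55 + ((resno * 3) %% 8) / 2,
         NE1 = 129.5, HE1 = 10.1,
         stop("no base shift for atom ", atom))
}

#' Generate a reference/query pair of shift tables with planted CSPs
#'
#' The query table equals the reference plus a planted per-(residue, atom)
#' perturbation plus Gaussian noise. The default planted map mimics a
#' triad-disrupting mutant: a positive valine-carbonyl CSP at residue 76, a
#' negative alpha-carbon CSP at residue 78, and amide perturbations at the
#' triad residues 67 and 80.
#'
#' @param csp data frame with columns `resno`, `atom`, `delta` (ppm).
#' @param noise_sd Gaussian noise sd (ppm) added to the query shifts.
#' @param seed integer seed.
#' @param variant_id label for the query table.
#' @return list with `ref` and `query` ([shift_table()]s) and `truth` (the
#'   planted CSP map).
#' @export
gen_shift_tables <- function(csp = NULL, noise_sd = 0, seed = 1L,
                             variant_id = "synthetic-mutant") {
  if (is.null(csp))
    csp <- data.frame(
      resno = c(76, 78, 67, 67, 80, 80, 78, 78),
      atom = c("C", "CA", "N", "H", "N", "H", "N", "H"),
      delta = c(0.94, -0.84, 2.0, 0.30, -1.5, -0.25, 1.2, 0.20))
  res <- default_residues()
  rows <- list()
  for (i in seq_len(nrow(res))) {
    atoms <- c("H", "N", "C", "CA")
    if (res$resname[i] == "TRP") atoms <- c(atoms, "NE1", "HE1")
    for (at in atoms)
      rows[[paste(res$resno[i], at)]] <- data.frame(
        resno = res$resno[i], resname = res$resname[i], atom = at,
        shift = base_shift(res$resno[i], res$resname[i], at),
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  ref <- shift_table(df$resno, df$resname, df$atom, df$shift, "synthetic-ref")
  q <- df
  for (j in seq_len(nrow(csp))) {
    i <- which(q$resno == csp$resno[j] & q$atom == csp$atom[j])
    if (length(i) == 1L) q$shift[i] <- q$shift[i] + csp$delta[j]
  }
  set.seed(split_seed(seed, 1L))
  q$shift <- q$shift + stats::rnorm(nrow(q), 0, noise_sd)
  query <- shift_table(q$resno, q$resname, q$atom, q$shift, variant_id)
  list(ref = ref, query = query, truth = csp)
}

#' Generate a relaxation decay-series set with planted rates
#'
#' Mono-exponential decays I0 * exp(-R t) plus Gaussian noise on the standard
#' six-delay grid (0, 5, 10, 20, 40, 80 ms); a faster-relaxing variant can be
#' emulated with the shorter 0-60 ms grid. Rates are per delay unit.
#'
#' @param rates named numeric vector of planted rates (reciprocal delay
#'   units), names = residue keys.
#' @param delays delay grid.
#' @param delay_unit unit label for the delays.
#' @param I0 common amplitude.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @param experiment `"R1rho"` or `"T1"`.
#' @return list with `set` (a `decay_series_set`) and `truth` (the rates).
#' @export
gen_decay_set <- function(rates = c(V76 = 0.015, G77 = 0.010, Y78 = 0.020,
                                    G79 = 0.030, D80 = 0.018),
                          delays = c(0, 5, 10, 20, 40, 80),
                          delay_unit = "ms", I0 = 1, noise_sd = 0, seed = 1L,
                          experiment = "R1rho") {
  set.seed(split_seed(seed, 2L))
  m <- t(vapply(rates, function(r)
    I0 * exp(-r * delays) + stats::rnorm(length(delays), 0, noise_sd),
    numeric(length(delays))))
  rownames(m) <- names(rates)
  list(set = decay_series_set(delays, m, experiment = experiment,
                              delay_unit = delay_unit),
       truth = rates)
}

# von Mises sampler (Best & Fisher 1979 rejection method); mean mu (deg),
# concentration kappa; returns degrees
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- sign(u3 - 0.5) * acos(f)
    }
  }
  ang_diff(mu + out * 180 / pi, 0)
}

#' Generate a two-state Markov dihedral series with planted populations
#'
#' Emulates the carbonyl inwards/outwards flipping of one filter residue: a
#' two-state Markov chain with stationary inwards probability `p_in`
#' (default 60:40 inwards:outwards, the equilibrium reported for the
#' conductive wild-type filter), with psi emitted from a von Mises
#' distribution around antipodal state centres and phi around a fixed centre.
#' The transition matrix is P(in->out) = switch_rate * (1 - p_in),
#' P(out->in) = switch_rate * p_in, which satisfies detailed balance for the
#' target stationary distribution.
#'
#' @param n_frames number of frames.
#' @param resno residue number of the classified carbonyl.
#' @param p_in stationary inwards probability in \[0, 1\].
#' @param switch_rate overall switching propensity in (0, 1/max(p_in, 1-p_in)).
#' @param center_in inwards psi centre (degrees); outwards is its antipode.
#' @param kappa von Mises concentration of the angular noise.
#' @param phi_center phi centre (degrees).
#' @param chain chain label.
#' @param seed integer seed.
#' @return list with `dihedrals` (a `dihedral_series`), `labels` (truth
#'   `state_assignment`), `windows` (the matching [state_windows()]) and
#'   `p_in`.
#' @export
gen_two_state_dihedrals <- function(n_frames = 10000L, resno = 76L,
                                    p_in = 0.6, switch_rate = 0.25,
                                    center_in = 120, kappa = 20,
                                    phi_center = -100, chain = "A",
                                    seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1)
  set.seed(split_seed(seed, 3L))
  p_io <- switch_rate * (1 - p_in)   # P(in -> out)
  p_oi <- switch_rate * p_in         # P(out -> in)
  state <- integer(n_frames)         # 1 = inwards, 0 = outwards
  state[1] <- stats::rbinom(1, 1, p_in)
  u <- stats::runif(n_frames)
  for (f in seq_len(n_frames - 1L)) {
    state[f + 1L] <- if (state[f] == 1L) {
      if (u[f] < p_io) 0L else 1L
    } else {
      if (u[f] < p_oi) 1L else 0L
    }
  }
  center_out <- ang_diff(center_in + 180, 0)
  psi <- numeric(n_frames)
  psi[state == 1L] <- rvonmises_deg(sum(state == 1L), center_in, kappa)
  psi[state == 0L] <- rvonmises_deg(sum(state == 0L), center_out, kappa)
  phi <- rvonmises_deg(n_frames, phi_center, kappa)
  dih <- data.frame(chain = chain, resno = as.integer(resno),
                    frame = seq_len(n_frames), phi = phi, psi = psi,
                    stringsAsFactors = FALSE)
  class(dih) <- c("dihedral_series", "data.frame")
  lab <- data.frame(chain = chain, resno = as.integer(resno),
                    frame = seq_len(n_frames),
                    label = factor(ifelse(state == 1L, "inwards", "outwards"),
                                   levels = c("inwards", "outwards", "other")),
                    stringsAsFactors = FALSE)
  class(lab) <- c("state_assignment", "data.frame")
  win <- state_windows(stats::setNames(center_in, resno))
  list(dihedrals = dih, labels = lab, windows = win, p_in = p_in,
       switch_rate = switch_rate)
}

#' Generate a toy trajectory with scripted hydrogen-bond and water events
#'
#' A minimal single-chain system carrying the analysis landmarks: a
#' three-residue peptide (defined backbone dihedrals), a tryptophan-67 indole
#' NH, a glutamate-71 side chain, an aspartate-80 carboxylate hydrogen-bonded
#' to the indole nitrogen, and three waters, one of which sits in the cavity
#' enclosed by the 67/71/80 side chains. Optional scripted events: at
#' `hbond_break_frame` the aspartate side chain swings away (breaking the
#' 67-80 bond and moving the rotamer from down to up); at `water_swap_frame`
#' the in-cavity water leaves and a bulk water enters (two exchange events).
#'
#' @param n_frames number of frames.
#' @param hbond_break_frame frame at which the 67-80 bond breaks (NULL =
#'   never).
#' @param water_swap_frame frame at which the cavity water is swapped (NULL =
#'   never).
#' @param jitter_sd Gaussian positional noise (Angstrom) added to every
#'   coordinate, small enough not to flip any scripted state.
#' @param seed integer seed.
#' @return list with `traj` (an [sf_trajectory()]) and `truth` (scripted
#'   per-frame hbond presence, rotamer labels, cavity counts and expected
#'   exchange events).
#' @export
gen_toy_trajectory <- function(n_frames = 20L, hbond_break_frame = NULL,
                               water_swap_frame = NULL, jitter_sd = 0,
                               seed = 1L) {
  atoms <- data.frame(
    chain = "A",
    resno = c(rep(64L, 3), rep(65L, 3), rep(66L, 3),
              rep(67L, 6), rep(71L, 5), rep(80L, 7),
              201L, 202L, 203L),
    resid = c(rep("GLY", 9), rep("TRP", 6), rep("GLU", 5), rep("ASP", 7),
              "HOH", "HOH", "HOH"),
    elety = c(rep(c("N", "CA", "C"), 3),
              "N", "CA", "C", "CB", "NE1", "HE1",
              "N", "CA", "C", "CB", "CD",
              "N", "CA", "C", "CB", "CG", "OD1", "OD2",
              "O", "O", "O"),
    stringsAsFactors = FALSE)
  base <- rbind(
    c(10, 0, 0), c(11.4, 0.4, 0.3), c(12.2, 1.5, -0.3),        # 64
    c(13.5, 1.6, -0.2), c(14.4, 2.7, -0.5), c(15.8, 2.4, -1.0),# 65
    c(16.6, 3.4, -1.2), c(18.0, 3.3, -1.6), c(18.8, 4.5, -2.0),# 66
    c(-2.5, -1.5, 0), c(-2.0, -0.9, 0.9), c(-3.0, -0.3, 1.5),  # 67 bb
    c(-1.4, -0.8, 0), c(0, 0, 0), c(0.98, 0, 0),               # 67 CB NE1 HE1
    c(0.2, -3.6, 1.2), c(0.9, -3.1, 1.6), c(0.3, -2.4, 2.4),   # 71 bb
    c(1.5, -2.5, 1.0), c(2.0, -2.0, 0.5),                      # 71 CB CD
    c(7.2, 1.2, 1.0), c(6.0, 0.8, 0.8), c(6.2, 1.5, -0.2),     # 80 bb
    c(4.9, 0.5, 0.5), c(3.8, 0.5, 0), c(2.9, 0, 0), c(3.4, 1, 0), # 80 sc
    c(2.0, -0.5, 0.3),      # water 201: in cavity
    c(20, 20, 20),          # water 202: bulk
    c(-15, 10, 5))          # water 203: bulk
  asp_sc <- which(atoms$resno == 80 & atoms$elety %in%
                    c("CB", "CG", "OD1", "OD2"))
  w201 <- which(atoms$resno == 201); w202 <- which(atoms$resno == 202)
  set.seed(split_seed(seed, 4L))
  frames <- vector("list", n_frames)
  hbond <- logical(n_frames); rot <- character(n_frames)
  count <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    m <- base
    broken <- !is.null(hbond_break_frame) && f >= hbond_break_frame
    swapped <- !is.null(water_swap_frame) && f >= water_swap_frame
    if (broken) m[asp_sc, 1] <- m[asp_sc, 1] + 5.5
    if (swapped) {
      m[w201, ] <- c(25, 25, 25)
      m[w202, ] <- c(2.2, -0.3, 0.2)
    }
    if (jitter_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, jitter_sd), nrow(m), 3)
    frames[[f]] <- m
    hbond[f] <- !broken
    rot[f] <- if (broken) "up" else "down"
    count[f] <- 1L
  }
  events <- if (is.null(water_swap_frame) || water_swap_frame > n_frames ||
                water_swap_frame < 2L) 0L else 2L
  list(traj = sf_trajectory(atoms, frames),
       truth = list(hbond_present = hbond,
                    rotamer = rot,
                    cavity_count = count,
                    exchange_events = events))
}

#' Generate paired protonated/deuterated intensity tables with planted
#' protection classes
#'
#' Protonated intensities are drawn around 1 and rescaled by an arbitrary
#' per-table factor (removed again by reference normalisation); deuterated
#' intensities equal protonated times a ratio drawn from the planted class
#' band (protected 0.95, attenuated 0.45, exchanged 0.02 at zero noise) plus
#' Gaussian noise, floored at 0. Reference residues are forced to ratio 1.
#'
#' @param classes named character vector of planted classes per residue key
#'   (values in exchanged/attenuated/protected). The default mimics a
#'   wild-type-like cavity: G79 and L81 exchanged, the rest of the filter
#'   protected.
#' @param refs reference residue keys (always protected, ratio 1).
#' @param noise_sd Gaussian noise sd on the ratio.
#' @param seed integer seed.
#' @return list with `protonated`, `deuterated` ([intensity_table()]s) and
#'   `truth` (the planted classes).
#' @export
gen_hdx_tables <- function(classes = c(G77 = "protected", Y78 = "protected",
                                       G79 = "exchanged", L81 = "exchanged",
                                       T74 = "protected", D80 = "attenuated"),
                           refs = c("S69", "V70"), noise_sd = 0, seed = 1L) {
  stopifnot(all(classes %in% c("exchanged", "attenuated", "protected")))
  set.seed(split_seed(seed, 5L))
  band <- c(exchanged = 0.02, attenuated = 0.45, protected = 0.95)
  residues <- c(refs, names(classes))
  ratio <- c(stats::setNames(rep(1, length(refs)), refs),
             band[classes] + stats::rnorm(length(classes), 0, noise_sd))
  ratio <- pmax(ratio, 0)
  names(ratio) <- residues
  prot <- 1 + stats::runif(length(residues), -0.2, 0.2)
  prot[seq_along(refs)] <- 1
  deut <- prot * ratio
  # arbitrary spectrometer scalings, removed by normalisation
  list(protonated = intensity_table(residues, 137.5 * prot, "protonated"),
       deuterated = intensity_table(residues, 82.3 * deut, "deuterated"),
       truth = classes)
}

#' Generate a synthetic filter structure (and perturbed variants)
#'
#' Builds an idealised tetrameric selectivity-filter backbone (residues
#' 75-79, atoms N/CA/C/O, four chains arranged around the pore axis). With
#' `perturb_sd > 0` the coordinates receive Gaussian noise and a random rigid
#' motion, emulating an independently solved crystal structure of a variant
#' whose filter is essentially unchanged. These are synthetic stand-ins, not
#' deposited coordinates.
#'
#' @param perturb_sd per-coordinate Gaussian noise in Angstrom (0 = the
#'   reference geometry).
#' @param n_chains number of subunits.
#' @param seed integer seed (used for the perturbation and rigid motion).
#' @return An [sf_structure()].
#' @export
gen_filter_structure <- function(perturb_sd = 0, n_chains = 4L, seed = 1L) {
  resno <- 75:79
  resname <- c("THR", "VAL", "GLY", "TYR", "GLY")
  rows <- list(); xyz <- list()
  for (k in seq_len(n_chains)) {
    th <- 2 * pi * (k - 1) / n_chains
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    for (i in seq_along(resno)) {
      ca <- c(2.3 * cos(1.75 * i) + 8, 2.3 * sin(1.75 * i), 1.5 * i)
      pos <- rbind(N = ca + c(-1.2, 0.3, -0.5),
                   CA = ca,
                   C = ca + c(1.0, 0.7, 0.5),
                   O = ca + c(1.6, -0.3, 0.7))
      rows[[paste(k, i)]] <- data.frame(
        chain = LETTERS[k], resno = resno[i], resid = resname[i],
        elety = rownames(pos), stringsAsFactors = FALSE)
      xyz[[paste(k, i)]] <- pos %*% t(Rz)
    }
  }
  atoms <- do.call(rbind, rows)
  m <- do.call(rbind, xyz)
  if (perturb_sd > 0) {
    set.seed(split_seed(seed, 6L))
    m <- m + matrix(stats::rnorm(length(m), 0, perturb_sd), nrow(m), 3)
    s <- sf_structure(atoms, m)
    return(rigid_transform(s, random_rotation(), stats::rnorm(3, 0, 20)))
  }
  sf_structure(atoms, m)
}

#' Generate a synthetic tetramer trajectory with frame times
#'
#' Frames are jittered copies of the idealised filter tetramer at a fixed
#' time spacing, used to exercise snapshot extraction (a 1000 ns run sampled
#' every 10 ns with four subunits yields 400 monomer snapshots).
#'
#' @param duration_ns total simulated time.
#' @param spacing_ns frame spacing.
#' @param include_t0 include a t = 0 frame (not counted as production).
#' @param jitter_sd per-coordinate Gaussian noise per frame.
#' @param seed integer seed.
#' @return An [sf_trajectory()].
#' @export
gen_filter_trajectory <- function(duration_ns = 1000, spacing_ns = 10,
                                  include_t0 = TRUE, jitter_sd = 0.05,
                                  seed = 1L) {
  base <- gen_filter_structure()
  times <- seq(if (include_t0) 0 else spacing_ns, duration_ns, by = spacing_ns)
  set.seed(split_seed(seed, 7L))
  frames <- lapply(times, function(t)
    base$xyz + matrix(stats::rnorm(length(base$xyz), 0, jitter_sd),
                      nrow(base$xyz), 3))
  sf_trajectory(base$atoms, frames, times = times, t0_production = FALSE)
}

#' Surrogate frame shifts from a state assignment (generator alias)
#'
#' Delegates to [surrogate_predict()]; part of the synthetic-data surface so
#' that a full synthetic study can be generated from one namespace.
#'
#' @inheritParams surrogate_predict
#' @return A [shift_ensemble()].
#' @export
gen_frame_shifts <- function(assign, params = surrogate_params(), seed = 1L) {
  surrogate_predict(assign, params, seed = split_seed(seed, 8L))
}
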