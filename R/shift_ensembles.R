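#' Construct a predicted-shift ensemble
#'
#' Per-frame predicted chemical shifts for selected residues/atoms, e.g. the
#' output of an external shift predictor run over trajectory snapshots, or of
#' the package's own state-conditioned surrogate.
#'
#' @param frames data frame with columns `frame`, `chain`, `resno`, `atom`,
#'   `shift`.
#' @param source `"external_table"` or `"surrogate"`.
#' @return object of class `shift_ensemble` (a data frame with attributes
#'   `source` and `offsets`, the per-atom-class offsets applied so far).
#' @export
shift_ensemble <- function(frames, source = c("external_table", "surrogate")) {
  source <- match.arg(source)
  need <- c("frame", "chain", "resno", "atom", "shift")
  if (!all(need %in% names(frames)))
    stop("frames needs columns: ", paste(need, collapse = ", "))
  key <- paste(frames$frame, frames$chain, frames$resno, frames$atom)
  if (anyDuplicated(key))
    stop("duplicate (frame, chain, residue, atom) key: ",
         key[duplicated(key)][1L])
  out <- as.data.frame(frames)[need]
  attr(out, "source") <- source
  attr(out, "offsets") <- numeric(0)
  class(out) <- c("shift_ensemble", "data.frame")
  out
}

#' @export
print.shift_ensemble <- function(x, ...) {
  off <- attr(x, "offsets")
  cat("<shift_ensemble>", attr(x, "source"), "-",
      length(unique(x$frame)), "frames,",
      length(unique(paste(x$resno, x$atom))), "residue/atom keys\n")
  if (length(off))
    cat("offsets applied:",
        paste(names(off), "=", off, "ppm", collapse = ", "), "\n")
  invisible(x)
}

#' Load per-frame predicted shifts from TSV
#'
#' Columns `frame`, `chain`, `resno`, `atom`, `shift`. Duplicate keys are an
#' error, and the frame index must be gap-free (a missing frame indicates a
#' truncated predictor run and is reported by number).
#'
#' @param path TSV file.
#' @return A [shift_ensemble()] with `source = "external_table"`.
#' @export
load_frame_shifts <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  fr <- sort(unique(df$frame))
  gaps <- setdiff(seq(min(fr), max(fr)), fr)
  if (length(gaps))
    stop("frame index has gaps; missing frame(s): ",
         paste(utils::head(gaps, 10L), collapse = ", "))
  shift_ensemble(df, source = "external_table")
}

#' Write a shift ensemble to TSV (round-trips through [load_frame_shifts()])
#' @param ens a [shift_ensemble()].
#' @param path output file.
#' @export
write_frame_shifts <- function(ens, path) {
  write_profile(as.data.frame(ens), path)
}

#' Apply a systematic offset to one atom class of predicted shifts
#'
#' External predictors can be systematically offset for particular nuclei;
#' for the backbone carbonyl carbon (atom `"C"`) the calibrated correction is
#' +2.5 ppm, applied identically to every channel variant so that
#' between-variant differences are untouched. Each atom class accepts the
#' offset exactly once; a second application is an error rather than a
#' silent double shift.
#'
#' @param ens a [shift_ensemble()].
#' @param atom_class atom name to offset (e.g. `"C"` for carbonyl carbons).
#' @param offset_ppm offset in ppm.
#' @return the ensemble with shifts of that class incremented and the offset
#'   recorded.
#' @export
apply_offset <- function(ens, atom_class = "C", offset_ppm = 2.5) {
  off <- attr(ens, "offsets")
  if (atom_class %in% names(off))
    stop("offset already applied to atom class '", atom_class, "' (",
         off[[atom_class]], " ppm)")
  sel <- ens$atom == atom_class
  ens$shift[sel] <- ens$shift[sel] + offset_ppm
  off[[atom_class]] <- offset_ppm
  attr(ens, "offsets") <- off
  ens
}

#' Default surrogate calibration for state-conditioned shift emissions
#'
#' Gaussian emission means per (residue, atom, state) with the inwards state
#' upfield of the outwards state by `delta_co` ppm for backbone carbonyls and
#' `delta_ca` ppm for alpha carbons, centred on typical membrane-protein
#' values. These separations are the calibration knob that links carbonyl
#' flips to observable shifts; they sit mid-range of back-calculated
#' inwards-outwards separations for filter carbonyls (+2 to +3 ppm for the
#' valine carbonyl, +2 ppm for the tyrosine alpha carbon).
#'
#' @param resno residues to cover.
#' @param delta_co inwards-minus-outwards separation for atom `"C"` (ppm).
#' @param delta_ca separation for atom `"CA"` (ppm).
#' @param sd emission standard deviation (ppm), > 0.
#' @param base_co,base_ca outwards-state means (ppm).
#' @return A `surrogate_params` data frame with columns `resno`, `atom`,
#'   `state`, `mean`, `sd`.
#' @export
surrogate_params <- function(resno = c(76, 78), delta_co = 2.5,
                             delta_ca = 2.0, sd = 0.5,
                             base_co = 175.5, base_ca = 56.0) {
  if (sd <= 0) stop("emission sd must be > 0")
  grid <- expand.grid(resno = resno, atom = c("C", "CA"),
                      state = c("inwards", "outwards"),
                      stringsAsFactors = FALSE)
  grid$mean <- ifelse(grid$atom == "C", base_co, base_ca) +
    ifelse(grid$state == "inwards",
           ifelse(grid$atom == "C", delta_co, delta_ca), 0)
  grid$sd <- sd
  class(grid) <- c("surrogate_params", "data.frame")
  grid
}

#' Surrogate per-frame shift prediction from a state assignment
#'
#' Stands in for an external per-frame shift predictor: for every (chain,
#' residue, frame) label in the assignment, emits one shift per parameterised
#' atom, drawn from the Gaussian for that (residue, atom, state). Seeded and
#' reproducible: the same assignment, parameters and seed give a bit-identical
#' ensemble.
#'
#' @param assign a `state_assignment` with inwards/outwards/other labels.
#' @param params a [surrogate_params()] covering every label present (frames
#'   labelled `other` are emitted from the mid-point of the two state means).
#' @param seed integer seed.
#' @return A [shift_ensemble()] with `source = "surrogate"`.
#' @export
surrogate_predict <- function(assign, params, seed = 1L) {
  set.seed(seed)
  resnos <- intersect(unique(assign$resno), unique(params$resno))
  if (length(resnos) == 0L)
    stop("params cover none of the assigned residues")
  rows <- list()
  for (rn in resnos) {
    lab <- assign[assign$resno == rn, ]
    for (at in unique(params$atom[params$resno == rn])) {
      p <- params[params$resno == rn & params$atom == at, ]
      mu_in <- p$mean[p$state == "inwards"]
      mu_out <- p$mean[p$state == "outwards"]
      sd <- p$sd[1]
      mu <- ifelse(lab$label == "inwards", mu_in,
                   ifelse(lab$label == "outwards", mu_out,
                          (mu_in + mu_out) / 2))
      rows[[paste(rn, at)]] <- data.frame(
        frame = lab$frame, chain = lab$chain, resno = rn, atom = at,
        shift = stats::rnorm(nrow(lab), mu, sd), stringsAsFactors = FALSE)
    }
  }
  shift_ensemble(do.call(rbind, rows), source = "surrogate")
}

#' Per-state histogram and moments of back-calculated shifts
#'
#' Partitions one residue/atom's predicted shifts by conformational state and
#' returns per-state counts on a common bin grid plus per-state means and
#' standard deviations. Chains are pooled, matching the monomer-snapshot
#' convention.
#'
#' @param ens a [shift_ensemble()].
#' @param assign the aligned `state_assignment` (same frames/chains).
#' @param resno,atom residue number and atom name to histogram.
#' @param breaks number of bins or break vector (see [graphics::hist()]).
#' @return list with `histograms` (named list of `hist` objects per state)
#'   and `stats` (data frame state/n/mean/sd).
#' @export
state_shift_histogram <- function(ens, assign, resno, atom, breaks = 30) {
  e <- ens[ens$resno == resno & ens$atom == atom, ]
  if (nrow(e) == 0L)
    stop("no predicted shifts for residue ", resno, " atom ", atom)
  key_e <- paste(e$frame, e$chain)
  a <- assign[assign$resno == resno, ]
  lab <- a$label[match(key_e, paste(a$frame, a$chain))]
  if (anyNA(lab))
    stop("state assignment does not align with the ensemble frames")
  br <- if (length(breaks) == 1L)
    seq(min(e$shift), max(e$shift), length.out = breaks + 1L) else breaks
  sts <- intersect(levels(lab), unique(as.character(lab)))
  hs <- lapply(sts, function(s)
    graphics::hist(e$shift[lab == s], breaks = br, plot = FALSE))
  names(hs) <- sts
  st <- do.call(rbind, lapply(sts, function(s) {
    x <- e$shift[lab == s]
    data.frame(state = s, n = length(x), mean = mean(x),
               sd = stats::sd(x), stringsAsFactors = FALSE)
  }))
  list(histograms = hs, stats = st)
}

#' Ensemble-mean predicted shift for one residue/atom
#'
#' Arithmetic mean over all frames (chains pooled), which by construction
#' equals the population-weighted average of the per-state means.
#'
#' @param ens a [shift_ensemble()].
#' @param resno,atom residue number and atom name.
#' @return mean shift in ppm.
#' @export
ensemble_mean_shift <- function(ens, resno, atom) {
  x <- ens$shift[ens$resno == resno & ens$atom == atom]
  if (length(x) == 0L)
    stop("no entries for residue ", resno, " atom ", atom)
  mean(x)
}

#' Predicted CSP profile between two shift ensembles
#'
#' Per-residue difference of ensemble-mean predicted shifts,
#' mutant-minus-WT sign convention matching [per_nucleus_csp()]. For a
#' two-state filter this reduces to delta-p(inwards) times the
#' inwards-outwards shift separation.
#'
#' @param ens_query,ens_ref [shift_ensemble()] objects (query = mutant-like,
#'   ref = WT-like).
#' @param resno residues to compare (default: all shared).
#' @param atom atom name (one per call, e.g. `"C"`).
#' @return A `csp_profile` with `kind = "predicted"`.
#' @export
predicted_csp <- function(ens_query, ens_ref, resno = NULL, atom = "C") {
  rq <- unique(ens_query$resno[ens_query$atom == atom])
  rr <- unique(ens_ref$resno[ens_ref$atom == atom])
  shared <- sort(intersect(rq, rr))
  if (!is.null(resno)) shared <- intersect(shared, resno)
  if (length(shared) == 0L)
    stop("no shared residues carry atom '", atom, "' in both ensembles")
  value <- vapply(shared, function(rn)
    ensemble_mean_shift(ens_query, rn, atom) -
      ensemble_mean_shift(ens_ref, rn, atom), numeric(1))
  csp_profile(shared, value, reference_id = "ensemble_ref",
              query_id = "ensemble_query", kind = "predicted", atom = atom)
}
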