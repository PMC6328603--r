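#' H/D-exchange intensity ratios with reference normalisation
#'
#' Scales the protonated and deuterated intensity tables so that the mean
#' intensity over the water-inaccessible reference residues is 1 in each, and
#' forms the per-residue ratio deuterated/protonated. A ratio of 1 means no
#' exchange (protected amide proton); 0 means complete exchange. The
#' attenuation is reported as 100 * (ratio - 1) percent. Reference residues
#' default to S69 and V70, which face the membrane and are not subject to
#' exchange.
#'
#' @param protonated,deuterated [intensity_table()] objects sharing residue
#'   keys.
#' @param refs reference residue keys; each must be present with positive
#'   intensity in both tables.
#' @param noise_floor a residue whose deuterated peak is absent/zero is coded
#'   ratio 0 (fully exchanged) only when its normalised protonated intensity
#'   exceeds this floor; otherwise it is excluded as insufficient sensitivity.
#' @return An `exchange_profile` data frame with columns `residue`, `ratio`,
#'   `attenuation_percent` and `class` (NA until [classify_protection()] is
#'   applied); attributes `reference_residues`, `excluded`.
#' @export
normalize_and_ratio <- function(protonated, deuterated,
                                refs = c("S69", "V70"), noise_floor = 0.05) {
  for (tab in list(protonated = protonated, deuterated = deuterated)) {
    miss <- setdiff(refs, tab$residue)
    if (length(miss))
      stop("reference residue(s) missing from ", attr(tab, "condition"),
           " table: ", paste(miss, collapse = ", "))
    iv <- tab$intensity[match(refs, tab$residue)]
    if (any(iv <= 0))
      stop("reference residue(s) with non-positive intensity: ",
           paste(refs[iv <= 0], collapse = ", "))
  }
  pn <- protonated$intensity /
    mean(protonated$intensity[match(refs, protonated$residue)])
  dn <- deuterated$intensity /
    mean(deuterated$intensity[match(refs, deuterated$residue)])
  names(pn) <- protonated$residue
  names(dn) <- deuterated$residue
  shared <- intersect(protonated$residue, deuterated$residue)
  excluded <- setdiff(union(protonated$residue, deuterated$residue), shared)
  res <- character(); ratio <- numeric()
  for (r in shared) {
    if (pn[[r]] == 0) { excluded <- c(excluded, r); next }
    if (dn[[r]] == 0 && pn[[r]] <= noise_floor) {
      excluded <- c(excluded, r); next  # below sensitivity, not exchange
    }
    res <- c(res, r)
    ratio <- c(ratio, dn[[r]] / pn[[r]])
  }
  out <- data.frame(residue = res, ratio = ratio,
                    attenuation_percent = 100 * (ratio - 1),
                    class = NA_character_, stringsAsFactors = FALSE)
  attr(out, "reference_residues") <- refs
  attr(out, "excluded") <- excluded
  class(out) <- c("exchange_profile", "data.frame")
  out
}

#' Classify H/D-exchange protection from intensity ratios
#'
#' Half-open bins on the deuterated/protonated ratio:
#' ratio < `t_low` is `exchanged`, `t_low` <= ratio < `t_high` is
#' `attenuated`, ratio >= `t_high` is `protected`. The defaults (0.15, 0.85)
#' separate completely disappeared peaks, partially attenuated peaks and
#' peaks showing no sign of exchange.
#'
#' @param profile an `exchange_profile` from [normalize_and_ratio()].
#' @param t_low,t_high thresholds with 0 <= t_low < t_high <= 1.
#' @return the profile with its `class` column filled (ordered factor
#'   exchanged < attenuated < protected) and attribute `thresholds`.
#' @export
classify_protection <- function(profile, t_low = 0.15, t_high = 0.85) {
  if (!(t_low >= 0 && t_low < t_high && t_high <= 1))
    stop("need 0 <= t_low < t_high <= 1, got (", t_low, ", ", t_high, ")")
  cls <- ifelse(profile$ratio < t_low, "exchanged",
                ifelse(profile$ratio < t_high, "attenuated", "protected"))
  profile$class <- factor(cls, levels = c("exchanged", "attenuated",
                                          "protected"), ordered = TRUE)
  attr(profile, "thresholds") <- c(t_low = t_low, t_high = t_high)
  profile
}

#' @export
print.exchange_profile <- function(x, ...) {
  cat("<exchange_profile>", nrow(x), "residues, refs:",
      paste(attr(x, "reference_residues"), collapse = ", "), "\n")
  print.data.frame(as.data.frame(x))
  ex <- attr(x, "excluded")
  if (length(ex)) cat("excluded:", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Water-cavity summary across channel variants
#'
#' Tabulates the protection class of the residues lining the buried-water
#' cavity behind the filter, side by side for each variant, and an ordinal
#' "cavity extent": the number of residues of interest that are not
#' protected. A variant whose cavity residues are all protected has extent 0
#' (no accessible cavity); a widened cavity raises the extent.
#'
#' @param profiles named list of classified `exchange_profile` objects, one
#'   per variant.
#' @param residues residue keys lining the cavity.
#' @return data frame: one row per variant, one column per residue of
#'   interest (class or NA when unobserved), plus `cavity_extent`.
#' @export
cavity_summary <- function(profiles,
                           residues = c("G77", "Y78", "G79", "L81")) {
  stopifnot(length(names(profiles)) == length(profiles))
  rows <- lapply(names(profiles), function(v) {
    p <- profiles[[v]]
    if (all(is.na(p$class)))
      stop("profile '", v, "' is unclassified; run classify_protection()")
    cls <- as.character(p$class[match(residues, p$residue)])
    extent <- sum(cls != "protected", na.rm = TRUE)
    out <- c(list(variant = v), stats::setNames(as.list(cls), residues),
             list(cavity_extent = extent))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
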