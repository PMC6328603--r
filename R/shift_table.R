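#' Construct a chemical-shift table
#'
#' A `shift_table` holds assigned chemical shifts for one channel variant,
#' keyed by residue number and atom name. Side-chain NH pairs (e.g. the
#' tryptophan indole Ne1/He1) live as ordinary rows with their own atom names;
#' they are never merged with the backbone amide.
#'
#' @param resno integer residue numbers (1-based, crystal-structure numbering
#'   convention of the channel: filter = T75-G79, triad = W67/E71/D80).
#' @param resname three-letter residue codes.
#' @param atom atom names (e.g. `"H"`, `"N"`, `"C"`, `"CA"`, `"NE1"`).
#' @param shift chemical shifts in ppm; must be finite.
#' @param variant_id text label for the variant (e.g. `"WT"`, `"E71A"`).
#' @return A data frame of class `shift_table` with columns `resno`,
#'   `resname`, `atom`, `shift` and attribute `variant_id`.
#' @examples
#' shift_table(76, "VAL", "C", 178.1, variant_id = "WT")
#' @export
shift_table <- function(resno, resname, atom, shift, variant_id = "unknown") {
  resno <- as.integer(resno)
  shift <- as.numeric(shift)
  if (any(is.na(resno)) || any(resno < 1L))
    stop("residue numbers must be integers >= 1")
  if (any(!is.finite(shift)))
    stop("chemical shifts must be finite")
  key <- paste(resno, atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (residue, atom) key: ", dup)
  }
  out <- data.frame(resno = resno, resname = as.character(resname),
                    atom = as.character(atom), shift = shift,
                    stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$atom), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variant_id") <- variant_id
  class(out) <- c("shift_table", "data.frame")
  out
}

#' @export
print.shift_table <- function(x, ...) {
  cat("<shift_table> variant:", attr(x, "variant_id"),
      "-", nrow(x), "assigned shifts,",
      length(unique(x$resno)), "residues\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

# shift lookup; NA when absent
shift_at <- function(tab, resno, atom) {
  i <- which(tab$resno == resno & tab$atom == atom)
  if (length(i) == 0L) NA_real_ else tab$shift[i]
}
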