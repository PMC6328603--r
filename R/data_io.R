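#' Read a chemical-shift table from NMR-STAR v3 or TSV
#'
#' The NMR-STAR reader targets the v3 assigned-chemical-shift loop
#' (`_Atom_chem_shift.*` tags) used by BMRB depositions; all other loops and
#' save frames are ignored. The TSV dialect is tab-separated, UTF-8, with one
#' header row (`resno`, `resname`, `atom`, `shift`) and `#`-prefixed comments.
#' Rows with an unparseable residue number, atom name or shift value are
#' skipped and counted in the `skipped` attribute, never silently dropped.
#'
#' @param path file to read.
#' @param format `"nmrstar"` or `"tsv"`.
#' @param variant_id label for the variant; defaults to the file name stem.
#' @return A [shift_table] with attribute `skipped` (number of rows skipped).
#' @export
read_shift_table <- function(path, format = c("nmrstar", "tsv"),
                             variant_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(variant_id))
    variant_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("resno", "resname", "atom", "shift")
    if (!all(need %in% names(df)))
      stop("TSV shift table needs columns: ", paste(need, collapse = ", "))
    ok <- !is.na(suppressWarnings(as.integer(df$resno))) &
      !is.na(suppressWarnings(as.numeric(df$shift))) & nzchar(df$atom)
    skipped <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    if (nrow(df) == 0L) stop("no parseable chemical-shift rows in ", path)
    out <- shift_table(df$resno, df$resname, df$atom, df$shift, variant_id)
  } else {
    rows <- parse_nmrstar_shift_loop(path)
    skipped <- attr(rows, "skipped")
    if (nrow(rows) == 0L)
      stop("no parseable assigned-chemical-shift rows in ", path,
           " (first offending line: ", attr(rows, "first_bad"), ")")
    out <- shift_table(rows$resno, rows$resname, rows$atom, rows$shift,
                       variant_id)
  }
  attr(out, "skipped") <- skipped
  out
}

# Minimal NMR-STAR v3 reader for the assigned-chemical-shift loop.
# Collects loop_ blocks whose tags start with _Atom_chem_shift. and extracts
# residue number (Seq_ID, falling back to Comp_index_ID / Auth_seq_ID),
# residue name (Comp_ID), atom name (Atom_ID) and value (Val).
parse_nmrstar_shift_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  skipped <- 0L
  first_bad <- NA_character_
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(tags) > 0L && all(startsWith(tags, "_Atom_chem_shift."))) {
        cols <- sub("^_Atom_chem_shift\\.", "", tags)
        seq_col <- intersect(c("Seq_ID", "Comp_index_ID", "Auth_seq_ID"), cols)[1]
        comp_col <- intersect(c("Comp_ID", "Auth_comp_ID"), cols)[1]
        atom_col <- intersect(c("Atom_ID", "Auth_atom_ID"), cols)[1]
        val_col <- if ("Val" %in% cols) "Val" else NA
        while (j <= n && !grepl("^\\s*stop_", lines[j])) {
          row <- trimws(lines[j])
          j <- j + 1L
          if (!nzchar(row) || startsWith(row, "#")) next
          f <- strsplit(row, "\\s+")[[1]]
          if (is.na(seq_col) || is.na(comp_col) || is.na(atom_col) ||
              is.na(val_col) || length(f) != length(cols)) {
            skipped <- skipped + 1L
            if (is.na(first_bad)) first_bad <- row
            next
          }
          resno <- suppressWarnings(as.integer(f[match(seq_col, cols)]))
          val <- suppressWarnings(as.numeric(f[match(val_col, cols)]))
          atom <- f[match(atom_col, cols)]
          if (is.na(resno) || is.na(val) || atom %in% c(".", "?")) {
            skipped <- skipped + 1L
            if (is.na(first_bad)) first_bad <- row
            next
          }
          out[[length(out) + 1L]] <- data.frame(
            resno = resno, resname = f[match(comp_col, cols)],
            atom = atom, shift = val, stringsAsFactors = FALSE)
        }
      }
    }
    i <- i + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(resno = integer(), resname = character(),
               atom = character(), shift = numeric())
  attr(res, "skipped") <- skipped
  attr(res, "first_bad") <- first_bad
  res
}

#' Read a relaxation decay series from TSV
#'
#' Expects a `residue` column followed by one column per relaxation delay,
#' with the delay values as column names (e.g. `0  5  10  20  40  80`).
#' Delays must be strictly increasing with the first delay >= 0. Residues
#' with a missing intensity are kept and flagged, never silently dropped.
#'
#' @param path TSV file.
#' @param experiment `"R1rho"` or `"T1"`.
#' @param delay_unit time unit of the delay columns (echoed in outputs).
#' @return A `decay_series_set`: list with `experiment`, `delays`,
#'   `delay_unit`, `intensities` (matrix, residues x delays) and `flagged`
#'   (residues with missing values).
#' @export
read_decay_series <- function(path, experiment = c("R1rho", "T1"),
                              delay_unit = "ms") {
  experiment <- match.arg(experiment)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "residue")
    stop("decay series TSV must start with a 'residue' column")
  delays <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(delays)))
    stop("delay columns must have numeric names, got: ",
         paste(names(df)[-1][is.na(delays)], collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$residue
  decay_series_set(delays, m, experiment = experiment,
                   delay_unit = delay_unit)
}

#' Construct a decay-series set
#'
#' @param delays numeric delay times, strictly increasing, first >= 0.
#' @param intensities matrix (residues x delays) with residue row names.
#' @param experiment `"R1rho"` or `"T1"`.
#' @param delay_unit time unit label.
#' @return object of class `decay_series_set`.
#' @export
decay_series_set <- function(delays, intensities,
                             experiment = c("R1rho", "T1"),
                             delay_unit = "ms") {
  experiment <- match.arg(experiment)
  delays <- as.numeric(delays)
  if (delays[1] < 0) stop("first delay must be >= 0")
  if (any(diff(delays) <= 0))
    stop("delays must be strictly increasing, got: ",
         paste(delays, collapse = ", "))
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(delays))
    stop("intensity columns (", ncol(intensities),
         ") must match number of delays (", length(delays), ")")
  flagged <- rownames(intensities)[apply(intensities, 1L, anyNA)]
  structure(list(experiment = experiment, delays = delays,
                 delay_unit = delay_unit, intensities = intensities,
                 flagged = flagged),
            class = "decay_series_set")
}

#' @export
print.decay_series_set <- function(x, ...) {
  cat("<decay_series_set>", x$experiment, "-", nrow(x$intensities),
      "residues,", length(x$delays), "delays (", x$delay_unit, "):",
      paste(x$delays, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("flagged (missing intensities):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Read a peak-intensity table from TSV
#'
#' Two columns: `residue` (character key, e.g. `"Y78"`) and `intensity`
#' (arbitrary units, >= 0).
#'
#' @param path TSV file.
#' @param condition `"protonated"` or `"deuterated"` buffer.
#' @return An `intensity_table` data frame with attribute `condition`.
#' @export
read_intensity_table <- function(path,
                                 condition = c("protonated", "deuterated")) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("cannot read file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  intensity_table(df$residue, df$intensity, condition)
}

#' Construct a peak-intensity table
#'
#' @param residue character residue keys.
#' @param intensity peak intensities, >= 0.
#' @param condition `"protonated"` or `"deuterated"`.
#' @return An `intensity_table` data frame.
#' @export
intensity_table <- function(residue, intensity,
                            condition = c("protonated", "deuterated")) {
  condition <- match.arg(condition)
  intensity <- as.numeric(intensity)
  if (any(is.na(intensity)) || any(intensity < 0))
    stop("intensities must be >= 0")
  if (anyDuplicated(residue))
    stop("duplicate residue keys: ",
         paste(unique(residue[duplicated(residue)]), collapse = ", "))
  out <- data.frame(residue = as.character(residue), intensity = intensity,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  class(out) <- c("intensity_table", "data.frame")
  out
}

#' Write an analysis profile to TSV
#'
#' Writes any of the pipeline's tabular outputs (CSP profiles, rate profiles,
#' exchange profiles, population tables, ...) as tab-separated text with a
#' stable column order and a `#`-comment provenance header. Numeric columns
#' round-trip to at least 6 decimals through [read_profile()].
#'
#' @param profile data frame (possibly classed).
#' @param path output file.
#' @param comments optional character vector written as `#` header lines.
#' @export
write_profile <- function(profile, path, comments = NULL) {
  df <- as.data.frame(profile)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV profile written by [write_profile()]
#' @param path TSV file.
#' @return data frame.
#' @export
read_profile <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
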