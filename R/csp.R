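#' Per-nucleus chemical-shift perturbation profile
#'
#' CSP(res) = delta_query(res, atom) - delta_ref(res, atom), i.e. the
#' mutant-minus-WT sign convention when the reference is the wild type.
#' Residues absent from either table are absent from the profile, never
#' zero-filled.
#'
#' @param ref reference [shift_table()] (e.g. WT).
#' @param query query [shift_table()] (e.g. a mutant).
#' @param atom nucleus to compare (e.g. `"C"` for the backbone carbonyl
#'   carbon, `"CA"`, `"N"`, `"H"`).
#' @return A `csp_profile` data frame with columns `resno`, `value` (signed
#'   ppm) and attributes `reference_id`, `query_id`, `kind = "per_nucleus"`,
#'   `atom`.
#' @examples
#' wt <- shift_table(c(76, 78), c("VAL", "TYR"), c("C", "C"), c(177.0, 175.0), "WT")
#' mu <- shift_table(c(76, 78), c("VAL", "TYR"), c("C", "C"), c(178.1, 175.0), "M")
#' per_nucleus_csp(wt, mu, "C")
#' @export
per_nucleus_csp <- function(ref, query, atom) {
  r <- ref[ref$atom == atom, c("resno", "shift")]
  q <- query[query$atom == atom, c("resno", "shift")]
  shared <- intersect(r$resno, q$resno)
  if (length(shared) == 0L)
    stop("no shared residues carry atom '", atom, "' in both tables")
  shared <- sort(shared)
  value <- q$shift[match(shared, q$resno)] - r$shift[match(shared, r$resno)]
  csp_profile(shared, value, reference_id = attr(ref, "variant_id"),
              query_id = attr(query, "variant_id"),
              kind = "per_nucleus", atom = atom)
}

#' Combined amide (HN) chemical-shift perturbation profile
#'
#' Combined CSP(res) = sqrt(ddH^2 + (alpha * ddN)^2), the standard weighted
#' merge of amide-proton and nitrogen perturbations. Residues missing either
#' nucleus in either table are excluded and listed in the `excluded`
#' attribute. Side-chain NH pairs (e.g. the tryptophan indole, Ne1/He1) are
#' reported as separate keys of the form `"<resno>:NE1"`.
#'
#' @param ref,query [shift_table()] objects holding `H` and `N` entries.
#' @param alpha nitrogen weighting, > 0. Default 0.14, the usual amide-CSP
#'   scaling; configurable because conventions differ between groups.
#' @param sidechain_pairs named list of side-chain N/H atom-name pairs to
#'   report as extra keys.
#' @return A `csp_profile` data frame with columns `key`, `resno`, `value`
#'   (unsigned ppm).
#' @export
combined_hn_csp <- function(ref, query, alpha = 0.14,
                            sidechain_pairs = list(NE1 = c("NE1", "HE1"))) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single value > 0")
  pairs <- c(list(backbone = c("N", "H")), sidechain_pairs)
  keys <- character(); resnos <- integer(); values <- numeric()
  excluded <- character()
  all_res <- sort(union(unique(ref$resno), unique(query$resno)))
  for (res in all_res) {
    for (pn in names(pairs)) {
      natom <- pairs[[pn]][1]; hatom <- pairs[[pn]][2]
      # only consider a pair that exists somewhere for this residue
      present <- any(ref$resno == res & ref$atom %in% pairs[[pn]]) ||
        any(query$resno == res & query$atom %in% pairs[[pn]])
      if (!present) next
      dn <- shift_at(query, res, natom) - shift_at(ref, res, natom)
      dh <- shift_at(query, res, hatom) - shift_at(ref, res, hatom)
      key <- if (pn == "backbone") as.character(res) else
        paste0(res, ":", natom)
      if (is.na(dn) || is.na(dh)) {
        excluded <- c(excluded, key)
        next
      }
      keys <- c(keys, key); resnos <- c(resnos, res)
      values <- c(values, sqrt(dh^2 + (alpha * dn)^2))
    }
  }
  if (length(values) == 0L)
    stop("no residue carries a complete N/H pair in both tables")
  out <- data.frame(key = keys, resno = resnos, value = values,
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- attr(ref, "variant_id")
  attr(out, "query_id") <- attr(query, "variant_id")
  attr(out, "kind") <- "combined_HN"
  attr(out, "alpha") <- alpha
  attr(out, "excluded") <- excluded
  class(out) <- c("csp_profile", "data.frame")
  out
}

# internal constructor for per-nucleus profiles
csp_profile <- function(resno, value, reference_id, query_id, kind, atom) {
  out <- data.frame(resno = as.integer(resno), value = as.numeric(value))
  attr(out, "reference_id") <- reference_id
  attr(out, "query_id") <- query_id
  attr(out, "kind") <- kind
  attr(out, "atom") <- atom
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' @export
print.csp_profile <- function(x, ...) {
  cat("<csp_profile>", attr(x, "kind"),
      if (attr(x, "kind") == "per_nucleus") paste0("(", attr(x, "atom"), ")"),
      ":", attr(x, "query_id"), "vs", attr(x, "reference_id"),
      "-", nrow(x), "residues\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Rank residues by CSP magnitude
#'
#' @param profile a `csp_profile`.
#' @param k number of residues to return; `k` larger than the profile returns
#'   the full ordering.
#' @return data frame of the top-`k` rows ordered by decreasing `|value|`,
#'   ties broken by ascending residue number.
#' @export
rank_csp <- function(profile, k = nrow(profile)) {
  if (nrow(profile) == 0L) stop("empty CSP profile")
  ord <- order(-abs(profile$value), profile$resno)
  out <- as.data.frame(profile)[ord[seq_len(min(k, nrow(profile)))], ,
                                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a CSP profile as a residue bar chart
#' @param x a `csp_profile`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.csp_profile <- function(x, ...) {
  graphics::barplot(x$value, names.arg = x$resno,
                    ylab = paste0("CSP (ppm), ", attr(x, "kind")),
                    xlab = "residue",
                    main = paste(attr(x, "query_id"), "vs",
                                 attr(x, "reference_id")), ...)
  invisible(x)
}
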