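#' Fit a mono-exponential relaxation decay
#'
#' Least-squares fit of I(t) = I0 * exp(-R * t) to one residue's decay
#' series, with the rate bounded at R >= 0. Initialisation is deterministic:
#' I0 starts at the first intensity and R at the slope of a log-linear
#' regression over the positive intensities, so identical inputs always give
#' identical fits. The standard error of the rate comes from the fit's
#' covariance matrix by default; a residual-resampling Monte-Carlo error is
#' available behind `se_method = "montecarlo"`.
#'
#' @param delays relaxation delays (any consistent time unit).
#' @param intensities signal intensities aligned with `delays`.
#' @param se_method `"covariance"` (default) or `"montecarlo"`.
#' @param n_boot Monte-Carlo replicates when `se_method = "montecarlo"`.
#' @return object of class `rate_fit`: list with `rate`, `I0`, `rate_se`,
#'   `n_points`, `residual_ss`, `converged`, `flag` (NA when clean). The rate
#'   is in reciprocal units of the delays; no unit conversion is attempted.
#' @examples
#' t <- c(0, 5, 10, 20, 40, 80)
#' fit_monoexponential(t, exp(-0.05 * t))
#' @export
fit_monoexponential <- function(delays, intensities,
                                se_method = c("covariance", "montecarlo"),
                                n_boot = 200L) {
  se_method <- match.arg(se_method)
  ok <- !is.na(intensities)
  t <- as.numeric(delays)[ok]
  y <- as.numeric(intensities)[ok]
  if (length(t) < 2L) stop("need at least 2 data points")
  if (all(y == 0)) stop("degenerate input: all intensities are zero")
  n <- length(t)
  # constant series: exact R = 0 solution, zero residual
  if (max(y) - min(y) == 0) {
    return(rate_fit(rate = 0, I0 = y[1], rate_se = 0, n_points = n,
                    residual_ss = 0, converged = TRUE))
  }
  i0_start <- if (y[1] != 0) y[1] else max(y)
  pos <- y > 0
  r_start <- 0
  if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2L]
    if (is.finite(sl)) r_start <- max(0, -sl)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ I0 * exp(-R * t),
      start = list(I0 = i0_start, R = r_start),
      lower = c(I0 = -Inf, R = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(rate_fit(rate = NA_real_, I0 = NA_real_, rate_se = NA_real_,
                    n_points = n, residual_ss = NA_real_, converged = FALSE,
                    flag = paste("non-convergence:", conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  se <- NA_real_
  if (n >= 3L) {
    if (se_method == "covariance") {
      se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["R"]],
                     error = function(e) NA_real_)
      # zero-residual fits have an exactly singular covariance scale
      if (is.na(se) && rss < 1e-20) se <- 0
    } else {
      res <- stats::residuals(fit)
      fitted <- stats::fitted(fit)
      boots <- vapply(seq_len(n_boot), function(b) {
        yb <- fitted + sample(res, n, replace = TRUE)
        fb <- tryCatch(minpack.lm::nlsLM(
          yb ~ I0 * exp(-R * t), start = as.list(cf),
          lower = c(I0 = -Inf, R = 0)), error = function(e) NULL)
        if (is.null(fb)) NA_real_ else stats::coef(fb)[["R"]]
      }, numeric(1))
      se <- stats::sd(boots, na.rm = TRUE)
    }
  }
  rate_fit(rate = cf[["R"]], I0 = cf[["I0"]], rate_se = se, n_points = n,
           residual_ss = rss, converged = TRUE)
}

rate_fit <- function(rate, I0, rate_se, n_points, residual_ss, converged,
                     flag = NA_character_) {
  structure(list(rate = rate, I0 = I0, rate_se = rate_se,
                 n_points = n_points, residual_ss = residual_ss,
                 converged = converged, flag = flag),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> R = %.6g +/- %.3g (n = %d, RSS = %.3g)%s\n",
              x$rate, x$rate_se, x$n_points, x$residual_ss,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) c(I0 = object$I0, R = object$rate)

#' Fit relaxation rates for every residue of a decay-series set
#'
#' One mono-exponential fit per residue. Residues whose fit fails (all-zero
#' series, non-convergence) are excluded from the profile and recorded with
#' the reason in the `failures` attribute.
#'
#' @param set a `decay_series_set` (see [read_decay_series()]).
#' @param ... passed to [fit_monoexponential()].
#' @return A `rate_profile` data frame with columns `residue`, `rate`, `se`,
#'   `I0`, `n`, `flag`, plus attributes `experiment` and `delay_unit` (rates
#'   are in the reciprocal of this unit).
#' @export
fit_rate_profile <- function(set, ...) {
  stopifnot(inherits(set, "decay_series_set"))
  residues <- rownames(set$intensities)
  rows <- list(); failures <- character()
  for (r in residues) {
    f <- tryCatch(fit_monoexponential(set$delays, set$intensities[r, ], ...),
                  error = function(e) e)
    if (inherits(f, "error") || !f$converged) {
      failures[r] <- if (inherits(f, "error")) conditionMessage(f) else f$flag
      next
    }
    rows[[r]] <- data.frame(residue = r, rate = f$rate, se = f$rate_se,
                            I0 = f$I0, n = f$n_points, flag = f$flag,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(), rate = numeric(), se = numeric(),
               I0 = numeric(), n = integer(), flag = character())
  rownames(out) <- NULL
  attr(out, "experiment") <- set$experiment
  attr(out, "delay_unit") <- set$delay_unit
  attr(out, "failures") <- failures
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' @export
print.rate_profile <- function(x, ...) {
  cat("<rate_profile>", attr(x, "experiment"), "-", nrow(x),
      "residues, rates per", attr(x, "delay_unit"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  fl <- attr(x, "failures")
  if (length(fl))
    cat("failed fits:", paste(names(fl), collapse = ", "), "\n")
  invisible(x)
}

#' Difference of two rate profiles (query minus reference)
#'
#' Per-residue rate differences over the shared residues, with standard
#' errors propagated as sqrt(se_q^2 + se_r^2). Used for mutant-vs-WT
#' dynamics difference plots.
#'
#' @param query,ref `rate_profile` objects from the same experiment type and
#'   delay unit.
#' @return A `rate_difference` data frame with columns `residue`, `delta`,
#'   `se`.
#' @export
rate_difference <- function(query, ref) {
  if (!identical(attr(query, "experiment"), attr(ref, "experiment")))
    stop("experiment mismatch: ", attr(query, "experiment"), " vs ",
         attr(ref, "experiment"))
  if (!identical(attr(query, "delay_unit"), attr(ref, "delay_unit")))
    stop("delay-unit mismatch: ", attr(query, "delay_unit"), " vs ",
         attr(ref, "delay_unit"))
  shared <- intersect(query$residue, ref$residue)
  if (length(shared) == 0L) {
    warning("no shared residues between the two profiles")
  }
  qi <- match(shared, query$residue); ri <- match(shared, ref$residue)
  out <- data.frame(residue = shared,
                    delta = query$rate[qi] - ref$rate[ri],
                    se = sqrt(query$se[qi]^2 + ref$se[ri]^2),
                    stringsAsFactors = FALSE)
  attr(out, "experiment") <- attr(query, "experiment")
  attr(out, "delay_unit") <- attr(query, "delay_unit")
  class(out) <- c("rate_difference", "data.frame")
  out
}

#' Fit a longitudinal (T1) relaxation profile
#'
#' Same contract as [fit_rate_profile()] with experiment `T1`; additionally
#' reports the relaxation time T1 = 1/R. Residues whose fitted rate is
#' (numerically) zero have an unbounded T1 and are flagged rather than given
#' a fabricated value.
#'
#' @param set a `decay_series_set` with `experiment = "T1"`.
#' @param rate_floor rates below this are treated as zero (unbounded T1).
#' @param ... passed to [fit_monoexponential()].
#' @return A `rate_profile` with an extra `t1` column.
#' @export
fit_t1_profile <- function(set, rate_floor = 1e-12, ...) {
  if (set$experiment != "T1")
    stop("decay-series set is not a T1 experiment")
  prof <- fit_rate_profile(set, ...)
  prof$t1 <- ifelse(prof$rate > rate_floor, 1 / prof$rate, NA_real_)
  prof$flag[prof$rate <= rate_floor] <- "unbounded T1 (rate ~ 0)"
  prof
}
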