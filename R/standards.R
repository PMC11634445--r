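#' Fit an immunoassay standard curve
#'
#' Fits the four-parameter logistic (4PL) model conventional for sandwich
#' ELISA standards,
#' \deqn{OD(c) = d + \frac{a - d}{1 + (c / c_{50})^{b}},}
#' with `a` the zero-dose response, `d` the upper asymptote, `c50` the
#' mid-point concentration and `b` the slope. Fitting uses
#' Levenberg-Marquardt least squares; if the 4PL fit fails to converge the
#' function falls back to monotone log-linear interpolation of the standard
#' points.
#'
#' @param conc Standard concentrations (e.g. mg/mL); at least 4 distinct
#'   positive values.
#' @param od Observed ODs at those concentrations (replicates allowed:
#'   `conc` may repeat).
#' @return An object of class `standard_curve` with `coef()` and
#'   [quantify()] support.
#' @examples
#' conc <- c(0.125, 0.25, 0.5, 1, 2, 4)
#' od <- 3 / (1 + (0.8 / conc)^1.3) + 0.05
#' sc <- fit_standard_curve(conc, od)
#' quantify(sc, predict(sc, 1.6))$concentration  # ~1.6
#' @export
fit_standard_curve <- function(conc, od) {
  stopifnot(is.numeric(conc), is.numeric(od), base::length(conc) == base::length(od))
  if (base::length(unique(conc)) < 4L)
    pep_stop("need at least 4 distinct standard concentrations", "bad_standards")
  if (any(conc <= 0)) pep_stop("standard concentrations must be positive",
                               "bad_standards")
  mu <- tapply(od, conc, mean)
  cs <- as.numeric(names(mu))
  o <- order(cs); cs <- cs[o]; mu <- as.numeric(mu)[o]
  # monotone up to noise: local inversions larger than 5% of the dynamic
  # range indicate genuinely non-monotone standards, not plate noise
  if (any(-diff(mu) > 0.05 * diff(range(mu))))
    pep_stop("standard ODs are not monotone increasing with concentration",
             "bad_standards")
  dat <- data.frame(conc = conc, od = od)
  start <- list(a = max(min(od) * 0.9, 1e-4), d = max(od) * 1.05,
                c50 = stats::median(cs), b = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(od ~ d + (a - d) / (1 + (conc / c50)^b),
                      data = dat, start = start,
                      lower = c(a = 0, d = 0, c50 = 1e-8, b = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (cf[["d"]] <= cf[["a"]]) fit <- NULL  # degenerate: not increasing
  }
  # isotonised means back the log-linear fallback (and keep its inversion
  # well defined when plate noise causes a local tie or dip)
  iso <- stats::isoreg(seq_along(mu), mu)$yf + seq_along(mu) * 1e-9
  structure(list(fit = fit,
                 coef = if (!is.null(fit)) stats::coef(fit) else NULL,
                 method = if (is.null(fit)) "loglinear" else "4pl",
                 standards = data.frame(conc = cs, od = mu, od_iso = iso),
                 range = range(cs)),
            class = "standard_curve")
}

#' @export
coef.standard_curve <- function(object, ...) object$coef

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s fit over %g-%g\n", x$method,
              x$range[1], x$range[2]))
  if (!is.null(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' @export
#' @rdname fit_standard_curve
#' @param object A `standard_curve`.
#' @param newconc Concentrations at which to evaluate the fitted curve.
#' @param ... Unused.
predict.standard_curve <- function(object, newconc, ...) {
  if (object$method == "4pl") {
    cf <- as.list(object$coef)
    cf$d + (cf$a - cf$d) / (1 + (newconc / cf$c50)^cf$b)
  } else {
    s <- object$standards
    stats::approx(log(s$conc), s$od_iso, xout = log(newconc), rule = 2)$y
  }
}

#' Concentration from OD via an inverted standard curve
#'
#' Inverts the fitted curve. ODs at or beyond the asymptotes are flagged
#' (`above_range` / `below_range`) and return `NA`; quantifiable ODs whose
#' concentration falls outside the standard range are flagged
#' `extrapolated` but still returned.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param od Numeric vector of blank-corrected ODs.
#' @return `data.frame` with `od`, `concentration`, `flag`
#'   (`ok`, `extrapolated`, `above_range`, `below_range`).
#' @export
quantify <- function(curve, od) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- rep(NA_real_, base::length(od))
  flag <- rep("ok", base::length(od))
  if (curve$method == "4pl") {
    cf <- as.list(curve$coef)
    hi <- od >= cf$d; lo <- od <= cf$a
    mid <- !hi & !lo
    # od = d + (a-d)/(1+(x/c50)^b)  =>  x = c50 * ((a-od)/(od-d))^(1/b)
    conc[mid] <- cf$c50 * ((cf$a - od[mid]) / (od[mid] - cf$d))^(1 / cf$b)
    flag[hi] <- "above_range"; flag[lo] <- "below_range"
  } else {
    s <- curve$standards
    hi <- od >= max(s$od_iso); lo <- od <= min(s$od_iso)
    mid <- !hi & !lo
    conc[mid] <- exp(stats::approx(s$od_iso, log(s$conc), xout = od[mid])$y)
    flag[hi] <- "above_range"; flag[lo] <- "below_range"
  }
  ex <- !is.na(conc) & (conc < curve$range[1] | conc > curve$range[2])
  flag[ex] <- "extrapolated"
  data.frame(od = od, concentration = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Total immunoglobulin quantification with reference ranges
#'
#' Quantifies per-patient immunoglobulin concentrations from an ELISA plate
#' set containing standards, then flags whether each value lies in the
#' healthy reference range (IgA 1.1-2.6 mg/mL, IgM 0.23-1.4 mg/mL in
#' citrate plasma).
#'
#' @param wells Raw well measurements with `role = "standard"` wells
#'   carrying `standard_conc` and `role = "sample"` wells carrying
#'   `patient_id` and `analyte` equal to the immunoglobulin class.
#' @param ig_class `"IgM"` or `"IgA"`.
#' @param tolerance Duplicate-spread tolerance.
#' @return `data.frame`: `patient_id`, `ig_class`, `concentration`, `flag`,
#'   `in_reference_range`.
#' @export
quantify_ig <- function(wells, ig_class = c("IgM", "IgA"), tolerance = 0.2) {
  ig_class <- match.arg(ig_class)
  ref <- switch(ig_class, IgA = c(1.1, 2.6), IgM = c(0.23, 1.4))
  avg <- average_duplicates(subtract_blanks(wells), tolerance = tolerance)
  avg <- avg[avg$analyte %in% ig_class, , drop = FALSE]
  std <- avg[avg$role == "standard", , drop = FALSE]
  smp <- avg[avg$role == "sample", , drop = FALSE]
  if (!nrow(std)) pep_stop("no standard wells for this analyte", "bad_standards")
  curve <- fit_standard_curve(std$standard_conc, std$mean_od)
  q <- quantify(curve, smp$mean_od)
  data.frame(patient_id = smp$patient_id, ig_class = ig_class,
             concentration = q$concentration, flag = q$flag,
             in_reference_range = !is.na(q$concentration) &
               q$concentration >= ref[1] & q$concentration <= ref[2],
             stringsAsFactors = FALSE)
}
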