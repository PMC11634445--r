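#' Residual ADAMTS13 activity of a mixing study
#'
#' Residual activity (RA) of a 1:1 mix of heat-inactivated patient plasma
#' and pooled normal plasma, expressed relative to the pooled-normal-plasma
#' control: `RA = 100 * mix_activity / pnp_activity`. RA between 25% and
#' 75% (inclusive) is the quantifiable inhibitor band; above 75% there is
#' no clinically significant inhibitor.
#'
#' @param mix_activity Activity of the mix, % of normal.
#' @param pnp_activity Activity of the pooled-normal-plasma control, %.
#' @return Residual activity in percent.
#' @examples
#' residual_activity(50, 100)  # 50
#' @export
residual_activity <- function(mix_activity, pnp_activity) {
  if (any(pnp_activity <= 0))
    pep_stop("pooled-normal-plasma control activity must be positive",
             "invalid_control")
  100 * mix_activity / pnp_activity
}

#' Bethesda units from residual activity
#'
#' One Bethesda unit (BU) is the amount of inhibitor that halves ADAMTS13
#' activity in pooled normal plasma, giving the classical relation
#' `RA = 100 * 2^(-BU)`, i.e. `BU = log2(100 / RA)`. `bu_from_residual(50)`
#' is exactly 1; `residual_from_bu()` is its inverse.
#'
#' @param ra Residual activity in percent, in `(0, 100]`.
#' @return Bethesda units at the tested dilution.
#' @examples
#' bu_from_residual(c(100, 50, 25))  # 0 1 2
#' @export
bu_from_residual <- function(ra) {
  if (any(ra <= 0))
    pep_stop("residual activity must be positive to quantify a titre",
             "no_residual_activity")
  log2(100 / ra)
}

#' @rdname bu_from_residual
#' @param bu Bethesda units.
#' @export
residual_from_bu <- function(bu) 100 * 2^(-bu)

#' Inhibitor classification from Bethesda titre
#'
#' Three-tier classification: `non_inhibitory` below 0.5 BU/mL, `low`
#' from 0.5 through 5 BU/mL, `strong` above 5 BU/mL. The boundaries
#' partition `[0, Inf)` with 5 BU assigned to `low`.
#'
#' @param bu_per_ml Non-negative Bethesda titre(s), BU/mL.
#' @return Character vector of classes.
#' @examples
#' classify_inhibitor(c(0.3, 1.85, 9.74))
#' @export
classify_inhibitor <- function(bu_per_ml) {
  stopifnot(all(bu_per_ml >= 0))
  ifelse(bu_per_ml < 0.5, "non_inhibitory",
         ifelse(bu_per_ml <= 5, "low", "strong"))
}

#' Bethesda titre from a dilution series
#'
#' Implements the modified Bethesda titration over a saline dilution ladder
#' of heat-inactivated patient plasma. Each dilution's residual activity is
#' computed against its pooled-normal-plasma control; the reported titre
#' comes from the dilution whose RA lies in the quantifiable 25%-75% band
#' (inclusive) and is closest to 50% (ties go to the lower dilution):
#' `BU/mL = log2(100 / RA) * dilution`. If every dilution reads above 75%
#' there is no significant inhibitor (0 BU/mL); if every dilution reads
#' below 25% the sample needs further dilution and an error of class
#' `needs_further_dilution` is raised.
#'
#' @param series `data.frame` with columns `dilution` (pre-mix fold-dilution,
#'   >= 1, distinct), `mix_activity`, `pnp_activity`; optionally
#'   `patient_id`.
#' @return An object of class `bethesda_result`: `patient_id`,
#'   `residual_activity`, `chosen_dilution`, `bu_per_ml`, `classification`,
#'   `interpretation`.
#' @examples
#' bethesda_titre(data.frame(dilution = 1, mix_activity = 50,
#'                           pnp_activity = 100))  # 1 BU/mL
#' @export
bethesda_titre <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("dilution", "mix_activity", "pnp_activity") %in% names(series)))
  if (!nrow(series)) pep_stop("empty dilution series", "empty_series")
  if (anyDuplicated(series$dilution))
    pep_stop("dilutions must be distinct", "duplicate_dilutions")
  if (any(series$dilution < 1))
    pep_stop("dilution must be >= 1 (fold-dilution)", "bad_dilution")
  pid <- series$patient_id[1L] %||% NA_character_
  ra <- residual_activity(series$mix_activity, series$pnp_activity)
  in_band <- ra >= 25 & ra <= 75
  if (any(in_band)) {
    cand <- which(in_band)
    cand <- cand[order(abs(ra[cand] - 50), series$dilution[cand])]
    i <- cand[1L]
    bu <- bu_from_residual(ra[i]) * series$dilution[i]
    res <- list(patient_id = pid, residual_activity = ra[i],
                chosen_dilution = series$dilution[i], bu_per_ml = bu,
                classification = classify_inhibitor(bu),
                interpretation = "inhibitor_present")
  } else if (all(ra > 75)) {
    i <- which.min(series$dilution)
    res <- list(patient_id = pid, residual_activity = ra[i],
                chosen_dilution = series$dilution[i], bu_per_ml = 0,
                classification = classify_inhibitor(0),
                interpretation = "no_significant_inhibitor")
  } else if (all(ra < 25)) {
    pep_stop("all residual activities below 25%; dilute further to quantify",
             "needs_further_dilution")
  } else {
    # mixture of <25 and >75 readings with nothing in band: not interpretable
    pep_stop("dilution series brackets the quantifiable band without entering it",
             "out_of_band")
  }
  structure(res, class = "bethesda_result")
}

#' @export
print.bethesda_result <- function(x, ...) {
  cat(sprintf(
    "<bethesda_result> %s: RA %.1f%% at 1:%g -> %.2f BU/mL (%s; %s)\n",
    x$patient_id %||% "?", x$residual_activity, x$chosen_dilution,
    x$bu_per_ml, x$classification, x$interpretation))
  invisible(x)
}

#' Bethesda titres for a cohort mixing-study table
#'
#' Applies [bethesda_titre()] per patient. Patients whose series cannot be
#' quantified (all residual activities below 25%) are reported with `NA`
#' titre and interpretation `out_of_band` rather than failing the batch.
#'
#' @param mixing `data.frame` with `patient_id`, `dilution`, `mix_activity`,
#'   `pnp_activity`.
#' @return `data.frame` with one row per patient.
#' @export
bethesda_all <- function(mixing) {
  stopifnot("patient_id" %in% names(mixing))
  out <- lapply(split(mixing, mixing$patient_id), function(s) {
    r <- tryCatch(bethesda_titre(s), pepscanr_error = function(e) {
      list(patient_id = s$patient_id[1L], residual_activity = NA_real_,
           chosen_dilution = NA_real_, bu_per_ml = NA_real_,
           classification = NA_character_, interpretation = "out_of_band")
    })
    data.frame(patient_id = r$patient_id, residual_activity = r$residual_activity,
               chosen_dilution = r$chosen_dilution, bu_per_ml = r$bu_per_ml,
               classification = r$classification,
               interpretation = r$interpretation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a mixing-study CSV
#'
#' @param path CSV with columns `patient_id`, `dilution`, `mix_activity`,
#'   `pnp_activity`.
#' @return `data.frame`.
#' @export
read_mixing_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dilution", "mix_activity", "pnp_activity")
  if (!all(need %in% names(d)))
    pep_stop(paste("mixing CSV must have columns:", paste(need, collapse = ", ")),
             "bad_mixing_file")
  d
}
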