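#' Read ELISA plate measurements
#'
#' Expected CSV columns: `plate_id`, `well` (A1-H12), `role` (`blank`,
#' `negative_control`, `standard` or `sample`), `analyte` (peptide name or
#' immunoglobulin class; may be empty for blanks), `replicate_group`,
#' `od`, and optionally `standard_conc` and `patient_id`.
#'
#' @param paths One or more CSV paths; files are concatenated.
#' @return A `data.frame` of well measurements.
#' @export
read_plates_csv <- function(paths) {
  if (!base::length(paths)) pep_stop("no plate files supplied", "missing_plates")
  missing <- paths[!file.exists(paths)]
  if (base::length(missing))
    pep_stop(paste("plate file not found:", paste(missing, collapse = ", ")),
             "missing_plates")
  d <- do.call(rbind, lapply(paths, utils::read.csv, stringsAsFactors = FALSE))
  validate_wells(d)
}

validate_wells <- function(d) {
  need <- c("plate_id", "well", "role", "od")
  if (!all(need %in% names(d)))
    pep_stop(paste("plate data must have columns:", paste(need, collapse = ", ")),
             "bad_plate_file")
  if (any(d$od < 0)) pep_stop("negative OD measurement", "bad_plate_file")
  roles <- c("blank", "negative_control", "standard", "sample")
  if (!all(d$role %in% roles))
    pep_stop(paste("role must be one of:", paste(roles, collapse = ", ")),
             "bad_plate_file")
  if (!grepl("^[A-H](1[0-2]|[1-9])$", d$well[1L]) && nrow(d))
    pep_warn("well labels do not look like A1-H12", "odd_well_labels")
  bad_std <- d$role == "standard" & (is.null(d$standard_conc) | is.na(d$standard_conc %||% NA))
  if (any(bad_std)) pep_stop("standard wells must carry standard_conc", "bad_plate_file")
  d
}

#' Subtract plate blanks from all other wells
#'
#' Subtracts, per plate, the mean blank OD from every non-blank well, the
#' first correction step of the plate workup. Corrected values below zero
#' are floored at 0 with a warning (class `negative_corrected_od`). Blank
#' wells themselves are set to 0, which makes the operation idempotent.
#'
#' @param wells Well-measurement `data.frame` (see [read_plates_csv()]).
#' @return The data frame with `od` blank-corrected and a logical
#'   `blank_corrected` column set.
#' @examples
#' w <- data.frame(plate_id = "p1", well = c("A1", "A2", "B1"),
#'                 role = c("blank", "blank", "sample"),
#'                 analyte = c(NA, NA, "MP1"), od = c(0.05, 0.07, 0.50))
#' subtract_blanks(w)$od  # sample becomes 0.44
#' @export
subtract_blanks <- function(wells) {
  wells <- validate_wells(wells)
  if (isTRUE(attr(wells, "blank_corrected"))) return(wells)
  out <- lapply(split(wells, wells$plate_id), function(p) {
    bl <- p$od[p$role == "blank"]
    if (!base::length(bl))
      pep_stop(sprintf("plate %s has no blank wells", p$plate_id[1L]),
               "missing_blanks")
    p$od <- p$od - mean(bl)
    p$od[p$role == "blank"] <- 0
    if (any(p$od < 0)) {
      pep_warn(sprintf("%d well(s) on plate %s below the blank mean; floored at 0",
                       sum(p$od < 0), p$plate_id[1L]), "negative_corrected_od")
      p$od[p$od < 0] <- 0
    }
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "blank_corrected") <- TRUE
  out
}

#' Average duplicate wells
#'
#' Collapses each replicate group (typically duplicate wells of one patient
#' x analyte) to its mean OD, recording the absolute spread and flagging
#' groups whose spread exceeds `tolerance` as a fraction of the mean
#' (discordant duplicates are flagged, not dropped).
#'
#' @param wells Blank-corrected well measurements.
#' @param tolerance Relative spread (|od1 - od2| / mean) above which a pair
#'   is flagged discordant; default 0.2.
#' @return A `data.frame` with one row per replicate group: `plate_id`,
#'   `patient_id`, `analyte`, `role`, `mean_od`, `spread`, `discordant`,
#'   plus `standard_conc` for standards.
#' @export
average_duplicates <- function(wells, tolerance = 0.2) {
  if (!nrow(wells)) pep_stop("no wells", "bad_plate_file")
  if (is.null(wells$replicate_group))
    wells$replicate_group <- seq_len(nrow(wells))
  if (is.null(wells$patient_id)) wells$patient_id <- NA_character_
  if (is.null(wells$analyte)) wells$analyte <- NA_character_
  if (is.null(wells$standard_conc)) wells$standard_conc <- NA_real_
  groups <- split(wells, wells$replicate_group)
  out <- lapply(groups, function(g) {
    m <- mean(g$od)
    spread <- if (nrow(g) > 1L) max(g$od) - min(g$od) else 0
    data.frame(plate_id = g$plate_id[1L], patient_id = g$patient_id[1L],
               analyte = g$analyte[1L], role = g$role[1L],
               replicate_group = g$replicate_group[1L],
               n_wells = nrow(g), mean_od = m, spread = spread,
               discordant = m > 0 && spread / m > tolerance,
               standard_conc = g$standard_conc[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plate_id, out$replicate_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positivity cut-off from negative controls
#'
#' `cutoff = mean(nc) + k * sd(nc)`, the standard serology convention. With
#' a single control the standard deviation is taken as 0.
#'
#' @param negative_controls Numeric vector of blank-corrected negative
#'   control ODs.
#' @param k Multiplier on the standard deviation (default 3).
#' @return The cut-off OD.
#' @examples
#' compute_cutoff(c(0.10, 0.12))  # 0.11 + 3 * sd
#' @export
compute_cutoff <- function(negative_controls, k = 3) {
  if (!base::length(negative_controls))
    pep_stop("no negative-control values", "missing_negative_controls")
  s <- if (base::length(negative_controls) > 1L) stats::sd(negative_controls) else 0
  mean(negative_controls) + k * s
}

#' Call peptide positivity against a plate cut-off
#'
#' A well is positive when its blank-corrected OD strictly exceeds the
#' cut-off; a value exactly at the cut-off is negative.
#'
#' @param corrected_od Numeric vector of blank-corrected mean ODs.
#' @param cutoff Cut-off from [compute_cutoff()] on the same plate.
#' @return Logical vector of positivity calls.
#' @export
call_binding <- function(corrected_od, cutoff) {
  stopifnot(is.numeric(corrected_od), is.numeric(cutoff))
  corrected_od > cutoff
}

#' Full plate workup: blanks, duplicates, cut-offs, positivity calls
#'
#' Runs [subtract_blanks()], [average_duplicates()] and, per plate,
#' [compute_cutoff()] on the negative controls, then calls each sample
#' replicate group against its own plate's cut-off.
#'
#' @param wells Raw well measurements for one or more plates.
#' @param library Optional `peptide_library`; when given, peptide
#'   coordinates are joined onto the calls and unknown analytes error.
#' @param k Cut-off multiplier (default 3).
#' @param tolerance Duplicate-spread tolerance passed to
#'   [average_duplicates()].
#' @return A `binding_calls` data frame: `patient_id`, `peptide`, `start`,
#'   `end`, `mean_od` (blank-corrected), `cutoff`, `positive`, `discordant`.
#' @export
call_plates <- function(wells, library = NULL, k = 3, tolerance = 0.2) {
  corrected <- subtract_blanks(wells)
  avg <- average_duplicates(corrected, tolerance = tolerance)
  cuts <- vapply(split(avg, avg$plate_id), function(p) {
    nc <- p$mean_od[p$role == "negative_control"]
    if (!base::length(nc))
      pep_stop(sprintf("plate %s has no negative control", p$plate_id[1L]),
               "missing_negative_controls")
    compute_cutoff(nc, k = k)
  }, numeric(1))
  smp <- avg[avg$role == "sample", , drop = FALSE]
  smp$cutoff <- unname(cuts[as.character(smp$plate_id)])
  smp$positive <- call_binding(smp$mean_od, smp$cutoff)
  calls <- data.frame(patient_id = smp$patient_id, peptide = smp$analyte,
                      mean_od = smp$mean_od, cutoff = smp$cutoff,
                      positive = smp$positive, discordant = smp$discordant,
                      stringsAsFactors = FALSE)
  if (!is.null(library)) {
    i <- match(calls$peptide, library$name)
    if (anyNA(i))
      pep_stop(paste("analyte(s) not in peptide library:",
                     paste(unique(calls$peptide[is.na(i)]), collapse = ", ")),
               "unknown_analyte")
    calls$start <- library$start[i]
    calls$end <- library$end[i]
    calls$region <- library$region[i]
    calls <- calls[order(calls$patient_id, calls$start), , drop = FALSE]
    rownames(calls) <- NULL
  }
  structure(calls, class = c("binding_calls", "data.frame"))
}

#' @export
print.binding_calls <- function(x, ...) {
  cat(sprintf("<binding_calls> %d calls, %d patient(s), %d positive (%.1f%%)\n",
              nrow(x), base::length(unique(x$patient_id)), sum(x$positive),
              100 * mean(x$positive)))
  invisible(x)
}
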