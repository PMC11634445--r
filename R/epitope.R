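#' Merge a patient's positive peptides into epitope regions
#'
#' Maximal runs of positive peptides whose intervals share at least one
#' residue are merged into candidate epitope regions (the interval union of
#' the run). Adjacent-but-not-overlapping positives (0 shared residues) stay
#' separate regions. Each region also carries its core sub-interval from
#' [core_epitope()].
#'
#' @param calls A `binding_calls` data frame for one patient, with `peptide`,
#'   `start`, `end`, `positive` columns (see [call_plates()]).
#' @param core_mode Core definition passed to [core_epitope()].
#' @return `data.frame`: `start`, `end`, `core_start`, `core_end`,
#'   `peptides` (comma-separated supporting peptide names), `n_peptides`.
#' @examples
#' calls <- data.frame(peptide = c("MP9", "MP10"), start = c(115, 120),
#'                     end = c(134, 139), positive = TRUE)
#' merge_positive_peptides(calls)  # one region 115-139, core 120-134
#' @export
merge_positive_peptides <- function(calls, core_mode = c("max_coverage", "intersection")) {
  core_mode <- match.arg(core_mode)
  stopifnot(all(c("peptide", "start", "end", "positive") %in% names(calls)))
  pos <- calls[calls$positive, , drop = FALSE]
  if (!nrow(pos)) {
    return(data.frame(start = integer(), end = integer(),
                      core_start = integer(), core_end = integer(),
                      peptides = character(), n_peptides = integer(),
                      stringsAsFactors = FALSE))
  }
  pos <- pos[order(pos$start, pos$end), , drop = FALSE]
  ir <- IRanges::IRanges(pos$start, pos$end)
  # min.gapwidth = 0: merge on residue overlap only, never across a gap
  merged <- IRanges::reduce(ir, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(ir, merged)
  member <- S4Vectors::subjectHits(hits)
  out <- lapply(seq_along(merged), function(j) {
    sel <- member == j
    core <- core_epitope(pos$start[sel], pos$end[sel], mode = core_mode)
    data.frame(start = IRanges::start(merged)[j], end = IRanges::end(merged)[j],
               core_start = core[1L], core_end = core[2L],
               peptides = paste(pos$peptide[sel], collapse = ","),
               n_peptides = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core sub-interval of an epitope region
#'
#' With `mode = "max_coverage"` (default) the core is the span of residues
#' covered by the maximal number of supporting peptides (the union of all
#' argmax positions, contiguous for fixed-offset tilings). Strict
#' all-peptide intersection is available as `mode = "intersection"` but is
#' empty for runs longer than `length/offset` peptides, in which case the
#' max-coverage core is returned with a warning.
#'
#' @param starts,ends Supporting peptide intervals (1-based inclusive).
#' @param mode `"max_coverage"` or `"intersection"`.
#' @return Integer vector `c(core_start, core_end)`.
#' @examples
#' core_epitope(c(115, 120), c(134, 139))              # 120 134
#' core_epitope(seq(645, 665, 5), seq(664, 684, 5))    # 660 669
#' @export
core_epitope <- function(starts, ends, mode = c("max_coverage", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(base::length(starts) >= 1L, base::length(starts) == base::length(ends),
            all(starts <= ends))
  if (mode == "intersection") {
    lo <- max(starts); hi <- min(ends)
    if (lo <= hi) return(c(as.integer(lo), as.integer(hi)))
    pep_warn("all-peptide intersection is empty; falling back to max-coverage core",
             "empty_intersection")
  }
  ir <- IRanges::IRanges(starts, ends)
  cov <- IRanges::coverage(ir)
  v <- as.integer(cov)
  at_max <- which(v == max(v))
  c(min(at_max), max(at_max))
}

#' Classify a patient's domain reactivity
#'
#' A domain is reactive when at least one positive peptide overlaps it;
#' peptides straddling a boundary count for both flanking domains. The
#' summary `category` follows the conventional proximal-domain reporting
#' over the metalloprotease/disintegrin-like pair and the
#' cysteine-rich/spacer pair: `none`, `MP_only`, `Dis_only`, `MP_and_Dis`,
#' `Cys_only`, `Spa_only`, `Cys_and_Spa` or `all_four`. When both pairs are
#' reactive but not all four domains, the pair with more reactive domains
#' labels the category (ties go to the cysteine-rich/spacer pair, the
#' immunodominant axis in this assay).
#'
#' @param calls `binding_calls` for one patient (with `start`, `end`,
#'   `positive`).
#' @param domains `data.frame` with `label`, `start`, `end` domain bounds,
#'   or a list of [tiling_region()] objects whose annotations are pooled.
#' @return List of class `domain_reactivity`: `reactive_domains`
#'   (character), `category`.
#' @export
classify_domains <- function(calls, domains) {
  dom <- as_domain_frame(domains)
  pos <- calls[calls$positive, , drop = FALSE]
  reactive <- character(0)
  if (nrow(pos)) {
    hit <- vapply(seq_len(nrow(dom)), function(i)
      any(pos$start <= dom$end[i] & pos$end >= dom$start[i]), logical(1))
    reactive <- dom$label[hit]
  }
  structure(list(reactive_domains = reactive,
                 category = domain_category(reactive)),
            class = "domain_reactivity")
}

as_domain_frame <- function(domains) {
  if (inherits(domains, "tiling_region")) domains <- list(domains)
  if (is.list(domains) && !is.data.frame(domains) &&
      all(vapply(domains, inherits, logical(1), "tiling_region"))) {
    domains <- do.call(rbind, lapply(domains, function(r) r$domains))
  }
  stopifnot(all(c("label", "start", "end") %in% names(domains)))
  domains
}

CORE_DOMAINS <- c("MP", "Dis", "Cys", "Spa")

domain_category <- function(reactive) {
  r <- intersect(CORE_DOMAINS, reactive)
  if (!base::length(r)) return("none")
  if (base::length(r) == 4L) return("all_four")
  n_pair <- intersect(r, c("MP", "Dis"))
  c_pair <- intersect(r, c("Cys", "Spa"))
  lab <- function(pair, both, only) {
    if (base::length(pair) == 2L) both else paste0(pair, "_only")
  }
  n_lab <- if (base::length(n_pair)) lab(n_pair, "MP_and_Dis") else NULL
  c_lab <- if (base::length(c_pair)) lab(c_pair, "Cys_and_Spa") else NULL
  if (is.null(c_lab)) return(n_lab)
  if (is.null(n_lab)) return(c_lab)
  if (base::length(n_pair) > base::length(c_pair)) n_lab else c_lab
}

#' @export
print.domain_reactivity <- function(x, ...) {
  cat(sprintf("<domain_reactivity> %s (category: %s)\n",
              if (base::length(x$reactive_domains))
                paste(x$reactive_domains, collapse = ", ") else "none",
              x$category))
  invisible(x)
}

#' Cohort-level epitope deconvolution
#'
#' Runs [merge_positive_peptides()] and [classify_domains()] for every
#' patient, then pools regions with identical supporting-peptide sets
#' across patients. A pooled region's frequency is the fraction of the
#' cohort positive for *all* of its supporting peptides; regions at or
#' above `shared_threshold` are marked shared.
#'
#' @param calls `binding_calls` for the whole cohort (column `patient_id`).
#' @param domains Domain annotations (see [classify_domains()]).
#' @param cohort_size Number of patients the frequencies are relative to;
#'   defaults to the number of distinct `patient_id`s in `calls`.
#' @param shared_threshold Frequency at or above which a region is shared
#'   (default 0.5).
#' @param core_mode Core definition (see [core_epitope()]).
#' @return An object of class `epitope_map` with elements
#'   `patient_regions`, `profiles`, `cohort_regions`, `category_counts`,
#'   `cohort_size`, `shared_threshold`.
#' @export
epitope_map <- function(calls, domains, cohort_size = NULL,
                        shared_threshold = 0.5,
                        core_mode = c("max_coverage", "intersection")) {
  core_mode <- match.arg(core_mode)
  if (!nrow(calls)) pep_stop("no binding calls", "empty_cohort")
  patients <- unique(calls$patient_id)
  cohort_size <- cohort_size %||% base::length(patients)
  by_pat <- split(as.data.frame(calls), calls$patient_id)

  patient_regions <- do.call(rbind, lapply(patients, function(p) {
    r <- merge_positive_peptides(by_pat[[p]], core_mode = core_mode)
    if (nrow(r)) cbind(patient_id = p, r, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(patient_regions))
    patient_regions <- data.frame(patient_id = character(), start = integer(),
                                  end = integer(), core_start = integer(),
                                  core_end = integer(), peptides = character(),
                                  n_peptides = integer(), stringsAsFactors = FALSE)

  profiles <- data.frame(
    patient_id = patients,
    category = vapply(patients, function(p)
      classify_domains(by_pat[[p]], domains)$category, character(1)),
    reactive_domains = vapply(patients, function(p)
      paste(classify_domains(by_pat[[p]], domains)$reactive_domains,
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)

  # positive-peptide set per patient, recovered from region membership
  pos_sets <- lapply(patients, function(p) {
    r <- patient_regions[patient_regions$patient_id == p, , drop = FALSE]
    unique(unlist(strsplit(r$peptides, ",")))
  })
  names(pos_sets) <- patients

  uniq <- patient_regions[!duplicated(patient_regions$peptides),
                          c("start", "end", "core_start", "core_end",
                            "peptides", "n_peptides"), drop = FALSE]
  if (nrow(uniq)) {
    uniq$patients_positive <- vapply(uniq$peptides, function(pp) {
      need <- strsplit(pp, ",")[[1]]
      sum(vapply(pos_sets, function(s) all(need %in% s), logical(1)))
    }, integer(1))
    uniq$frequency <- uniq$patients_positive / cohort_size
    uniq$shared <- uniq$frequency >= shared_threshold
    uniq <- uniq[order(uniq$start, -uniq$frequency), , drop = FALSE]
    rownames(uniq) <- NULL
  } else {
    uniq$patients_positive <- integer(); uniq$frequency <- numeric()
    uniq$shared <- logical()
  }

  cats <- c("MP_only", "Dis_only", "MP_and_Dis", "Cys_only", "Spa_only",
            "Cys_and_Spa", "all_four", "none")
  category_counts <- as.data.frame(table(factor(profiles$category, levels = cats)),
                                   stringsAsFactors = FALSE)
  names(category_counts) <- c("category", "n")

  structure(list(patient_regions = patient_regions, profiles = profiles,
                 cohort_regions = uniq, category_counts = category_counts,
                 cohort_size = cohort_size, shared_threshold = shared_threshold,
                 core_mode = core_mode, domains = as_domain_frame(domains)),
            class = "epitope_map")
}

#' @export
print.epitope_map <- function(x, ...) {
  cat(sprintf(
    "<epitope_map> %d patients, %d distinct regions (%d shared at >= %.0f%%)\n",
    x$cohort_size, nrow(x$cohort_regions), sum(x$cohort_regions$shared),
    100 * x$shared_threshold))
  invisible(x)
}

#' @export
summary.epitope_map <- function(object, ...) {
  cat(sprintf("Cohort of %d patients; %d distinct epitope regions\n",
              object$cohort_size, nrow(object$cohort_regions)))
  shared <- object$cohort_regions[object$cohort_regions$shared, , drop = FALSE]
  if (nrow(shared)) {
    cat(sprintf("Shared regions (frequency >= %.0f%%):\n",
                100 * object$shared_threshold))
    for (i in seq_len(nrow(shared)))
      cat(sprintf("  %d-%d (core %d-%d): %s\n", shared$start[i], shared$end[i],
                  shared$core_start[i], shared$core_end[i],
                  fmt_pct(shared$patients_positive[i], object$cohort_size)))
  }
  cat("Domain reactivity categories:\n")
  cc <- object$category_counts[object$category_counts$n > 0, , drop = FALSE]
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-12s %s\n", cc$category[i],
                fmt_pct(cc$n[i], object$cohort_size)))
  invisible(object)
}

#' Per-residue positivity coverage plot
#'
#' Base-graphics profile of, per residue, the fraction of the cohort with a
#' positive peptide covering that residue; shared-region cores are shaded.
#'
#' @param x An `epitope_map`.
#' @param ... Passed to [plot()].
#' @export
plot.epitope_map <- function(x, ...) {
  pr <- x$patient_regions
  if (!nrow(pr)) {
    plot.new(); return(invisible(x))
  }
  rng <- range(pr$start, pr$end)
  pos <- rng[1]:rng[2]
  cov <- numeric(base::length(pos))
  for (p in unique(pr$patient_id)) {
    r <- pr[pr$patient_id == p, , drop = FALSE]
    covered <- rep(FALSE, base::length(pos))
    for (i in seq_len(nrow(r)))
      covered[pos >= r$start[i] & pos <= r$end[i]] <- TRUE
    cov <- cov + covered
  }
  plot(pos, cov / x$cohort_size, type = "s", xlab = "residue position",
       ylab = "fraction of cohort positive", ylim = c(0, 1), ...)
  sh <- x$cohort_regions[x$cohort_regions$shared, , drop = FALSE]
  if (nrow(sh))
    graphics::rect(sh$core_start, 0, sh$core_end, 1,
                   col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  invisible(x)
}

#' Report tables for an epitope map
#'
#' Produces the cohort reporting layouts: a domain-reactivity table with
#' the seven conventional category rows (counts over each domain pair are
#' not mutually exclusive, matching how such cohorts are reported), a
#' region table ordered by start then descending frequency with
#' whole-number percentages, and the shared/non-shared split.
#'
#' @param map An `epitope_map`.
#' @param library Optional `peptide_library` used to attach region peptide
#'   sequences.
#' @return Named list of data frames: `domain_reactivity`, `regions`,
#'   `shared`, `category_counts`.
#' @export
report_tables <- function(map, library = NULL) {
  stopifnot(inherits(map, "epitope_map"))
  n <- map$cohort_size
  react <- strsplit(map$profiles$reactive_domains, ",")
  has <- function(d) vapply(react, function(r) d %in% r, logical(1))
  mp <- has("MP"); dis <- has("Dis"); cys <- has("Cys"); spa <- has("Spa")
  rows <- list(
    c("Metalloprotease domain only", sum(mp & !dis)),
    c("Disintegrin-like domain only", sum(dis & !mp)),
    c("Both metalloprotease and disintegrin-like domains", sum(mp & dis)),
    c("Cysteine-rich domain only", sum(cys & !spa)),
    c("Spacer domain only", sum(spa & !cys)),
    c("Both cysteine-rich and spacer domains", sum(cys & spa)),
    c("All four domains", sum(mp & dis & cys & spa)))
  domain_reactivity <- data.frame(
    domains = vapply(rows, `[`, character(1), 1L),
    n_positive = as.integer(vapply(rows, `[`, character(1), 2L)),
    stringsAsFactors = FALSE)
  domain_reactivity$out_of <- n
  domain_reactivity$percent <- vapply(domain_reactivity$n_positive, fmt_pct,
                                      character(1), den = n)

  regions <- map$cohort_regions
  if (nrow(regions)) {
    regions$positive <- sprintf("%d/%d", regions$patients_positive, n)
    regions$percent <- vapply(regions$patients_positive, fmt_pct, character(1),
                              den = n)
    first_last <- function(pp) {
      p <- strsplit(pp, ",")[[1]]
      if (base::length(p) == 1L) p else paste0(p[1L], "-", p[base::length(p)])
    }
    regions$peptide_span <- vapply(regions$peptides, first_last, character(1))
    if (!is.null(library)) {
      regions$sequence <- vapply(seq_len(nrow(regions)), function(i) {
        first <- strsplit(regions$peptides[i], ",")[[1]][1L]
        j <- match(first, library$name)
        if (is.na(j)) return(NA_character_)
        reconstruct_region_sequence(regions$start[i], regions$end[i], library)
      }, character(1))
    }
    regions <- regions[order(regions$start, -regions$frequency), , drop = FALSE]
    rownames(regions) <- NULL
  }
  shared <- regions[regions$shared %in% TRUE, , drop = FALSE]
  list(domain_reactivity = domain_reactivity, regions = regions,
       shared = shared, category_counts = map$category_counts)
}

reconstruct_region_sequence <- function(start, end, library) {
  seqv <- rep(NA_character_, end - start + 1L)
  sel <- which(library$start <= end & library$end >= start)
  for (j in sel) {
    pp <- strsplit(library$sequence[j], "")[[1]]
    for (k in seq_along(pp)) {
      p <- library$start[j] + k - 1L
      if (p >= start && p <= end) seqv[p - start + 1L] <- pp[k]
    }
  }
  paste(ifelse(is.na(seqv), "x", seqv), collapse = "")
}

#' Write report tables to a directory
#'
#' @param map An `epitope_map`.
#' @param dir Output directory (created if missing).
#' @param library Optional `peptide_library` for sequences.
#' @return Invisibly, the list from [report_tables()].
#' @export
write_report_tables <- function(map, dir, library = NULL) {
  tabs <- report_tables(map, library = library)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tabs)
}
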