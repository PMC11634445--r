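#' Tile a protein region into overlapping peptides
#'
#' Generates the fixed-length sliding-window peptide set used for linear
#' B-cell epitope scanning: windows of `length` residues advanced `offset`
#' residues at a time, so consecutive peptides overlap by `length - offset`
#' residues. The final peptide always ends exactly at `region$end`; when the
#' region span minus the window length is not a multiple of `offset`, that
#' final window is off the offset grid and a warning of class
#' `off_grid_final_peptide` is raised.
#'
#' @param protein A [protein_record()] covering the region.
#' @param region A [tiling_region()].
#' @param length Peptide length in residues (default 20).
#' @param offset Window step in residues (default 5); must satisfy
#'   `1 <= offset <= length`.
#' @return A `peptide_library` data frame with columns `name` (unset until
#'   [name_peptides()] is applied), `region`, `index`, `start`, `end`,
#'   `sequence`, `biotinylated`.
#' @examples
#' p <- adamts13_proximal()
#' r <- adamts13_regions()
#' nrow(tile_peptides(p, r[["MP-Dis"]]))   # 59
#' nrow(tile_peptides(p, r[["Cys-Spa"]]))  # 46
#' @export
tile_peptides <- function(protein, region, length = 20L, offset = 5L) {
  stopifnot(inherits(protein, "protein_record"), inherits(region, "tiling_region"))
  length <- assert_scalar_int(length, "length", min = 1L)
  offset <- assert_scalar_int(offset, "offset", min = 1L)
  if (offset > length)
    pep_stop("offset must not exceed peptide length", "bad_argument")
  span <- region$end - region$start + 1L
  if (span < length)
    pep_stop(sprintf("region %s (%d aa) is shorter than the peptide length %d",
                     region$name, span, length), "region_too_short")
  last_start <- region$end - length + 1L
  starts <- seq.int(region$start, last_start, by = offset)
  if (starts[base::length(starts)] != last_start) {
    starts <- c(starts, last_start)
    pep_warn(sprintf(
      "final peptide of region %s (start %d) is off the %d-residue offset grid",
      region$name, last_start, offset), "off_grid_final_peptide")
  }
  ends <- starts + length - 1L
  seqs <- vapply(seq_along(starts),
                 function(i) protein_substring(protein, starts[i], ends[i]),
                 character(1))
  lib <- data.frame(name = NA_character_, region = region$name,
                    index = seq_along(starts), start = starts, end = ends,
                    sequence = seqs, biotinylated = TRUE,
                    stringsAsFactors = FALSE)
  new_peptide_library(lib, length = length, offset = offset)
}

new_peptide_library <- function(df, length = NULL, offset = NULL) {
  structure(df, class = c("peptide_library", "data.frame"),
            peptide_length = length, offset = offset)
}

#' @export
print.peptide_library <- function(x, ...) {
  cat(sprintf("<peptide_library> %d peptides (%s-mers, offset %s) over region(s): %s\n",
              nrow(x), attr(x, "peptide_length") %||% "?",
              attr(x, "offset") %||% "?",
              paste(unique(x$region), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("... (", nrow(x) - 8, " more)\n", sep = "")
  invisible(x)
}

#' Name peptides from the domain annotations they cover
#'
#' Follows the field convention of deriving peptide names from domain names:
#' a peptide lying inside a single annotated domain is named
#' `<label><index>`; a peptide straddling a domain boundary gets a compound
#' label with the N-terminal domain first (`"MP/Dis41"`). Indices run
#' continuously across the region. Labels ending in a digit are separated
#' from the index by a space (`"Dis/TSP1 59"`).
#'
#' @param peptides A `peptide_library` from [tile_peptides()], sorted by start.
#' @param region The [tiling_region()] carrying the domain annotations.
#' @return The library with `name` filled in.
#' @export
name_peptides <- function(peptides, region) {
  stopifnot(inherits(region, "tiling_region"))
  dom <- region$domains
  sel <- peptides$region == region$name
  idx <- which(sel)
  if (any(diff(peptides$start[idx]) < 0))
    pep_stop("peptides must be sorted by start", "bad_argument")
  for (i in idx) {
    s <- peptides$start[i]; e <- peptides$end[i]
    ov <- pmin(e, dom$end) - pmax(s, dom$start) + 1L
    hit <- ov > 0L
    if (!any(hit))
      pep_stop(sprintf("peptide %d-%d overlaps no domain annotation", s, e),
               "unannotated_span")
    label <- paste(dom$label[hit], collapse = "/")
    sep <- if (grepl("[0-9]$", label)) " " else ""
    peptides$name[i] <- paste0(label, sep, peptides$index[i])
  }
  peptides
}

#' Design a full overlapping-peptide library
#'
#' Convenience wrapper: tiles and names every region, concatenating the
#' per-region libraries. The packaged ADAMTS13 proximal-domain fixtures
#' reproduce the published 105-peptide library (59 + 46 peptides).
#'
#' @inheritParams tile_peptides
#' @param regions List of [tiling_region()] objects.
#' @return A named `peptide_library`.
#' @examples
#' lib <- design_library(adamts13_proximal(), adamts13_regions())
#' lib[lib$name == "MP1", ]
#' @export
design_library <- function(protein, regions, length = 20L, offset = 5L) {
  if (!base::length(regions)) pep_stop("no regions supplied", "empty_regions")
  if (inherits(regions, "tiling_region")) regions <- list(regions)
  parts <- lapply(regions, function(r)
    name_peptides(tile_peptides(protein, r, length, offset), r))
  lib <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(lib) <- NULL
  new_peptide_library(lib, length = length, offset = offset)
}

#' Write / read a peptide library
#'
#' `write_peptide_library()` emits a FASTA file of peptide sequences named by
#' peptide name plus a TSV manifest (`name`, `region`, `index`, `start`,
#' `end`, `sequence`, `biotinylated`). `read_peptide_library()` reads the
#' manifest back; the pair round-trips losslessly.
#'
#' @param peptides A named `peptide_library`.
#' @param fasta,tsv Output paths; either may be `NULL` to skip.
#' @return `write_peptide_library()` returns the input invisibly;
#'   `read_peptide_library()` returns a `peptide_library`.
#' @export
write_peptide_library <- function(peptides, fasta = NULL, tsv = NULL) {
  if (!nrow(peptides)) pep_stop("empty peptide library", "empty_library")
  if (anyNA(peptides$name)) pep_stop("peptides are unnamed; run name_peptides()",
                                     "unnamed_peptides")
  if (anyDuplicated(peptides$name))
    pep_stop("duplicate peptide names", "name_collision")
  if (!is.null(fasta)) {
    aa <- Biostrings::AAStringSet(stats::setNames(peptides$sequence, peptides$name))
    Biostrings::writeXStringSet(aa, fasta)
  }
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(peptides), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(peptides)
}

#' @rdname write_peptide_library
#' @param path Manifest TSV path.
#' @export
read_peptide_library <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "sequence")
  if (!all(need %in% names(d)))
    pep_stop(paste("library manifest must have columns:",
                   paste(need, collapse = ", ")), "bad_library_file")
  if (anyDuplicated(d$name)) pep_stop("duplicate peptide names", "name_collision")
  if (is.null(d$region)) d$region <- "region"
  if (is.null(d$index)) d$index <- stats::ave(d$start, d$region, FUN = seq_along)
  if (is.null(d$biotinylated)) d$biotinylated <- TRUE
  len <- unique(d$end - d$start + 1L)
  off <- unique(unlist(tapply(d$start, d$region, diff, simplify = FALSE)))
  new_peptide_library(d[, c("name", "region", "index", "start", "end",
                            "sequence", "biotinylated")],
                      length = if (base::length(len) == 1L) len else NULL,
                      offset = if (base::length(off) == 1L) off else NULL)
}
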