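#' Protein record with explicit residue numbering
#'
#' A minimal container for a (possibly partial) protein sequence whose first
#' residue sits at position `numbering_offset` of the full-length protein.
#' This supports libraries built from proximal-domain fragments while keeping
#' all peptide coordinates on full-length numbering.
#'
#' @param id Character scalar, sequence identifier.
#' @param residues Character scalar of one-letter amino-acid codes.
#' @param numbering_offset 1-based position, on the full-length protein, of
#'   the first residue of `residues`.
#' @return An object of class `protein_record`.
#' @examples
#' protein_record("toy", "MKTAYIAKQR", numbering_offset = 10)
#' @export
protein_record <- function(id, residues, numbering_offset = 1L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    pep_stop("protein has no residues", "empty_sequence")
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    pep_stop(paste0("non-standard residue code(s): ", paste(bad, collapse = ", ")),
             "bad_residue")
  numbering_offset <- assert_scalar_int(numbering_offset, "numbering_offset", min = 1L)
  structure(list(id = id, residues = residues,
                 numbering_offset = numbering_offset),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  last <- x$numbering_offset + nchar(x$residues) - 1L
  cat(sprintf("<protein_record> %s: %d aa, numbered %d-%d\n",
              x$id, nchar(x$residues), x$numbering_offset, last))
  invisible(x)
}

# substring on full-length numbering
protein_substring <- function(protein, start, end) {
  i <- start - protein$numbering_offset + 1L
  j <- end - protein$numbering_offset + 1L
  if (i < 1L || j > nchar(protein$residues))
    pep_stop(sprintf("span %d-%d outside numbered range of %s", start, end,
                     protein$id), "outside_protein")
  substr(protein$residues, i, j)
}

#' Region of a protein selected for peptide tiling
#'
#' @param name Region name (e.g. `"MP-Dis"`).
#' @param start,end 1-based inclusive bounds on full-length numbering.
#' @param domains `data.frame` with columns `label`, `start`, `end`: ordered,
#'   non-overlapping sub-annotations (protein domains) lying within
#'   `[start, end]`. Used for peptide naming and domain-reactivity calls.
#' @return An object of class `tiling_region`.
#' @export
tiling_region <- function(name, start, end, domains = NULL) {
  start <- assert_scalar_int(start, "start", min = 1L)
  end <- assert_scalar_int(end, "end", min = 1L)
  if (start > end) pep_stop("region start exceeds end", "bad_region")
  if (is.null(domains)) {
    domains <- data.frame(label = name, start = start, end = end,
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "start", "end") %in% names(domains)))
  domains <- domains[order(domains$start), , drop = FALSE]
  if (any(domains$start > domains$end) ||
      any(domains$start < start) || any(domains$end > end))
    pep_stop("domain annotations must lie within the region", "bad_region")
  if (nrow(domains) > 1L &&
      any(domains$start[-1L] <= domains$end[-nrow(domains)]))
    pep_stop("domain annotations must not overlap", "bad_region")
  structure(list(name = name, start = start, end = end, domains = domains),
            class = "tiling_region")
}

#' @export
print.tiling_region <- function(x, ...) {
  cat(sprintf("<tiling_region> %s: %d-%d (%d aa); domains: %s\n",
              x$name, x$start, x$end, x$end - x$start + 1L,
              paste(sprintf("%s %d-%d", x$domains$label, x$domains$start,
                            x$domains$end), collapse = ", ")))
  invisible(x)
}

#' Read a protein from FASTA
#'
#' Reads the first record of a FASTA file. A `offset=<n>` token in the
#' description line sets the numbering offset (residue 1 of the record on
#' full-length numbering); otherwise numbering starts at 1.
#'
#' @param path Path to a FASTA file of amino-acid sequence.
#' @return A [protein_record()].
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) pep_stop("no FASTA records found", "empty_fasta")
  header <- names(aa)[1L]
  off <- 1L
  m <- regmatches(header, regexpr("offset=([0-9]+)", header))
  if (length(m)) off <- as.integer(sub("offset=", "", m))
  id <- strsplit(header, "\\s+")[[1]][1L]
  protein_record(id, as.character(aa[[1L]]), numbering_offset = off)
}

#' Read tiling regions and domain annotations from TSV
#'
#' Expected columns: `region`, `region_start`, `region_end`, `label`,
#' `start`, `end` — one row per domain annotation, grouped into regions.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [tiling_region()] objects.
#' @export
read_regions_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "region_start", "region_end", "label", "start", "end")
  if (!all(need %in% names(d)))
    pep_stop(paste("regions TSV must have columns:", paste(need, collapse = ", ")),
             "bad_regions_file")
  out <- lapply(split(d, d$region), function(g) {
    tiling_region(g$region[1L], g$region_start[1L], g$region_end[1L],
                  domains = g[, c("label", "start", "end")])
  })
  out[order(vapply(out, function(r) r$start, integer(1)))]
}

#' Packaged synthetic ADAMTS13 proximal-region fixtures
#'
#' The package ships a synthetic stand-in for the proximal region
#' (metalloprotease through spacer domains) of human ADAMTS13, assembled
#' from published peptide fragments with internally consistent coordinates;
#' unanchored positions carry deterministic placeholder residues. Domain
#' bounds (MP 75-285, Dis 286-383, Cys 440-549, Spa 550-680, with short
#' TSP stubs closing each tiled region) are inferred from published peptide
#' names and coordinates. Geometry is exact; see the methods vignette.
#'
#' @return `adamts13_proximal()`: a [protein_record()] numbered from 75.
#'   `adamts13_regions()`: list of two [tiling_region()] objects,
#'   `MP-Dis` (75-384) and `Cys-Spa` (440-684).
#' @examples
#' lib <- design_library(adamts13_proximal(), adamts13_regions())
#' nrow(lib)  # 105
#' @export
adamts13_proximal <- function() {
  read_protein_fasta(system.file("extdata", "adamts13_proximal_synthetic.fasta",
                                 package = "pepscanr", mustWork = TRUE))
}

#' @rdname adamts13_proximal
#' @export
adamts13_regions <- function() {
  read_regions_tsv(system.file("extdata", "adamts13_domains_synthetic.tsv",
                               package = "pepscanr", mustWork = TRUE))
}
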