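# deterministic toy fixtures built in code

toy_protein <- function(n = 200L, offset = 1L, id = "toy") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  protein_record(id, paste(rep_len(aa, n), collapse = ""),
                 numbering_offset = offset)
}

# binding-call table from explicit peptide intervals
make_calls <- function(starts, ends = starts + 19L, positive = TRUE,
                       patient = "PT01", names = NULL) {
  data.frame(patient_id = patient,
             peptide = names %||% sprintf("pep%02d", seq_along(starts)),
             start = as.integer(starts), end = as.integer(ends),
             positive = rep_len(positive, length(starts)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force oracle for region merging and core extraction: chains sorted
# intervals while the next interval shares >= 1 residue with the running
# union (adjacency does not chain), then counts per-residue coverage within
# each chain and takes as core the residues at maximal coverage
brute_regions <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  chain <- cumsum(c(1L, as.integer(starts[-1L] > cummax(ends)[-length(ends)])))
  out <- NULL
  for (g in split(seq_along(starts), chain)) {
    lo <- min(starts[g]); hi <- max(ends[g])
    cov <- integer(hi - lo + 1L)
    for (i in g) {
      idx <- (starts[i]:ends[i]) - lo + 1L
      cov[idx] <- cov[idx] + 1L
    }
    at_max <- which(cov == max(cov))
    out <- rbind(out, data.frame(
      start = lo, end = hi,
      core_start = min(at_max) + lo - 1L, core_end = max(at_max) + lo - 1L))
  }
  rownames(out) <- NULL
  out
}
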