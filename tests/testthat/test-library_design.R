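test_that("tiling geometry matches closed-form count and brute-force enumeration", {
  p <- toy_protein(400L)
  # divisible geometry: count == (end - length + 1 - start)/offset + 1
  withr::with_seed(421, {
    for (i in 1:25) {
      len <- sample(8:25, 1)
      off <- sample(seq_len(len), 1)
      start <- sample(1:50, 1)
      k <- sample(1:12, 1)
      end <- start + len - 1L + k * off       # on-grid region
      r <- tiling_region("r", start, end)
      lib <- tile_peptides(p, r, length = len, offset = off)
      expect_identical(nrow(lib), as.integer((end - len + 1 - start) / off + 1))
      expect_identical(lib$start, seq.int(start, end - len + 1L, by = off))
      # brute force: every on-grid start s with s + len - 1 <= end
      cand <- start:(end - len + 1L)
      expect_identical(lib$start, cand[(cand - start) %% off == 0L])
      # full length, coverage, exact overlap
      expect_true(all(lib$end - lib$start + 1L == len))
      covered <- sort(unique(unlist(Map(seq.int, lib$start, lib$end))))
      expect_identical(covered, start:end)
      if (nrow(lib) > 1)
        expect_true(all(lib$end[-nrow(lib)] - lib$start[-1] + 1L == len - off))
    }
  })
})

test_that("off-grid regions emit a warned final full-length peptide at the region end", {
  p <- toy_protein(100L)
  r <- tiling_region("r", 1, 27)  # (27 - 20 + 1 - 1) = 7, not divisible by 5
  expect_warning(lib <- tile_peptides(p, r, 20, 5),
                 class = "off_grid_final_peptide")
  expect_identical(lib$start, c(1L, 6L, 8L))
  expect_identical(lib$end[nrow(lib)], 27L)
})

test_that("degenerate and invalid regions are handled", {
  p <- toy_protein(100L)
  # single-window region
  lib <- tile_peptides(p, tiling_region("r", 11, 30), 20, 5)
  expect_identical(nrow(lib), 1L)
  expect_identical(c(lib$start, lib$end), c(11L, 30L))
  # too short
  expect_error(tile_peptides(p, tiling_region("r", 1, 10), 20, 5),
               class = "region_too_short")
  # outside the protein's numbered span
  off_p <- toy_protein(50L, offset = 100L)
  expect_error(tile_peptides(off_p, tiling_region("r", 1, 40), 20, 5),
               class = "outside_protein")
})

test_that("peptide sequences equal the protein substring at their coordinates", {
  p <- toy_protein(120L, offset = 31L)
  lib <- tile_peptides(p, tiling_region("r", 31, 150), 20, 5)
  for (i in seq_len(nrow(lib))) {
    idx <- lib$start[i] - 31L + 1L
    expect_identical(lib$sequence[i], substr(p$residues, idx, idx + 19L))
  }
})

test_that("naming uses domains, compound labels for straddlers, continuous numbering", {
  p <- toy_protein(200L)
  dom <- data.frame(label = c("A", "B"), start = c(1L, 61L), end = c(60L, 140L))
  r <- tiling_region("r", 1, 140, domains = dom)
  lib <- name_peptides(tile_peptides(p, r, 20, 5), r)
  expect_identical(lib$name[1], "A1")
  # peptide 9 spans 41-60: fully inside A; peptide 10 spans 46-65: straddler
  expect_identical(lib$name[9], "A9")
  expect_identical(lib$name[10], "A/B10")
  # exactly half in each annotation -> compound, N-terminal domain first
  straddle <- lib[lib$start == 51L, ]  # 51-70: 10 residues in A, 10 in B
  expect_identical(straddle$name, "A/B11")
  # numbering continuous across the region
  expect_identical(lib$index, seq_len(nrow(lib)))
  # labels ending in a digit get a space before the index
  dom2 <- data.frame(label = c("TSP1"), start = 1L, end = 140L)
  r2 <- tiling_region("r", 1, 140, domains = dom2)
  lib2 <- name_peptides(tile_peptides(p, r2, 20, 5), r2)
  expect_identical(lib2$name[1], "TSP1 1")
})

test_that("peptides outside all annotations error as unannotated", {
  p <- toy_protein(200L)
  r <- tiling_region("r", 1, 140,
                     domains = data.frame(label = "A", start = 1L, end = 100L))
  expect_error(suppressWarnings(name_peptides(tile_peptides(p, r, 20, 5), r)),
               class = "unannotated_span")
})

test_that("packaged fixtures reproduce the 105-peptide proximal-domain library", {
  lib <- design_library(adamts13_proximal(), adamts13_regions())
  expect_identical(nrow(lib), 105L)
  expect_identical(sum(lib$region == "MP-Dis"), 59L)
  expect_identical(sum(lib$region == "Cys-Spa"), 46L)
  expect_identical(lib$name[1], "MP1")
  expect_identical(lib$sequence[1], "AAGGILHLELLVAVGPDVFQ")
  expect_identical(c(lib$start[1], lib$end[1]), c(75L, 94L))
  expect_identical(lib$name[59], "Dis/TSP1 59")
  expect_identical(tail(lib$start, 1), 665L)
  expect_identical(tail(lib$end, 1), 684L)
})

test_that("library FASTA/TSV writing round-trips and rejects collisions", {
  lib <- design_library(adamts13_proximal(), adamts13_regions())
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_peptide_library(lib, fasta = fa, tsv = tsv)
  aa <- Biostrings::readAAStringSet(fa)
  expect_length(aa, 105L)
  back <- read_peptide_library(tsv)
  expect_identical(as.data.frame(back), as.data.frame(lib))
  lib2 <- lib; lib2$name[2] <- lib2$name[1]
  expect_error(write_peptide_library(lib2, tsv = tempfile()),
               class = "name_collision")
  expect_error(design_library(adamts13_proximal(), list()),
               class = "empty_regions")
})
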