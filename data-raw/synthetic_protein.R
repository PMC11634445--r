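# Builds the packaged synthetic ADAMTS13 proximal-region fixture.
#
# No ADAMTS13 accession is bundled with this package. The fixture sequence is
# a SYNTHETIC stand-in assembled from published peptide fragments of the
# proximal domains (metalloprotease, disintegrin-like, cysteine-rich, spacer):
# fragments whose printed coordinates and lengths agree are laid onto a
# 75..684 scaffold; positions not covered by any internally consistent
# fragment are filled with deterministic pseudo-random residues (seed 13).
# The geometry (region bounds, domain bounds) is exact; the filled residues
# are placeholders, which is irrelevant to every computation in the package
# except cosmetic sequence display for unanchored spans.
#
# Run from the package root: Rscript data-raw/synthetic_protein.R

anchors <- list(
  # fragment, start, end (1-based inclusive, full-length ADAMTS13 numbering)
  list("AAGGILHLELLVAVGPDVFQ", 75, 94),
  list("LHLELLVAVGPDVFQAHQEDTERYVLTNLNIGAELLRDPSLGAQFRVHLV", 80, 129),
  list("LRDPSLGAQFRVHLVKMVILTEPEG", 115, 139),
  list("TINPEDDTDPGHADLVLYITRFDLELPDGNRQVRG", 160, 194),
  list("DDTDPGHADLVLYITRFDLELPDGN", 165, 189),
  list("DDTDPGHADLVLYITRFDLELPDGNRQVRG", 165, 194),
  list("DGAPGSGCGPSGHVMASDGAAPRAGLAWSPCSRRQ", 235, 269),
  list("APRAGLAWSPCSRRQLLSLLSAGRARCVWD", 255, 284),
  list("APRAGLAWSPCSRRQLLSLLSAGRARCVWDPPRPQ", 255, 289),
  list("SAGRARCVWDPPRPQPGSAGHPPDAQPGLYYSANE", 275, 309),
  list("PPRPQPGSAGHPPDAQPGLYYSANEQCRVAFGPKA", 285, 319),
  list("PGSAGHPPDAQPGLYYSANEQCRVAFGPKAVACTF", 290, 324),
  list("FGPKAVACTFAREHLDMCQALSCHTDPLDQSSCSR", 315, 349),
  list("WCSKGRCRSLVELTPIAAVH", 365, 384),
  list("KTQLEFMSQQCARTDGQPLRSSPGGASFYHWGAAV", 440, 474),
  list("FMSQQCARTDGQPLRSSPGGASFYHWGAAVPHSQG", 445, 479),
  list("CARTDGQPLRSSPGGASFYHWGAAVPHSQG", 450, 479),
  list("DSFLDGTRCMPSGPREDGTLSLCVSGSCRTFGCDG", 500, 534),
  list("CSPRKGSFTAGRAREYVTFLTVTPNLTSVYIANHRPLFTH", 555, 594),
  list("PLFTHLAVRIGGRYVVAGKMSISPNTTYPSLLEDG", 590, 624),
  list("PLFTHLAVRIGGRYVVAGKMSISPNTTYPSLLEDGRVEYRVALTEDRLPRLEEIRIWGPL", 590, 649),
  list("LLEDGRVEYRVALTEDRLPRLEEIRIWGPLQEDAD", 620, 654),
  list("IWGPLQEDADIQVYRRYGEEYGNLTRPDITFTYFQPKPRQ", 645, 684)
)

off <- 75L
scaffold <- rep(NA_character_, 684L - off + 1L)
for (a in anchors) {
  seqv <- strsplit(a[[1]], "")[[1]]
  stopifnot(length(seqv) == a[[3]] - a[[2]] + 1L)
  idx <- (a[[2]]:a[[3]]) - off + 1L
  clash <- !is.na(scaffold[idx]) & scaffold[idx] != seqv
  if (any(clash)) {
    stop("anchor conflict at positions ",
         paste(which(clash) + off - 1L, collapse = ", "))
  }
  scaffold[idx] <- seqv
}
message(sum(is.na(scaffold)), " of ", length(scaffold),
        " positions filled with placeholder residues")

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
set.seed(13)
scaffold[is.na(scaffold)] <- sample(aa20, sum(is.na(scaffold)), replace = TRUE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

fa <- file.path("inst/extdata", "adamts13_proximal_synthetic.fasta")
lines <- c(
  ">ADAMTS13_proximal_synthetic offset=75 (synthetic scaffold; see package docs)",
  substring(paste(scaffold, collapse = ""),
            seq(1, length(scaffold), 60),
            pmin(seq(1, length(scaffold), 60) + 59, length(scaffold)))
)
writeLines(lines, fa)

# Tiling regions + domain sub-annotations. Region ends 384/684 follow the
# published peptide coordinates (last peptides end at 384 and 684) rather
# than the domain-table ends 383/680. Domain boundaries are inferred from
# which peptides carry simple vs. compound names:
#   MP|Dis between 285/286; Dis|TSP1 at 383/384; Cys|Spa between 549/550
#   (midpoint of the feasible 545..554 window); Spa|TSP2 at 680/681.
dom <- data.frame(
  region = c("MP-Dis", "MP-Dis", "MP-Dis", "Cys-Spa", "Cys-Spa", "Cys-Spa"),
  region_start = c(75L, 75L, 75L, 440L, 440L, 440L),
  region_end = c(384L, 384L, 384L, 684L, 684L, 684L),
  label = c("MP", "Dis", "TSP1", "Cys", "Spa", "TSP2"),
  start = c(75L, 286L, 384L, 440L, 550L, 681L),
  end = c(285L, 383L, 384L, 549L, 680L, 684L)
)
write.table(dom, file.path("inst/extdata", "adamts13_domains_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("fixtures written to inst/extdata/")
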