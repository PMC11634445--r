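test_that("overlapping positive peptides merge; gaps and adjacency do not", {
  # MP9 (115-134) + MP10 (120-139) -> one region 115-139, core 120-134
  r <- merge_positive_peptides(make_calls(c(115, 120)))
  expect_identical(c(r$start, r$end), c(115L, 139L))
  expect_identical(c(r$core_start, r$core_end), c(120L, 134L))
  expect_identical(r$peptides, "pep01,pep02")
  # single positive peptide: region equals its span, core equals region
  r1 <- merge_positive_peptides(make_calls(200))
  expect_identical(unlist(r1[, 1:4], use.names = FALSE),
                   c(200L, 219L, 200L, 219L))
  # separated by a negative gap peptide: two regions
  r2 <- merge_positive_peptides(make_calls(c(100, 120, 160),
                                           positive = c(TRUE, FALSE, TRUE)))
  expect_identical(nrow(r2), 2L)
  # adjacent but zero shared residues: NOT merged
  r3 <- merge_positive_peptides(make_calls(c(100, 120), ends = c(119, 139)))
  expect_identical(nrow(r3), 2L)
  # no positives: empty frame
  expect_identical(nrow(merge_positive_peptides(make_calls(100, positive = FALSE))), 0L)
})

test_that("merging is idempotent and order-independent", {
  withr::with_seed(7, {
    for (i in 1:20) {
      starts <- sample(seq(1, 200, 5), sample(3:12, 1))
      calls <- make_calls(starts)
      ref <- merge_positive_peptides(calls)
      perm <- calls[sample(nrow(calls)), ]
      expect_identical(merge_positive_peptides(perm), ref)
    }
  })
})

test_that("max-coverage core matches hand-derived cases and intersection mode", {
  # five consecutive spacer 20-mers starting 645..665: max coverage 4 at 660-669
  expect_identical(core_epitope(seq(645, 665, 5), seq(664, 684, 5)),
                   c(660L, 669L))
  # single peptide
  expect_identical(core_epitope(300, 319), c(300L, 319L))
  # strict intersection of two peptides
  expect_identical(core_epitope(c(115, 120), c(134, 139), mode = "intersection"),
                   c(120L, 134L))
  # empty intersection falls back to max coverage with a warning
  expect_warning(
    core <- core_epitope(seq(645, 665, 5), seq(664, 684, 5),
                         mode = "intersection"),
    class = "empty_intersection")
  expect_identical(core, c(660L, 669L))
})

test_that("regions and cores match the brute-force per-residue oracle", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(1:30, 1)
      len <- sample(6:20, 1)
      off <- sample(1:len, 1)
      starts <- sort(sample(seq(1, 60 * off, off), n, replace = FALSE))
      ends <- starts + len - 1L
      got <- merge_positive_peptides(make_calls(starts, ends))
      want <- brute_regions(starts, ends)
      expect_identical(got[, c("start", "end", "core_start", "core_end")],
                       want, info = sprintf("case %d", i))
      # invariants: span is the union of members; core inside region
      expect_true(all(got$core_start >= got$start & got$core_end <= got$end))
    }
  })
})

dom4 <- data.frame(label = c("MP", "Dis", "Cys", "Spa"),
                   start = c(75L, 286L, 440L, 550L),
                   end = c(285L, 383L, 549L, 680L))

test_that("domain reactivity categories follow the proximal-domain convention", {
  expect_identical(classify_domains(make_calls(100), dom4)$category, "MP_only")
  expect_identical(classify_domains(make_calls(c(100, 300, 460, 600)), dom4)$category,
                   "all_four")
  # a single straddling peptide makes both flanking domains reactive
  straddle <- classify_domains(make_calls(275), dom4)
  expect_setequal(straddle$reactive_domains, c("MP", "Dis"))
  expect_identical(straddle$category, "MP_and_Dis")
  expect_identical(classify_domains(make_calls(100, positive = FALSE), dom4)$category,
                   "none")
  expect_identical(classify_domains(make_calls(c(460, 600)), dom4)$category,
                   "Cys_and_Spa")
})

test_that("cohort pooling computes frequencies, sharing and category totals", {
  # 10 patients; region planted in 3 -> frequency 0.3, not shared at 0.5
  calls <- do.call(rbind, lapply(1:10, function(i) {
    make_calls(c(100, 460), positive = c(i <= 3, TRUE),
               patient = sprintf("PT%02d", i))
  }))
  m <- epitope_map(calls, dom4)
  reg <- m$cohort_regions
  r100 <- reg[reg$start == 100, ]
  expect_equal(r100$frequency, 0.3)
  expect_false(r100$shared)
  r460 <- reg[reg$start == 460, ]
  expect_equal(r460$frequency, 1.0)
  expect_true(r460$shared)
  # category counts sum to cohort size
  expect_identical(sum(m$category_counts$n), 10L)
  # cohort of 1: every region at frequency 1
  m1 <- epitope_map(make_calls(c(100, 460)), dom4)
  expect_true(all(m1$cohort_regions$frequency == 1))
})

test_that("report tables have the conventional layout and whole-number percents", {
  calls <- do.call(rbind, lapply(1:10, function(i)
    make_calls(c(100, 460, 600), patient = sprintf("PT%02d", i))))
  tabs <- report_tables(epitope_map(calls, dom4))
  expect_identical(nrow(tabs$domain_reactivity), 7L)
  expect_identical(tabs$domain_reactivity$percent[1], "100%") # MP only (no Dis)
  expect_identical(tabs$domain_reactivity$percent[3], "0%")   # MP and Dis
  expect_identical(tabs$domain_reactivity$percent[6], "100%") # Cys and Spa
  # rounding convention: 53 of 59 prints as 90%
  expect_identical(pepscanr:::fmt_pct(53, 59), "90%")
  # deterministic ordering by start
  expect_true(!is.unsorted(tabs$regions$start))
})
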