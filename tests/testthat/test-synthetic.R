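small_cfg <- function(...) synthetic_config(n_patients = 6L, seed = 42L, ...)

test_that("generation is deterministic under a seed and leaves the RNG alone", {
  set.seed(1); before <- runif(1)
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(a$wells, b$wells)
  expect_identical(a$mixing, b$mixing)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(synthetic_config(n_patients = 6L, seed = 43L))
  expect_false(identical(a$wells$od, c$wells$od))
  # caller RNG stream unaffected by the generator
  set.seed(1); runif(1)
  expect_identical(runif(1), { set.seed(1); runif(2)[2] })
  # written outputs are byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(small_cfg(), dir = d1)
  generate_cohort(small_cfg(), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_patients = 0), class = "bad_argument")
  expect_error(synthetic_config(bu_mixture = data.frame(
    weight = c(0.5, 0.2), meanlog = c(0, 1), sdlog = c(1, 1))),
    class = "bad_config")
})

test_that("noiseless step model lights exactly the peptides overlapping the epitope", {
  cfg <- synthetic_config(
    n_patients = 1L, seed = 1L, noise_sd = 0, activity_noise_sd = 0,
    epitope_catalog = data.frame(start = 650L, end = 669L, frequency = 1))
  co <- generate_cohort(cfg)
  calls <- call_plates(co$wells, library = co$library)
  # brute-force enumeration: 20-mers starting 440 + 5k with >= 10 residues
  # inside 650-669 are exactly those starting 640..660
  want <- co$library$start >= 640 & co$library$start <= 660
  expect_identical(calls$positive[match(co$library$name, calls$peptide)], want)
})

test_that("noiseless pipeline output equals the closed-form expectation", {
  cfg <- synthetic_config(
    n_patients = 4L, seed = 9L, noise_sd = 0, activity_noise_sd = 0,
    epitope_catalog = data.frame(start = c(165L, 520L), end = c(189L, 554L),
                                 frequency = c(1, 1)))
  co <- generate_cohort(cfg)
  calls <- call_plates(co$wells, library = co$library)
  map <- epitope_map(calls, adamts13_regions())
  # positives run 155..180 and 510..545 (a 20-mer starting at 510 overlaps
  # 520-554 by exactly the 10-residue threshold) -> regions 155-199 /
  # 510-564, max-coverage cores 170-184 / 525-549
  reg <- map$cohort_regions
  expect_identical(reg$start, c(155L, 510L))
  expect_identical(reg$end, c(199L, 564L))
  expect_identical(reg$core_start, c(170L, 525L))
  expect_identical(reg$core_end, c(184L, 549L))
  expect_true(all(reg$frequency == 1))
  bu <- bethesda_all(co$mixing)
  rec <- score_recovery(co, map, bu = bu)
  # interior epitopes: core midpoint within offset/2 of the planted midpoint
  expect_true(all(rec$epitopes$midpoint_error <= 2.5))
  expect_equal(rec$epitope_recovery_rate, 1)
  expect_equal(rec$region_sensitivity, 1)
  expect_equal(rec$region_precision, 1)
  # noiseless Bethesda titres are exact
  i <- match(bu$patient_id, co$truth$inhibitor$patient_id)
  quant <- bu$bu_per_ml > 0
  expect_equal(bu$bu_per_ml[quant], co$truth$inhibitor$true_bu[i][quant],
               tolerance = 1e-9)
})

test_that("scoring a map built from the truth itself is perfect", {
  co <- generate_cohort(small_cfg())
  truth <- co$truth$epitopes
  calls <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
    make_calls(truth$start[i], truth$end[i], patient = truth$patient_id[i],
               names = sprintf("t%d", i))))
  map <- epitope_map(calls, adamts13_regions(),
                     cohort_size = co$config$n_patients)
  rec <- score_recovery(co, map)
  expect_equal(rec$epitope_recovery_rate, 1)
  expect_equal(rec$mean_midpoint_error, 0)
  expect_equal(rec$region_sensitivity, 1)
  expect_equal(rec$region_precision, 1)
})

test_that("raising plate noise degrades mean epitope recovery", {
  rate <- function(noise, seeds = 1:3) {
    mean(vapply(seeds, function(s) {
      co <- generate_cohort(synthetic_config(n_patients = 8L, seed = s,
                                             noise_sd = noise))
      calls <- suppressWarnings(call_plates(co$wells, library = co$library))
      score_recovery(co, epitope_map(calls, adamts13_regions()))$epitope_recovery_rate
    }, numeric(1)))
  }
  r_lo <- rate(0.02); r_mid <- rate(0.15); r_hi <- rate(0.40)
  # monotone within Monte-Carlo slack
  expect_lte(r_mid, r_lo + 0.05)
  expect_lte(r_hi, r_mid + 0.05)
  expect_lt(r_hi, r_lo)
})
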