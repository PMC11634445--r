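test_that("residual activity is the mix-to-control ratio in percent", {
  expect_equal(residual_activity(50, 100), 50)
  expect_equal(residual_activity(30, 100), 30)   # in the inhibitor band
  expect_equal(residual_activity(80, 100), 80)   # above: no significant inhibitor
  expect_equal(residual_activity(45, 90), 50)
  expect_error(residual_activity(50, 0), class = "invalid_control")
})

test_that("Bethesda closed form: 50% residual activity is exactly one unit", {
  expect_identical(bu_from_residual(50), 1)
  expect_identical(bu_from_residual(100), 0)
  expect_identical(bu_from_residual(25), 2)
  expect_error(bu_from_residual(0), class = "no_residual_activity")
})

test_that("residual activity and Bethesda units round-trip to machine precision", {
  ra <- c(1e-6, seq(0.5, 100, length.out = 400))
  expect_equal(residual_from_bu(bu_from_residual(ra)), ra, tolerance = 1e-12)
  bu <- bu_from_residual(ra)
  expect_true(all(diff(bu) < 0))  # strictly decreasing in RA
})

test_that("titration picks the in-band dilution closest to 50% residual activity", {
  one <- function(dil, mix, pnp = 100)
    data.frame(dilution = dil, mix_activity = mix, pnp_activity = pnp)
  # neat measurement at RA 50 -> 1 BU/mL
  expect_equal(bethesda_titre(one(1, 50))$bu_per_ml, 1)
  # RA 50 at 8-fold dilution -> 8 BU/mL
  expect_equal(bethesda_titre(one(8, 50))$bu_per_ml, 8)
  # ladder: only dilution 16 in band, BU = log2(100/55) * 16
  lad <- one(c(1, 4, 16), c(5, 20, 55))
  r <- bethesda_titre(lad)
  expect_equal(r$chosen_dilution, 16)
  expect_equal(r$bu_per_ml, log2(100 / 55) * 16, tolerance = 1e-12)
  expect_equal(r$bu_per_ml, 13.8, tolerance = 0.01)
  expect_identical(r$classification, "strong")
  # band ends are inclusive; ties in |RA - 50| go to the lower dilution
  expect_equal(bethesda_titre(one(2, 75))$chosen_dilution, 2)
  expect_equal(bethesda_titre(one(c(2, 4), c(45, 55)))$chosen_dilution, 2)
  # all above 75: no significant inhibitor, 0 BU/mL
  r0 <- bethesda_titre(one(c(1, 2), c(85, 92)))
  expect_identical(r0$bu_per_ml, 0)
  expect_identical(r0$interpretation, "no_significant_inhibitor")
  # all below 25: needs further dilution
  expect_error(bethesda_titre(one(c(1, 2), c(5, 10))),
               class = "needs_further_dilution")
  expect_error(bethesda_titre(one(numeric(0), numeric(0), numeric(0))),
               class = "empty_series")
  expect_error(bethesda_titre(one(c(2, 2), c(40, 50))),
               class = "duplicate_dilutions")
})

test_that("classification partitions the titre axis with published group medians", {
  expect_identical(classify_inhibitor(0.3), "non_inhibitory")
  expect_identical(classify_inhibitor(1.85), "low")   # low-group median
  expect_identical(classify_inhibitor(9.74), "strong")  # strong-group median
  # boundaries: 0.5 is low, 5 is low, just above 5 is strong
  expect_identical(classify_inhibitor(c(0.4999, 0.5, 5, 5.0001)),
                   c("non_inhibitory", "low", "low", "strong"))
  # partition: every non-negative titre gets exactly one class
  withr::with_seed(5, bu <- c(0, 0.5, 5, runif(500, 0, 30)))
  cls <- classify_inhibitor(bu)
  expect_true(all(cls %in% c("non_inhibitory", "low", "strong")))
  expect_identical(cls, classify_inhibitor(bu))  # deterministic
})

test_that("noiseless dilution ladders recover the planted titre", {
  for (true_bu in c(0.7, 1.85, 4.2, 9.74, 20)) {
    d <- c(1, 2, 4, 8, 16, 32, 64)
    series <- data.frame(dilution = d, mix_activity = 100 * 2^(-true_bu / d),
                         pnp_activity = 100)
    est <- bethesda_titre(series)$bu_per_ml
    expect_equal(est, true_bu, tolerance = 0.05 * true_bu)
  }
})

test_that("cohort batch titration survives unquantifiable patients", {
  mixing <- rbind(
    data.frame(patient_id = "A", dilution = 1, mix_activity = 50,
               pnp_activity = 100),
    data.frame(patient_id = "B", dilution = 1, mix_activity = 5,
               pnp_activity = 100))
  out <- bethesda_all(mixing)
  expect_equal(out$bu_per_ml[out$patient_id == "A"], 1)
  expect_identical(out$interpretation[out$patient_id == "B"], "out_of_band")
  expect_true(is.na(out$bu_per_ml[out$patient_id == "B"]))
})
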