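test_that("noiseless 4PL dose-response data are recovered exactly", {
  d <- gen_dose_response(1, ic50_gy = 4.3, hill = 1, top = 5000,
                         bottom = 0, noise = "none", noise_scale = 0)
  f <- fit_dose_response(d)
  expect_true(f$converged)
  expect_lt(rel_err(f$ic50, 4.3), 1e-6)
  expect_lt(rel_err(f$hill_slope, 1), 1e-5)
  expect_lte(f$bottom, f$top)
})

test_that("dose-response fit matches the 2-D grid oracle on a noisy experiment", {
  d <- gen_dose_response(7)
  f <- fit_dose_response(d)
  o <- oracle_dose_response(d, ic50_grid = seq(3.5, 5.2, by = 0.005),
                            hill_grid = seq(0.6, 1.6, by = 0.01))
  expect_lt(rel_err(f$ic50, o$ic50), 0.01)
})

test_that("radiation IC50 recovery is unbiased across seeds", {
  ic <- sapply(1:50, function(s) fit_dose_response(gen_dose_response(s))$ic50)
  expect_lt(rel_err(median(ic), 4.3), 0.05)
})

test_that("a monotone-increasing response is flagged as no inhibition", {
  dose <- c(0, 2, 4, 6, 8)
  resp <- cbind(c(100, 150, 220, 300, 380))
  d <- dose_response_dataset(dose, resp)
  f <- fit_dose_response(d)
  expect_false(f$converged)
  expect_match(f$diagnostics, "no inhibition")
})

test_that("the ten-dose grid with the extra 0.05 Gy point is accepted", {
  d <- gen_dose_response(3, dose = c(0, 0.05, 0.2, 2, 4, 6, 8, 10, 15, 30),
                         noise = "none", noise_scale = 0)
  f <- fit_dose_response(d)
  expect_lt(rel_err(f$ic50, 4.3), 1e-6)
})

test_that("delta-delta-Ct reproduces the hand-worked fold change", {
  # sample A: target Ct 20, reference mean Ct 18 -> dCt 2
  # calibrator B: dCt 4 -> ddCt = -2 -> fold 4
  tab <- ct_table(sample = rep(c("A", "B"), each = 3),
                  gene = rep(c("ITGB6", "UBC", "GAPDH"), 2),
                  ct = c(20, 17, 19, 24, 19, 21))
  out <- suppressWarnings(ddct_normalize(tab, calibrator = "B"))
  expect_equal(out$fold[out$sample == "A"], 4.0)
  expect_equal(out$fold[out$sample == "B"], 1.0)  # calibrator identity
})

test_that("delta-delta-Ct is invariant to a common Ct shift within a sample", {
  base <- ct_table(sample = rep(c("A", "B"), each = 3),
                   gene = rep(c("ITGB6", "UBC", "GAPDH"), 2),
                   ct = c(22, 18, 20, 25, 20, 22))
  shifted <- ct_table(sample = rep(c("A", "B"), each = 3),
                      gene = rep(c("ITGB6", "UBC", "GAPDH"), 2),
                      ct = c(23, 19, 21, 25, 20, 22))  # sample A +1 cycle
  f0 <- suppressWarnings(ddct_normalize(base, "B"))
  f1 <- suppressWarnings(ddct_normalize(shifted, "B"))
  expect_equal(f1$fold, f0$fold)
})

test_that("replicate Ct values are averaged and singletons warn", {
  tab <- ct_table(sample = rep("A", 7),
                  gene = c("ITGB6", "ITGB6", "ITGB6", "UBC", "UBC",
                           "GAPDH", "GAPDH"),
                  ct = c(19, 20, 21, 18, 18, 18, 18))
  out <- ddct_normalize(tab, "A")
  expect_equal(out$delta_ct, 2)  # mean target 20 - mean refs 18
  single <- ct_table(sample = "A", gene = c("ITGB6", "UBC", "GAPDH"),
                     ct = c(20, 18, 18))
  expect_warning(ddct_normalize(single, "A"), "single-replicate")
})

test_that("a sample missing a reference gene is rejected by name", {
  expect_error(
    ct_table(sample = c("A", "A", "B"), gene = c("ITGB6", "UBC", "ITGB6"),
             ct = c(20, 18, 21)),
    "A.*GAPDH|GAPDH")
})
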