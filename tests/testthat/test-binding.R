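test_that("noiseless one-site saturation data are recovered exactly", {
  d <- gen_saturation(1, kd = 1.0, bmax_cpm = 1000, ns_slope = 10,
                      background = 0, noise = "none", noise_scale = 0)
  f <- fit_saturation(d)
  expect_true(f$converged)
  expect_lt(rel_err(f$kd, 1.0), 1e-6)
  expect_lt(rel_err(f$bmax_cpm, 1000), 1e-6)
  expect_lt(rel_err(f$ns_slope, 10), 1e-6)
})

test_that("saturation fit matches the profiled grid-search oracle on a noisy plate", {
  d <- gen_saturation(42)
  f <- fit_saturation(d)
  o <- oracle_saturation(d, kd_grid = seq(0.15, 0.6, by = 0.0005))
  expect_lt(rel_err(f$kd, o$kd), 0.01)
  expect_lt(rel_err(f$bmax_cpm, o$bmax), 0.01)
})

test_that("fitted specific binding is nonnegative at every design concentration", {
  for (s in 1:20) {
    d <- gen_saturation(s)
    f <- fit_saturation(d)
    expect_true(f$converged)
    specific <- f$bmax_cpm * d$ligand_conc / (f$kd + d$ligand_conc)
    expect_true(all(specific >= 0))
  }
})

test_that("saturation parameter recovery is unbiased across seeds", {
  fits <- lapply(1:50, function(s) fit_saturation(gen_saturation(s)))
  expect_lt(rel_err(median(sapply(fits, `[[`, "kd")), 0.30), 0.05)
  expect_lt(rel_err(median(sapply(fits, `[[`, "bmax_sites_per_cell")),
                    11874), 0.05)
})

test_that("degenerate saturation data raise an error", {
  z <- matrix(0, 12, 3)
  d <- saturation_dataset(default_ligand_conc(), z, z)
  expect_error(fit_saturation(d), "degenerate")
})

test_that("cpm to sites-per-cell evaluates the printed conversion", {
  # 2175 Ci/mmol * 2.22e12 dpm/Ci * 0.65 / 1e12 = 3138.525 cpm/fmol
  expect_equal(cpm_per_fmol(2175, 0.65), 3138.525)
  # 3138.525 cpm == 1 fmol -> 6.02e8 molecules / 50,000 cells
  expect_equal(cpm_to_sites_per_cell(3138.525, 2175, 0.65, 5e4), 12040)
  expect_equal(cpm_to_sites_per_cell(0, 2175, 0.65, 5e4), 0)
  # linear in 1/efficiency (suppress the narrative-value warning at 0.5)
  expect_equal(suppressWarnings(
    cpm_to_sites_per_cell(1000, 2175, 0.5, 5e4)),
    2 * cpm_to_sites_per_cell(1000, 2175, 1.0, 5e4))
  expect_error(cpm_to_sites_per_cell(1000, 2175, 0.65, 0), "cells")
  expect_error(cpm_to_sites_per_cell(1000, 2175, 1.5, 5e4), "efficiency")
})

test_that("cpm to concentration uses the assay volume correctly", {
  expect_equal(cpm_to_concentration(1e5, 2175, 0.65, 100),
               1e5 / 3138.525 / 100, tolerance = 1e-12)
  expect_equal(round(cpm_to_concentration(1e5, 2175, 0.65, 100), 3), 0.319)
  expect_equal(cpm_to_concentration(0, 2175, 0.65, 100), 0)
  expect_equal(cpm_to_concentration(1e5, 2175, 0.65, 50),
               2 * cpm_to_concentration(1e5, 2175, 0.65, 100))
  expect_error(cpm_to_concentration(1e5, 2175, 0.65, 0), "volume")
})

test_that("noiseless displacement curve recovers logIC50 exactly", {
  d <- gen_competition(1, ic50_nm = 1, top = 1e5, bottom = 5e3,
                       noise = "none", noise_scale = 0)
  f <- fit_competition(d)
  expect_true(f$converged)
  expect_equal(f$log_ic50, -9, tolerance = 1e-6)
  expect_equal(f$ic50_nm, 1, tolerance = 1e-5)
  expect_lte(f$bottom, f$top)
})

test_that("competition fit matches the 1-D grid oracle on a noisy plate", {
  d <- gen_competition(42)
  f <- fit_competition(d)
  o <- oracle_competition(d)
  expect_lt(abs(f$log_ic50 - o$log_ic50), 0.02)
})

test_that("competition Ki recovery is unbiased across seeds", {
  ki <- sapply(1:50, function(s)
    fit_competition(gen_competition(s, ki_nm = 9.46, kd_nm = 0.75),
                    kd = 0.75)$ki_nm)
  expect_lt(rel_err(median(ki), 9.46), 0.05)
})

test_that("a flat displacement curve is flagged, not silently fitted", {
  d <- competition_dataset(default_competitor_conc(),
                           matrix(10000, 12, 3))
  f <- fit_competition(d)
  expect_false(f$converged)
  expect_match(f$diagnostics, "displacement|flat")
})

test_that("Cheng-Prusoff correction behaves as the occupancy model requires", {
  expect_equal(cheng_prusoff(5, 0, 0.3), 5)          # no hot ligand
  expect_equal(cheng_prusoff(2.0, 0.319, 0.30), 2.0 / (1 + 0.319 / 0.30))
  expect_equal(round(cheng_prusoff(2.0, 0.319, 0.30), 3), 0.969)
  hots <- seq(0, 5, by = 0.5)
  kis <- cheng_prusoff(2.0, hots, 0.30)
  expect_true(all(diff(kis) < 0))                    # strictly decreasing
  expect_true(all(kis[hots > 0] < 2.0))              # Ki < IC50 iff hot > 0
  expect_error(cheng_prusoff(2, 0.3, 0), "kd")
})

test_that("fitted Ki never exceeds the fitted IC50 when hot ligand is present", {
  for (s in 1:10) {
    f <- fit_competition(gen_competition(s), kd = 0.30)
    expect_true(f$hot_conc_nm > 0)
    expect_lt(f$ki_nm, f$ic50_nm)
  }
})
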