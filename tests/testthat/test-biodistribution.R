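ref_tac_table <- function() reference_biodistribution()

one_row_table <- function(cpm, mass = 0.25, std = 2000, frac = 0.01) {
  biodistribution_table(data.frame(
    animal = "m1", organ = "tumor", time_h = 24, mass_g = mass,
    cpm = cpm, standard_cpm = std, standard_fraction = frac,
    count_offset_h = 24))
}

test_that("counter rows reduce to the hand-computed %IA/g", {
  # 500 cpm sample; 2000 cpm standard representing 1% of the injection
  # -> whole-injection equivalent 200,000 cpm; 0.25 g sample
  out <- compute_pia_per_gram(one_row_table(500))
  expect_equal(out$pia_per_g, (500 / 2e5) * 100 / 0.25)
  expect_equal(out$pia_per_g, 1.00)
})

test_that("reduction is linear in counts and inverse in mass", {
  expect_equal(compute_pia_per_gram(one_row_table(0))$pia_per_g, 0)
  expect_equal(compute_pia_per_gram(one_row_table(500, mass = 0.5))$pia_per_g,
               0.5)
  expect_warning(out <- compute_pia_per_gram(one_row_table(-10)),
                 "clamped")
  expect_equal(out$pia_per_g, 0)
})

test_that("explicit decay correction applies when sessions differ", {
  # standard counted at injection, sample 159.528 h later: one half-life
  tab <- one_row_table(250)
  tab$count_offset_h <- 159.528
  out <- compute_pia_per_gram(tab, standard_offset_h = 0)
  expect_equal(out$pia_per_g, 1.00, tolerance = 1e-9)
})

test_that("decay correction has the right fixed points and factors", {
  expect_equal(decay_correct(5, 0), 5)
  expect_equal(decay_correct(1, 159.528), 2)             # one half-life
  expect_equal(decay_correct(1, 24, 159.53), 2^(24 / 159.53))
  expect_equal(round(decay_correct(1, 24, 159.53), 3), 1.110)
  expect_equal(decay_correct(decay_correct(3, 48), 48, direction = "forward"),
               3)
  expect_error(decay_correct(1, 5, half_life_h = -1), "half_life")
})

test_that("zero-noise synthetic data round-trip to the reference kidney curve", {
  bt <- gen_biodistribution(1, sigma = 0)
  tac <- build_tac(bt, "kidney")
  expect_equal(tac$time_h, c(24, 48, 72, 192))
  expect_equal(tac$mean_pia_per_g, c(19.21, 12.50, 14.71, 2.28),
               tolerance = 1e-10)
  expect_equal(tac$sd, rep(0, 4))
  expect_equal(tac$n, rep(5L, 4))
})

test_that("time-activity curves are order-invariant and handle single animals", {
  bt <- gen_biodistribution(5)
  shuffled <- bt[withr::with_seed(9, sample(nrow(bt))), ]
  expect_equal(build_tac(bt, "liver")$mean_pia_per_g,
               build_tac(biodistribution_table(shuffled),
                         "liver")$mean_pia_per_g)
  single <- gen_biodistribution(2, n_animals = 1)
  tac <- build_tac(single, "tumor")
  expect_equal(tac$n, rep(1L, 4))
  expect_equal(tac$sd, rep(0, 4))
})

test_that("unknown organs are rejected with the vocabulary listed", {
  bt <- gen_biodistribution(3, sigma = 0)
  expect_error(build_tac(bt, "gallbladder"), "kidney")
  expect_equal(build_tac(bt, "Kidneys")$mean_pia_per_g[1], 19.21,
               tolerance = 1e-10)  # alias, case-insensitive, plural
})

test_that("tumor-to-organ ratios reproduce the published ratio cells", {
  curves <- lapply(
    setNames(nm = unique(ref_tac_table()$organ)), function(o) {
      d <- ref_tac_table()[ref_tac_table()$organ == o, ]
      time_activity_curve(o, d$time_h, d$mean)
    })
  r <- tumor_to_organ_ratios(curves)
  pick <- function(o, t) r$ratio_of_means[r$organ == o & r$time_h == t]
  expect_equal(round(pick("kidney", 72), 3), 0.235)       # printed 0.24
  expect_equal(round(pick("pancreas", 192), 2), 38.67)    # printed 38.69
  # ratio-of-means within 2% of the printed cells where rounding permits
  expect_lt(rel_err(pick("kidney", 72), 0.24), 0.02)
  expect_lt(rel_err(pick("kidney", 192), 0.51), 0.02)
  expect_lt(rel_err(pick("pancreas", 192), 38.69), 0.02)
  expect_lt(rel_err(pick("liver", 48), 13.58), 0.02)
})

test_that("ratio conventions degenerate correctly", {
  tum <- time_activity_curve("tumor", c(24, 48), c(2, 1))
  same <- time_activity_curve("liver", c(24, 48), c(2, 1))
  zero <- time_activity_curve("muscle", c(24, 48), c(0, 0))
  r <- tumor_to_organ_ratios(list(tum, same, zero))
  expect_equal(r$ratio_of_means[r$organ == "liver"], c(1, 1))
  expect_true(all(is.na(r$ratio_of_means[r$organ == "muscle"])))
})

test_that("per-animal pairing yields a mean-of-ratios alongside", {
  bt <- gen_biodistribution(11)
  r <- tumor_to_organ_ratios(bt, organs = "kidney")
  expect_true(all(c("mean_of_ratios", "sd_of_ratios") %in% names(r)))
  expect_true(all(r$mean_of_ratios > 0))
})

test_that("total recovered activity never exceeds the injection", {
  for (s in 1:5) {
    bt <- compute_pia_per_gram(gen_biodistribution(s))
    per_animal <- tapply(bt$pia_per_g * bt$mass_g / 100,
                         bt$animal, sum)  # fraction of IA in sampled organs
    expect_true(all(per_animal <= 1))
  }
})

test_that("reduced means converge to the generating means at large n", {
  means <- data.frame(organ = "tumor", time_h = 24, mean = 3.13)
  bt <- gen_biodistribution(77, organ_means = means, n_animals = 1000)
  tac <- build_tac(bt, "tumor")
  se <- 3.13 * sqrt(exp(0.25^2) - 1) / sqrt(1000)
  expect_lt(abs(tac$mean_pia_per_g - 3.13), 3 * se)
})
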