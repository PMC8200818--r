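masses <- mass_table()

test_that("uptake scaling to the human organ matches the closed form", {
  # (%IA/organ)_human = (%IA/g)_mouse * M_mouse(kg) * m(g)/M(kg)
  expect_equal(scale_uptake_to_human(19.21, masses, "kidney"),
               19.21 * 0.025 * 299 / 73.7)
  expect_equal(signif(scale_uptake_to_human(19.21, masses, "kidney"), 4),
               1.948)
  expect_equal(scale_uptake_to_human(0, masses, "kidney"), 0)
  expect_equal(scale_uptake_to_human(2 * 19.21, masses, "kidney"),
               2 * scale_uptake_to_human(19.21, masses, "kidney"))
  expect_error(scale_uptake_to_human(1, masses, "tail"), "organ mass")
})

test_that("time scaling follows the quarter-power rule", {
  expect_equal(scale_time_to_human(24, masses), 24 * (73.7 / 0.025)^0.25)
  expect_equal(signif(scale_time_to_human(24, masses), 4), 176.8)
  expect_equal(scale_time_to_human(0, masses), 0)
  same <- mass_table(mouse_body_kg = 70, human_body_kg = 70)
  expect_equal(scale_time_to_human(24, same), 24)  # identity at ratio 1
  # monotone increasing in the mass ratio
  ratios <- sapply(c(1, 10, 100, 1000), function(r)
    scale_time_to_human(24, mass_table(mouse_body_kg = 70 / r,
                                       human_body_kg = 70)))
  expect_true(all(diff(ratios) > 0))
})

test_that("mono-exponential fits recover noiseless decays exactly", {
  t <- c(24, 48, 72, 192)
  tac <- time_activity_curve("kidney", t, 5 * exp(-0.01 * t))
  for (resid in c("linear", "log")) {
    f <- fit_exponential(tac, model = "mono", residuals = resid)
    expect_lt(rel_err(f$amplitudes, 5), 1e-6)
    expect_lt(rel_err(f$rates, 0.01), 1e-6)
    expect_lt(rel_err(f$effective_half_life_h, log(2) / 0.01), 1e-6)
  }
})

test_that("log-residual mono fit equals the closed-form log-linear slope", {
  ref <- reference_biodistribution()
  kid <- ref[ref$organ == "kidney", ]
  f <- fit_exponential(time_activity_curve("kidney", kid$time_h, kid$mean),
                       model = "mono", residuals = "log")
  expect_lt(abs(f$rates - loglinear_lambda(kid$time_h, kid$mean)), 1e-6)
})

test_that("a bi-exponential fit degenerates gracefully on mono data", {
  t <- c(12, 24, 48, 96, 144, 192)
  y <- 3 * exp(-0.02 * t)
  tac <- time_activity_curve("tumor", t, y)
  fb <- fit_exponential(tac, model = "bi")
  pred <- sapply(t, function(tt) sum(fb$amplitudes * exp(-fb$rates * tt)))
  expect_lt(max(rel_err(pred, y)), 1e-5)
  expect_lt(rel_err(sum(fb$amplitudes), 3), 1e-4)
  # auto selection prefers mono on <= 4 points
  fa <- fit_exponential(time_activity_curve("tumor", t[1:4], y[1:4]))
  expect_equal(fa$model, "mono")
})

test_that("time-integrated activity matches the closed form and quadrature", {
  t <- c(24, 48, 96, 192)
  a0 <- 0.02; thalf_eff <- 54.6
  tac <- data.frame(time_h = t,
                    fraction_ia = a0 * exp(-log(2) / thalf_eff * t))
  f <- fit_exponential(tac, model = "mono")
  # floor inactive here: 54.6 h is faster than physical decay
  tau <- time_integrated_activity(f)
  expect_equal(tau$tau_h, a0 * thalf_eff / log(2), tolerance = 1e-6)
  expect_equal(round(tau$tau_h, 3), 1.575)
  tau_q <- time_integrated_activity(f, method = "trapezoid_plus_tail")
  expect_lt(rel_err(tau_q$tau_h, tau$tau_h), 1e-6)
  # independent quadrature oracle (dense trapezoid + analytic tail)
  grid <- seq(0, 10 * thalf_eff, length.out = 2e5)
  fx <- a0 * exp(-log(2) / thalf_eff * grid)
  oracle <- sum((fx[-1] + fx[-length(fx)]) / 2) * diff(grid[1:2]) +
    fx[length(fx)] / (log(2) / thalf_eff)
  expect_lt(rel_err(tau$tau_h, oracle), 1e-6)
})

test_that("zero amplitude integrates to zero tau", {
  f <- structure(list(model = "mono", amplitudes = 0, rates = 0.01,
                      effective_half_life_h = log(2) / 0.01,
                      rss = 0, aicc = NA, residuals = "linear",
                      converged = TRUE), class = "exponential_fit")
  expect_equal(time_integrated_activity(f)$tau_h, 0)
})

test_that("rates slower than physical decay are floored and tau stays bounded", {
  lambda_phys <- log(2) / 159.528
  f <- structure(list(model = "mono", amplitudes = 0.05,
                      rates = lambda_phys / 10,
                      effective_half_life_h = 10 * 159.528 / log(2),
                      rss = 0, aicc = NA, residuals = "linear",
                      converged = TRUE), class = "exponential_fit")
  expect_message(tau <- time_integrated_activity(f), "floored")
  expect_true(tau$floored)
  expect_equal(tau$tau_h, 0.05 / lambda_phys)
  expect_lte(tau$tau_h, 0.05 * 159.528 / log(2) + 1e-12)
  # a non-positive rate cannot be integrated to infinity
  f$rates <- 0
  expect_error(time_integrated_activity(f, physical_half_life_h = Inf),
               "non-integrable")
})

test_that("scaled residence times follow uptake for comparable organ masses", {
  ref <- reference_biodistribution()
  tau_for <- function(organ) {
    d <- ref[ref$organ == organ, ]
    tac <- time_activity_curve(organ, d$time_h, d$mean)
    f <- fit_exponential(extrapolate_tac_to_human(tac, masses, organ))
    suppressMessages(time_integrated_activity(f)$tau_h)
  }
  # kidney uptake (19.21 %IA/g at 24 h) dwarfs spleen (0.06) and liver
  # (0.24); with organ masses of the same order the tau ordering follows
  expect_gt(tau_for("kidney"), tau_for("spleen"))
  expect_gt(tau_for("kidney"), tau_for("liver"))
  # per unit organ mass the kidney also out-ranks muscle, whose huge
  # reference mass (28 kg) inflates its whole-organ tau
  expect_gt(tau_for("kidney") / 299, tau_for("muscle") / 28000)
})
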