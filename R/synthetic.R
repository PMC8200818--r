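## Seeded synthetic-data generators emulating each assay: one-site binding
## with linear nonspecific background, logistic displacement, 4PL
## dose-response, and lognormal per-animal scatter around organ
## time-activity curves. Every generator takes an explicit seed and leaves
## the global random state untouched.

apply_noise <- function(x, noise, scale) {
  if (scale == 0 || noise == "none") return(x)
  switch(noise,
    gaussian_cv = pmax(x * (1 + stats::rnorm(length(x), 0, scale)), 0),
    poisson_counts = stats::rpois(length(x), x),
    lognormal = x * stats::rlnorm(length(x), -scale^2 / 2, scale),
    stop("unknown noise model: ", noise))
}

default_ligand_conc <- function()
  c(0, 0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 15, 20)

default_competitor_conc <- function()
  c(0, 0.00001, 0.00003, 0.0001, 0.0003, 0.001, 0.003, 0.01, 0.03,
    0.1, 0.3, 1)

#' Generate a synthetic saturation binding plate
#'
#' Total and nonspecific counts from the one-site + linear-background
#' model at the standard 12-point ligand ladder, with configurable noise.
#' Defaults emulate the BxPC-3 assay (Kd 0.30 nM, Bmax 11,874 sites/cell
#' at 50,000 cells, counter efficiency 0.65) with 5% CV Gaussian counter
#' noise.
#'
#' @param seed integer seed (required; the global RNG state is preserved).
#' @param kd,ns_slope,background generating parameters (nM, cpm/nM, cpm).
#' @param bmax_cpm generating Bmax in cpm; if `NULL`, derived from
#'   `bmax_sites_per_cell` through the printed conversion.
#' @param bmax_sites_per_cell generating Bmax in sites/cell.
#' @param ligand_conc concentration ladder (nM).
#' @param replicates wells per concentration and condition.
#' @param noise `"gaussian_cv"`, `"poisson_counts"`, `"lognormal"` or
#'   `"none"`; `noise_scale` is the CV (or sigma).
#' @inheritParams saturation_dataset
#' @return a [saturation_dataset()].
#' @export
gen_saturation <- function(seed, kd = 0.30, bmax_cpm = NULL,
                           bmax_sites_per_cell = 11874,
                           ns_slope = 20, background = 50,
                           ligand_conc = default_ligand_conc(),
                           replicates = 3,
                           noise = "gaussian_cv", noise_scale = 0.05,
                           cells_seeded = 5e4, counter_efficiency = 0.65,
                           specific_activity = 2175) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (kd <= 0 || ns_slope < 0 || background < 0 || noise_scale < 0)
    stop("invalid generating parameters")
  if (is.null(bmax_cpm)) {
    cpf <- cpm_per_fmol(specific_activity, counter_efficiency)
    bmax_cpm <- bmax_sites_per_cell * cells_seeded / 6.02e8 * cpf
  }
  specific <- bmax_cpm * ligand_conc / (kd + ligand_conc)
  nsb <- ns_slope * ligand_conc + background
  withr::with_seed(seed, {
    tot <- replicate(replicates, apply_noise(specific + nsb, noise,
                                             noise_scale))
    nsp <- replicate(replicates, apply_noise(nsb, noise, noise_scale))
    saturation_dataset(ligand_conc, tot, nsp, cells_seeded,
                       counter_efficiency, specific_activity)
  })
}

#' Generate a synthetic competition binding plate
#'
#' Logistic one-site displacement counts at the standard 12-point
#' competitor ladder. The generating midpoint may be given either as an
#' `ic50_nm` directly or as a `ki_nm` together with the radioligand `kd`;
#' in the latter case the curve is generated at
#' `IC50 = Ki (1 + hot/Kd)` so that a Cheng-Prusoff-corrected fit
#' recovers the generating Ki.
#'
#' @param seed integer seed.
#' @param ki_nm generating inhibitory constant (nM); used when `ic50_nm`
#'   is `NULL`.
#' @param kd_nm radioligand dissociation constant (nM).
#' @param ic50_nm generating IC50 (nM), overrides `ki_nm`.
#' @param top,bottom bound counts at zero and saturating competitor (cpm).
#' @param competitor_conc_um competitor ladder (uM).
#' @inheritParams gen_saturation
#' @inheritParams competition_dataset
#' @return a [competition_dataset()].
#' @export
gen_competition <- function(seed, ki_nm = 1.69, kd_nm = 0.30,
                            ic50_nm = NULL,
                            top = 20000, bottom = 500,
                            competitor_conc_um = default_competitor_conc(),
                            replicates = 3,
                            noise = "gaussian_cv", noise_scale = 0.05,
                            hot_cpm_added = 1e5, assay_volume_ul = 100,
                            counter_efficiency = 0.65,
                            specific_activity = 2175) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  hot_nm <- cpm_to_concentration(hot_cpm_added, specific_activity,
                                 counter_efficiency, assay_volume_ul)
  if (is.null(ic50_nm)) {
    if (ki_nm <= 0 || kd_nm <= 0) stop("invalid generating parameters")
    ic50_nm <- ki_nm * (1 + hot_nm / kd_nm)
  }
  if (ic50_nm <= 0 || top <= bottom || noise_scale < 0)
    stop("invalid generating parameters")
  c_nm <- competitor_conc_um * 1000
  y <- bottom + (top - bottom) / (1 + c_nm / ic50_nm)
  withr::with_seed(seed, {
    cpm <- replicate(replicates, apply_noise(y, noise, noise_scale))
    competition_dataset(competitor_conc_um, cpm, hot_cpm_added,
                        assay_volume_ul, counter_efficiency,
                        specific_activity)
  })
}

#' Generate a synthetic radiation dose-response experiment
#'
#' 4PL nuclei-count (or colony-area) readouts over the standard dose
#' ladder; the default grid is the nine-dose nuclei-count design, and the
#' ten-dose variant with the extra 0.05 Gy point is accepted through
#' `dose`.
#'
#' @param seed integer seed.
#' @param ic50_gy,hill,top,bottom generating 4PL parameters.
#' @param dose dose ladder (Gy), must include 0.
#' @inheritParams gen_saturation
#' @inheritParams dose_response_dataset
#' @return a [dose_response_dataset()].
#' @export
gen_dose_response <- function(seed, ic50_gy = 4.3, hill = 1,
                              top = 15000, bottom = 500,
                              dose = c(0, 0.2, 2, 4, 6, 8, 10, 15, 30),
                              replicates = 5,
                              noise = "gaussian_cv", noise_scale = 0.05,
                              response_kind = "nuclei") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (ic50_gy <= 0 || hill <= 0 || top <= bottom || noise_scale < 0)
    stop("invalid generating parameters")
  y <- bottom + (top - bottom) / (1 + (dose / ic50_gy)^hill)
  withr::with_seed(seed, {
    resp <- replicate(replicates, apply_noise(y, noise, noise_scale))
    dose_response_dataset(dose, resp, response_kind)
  })
}

#' Default mouse sample masses
#'
#' Typical dissection sample masses (g) per organ for an adult mouse, used
#' by [gen_biodistribution()] to convert %IA/g to counted cpm.
#'
#' @return named numeric vector (g).
#' @export
default_sample_masses <- function() {
  c("tumor" = 0.25, "small intestine" = 1.0, "colon" = 0.8,
    "liver" = 1.3, "spleen" = 0.10, "kidney" = 0.35, "heart" = 0.15,
    "blood" = 0.20, "lung" = 0.15, "muscle" = 0.30, "femur" = 0.10,
    "stomach" = 0.50, "pancreas" = 0.15, "tail" = 0.40)
}

#' Generate a synthetic biodistribution experiment
#'
#' Per-animal organ uptake drawn lognormally around the generating organ
#' means (mean-preserving parameterisation, so reduced per-time means are
#' unbiased), converted to gamma-counter cpm via the sample mass and a
#' co-counted standard representing a known fraction of the injected
#' activity, with physical decay applied identically to samples and
#' standard of each counting session. Reducing the result with
#' [compute_pia_per_gram()] round-trips to the generating means (exactly
#' at zero noise).
#'
#' @param seed integer seed.
#' @param organ_means data frame `organ`, `time_h`, `mean` (%IA/g);
#'   defaults to the packaged reference biodistribution.
#' @param n_animals animals per time point (study design: 4-5).
#' @param sigma lognormal inter-animal sigma (default 0.25); 0 for
#'   noiseless data.
#' @param injected_mbq injected activity per animal (MBq), default 1.
#' @param standard_cpm counts of the reference standard at injection time.
#' @param standard_fraction fraction of the injected activity the
#'   standard represents.
#' @param sample_masses named organ sample masses (g).
#' @param half_life_h physical half-life used for the decay of counts.
#' @return a [biodistribution_table()].
#' @export
gen_biodistribution <- function(seed,
                                organ_means = reference_biodistribution(),
                                n_animals = 5, sigma = 0.25,
                                injected_mbq = 1,
                                standard_cpm = 2e4,
                                standard_fraction = 0.01,
                                sample_masses = default_sample_masses(),
                                half_life_h = LU177_HALF_LIFE_H) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (any(organ_means$mean < 0)) stop("negative generating means")
  if (sigma < 0 || n_animals < 1) stop("invalid generating parameters")
  organ_means$organ <- normalize_organ(organ_means$organ)
  times <- sort(unique(organ_means$time_h))
  cpm_per_ia <- standard_cpm / standard_fraction  # cpm equivalent of 100% IA
  withr::with_seed(seed, {
    rows <- list()
    for (tt in times) {
      om <- organ_means[organ_means$time_h == tt, , drop = FALSE]
      for (a in seq_len(n_animals)) {
        id <- sprintf("t%g_a%d", tt, a)
        mu <- om$mean
        pia <- if (sigma > 0)
          ifelse(mu > 0,
                 mu * stats::rlnorm(nrow(om), -sigma^2 / 2, sigma), 0)
        else mu
        mass <- unname(sample_masses[om$organ])
        decay_f <- 2^(-tt / half_life_h)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id, organ = om$organ, time_h = tt, mass_g = mass,
          cpm = pia / 100 * mass * cpm_per_ia * decay_f,
          standard_cpm = standard_cpm * decay_f,
          standard_fraction = standard_fraction,
          injected_mbq = injected_mbq, count_offset_h = tt,
          stringsAsFactors = FALSE)
      }
    }
    biodistribution_table(do.call(rbind, rows))
  })
}
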