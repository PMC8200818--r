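## Radioligand binding pharmacology: one-site saturation and competition
## fits on gamma-counter plate data, plus the cpm <-> amount conversions.

#' Assemble a saturation binding dataset
#'
#' Holds replicate total and nonspecific counts measured at a common ladder
#' of radioligand concentrations, together with the assay constants needed
#' to convert fitted cpm maxima into receptor sites per cell.
#'
#' @param ligand_conc radioligand concentrations (nM), one per plate row.
#' @param total_cpm numeric matrix (or vector) of total-binding counts,
#'   `length(ligand_conc)` rows, one column per replicate well.
#' @param nonspecific_cpm counts with excess unlabelled blocker, same shape.
#' @param cells_seeded cells per well (default 50,000).
#' @param counter_efficiency gamma-counter efficiency, fraction in (0, 1].
#'   Default 0.65 (the value used by the printed cpm/fmol conversion); a
#'   warning is emitted when the narrative value 0.5 is chosen instead.
#' @param specific_activity radioligand specific activity (Ci/mmol),
#'   default 2175 for carrier-free 125I.
#' @return An object of class `saturation_dataset`.
#' @seealso [fit_saturation()], [gen_saturation()]
#' @export
saturation_dataset <- function(ligand_conc, total_cpm, nonspecific_cpm,
                               cells_seeded = 5e4,
                               counter_efficiency = 0.65,
                               specific_activity = 2175) {
  total_cpm <- as.matrix(total_cpm)
  nonspecific_cpm <- as.matrix(nonspecific_cpm)
  if (any(ligand_conc < 0)) stop("ligand concentrations must be nonnegative")
  if (anyDuplicated(ligand_conc)) stop("ligand concentrations must be distinct")
  if (nrow(total_cpm) != length(ligand_conc) ||
      nrow(nonspecific_cpm) != length(ligand_conc))
    stop("replicate count rows must match the concentration ladder")
  check_efficiency(counter_efficiency)
  if (specific_activity <= 0) stop("specific_activity must be > 0")
  if (cells_seeded <= 0) stop("cells_seeded must be > 0")
  ord <- order(ligand_conc)
  structure(list(ligand_conc = ligand_conc[ord],
                 total_cpm = total_cpm[ord, , drop = FALSE],
                 nonspecific_cpm = nonspecific_cpm[ord, , drop = FALSE],
                 cells_seeded = cells_seeded,
                 counter_efficiency = counter_efficiency,
                 specific_activity = specific_activity),
            class = "saturation_dataset")
}

check_efficiency <- function(eff) {
  if (!is.numeric(eff) || length(eff) != 1 || eff <= 0 || eff > 1)
    stop("counter_efficiency must be a fraction in (0, 1]")
  if (isTRUE(all.equal(eff, 0.5)))
    warning("counter_efficiency 0.5 selected (narrative value); ",
            "the printed conversion uses 0.65", call. = FALSE)
  invisible(eff)
}

#' Fit the one-site total-and-nonspecific saturation model
#'
#' Simultaneous least-squares fit of
#' \deqn{Total(c) = B_{max} c / (K_d + c) + m c + b}
#' \deqn{Nonspecific(c) = m c + b}
#' to all replicate wells (not their means). The specific curve is the
#' difference of the two fitted curves. The fitted `Bmax` (cpm) is also
#' converted to receptor sites per cell using the dataset's assay constants.
#'
#' @param data a [saturation_dataset()].
#' @param weighting `"none"` (default, matching common plate-fitting
#'   software defaults) or `"inverse_y"` for 1/Y weights.
#' @return An object of class `saturation_fit` with elements `kd` (nM),
#'   `bmax_cpm`, `bmax_sites_per_cell`, `ns_slope` (cpm/nM), `background`
#'   (cpm), `standard_errors`, `converged`, and `diagnostics`.
#' @export
fit_saturation <- function(data, weighting = c("none", "inverse_y")) {
  stopifnot(inherits(data, "saturation_dataset"))
  weighting <- match.arg(weighting)
  conc <- data$ligand_conc
  if (length(conc) < 4) stop("need at least 4 distinct concentrations")
  df <- rbind(
    data.frame(conc = rep(conc, ncol(data$total_cpm)),
               cpm = as.vector(data$total_cpm), is_total = 1),
    data.frame(conc = rep(conc, ncol(data$nonspecific_cpm)),
               cpm = as.vector(data$nonspecific_cpm), is_total = 0))
  if (all(df$cpm == 0)) stop("degenerate data: all counts are zero")

  mean_tot <- rowMeans(data$total_cpm)
  mean_ns <- rowMeans(data$nonspecific_cpm)
  ns_lm <- lm(y ~ conc, data = data.frame(conc = conc, y = mean_ns))
  start <- list(kd = max(stats::median(conc[conc > 0]), 1e-3),
                bmax = max(max(mean_tot - mean_ns), 1),
                ns = max(coef(ns_lm)[["conc"]], 0),
                bg = max(coef(ns_lm)[["(Intercept)"]], 0))
  w <- if (weighting == "inverse_y") 1 / pmax(df$cpm, 1) else rep(1, nrow(df))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      cpm ~ is_total * bmax * conc / (kd + conc) + ns * conc + bg,
      data = df, start = start, weights = w,
      lower = c(kd = 1e-8, bmax = 0, ns = 0, bg = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    res <- list(kd = NA_real_, bmax_cpm = NA_real_,
                bmax_sites_per_cell = NA_real_,
                ns_slope = NA_real_, background = NA_real_,
                standard_errors = NULL, converged = FALSE,
                diagnostics = conditionMessage(fit), data = data)
    return(structure(res, class = "saturation_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(
    kd = unname(cf["kd"]),
    bmax_cpm = unname(cf["bmax"]),
    bmax_sites_per_cell = cpm_to_sites_per_cell(
      unname(cf["bmax"]), data$specific_activity,
      data$counter_efficiency, data$cells_seeded),
    ns_slope = unname(cf["ns"]),
    background = unname(cf["bg"]),
    standard_errors = setNames(as.numeric(se),
                               c("kd", "bmax", "ns", "bg")[seq_along(se)]),
    converged = isTRUE(fit$convInfo$isConv),
    diagnostics = fit$convInfo$stopMessage,
    data = data), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("One-site saturation binding fit\n")
  if (!isTRUE(x$converged)) cat("  [not converged:", x$diagnostics, "]\n")
  cat(sprintf("  Kd   = %.4g nM\n  Bmax = %.5g cpm (%.5g sites/cell)\n",
              x$kd, x$bmax_cpm, x$bmax_sites_per_cell))
  cat(sprintf("  nonspecific slope = %.4g cpm/nM, background = %.4g cpm\n",
              x$ns_slope, x$background))
  invisible(x)
}

#' Counts-per-minute per femtomole of radioligand
#'
#' The printed conversion: specific activity (Ci/mmol) times
#' 2.22e12 (dpm/Ci) times the counter efficiency, rescaled from per-mmol to
#' per-fmol. At 2175 Ci/mmol and efficiency 0.65 this is 3138.525 cpm/fmol.
#'
#' @inheritParams cpm_to_sites_per_cell
#' @return cpm per fmol.
#' @export
cpm_per_fmol <- function(specific_activity, counter_efficiency) {
  check_efficiency(counter_efficiency)
  if (specific_activity <= 0) stop("specific_activity must be > 0")
  specific_activity * 2.22e12 * counter_efficiency / 1e12
}

#' Convert a fitted Bmax in cpm to receptor sites per cell
#'
#' Evaluates the two-step printed conversion: cpm are divided by cpm/fmol
#' (see [cpm_per_fmol()]) to give femtomoles of bound ligand, multiplied by
#' 6.02e8 molecules per fmol (Avogadro), and divided by the number of
#' seeded cells.
#'
#' @param bmax_cpm fitted maximal specific binding (cpm), >= 0.
#' @param specific_activity radioligand specific activity (Ci/mmol).
#' @param counter_efficiency counter efficiency, fraction in (0, 1].
#' @param cells_seeded cells per well.
#' @return receptor sites per cell.
#' @examples
#' cpm_to_sites_per_cell(3138.525, 2175, 0.65, 5e4)  # 12040
#' @export
cpm_to_sites_per_cell <- function(bmax_cpm, specific_activity,
                                  counter_efficiency, cells_seeded) {
  if (any(bmax_cpm < 0)) stop("bmax_cpm must be >= 0")
  if (cells_seeded <= 0) stop("cells_seeded must be > 0")
  cpf <- cpm_per_fmol(specific_activity, counter_efficiency)
  (bmax_cpm / cpf) * 6.02e8 / cells_seeded
}

#' Convert counts to a radioligand concentration
#'
#' Counts divided by cpm/fmol give femtomoles; divided by the assay volume
#' this is a molar concentration (1 fmol/uL = 1 nM). Used to express the
#' hot-ligand input of a competition assay as a concentration for the
#' Cheng-Prusoff correction.
#'
#' @param cpm counts per minute added to the well.
#' @inheritParams cpm_to_sites_per_cell
#' @param volume_ul assay volume in microlitres (> 0); default 100.
#' @return concentration in nM.
#' @examples
#' cpm_to_concentration(1e5, 2175, 0.65, 100)  # ~0.319 nM
#' @export
cpm_to_concentration <- function(cpm, specific_activity, counter_efficiency,
                                 volume_ul = 100) {
  if (volume_ul <= 0) stop("volume_ul must be > 0")
  if (any(cpm < 0)) stop("cpm must be >= 0")
  fmol <- cpm / cpm_per_fmol(specific_activity, counter_efficiency)
  fmol / volume_ul  # fmol/uL == nM
}

#' Assemble a competition binding dataset
#'
#' Replicate bound counts at a ladder of unlabelled competitor
#' concentrations, with a fixed amount of radioligand per well. Wells at
#' zero competitor define the top of the displacement curve.
#'
#' @param competitor_conc_um competitor concentrations (uM), must include 0.
#' @param cpm numeric matrix (or vector) of bound counts, one row per
#'   concentration, one column per replicate.
#' @param hot_cpm_added radioligand added per well (cpm), default 100,000.
#' @param assay_volume_ul assay volume (uL); unreported in typical
#'   protocols, default 100 and flagged in reports.
#' @inheritParams saturation_dataset
#' @return An object of class `competition_dataset` with derived
#'   `hot_conc_nm` (see [cpm_to_concentration()]).
#' @export
competition_dataset <- function(competitor_conc_um, cpm,
                                hot_cpm_added = 1e5,
                                assay_volume_ul = 100,
                                counter_efficiency = 0.65,
                                specific_activity = 2175) {
  cpm <- as.matrix(cpm)
  if (any(competitor_conc_um < 0)) stop("concentrations must be nonnegative")
  if (!any(competitor_conc_um == 0))
    stop("zero-competitor wells are required to define the curve top")
  if (nrow(cpm) != length(competitor_conc_um))
    stop("count rows must match the concentration ladder")
  if (hot_cpm_added <= 0) stop("hot_cpm_added must be > 0")
  ord <- order(competitor_conc_um)
  structure(list(
    competitor_conc_um = competitor_conc_um[ord],
    cpm = cpm[ord, , drop = FALSE],
    hot_cpm_added = hot_cpm_added,
    assay_volume_ul = assay_volume_ul,
    counter_efficiency = counter_efficiency,
    specific_activity = specific_activity,
    hot_conc_nm = cpm_to_concentration(hot_cpm_added, specific_activity,
                                       counter_efficiency, assay_volume_ul)),
    class = "competition_dataset")
}

#' Fit the one-site competition (displacement) model
#'
#' Unit-slope log-logistic displacement,
#' \deqn{Y(c) = Bottom + (Top - Bottom) / (1 + 10^{\log_{10} c - \log IC_{50}})}
#' fitted by least squares over all replicate wells; the zero-competitor
#' wells pin the top. The IC50 is reported in nM; when `kd` of the
#' radioligand is supplied, the Cheng-Prusoff inhibitory constant Ki is
#' reported alongside (both values are returned, labelled, because a
#' Ki-parameterised fit and an IC50 fit differ only by that transform).
#'
#' @param data a [competition_dataset()].
#' @param kd radioligand dissociation constant (nM) for the Cheng-Prusoff
#'   correction; `NULL` leaves `ki_nm` as `NA`.
#' @param weighting `"none"` or `"inverse_y"`.
#' @return An object of class `competition_fit`: `log_ic50` (log10 molar),
#'   `ic50_nm`, `ki_nm`, `top`, `bottom`, `hot_conc_nm`, `standard_errors`,
#'   `converged`, `diagnostics`.
#' @export
fit_competition <- function(data, kd = NULL,
                            weighting = c("none", "inverse_y")) {
  stopifnot(inherits(data, "competition_dataset"))
  weighting <- match.arg(weighting)
  conc_um <- data$competitor_conc_um
  pos <- conc_um > 0
  if (length(unique(conc_um)) < 5 ||
      diff(log10(range(conc_um[pos]))) < 3)
    stop("need >= 5 distinct concentrations spanning >= 3 log-decades")

  df <- data.frame(conc_m = rep(conc_um * 1e-6, ncol(data$cpm)),
                   cpm = as.vector(data$cpm))
  means <- rowMeans(data$cpm)
  top0 <- mean(data$cpm[conc_um == 0, ])
  bottom0 <- min(means)
  half <- (top0 + bottom0) / 2
  log_ic50_0 <- log10(conc_um[pos][which.min(abs(means[pos] - half))] * 1e-6)
  w <- if (weighting == "inverse_y") 1 / pmax(df$cpm, 1) else rep(1, nrow(df))

  flat <- (top0 - bottom0) <= 0.1 * max(top0, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      # equivalent to the log10 form but well-defined at conc 0
      cpm ~ bottom + (top - bottom) / (1 + conc_m / 10^log_ic50),
      data = df, weights = w,
      start = list(top = top0, bottom = max(bottom0, 0),
                   log_ic50 = log_ic50_0),
      lower = c(top = 0, bottom = 0, log_ic50 = -15),
      upper = c(top = Inf, bottom = Inf, log_ic50 = -2),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)

  if (inherits(fit, "error") || flat) {
    diag <- if (flat) "no displacement: curve is flat" else
      conditionMessage(fit)
    cf <- if (inherits(fit, "error")) c(top = NA_real_, bottom = NA_real_,
                                        log_ic50 = NA_real_) else coef(fit)
    res <- list(log_ic50 = unname(cf["log_ic50"]),
                ic50_nm = 10^unname(cf["log_ic50"]) * 1e9,
                ki_nm = NA_real_, top = unname(cf["top"]),
                bottom = unname(cf["bottom"]),
                hot_conc_nm = data$hot_conc_nm,
                standard_errors = NULL, converged = FALSE,
                diagnostics = diag, data = data)
    return(structure(res, class = "competition_fit"))
  }
  cf <- coef(fit)
  ic50_nm <- 10^unname(cf["log_ic50"]) * 1e9
  ki_nm <- if (is.null(kd)) NA_real_ else
    cheng_prusoff(ic50_nm, data$hot_conc_nm, kd)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(
    log_ic50 = unname(cf["log_ic50"]),
    ic50_nm = ic50_nm, ki_nm = ki_nm,
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    hot_conc_nm = data$hot_conc_nm,
    standard_errors = setNames(as.numeric(se),
                               c("top", "bottom", "log_ic50")[seq_along(se)]),
    converged = isTRUE(fit$convInfo$isConv),
    diagnostics = fit$convInfo$stopMessage,
    data = data), class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("One-site competition binding fit\n")
  if (!isTRUE(x$converged)) cat("  [not converged:", x$diagnostics, "]\n")
  cat(sprintf("  logIC50 = %.4f (IC50 = %.4g nM)\n", x$log_ic50, x$ic50_nm))
  if (!is.na(x$ki_nm))
    cat(sprintf("  Ki (Cheng-Prusoff, hot %.3g nM) = %.4g nM\n",
                x$hot_conc_nm, x$ki_nm))
  cat(sprintf("  top = %.5g cpm, bottom = %.5g cpm\n", x$top, x$bottom))
  invisible(x)
}

#' Cheng-Prusoff correction of an IC50 to a Ki
#'
#' \deqn{K_i = IC_{50} / (1 + [hot]/K_d)}
#' With no radioligand occupancy (`hot_conc = 0`) the Ki equals the IC50;
#' it decreases strictly as hot-ligand concentration rises.
#'
#' @param ic50 half-maximal inhibitory concentration (nM).
#' @param hot_conc free radioligand concentration (nM), >= 0.
#' @param kd radioligand dissociation constant (nM), > 0.
#' @return Ki in nM.
#' @examples
#' cheng_prusoff(2.0, 0.319, 0.30)  # 0.969
#' @export
cheng_prusoff <- function(ic50, hot_conc, kd) {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(hot_conc < 0)) stop("hot_conc must be >= 0")
  ic50 / (1 + hot_conc / kd)
}
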