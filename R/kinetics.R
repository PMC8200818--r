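## Time-activity kinetics and mouse-to-human allometric extrapolation:
## exponential TAC fits, mass/time scaling, time-integrated activity.

#' Assemble a mouse/human mass table
#'
#' Body masses of the animal and the human reference adult, plus human
#' organ masses, used by the allometric extrapolation.
#'
#' @param mouse_body_kg mouse body mass (kg); default 0.025.
#' @param human_body_kg human reference adult body mass (kg); default 73.7.
#' @param organ_masses_g named numeric vector of human organ masses (g);
#'   defaults to the packaged reference adult male table
#'   (`extdata/human_organ_masses_adult_male.csv`, user-replaceable).
#' @return An object of class `mass_table`.
#' @export
mass_table <- function(mouse_body_kg = 0.025, human_body_kg = 73.7,
                       organ_masses_g = NULL) {
  if (is.null(organ_masses_g)) {
    path <- system.file("extdata", "human_organ_masses_adult_male.csv",
                        package = "radioknot", mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    organ_masses_g <- setNames(tab$mass_g, tab$organ)
  }
  if (mouse_body_kg <= 0 || human_body_kg <= 0)
    stop("body masses must be > 0")
  if (any(organ_masses_g <= 0)) stop("organ masses must be > 0")
  if (sum(organ_masses_g) >= human_body_kg * 1000)
    stop("organ masses must sum to less than the body mass")
  structure(list(mouse_body_kg = mouse_body_kg,
                 human_body_kg = human_body_kg,
                 organ_masses_g = organ_masses_g),
            class = "mass_table")
}

#' Scale mouse uptake concentration to human whole-organ uptake
#'
#' Relative-mass extrapolation, assuming equal organ-to-whole-body activity
#' concentration ratios across species:
#' \deqn{(\%IA/organ)_{human} = (\%IA/g)_{mouse} \times M_{mouse}(kg)
#'       \times [m(g)/M(kg)]_{human}}
#'
#' @param pia_per_g_mouse mouse uptake (%IA/g).
#' @param masses a [mass_table()].
#' @param organ organ name present in the human organ-mass table.
#' @return human whole-organ uptake (%IA/organ).
#' @examples
#' scale_uptake_to_human(19.21, mass_table(), "kidney")  # 1.949
#' @export
scale_uptake_to_human <- function(pia_per_g_mouse, masses, organ) {
  stopifnot(inherits(masses, "mass_table"))
  m <- masses$organ_masses_g[organ]
  if (any(is.na(m)))
    stop(sprintf("no human organ mass for '%s'", organ))
  pia_per_g_mouse * masses$mouse_body_kg *
    unname(m) / masses$human_body_kg
}

#' Scale animal time to human time
#'
#' Quarter-power allometric time dilation:
#' \deqn{t_{human} = t_{animal} [M_{human}/M_{animal}]^{0.25}}
#'
#' @param t_animal_h animal time (h).
#' @param masses a [mass_table()].
#' @return human-equivalent time (h).
#' @examples
#' scale_time_to_human(24, mass_table())  # 176.8
#' @export
scale_time_to_human <- function(t_animal_h, masses) {
  stopifnot(inherits(masses, "mass_table"))
  t_animal_h * (masses$human_body_kg / masses$mouse_body_kg)^0.25
}

#' Fit a mono- or bi-exponential model to a time-activity curve
#'
#' Least squares on the per-time-point mean curve. `model = "auto"`
#' chooses mono for four or fewer points and otherwise selects by AICc.
#' With `residuals = "log"` the mono fit is the exact log-linear
#' regression (closed form); bi-exponential log fits minimise squared
#' log residuals numerically.
#'
#' @param tac a [time_activity_curve()] (values in %IA/g or fraction of
#'   IA), or any data frame with `time_h` and `mean_pia_per_g`.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @param residuals `"linear"` (default) or `"log"`.
#' @return An object of class `exponential_fit`: `model`, `amplitudes`,
#'   `rates` (1/h, for bi sorted fast-to-slow and distinct),
#'   `effective_half_life_h` (terminal), `rss`, `aicc`, `converged`.
#' @export
fit_exponential <- function(tac, model = c("auto", "mono", "bi"),
                            residuals = c("linear", "log")) {
  model <- match.arg(model)
  residuals <- match.arg(residuals)
  t <- tac$time_h
  y <- if (!is.null(tac$mean_pia_per_g)) tac$mean_pia_per_g else
    tac$fraction_ia
  if (is.null(y)) stop("need a mean_pia_per_g or fraction_ia column")
  if (any(y <= 0)) stop("non-positive means: cannot fit exponential decay")
  n <- length(t)
  if (n < 2) stop("need at least 2 time points")
  if (model == "bi" && n < 4) stop("bi-exponential needs >= 4 time points")
  if (model == "auto") model <- if (n <= 4) "mono" else "aicc"

  fit_mono <- function() {
    if (residuals == "log") {
      fm <- lm(log(y) ~ t)
      a <- exp(coef(fm)[[1]]); l <- -coef(fm)[[2]]
      pred <- a * exp(-l * t)
    } else {
      fm0 <- lm(log(y) ~ t)
      st <- list(a = exp(coef(fm0)[[1]]), l = max(-coef(fm0)[[2]], 1e-6))
      fm <- minpack.lm::nlsLM(y ~ a * exp(-l * t),
                              data = data.frame(t = t, y = y),
                              start = st, lower = c(a = 0, l = 1e-9))
      a <- coef(fm)[["a"]]; l <- coef(fm)[["l"]]
      pred <- a * exp(-l * t)
    }
    list(model = "mono", amplitudes = a, rates = l, pred = pred)
  }
  fit_bi <- function() {
    lf0 <- {  # curve peeling for starts: tail gives the slow phase
      tail_idx <- seq(max(1, n - 1), n)
      lm(log(y[tail_idx]) ~ t[tail_idx])
    }
    l2 <- max(-coef(lf0)[[2]], 1e-5)
    a2 <- exp(coef(lf0)[[1]])
    resid_fast <- pmax(y - a2 * exp(-l2 * t), y * 1e-3)
    lf1 <- lm(log(resid_fast) ~ t)
    st <- list(a1 = exp(coef(lf1)[[1]]), l1 = max(-coef(lf1)[[2]], 10 * l2),
               a2 = a2, l2 = l2)
    obj <- if (residuals == "log")
      log(y) ~ log(a1 * exp(-l1 * t) + a2 * exp(-l2 * t)) else
      y ~ a1 * exp(-l1 * t) + a2 * exp(-l2 * t)
    yy <- if (residuals == "log") log(y) else y
    fm <- minpack.lm::nlsLM(obj, data = data.frame(t = t, y = y),
                            start = st,
                            lower = c(a1 = 0, l1 = 1e-9, a2 = 0, l2 = 1e-9))
    cf <- coef(fm)
    ord <- order(c(cf[["l1"]], cf[["l2"]]), decreasing = TRUE)
    a <- c(cf[["a1"]], cf[["a2"]])[ord]
    l <- c(cf[["l1"]], cf[["l2"]])[ord]
    pred <- a[1] * exp(-l[1] * t) + a[2] * exp(-l[2] * t)
    list(model = "bi", amplitudes = a, rates = l, pred = pred)
  }
  aicc <- function(pred, k) {
    rss <- sum((if (residuals == "log") log(y) - log(pred) else y - pred)^2)
    aic <- n * log(rss / n) + 2 * k
    if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  }

  res <- switch(model,
    mono = fit_mono(),
    # a second phase with vanishing amplitude makes the bi model singular;
    # degenerate bi fits reduce to the mono solution
    bi = tryCatch(fit_bi(), error = function(e) fit_mono()),
    aicc = {
      fm <- fit_mono()
      fb <- tryCatch(fit_bi(), error = function(e) NULL)
      if (!is.null(fb) && aicc(fb$pred, 4) < aicc(fm$pred, 2)) fb else fm
    })
  rss <- sum((y - res$pred)^2)
  terminal <- min(res$rates)
  structure(list(model = res$model, amplitudes = res$amplitudes,
                 rates = res$rates,
                 effective_half_life_h = log(2) / terminal,
                 rss = rss, aicc = aicc(res$pred, 2 * length(res$rates)),
                 residuals = residuals, converged = TRUE),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("%s-exponential fit (%s residuals)\n", x$model, x$residuals))
  for (i in seq_along(x$rates))
    cat(sprintf("  A%d = %.4g, lambda%d = %.4g /h (T1/2 = %.4g h)\n",
                i, x$amplitudes[i], i, x$rates[i], log(2) / x$rates[i]))
  cat(sprintf("  terminal effective half-life = %.4g h, RSS = %.3g\n",
              x$effective_half_life_h, x$rss))
  invisible(x)
}

#' Time-integrated activity coefficient (residence time)
#'
#' Integrates the fitted organ activity curve, expressed as fraction of
#' injected activity, to give tau in hours (MBq h per MBq injected).
#' Analytically tau = sum(A_i / lambda_i); the `trapezoid_plus_tail`
#' method integrates a dense trapezoid up to `horizon` and adds the
#' analytic tail beyond, as a numerical cross-check. Terminal decay in
#' (scaled) time can come out slower than physical decay, which is
#' unphysical for a nuclide-bound tracer; each rate is therefore floored
#' at the physical decay constant and the adjustment is reported.
#'
#' @param fit an [fit_exponential()] result with amplitudes in fraction of
#'   injected activity (not percent).
#' @param physical_half_life_h physical half-life of the nuclide (h);
#'   default 177Lu. Set `Inf` to disable the floor.
#' @param horizon switchover time (h) for the trapezoid method; `Inf`
#'   (default) selects the analytic closed form.
#' @param method `"analytic"` or `"trapezoid_plus_tail"`.
#' @return An object of class `residence_time`: `tau_h`, `method`,
#'   `rates_used` (1/h), `floored` (logical per phase).
#' @export
time_integrated_activity <- function(fit,
                                     physical_half_life_h = LU177_HALF_LIFE_H,
                                     horizon = Inf,
                                     method = c("analytic",
                                                "trapezoid_plus_tail")) {
  stopifnot(inherits(fit, "exponential_fit"))
  method <- match.arg(method)
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  a <- fit$amplitudes
  l <- fit$rates
  if (any(l <= 0) && is.infinite(horizon))
    stop("non-integrable: a rate constant is <= 0")
  lambda_phys <- log(2) / physical_half_life_h
  floored <- l < lambda_phys
  l_used <- pmax(l, lambda_phys)
  if (any(floored))
    message("terminal rate floored at the physical decay constant")
  if (method == "analytic") {
    tau <- sum(a / l_used)
  } else {
    t_split <- if (is.finite(horizon)) horizon else
      5 * log(2) / min(l_used)
    # step fine enough for <1e-6 relative trapezoid error on exponentials
    grid <- seq(0, t_split, length.out = max(2e4, 2L))
    f <- sapply(l_used, function(li) exp(-li * grid)) %*% a
    h <- grid[2] - grid[1]
    tau <- sum((f[-1] + f[-length(f)]) / 2) * h +
      sum(a * exp(-l_used * t_split) / l_used)
  }
  structure(list(tau_h = as.numeric(tau), method = method,
                 rates_used = l_used, floored = floored),
            class = "residence_time")
}

#' @export
print.residence_time <- function(x, ...) {
  cat(sprintf("time-integrated activity coefficient tau = %.5g h (%s)\n",
              x$tau_h, x$method))
  if (any(x$floored)) cat("  (rate floored at physical decay)\n")
  invisible(x)
}

#' Extrapolate a mouse time-activity curve to the human reference adult
#'
#' Applies the mass scaling ([scale_uptake_to_human()]) to every uptake
#' value and the quarter-power time dilation ([scale_time_to_human()]) to
#' every time point, returning the human whole-organ curve as fraction of
#' injected activity versus human time. Amplitudes and times are scaled
#' before any fitting or integration.
#'
#' @param tac a [time_activity_curve()] in mouse %IA/g.
#' @param masses a [mass_table()].
#' @param organ organ name; defaults to the curve's organ attribute.
#' @return data frame with `time_h` (human) and `fraction_ia` (fraction of
#'   injected activity in the whole organ), plus attribute `organ`.
#' @export
extrapolate_tac_to_human <- function(tac, masses, organ = attr(tac, "organ")) {
  stopifnot(inherits(masses, "mass_table"))
  pia_organ <- scale_uptake_to_human(tac$mean_pia_per_g, masses, organ)
  structure(data.frame(time_h = scale_time_to_human(tac$time_h, masses),
                       fraction_ia = pia_organ / 100),
            organ = organ, class = c("human_tac", "data.frame"))
}
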