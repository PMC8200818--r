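## Biodistribution reduction: gamma-counter rows -> decay-corrected %IA/g,
## organ time-activity curves and tumor-to-organ ratios.

#' Controlled organ vocabulary
#'
#' The organ names accepted by the biodistribution reducers, matching the
#' dissection list of the Capan-2 xenograft study (tumor plus thirteen
#' tissues). Aliases are matched case-insensitively and a trailing "s" is
#' tolerated ("kidneys" -> "kidney").
#'
#' @return character vector of canonical organ names.
#' @export
organ_vocabulary <- function() {
  c("tumor", "small intestine", "colon", "liver", "spleen", "kidney",
    "heart", "blood", "lung", "muscle", "femur", "stomach", "pancreas",
    "tail")
}

normalize_organ <- function(organ) {
  vocab <- organ_vocabulary()
  key <- gsub("_", " ", tolower(trimws(organ)))
  hit <- match(key, vocab)
  plural <- match(sub("s$", "", key), vocab)
  out <- ifelse(is.na(hit), vocab[plural], vocab[hit])
  if (any(is.na(out)))
    stop(sprintf("unknown organ(s): %s; expected one of: %s",
                 paste(unique(organ[is.na(out)]), collapse = ", "),
                 paste(vocab, collapse = ", ")))
  out
}

#' Assemble a per-animal biodistribution table
#'
#' One row per counted sample: animal, organ, time post injection, sample
#' mass, sample counts, the co-counted reference standard (a known fraction
#' of the injected activity), and the counting-session offset from
#' injection used for decay correction.
#'
#' @param df data frame with columns `animal`, `organ`, `time_h`, `mass_g`,
#'   `cpm`, `standard_cpm`, `standard_fraction`, and optionally
#'   `injected_mbq` (default 1) and `count_offset_h` (default equal to
#'   `time_h`, i.e. counted at dissection alongside the standard).
#' @return An object of class `biodistribution_table` (validated data
#'   frame with canonical organ names).
#' @export
biodistribution_table <- function(df) {
  req <- c("animal", "organ", "time_h", "mass_g", "cpm",
           "standard_cpm", "standard_fraction")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$injected_mbq)) df$injected_mbq <- 1
  if (is.null(df$count_offset_h)) df$count_offset_h <- df$time_h
  if (any(df$mass_g <= 0)) stop("sample masses must be > 0")
  if (any(df$time_h <= 0)) stop("times post injection must be > 0")
  if (any(df$standard_cpm <= 0)) stop("every animal needs a positive standard")
  if (any(df$standard_fraction <= 0 | df$standard_fraction > 1))
    stop("standard_fraction must be in (0, 1]")
  df$organ <- normalize_organ(df$organ)
  structure(df, class = c("biodistribution_table", "data.frame"))
}

#' Decay-correct an activity or count rate
#'
#' Back-corrects to the reference time by multiplying with
#' `2^(elapsed / half_life)` (or forward-corrects with the inverse).
#'
#' @param activity measured activity or count rate.
#' @param elapsed_h time elapsed since the reference time (h).
#' @param half_life_h physical half-life (h); defaults to 177Lu.
#' @param direction `"back"` (to the reference time, default) or
#'   `"forward"`.
#' @return corrected activity.
#' @examples
#' decay_correct(1, 24)  # 1.110 for 177Lu
#' @export
decay_correct <- function(activity, elapsed_h,
                          half_life_h = LU177_HALF_LIFE_H,
                          direction = c("back", "forward")) {
  direction <- match.arg(direction)
  if (half_life_h <= 0) stop("half_life_h must be > 0")
  f <- 2^(elapsed_h / half_life_h)
  if (direction == "back") activity * f else activity / f
}

#' Reduce counter rows to percent injected activity per gram
#'
#' The co-counted standard represents a known fraction of the injected
#' activity, so the whole-injection count-rate equivalent is
#' `standard_cpm / standard_fraction`. Sample and standard counted in the
#' same session share the decay factor, which cancels; with differing
#' session offsets both are decay-corrected to injection time explicitly.
#' \deqn{\%IA/g = \frac{cpm_{sample}}{cpm_{std}/f_{std}} \times \frac{100}{mass}}
#' Negative net counts are clamped to zero with a warning.
#'
#' @param table a [biodistribution_table()] (or a conforming data frame).
#' @param half_life_h physical half-life for decay correction (h).
#' @param standard_offset_h counting offset of the standard from injection
#'   (h); default `NULL` means same session as each sample (decay cancels).
#' @return the table with an added `pia_per_g` column.
#' @export
compute_pia_per_gram <- function(table, half_life_h = LU177_HALF_LIFE_H,
                                 standard_offset_h = NULL) {
  if (!inherits(table, "biodistribution_table"))
    table <- biodistribution_table(table)
  cpm <- table$cpm
  if (any(cpm < 0)) {
    warning("negative net counts clamped to 0", call. = FALSE)
    cpm <- pmax(cpm, 0)
  }
  sample_corr <- decay_correct(cpm, table$count_offset_h, half_life_h)
  std_offset <- if (is.null(standard_offset_h)) table$count_offset_h else
    standard_offset_h
  std_corr <- decay_correct(table$standard_cpm, std_offset, half_life_h)
  frac <- sample_corr / (std_corr / table$standard_fraction)
  table$pia_per_g <- frac * 100 / table$mass_g
  table
}

#' Build an organ time-activity curve
#'
#' Per-time-point mean, SD and n of %IA/g for one organ.
#'
#' @param table a reduced [biodistribution_table()] carrying `pia_per_g`
#'   (see [compute_pia_per_gram()]); raw tables are reduced on the fly.
#' @param organ canonical organ name (see [organ_vocabulary()]).
#' @return An object of class `time_activity_curve`: data frame with
#'   `time_h`, `mean_pia_per_g`, `sd`, `n`, and an `organ` attribute.
#' @export
build_tac <- function(table, organ) {
  organ <- normalize_organ(organ)
  if (!inherits(table, "biodistribution_table"))
    table <- biodistribution_table(table)
  if (is.null(table$pia_per_g)) table <- compute_pia_per_gram(table)
  rows <- table[table$organ == organ, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("no rows for organ '%s'", organ))
  sp <- split(rows$pia_per_g, rows$time_h)
  out <- data.frame(
    time_h = as.numeric(names(sp)),
    mean_pia_per_g = vapply(sp, mean, 0),
    sd = vapply(sp, function(x) if (length(x) > 1) sd(x) else 0, 0),
    n = vapply(sp, length, 0L))
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, organ = organ,
            class = c("time_activity_curve", "data.frame"))
}

#' Construct a time-activity curve directly from summary values
#'
#' @param organ canonical organ name.
#' @param time_h strictly increasing times (h).
#' @param mean_pia_per_g mean %IA/g per time point.
#' @param sd,n optional per-point SD and animal count.
#' @return a `time_activity_curve`.
#' @export
time_activity_curve <- function(organ, time_h, mean_pia_per_g,
                                sd = rep(0, length(time_h)),
                                n = rep(1L, length(time_h))) {
  organ <- normalize_organ(organ)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(n < 1) || any(sd < 0)) stop("need n >= 1 and sd >= 0")
  structure(data.frame(time_h = time_h, mean_pia_per_g = mean_pia_per_g,
                       sd = sd, n = as.integer(n)),
            organ = organ, class = c("time_activity_curve", "data.frame"))
}

#' Tumor-to-organ uptake ratios
#'
#' Ratio of mean tumor %IA/g to mean organ %IA/g per time point
#' (ratio-of-means). When a reduced per-animal table is supplied, the mean
#' and SD of per-animal tumor/organ ratios (mean-of-ratios) are reported
#' alongside, because published tables do not always state which
#' convention they use. Zero organ means yield `NA` (undefined), never
#' infinity.
#'
#' @param x either a named list of [time_activity_curve()]s including
#'   `"tumor"`, or a reduced [biodistribution_table()].
#' @param organs organs to report (default: all non-tumor organs present).
#' @return data frame with `organ`, `time_h`, `ratio_of_means`, and (when
#'   per-animal pairing exists) `mean_of_ratios`, `sd_of_ratios`.
#' @export
tumor_to_organ_ratios <- function(x, organs = NULL) {
  if (inherits(x, "biodistribution_table")) {
    tab <- if (is.null(x$pia_per_g)) compute_pia_per_gram(x) else x
    curves <- lapply(setNames(nm = unique(tab$organ)),
                     function(o) build_tac(tab, o))
    per_animal <- tab
  } else {
    curves <- x
    names(curves) <- vapply(curves, attr, "", "organ")
    per_animal <- NULL
  }
  if (!"tumor" %in% names(curves)) stop("tumor curve is required")
  tumor <- curves[["tumor"]]
  if (is.null(organs))
    organs <- setdiff(names(curves), "tumor")
  organs <- normalize_organ(organs)
  out <- do.call(rbind, lapply(organs, function(o) {
    oc <- curves[[o]]
    m <- merge(tumor[, c("time_h", "mean_pia_per_g")],
               oc[, c("time_h", "mean_pia_per_g")],
               by = "time_h", suffixes = c("_tumor", "_organ"))
    res <- data.frame(organ = o, time_h = m$time_h,
                      ratio_of_means = ifelse(m$mean_pia_per_g_organ > 0,
                        m$mean_pia_per_g_tumor / m$mean_pia_per_g_organ,
                        NA_real_))
    if (!is.null(per_animal)) {
      mor <- vapply(res$time_h, function(tt) {
        tu <- per_animal[per_animal$organ == "tumor" &
                         per_animal$time_h == tt, c("animal", "pia_per_g")]
        og <- per_animal[per_animal$organ == o &
                         per_animal$time_h == tt, c("animal", "pia_per_g")]
        mm <- merge(tu, og, by = "animal", suffixes = c("_t", "_o"))
        r <- mm$pia_per_g_t / mm$pia_per_g_o
        r <- r[is.finite(r)]
        c(mean = if (length(r)) mean(r) else NA_real_,
          sd = if (length(r) > 1) sd(r) else NA_real_)
      }, c(mean = 0, sd = 0))
      res$mean_of_ratios <- mor["mean", ]
      res$sd_of_ratios <- mor["sd", ]
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Reference biodistribution of the 177Lu-DOTA alpha-v-beta-6 knottin
#'
#' Published mean and SD %IA/g per organ and time point (24, 48, 72 and
#' 192 h post injection; 4-5 Capan-2 xenograft mice per point) for the
#' 177Lu-DOTA integrin alpha-v-beta-6 knottin. Shipped as a plain CSV in
#' `extdata` and used as the default generating values of
#' [gen_biodistribution()] and as input to the dosimetry projection.
#'
#' @return data frame with columns `organ`, `time_h`, `mean`, `sd`.
#' @export
reference_biodistribution <- function() {
  path <- system.file("extdata", "biodist_reference_capan2.csv",
                      package = "radioknot", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$organ <- normalize_organ(df$organ)
  df
}

#' Reference binding and radiosensitivity parameters
#'
#' Published in-vitro parameters for the DOTA alpha-v-beta-6 knottin on
#' BxPC-3 and Capan-2 cells: saturation Kd (nM), Bmax (sites/cell),
#' competition Ki (nM, DOTA-knottin), and the radiation IC50 (Gy, nuclei
#' count readout). Used as default generating values by the synthetic-data
#' module.
#'
#' @return data frame keyed by `cell_line`.
#' @export
reference_binding <- function() {
  data.frame(
    cell_line = c("BxPC-3", "Capan-2"),
    kd_nm = c(0.30, 0.75),
    bmax_sites_per_cell = c(11874, 11545),
    ki_dota_nm = c(1.69, 9.46),
    radiation_ic50_gy = c(4.3, 5.5),
    stringsAsFactors = FALSE)
}
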