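## Cell-based assays: 4PL radiation dose-response and delta-delta-Ct qPCR.

#' Assemble a radiation dose-response dataset
#'
#' @param dose doses in Gy; must be nonnegative and include the 0 Gy
#'   control.
#' @param response numeric matrix (or vector) of replicate readouts, one
#'   row per dose: nuclei counts or colony-area fractions.
#' @param response_kind `"nuclei"` or `"colony_area"` (tabulated area
#'   fractions; image segmentation is upstream of this package).
#' @return An object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(dose, response,
                                  response_kind = c("nuclei", "colony_area")) {
  response_kind <- match.arg(response_kind)
  response <- as.matrix(response)
  if (any(dose < 0)) stop("doses must be nonnegative")
  if (!any(dose == 0)) stop("a 0 Gy control is required")
  if (anyDuplicated(dose)) stop("doses must be distinct")
  if (nrow(response) != length(dose))
    stop("response rows must match the dose ladder")
  ord <- order(dose)
  structure(list(dose = dose[ord],
                 response = response[ord, , drop = FALSE],
                 response_kind = response_kind),
            class = "dose_response_dataset")
}

#' Fit a four-parameter logistic radiation dose-response curve
#'
#' \deqn{Y(d) = Bottom + (Top - Bottom) / (1 + (d / IC_{50})^{h})}
#' with variable Hill slope `h` constrained to `[0.2, 10]`, fitted by least
#' squares over all replicate wells. `IC50` is the dose (Gy) of
#' half-maximal growth inhibition.
#'
#' @param data a [dose_response_dataset()].
#' @param weighting `"none"` or `"inverse_y"`.
#' @return An object of class `dose_response_fit`: `ic50` (Gy),
#'   `hill_slope`, `top`, `bottom`, `standard_errors`, `converged`,
#'   `diagnostics`.
#' @export
fit_dose_response <- function(data, weighting = c("none", "inverse_y")) {
  stopifnot(inherits(data, "dose_response_dataset"))
  weighting <- match.arg(weighting)
  dose <- data$dose
  if (length(dose) < 4) stop("need at least 4 distinct doses")
  df <- data.frame(dose = rep(dose, ncol(data$response)),
                   y = as.vector(data$response))
  means <- rowMeans(data$response)
  # monotone-increasing response means no inhibition: flag, don't fit
  if (stats::cor(dose, means, method = "spearman") > 0.5) {
    return(structure(list(ic50 = NA_real_, hill_slope = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          standard_errors = NULL, converged = FALSE,
                          diagnostics = "no inhibition: response rises with dose",
                          data = data), class = "dose_response_fit"))
  }
  top0 <- means[dose == 0]
  bottom0 <- min(means)
  half <- (top0 + bottom0) / 2
  pos <- dose > 0
  ic50_0 <- dose[pos][which.min(abs(means[pos] - half))]
  w <- if (weighting == "inverse_y") 1 / pmax(df$y, 1) else rep(1, nrow(df))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (dose / exp(log_ic50))^hill),
      data = df, weights = w,
      start = list(top = top0, bottom = max(bottom0, 0),
                   log_ic50 = log(max(ic50_0, 1e-3)), hill = 1),
      lower = c(top = 0, bottom = 0, log_ic50 = log(1e-4), hill = 0.2),
      upper = c(top = Inf, bottom = Inf, log_ic50 = log(1e4), hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(ic50 = NA_real_, hill_slope = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          standard_errors = NULL, converged = FALSE,
                          diagnostics = conditionMessage(fit), data = data),
                     class = "dose_response_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(
    ic50 = exp(unname(cf["log_ic50"])),
    hill_slope = unname(cf["hill"]),
    top = unname(cf["top"]), bottom = unname(cf["bottom"]),
    standard_errors = setNames(as.numeric(se),
                               c("top", "bottom", "log_ic50", "hill")[seq_along(se)]),
    converged = isTRUE(fit$convInfo$isConv),
    diagnostics = fit$convInfo$stopMessage,
    data = data), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (!isTRUE(x$converged)) cat("  [not converged:", x$diagnostics, "]\n")
  cat(sprintf("  IC50 = %.4g Gy, Hill slope = %.3g\n", x$ic50, x$hill_slope))
  cat(sprintf("  top = %.5g, bottom = %.5g\n", x$top, x$bottom))
  invisible(x)
}

#' Assemble a qPCR Ct table
#'
#' @param sample sample identifiers (character).
#' @param gene gene names.
#' @param ct threshold-cycle values (finite, positive); replicates are
#'   additional rows with the same (sample, gene).
#' @param reference_genes housekeeping genes used for normalisation; every
#'   sample must carry Ct values for all of them.
#' @return An object of class `ct_table` (a validated data frame).
#' @export
ct_table <- function(sample, gene, ct, reference_genes = c("UBC", "GAPDH")) {
  df <- data.frame(sample = as.character(sample), gene = as.character(gene),
                   ct = as.numeric(ct), stringsAsFactors = FALSE)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and positive")
  for (s in unique(df$sample)) {
    missing_ref <- setdiff(reference_genes, df$gene[df$sample == s])
    if (length(missing_ref))
      stop(sprintf("sample '%s' lacks reference gene(s): %s",
                   s, paste(missing_ref, collapse = ", ")))
  }
  structure(list(data = df, reference_genes = reference_genes),
            class = "ct_table")
}

#' Delta-delta-Ct relative expression
#'
#' Replicate Ct values are averaged per (sample, gene); the reference level
#' per sample is the arithmetic mean of the reference-gene mean Cts (which
#' corresponds to normalising quantities on the geometric mean of the
#' reference-gene expression levels). Then
#' \deqn{\Delta Ct = Ct_{target} - \bar{Ct}_{ref}, \quad
#'       \Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}, \quad
#'       fold = 2^{-\Delta\Delta Ct}.}
#'
#' @param table a [ct_table()].
#' @param calibrator sample id used as the calibrator (fold = 1 by
#'   construction for that sample).
#' @return A data frame with one row per (sample, target gene):
#'   `sample`, `gene`, `delta_ct`, `ddct`, `fold`.
#' @export
ddct_normalize <- function(table, calibrator) {
  stopifnot(inherits(table, "ct_table"))
  df <- table$data
  refs <- table$reference_genes
  if (!calibrator %in% df$sample)
    stop(sprintf("calibrator sample '%s' not found", calibrator))
  agg <- stats::aggregate(ct ~ sample + gene, data = df, FUN = mean)
  n_rep <- stats::aggregate(ct ~ sample + gene, data = df, FUN = length)
  if (any(n_rep$ct == 1))
    warning("single-replicate Ct value(s) accepted", call. = FALSE)
  ref_level <- sapply(split(agg, agg$sample), function(d)
    mean(d$ct[d$gene %in% refs]))
  targets <- agg[!agg$gene %in% refs, , drop = FALSE]
  targets$delta_ct <- targets$ct - ref_level[targets$sample]
  cal <- targets[targets$sample == calibrator, c("gene", "delta_ct")]
  targets$ddct <- targets$delta_ct -
    cal$delta_ct[match(targets$gene, cal$gene)]
  targets$fold <- 2^(-targets$ddct)
  rownames(targets) <- NULL
  targets[, c("sample", "gene", "delta_ct", "ddct", "fold")]
}
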