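# Independent brute-force oracles for the nonlinear fitters: a grid over
# the nonlinear parameter(s) with the conditionally linear parameters
# profiled out by exact linear least squares (base qr, no optimizer).

stack_saturation <- function(data) {
  conc <- data$ligand_conc
  rbind(
    data.frame(conc = rep(conc, ncol(data$total_cpm)),
               cpm = as.vector(data$total_cpm), is_total = 1),
    data.frame(conc = rep(conc, ncol(data$nonspecific_cpm)),
               cpm = as.vector(data$nonspecific_cpm), is_total = 0))
}

oracle_saturation <- function(data, kd_grid) {
  df <- stack_saturation(data)
  best <- list(sse = Inf)
  for (kd in kd_grid) {
    X <- cbind(bmax = df$is_total * df$conc / (kd + df$conc),
               ns = df$conc, bg = 1)
    beta <- qr.solve(qr(X), df$cpm)
    sse <- sum((df$cpm - X %*% beta)^2)
    if (sse < best$sse)
      best <- list(sse = sse, kd = kd, bmax = beta[["bmax"]],
                   ns = beta[["ns"]], bg = beta[["bg"]])
  }
  best
}

oracle_competition <- function(data, log_ic50_grid = seq(-12, -5, by = 0.001)) {
  df <- data.frame(conc_m = rep(data$competitor_conc_um * 1e-6,
                                ncol(data$cpm)),
                   cpm = as.vector(data$cpm))
  best <- list(sse = Inf)
  for (lg in log_ic50_grid) {
    f <- 1 / (1 + df$conc_m / 10^lg)  # fraction still bound
    X <- cbind(bottom = 1 - f, top = f)
    beta <- qr.solve(qr(X), df$cpm)
    sse <- sum((df$cpm - X %*% beta)^2)
    if (sse < best$sse)
      best <- list(sse = sse, log_ic50 = lg,
                   top = beta[["top"]], bottom = beta[["bottom"]])
  }
  best
}

oracle_dose_response <- function(data, ic50_grid, hill_grid) {
  df <- data.frame(dose = rep(data$dose, ncol(data$response)),
                   y = as.vector(data$response))
  best <- list(sse = Inf)
  for (ic in ic50_grid) for (h in hill_grid) {
    f <- 1 / (1 + (df$dose / ic)^h)
    X <- cbind(bottom = 1 - f, top = f)
    beta <- qr.solve(qr(X), df$y)
    # respect the model's bottom >= 0 constraint when profiling
    if (beta[["bottom"]] < 0)
      beta <- c(bottom = 0, top = sum(df$y * f) / sum(f^2))
    sse <- sum((df$y - X %*% beta[colnames(X)])^2)
    if (sse < best$sse)
      best <- list(sse = sse, ic50 = ic, hill = h,
                   top = beta[["top"]], bottom = beta[["bottom"]])
  }
  best
}

# closed-form log-linear regression slope (hand formula, no lm)
loglinear_lambda <- function(t, y) {
  ly <- log(y)
  -sum((t - mean(t)) * (ly - mean(ly))) / sum((t - mean(t))^2)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
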