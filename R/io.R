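## Tabular I/O, configuration and report rendering. CSV in (RFC-4180,
## dot decimal), JSON reports out; every report embeds the config hash and
## seed so results are regenerable from the report alone.

config_defaults <- function() {
  list(counter_efficiency = 0.65,     # printed-formula value, not the 50%
       specific_activity_ci_mmol = 2175,
       assay_volume_ul = 100,         # unreported in protocols; flagged
       half_life_h = LU177_HALF_LIFE_H,
       mean_electron_mev = LU177_MEAN_ELECTRON_MEV,
       mouse_body_kg = 0.025,
       human_body_kg = 73.7,
       mass_table_path = NULL,        # NULL -> packaged reference table
       tissue_weight_set = "icrp60",
       ratio_convention = "both")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file, fills unset fields with the
#' package defaults, validates every constant, and records the provenance
#' (`"default"` or `"user"`) of each field. An empty or missing-field file
#' yields the full default configuration. Selecting the narrative counter
#' efficiency of 0.5 triggers a warning, since the printed conversion
#' formula uses 0.65.
#'
#' @param path configuration file path, or `NULL` for pure defaults.
#' @return An object of class `pipeline_config`: the validated settings
#'   with a `provenance` attribute.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  check_efficiency(cfg$counter_efficiency)
  for (f in c("specific_activity_ci_mmol", "assay_volume_ul",
              "half_life_h", "mean_electron_mev", "mouse_body_kg",
              "human_body_kg"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive number", f))
  if (!cfg$tissue_weight_set %in% c("icrp60", "icrp103"))
    stop("config field 'tissue_weight_set' must be icrp60 or icrp103")
  if (!cfg$ratio_convention %in% c("both", "ratio_of_means",
                                   "mean_of_ratios"))
    stop("config field 'ratio_convention' is invalid")
  if (!is.null(cfg$mass_table_path) && !file.exists(cfg$mass_table_path))
    stop("config field 'mass_table_path': file not found")
  prov <- setNames(ifelse(names(defaults) %in% names(user),
                          "user", "default"), names(defaults))
  structure(cfg, provenance = prov, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("pipeline configuration\n")
  for (f in names(prov)) {
    v <- x[[f]]
    cat(sprintf("  %-26s %-10s [%s]\n", f,
                if (is.null(v)) "<packaged>" else format(v), prov[[f]]))
  }
  invisible(x)
}

table_schemas <- function() {
  list(
    saturation_plate = list(
      required = c("conc", "replicate", "cpm", "condition"),
      numeric = c("conc", "cpm")),
    competition_plate = list(
      required = c("conc", "replicate", "cpm"),
      numeric = c("conc", "cpm")),
    dose_response = list(
      required = c("dose_gy", "replicate", "response"),
      numeric = c("dose_gy", "response")),
    ct = list(required = c("sample", "gene", "ct"), numeric = "ct"),
    biodistribution = list(
      required = c("animal", "organ", "time_h", "mass_g", "cpm",
                   "standard_cpm", "standard_fraction"),
      numeric = c("time_h", "mass_g", "cpm", "standard_cpm",
                  "standard_fraction")),
    masses = list(required = c("organ", "mass_g"), numeric = "mass_g"))
}

#' Read and validate a pipeline CSV
#'
#' @param path CSV file (RFC-4180, UTF-8, dot decimal).
#' @param schema one of `"saturation_plate"`, `"competition_plate"`,
#'   `"dose_response"`, `"ct"`, `"biodistribution"`, `"masses"`.
#' @return validated data frame; columns beyond the schema are preserved
#'   and listed in the `extra_columns` attribute.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema '", schema, "'; expected one of: ",
         paste(names(schemas), collapse = ", "))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  sc <- schemas[[schema]]
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s (check the delimiter",
                 basename(path), paste(miss, collapse = ", ")),
         " and header line)")
  for (col in sc$numeric)
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
  structure(df, extra_columns = setdiff(names(df), sc$required))
}

#' Build a saturation dataset from a long-format plate table
#'
#' @param df plate table with columns `conc` (nM), `replicate`, `cpm`,
#'   `condition` (`"total"` or `"nonspecific"`), as returned by
#'   [read_table()] with schema `"saturation_plate"`.
#' @param config a [load_config()] object supplying the assay constants.
#' @param cells_seeded cells per well.
#' @return a [saturation_dataset()].
#' @export
plate_to_saturation <- function(df, config = load_config(),
                                cells_seeded = 5e4) {
  stopifnot(all(df$condition %in% c("total", "nonspecific")))
  wide <- function(cond) {
    d <- df[df$condition == cond, ]
    m <- tapply(d$cpm, list(d$conc, d$replicate), mean)
    m[order(as.numeric(rownames(m))), , drop = FALSE]
  }
  tot <- wide("total"); nsp <- wide("nonspecific")
  saturation_dataset(as.numeric(rownames(tot)), tot, nsp, cells_seeded,
                     config$counter_efficiency,
                     config$specific_activity_ci_mmol)
}

#' Build a competition dataset from a long-format plate table
#'
#' @param df plate table with columns `conc` (uM), `replicate`, `cpm`.
#' @param config a [load_config()] object.
#' @param hot_cpm_added radioligand added per well (cpm).
#' @return a [competition_dataset()].
#' @export
plate_to_competition <- function(df, config = load_config(),
                                 hot_cpm_added = 1e5) {
  m <- tapply(df$cpm, list(df$conc, df$replicate), mean)
  m <- m[order(as.numeric(rownames(m))), , drop = FALSE]
  competition_dataset(as.numeric(rownames(m)), m, hot_cpm_added,
                      config$assay_volume_ul, config$counter_efficiency,
                      config$specific_activity_ci_mmol)
}

# small rolling hash so reports can embed a config fingerprint without
# external digest dependencies
config_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

strip_heavy <- function(x) {
  if (inherits(x, c("saturation_fit", "competition_fit",
                    "dose_response_fit"))) {
    x <- unclass(x); x$data <- NULL
  } else if (inherits(x, "dose_report")) {
    x <- unclass(x); x$fits <- lapply(x$fits, strip_heavy)
  } else if (inherits(x, "exponential_fit") ||
             inherits(x, "residence_time")) {
    x <- unclass(x)
  } else if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_heavy)
  }
  x
}

#' Write a machine-readable pipeline report
#'
#' Serialises stage results to JSON together with the configuration, its
#' hash, and any seeds, so that every figure or table can be regenerated
#' from the report alone. A human-readable rendering (fit parameters with
#' standard errors, %IA/g mean-and-SD tables, organ doses in mSv/MBq) is
#' returned invisibly as character lines.
#'
#' @param results named list of stage results (fits, curves, dose
#'   reports, plain values); an empty list yields a valid empty report.
#' @param path output JSON path.
#' @param config a [load_config()] object (defaults embedded otherwise).
#' @param seed the seed(s) used by any stochastic stage, if applicable.
#' @return invisibly, the rendered text lines.
#' @export
write_report <- function(results, path, config = load_config(),
                         seed = NULL) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null")
  report <- list(
    config = unclass(config),
    config_hash = config_hash(as.character(cfg_json)),
    config_provenance = as.list(attr(config, "provenance")),
    seed = seed,
    results = strip_heavy(results))
  ok <- tryCatch({
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write report to '", path, "': ",
         conditionMessage(ok))
  lines <- c(sprintf("radioknot report (config %s)",
                     config_hash(as.character(cfg_json))),
             utils::capture.output(utils::str(results, max.level = 2)))
  invisible(lines)
}

#' Re-read a written report
#'
#' @param path JSON report path written by [write_report()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
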