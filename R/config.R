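#' Run configuration for the phenotyping pipeline
#'
#' Collects the tunable analysis parameters in one validated object.
#' Defaults follow the reference protocol: significance stars at
#' p < 0.1 / 0.01 / 0.001, correlations masked at the 0.95 confidence
#' level, sample (n - 1) standard deviation in the coefficient of
#' variation, and a mass-balance acceptance band of 80--105 % of the
#' cell wall accounted for by the eight sugars plus Klason lignin.
#'
#' @param star_thresholds Named numeric vector mapping star codes to the
#'   p-value below which they apply; must be strictly decreasing.
#' @param confidence Confidence level used to mask non-significant
#'   Pearson correlations; in (0, 1).
#' @param mass_balance_band Length-2 numeric, the \[lo, hi\] band (percent
#'   of cell wall) outside which a composition total triggers a warning.
#' @param concentration_unit Unit the chromatography detector reports;
#'   only "mg/ml" is currently understood (masses are mg, volumes ml).
#' @param delimiter Field delimiter for all table I/O, "," or "\t".
#' @param correlation_level Whether correlations use replicate-level
#'   rows or accession means.
#' @param crystalline_tolerance Relative tolerance within which a
#'   crystalline amount exceeding the total is clamped to the total.
#' @param seed Integer seed for synthetic-data generation; `NULL` until
#'   a simulation is requested.
#' @param truth A [synth_truth()] object used by the simulation stage,
#'   or `NULL` for the defaults.
#'
#' @return A list of class `hemp_config`.
#' @export
#' @examples
#' cfg <- hemp_config(confidence = 0.99)
#' cfg$star_thresholds
hemp_config <- function(star_thresholds = c("*" = 0.1, "**" = 0.01, "***" = 0.001),
                        confidence = 0.95,
                        mass_balance_band = c(80, 105),
                        concentration_unit = "mg/ml",
                        delimiter = ",",
                        correlation_level = c("replicate", "accession_mean"),
                        crystalline_tolerance = 0.005,
                        seed = NULL,
                        truth = NULL) {
  correlation_level <- match.arg(correlation_level)
  if (!is.numeric(star_thresholds) || is.null(names(star_thresholds)) ||
      any(diff(unname(star_thresholds)) >= 0)) {
    abort("`star_thresholds` must be a named numeric vector with strictly decreasing p cut-offs.")
  }
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be a single number in (0, 1).")
  }
  if (length(mass_balance_band) != 2L || mass_balance_band[1] >= mass_balance_band[2]) {
    abort("`mass_balance_band` must be an increasing [lo, hi] pair.")
  }
  if (!identical(concentration_unit, "mg/ml")) {
    abort(paste0("Unsupported concentration unit '", concentration_unit,
                 "': AIR masses are tracked in mg and hydrolysate volumes in ml, so concentrations must be mg/ml."))
  }
  if (!delimiter %in% c(",", "\t")) abort("`delimiter` must be ',' or '\\t'.")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) abort("`seed` must be coercible to integer.")
  }
  structure(
    list(
      star_thresholds = star_thresholds,
      confidence = confidence,
      mass_balance_band = as.numeric(mass_balance_band),
      concentration_unit = concentration_unit,
      delimiter = delimiter,
      correlation_level = correlation_level,
      crystalline_tolerance = crystalline_tolerance,
      seed = seed,
      truth = truth
    ),
    class = "hemp_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [hemp_config()]; `star_thresholds` is a
#' mapping from star code to p cut-off, and `truth` a mapping passed on
#' to [synth_truth()]. Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A `hemp_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(hemp_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$star_thresholds)) {
    raw$star_thresholds <- unlist(raw$star_thresholds)
  }
  if (!is.null(raw$truth)) {
    raw$truth <- do.call(synth_truth, raw$truth)
  }
  do.call(hemp_config, raw)
}

#' @export
print.hemp_config <- function(x, ...) {
  cat("<hemp_config>\n")
  cat("  stars:", paste(sprintf("%s p<%g", names(x$star_thresholds), x$star_thresholds),
                        collapse = ", "), "\n")
  cat("  correlation confidence:", x$confidence,
      sprintf("(%s level)", x$correlation_level), "\n")
  cat("  mass balance band:", paste(x$mass_balance_band, collapse = "-"), "%\n")
  cat("  delimiter:", if (x$delimiter == ",") "comma" else "tab", "\n")
  cat("  seed:", if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}

star_code <- function(p, thresholds = c("*" = 0.1, "**" = 0.01, "***" = 0.001)) {
  thresholds <- sort(thresholds)  # most significant first
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    hit <- which(pi < thresholds)
    if (length(hit)) names(thresholds)[hit[1]] else "n.s."
  }, character(1))
}
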