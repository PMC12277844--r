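config_defaults <- function() {
  list(
    bin_width = 0.020,              # PSTH bin, s (20 ms)
    filter_order = 4,               # binomial filter order
    onset_window = 0.5,             # s after light onset
    offset_window = c(0.05, 0.3),   # s after light offset
    low_signal_cutoff = 10,         # spikes/s, corrected-peak low rule
    sd_multiplier = 4,              # threshold = mean + 4 SD
    dark_duration = 10,             # s of dark spontaneous activity
    ir_i50_expand = 10,             # I50 grid spans [min(I)/x, max(I)*x]
    ir_n_range = c(0.1, 10),        # Hill exponent grid range
    ir_grid_size = 60,              # grid nodes per parameter
    dilation_magnifications = c(1, 5, 10, 15),
    dilation_base_radius = 200,     # um, one electrode pitch
    synapse_radius = 1.5,           # um, triple-proximity rule
    rbc_reach = 10,                 # um, RBC-to-rosette selection
    circle_diameter = 500,          # um, sampling circles
    nnd_bin_width = 5,              # um, NND histogram bin
    nnd_range_max = 100,            # um, NND histogram nominal range
    seed = 1L
  )
}

validate_config <- function(cfg) {
  for (nm in c("bin_width", "low_signal_cutoff", "sd_multiplier",
               "dark_duration", "synapse_radius", "rbc_reach",
               "circle_diameter", "nnd_bin_width", "nnd_range_max",
               "dilation_base_radius", "onset_window"))
    if (cfg[[nm]] <= 0 && nm != "sd_multiplier")
      stopf("config field '%s' must be positive (got %g)", nm, cfg[[nm]])
  check_number(cfg$sd_multiplier, "sd_multiplier", lower = 0)
  check_number(cfg$filter_order, "filter_order", lower = 1)
  if (length(cfg$offset_window) != 2L ||
      cfg$offset_window[1] >= cfg$offset_window[2] || cfg$offset_window[1] < 0)
    stopf("config field 'offset_window' must be an increasing (start, end) pair")
  if (length(cfg$dilation_magnifications) != 4L ||
      is.unsorted(cfg$dilation_magnifications, strictly = TRUE))
    stopf("config field 'dilation_magnifications' must be 4 increasing values")
  if (length(cfg$ir_n_range) != 2L || cfg$ir_n_range[1] <= 0 ||
      cfg$ir_n_range[1] >= cfg$ir_n_range[2])
    stopf("config field 'ir_n_range' must be an increasing positive pair")
  check_number(cfg$ir_grid_size, "ir_grid_size", lower = 10)
  check_number(cfg$seed, "seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Analysis configuration
#'
#' All tunable constants of the pipeline in one validated object. Every
#' default mirrors the published analysis settings: 20-ms PSTH bins,
#' order-4 binomial smoothing, mean + 4 SD response threshold over 10 s of
#' dark activity, 500-ms onset / 50-300-ms offset response windows, 10-Hz
#' low-signal cutoff, dilation magnifications 1/5/10/15, 1.5-um synapse
#' radius, 10-um RBC reach, 500-um sampling circles.
#'
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return object of class `grafteval_config` (a validated named list).
#' @examples
#' grafteval_config(seed = 42)$sd_multiplier # 4
#' @export
grafteval_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stopf("config overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(validate_config(cfg), class = "grafteval_config")
}

#' @export
print.grafteval_config <- function(x, ...) {
  cat("grafteval configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Missing fields take their defaults; unknown fields are rejected with a
#' field-level message; all invariants are validated. An empty file yields
#' the full default configuration. `load_config(save_config(cfg))` is the
#' identity.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return a [grafteval_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stopf("config file must contain a mapping of fields")
  do.call(grafteval_config, raw)
}

#' Write an analysis configuration to YAML or JSON
#'
#' @param config a [grafteval_config].
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "grafteval_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
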