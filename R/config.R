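# Run configuration: versioned YAML schema with strict key checking.

RUN_CONFIG_SCHEMA <- list(
  version = 1L,
  scenario = "rest",
  seed = 1L,
  out_dir = ".",
  alarm = list(spo2_threshold_pct = 95, spo2_mean_window = 10,
               spo2_warmup_discard = 4, brady_bpm = 60, tachy_bpm = 100,
               pre_event_s = 300, post_event_s = 300),
  dsp = list(fir_order = 51, fir_cutoff_hz = 10, notch_hz = 50,
             qrs_threshold_fraction = 0.5, qrs_refractory_ms = 200,
             calibration_csv = NULL)
)

#' Build or load a run configuration
#'
#' `run_config()` fills defaults; `load_run_config()` reads a YAML file and
#' validates it against the schema, rejecting unknown keys.
#'
#' @param ... overrides of the top-level schema fields (`scenario`, `seed`,
#'   `out_dir`, `alarm`, `dsp`).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(...) {
  validate_run_config(utils::modifyList(RUN_CONFIG_SCHEMA, list(...)))
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  raw_cfg <- yaml::read_yaml(path)
  if (!is.list(raw_cfg)) stopf("config file must contain a YAML mapping")
  validate_run_config(utils::modifyList(RUN_CONFIG_SCHEMA, raw_cfg))
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_SCHEMA))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (section in c("alarm", "dsp")) {
    bad <- setdiff(names(cfg[[section]]), names(RUN_CONFIG_SCHEMA[[section]]))
    if (length(bad))
      stopf("unknown %s config keys: %s", section, paste(bad, collapse = ", "))
  }
  if (!identical(as.integer(cfg$version), 1L))
    stopf("unsupported config version: %s", cfg$version)
  if (!cfg$scenario %in% scenario_names())
    stopf("unknown scenario in config: %s", cfg$scenario)
  # constructor validation
  do.call(alarm_config, cfg$alarm)
  structure(cfg, class = "run_config")
}
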