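# DIM attribute configurations for the pulse-oximeter (11073-10404) and
# basic-ECG (11073-10406) specializations.

# attribute id constants (hex values as used on the textual dialect too)
ATTR_IDS <- c(type = 2636L + 1L,          # object type
              observed_value = 2636L,     # 0x0A4C, basic numeric observed value
              unit_code = 2282L,
              sample_period = 2445L,
              timestamp = 2448L)

#' Standard / extended device configuration
#'
#' The pulse-oximeter configuration is *standard*: managers know its layout
#' a priori (config id in the standard number space, no configuration
#' exchange needed). The basic-ECG configuration is *extended* (config id
#' in the extended space, >= 0x4000): the agent must describe it with a
#' configuration report before data can flow. The ECG configuration carries
#' a realtime sample-array object for the lead-II waveform, a numeric
#' object for the heart rate, and a status object for the lead-off flags.
#'
#' @param specialization `"pulse_oximeter_10404"` or `"basic_ecg_10406"`.
#' @return an object of class `device_config` with `specialization`,
#'   `config_id`, `standard` (logical), and `objects` (list of
#'   `handle` / `object_class` / `attributes`).
#' @export
standard_config <- function(specialization = c("pulse_oximeter_10404",
                                               "basic_ecg_10406")) {
  specialization <- match.arg(specialization)
  if (specialization == "pulse_oximeter_10404") {
    objects <- list(
      list(handle = 1L, object_class = "numeric",          # SpO2 saturation
           attributes = c(ATTR_IDS[["type"]], ATTR_IDS[["observed_value"]],
                          ATTR_IDS[["unit_code"]], ATTR_IDS[["timestamp"]])),
      list(handle = 10L, object_class = "numeric",         # pulse rate
           attributes = c(ATTR_IDS[["type"]], ATTR_IDS[["observed_value"]],
                          ATTR_IDS[["unit_code"]], ATTR_IDS[["timestamp"]])))
    config_id <- 0x0190L   # standard config space
    standard <- TRUE
  } else {
    objects <- list(
      list(handle = 1L, object_class = "realtime_sample_array",  # lead II
           attributes = c(ATTR_IDS[["type"]], ATTR_IDS[["sample_period"]],
                          ATTR_IDS[["unit_code"]])),
      list(handle = 2L, object_class = "numeric",                # heart rate
           attributes = c(ATTR_IDS[["type"]], ATTR_IDS[["observed_value"]],
                          ATTR_IDS[["unit_code"]], ATTR_IDS[["timestamp"]])),
      list(handle = 3L, object_class = "status",                 # lead-off
           attributes = c(ATTR_IDS[["type"]], ATTR_IDS[["observed_value"]])))
    config_id <- 0x4001L   # extended config space (>= 0x4000)
    standard <- FALSE
  }
  structure(list(specialization = specialization, config_id = config_id,
                 standard = standard, objects = objects),
            class = "device_config")
}

encode_device_config <- function(cfg) {
  stopifnot(inherits(cfg, "device_config"))
  out <- c(u16(SPECIALIZATIONS[[cfg$specialization]]), u16(cfg$config_id),
           as.raw(as.integer(cfg$standard)), u16(length(cfg$objects)))
  for (ob in cfg$objects) {
    out <- c(out, u16(ob$handle), u16(OBJECT_CLASSES[[ob$object_class]]),
             u16(length(ob$attributes)), u16(ob$attributes))
  }
  out
}

decode_device_config <- function(bytes) {
  spec_code <- r_u16(bytes, 1L)
  specialization <- names(SPECIALIZATIONS)[match(spec_code, SPECIALIZATIONS)]
  if (is.na(specialization)) stopf("unknown specialization code %d", spec_code)
  config_id <- r_u16(bytes, 3L)
  standard <- as.logical(as.integer(bytes[5L]))
  nobj <- r_u16(bytes, 6L)
  at <- 8L
  objects <- vector("list", nobj)
  for (i in seq_len(nobj)) {
    handle <- r_u16(bytes, at)
    cls <- names(OBJECT_CLASSES)[r_u16(bytes, at + 2L)]
    nattr <- r_u16(bytes, at + 4L)
    attrs <- vapply(seq_len(nattr) - 1L,
                    function(j) r_u16(bytes, at + 6L + 2L * j), integer(1))
    objects[[i]] <- list(handle = handle, object_class = cls,
                         attributes = attrs)
    at <- at + 6L + 2L * nattr
  }
  structure(list(specialization = specialization, config_id = config_id,
                 standard = standard, objects = objects),
            class = "device_config")
}
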