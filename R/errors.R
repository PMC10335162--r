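# Classed conditions so callers can branch on failure mode rather than
# matching message strings.

fm_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fm_error"), call = call))
}

fm_parse_error    <- function(msg) fm_error(msg, "fm_parse_error")
fm_schema_error   <- function(msg) fm_error(msg, "fm_schema_error")
fm_geometry_error <- function(msg) fm_error(msg, "fm_geometry_error")
fm_param_error    <- function(msg) fm_error(msg, "fm_param_error")
fm_io_error       <- function(msg) fm_error(msg, "fm_io_error")
fm_segmentation_failure <- function(msg) fm_error(msg, "fm_segmentation_failure")
fm_config_error   <- function(msg) fm_error(msg, "fm_config_error")
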