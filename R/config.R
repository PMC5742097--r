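#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list; any subset can
#' be overridden from a YAML file via [read_config()].  Units: frequencies
#' in Hz, durations in ms, gaze coordinates in screen pixels (origin
#' top-left; the default geometry is 1024 x 768).
#'
#' @return nested named list of parameters.
#' @export
#' @examples
#' default_config()$asynchrony$win_ms
default_config <- function() {
  list(
    screen = list(width_px = 1024, height_px = 768),
    preprocess = list(target_rate = 256, highpass_hz = 1.5,
                      notch_hz = c(50, 100), notch_q = 30,
                      filter_order = 4, pre_ms = 2000, post_ms = 2000),
    tfr = list(f_min = 1, f_max = 80, f_step = 0.5, n_cycles = 7,
               power_rate = 8),
    bands = list(beta = list(c(14, 16), c(16, 18), c(18, 20)),
                 gamma = list(c(40, 48), c(52, 60), c(60, 70), c(52, 70))),
    congruency = list(shrinkage = NULL),
    asynchrony = list(win_ms = 250, hop_ms = 50, frac = 0.30,
                      ci_level = 0.90, n_draws = 1000, min_valid = 0.5,
                      rule = "inside", max_null_pool = 2e5),
    behavioral = list(outlier_z = 4),
    prediction = list(bootstrap_B = 2000,
                      combined_band = c(52, 70)),
    seed = 1L
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested named list as [default_config()], with overrides applied.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_("config file not found: %s", path)
  modifyList(cfg, yaml::read_yaml(path))
}
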