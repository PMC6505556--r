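#' Read a run configuration file
#'
#' Parses a YAML configuration describing geometry, material, kinematics
#' and neural-filter settings into ready-to-use model objects. See
#' `system.file("extdata", "haltere_default.yaml", package = "halteredyn")`
#' for a complete annotated example. All lengths in the file are in
#' micrometres; they are converted to SI metres when the model is built.
#'
#' @param path Path to the YAML file.
#' @return List with `model` ([haltere_model()]), `kinematics`
#'   ([kinematics_spec()]) and `filter` ([neural_filter()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses exponents without an explicit sign (1.5e9) as strings
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  g <- cfg$geometry
  sec <- switch(g$section$kind,
    annulus = annulus_section(g$section$r_out_um, g$section$r_in_um),
    plus = plus_section(g$section$height_um, g$section$thickness_um),
    stop("unknown section kind '", g$section$kind, "'")
  )
  b <- g$bulb
  bulb <- if (identical(b$shape, "sphere")) {
    bulb_spec("sphere", radius = b$radius_um,
              offset = as.numeric(b$offset_um %||% c(0, 0)),
              density = b$density %||% 1200)
  } else {
    bulb_spec("ellipsoid", semi_axes = as.numeric(b$semi_axes_um),
              offset = as.numeric(b$offset_um %||% c(0, 0)),
              density = b$density %||% 1200)
  }
  m <- cfg$material
  mat <- material_spec(youngs_modulus = num(m$youngs_modulus_pa),
                       density = num(m$density_kg_m3), poisson = num(m$poisson))
  model <- haltere_model(sec, material = mat, bulb = bulb,
                         length = g$stalk_length_um,
                         n_elements = g$n_elements %||% 31)
  k <- cfg$kinematics
  kin <- kinematics_spec(
    amplitude = k$amplitude_rad %||% (pi / 2),
    frequency = k$frequency_hz %||% 40,
    rotation_rate = k$rotation_rate_rad_s %||% 0,
    ramp_periods = k$ramp_periods %||% 2,
    total_periods = k$total_periods %||% 10,
    analysis_periods = k$analysis_periods %||% 5,
    dt = num(k$dt_s) %||% 1e-5
  )
  f <- cfg$filter
  filt <- if (is.null(f)) neural_filter() else {
    sta <- make_sta(sta_params(
      window = (f$window_ms %||% 20) * 1e-3,
      freq = f$freq_hz %||% 45,
      center = (f$center_ms %||% 8) * 1e-3,
      sd_decay = (f$sd_ms %||% 3.5) * 1e-3,
      dt = (f$dt_ms %||% 0.1) * 1e-3
    ))
    neural_filter(taps = sta$taps, dt = sta$params$dt,
                  xi0 = f$xi0 %||% 0.5, slope = f$slope %||% 0.08,
                  pmax = f$pmax %||% 1, threshold = f$threshold %||% 0.9,
                  strain_floor = num(f$strain_floor) %||% 5e-6,
                  floor_exponent = f$floor_exponent %||% 4)
  }
  list(model = model, kinematics = kin, filter = filt)
}
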