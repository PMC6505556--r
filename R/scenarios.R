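#' Registry of standard haltere scenarios
#'
#' Hard-codes the canonical parameter matrix explored by the analysis: two
#' stalk cross-sections (CS: hollow circle, outer/inner radius 150/50
#' \eqn{\mu m}; PS: plus-shaped, 481 x 40.8 \eqn{\mu m}), three bulb
#' geometries (sphere of radius 500 \eqn{\mu m}; equal-volume prolate
#' ellipsoids with semi-major axis 1000 \eqn{\mu m} oriented vertically
#' (z', in the stroke plane) or horizontally (y', lateral), each mounted
#' asymmetrically with a 150 \eqn{\mu m} centre-of-mass offset along its
#' long axis), and two kinematic conditions (flapping only, or flapping
#' plus a 10 rad/s body rotation about global Z).
#'
#' @return Named list of scenario definitions. Names are stable:
#'   `cs_flap`, `cs_rot`, `ps_flap`, `ps_rot`, `ellipsoid_v_flap`,
#'   `ellipsoid_v_rot`, `ellipsoid_h_flap`, `ellipsoid_h_rot`.
#' @export
scenario_registry <- function() {
  cs <- annulus_section(150, 50)
  ps <- plus_section(481, 40.8)
  sphere <- bulb_spec("sphere", radius = 500)
  b <- equal_volume_ellipsoid(500, 1000)
  ell_v <- bulb_spec("ellipsoid", semi_axes = c(b, b, 1000), offset = c(0, 150))
  ell_h <- bulb_spec("ellipsoid", semi_axes = c(b, 1000, b), offset = c(150, 0))
  mk <- function(section, bulb, rotation, description) {
    list(section = section, bulb = bulb, rotation = rotation,
         description = description)
  }
  list(
    cs_flap = mk(cs, sphere, 0, "circular stalk, spherical bulb, flapping only"),
    cs_rot = mk(cs, sphere, 10, "circular stalk, spherical bulb, flapping + rotation"),
    ps_flap = mk(ps, sphere, 0, "plus-shaped stalk, spherical bulb, flapping only"),
    ps_rot = mk(ps, sphere, 10, "plus-shaped stalk, spherical bulb, flapping + rotation"),
    ellipsoid_v_flap = mk(cs, ell_v, 0,
                          "vertical ellipsoid bulb, z' offset, flapping only"),
    ellipsoid_v_rot = mk(cs, ell_v, 10,
                         "vertical ellipsoid bulb, z' offset, flapping + rotation"),
    ellipsoid_h_flap = mk(cs, ell_h, 0,
                          "horizontal ellipsoid bulb, y' offset, flapping only"),
    ellipsoid_h_rot = mk(cs, ell_h, 10,
                         "horizontal ellipsoid bulb, y' offset, flapping + rotation")
  )
}

#' Run one haltere scenario end to end
#'
#' Builds the model and kinematics for a named scenario (or an explicit
#' definition), integrates the beam dynamics, and derives deformation
#' angles, base strains at 16 circumferential positions, and a summary of
#' peak-to-peak amplitudes and dominant frequencies over the post-transient
#' analysis window.
#'
#' @param scenario A name from [scenario_registry()] or a list with fields
#'   `section`, `bulb`, `rotation`.
#' @param n_elements Stalk elements (default 31).
#' @param kin Optional [kinematics_spec()] override; `rotation_rate` is
#'   taken from the scenario.
#' @param rotation_rate Optional override of the scenario's rotation rate
#'   (rad/s).
#' @param strain_x Span position for strain recovery (\eqn{\mu m}).
#' @param alpha Circumferential strain angles (rad).
#' @param alpha_k,alpha_m Rayleigh damping coefficients.
#' @param keep_history Keep the full nodal history in the result (large).
#' @param out_dir Optional directory: writes `angles.csv`, `strains.csv`
#'   (tidy long format) and `summary.csv`.
#' @return Object of class `haltere_run`: the model, kinematics, angle
#'   data frame, strain matrix (attribute `t`), and `summary` list.
#' @export
run_scenario <- function(scenario, n_elements = 31, kin = NULL,
                         rotation_rate = NULL, strain_x = 300,
                         alpha = seq(0, 2 * pi, length.out = 17)[-17],
                         alpha_k = 1e-5, alpha_m = 0,
                         keep_history = FALSE, out_dir = NULL) {
  if (is.character(scenario)) {
    reg <- scenario_registry()
    if (!scenario %in% names(reg)) {
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(reg), collapse = ", "))
    }
    name <- scenario
    scenario <- reg[[scenario]]
  } else {
    name <- scenario$description %||% "custom"
  }
  rot <- rotation_rate %||% scenario$rotation
  if (is.null(kin)) {
    kin <- kinematics_spec(rotation_rate = rot)
  } else {
    kin$rotation_rate <- rot
  }
  model <- haltere_model(scenario$section, bulb = scenario$bulb,
                         n_elements = n_elements)
  sys <- build_beam(model, alpha_k = alpha_k, alpha_m = alpha_m)
  F <- load_history(model, kin)
  sim <- newmark_simulate(sys, F, dt = kin$dt, duration = kin$duration)
  angles <- deformation_angles(sim)
  strains <- strain_at(sim, strain_x, alpha)
  win <- analysis_window(kin)
  summ <- list(
    scenario = name,
    rotation_rate = rot,
    window = win,
    p2p_dphi = peak_to_peak(angles$t, angles$dphi, win),
    p2p_dtheta = peak_to_peak(angles$t, angles$dtheta, win),
    p2p_dgamma = peak_to_peak(angles$t, angles$dgamma, win),
    freq_dphi = dominant_frequency(angles$t, angles$dphi, win),
    freq_dtheta = dominant_frequency(angles$t, angles$dtheta, win),
    freq_dgamma = dominant_frequency(angles$t, angles$dgamma, win),
    mean_dtheta = mean(angles$dtheta[angles$t >= win[1]]),
    f1_hz = NA_real_
  )
  run <- list(name = name, model = model, kin = kin, angles = angles,
              strains = strains, strain_x = strain_x, alpha = alpha,
              summary = summ)
  if (keep_history) run$sim <- sim
  class(run) <- "haltere_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.haltere_run <- function(x, ...) {
  s <- x$summary
  cat("<haltere_run>", x$name, "\n")
  cat(sprintf("  rotation %g rad/s | p2p dphi %.3g, dtheta %.3g, dgamma %.3g rad\n",
              s$rotation_rate, s$p2p_dphi, s$p2p_dtheta, s$p2p_dgamma))
  cat(sprintf("  dominant freqs (Hz): dphi %g, dtheta %g, dgamma %g\n",
              s$freq_dphi, s$freq_dtheta, s$freq_dgamma))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$angles, file.path(out_dir, "angles.csv"),
                   row.names = FALSE)
  t <- attr(run$strains, "t")
  long <- do.call(rbind, lapply(seq_along(run$alpha), function(i) {
    data.frame(t = t, quantity = "strain_xx", alpha = run$alpha[i],
               value = run$strains[, i])
  }))
  utils::write.csv(long, file.path(out_dir, "strains.csv"), row.names = FALSE)
  s <- run$summary
  utils::write.csv(
    data.frame(metric = c("p2p_dphi", "p2p_dtheta", "p2p_dgamma",
                          "freq_dphi", "freq_dtheta", "freq_dgamma"),
               value = c(s$p2p_dphi, s$p2p_dtheta, s$p2p_dgamma,
                         s$freq_dphi, s$freq_dtheta, s$freq_dgamma)),
    file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Compare two scenario runs on a summary metric
#'
#' @param a,b `haltere_run` objects.
#' @param metric One of the numeric summary fields, e.g. `"p2p_dphi"`,
#'   `"p2p_dtheta"`, `"p2p_dgamma"`.
#' @param type `"ratio"` (a / b) or `"difference"` (a - b).
#' @return A single number.
#' @export
compare_scenarios <- function(a, b, metric, type = c("ratio", "difference")) {
  type <- match.arg(type)
  stopifnot(inherits(a, "haltere_run"), inherits(b, "haltere_run"))
  if (!metric %in% names(a$summary) || !metric %in% names(b$summary)) {
    stop("metric '", metric, "' not present in the run summaries")
  }
  va <- a$summary[[metric]]
  vb <- b$summary[[metric]]
  if (!is.numeric(va) || !is.numeric(vb)) stop("metric '", metric, "' is not numeric")
  if (type == "ratio") va / vb else va - vb
}

#' Predict circumferential spike trains for a pair of runs
#'
#' Applies the strain-to-spike pipeline to matching circumferential
#' positions of a flapping-only run and a flapping-plus-rotation run, and
#' tabulates per-location spike counts and timing shifts.
#'
#' @param run_flap,run_rot `haltere_run` objects from [run_scenario()]
#'   sharing the same strain sampling positions.
#' @param filt A [neural_filter()].
#' @param alpha Circumferential angles to encode (must be among the runs'
#'   strain columns); defaults to the five first-quadrant positions
#'   0, pi/8, pi/4, 3pi/8, pi/2.
#' @return Object of class `spike_summary`: data frame with one row per
#'   location (`alpha`, `n_flap`, `n_rot`, `spikes_per_cycle_rot`,
#'   `mean_shift_ms`, `rotation_only`) plus the spike trains as attribute
#'   `trains`.
#' @export
encode_runs <- function(run_flap, run_rot, filt = neural_filter(),
                        alpha = c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2)) {
  stopifnot(inherits(run_flap, "haltere_run"), inherits(run_rot, "haltere_run"))
  f <- run_flap$kin$frequency
  win <- analysis_window(run_flap$kin)
  dt <- run_flap$kin$dt
  cols <- vapply(alpha, function(a) {
    i <- which(abs(run_flap$alpha - a) < 1e-9)
    if (length(i) != 1) stop("alpha = ", a, " not among the run's strain positions")
    i
  }, integer(1))
  trains <- list()
  rows <- lapply(seq_along(alpha), function(j) {
    a <- alpha[j]
    tf <- predict_spikes(run_flap$strains[, cols[j]], filt, dt, window = win,
                         location = a, condition = "flapping")
    tr <- predict_spikes(run_rot$strains[, cols[j]], filt, dt, window = win,
                         location = a, condition = "rotation")
    trains[[j]] <<- list(flap = tf, rot = tr)
    ts <- timing_shift(tf, tr, f)
    data.frame(alpha = a,
               n_flap = nrow(tf),
               n_rot = nrow(tr),
               spikes_per_cycle_rot = spikes_per_cycle(tr, f, win),
               mean_shift_ms = ts$mean_shift_ms,
               rotation_only = ts$rotation_only)
  })
  out <- do.call(rbind, rows)
  attr(out, "trains") <- trains
  attr(out, "frequency") <- f
  class(out) <- c("spike_summary", "data.frame")
  out
}
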