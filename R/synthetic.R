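#' Parameters of the synthetic spike-triggered average
#'
#' The measured STA of campaniform sensilla is published only as a
#' normalised curve: a decaying oscillation over a few tens of
#' milliseconds. This generator produces a Gabor-like stand-in,
#' \deqn{g(\tau) = \exp\!\big(-(\tau - \tau_0)^2 / 2\sigma^2\big)\,
#'   \sin\!\big(2\pi f_{STA} (\tau - \tau_0)\big),}
#' sampled on lags \eqn{\tau \in [0, W]} (most recent lag first) and
#' normalised to unit Euclidean norm.
#'
#' Defaults: window `W` = 20 ms, envelope centre \eqn{\tau_0} = 8 ms,
#' envelope width \eqn{\sigma} = 3.5 ms, oscillation frequency 45 Hz.
#' The short, broadband wavelet responds to both the flapping line (40 Hz)
#' and its first harmonic (80 Hz, the Coriolis signature) with similar
#' normalised projections, which is what lets a single filter describe
#' sensilla all around the stalk circumference.
#'
#' @param window Window length (s).
#' @param freq Oscillation frequency (Hz).
#' @param center Envelope centre \eqn{\tau_0} (s).
#' @param sd_decay Gaussian envelope width \eqn{\sigma} (s).
#' @param dt Sample interval (s).
#' @return Object of class `sta_params`.
#' @export
sta_params <- function(window = 0.020, freq = 45, center = 0.008,
                       sd_decay = 0.0035, dt = 1e-4) {
  stopifnot(window > 0, freq > 0, center > 0, center < window,
            sd_decay > 0, dt > 0, dt < window)
  p <- list(window = window, freq = freq, center = center,
            sd_decay = sd_decay, dt = dt)
  class(p) <- "sta_params"
  p
}

#' Generate a synthetic spike-triggered average
#'
#' @param params A [sta_params()].
#' @return List with `taps` (unit-norm numeric vector, most recent lag
#'   first), `lags` (s) and the originating `params`. Warns if the Gaussian
#'   envelope is not essentially contained in the window
#'   (`center + 2 sd_decay > window`).
#' @export
make_sta <- function(params = sta_params()) {
  stopifnot(inherits(params, "sta_params"))
  if (params$center + 2 * params$sd_decay > params$window) {
    warning("STA envelope extends beyond the window; filter is truncated")
  }
  lags <- seq(0, params$window, by = params$dt)
  taps <- exp(-(lags - params$center)^2 / (2 * params$sd_decay^2)) *
    sin(2 * pi * params$freq * (lags - params$center))
  taps <- taps / sqrt(sum(taps^2))
  list(taps = taps, lags = lags, params = params)
}

#' Parameters of a synthetic strain series
#'
#' Generates strain signals with the structure the haltere simulations
#' produce at the stalk base: a dominant component at the flapping
#' frequency `f`, a small quadrature component at `2f` (the Coriolis
#' signature; relative amplitude defaulting to 1/25, mirroring the
#' in-plane to out-of-plane amplitude ratio), a constant tensile offset
#' from centrifugal tension, and optional white noise.
#'
#' @param amplitude Base strain amplitude at `f` (dimensionless strain).
#' @param freq Fundamental frequency `f` (Hz).
#' @param rel_2f Relative amplitude of the `2f` component.
#' @param phase_2f Phase of the `2f` component (rad).
#' @param offset Constant tensile strain offset.
#' @param noise_sd Standard deviation of additive white noise.
#' @param duration Series duration (s).
#' @param dt Sample interval (s).
#' @param seed RNG seed; generation is bit-reproducible for a fixed seed.
#' @return Object of class `strain_params`.
#' @export
strain_params <- function(amplitude = 3e-4, freq = 40, rel_2f = 1 / 25,
                          phase_2f = 0, offset = 3e-6, noise_sd = 0,
                          duration = 0.5, dt = 1e-4, seed = 1L) {
  stopifnot(amplitude >= 0, freq > 0, noise_sd >= 0, duration > 0, dt > 0)
  p <- list(amplitude = amplitude, freq = freq, rel_2f = rel_2f,
            phase_2f = phase_2f, offset = offset, noise_sd = noise_sd,
            duration = duration, dt = dt, seed = seed)
  class(p) <- "strain_params"
  p
}

#' Generate a synthetic strain time series
#'
#' \deqn{s(t) = o + A \sin(2\pi f t) + r A \sin(4\pi f t + \psi) + \eta(t)}
#' with Gaussian white noise \eqn{\eta}. The RNG state of the session is
#' left untouched.
#'
#' @param params A [strain_params()].
#' @return Data frame with columns `t` and `strain`.
#' @export
make_strain <- function(params = strain_params()) {
  stopifnot(inherits(params, "strain_params"))
  t <- seq(0, params$duration, by = params$dt)
  s <- params$offset +
    params$amplitude * sin(2 * pi * params$freq * t) +
    params$rel_2f * params$amplitude * sin(4 * pi * params$freq * t + params$phase_2f)
  if (params$noise_sd > 0) {
    noise <- local_rng_normal(length(t), params$seed) * params$noise_sd
    s <- s + noise
  }
  data.frame(t = t, strain = s)
}

# draw n standard normals under a private RNG state
local_rng_normal <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Reference end-to-end encoding fixture
#'
#' Writes a small frozen fixture bundle for regression tests: the default
#' STA taps, five synthetic strain series whose `2f` phases mimic
#' circumferential sampling positions, and the spike tables computed for
#' each series by a deliberately naive brute-force projection loop
#' (independent of the vectorised [project_stimulus()] path). The bundle
#' is deterministic under a fixed seed, so regenerating it must reproduce
#' identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the noise in the synthetic strains.
#' @return Invisibly, a list with the file paths, the per-file MD5 hashes
#'   and the generation metadata.
#' @export
reference_pipeline_fixture <- function(dir = file.path(tempdir(), "haltere_fixture"),
                                       seed = 104L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  filt <- neural_filter()
  sta <- data.frame(lag_ms = (seq_along(filt$taps) - 1) * filt$dt * 1e3,
                    tap = filt$taps)
  sta_path <- file.path(dir, "sta.csv")
  utils::write.csv(sta, sta_path, row.names = FALSE)
  phases <- c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2)
  paths <- character(0)
  spike_rows <- list()
  for (i in seq_along(phases)) {
    sp <- strain_params(phase_2f = phases[i], noise_sd = 2e-6,
                        seed = seed + i)
    ser <- make_strain(sp)
    p <- file.path(dir, sprintf("strain_phase%02d.csv", i))
    utils::write.csv(ser, p, row.names = FALSE)
    paths <- c(paths, p)
    train <- brute_force_spikes(ser$strain, filt, sp$dt)
    if (length(train) > 0) {
      spike_rows[[i]] <- data.frame(series = i, phase_2f = phases[i],
                                    time_s = train)
    }
  }
  spikes <- do.call(rbind, spike_rows)
  spike_path <- file.path(dir, "expected_spikes.csv")
  utils::write.csv(spikes, spike_path, row.names = FALSE)
  files <- c(sta_path, paths, spike_path)
  invisible(list(files = files,
                 md5 = tools::md5sum(files),
                 seed = seed, phases = phases))
}

# straightforward O(n L) reference implementation of the projection,
# probability and peak-picking chain; kept simple on purpose so it can
# serve as an oracle for the vectorised path
brute_force_spikes <- function(strain, filt, dt) {
  dec <- round(filt$dt / dt)
  x <- strain[seq(1, length(strain), by = dec)]
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  gate <- r^filt$floor_exponent /
    (r^filt$floor_exponent + filt$strain_floor^filt$floor_exponent)
  L <- length(filt$taps)
  n <- length(x)
  xi <- rep(NA_real_, n)
  for (i in L:n) {
    w <- x[i:(i - L + 1)]  # most recent sample first, matching tap order
    xi[i] <- gate * sum(w * filt$taps) / sqrt(sum(w^2))
  }
  p <- filt$pmax / (1 + exp(-(xi - filt$xi0) / filt$slope))
  tt <- (seq_len(n) - 1) * filt$dt
  times <- numeric(0)
  for (i in (L + 1):(n - 1)) {
    if (!is.na(p[i]) && !is.na(p[i - 1]) && !is.na(p[i + 1]) &&
        p[i] > p[i - 1] && p[i] > p[i + 1] && p[i] > filt$threshold) {
      denom <- p[i - 1] - 2 * p[i] + p[i + 1]
      shift <- if (abs(denom) > 1e-15) 0.5 * (p[i - 1] - p[i + 1]) / denom else 0
      times <- c(times, tt[i] + shift * filt$dt)
    }
  }
  times
}
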