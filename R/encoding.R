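#' Linear-nonlinear neural filter for campaniform spike prediction
#'
#' Bundles the two stages of the spike-prediction model: a unit-norm
#' spike-triggered average (STA) used as a linear filter on the strain
#' history, and a sigmoidal nonlinear decision function (NLD) mapping the
#' normalised projection \eqn{\xi} to a firing probability.
#'
#' The projection is a windowed cosine similarity, so spike *timing* is
#' independent of the overall strain scale. Spike *existence* additionally
#' encodes absolute strain amplitude through a saturating sensitivity gate
#' \eqn{g(r) = r^n / (r^n + \epsilon_0^n)} on the root-mean-square strain
#' `r` of the series: signals well above the detection floor
#' \eqn{\epsilon_0} are unaffected (g ~ 1) while sub-floor signals cannot
#' fire, emulating the finite mechanical sensitivity of the sensilla.
#' Because the gate is a single number per series, it scales \eqn{\xi(t)}
#' uniformly and never moves the time of a peak.
#'
#' @param taps STA filter taps, most recent lag first; defaults to
#'   [make_sta()] with standard parameters. Normalised to unit Euclidean
#'   norm.
#' @param dt Sample interval of the taps (s).
#' @param xi0 NLD sigmoid midpoint.
#' @param slope NLD sigmoid slope parameter k.
#' @param pmax NLD ceiling (maximum firing probability).
#' @param threshold Firing-probability threshold above which a local peak
#'   produces a spike.
#' @param strain_floor Detection floor \eqn{\epsilon_0} on RMS strain
#'   (dimensionless strain; default 5e-6, i.e. 5 microstrain).
#' @param floor_exponent Hill exponent `n` of the sensitivity gate.
#' @return Object of class `neural_filter`.
#' @export
neural_filter <- function(taps = NULL, dt = 1e-4, xi0 = 0.5, slope = 0.08,
                          pmax = 1, threshold = 0.9, strain_floor = 5e-6,
                          floor_exponent = 4) {
  if (is.null(taps)) {
    sta <- make_sta(sta_params(dt = dt))
    taps <- sta$taps
  }
  stopifnot(length(taps) > 1, all(is.finite(taps)), dt > 0,
            slope > 0, pmax > 0, pmax <= 1, threshold > 0, threshold < 1,
            strain_floor >= 0)
  taps <- taps / sqrt(sum(taps^2))
  filt <- list(taps = taps, dt = dt, xi0 = xi0, slope = slope, pmax = pmax,
               threshold = threshold, strain_floor = strain_floor,
               floor_exponent = floor_exponent)
  class(filt) <- "neural_filter"
  filt
}

#' @export
print.neural_filter <- function(x, ...) {
  cat("<neural_filter>", length(x$taps), "taps @", x$dt * 1e3, "ms,",
      "window", (length(x$taps) - 1) * x$dt * 1e3, "ms\n")
  cat(sprintf("  NLD: xi0 = %g, k = %g, Pmax = %g, spike threshold = %g\n",
              x$xi0, x$slope, x$pmax, x$threshold))
  cat(sprintf("  sensitivity gate: floor %g strain, exponent %g\n",
              x$strain_floor, x$floor_exponent))
  invisible(x)
}

#' Normalised projection of the STA onto a strain stimulus
#'
#' Computes \eqn{\xi(t)}: the mean-removed strain window ending at `t` is
#' correlated with the unit-norm STA and divided by the window's Euclidean
#' norm, giving a cosine similarity in \[-1, 1\]; this is then multiplied
#' by the series-level sensitivity gate (see [neural_filter()]). The
#' stimulus is resampled to the filter's sample interval if needed (the
#' ratio must be an integer; the simulated strains are heavily
#' oversampled, so plain decimation is exact to numerical precision).
#'
#' @param strain Strain time series (numeric vector).
#' @param filt A [neural_filter()].
#' @param dt Sample interval of `strain` (s).
#' @return Data frame with columns `t` (window-end time, s) and `xi`.
#'   Times earlier than one filter window from the start are dropped.
#' @export
project_stimulus <- function(strain, filt, dt) {
  stopifnot(inherits(filt, "neural_filter"), is.numeric(strain), dt > 0)
  dec <- filt$dt / dt
  if (abs(dec - round(dec)) > 1e-8) {
    stop("strain sample interval must divide the filter interval (got dt = ",
         dt, ", filter dt = ", filt$dt, ")")
  }
  dec <- round(dec)
  idx <- seq(1L, length(strain), by = dec)
  x <- strain[idx]
  L <- length(filt$taps)
  if (length(x) < L) {
    stop("strain series (", length(x), " samples at the filter interval) ",
         "is shorter than the STA window (", L, " taps)")
  }
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  gate <- if (filt$strain_floor > 0) {
    r^filt$floor_exponent /
      (r^filt$floor_exponent + filt$strain_floor^filt$floor_exponent)
  } else 1
  # correlation: sum_k taps[k] * x[i - k + 1]  (taps[1] = most recent lag)
  num <- stats::filter(x, filt$taps, sides = 1)
  nrm <- sqrt(stats::filter(x^2, rep(1, L), sides = 1))
  xi <- gate * as.numeric(num) / pmax(as.numeric(nrm), .Machine$double.eps)
  keep <- L:length(x)
  data.frame(t = (idx[keep] - 1L) * dt, xi = xi[keep])
}

#' Firing probability from the nonlinear decision function
#'
#' Sigmoidal NLD: \eqn{P = P_{max} / (1 + \exp(-(\xi - \xi_0)/k))}.
#'
#' @param xi Normalised projection values (vector, or the data frame
#'   returned by [project_stimulus()]).
#' @param filt A [neural_filter()].
#' @return Same shape as the input: a vector of probabilities, or the data
#'   frame with a `p` column added.
#' @export
firing_probability <- function(xi, filt) {
  stopifnot(inherits(filt, "neural_filter"))
  if (is.data.frame(xi)) {
    xi$p <- firing_probability(xi$xi, filt)
    return(xi)
  }
  filt$pmax / (1 + exp(-(xi - filt$xi0) / filt$slope))
}

#' Extract spike times from a firing-probability series
#'
#' A spike occurs at each strict local maximum of the firing probability
#' whose peak value exceeds the threshold. Peak times are refined by
#' quadratic interpolation through the three samples around the maximum;
#' plateaus (runs of equal values flanked by lower ones) yield a single
#' spike at the plateau midpoint.
#'
#' @param p Firing-probability series, or the data frame from
#'   [firing_probability()] (columns `t`, `p`).
#' @param t Sample times (ignored if `p` is a data frame).
#' @param threshold Probability threshold; defaults to the filter's 0.9.
#' @param location Optional location label (e.g. circumferential angle).
#' @param condition Optional condition label.
#' @return Object of class `spike_train`: data frame with column `time`
#'   (s), possibly empty, with the labels as attributes.
#' @export
extract_spikes <- function(p, t = NULL, threshold = 0.9, location = NA,
                           condition = NA_character_) {
  if (is.data.frame(p)) {
    t <- p$t
    p <- p$p
  }
  stopifnot(length(p) == length(t), threshold > 0, threshold < 1)
  n <- length(p)
  times <- numeric(0)
  if (n >= 3) {
    dp <- diff(p)
    # indices where the series stops rising and starts falling; handle
    # plateaus by tracking the start of each non-decreasing run
    i <- 2L
    while (i <= n - 1L) {
      if (p[i] > p[i - 1L]) {
        j <- i
        while (j < n && p[j + 1L] == p[j]) j <- j + 1L
        if (j < n && p[j + 1L] < p[j]) {
          # peak (or plateau) spanning samples i..j
          if (p[i] > threshold) {
            if (j == i) {
              denom <- p[i - 1L] - 2 * p[i] + p[i + 1L]
              shift <- if (abs(denom) > 1e-12 * max(abs(p[i]), 1)) {
                0.5 * (p[i - 1L] - p[i + 1L]) / denom
              } else 0
              shift <- max(min(shift, 0.5), -0.5)
              times <- c(times, t[i] + shift * (t[2] - t[1]))
            } else {
              times <- c(times, (t[i] + t[j]) / 2)
            }
          }
          i <- j + 1L
        } else {
          i <- j + 1L
        }
      } else {
        i <- i + 1L
      }
    }
  }
  train <- data.frame(time = times)
  attr(train, "location") <- location
  attr(train, "condition") <- condition
  class(train) <- c("spike_train", "data.frame")
  train
}

#' Spikes per flapping cycle
#'
#' @param train A [extract_spikes()] spike train.
#' @param f Flapping frequency (Hz).
#' @param window Length-2 analysis window (s) spanning an integer number
#'   of flapping periods; defaults to the span of the train.
#' @return Spike count divided by the number of periods in the window.
#' @export
spikes_per_cycle <- function(train, f, window = NULL) {
  stopifnot(inherits(train, "spike_train"), f > 0)
  if (is.null(window)) {
    if (nrow(train) == 0) return(0)
    window <- range(train$time)
    window[2] <- window[1] + max(1, round((window[2] - window[1]) * f)) / f
  }
  n_per <- (window[2] - window[1]) * f
  sel <- train$time >= window[1] & train$time <= window[2]
  sum(sel) / n_per
}

#' Per-location spike-timing shift between two conditions
#'
#' Pairs each spike of the rotation-condition train with the nearest spike
#' of the flapping-only train within half a flapping period, and reports
#' the mean signed timing difference (rotation minus flapping, in
#' milliseconds; positive = rotation delays the spike). Locations that
#' spike under rotation but are silent under flapping alone are flagged
#' `rotation_only`.
#'
#' @param train_flap Spike train under flapping only.
#' @param train_rot Spike train under flapping plus rotation.
#' @param f Flapping frequency (Hz).
#' @return List with `mean_shift_ms`, `sd_shift_ms`, `n_pairs`,
#'   `rotation_only` and the per-pair differences `shifts_ms`.
#' @export
timing_shift <- function(train_flap, train_rot, f) {
  stopifnot(inherits(train_flap, "spike_train"), inherits(train_rot, "spike_train"),
            f > 0)
  if (nrow(train_rot) == 0) {
    return(list(mean_shift_ms = NA_real_, sd_shift_ms = NA_real_,
                n_pairs = 0L, rotation_only = FALSE, shifts_ms = numeric(0)))
  }
  if (nrow(train_flap) == 0) {
    return(list(mean_shift_ms = NA_real_, sd_shift_ms = NA_real_,
                n_pairs = 0L, rotation_only = TRUE, shifts_ms = numeric(0)))
  }
  half <- 1 / (2 * f)
  shifts <- vapply(train_rot$time, function(tr) {
    d <- tr - train_flap$time
    i <- which.min(abs(d))
    if (abs(d[i]) <= half) d[i] else NA_real_
  }, numeric(1))
  shifts <- shifts[!is.na(shifts)] * 1e3
  if (length(shifts) == 0) {
    return(list(mean_shift_ms = NA_real_, sd_shift_ms = NA_real_,
                n_pairs = 0L, rotation_only = FALSE, shifts_ms = numeric(0)))
  }
  list(mean_shift_ms = mean(shifts),
       sd_shift_ms = stats::sd(shifts),
       n_pairs = length(shifts),
       rotation_only = FALSE,
       shifts_ms = shifts)
}

#' Full strain-to-spike pipeline for one series
#'
#' Convenience chain: [project_stimulus()], [firing_probability()],
#' [extract_spikes()], optionally restricted to an analysis window.
#'
#' @inheritParams project_stimulus
#' @param window Optional length-2 time window (s) to which spikes are
#'   restricted.
#' @param location,condition Labels attached to the returned train.
#' @return A `spike_train`.
#' @export
predict_spikes <- function(strain, filt, dt, window = NULL, location = NA,
                           condition = NA_character_) {
  pr <- firing_probability(project_stimulus(strain, filt, dt), filt)
  train <- extract_spikes(pr, threshold = filt$threshold,
                          location = location, condition = condition)
  if (!is.null(window)) {
    keep <- train$time >= window[1] & train$time <= window[2]
    train <- train[keep, , drop = FALSE]
    class(train) <- c("spike_train", "data.frame")
    attr(train, "location") <- location
    attr(train, "condition") <- condition
  }
  train
}
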