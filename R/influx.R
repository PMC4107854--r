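#' Goldman-Hodgkin-Katz calcium channel
#'
#' Describes a calcium permeability obeying the GHK current equation. The
#' default temperature (34 C) and external calcium (2 mM, the standard ACSF
#' level) match common slice conditions for cerebellar recordings.
#'
#' `activation` is a function of voltage (mV) and time (ms) returning an open
#' probability in `[0, 1]`. The default is a Boltzmann steady-state gate with
#' half-activation -19 mV and slope 5.5 mV, typical of high-threshold P-type
#' channels, so the channel is essentially shut at a -60 mV holding potential
#' and opens along the depolarizing ramp. Pass `activation = 1` (or any
#' constant) for an always-open permeability.
#'
#' @param P_max Maximum permeability, cm/s.
#' @param z Ion valence (2 for calcium).
#' @param temperature_K Absolute temperature, K.
#' @param Ca_o External calcium, mM.
#' @param activation Function `f(V, t)` in `[0,1]`, or a single number.
#' @return Object of class `ghk_channel`.
#' @export
ghk_channel <- function(P_max = 5.2e-5, z = 2, temperature_K = 307.15,
                        Ca_o = 2, activation = boltzmann_activation()) {
  check_scalar_positive(P_max, "P_max")
  check_scalar_positive(temperature_K, "temperature_K")
  if (!is.numeric(Ca_o) || Ca_o < 0) stop("Ca_o must be non-negative")
  if (is.numeric(activation)) {
    a <- activation
    activation <- function(V, t) rep_len(a, length(V))
  }
  stopifnot(is.function(activation))
  structure(list(P_max = P_max, z = z, temperature_K = temperature_K,
                 Ca_o = Ca_o, activation = activation),
            class = "ghk_channel")
}

#' Boltzmann steady-state activation gate
#'
#' @param v_half Half-activation voltage, mV.
#' @param slope Slope factor, mV.
#' @return A function `f(V, t)` returning `1/(1 + exp(-(V - v_half)/slope))`.
#' @export
boltzmann_activation <- function(v_half = -19, slope = 5.5) {
  force(v_half); force(slope)
  function(V, t) 1 / (1 + exp(-(V - v_half) / slope))
}

# x / (1 - exp(-x)) with a series fallback near 0
ghk_xi_factor <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 + x / 2, x / (-expm1(-x)))
  out
}

#' GHK calcium current density
#'
#' Goldman-Hodgkin-Katz current equation for a divalent ion, returning a
#' membrane current density in mA/cm^2 (inward negative). The removable
#' singularity at V = 0 is handled by its analytic limit, so the current is
#' continuous in V.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param Ca_i Intracellular calcium, mM (vectorized or scalar).
#' @param channel A [ghk_channel()].
#' @param t Time, ms (passed to the activation gate; default 0).
#' @return Current density, mA/cm^2.
#' @export
ghk_current_density <- function(V, Ca_i, channel, t = 0) {
  stopifnot(inherits(channel, "ghk_channel"))
  if (any(Ca_i < 0)) stop("Ca_i must be non-negative")
  F <- dca_constants$FARADAY
  rtf <- 1000 * dca_constants$GAS_CONSTANT * channel$temperature_K / F  # mV
  xi <- channel$z * V / rtf
  act <- channel$activation(V, t)
  # concentrations mM -> mol/cm^3 is 1e-6; A/cm^2 -> mA/cm^2 is 1e3
  drive <- (Ca_i - channel$Ca_o * exp(-xi)) * 1e-6
  1e3 * channel$P_max * act * channel$z * F * ghk_xi_factor(xi) * drive
}

#' Ramp-like voltage protocol
#'
#' Piecewise-linear command: hold at `hold_mV`, ramp linearly to `target_mV`,
#' stay at the plateau, then step back to the holding level for a decay tail.
#' This emulates depolarizing a compartment to the voltage range where
#' dendritic calcium spikes are generated.
#'
#' @param hold_mV Holding level, mV.
#' @param hold_ms Duration of the initial hold, ms.
#' @param ramp_ms Ramp duration, ms.
#' @param target_mV Plateau level, mV.
#' @param plateau_ms Plateau duration, ms.
#' @param tail_ms Post-plateau duration back at `hold_mV`, ms.
#' @return Object of class `voltage_protocol`: list with the parameters,
#'   `t_end`, and `V(t)` evaluator.
#' @export
ramp_protocol <- function(hold_mV = -60, hold_ms = 10, ramp_ms = 10,
                          target_mV = -20, plateau_ms = 100, tail_ms = 60) {
  t1 <- hold_ms; t2 <- hold_ms + ramp_ms; t3 <- t2 + plateau_ms
  t_end <- t3 + tail_ms
  Vfun <- function(t) {
    ifelse(t < t1, hold_mV,
      ifelse(t < t2, hold_mV + (target_mV - hold_mV) * (t - t1) / ramp_ms,
        ifelse(t < t3, target_mV, hold_mV)))
  }
  structure(list(hold_mV = hold_mV, hold_ms = hold_ms, ramp_ms = ramp_ms,
                 target_mV = target_mV, plateau_ms = plateau_ms,
                 tail_ms = tail_ms, t_end = t_end, V = Vfun),
            class = "voltage_protocol")
}

#' Prescribed calcium current-density waveform
#'
#' @param time Strictly increasing time grid, ms.
#' @param current Calcium current density at each time, mA/cm^2 (inward
#'   negative), applied uniformly per unit membrane area.
#' @return Object of class `current_waveform`.
#' @export
current_waveform <- function(time, current) {
  stopifnot(is.numeric(time), is.numeric(current),
            length(time) == length(current), length(time) >= 2)
  if (any(!is.finite(time)) || any(!is.finite(current))) {
    stop("waveform must be finite")
  }
  if (any(diff(time) <= 0)) stop("waveform time grid must be strictly increasing")
  structure(list(time = time, current = current), class = "current_waveform")
}

# evaluate a waveform on an arbitrary grid (linear interpolation, 0 outside)
waveform_at <- function(wf, t) {
  stopifnot(inherits(wf, "current_waveform"))
  stats::approx(wf$time, wf$current, xout = t, rule = 2, yleft = 0, yright = 0)$y
}

#' Burst of alpha-shaped calcium current pulses
#'
#' Stand-in for a calcium current recorded during a spike burst: a sum of
#' `n_spikes` alpha functions `-(peak) * (s/width) * exp(1 - s/width)` with
#' onsets `period` apart (inward, hence negative). Each pulse has amplitude
#' `peak` (magnitude) and integrates to `exp(1) * peak * width`, so the full
#' waveform integrates to `-n_spikes * exp(1) * peak * width` (up to the
#' truncation at `t_end`).
#'
#' @param n_spikes Number of pulses (0 gives the zero waveform).
#' @param period Onset spacing, ms.
#' @param peak Pulse amplitude magnitude, mA/cm^2.
#' @param width Alpha time-to-peak, ms.
#' @param dt Sampling step, ms.
#' @param t_end Waveform duration, ms (default covers the burst plus a tail).
#' @return A [current_waveform()].
#' @export
make_spike_burst_waveform <- function(n_spikes, period, peak, width,
                                      dt = 0.02, t_end = NULL) {
  stopifnot(n_spikes >= 0, n_spikes == round(n_spikes))
  if (n_spikes > 0) {
    check_scalar_positive(period, "period")
    check_scalar_positive(peak, "peak")
    check_scalar_positive(width, "width")
  }
  if (is.null(t_end)) {
    t_end <- if (n_spikes > 0) (n_spikes - 1) * period + 12 * width else 1
  }
  tt <- seq(0, t_end, by = dt)
  cur <- numeric(length(tt))
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes)) {
      s <- tt - (k - 1) * period
      on <- s > 0
      cur[on] <- cur[on] - peak * (s[on] / width) * exp(1 - s[on] / width)
    }
  }
  current_waveform(tt, cur)
}

#' GHK-driven influx description
#'
#' Couples a [ghk_channel()] to a [ramp_protocol()] (or any object with a
#' `V(t)` function and `t_end`). When simulated self-consistently the channel
#' sees the model's own submembrane calcium; in prescribed mode the current is
#' precomputed with calcium clamped at rest, so every mechanism receives an
#' identical influx.
#'
#' @param channel A [ghk_channel()].
#' @param protocol A [ramp_protocol()].
#' @param scale Multiplicative scaling of the permeability (for influx sweeps).
#' @return Object of class `ghk_drive`.
#' @export
ghk_drive <- function(channel, protocol = ramp_protocol(), scale = 1) {
  stopifnot(inherits(channel, "ghk_channel"))
  structure(list(channel = channel, protocol = protocol, scale = scale),
            class = "ghk_drive")
}

#' Precompute the GHK current waveform at fixed intracellular calcium
#'
#' Converts a [ghk_drive()] into a prescribed [current_waveform()] with the
#' intracellular concentration clamped (at rest by default), so different
#' mechanisms can be driven by byte-identical influx.
#'
#' @param drive A [ghk_drive()].
#' @param dt Sampling step, ms.
#' @param Ca_i Clamped intracellular calcium, mM.
#' @param t_end Duration, ms (defaults to the protocol length).
#' @return A [current_waveform()].
#' @export
ghk_waveform <- function(drive, dt = 0.02, Ca_i = CA_REST_DEFAULT,
                         t_end = NULL) {
  stopifnot(inherits(drive, "ghk_drive"))
  if (is.null(t_end)) t_end <- drive$protocol$t_end
  tt <- seq(0, t_end, by = dt)
  V <- drive$protocol$V(tt)
  I <- drive$scale * ghk_current_density(V, Ca_i, drive$channel, tt)
  current_waveform(tt, I)
}
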