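#' Integrated calcium over a time window
#'
#' The sum of concentration samples multiplied by the sampling step over a
#' window (a left-closed, right-open Riemann sum, so a constant trace of
#' value `c` over a window of width `w` integrates to exactly `c * w` when
#' the step divides the width).
#'
#' @param trace A [ca_trace()] with a uniform time grid.
#' @param window Length-2 numeric, window start and end in ms; must lie within
#'   the trace span.
#' @return Object of class `integrated_ca`: list with `value` (mM ms),
#'   `window`, and the step used.
#' @export
integrated_ca <- function(trace, window) {
  stopifnot(inherits(trace, "ca_trace"), length(window) == 2L,
            window[1L] < window[2L])
  dt <- trace$time[2L] - trace$time[1L]
  eps <- dt * 1e-6
  if (window[1L] < trace$time[1L] - eps ||
      window[2L] > trace$time[length(trace$time)] + dt + eps) {
    stop("window [", window[1L], ", ", window[2L], "] outside trace span [",
         trace$time[1L], ", ", trace$time[length(trace$time)], "]")
  }
  sel <- trace$time >= window[1L] - eps & trace$time < window[2L] - eps
  structure(list(value = sum(trace$ca[sel]) * dt, window = window, dt = dt),
            class = "integrated_ca")
}

#' @export
print.integrated_ca <- function(x, ...) {
  cat(sprintf("integrated calcium: %.6g mM ms over [%g, %g] ms\n",
              x$value, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Time of the first calcium peak
#'
#' First local maximum of the trace exceeding rest by at least `rise_frac`
#' (a plateau or end-of-trace maximum counts as a peak). Used to center
#' integration windows on the transient.
#'
#' @param trace A [ca_trace()].
#' @param rest Resting level, mM.
#' @param rise_frac Minimum relative rise above rest to qualify.
#' @return Peak time, ms (`NA` if the trace never rises above threshold).
#' @export
first_peak_time <- function(trace, rest = CA_REST_DEFAULT, rise_frac = 0.1) {
  ca <- trace$ca
  thr <- rest * (1 + rise_frac)
  n <- length(ca)
  up <- which(ca >= thr)
  if (!length(up)) return(NA_real_)
  for (i in up) {
    left_ok <- i == 1L || ca[i - 1L] <= ca[i]
    right_ok <- i == n || ca[i + 1L] < ca[i]
    if (left_ok && right_ok) return(trace$time[i])
  }
  trace$time[up[which.max(ca[up])]]
}

# window of a given width centered on the first peak, clipped to the trace
peak_window <- function(trace, width, rest = CA_REST_DEFAULT) {
  tp <- first_peak_time(trace, rest)
  if (is.na(tp)) tp <- trace$time[which.max(trace$ca)]
  lo <- max(tp - width / 2, trace$time[1L])
  c(lo, min(lo + width, trace$time[length(trace$time)]))
}

#' Ratios of a quantity between adjacent compartments
#'
#' Each adjacent pair contributes the ratio larger/smaller (>= 1). Pairs with
#' a non-positive member are skipped (counted in the `skipped` attribute).
#'
#' @param values Named or indexed numeric vector, one value per compartment.
#' @param adjacency data.frame with columns `a`, `b` of compartment indices.
#' @return Numeric vector of ratios with attribute `skipped`.
#' @export
adjacent_ratios <- function(values, adjacency) {
  stopifnot(all(c("a", "b") %in% names(adjacency)))
  va <- values[adjacency$a]
  vb <- values[adjacency$b]
  ok <- is.finite(va) & is.finite(vb) & va > 0 & vb > 0
  r <- pmax(va[ok], vb[ok]) / pmin(va[ok], vb[ok])
  attr(r, "skipped") <- sum(!ok)
  r
}

#' Histogram of adjacent-compartment ratios
#'
#' @inheritParams adjacent_ratios
#' @param breaks Passed to [graphics::hist()] (computed, not plotted).
#' @return data.frame with `mid`, `count`, `density`.
#' @export
adjacent_ratio_histogram <- function(values, adjacency, breaks = seq(1, 3, by = 0.1)) {
  r <- adjacent_ratios(values, adjacency)
  r <- pmin(r, max(breaks))  # overflow collected in the last bin
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}

#' Integrated calcium per compartment diameter for one mechanism
#'
#' Simulates an isolated single compartment for each diameter under the same
#' influx and integrates the (submembrane) calcium over a window centered on
#' the first peak.
#'
#' @param diams Diameters, um.
#' @param mechanism `"SP_new"`, `"SP_old"`, `"DM"` or `"DM_FD"`.
#' @param window Window width, ms.
#' @param channel,protocol Influx description ([ghk_channel()], [ramp_protocol()]).
#' @param scale Influx scaling.
#' @param pool_d,pool_beta Pool parameters for the SP mechanisms.
#' @param shell_d Nominal shell depth for the diffusion mechanisms, um.
#' @param buffers,pump Detailed-model configuration.
#' @param dt,L Step (ms) and compartment length (um).
#' @return data.frame with `diam` and `integrated` (mM ms; `NA` where the
#'   mechanism is invalid at that diameter, e.g. SP_new with `pool_d >= diam`).
#' @export
integrated_ca_by_diameter <- function(diams, mechanism = c("SP_new", "SP_old", "DM", "DM_FD"),
                                      window = 100,
                                      channel = ghk_channel(),
                                      protocol = ramp_protocol(),
                                      scale = 1,
                                      pool_d = 0.169, pool_beta = 6.86,
                                      shell_d = 0.1,
                                      buffers = default_buffers(),
                                      pump = pump_spec(),
                                      dt = 0.02, L = 1) {
  mechanism <- match.arg(mechanism)
  drv <- ghk_drive(channel, protocol, scale = scale)
  out <- data.frame(diam = diams, integrated = NA_real_)
  for (i in seq_along(diams)) {
    geom <- compartment_geometry(diams[i], L)
    tr <- if (mechanism %in% c("SP_new", "SP_old")) {
      if (mechanism == "SP_new" && pool_d >= diams[i]) next
      simulate_pool(geom, pool_params(pool_d, pool_beta, variant = mechanism),
                    drv, dt = dt)
    } else {
      stack <- if (mechanism == "DM") dm_stack_or_single(geom, shell_d)
               else shells_fixed_depth(geom, shell_d)
      submembrane_trace(simulate_system(build_system(stack, buffers, pump),
                                        drv, t_end = protocol$t_end, dt = dt))
    }
    out$integrated[i] <- integrated_ca(tr, peak_window(tr, window))$value
  }
  out
}

#' Diameter-pair ratio map of integrated calcium
#'
#' For every pair of diameters, the ratio of integrated calcium between two
#' isolated compartments of those diameters under identical influx
#' (larger/smaller, so the map is symmetric and its diagonal is 1). This is
#' the prediction of how much calcium levels jump across a diameter change
#' under each modeling mechanism.
#'
#' @inheritParams integrated_ca_by_diameter
#' @return Matrix of ratios with diameters as dimnames; entries involving an
#'   invalid diameter are `NA`.
#' @export
diameter_pair_ratio_map <- function(diams, mechanism = c("SP_new", "DM", "DM_FD"),
                                    window = 100, ...) {
  mechanism <- match.arg(mechanism)
  ic <- integrated_ca_by_diameter(diams, mechanism, window = window, ...)
  v <- ic$integrated
  m <- outer(v, v, function(a, b) pmax(a, b) / pmin(a, b))
  dimnames(m) <- list(format(diams), format(diams))
  m
}

#' Integrated-calcium adjacent ratios over a compartmentalized tree
#'
#' Assigns each compartment of a [compartmentalize()]d morphology the
#' integrated calcium of an isolated compartment of its diameter (diameters
#' rounded to `round_to` um so repeated values are simulated once) and
#' returns the adjacent-pair ratios. This captures the surface-to-volume-led
#' spatial variability while keeping every compartment simulation independent.
#'
#' @param comp A [compartmentalize()] result.
#' @param mechanism,window,... Passed to [integrated_ca_by_diameter()].
#' @param round_to Diameter rounding step, um.
#' @return Numeric vector of ratios (attribute `skipped` counts unusable pairs).
#' @export
tree_adjacent_ratios <- function(comp, mechanism = "DM", window = 100,
                                 round_to = 0.05, ...) {
  stopifnot(inherits(comp, "compartmentalization"))
  dd <- pmax(round(comp$compartments$diam / round_to) * round_to, round_to)
  uniq <- sort(unique(dd))
  ic <- integrated_ca_by_diameter(uniq, mechanism, window = window, ...)
  vals <- ic$integrated[match(dd, uniq)]
  adjacent_ratios(vals, comp$adjacency)
}
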