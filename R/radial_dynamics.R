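#' Calcium buffer specification
#'
#' One class of buffer binding sites with first-order calcium kinetics and,
#' optionally, competing magnesium binding (free Mg held constant). A
#' `mobile_fraction` below 1 splits the buffer into a diffusible sub-pool and
#' an immobile sub-pool with identical kinetics.
#'
#' @param name Buffer name.
#' @param total Total site concentration, mM.
#' @param kon Calcium association rate, mM^-1 ms^-1.
#' @param koff Calcium dissociation rate, ms^-1.
#' @param D Diffusion coefficient of the mobile pool, um^2/ms.
#' @param mobile_fraction Fraction of sites that diffuse, in `[0, 1]`.
#' @param mg Optional list `list(kon=, koff=, conc=)` describing competing Mg
#'   binding (rates in mM^-1 ms^-1 / ms^-1, free Mg in mM).
#' @return Object of class `buffer_spec`.
#' @export
buffer_spec <- function(name, total, kon, koff, D = 0, mobile_fraction = 1,
                        mg = NULL) {
  stopifnot(is.character(name), total >= 0, kon >= 0, koff >= 0, D >= 0,
            mobile_fraction >= 0, mobile_fraction <= 1)
  if (!is.null(mg)) {
    stopifnot(is.list(mg), all(c("kon", "koff", "conc") %in% names(mg)),
              mg$kon >= 0, mg$koff >= 0, mg$conc >= 0)
  }
  structure(list(name = name, total = total, kon = kon, koff = koff, D = D,
                 mobile_fraction = mobile_fraction, mg = mg),
            class = "buffer_spec")
}

#' Default Purkinje-cell buffer set
#'
#' Calbindin-D28k and parvalbumin at the concentrations and kinetics of the
#' standard Purkinje-cell calcium-dynamics literature: calbindin 0.16 mM with
#' four binding sites modeled as two independent site classes (two
#' high-affinity and two medium-affinity sites, i.e. 0.32 mM of sites per
#' class), 80% of calbindin diffusible; parvalbumin 0.08 mM with two sites,
#' fully diffusible, competing with 0.59 mM free magnesium. Site kinetics
#' (mM^-1 ms^-1 / ms^-1): calbindin high-affinity (slow) 5.5 / 0.0026, medium 43.5 / 0.0358;
#' parvalbumin Ca 107 / 0.00095, Mg 0.8 / 0.025. Diffusion coefficients:
#' calbindin 0.028, parvalbumin 0.043 um^2/ms.
#'
#' @return List of [buffer_spec()] objects.
#' @export
default_buffers <- function() {
  list(
    buffer_spec("calbindin_high", total = 0.32, kon = 5.5, koff = 0.0026,
                D = 0.028, mobile_fraction = 0.8),
    buffer_spec("calbindin_med", total = 0.32, kon = 43.5, koff = 0.0358,
                D = 0.028, mobile_fraction = 0.8),
    buffer_spec("parvalbumin", total = 0.16, kon = 107, koff = 0.00095,
                D = 0.043, mobile_fraction = 1,
                mg = list(kon = 0.8, koff = 0.025, conc = 0.59))
  )
}

#' Surface calcium pump specification
#'
#' Michaelis-Menten style surface pump
#' `pump + Ca <-> pump-Ca -> pump` with binding rate `k_f`, unbinding `k_b`
#' and extrusion `k_ext`; the pump lives on the membrane at the given surface
#' density and its states are tracked as concentrations in the submembrane
#' shell. With `leak_balance = TRUE` a constant compensating leak influx is
#' sized so the net submembrane flux is zero at the resting concentration,
#' making rest a true steady state.
#'
#' @param density Surface density, mol/cm^2.
#' @param k_f Binding rate, mM^-1 ms^-1.
#' @param k_b Unbinding rate, ms^-1.
#' @param k_ext Extrusion rate, ms^-1.
#' @param leak_balance Add the compensating resting leak?
#' @return Object of class `pump_spec`.
#' @export
pump_spec <- function(density = 1e-15, k_f = 3e3, k_b = 17.5, k_ext = 72.55,
                      leak_balance = TRUE) {
  stopifnot(density >= 0, k_f >= 0, k_b >= 0, k_ext >= 0)
  structure(list(density = density, k_f = k_f, k_b = k_b, k_ext = k_ext,
                 leak_balance = leak_balance),
            class = "pump_spec")
}

# split user buffer specs into internal species (mobile/immobile sub-pools)
# and compute the resting equilibrium occupancies
internal_buffers <- function(buffers, Ca0) {
  out <- list()
  for (b in buffers) {
    stopifnot(inherits(b, "buffer_spec"))
    split_one <- function(total, D, tag) {
      if (total <= 0) return(NULL)
      kd_term <- if (b$koff > 0) Ca0 * b$kon / b$koff else Inf
      mg_term <- if (!is.null(b$mg) && b$mg$koff > 0)
        b$mg$conc * b$mg$kon / b$mg$koff else 0
      free0 <- if (is.finite(kd_term)) total / (1 + kd_term + mg_term) else 0
      list(name = paste0(b$name, tag), kon = b$kon, koff = b$koff, D = D,
           free0 = free0, bound0 = free0 * kd_term,
           has_mg = !is.null(b$mg),
           mgkon = if (!is.null(b$mg)) b$mg$kon * b$mg$conc else 0,
           mgkoff = if (!is.null(b$mg)) b$mg$koff else 0,
           mgb0 = free0 * mg_term)
    }
    mob <- split_one(b$total * b$mobile_fraction, b$D, "_mobile")
    imm <- split_one(b$total * (1 - b$mobile_fraction), 0, "_immobile")
    out <- c(out, Filter(Negate(is.null), list(mob, imm)))
  }
  out
}

#' Build a buffered radial reaction-diffusion system
#'
#' Assembles free calcium, buffer species and the surface pump over one or
#' more radial shell stacks (one stack per compartment). Pump states are
#' attached to the outermost (submembrane) shell of each compartment and the
#' surface density is converted to a concentration through that shell's
#' membrane area and volume. Immobile buffer sub-pools get zero diffusive
#' coupling. Compartments are uncoupled until [longitudinal_couple()] is
#' applied.
#'
#' @param stacks A `shell_stack` or list of them (one per compartment).
#' @param buffers List of [buffer_spec()] (may be empty for pure diffusion).
#' @param pump A [pump_spec()] or `NULL` for no pump.
#' @param Ca0 Resting calcium, mM.
#' @param D_ca Calcium diffusion coefficient, um^2/ms.
#' @param influx_scale Per-compartment multiplicative influx scaling.
#' @return Object of class `rd_system`.
#' @export
build_system <- function(stacks, buffers = default_buffers(), pump = pump_spec(),
                         Ca0 = CA_REST_DEFAULT, D_ca = 0.223,
                         influx_scale = 1) {
  if (inherits(stacks, "shell_stack")) stacks <- list(stacks)
  if (!length(stacks) || !all(vapply(stacks, inherits, TRUE, "shell_stack"))) {
    stop("stacks must be shell_stack objects")
  }
  if (!is.null(pump)) stopifnot(inherits(pump, "pump_spec"))
  ncomp <- length(stacks)
  influx_scale <- rep_len(influx_scale, ncomp)

  ptot <- numeric(ncomp)
  leak <- numeric(ncomp)
  for (c in seq_len(ncomp)) {
    st <- stacks[[c]]
    if (!is.null(pump) && pump$density > 0) {
      sv <- st$geom$SA / st$volumes[1L]
      ptot[c] <- pump$density * dca_constants$PUMP_DENSITY_TO_CONC * sv
      if (pump$leak_balance) {
        denom <- pump$k_f * Ca0 + pump$k_b + pump$k_ext
        pb0 <- ptot[c] * pump$k_f * Ca0 / denom
        leak[c] <- pump$k_ext * pb0 * st$volumes[1L]  # amount/ms
      }
    }
  }
  structure(
    list(stacks = stacks,
         buffers = buffers,
         species = internal_buffers(buffers, Ca0),
         pump = if (is.null(pump)) pump_spec(density = 0, leak_balance = FALSE) else pump,
         ptot = ptot, leak = leak,
         cscale = influx_scale,
         pairs = matrix(numeric(0), ncol = 5),
         Ca0 = Ca0, D_ca = D_ca),
    class = "rd_system"
  )
}

#' Couple adjacent compartments for longitudinal diffusion
#'
#' Adds flux-conservative longitudinal coupling between consecutive
#' compartments of the system (in list order). Unequal shell counts are
#' handled by apportioning the exchange over the overlap of the two radial
#' interval partitions: shell `a` of one compartment exchanges with shell `b`
#' of the next through the annular area where their radial intervals overlap,
#' over the distance between the compartment midpoints. Every pairwise flux
#' is antisymmetric, so total matter is conserved across junctions exactly.
#'
#' @param system An [build_system()] result.
#' @return The system with the coupling map attached.
#' @export
longitudinal_couple <- function(system) {
  stopifnot(inherits(system, "rd_system"))
  stacks <- system$stacks
  if (length(stacks) < 2) return(system)
  rows <- list()
  for (c in seq_len(length(stacks) - 1L)) {
    A <- stacks[[c]]; B <- stacks[[c + 1L]]
    dist <- (A$geom$L + B$geom$L) / 2
    for (i in seq_along(A$depths)) {
      for (j in seq_along(B$depths)) {
        ro <- min(A$r_out[i], B$r_out[j])
        ri <- max(A$r_in[i], B$r_in[j])
        if (ro > ri) {
          area <- pi * (ro^2 - ri^2)
          rows[[length(rows) + 1L]] <- c(c, i, c + 1L, j, area / dist)
        }
      }
    }
  }
  system$pairs <- do.call(rbind, rows)
  system
}

# build the C++ drive description on the step grid
build_drive <- function(influx, dt, nsteps) {
  tmid <- (seq_len(nsteps) - 0.5) * dt
  if (is.null(influx)) {
    list(type = 0L)
  } else if (inherits(influx, "current_waveform")) {
    list(type = 1L, ivec = waveform_at(influx, tmid))
  } else if (inherits(influx, "ghk_drive")) {
    ch <- influx$channel
    V <- influx$protocol$V(tmid)
    list(type = 2L, vvec = V,
         pvec = influx$scale * ch$P_max * ch$activation(V, tmid),
         cao = ch$Ca_o,
         rtf = 1000 * dca_constants$GAS_CONSTANT * ch$temperature_K /
           dca_constants$FARADAY)
  } else {
    stop("influx must be NULL, a current_waveform or a ghk_drive")
  }
}

#' Simulate a radial reaction-diffusion system
#'
#' Time-steps the system with operator splitting: RK4 sub-stepped local
#' reactions, implicit (backward-Euler, tridiagonal) radial diffusion for
#' every mobile species, then explicit longitudinal exchange. Returns the
#' submembrane free-calcium trace of every compartment, an optional all-shell
#' trace for the first compartment, and a running conservation audit
#' (total calcium amount in all pools plus extruded minus influx minus leak,
#' which is constant for a conservative scheme).
#'
#' @param system An [build_system()] result.
#' @param influx `NULL`, a [current_waveform()] or a [ghk_drive()]; applied
#'   per unit membrane area to every compartment (scaled by the system's
#'   per-compartment `influx_scale`).
#' @param t_end End time, ms.
#' @param dt Time step, ms.
#' @param nsub Reaction sub-steps per time step.
#' @param record_every Record every n-th step.
#' @param record_shells Also record all shells of compartment 1?
#' @return Object of class `rd_result`: `time`, `sm_ca` (compartments x
#'   samples), `shell_ca`, `audit`, amount tallies, and the system.
#' @export
simulate_system <- function(system, influx, t_end, dt = 0.02, nsub = 2L,
                            record_every = 5L, record_shells = FALSE) {
  stopifnot(inherits(system, "rd_system"))
  check_scalar_positive(dt, "dt")
  check_scalar_positive(t_end, "t_end")
  nsteps <- as.integer(ceiling(t_end / dt))
  sys_cpp <- list(
    volumes = lapply(system$stacks, `[[`, "volumes"),
    gface = lapply(system$stacks, function(st) {
      n <- length(st$depths)
      if (n < 2) numeric(0)
      else st$interface_areas / (st$centers[-n] - st$centers[-1L])
    }),
    outer_area = vapply(system$stacks, function(st) st$geom$SA, 0),
    ptot = system$ptot, leak = system$leak, cscale = system$cscale,
    kf = system$pump$k_f, kb = system$pump$k_b, kext = system$pump$k_ext,
    d_ca = system$D_ca, ca0 = system$Ca0,
    buffers = system$species,
    pairs = if (nrow(system$pairs)) system$pairs else matrix(0, 0, 5)
  )
  drive <- build_drive(influx, dt, nsteps)
  res <- rd_simulate_cpp(sys_cpp, drive, dt, nsteps, as.integer(nsub),
                         as.integer(record_every), isTRUE(record_shells))
  structure(c(res, list(system = system, dt = dt)), class = "rd_result")
}

#' @export
print.rd_result <- function(x, ...) {
  cat(sprintf("rd_result: %d compartment(s), %d samples over %.4g ms, submembrane peak %.4g mM\n",
              nrow(x$sm_ca), ncol(x$sm_ca), max(x$time), max(x$sm_ca)))
  invisible(x)
}

#' Submembrane trace of one compartment as a ca_trace
#'
#' @param result An [simulate_system()] result.
#' @param compartment Compartment index.
#' @return A [ca_trace()].
#' @export
submembrane_trace <- function(result, compartment = 1L) {
  stopifnot(inherits(result, "rd_result"))
  ca_trace(result$time, result$sm_ca[compartment, ],
           meta = list(compartment = compartment))
}

#' Average free calcium over a fixed submembrane depth
#'
#' Volume-weighted average of the recorded shell traces over the outermost
#' `depth` um of compartment 1, for resolution-independent comparisons
#' between stacks whose outer shells have different depths.
#'
#' @param result A result from [simulate_system()] with `record_shells = TRUE`.
#' @param depth Averaging depth from the membrane, um.
#' @return A [ca_trace()].
#' @export
submembrane_average <- function(result, depth = 0.1) {
  stopifnot(inherits(result, "rd_result"), ncol(result$shell_ca) > 0)
  st <- result$system$stacks[[1L]]
  R <- st$geom$diam / 2
  rlim <- R - depth
  w <- pmax(pmin(st$r_out, R)^2 - pmax(st$r_in, rlim)^2, 0)
  w <- w / sum(w)
  ca_trace(result$time, as.numeric(crossprod(w, result$shell_ca)),
           meta = list(depth = depth))
}

# DM stack for audits: falls back to the single full-radius shell where the
# variable-depth formula yields fewer than 2 shells (thin compartments, where
# the two schemes coincide by construction)
dm_stack_or_single <- function(geom, d) {
  if (variable_depth_count(geom$diam, d) >= 2L) shells_variable_depth(geom, d)
  else shell_single(geom)
}

#' Peak submembrane error of DM vs DM_FD across diameters
#'
#' For each diameter and influx scaling, simulates the buffered radial model
#' with the variable-depth stack (DM) and the fixed-depth stack (DM_FD,
#' reference) under the same influx and reports the relative error in peak
#' submembrane free calcium, in percent.
#'
#' @param diams Diameters, um.
#' @param scalings Influx scalings (multiples of the channel permeability).
#' @param d Nominal shell depth, um.
#' @param channel A [ghk_channel()].
#' @param protocol A [ramp_protocol()].
#' @param buffers,pump Passed to [build_system()].
#' @param t_end,dt,L Simulation horizon (ms), step (ms), compartment length (um).
#' @return data.frame with `diam`, `scaling`, `peak_dm`, `peak_dmfd`,
#'   `error_pct`.
#' @export
dm_dmfd_peak_errors <- function(diams, scalings = 1,
                                d = 0.1,
                                channel = ghk_channel(),
                                protocol = ramp_protocol(),
                                buffers = default_buffers(),
                                pump = pump_spec(),
                                t_end = 140, dt = 0.02, L = 1) {
  grid <- expand.grid(diam = diams, scaling = scalings, KEEP.OUT.ATTRS = FALSE)
  peak_of <- function(stack, scale) {
    sys <- build_system(stack, buffers, pump)
    drv <- ghk_drive(channel, protocol, scale = scale)
    max(simulate_system(sys, drv, t_end = t_end, dt = dt)$sm_ca)
  }
  grid$peak_dm <- NA_real_
  grid$peak_dmfd <- NA_real_
  for (i in seq_len(nrow(grid))) {
    geom <- compartment_geometry(grid$diam[i], L)
    grid$peak_dm[i] <- peak_of(dm_stack_or_single(geom, d), grid$scaling[i])
    grid$peak_dmfd[i] <- peak_of(shells_fixed_depth(geom, d), grid$scaling[i])
  }
  grid$error_pct <- 100 * (grid$peak_dm - grid$peak_dmfd) / grid$peak_dmfd
  grid
}

#' Error audit for diameter-independent shell counts
#'
#' Quantifies the error of imposing a fixed number of radial shells regardless
#' of diameter, against the DM_FD reference (variable shell count, fixed depth
#' `d`). Two fixed-count schemes are audited: `variable_all` (all shells of
#' variable depth, the classic fixed-count layout) and `hybrid_fd` (outer
#' shell fixed at `d`, inner shells share the remaining radius equally).
#'
#' @param n_shells Fixed shell counts to audit (e.g. `c(4, 8, 12)`).
#' @param scheme `"variable_all"` or `"hybrid_fd"`.
#' @param diams Diameters, um.
#' @param channel,protocol,buffers,pump,t_end,dt,L As in [dm_dmfd_peak_errors()].
#' @param scale Influx scaling.
#' @return data.frame with `diam`, `n_shells`, `scheme`, `error_pct` (relative
#'   peak submembrane error vs DM_FD, percent; `NA` where the scheme is
#'   geometrically impossible, e.g. hybrid outer depth >= radius).
#' @export
fixed_shellcount_error_audit <- function(n_shells = c(4, 8, 12),
                                         scheme = c("variable_all", "hybrid_fd"),
                                         diams = seq(0.4, 6, by = 0.4),
                                         channel = ghk_channel(),
                                         protocol = ramp_protocol(),
                                         buffers = default_buffers(),
                                         pump = pump_spec(),
                                         t_end = 140, dt = 0.02, L = 1,
                                         scale = 1) {
  scheme <- match.arg(scheme)
  grid <- expand.grid(diam = diams, n_shells = n_shells, KEEP.OUT.ATTRS = FALSE)
  grid$scheme <- scheme
  grid$error_pct <- NA_real_
  peak_of <- function(stack) {
    sys <- build_system(stack, buffers, pump)
    drv <- ghk_drive(channel, protocol, scale = scale)
    max(simulate_system(sys, drv, t_end = t_end, dt = dt)$sm_ca)
  }
  for (i in seq_len(nrow(grid))) {
    geom <- compartment_geometry(grid$diam[i], L)
    ref <- peak_of(shells_fixed_depth(geom, 0.1))
    test_stack <- tryCatch(
      if (scheme == "variable_all") shells_variable_forced(geom, grid$n_shells[i])
      else shells_hybrid_fd(geom, 0.1, grid$n_shells[i]),
      dendroca_invalid_geometry = function(e) NULL)
    if (is.null(test_stack)) next
    grid$error_pct[i] <- 100 * (peak_of(test_stack) - ref) / ref
  }
  grid
}
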