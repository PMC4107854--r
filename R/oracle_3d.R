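#' Axisymmetric (r,z) finite-volume grid
#'
#' Discretizes a cylindrical or tapered dendritic segment (stacked frusta,
#' piecewise-constant radius per z-slab) into `nz` axial slabs of `nr` radial
#' cells each. Ends are closed (no-flux); the lateral surface, any exposed
#' annular steps between slabs of different radii, and optionally the two end
#' caps are membrane. Cell volumes and face areas are exact annular-cylinder
#' quantities, and shared faces between neighbors are identical, so the grid
#' is conservative by construction.
#'
#' @param radius Segment radius, um: a scalar (uniform cylinder), a vector of
#'   length `nz` (radius per slab), or a function of axial position z.
#' @param L Segment length, um.
#' @param nr Radial cells per slab.
#' @param nz Axial slabs.
#' @param cap_membrane Treat the closed end caps as membrane (they then
#'   receive influx, pump and leak like the lateral surface)?
#' @param sm_depth Depth of the submembrane averaging layer, um.
#' @return Object of class `axisym_grid`.
#' @export
axisym_grid <- function(radius, L, nr = 10L, nz = 10L, cap_membrane = TRUE,
                        sm_depth = 0.1) {
  check_scalar_positive(L, "L")
  stopifnot(nr >= 1, nz >= 1)
  nr <- as.integer(nr); nz <- as.integer(nz)
  dz <- L / nz
  zc <- (seq_len(nz) - 0.5) * dz
  R <- if (is.function(radius)) vapply(zc, radius, 0)
       else rep_len(radius, nz)
  if (any(R <= 0)) stop_invalid_geometry("all slab radii must be positive")

  vol <- matrix(0, nr, nz)
  gr <- matrix(0, max(nr - 1L, 1L), nz)
  amem <- matrix(0, nr, nz)
  sm_weight <- matrix(0, nr, nz)
  edges <- vector("list", nz)
  for (k in seq_len(nz)) {
    e <- seq(0, R[k], length.out = nr + 1L)
    edges[[k]] <- e
    ro <- e[-1L]; ri <- e[-(nr + 1L)]
    vol[, k] <- pi * (ro^2 - ri^2) * dz
    if (nr > 1L) {
      centers <- (ro + ri) / 2
      gr[, k] <- 2 * pi * ro[-nr] * dz / diff(centers)
    }
    amem[nr, k] <- 2 * pi * R[k] * dz
    w <- pmax(pmin(ro, R[k])^2 - pmax(ri, R[k] - sm_depth)^2, 0)
    sm_weight[, k] <- w / sum(w)
  }
  # exposed annular membrane where the radius steps down between slabs
  for (k in seq_len(nz - 1L)) {
    Rbig <- max(R[k], R[k + 1L]); Rsml <- min(R[k], R[k + 1L])
    if (Rbig > Rsml) {
      kk <- if (R[k] > R[k + 1L]) k else k + 1L
      e <- edges[[kk]]
      ov <- pmax(pmin(e[-1L], Rbig)^2 - pmax(e[-(nr + 1L)], Rsml)^2, 0)
      amem[, kk] <- amem[, kk] + pi * ov
    }
  }
  if (cap_membrane) {
    for (k in c(1L, nz)) {
      e <- edges[[k]]
      amem[, k] <- amem[, k] + pi * (e[-1L]^2 - e[-(nr + 1L)]^2)
    }
  }
  # axial coupling: overlap of the radial partitions of adjacent slabs
  rows <- list()
  for (k in seq_len(nz - 1L)) {
    eA <- edges[[k]]; eB <- edges[[k + 1L]]
    for (i in seq_len(nr)) {
      for (j in seq_len(nr)) {
        ro <- min(eA[i + 1L], eB[j + 1L]); ri <- max(eA[i], eB[j])
        if (ro > ri) {
          rows[[length(rows) + 1L]] <-
            c((k - 1L) * nr + i, k * nr + j, pi * (ro^2 - ri^2) / dz)
        }
      }
    }
  }
  zpairs <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, 3)
  structure(list(nr = nr, nz = nz, dz = dz, R = R, L = L,
                 vol = vol, gr = gr, amem = amem, sm_weight = sm_weight,
                 zpairs = zpairs, cap_membrane = cap_membrane,
                 sm_depth = sm_depth),
            class = "axisym_grid")
}

#' @export
print.axisym_grid <- function(x, ...) {
  cat(sprintf("axisymmetric grid: %d x %d cells (r x z), L %.4g um, radius %.4g-%.4g um\n",
              x$nr, x$nz, x$L, min(x$R), max(x$R)))
  invisible(x)
}

#' Simulate buffered calcium dynamics on an axisymmetric grid
#'
#' Deterministic continuum reference for the 1D radial models: the same
#' reaction network (buffers, surface pump, compensating leak) evolved with
#' implicit radial diffusion per slab and conservative explicit axial
#' exchange, on the finite-volume grid from [axisym_grid()]. Influx is applied
#' per unit membrane area over the grid's membrane faces.
#'
#' @param grid An [axisym_grid()].
#' @param influx `NULL`, a [current_waveform()] or [ghk_drive()].
#' @param buffers List of [buffer_spec()].
#' @param pump A [pump_spec()] or `NULL`.
#' @param t_end,dt,nsub,record_every Integration controls (ms, ms, sub-steps,
#'   recording stride).
#' @param Ca0 Resting calcium, mM.
#' @param D_ca Calcium diffusion coefficient, um^2/ms.
#' @return Object of class `axisym_result`: `time`, `sm_ca` (slabs x samples,
#'   per-slab submembrane average), `audit`, `ca_end` (final free-calcium
#'   field), amount tallies and the grid.
#' @export
simulate_axisym <- function(grid, influx, buffers = default_buffers(),
                            pump = pump_spec(), t_end = 140, dt = 0.02,
                            nsub = 2L, record_every = 5L,
                            Ca0 = CA_REST_DEFAULT, D_ca = 0.223) {
  stopifnot(inherits(grid, "axisym_grid"))
  nsteps <- as.integer(ceiling(t_end / dt))
  if (is.null(pump)) pump <- pump_spec(density = 0, leak_balance = FALSE)
  ptot <- matrix(0, grid$nr, grid$nz)
  leak <- matrix(0, grid$nr, grid$nz)
  if (pump$density > 0) {
    on <- grid$amem > 0
    ptot[on] <- pump$density * dca_constants$PUMP_DENSITY_TO_CONC *
      grid$amem[on] / grid$vol[on]
    if (pump$leak_balance) {
      denom <- pump$k_f * Ca0 + pump$k_b + pump$k_ext
      leak[on] <- pump$k_ext * ptot[on] * pump$k_f * Ca0 / denom * grid$vol[on]
    }
  }
  grid_cpp <- list(nr = grid$nr, nz = grid$nz, vol = grid$vol, gr = grid$gr,
                   amem = grid$amem, ptot = ptot, leak = leak,
                   sm_weight = grid$sm_weight, zpairs = grid$zpairs)
  spec <- list(kf = pump$k_f, kb = pump$k_b, kext = pump$k_ext,
               d_ca = D_ca, ca0 = Ca0,
               buffers = internal_buffers(buffers, Ca0))
  drive <- build_drive(influx, dt, nsteps)
  res <- axisym_simulate_cpp(grid_cpp, spec, drive, dt, nsteps,
                             as.integer(nsub), as.integer(record_every))
  structure(c(res, list(grid = grid, dt = dt)), class = "axisym_result")
}

#' @export
print.axisym_result <- function(x, ...) {
  cat(sprintf("axisym_result: %d slabs, %d samples over %.4g ms, submembrane peak %.4g mM\n",
              nrow(x$sm_ca), ncol(x$sm_ca), max(x$time), max(x$sm_ca)))
  invisible(x)
}
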