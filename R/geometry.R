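#' Cylindrical compartment geometry
#'
#' A dendritic compartment is modeled as a cylinder of diameter `diam` and
#' length `L` (both um). Lateral surface area and full volume are derived and
#' carried along so downstream code never recomputes them inconsistently.
#'
#' @param diam Cylinder diameter, um.
#' @param L Cylinder length, um.
#' @return An object of class `compartment_geometry`: list with `diam`, `L`,
#'   `SA` (lateral surface, um^2) and `Vol_f` (full volume, um^3).
#' @examples
#' compartment_geometry(1, 1)
#' @export
compartment_geometry <- function(diam, L) {
  check_scalar_positive(diam, "diam")
  check_scalar_positive(L, "L")
  structure(
    list(diam = diam, L = L,
         SA = pi * diam * L,
         Vol_f = pi * diam^2 * L / 4),
    class = "compartment_geometry"
  )
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("cylindrical compartment: diam %.4g um, L %.4g um, SA %.4g um^2, Vol %.4g um^3\n",
              x$diam, x$L, x$SA, x$Vol_f))
  invisible(x)
}

as_geometry <- function(geom) {
  if (inherits(geom, "compartment_geometry")) return(geom)
  stop_invalid_geometry("expected a compartment_geometry object")
}

#' Equivalent submembrane depth
#'
#' Depth `d_eq` such that `SA * d_eq` equals the true annular volume of a
#' submembrane shell of depth `d` in a cylinder of diameter `diam`:
#' `d_eq = d - d^2/diam`. This is the correction that gives single-pool models
#' a diameter-dependent surface-to-volume ratio.
#'
#' @param d Nominal shell depth, um.
#' @param diam Compartment diameter, um. `d` must be smaller than `diam`
#'   (otherwise the equivalent depth is non-positive and the conversion of
#'   influx to concentration is meaningless); violations raise an
#'   invalid-geometry error.
#' @return Equivalent depth, um (vectorized over `d` and `diam`).
#' @examples
#' equivalent_depth(0.1, 1.0)   # 0.09
#' equivalent_depth(0.1, 0.3)   # 0.0667
#' @export
equivalent_depth <- function(d, diam) {
  if (!is.numeric(d) || !is.numeric(diam) || any(!is.finite(d)) || any(!is.finite(diam))) {
    stop_invalid_geometry("d and diam must be finite numerics")
  }
  if (any(d <= 0) || any(diam <= 0)) {
    stop_invalid_geometry("non-positive geometry: d = ", paste(format(d), collapse = ","),
                          ", diam = ", paste(format(diam), collapse = ","))
  }
  if (any(d >= diam)) {
    bad <- which(d >= diam)
    stop_invalid_geometry("shell depth d >= diam gives non-positive equivalent depth (d = ",
                          paste(format(d[bad]), collapse = ","), ", diam = ",
                          paste(format(rep_len(diam, max(bad))[bad]), collapse = ","), ")")
  }
  d - d^2 / diam
}

#' Submembrane pool geometry under the legacy and corrected conventions
#'
#' Computes the submembrane shell volume, surface-to-volume ratio and
#' equivalent depth for a single-pool calcium model. The corrected convention
#' (`SP_new`) uses the annular volume `pi*d*(diam-d)*L`, giving a
#' diameter-dependent SVR of `diam/(d*(diam-d))`. The legacy convention
#' (`SP_old`) uses `SA*d = pi*diam*L*d`, giving a constant SVR of `1/d`
#' independent of diameter.
#'
#' For `SP_new` any `0 < d < diam` is accepted: beyond `d = diam/2` the
#' annulus picture degenerates (the nominal core would be negative) but the
#' volume formula stays positive and below the full compartment volume, and
#' it is exactly what the corrected pool mechanism uses; `d >= diam` is
#' rejected.
#'
#' @param geom A [compartment_geometry()].
#' @param d Nominal shell depth, um.
#' @param variant `"SP_new"` (corrected) or `"SP_old"` (legacy).
#' @return Object of class `pool_geometry`: list with `d`, `d_eq`, `variant`,
#'   `Vol_s` (um^3), `SVR` (um^-1) and the parent `geom`.
#' @examples
#' g <- compartment_geometry(1, 1)
#' pool_geometry(g, 0.1, "SP_new")  # Vol_s 0.2827, SVR 11.11
#' pool_geometry(g, 0.1, "SP_old")  # Vol_s 0.3142, SVR 10
#' @export
pool_geometry <- function(geom, d, variant = c("SP_new", "SP_old")) {
  geom <- as_geometry(geom)
  variant <- match.arg(variant)
  check_scalar_positive(d, "d")
  if (variant == "SP_new") {
    d_eq <- equivalent_depth(d, geom$diam)  # errors when d >= diam
    Vol_s <- pi * d * (geom$diam - d) * geom$L
    SVR <- geom$diam / (d * (geom$diam - d))
  } else {
    d_eq <- d
    Vol_s <- pi * geom$diam * geom$L * d
    SVR <- 1 / d
  }
  structure(
    list(d = d, d_eq = d_eq, variant = variant, Vol_s = Vol_s, SVR = SVR,
         geom = geom),
    class = "pool_geometry"
  )
}

# internal: assemble a shell_stack from ordered depths (outermost first)
make_shell_stack <- function(geom, depths, scheme) {
  radius <- geom$diam / 2
  edges <- radius - cumsum(c(0, depths))   # outer radius of each shell, then 0
  n <- length(depths)
  r_out <- edges[seq_len(n)]
  r_in <- edges[seq_len(n) + 1L]
  # guard tiny negative round-off on the core
  r_in[n] <- max(r_in[n], 0)
  volumes <- pi * (r_out^2 - r_in^2) * geom$L
  interface_areas <- if (n > 1L) 2 * pi * r_in[-n] * geom$L else numeric(0)
  structure(
    list(scheme = scheme, depths = depths, volumes = volumes,
         interface_areas = interface_areas,
         r_out = r_out, r_in = r_in,
         centers = (r_out + r_in) / 2,
         d1 = depths[1L], geom = geom),
    class = "shell_stack"
  )
}

#' @export
print.shell_stack <- function(x, ...) {
  cat(sprintf("shell stack (%s): %d shells, d1 = %.4g um, diam = %.4g um\n",
              x$scheme, length(x$depths), x$d1, x$geom$diam))
  invisible(x)
}

#' Variable-depth radial shell stack (DM scheme)
#'
#' The classic NEURON-book discretization: the shell count is
#' `floor(diam/(4 d) + 1.5)` and the outermost and innermost shells have depth
#' `d1 = diam / (4 (Shells - 1))` while all intermediate shells have depth
#' `2 d1`. The realized submembrane depth `d1` therefore drifts with diameter
#' (between `0.75 d` and `1.25 d` once at least 3 shells are present).
#'
#' @param geom A [compartment_geometry()].
#' @param d Nominal outer shell depth, um (0.1 um is the conventional value).
#' @return A `shell_stack` (scheme `"variable_depth"`).
#' @examples
#' shells_variable_depth(compartment_geometry(0.6, 1), 0.1)  # 3 shells, d1 0.075
#' @export
shells_variable_depth <- function(geom, d) {
  geom <- as_geometry(geom)
  check_scalar_positive(d, "d")
  n <- variable_depth_count(geom$diam, d)
  if (n < 2L) {
    stop_invalid_geometry("variable-depth scheme needs at least 2 shells; diam = ",
                          format(geom$diam), " um with d = ", format(d),
                          " um yields ", n)
  }
  d1 <- geom$diam / (4 * (n - 1))
  depths <- c(d1, rep(2 * d1, n - 2L), d1)
  make_shell_stack(geom, depths, "variable_depth")
}

#' Shell count of the variable-depth scheme
#'
#' @param diam Compartment diameter(s), um.
#' @param d Nominal outer shell depth, um.
#' @return Integer shell count(s), `floor(diam/(4d) + 1.5)`.
#' @export
variable_depth_count <- function(diam, d) {
  # small tolerance so diameters carrying float round-off (e.g. from seq())
  # land on the literal integer-boundary value of the printed formula
  as.integer(floor(diam / (4 * d) + 1.5 + 1e-9))
}

#' Outer-shell depth of the variable-depth scheme
#'
#' @inheritParams variable_depth_count
#' @return `d1 = diam / (4 (Shells - 1))` (NA where fewer than 2 shells).
#' @export
variable_depth_d1 <- function(diam, d) {
  n <- variable_depth_count(diam, d)
  ifelse(n >= 2L, diam / (4 * (n - 1)), NA_real_)
}

#' Fixed-depth radial shell stack (DM_FD scheme)
#'
#' All shells have the nominal depth `d` except the core, whose depth is
#' adjusted so the depths sum to the radius. The shell count is
#' `ceiling(diam/(2 d))`; a diameter at or below `2 d` yields a single
#' full-radius shell.
#'
#' @inheritParams shells_variable_depth
#' @return A `shell_stack` (scheme `"fixed_depth"`).
#' @examples
#' shells_fixed_depth(compartment_geometry(0.9, 1), 0.1)  # 5 shells, core 0.05
#' @export
shells_fixed_depth <- function(geom, d) {
  geom <- as_geometry(geom)
  check_scalar_positive(d, "d")
  radius <- geom$diam / 2
  # tolerance keeps an exact-multiple diameter from gaining a zero-depth core
  n <- as.integer(ceiling(geom$diam / (2 * d) - 1e-9))
  n <- max(n, 1L)
  depths <- if (n == 1L) radius else c(rep(d, n - 1L), radius - (n - 1L) * d)
  make_shell_stack(geom, depths, "fixed_depth")
}

#' Hybrid shell stack: fixed submembrane depth, equal variable inner depths
#'
#' The outermost shell has the prescribed depth `d1` and the remaining radius
#' is split equally over `n_shells - 1` inner shells. Used to isolate the
#' submembrane-conversion error from the interior-discretization error when a
#' fixed shell count is imposed.
#'
#' @param geom A [compartment_geometry()].
#' @param d1 Outer shell depth, um; must be smaller than the radius.
#' @param n_shells Total number of shells (>= 2).
#' @return A `shell_stack` (scheme `"hybrid_fd"`).
#' @export
shells_hybrid_fd <- function(geom, d1, n_shells) {
  geom <- as_geometry(geom)
  check_scalar_positive(d1, "d1")
  radius <- geom$diam / 2
  if (!is.numeric(n_shells) || n_shells < 2 || n_shells != round(n_shells)) {
    stop_invalid_geometry("n_shells must be an integer >= 2, got ", format(n_shells))
  }
  if (d1 >= radius) {
    stop_invalid_geometry("outer depth d1 = ", format(d1),
                          " um must be smaller than the radius ", format(radius), " um")
  }
  n_shells <- as.integer(n_shells)
  depths <- c(d1, rep((radius - d1) / (n_shells - 1L), n_shells - 1L))
  make_shell_stack(geom, depths, "hybrid_fd")
}

# internal: all-variable stack with a forced shell count (fixed n, DM layout)
shells_variable_forced <- function(geom, n_shells) {
  geom <- as_geometry(geom)
  n_shells <- as.integer(n_shells)
  if (n_shells < 2L) stop_invalid_geometry("forced shell count must be >= 2")
  d1 <- geom$diam / (4 * (n_shells - 1L))
  depths <- c(d1, rep(2 * d1, n_shells - 2L), d1)
  make_shell_stack(geom, depths, "variable_depth_forced")
}

# internal: single well-mixed shell spanning the full radius
shell_single <- function(geom) {
  geom <- as_geometry(geom)
  make_shell_stack(geom, geom$diam / 2, "single")
}

#' Per-diameter shell geometry audit table
#'
#' Tabulates, per diameter, the shell count and realized outer depth of the
#' variable-depth and fixed-depth schemes (nominal depth `d`), along with the
#' full compartment volume.
#'
#' @param diams Numeric vector of diameters, um.
#' @param d Nominal shell depth, um.
#' @param L Compartment length, um.
#' @return data.frame with columns `diam`, `shells_dm`, `d1_dm`,
#'   `shells_dmfd`, `core_depth_dmfd`, `vol_um3`.
#' @export
geometry_audit <- function(diams, d = 0.1, L = 1) {
  rows <- lapply(diams, function(dm) {
    g <- compartment_geometry(dm, L)
    n_dm <- variable_depth_count(dm, d)
    fd <- shells_fixed_depth(g, d)
    data.frame(
      diam = dm,
      shells_dm = n_dm,
      d1_dm = if (n_dm >= 2L) dm / (4 * (n_dm - 1)) else NA_real_,
      shells_dmfd = length(fd$depths),
      core_depth_dmfd = fd$depths[length(fd$depths)],
      vol_um3 = g$Vol_f
    )
  })
  do.call(rbind, rows)
}
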