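#' Sovova broken-and-intact-cells model parameters
#'
#' The Sovova model splits the initial solute load per insoluble solid,
#' `x0`, into an easily accessible part `x0 - xk` (broken cells, extracted
#' under fluid-film control) and an inaccessible part `xk` (intact cells,
#' extracted under solid-diffusion control). `yr` is the solute solubility in
#' the solvent (kg solute per kg solvent, in the model's dimensionless
#' scaling), and `Z` and `W` are the dimensionless fast- and slow-period
#' parameters, proportional to the fluid- and solid-phase mass-transfer
#' coefficients.
#'
#' @param x0 Initial solute per insoluble solid, kg/kg.
#' @param xk Inaccessible (intact-cell) solute, kg/kg, with `0 <= xk <= x0`.
#' @param yr Solubility, kg/kg (> 0).
#' @param Z Fast-period (fluid-phase) parameter (> 0).
#' @param W Slow-period (solid-phase) parameter (> 0).
#' @return A validated list of class `sovova_parameters`.
#' @examples
#' sovova_parameters(x0 = 0.06, xk = 0.035, yr = 0.54, Z = 0.05, W = 0.08)
#' @export
sovova_parameters <- function(x0, xk, yr, Z, W) {
  for (nm in c("x0", "xk", "yr", "Z", "W")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0(nm, " must be a single finite number"))
    }
  }
  if (x0 <= 0) abort("x0 must be positive")
  if (xk < 0 || xk > x0) abort("xk must satisfy 0 <= xk <= x0")
  if (yr <= 0) abort("yr must be positive")
  if (Z <= 0) abort("Z must be positive")
  if (W <= 0) abort("W must be positive")
  structure(list(x0 = x0, xk = xk, yr = yr, Z = Z, W = W),
            class = "sovova_parameters")
}

#' Period boundaries of the Sovova model
#'
#' The fast period ends at the specific solvent consumption
#' `qm = (x0 - xk) / (yr * Z)`, when the easily accessible solute starts to
#' run out at the bed inlet; the transition period ends at
#' `qn = qm + (1/W) * log((xk + (x0 - xk) * exp(W * x0 / yr)) / x0)`, when the
#' fast/slow boundary reaches the bed outlet. Always `qm <= qn`. When
#' `xk = x0` (no accessible solute) `qm = 0`; as `xk -> 0` the transition
#' width tends to `x0 / yr`, the consumption needed to carry off the whole
#' accessible load at saturation.
#'
#' @param params A [sovova_parameters()] object.
#' @return Named numeric vector `c(qm, qn)` (dimensionless solvent/solid).
#' @examples
#' sovova_transitions(sovova_parameters(0.06, 0.035, 0.54, 0.05, 0.08))
#' @export
sovova_transitions <- function(params) {
  stopifnot(inherits(params, "sovova_parameters"))
  with(params, {
    qm <- (x0 - xk) / (yr * Z)
    qn <- qm + log((xk + (x0 - xk) * exp(W * x0 / yr)) / x0) / W
    if (qn < qm) abort("invalid parameters: qn < qm")
    c(qm = qm, qn = qn)
  })
}

#' Three-period Sovova extraction yield
#'
#' Evaluates the analytic broken-and-intact-cells solution for the extract
#' mass per insoluble solid, `e`, as a function of the specific solvent
#' consumption `q` (solvent mass passed per insoluble-solid mass). The three
#' periods, on left-closed intervals, are:
#'
#' * `q < qm` (fast): `e = q * yr * (1 - exp(-Z))` - solubility-limited
#'   extraction of accessible solute.
#' * `qm <= q < qn` (transition): `e = yr * (q - qm * exp(zw - Z))`, where
#'   the boundary coordinate satisfies
#'   `zw / Z = (yr / (W x0)) * log((x0 * exp(W (q - qm)) - xk) / (x0 - xk))`.
#' * `q >= qn` (slow): diffusion-limited depletion of intact-cell solute,
#'   `e = x0 - (yr/W) * log(1 + (exp(W x0 / yr) - 1) * exp(W (qm - q)) * xk / x0)`.
#'
#' The curve is continuous at both boundaries, nondecreasing, and approaches
#' `x0` as `q -> Inf`.
#'
#' @param q Specific solvent consumption(s), dimensionless, `>= 0`.
#' @param params A [sovova_parameters()] object.
#' @return Extract per insoluble solid `e(q)`, same length as `q`.
#' @examples
#' p <- sovova_parameters(0.06, 0.035, 0.54, 0.05, 0.08)
#' sovova_yield(c(0, 0.5, 1, 5), p)
#' @export
sovova_yield <- function(q, params) {
  stopifnot(inherits(params, "sovova_parameters"))
  if (any(q < 0)) abort("q must be non-negative")
  tr <- sovova_transitions(params)
  qm <- tr[["qm"]]; qn <- tr[["qn"]]
  x0 <- params$x0; xk <- params$xk; yr <- params$yr
  Z <- params$Z; W <- params$W
  e <- numeric(length(q))

  p1 <- q < qm
  e[p1] <- q[p1] * yr * (1 - exp(-Z))

  p2 <- q >= qm & q < qn
  if (any(p2)) {
    if (x0 == xk) abort("transition period undefined when xk = x0") # unreachable: qm = qn = 0
    arg <- (x0 * exp(W * (q[p2] - qm)) - xk) / (x0 - xk)
    if (any(arg <= 0)) {
      abort("boundary-coordinate logarithm has non-positive argument; parameters outside the model's validity")
    }
    zw <- Z * yr / (W * x0) * log(arg)
    e[p2] <- yr * (q[p2] - qm * exp(zw - Z))
  }

  p3 <- q >= qn
  if (any(p3)) {
    e[p3] <- x0 - yr / W *
      log(1 + (exp(W * x0 / yr) - 1) * exp(W * (qm - q[p3])) * xk / x0)
  }
  e
}

#' Sovova yield as a time curve
#'
#' Maps extraction time to specific solvent consumption through the specific
#' flow `qdot = Q / N` (solvent mass flow per insoluble-solid mass, s^-1) and
#' evaluates [sovova_yield()].
#'
#' @param times Times, s.
#' @param params A [sovova_parameters()] object.
#' @param qdot Specific solvent flow, s^-1.
#' @return Tibble with `time` and `yield` (extract per insoluble solid).
#' @export
sovova_curve <- function(times, params, qdot) {
  if (!is.numeric(qdot) || length(qdot) != 1L || qdot <= 0) {
    abort("qdot must be a single positive number (s^-1)")
  }
  tibble::tibble(time = times, yield = sovova_yield(qdot * times, params))
}

#' Convert between Sovova model parameters and mass-transfer coefficients
#'
#' The dimensionless fit parameters relate to the physical film coefficients
#' through the bed properties:
#' `Z = kf * a0 * rho / (qdot * (1 - eps) * rho_s)` and
#' `W = ks * a0 / (qdot * (1 - eps))`, where `a0` is the interfacial area per
#' bed volume, `rho` the solvent density, `rho_s` the solid density, `eps`
#' the porosity and `qdot` the specific solvent flow. `sovova_mass_transfer()`
#' inverts these for `kf`, `ks`; `sovova_zw_parameters()` applies them
#' forward. The round trip is exact.
#'
#' @param Z,W Dimensionless Sovova parameters.
#' @param kf,ks Fluid- and solid-phase mass-transfer coefficients, m s^-1.
#' @param bed A [bed_properties()] object with `specific_flow`, `porosity`,
#'   `specific_area`, `fluid_density` and `solid_density`.
#' @return `sovova_mass_transfer()`: named vector `c(kf, ks)` in m s^-1;
#'   `sovova_zw_parameters()`: named vector `c(Z, W)`.
#' @examples
#' sovova_mass_transfer(Z = 4.721e-2, W = 7.753e-2, bed = default_bed())
#' @export
sovova_mass_transfer <- function(Z, W, bed) {
  bed_require(bed, c("specific_flow", "porosity", "specific_area",
                     "fluid_density", "solid_density"),
              "sovova_mass_transfer()")
  hold <- bed$specific_flow * (1 - bed$porosity)
  kf <- Z * hold * bed$solid_density / (bed$specific_area * bed$fluid_density)
  ks <- W * hold / bed$specific_area
  c(kf = kf, ks = ks)
}

#' @rdname sovova_mass_transfer
#' @export
sovova_zw_parameters <- function(kf, ks, bed) {
  bed_require(bed, c("specific_flow", "porosity", "specific_area",
                     "fluid_density", "solid_density"),
              "sovova_zw_parameters()")
  hold <- bed$specific_flow * (1 - bed$porosity)
  Z <- kf * bed$specific_area * bed$fluid_density / (hold * bed$solid_density)
  W <- ks * bed$specific_area / hold
  c(Z = Z, W = W)
}
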