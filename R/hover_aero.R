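#' Physical constants used in the hover parameter definitions
#'
#' Gravitational acceleration and the dynamic viscosity of air at standard
#' conditions (15 degC). Overridable wherever they appear.
#' @name hover-constants
#' @keywords internal
NULL

.g_default <- 9.81       # m s^-2
.mu_default <- 1.81e-5   # Pa s, air at 15 degC

.check_pos <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v) | v <= 0))
      stop("non-positive or non-finite input: ", nm)
  }
  invisible(TRUE)
}

#' Mean wing-tip velocity in hover
#'
#' \eqn{U = 2 \Phi f R}: the wing tip sweeps an arc \eqn{\Phi R} twice per
#' flapping cycle. `Phi` must be the peak-to-peak stroke amplitude in
#' radians.
#'
#' @param Phi peak-to-peak stroke amplitude, rad.
#' @param f flapping frequency, Hz.
#' @param R wing length, m.
#' @return Mean tip velocity, m s^-1. Vectorised.
#' @export
tip_velocity <- function(Phi, f, R) {
  .check_pos(Phi = Phi, f = f, R = R)
  2 * Phi * f * R
}

#' Reduced frequency of hovering flight
#'
#' \eqn{k = \pi f c / U = \pi / (2 \Phi AR)}: the ratio of the dynamic-stall
#' timescale \eqn{c/U} to the flapping period \eqn{1/f}; equivalently the
#' inverse of the stroke-arc-to-chord ratio. Leading-edge-vortex lift
#' enhancement requires these timescales in balance (roughly
#' \eqn{0.15 < k < 0.25}).
#'
#' @param Phi peak-to-peak stroke amplitude, rad.
#' @param AR wing aspect ratio, \eqn{R^2/S}.
#' @return Reduced frequency (dimensionless). Vectorised.
#' @export
reduced_frequency <- function(Phi, AR) {
  .check_pos(Phi = Phi, AR = AR)
  pi / (2 * Phi * AR)
}

#' Cycle-averaged hover lift coefficient
#'
#' \eqn{C_L = 2 m g / (\rho U^2 S)}, the lift coefficient that closes the
#' hover equilibrium (cycle-averaged lift equals weight). It absorbs all
#' unsteady lift mechanisms rather than modelling them.
#'
#' @param m body mass, kg.
#' @param rho air density, kg m^-3.
#' @param U mean wing-tip velocity, m s^-1.
#' @param S wing area, m^2 (dataset convention; see [derive_aero()]).
#' @param g gravitational acceleration, m s^-2.
#' @return Lift coefficient (dimensionless). Vectorised.
#' @export
lift_coefficient <- function(m, rho, U, S, g = .g_default) {
  .check_pos(m = m, rho = rho, U = U, S = S, g = g)
  2 * m * g / (rho * U^2 * S)
}

#' Wing Reynolds number
#'
#' \eqn{Re = \rho U c / \mu} with the mean chord \eqn{c = S/R} as length
#' scale.
#'
#' @param rho air density, kg m^-3.
#' @param U mean wing-tip velocity, m s^-1.
#' @param c mean chord, m.
#' @param mu dynamic viscosity of air, Pa s.
#' @return Reynolds number (dimensionless). Vectorised.
#' @export
reynolds_number <- function(rho, U, c, mu = .mu_default) {
  .check_pos(rho = rho, U = U, c = c, mu = mu)
  rho * U * c / mu
}

#' Derive all hover aerodynamic parameters for observation records
#'
#' Appends the derived dimensional and nondimensional hover parameters to a
#' set of observation records: mean chord `c = S/R`, aspect ratio
#' `AR = R^2/S`, and — for rows with complete kinematics (`f` and `Phi`
#' present) — tip velocity `U`, reduced frequency `k`, lift coefficient
#' `C_L` and Reynolds number `Re`. Rows with incomplete kinematics keep `NA`
#' in the kinematic columns and remain usable for morphology-only
#' regressions (the partial-data contract of the comparative dataset, where
#' not every literature source reports kinematics).
#'
#' @param obs a `"hover_obs"` data frame from [as_observations()] (SI
#'   units), or any data frame with columns `m, R, S, rho` and optionally
#'   `f, Phi`.
#' @param g gravitational acceleration, m s^-2.
#' @param mu air dynamic viscosity, Pa s.
#' @return The input with columns `c, AR, U, k, C_L, Re` appended.
#' @export
derive_aero <- function(obs, g = .g_default, mu = .mu_default) {
  stopifnot(all(c("m", "R", "S", "rho") %in% names(obs)))
  out <- obs
  out$c <- obs$S / obs$R
  out$AR <- obs$R^2 / obs$S
  out$U <- out$k <- out$C_L <- out$Re <- rep(NA_real_, nrow(obs))
  kin <- !is.na(obs$f) & !is.na(obs$Phi)
  if (any(kin)) {
    out$U[kin] <- tip_velocity(obs$Phi[kin], obs$f[kin], obs$R[kin])
    out$k[kin] <- reduced_frequency(obs$Phi[kin], out$AR[kin])
    out$C_L[kin] <- lift_coefficient(obs$m[kin], obs$rho[kin], out$U[kin],
                                     obs$S[kin], g = g)
    out$Re[kin] <- reynolds_number(obs$rho[kin], out$U[kin], out$c[kin],
                                   mu = mu)
  }
  out
}
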