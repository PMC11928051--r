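#' Base scaling assumptions for normal hovering
#'
#' The theoretical allometry of hovering flight follows from a small set of
#' assumptions about how quantities scale with body mass \eqn{m}:
#' \itemize{
#'   \item geometric similarity (isometry) of the wing and body:
#'     \eqn{R \sim m^{1/3}}, \eqn{S \sim m^{2/3}}, \eqn{R_b \sim m^{1/3}},
#'     and the moment arm \eqn{\delta \sim m^{1/3}};
#'   \item bounded angles: stroke amplitude \eqn{\Phi}, wing pitch
#'     \eqn{\alpha}, mean body pitch \eqn{\theta_m} and body pitch amplitude
#'     \eqn{\theta_a} are all mass-invariant (\eqn{m^0}) because they are
#'     geometrically and mechanically restricted;
#'   \item mass-invariant nondimensional body properties:
#'     \eqn{I^* = I/(m R_b^2) \sim m^0} and
#'     \eqn{\delta^* = \delta/R_b \sim m^0};
#'   \item environmental constants \eqn{\rho}, \eqn{\mu}, \eqn{g} carry mass
#'     exponent 0 by definition.
#' }
#' Exponents are exact [rational()] numbers.
#'
#' @return Named list of `rational` exponents for the base quantities
#'   `m, R, S, R_b, delta, Phi, alpha, theta_m, theta_a, I_star, delta_star,
#'   rho, mu, g`.
#' @seealso [derive_exponents()], [solve_frequency_exponent()]
#' @export
hover_assumptions <- function() {
  list(
    m          = rational(1L),
    R          = rational(1L, 3L),
    S          = rational(2L, 3L),
    R_b        = rational(1L, 3L),
    delta      = rational(1L, 3L),
    Phi        = rational(0L),
    alpha      = rational(0L),
    theta_m    = rational(0L),
    theta_a    = rational(0L),
    I_star     = rational(0L),
    delta_star = rational(0L),
    rho        = rational(0L),
    mu         = rational(0L),
    g          = rational(0L)
  )
}

#' Combine mass exponents of a product of powers
#'
#' For a quantity \eqn{q = \prod_i x_i^{p_i}} whose factors scale as
#' \eqn{x_i \sim m^{\gamma_i}}, the mass exponent of \eqn{q} is
#' \eqn{\sum_i p_i \gamma_i}, computed in exact rational arithmetic.
#'
#' @param terms named list: each element is `list(gamma = <rational>,
#'   power = <rational or integer>)`. An element whose `gamma` is `NULL`
#'   raises a dependency error naming the unresolved term.
#' @return A `rational` exponent.
#' @examples
#' # c = S / R with S ~ m^(2/3), R ~ m^(1/3)  =>  c ~ m^(1/3)
#' combine_exponents(list(
#'   S = list(gamma = rational(2, 3), power = 1L),
#'   R = list(gamma = rational(1, 3), power = -1L)))
#' @export
combine_exponents <- function(terms) {
  stopifnot(is.list(terms), length(terms) >= 1L)
  out <- rational(0L)
  for (nm in names(terms)) {
    term <- terms[[nm]]
    if (is.null(term$gamma))
      stop("unresolved term in exponent combination: ", nm)
    out <- out + .as_rational(term$power) * .as_rational(term$gamma)
  }
  out
}

.term <- function(gamma, power) list(gamma = gamma, power = power)

#' Solve the attitude constraint for the flapping-frequency exponent
#'
#' During hover the oscillatory aerodynamic pitch moment (lift scaling with
#' weight, \eqn{L \sim m g}, acting on moment arm \eqn{\delta}) balances the
#' body pitch acceleration. With harmonic body pitch the pitch amplitude
#' scales as \eqn{\theta_a \sim g/(R_b f^2)}. Requiring a mass-invariant
#' (bounded) pitch amplitude therefore pins the frequency exponent:
#' \deqn{\gamma(\theta_a) = \gamma(g) - \gamma(R_b) - 2 e_f = 0
#'       \;\Rightarrow\; e_f = -\gamma(R_b)/2 = -1/6.}
#' The same one-equation linear system can be solved in the other direction:
#' given a frequency exponent, the implied \eqn{\theta_a} exponent is
#' returned, which is non-zero for every \eqn{e_f \neq -1/6} (the
#' instability argument at the exponent level).
#'
#' @param assumptions assumption set from [hover_assumptions()].
#' @param theta_a_target target mass exponent for the pitch amplitude
#'   (`rational`; default 0, the bounded-attitude constraint).
#' @param freq_exponent if supplied (`rational`), solve for the
#'   \eqn{\theta_a} exponent implied by this frequency exponent instead.
#' @return A list with `quantity` (`"f"` or `"theta_a"`), `gamma`
#'   (`rational`), and `provenance` (character vector of derivation steps).
#' @examples
#' solve_frequency_exponent()$gamma                       # -1/6
#' solve_frequency_exponent(freq_exponent = rational(-1, 6))$gamma  # 0
#' @export
solve_frequency_exponent <- function(assumptions = hover_assumptions(),
                                     theta_a_target = rational(0L),
                                     freq_exponent = NULL) {
  for (nm in c("g", "R_b"))
    if (is.null(assumptions[[nm]]))
      stop("assumption set incomplete: missing ", nm)
  g_g  <- assumptions$g
  g_Rb <- assumptions$R_b
  if (is.null(freq_exponent)) {
    # gamma(theta_a) = gamma(g) - gamma(R_b) - 2 e_f = target
    e_f <- (g_g - g_Rb - .as_rational(theta_a_target)) / 2L
    list(
      quantity = "f",
      gamma = e_f,
      provenance = c(
        "theta_a ~ g / (R_b f^2)  [pitch-moment balance, harmonic pitch]",
        sprintf("bounded attitude: gamma(theta_a) = %s",
                as.character(.as_rational(theta_a_target))),
        sprintf("solve gamma(g) - gamma(R_b) - 2 e_f = %s  =>  e_f = %s",
                as.character(.as_rational(theta_a_target)),
                as.character(e_f))
      )
    )
  } else {
    e_f <- .as_rational(freq_exponent)
    g_ta <- g_g - g_Rb - rational(2L) * e_f
    list(
      quantity = "theta_a",
      gamma = g_ta,
      provenance = c(
        "theta_a ~ g / (R_b f^2)  [pitch-moment balance, harmonic pitch]",
        sprintf("given e_f = %s  =>  gamma(theta_a) = %s",
                as.character(e_f), as.character(g_ta))
      )
    )
  }
}

#' Derive the full table of theoretical allometric exponents
#'
#' Propagates the base assumptions through the definitional relations of
#' hovering aerodynamics, in exact rational arithmetic:
#' \deqn{c = S/R,\quad AR = R^2/S,\quad I = m R_b^2,\quad U = 2\Phi f R,}
#' \deqn{k = \pi f c / U = \pi/(2\Phi AR),\quad
#'       C_L = 2 m g/(\rho U^2 S),\quad Re = \rho U c/\mu,}
#' with the frequency exponent obtained from the attitude constraint
#' ([solve_frequency_exponent()]). The result is independent of evaluation
#' order because every quantity is a product of powers of already-resolved
#' quantities.
#'
#' @param assumptions assumption set from [hover_assumptions()].
#' @return A data frame with one row per quantity
#'   (`R, S, AR, R_b, theta_m, f, Phi, U, k, C_L, Re` plus the auxiliary
#'   `c, I, theta_a`): columns `quantity`, `gamma` (fraction string),
#'   `gamma_num` (numeric), `provenance`, and attribute `"rationals"`
#'   holding the exact values.
#' @examples
#' derive_exponents()[, c("quantity", "gamma")]
#' @export
derive_exponents <- function(assumptions = hover_assumptions()) {
  need <- c("m", "R", "S", "R_b", "Phi", "theta_m", "rho", "mu", "g")
  miss <- setdiff(need, names(assumptions))
  if (length(miss))
    stop("assumption set incomplete: missing ", paste(miss, collapse = ", "))
  a <- assumptions

  g_c  <- combine_exponents(list(S = .term(a$S, 1L), R = .term(a$R, -1L)))
  g_AR <- combine_exponents(list(R = .term(a$R, 2L), S = .term(a$S, -1L)))
  g_I  <- combine_exponents(list(m = .term(a$m, 1L), R_b = .term(a$R_b, 2L)))
  ef   <- solve_frequency_exponent(a)
  g_f  <- ef$gamma
  g_U  <- combine_exponents(list(Phi = .term(a$Phi, 1L), f = .term(g_f, 1L),
                                 R = .term(a$R, 1L)))
  g_k  <- combine_exponents(list(f = .term(g_f, 1L), c = .term(g_c, 1L),
                                 U = .term(g_U, -1L)))
  g_k2 <- combine_exponents(list(Phi = .term(a$Phi, -1L),
                                 AR = .term(g_AR, -1L)))
  stopifnot(g_k == g_k2)  # two routes to k must agree
  g_CL <- combine_exponents(list(m = .term(a$m, 1L), g = .term(a$g, 1L),
                                 rho = .term(a$rho, -1L),
                                 U = .term(g_U, -2L), S = .term(a$S, -1L)))
  g_Re <- combine_exponents(list(rho = .term(a$rho, 1L), U = .term(g_U, 1L),
                                 c = .term(g_c, 1L), mu = .term(a$mu, -1L)))
  g_ta <- solve_frequency_exponent(a, freq_exponent = g_f)$gamma

  quantities <- c("R", "S", "AR", "R_b", "theta_m", "f", "Phi",
                  "U", "k", "C_L", "Re", "c", "I", "theta_a")
  gammas <- list(a$R, a$S, g_AR, a$R_b, a$theta_m, g_f, a$Phi,
                 g_U, g_k, g_CL, g_Re, g_c, g_I, g_ta)
  provenance <- c(
    "assumed: wing-length isometry",
    "assumed: wing-area isometry",
    "AR = R^2/S",
    "assumed: body-length isometry",
    "assumed: bounded mean pitch",
    paste(ef$provenance, collapse = "; "),
    "assumed: bounded stroke amplitude",
    "U = 2 Phi f R",
    "k = pi f c / U = pi/(2 Phi AR)",
    "C_L = 2 m g / (rho U^2 S)",
    "Re = rho U c / mu",
    "c = S/R",
    "I = I* m R_b^2",
    paste(solve_frequency_exponent(a, freq_exponent = g_f)$provenance,
          collapse = "; ")
  )
  out <- data.frame(
    quantity = quantities,
    gamma = vapply(gammas, as.character, character(1)),
    gamma_num = vapply(gammas, as.numeric, numeric(1)),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  names(gammas) <- quantities
  attr(out, "rationals") <- gammas
  out
}

#' Exact theoretical exponent of one quantity
#'
#' @param quantity quantity name as in [derive_exponents()].
#' @param assumptions assumption set.
#' @return The `rational` mass exponent.
#' @export
theory_exponent <- function(quantity, assumptions = hover_assumptions()) {
  tab <- attr(derive_exponents(assumptions), "rationals")
  if (is.null(tab[[quantity]]))
    stop("no theoretical exponent derived for quantity: ", quantity)
  tab[[quantity]]
}
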