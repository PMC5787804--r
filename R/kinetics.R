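# Bell-Evans single-energy-barrier kinetics at constant loading rate.
# The escape rate grows exponentially with force,
#   k(F) = k_off * exp(F * x_beta / kBT),
# which at constant loading rate r yields the closed-form rupture-force
# distribution and the most probable unbinding force
#   F* = (kBT / x_beta) * ln(x_beta * r / (kBT * k_off)).

# Boltzmann constant in pN nm / K.
.kB_pN_nm <- 1.380649e-2

#' Thermal context
#'
#' Bundles the absolute temperature with the thermal energy `kBT`
#' expressed in the package's internal unit system (pN nm). At the default
#' room temperature of 298 K, `kBT` is 4.114 pN nm.
#'
#' @param temperature Absolute temperature in K (> 0).
#' @return An object of class `thermal_context` with fields `temperature`
#'   (K) and `kBT` (pN nm).
#' @examples
#' thermal_context()$kBT      # 4.114 pN nm
#' @export
thermal_context <- function(temperature = 298) {
  check_positive_scalar(temperature, "temperature")
  structure(
    list(temperature = temperature, kBT = .kB_pN_nm * temperature),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("<thermal_context> T = %g K, kBT = %.4g pN nm\n",
              x$temperature, x$kBT))
  invisible(x)
}

#' Bell-Evans kinetic parameters
#'
#' The two parameters of the single-energy-barrier model: the zero-force
#' dissociation rate constant `k_off` and the barrier width `x_beta`, the
#' thermally averaged projection of the transition state along the force
#' direction.
#'
#' @param k_off Dissociation rate constant in 1/s (> 0).
#' @param x_beta Barrier width in nm (> 0).
#' @return An object of class `bell_parameters`.
#' @export
bell_parameters <- function(k_off, x_beta) {
  check_positive_scalar(k_off, "k_off")
  check_positive_scalar(x_beta, "x_beta")
  structure(list(k_off = k_off, x_beta = x_beta), class = "bell_parameters")
}

#' @export
print.bell_parameters <- function(x, ...) {
  cat(sprintf("<bell_parameters> k_off = %g 1/s, x_beta = %g nm\n",
              x$k_off, x$x_beta))
  invisible(x)
}

.check_force <- function(force) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0))
    stop_domain("`force` must be finite and non-negative (pN)")
  force
}

.check_rate <- function(loading_rate) {
  if (!is.numeric(loading_rate) || any(!is.finite(loading_rate)) ||
      any(loading_rate <= 0))
    stop_domain("`loading_rate` must be finite and positive (pN/s)")
  loading_rate
}

#' Force-dependent escape rate of the Bell model
#'
#' `k(F) = k_off * exp(F * x_beta / kBT)`, strictly increasing in the
#' applied force.
#'
#' @param force Applied force in pN (vectorised, >= 0).
#' @param params A [bell_parameters()] object.
#' @param ctx A [thermal_context()].
#' @return Escape rate(s) in 1/s.
#' @examples
#' bell_rate(0, bell_parameters(0.1, 0.5))            # k_off
#' @export
bell_rate <- function(force, params, ctx = thermal_context()) {
  .check_force(force)
  params$k_off * exp(force * params$x_beta / ctx$kBT)
}

#' Most probable unbinding force at constant loading rate
#'
#' The mode of the rupture-force distribution of the single-energy-barrier
#' model, `F* = (kBT/x_beta) * ln(x_beta * r / (kBT * k_off))`, clamped at
#' zero below the threshold loading rate `kBT * k_off / x_beta` (rupture
#' forces are magnitudes; in the sub-threshold regime the distribution's
#' mode sits at zero force). Above threshold, F* rises linearly in
#' `ln r` with slope `kBT / x_beta`.
#'
#' @param loading_rate Loading rate(s) r in pN/s (> 0).
#' @inheritParams bell_rate
#' @return Most probable force(s) in pN.
#' @examples
#' most_probable_force(5000, bell_parameters(0.1, 0.5))   # ~71.7 pN
#' @export
most_probable_force <- function(loading_rate, params, ctx = thermal_context()) {
  .check_rate(loading_rate)
  pmax(0, (ctx$kBT / params$x_beta) *
            log(params$x_beta * loading_rate / (ctx$kBT * params$k_off)))
}

#' Rupture-force probability density at constant loading rate
#'
#' Exact density implied by the Bell escape rate when the bond is loaded
#' at constant rate r:
#' `p(F) = (k_off/r) exp(x_beta F/kBT) exp(-(k_off kBT/(r x_beta)) (exp(x_beta F/kBT) - 1))`.
#' It integrates to 1 over F in `[0, Inf)` and its mode equals
#' [most_probable_force()] whenever `x_beta * r > kBT * k_off` (zero
#' otherwise). Used as the closed-form oracle for the curve simulator.
#'
#' @param force Force grid in pN (>= 0).
#' @inheritParams most_probable_force
#' @return Density values in 1/pN.
#' @export
rupture_force_density <- function(force, loading_rate, params,
                                  ctx = thermal_context()) {
  .check_force(force)
  .check_rate(loading_rate)
  a <- params$x_beta / ctx$kBT
  scale <- params$k_off * ctx$kBT / (loading_rate * params$x_beta)
  (params$k_off / loading_rate) * exp(a * force) *
    exp(-scale * (exp(a * force) - 1))
}

#' Rupture-force cumulative distribution at constant loading rate
#'
#' `P(F_rupture <= F) = 1 - exp(-(k_off kBT/(r x_beta)) (exp(x_beta F/kBT) - 1))`.
#' Companion of [rupture_force_density()], convenient for
#' Kolmogorov-Smirnov comparisons against simulated ensembles.
#'
#' @inheritParams rupture_force_density
#' @return Cumulative probabilities.
#' @export
rupture_force_cdf <- function(force, loading_rate, params,
                              ctx = thermal_context()) {
  .check_force(force)
  .check_rate(loading_rate)
  a <- params$x_beta / ctx$kBT
  scale <- params$k_off * ctx$kBT / (loading_rate * params$x_beta)
  -expm1(-scale * expm1(a * force))
}

#' Sample rupture forces by inverse-CDF transform
#'
#' Maps uniform deviates `u` in (0, 1) to rupture forces distributed per
#' [rupture_force_density()]:
#' `F = (kBT/x_beta) * ln(1 - (x_beta r/(k_off kBT)) * ln u)`.
#'
#' @param u Uniform deviates strictly inside (0, 1); vectorised.
#' @inheritParams most_probable_force
#' @return Rupture force(s) in pN.
#' @export
sample_rupture_force <- function(loading_rate, params,
                                 ctx = thermal_context(),
                                 u = stats::runif(1)) {
  .check_rate(loading_rate)
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop_domain("`u` must lie strictly inside (0, 1)")
  (ctx$kBT / params$x_beta) *
    log1p(-(params$x_beta * loading_rate / (params$k_off * ctx$kBT)) * log(u))
}
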