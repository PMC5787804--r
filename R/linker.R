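# Freely-jointed-chain (FJC) mechanics of the PEG tether and the series
# force balance of tether + cantilever during retraction. PEG linkers are
# classically described by the FJC; the interface keeps the tether model
# behind three functions so an alternative (e.g. WLC) could be slotted in.

#' Tether (PEG linker) mechanical parameters
#'
#' Freely-jointed-chain description of the flexible PEG tether that
#' couples the ligand to the cantilever tip. The defaults (contour length
#' 10 nm, Kuhn length 0.7 nm) emulate PEG18/PEG27 chemistry with short
#' peptide spacers and place specific ruptures at 5-15 nm tip-surface
#' separation, clearly beyond the contact-adhesion zone. They are modelling
#' choices, not measured constants.
#'
#' @param contour_length Contour length Lc in nm (> 0).
#' @param kuhn_length Kuhn segment length lk in nm (> 0, < Lc).
#' @return An object of class `linker_parameters`.
#' @export
linker_parameters <- function(contour_length = 10, kuhn_length = 0.7) {
  check_positive_scalar(contour_length, "contour_length")
  check_positive_scalar(kuhn_length, "kuhn_length")
  if (kuhn_length >= contour_length)
    stop_domain("`kuhn_length` must be smaller than `contour_length`")
  structure(
    list(contour_length = contour_length, kuhn_length = kuhn_length),
    class = "linker_parameters"
  )
}

#' @export
print.linker_parameters <- function(x, ...) {
  cat(sprintf("<linker_parameters> Lc = %g nm, lk = %g nm (FJC)\n",
              x$contour_length, x$kuhn_length))
  invisible(x)
}

# Langevin function L(b) = coth(b) - 1/b, numerically safe near 0.
.langevin <- function(b) {
  out <- numeric(length(b))
  small <- b < 1e-4
  out[small] <- b[small] / 3 - b[small]^3 / 45
  bb <- b[!small]
  out[!small] <- 1 / tanh(bb) - 1 / bb
  out
}

#' Freely-jointed-chain force-extension relation
#'
#' Extension of an FJC tether at force F:
#' `x(F) = Lc * (coth(F lk / kBT) - kBT / (F lk))`, with `x(0) = 0` and
#' saturation `x -> Lc` as F grows.
#'
#' @param force Stretching force in pN (vectorised, >= 0).
#' @param linker A [linker_parameters()] object.
#' @param ctx A [thermal_context()].
#' @return Extension(s) in nm, in `[0, Lc)`.
#' @examples
#' fjc_extension(10, linker_parameters())   # ~4.81 nm
#' @export
fjc_extension <- function(force, linker, ctx = thermal_context()) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0))
    stop_domain("`force` must be finite and non-negative (pN)")
  linker$contour_length * .langevin(force * linker$kuhn_length / ctx$kBT)
}

#' Tangent stiffness of the FJC tether
#'
#' `dF/dx` at the given force, the reciprocal slope of the
#' force-extension relation. This is the quantity read off a force curve
#' at rupture as the PEG spring constant `k_PEG`. Strictly positive and
#' increasing in force; the zero-force limit is `3 kBT / (Lc lk)`.
#'
#' @inheritParams fjc_extension
#' @return Stiffness(es) in pN/nm.
#' @export
linker_stiffness <- function(force, linker, ctx = thermal_context()) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0))
    stop_domain("`force` must be finite and non-negative (pN)")
  b <- force * linker$kuhn_length / ctx$kBT
  # dx/dF = (Lc lk / kBT) * (1/b^2 - csch^2 b); series for small b,
  # csch^2 underflows safely to 0 for large b.
  dLdb <- numeric(length(b))
  small <- b < 1e-4
  dLdb[small] <- 1 / 3 - b[small]^2 / 15
  bb <- b[!small]
  csch2 <- ifelse(bb > 350, 0, 1 / sinh(bb)^2)
  dLdb[!small] <- 1 / bb^2 - csch2
  kBT <- ctx$kBT
  kBT / (linker$contour_length * linker$kuhn_length * dLdb)
}

#' Force at a given tip-surface separation (tether + cantilever in series)
#'
#' During retraction the piezo displacement d is shared between tether
#' extension and cantilever deflection: `d = x(F) + F / k_c`. Both terms
#' increase in F, so the root is unique; it is found by safeguarded
#' bisection on `F` in `[0, 500]` pN to a residual tolerance of 1e-9 nm.
#'
#' @param distance Tip-surface separation(s) d in nm (>= 0, vectorised).
#' @param linker A [linker_parameters()] object.
#' @param k_c Cantilever spring constant in pN/nm (> 0).
#' @param ctx A [thermal_context()].
#' @param f_max Upper bracket for the force search, pN.
#' @param tol Residual tolerance on the separation, nm.
#' @return Force(s) in pN (magnitude of the attractive load).
#' @export
solve_force_at_separation <- function(distance, linker, k_c,
                                      ctx = thermal_context(),
                                      f_max = 500, tol = 1e-9) {
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0))
    stop_domain("`distance` must be finite and non-negative (nm)")
  check_positive_scalar(k_c, "k_c")
  sep_at <- function(f) fjc_extension(f, linker, ctx) + f / k_c
  if (any(distance > sep_at(f_max) - tol))
    stop_numeric(
      "separation %.3g nm not reachable below %g pN (Lc = %g nm, k_c = %g pN/nm)",
      max(distance), f_max, linker$contour_length, k_c)
  lo <- numeric(length(distance))
  hi <- rep(f_max, length(distance))
  for (i in seq_len(110)) {
    mid <- (lo + hi) / 2
    sep_mid <- sep_at(mid)
    too_low <- sep_mid < distance
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
    if (max(abs(sep_mid - distance)) < tol) break
  }
  f <- (lo + hi) / 2
  if (max(abs(sep_at(f) - distance)) > 1e-6)
    stop_numeric("bisection failed to reach the separation tolerance")
  f[distance == 0] <- 0
  f
}
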