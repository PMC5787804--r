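# Per-curve processing: baseline estimation, Hooke's-law conversion, and
# detection of specific unbinding events. An event is the signature of a
# tether rupture during retraction: a nonlinear attractive force ramp
# (stretching of the PEG linker) terminated by an abrupt single-step jump
# back to the baseline. The jump height is the rupture force; the slope
# just before the jump is the tether spring constant k_PEG.

#' Event-detection settings
#'
#' Tunables of the unbinding-event detector. The source instrument
#' publishes no thresholds, so these are calibrated on synthetic
#' ensembles: `smooth_window` moving-average points, detection threshold
#' in multiples of the baseline noise, the minimum number of points the
#' attractive stretch must span, the window (points) within which the
#' jump must return to baseline, and the tip-surface separation window
#' (nm) a specific event must fall in — its lower edge rejects
#' contact-zone adhesion, its upper edge is 1.5 x the tether contour
#' length.
#'
#' @param smooth_window Moving-average window, points (odd recommended).
#' @param threshold_mult Detection threshold, multiples of baseline sigma.
#' @param min_stretch_points Minimum points in the attractive stretch.
#' @param return_window Points allowed between force minimum and return
#'   to baseline.
#' @param separation_window Two-element numeric, nm: acceptance window on
#'   the rupture separation.
#' @return An object of class `detection_settings`.
#' @export
detection_settings <- function(smooth_window = 5,
                               threshold_mult = 3,
                               min_stretch_points = 8,
                               return_window = 3,
                               separation_window = c(5, 15)) {
  check_positive_scalar(smooth_window, "smooth_window")
  check_positive_scalar(threshold_mult, "threshold_mult")
  check_positive_scalar(min_stretch_points, "min_stretch_points")
  check_positive_scalar(return_window, "return_window")
  if (!is.numeric(separation_window) || length(separation_window) != 2L ||
      any(separation_window <= 0) ||
      separation_window[1] >= separation_window[2])
    stop_domain("`separation_window` must be an ordered positive pair (nm)")
  structure(
    list(smooth_window = as.integer(smooth_window),
         threshold_mult = threshold_mult,
         min_stretch_points = as.integer(min_stretch_points),
         return_window = as.integer(return_window),
         separation_window = separation_window),
    class = "detection_settings"
  )
}

#' Convert cantilever deflection to force (Hooke's law)
#'
#' `F = k_c * deflection`.
#'
#' @param deflection Deflection(s) in nm.
#' @param k_c Cantilever spring constant in pN/nm (> 0).
#' @return Force(s) in pN.
#' @export
deflection_to_force <- function(deflection, k_c) {
  check_positive_scalar(k_c, "k_c")
  deflection * k_c
}

#' Estimate the retraction baseline
#'
#' Robust linear fit (offset + tilt) over the far-from-surface quarter of
#' the retract trace, i.e. the 25% of samples at the largest tip-surface
#' separations, where no tether or adhesion force can act. After an
#' initial least-squares fit, samples with residuals beyond 3 robust
#' standard deviations are dropped and the line refit. The noise scale is
#' `1.4826 x` the median absolute deviation of the residuals.
#'
#' @param curve A `force_curve`, or a numeric force vector (then `piezo`
#'   must be given).
#' @param piezo Piezo positions (nm) when `curve` is a bare vector.
#' @return List with `offset` (pN), `tilt` (pN/nm) and `sigma` (pN).
#' @export
estimate_baseline <- function(curve, piezo = NULL) {
  if (inherits(curve, "force_curve")) {
    force <- curve$retrace_force
    piezo <- curve$piezo
  } else {
    force <- curve
  }
  if (length(force) < 50)
    stop_input("retract trace must have at least 50 points (got %d)",
               length(force))
  if (length(piezo) != length(force))
    stop_input("`piezo` and force trace lengths differ")
  ord <- order(piezo)
  n_far <- max(25L, ceiling(length(force) * 0.25))
  far <- utils::tail(ord, n_far)
  x <- piezo[far]; y <- force[far]
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  s <- stats::mad(res)
  if (s > 0) {
    keep <- abs(res) <= 3 * s
    if (sum(keep) >= 10) {
      fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
      s <- stats::mad(fit$residuals)
    }
  }
  list(offset = unname(fit$coefficients[1]),
       tilt = unname(fit$coefficients[2]),
       sigma = s)
}

#' Effective spring constant of tether and cantilever in series
#'
#' `k_eff = (k_PEG^-1 + k_c^-1)^-1`, never exceeding the smaller of the
#' two stiffnesses.
#'
#' @param k_peg Tether stiffness at rupture, pN/nm (> 0).
#' @param k_c Cantilever stiffness, pN/nm (> 0).
#' @return Effective stiffness, pN/nm (vectorised over `k_peg`).
#' @export
effective_spring_constant <- function(k_peg, k_c) {
  if (!is.numeric(k_peg) || any(!is.finite(k_peg)) || any(k_peg <= 0))
    stop_domain("`k_peg` must be finite and positive")
  check_positive_scalar(k_c, "k_c")
  1 / (1 / k_peg + 1 / k_c)
}

#' Loading rate of a force curve
#'
#' `r = k_eff x velocity`: the rate at which force builds on the bond.
#'
#' @param k_eff Effective spring constant, pN/nm (> 0).
#' @param velocity Pulling velocity, nm/s (> 0).
#' @return Loading rate in pN/s.
#' @export
loading_rate <- function(k_eff, velocity) {
  if (!is.numeric(k_eff) || any(!is.finite(k_eff)) || any(k_eff <= 0))
    stop_domain("`k_eff` must be finite and positive")
  if (!is.numeric(velocity) || any(!is.finite(velocity)) || any(velocity <= 0))
    stop_domain("`velocity` must be finite and positive")
  k_eff * velocity
}

.empty_events <- function() {
  data.frame(curve_id = character(), velocity_nm_s = numeric(),
             rupture_force_pN = numeric(), rupture_separation_nm = numeric(),
             k_peg_pN_nm = numeric(), k_eff_pN_nm = numeric(),
             loading_rate_pN_s = numeric(), baseline_sigma_pN = numeric(),
             accepted = logical())
}

#' Detect unbinding events in one force-distance curve
#'
#' After baseline/tilt subtraction and moving-average smoothing, a
#' candidate event is a contiguous attractive excursion below
#' `-threshold_mult x sigma` that lasts at least `min_stretch_points`,
#' builds force monotonically towards its minimum (negative fitted slope
#' versus separation), and returns to baseline within `return_window`
#' points of the minimum by one abrupt jump. The rupture force is the
#' height of the jump back to the local baseline. The loading stiffness
#' `dF/dd` is the least-squares slope over the final
#' `min_stretch_points` of the stretch against the piezo axis; it equals
#' the tether + cantilever series stiffness, so the tether spring
#' constant `k_PEG` (the slope at rupture versus tip-sample separation)
#' follows from the series relation, and `k_eff` and the loading rate
#' from [effective_spring_constant()] and [loading_rate()]. A candidate is
#' `accepted` (specific) if its rupture separation falls inside the
#' configured separation window, which rejects contact-zone adhesion.
#'
#' @param curve A `force_curve` with the retract trace in pN.
#' @param settings A [detection_settings()] object.
#' @return A data.frame of candidate events (possibly zero rows) with
#'   columns `curve_id`, `velocity_nm_s`, `rupture_force_pN`,
#'   `rupture_separation_nm`, `k_peg_pN_nm`, `k_eff_pN_nm`,
#'   `loading_rate_pN_s`, `baseline_sigma_pN`, `accepted`.
#' @export
detect_events <- function(curve, settings = detection_settings()) {
  if (!inherits(curve, "force_curve"))
    stop_input("`curve` must be a force_curve")
  bl <- estimate_baseline(curve)
  d <- curve$piezo
  f <- curve$retrace_force - (bl$offset + bl$tilt * d)
  w <- settings$smooth_window
  fs <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
  fs[is.na(fs)] <- f[is.na(fs)]
  thr <- -settings$threshold_mult * bl$sigma

  below <- fs < thr & d > 0          # attractive excursions beyond contact
  if (!any(below)) return(.empty_events())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  out <- .empty_events()
  for (ri in runs) {
    i0 <- starts[ri]; i1 <- ends[ri]
    if (i1 - i0 + 1L < settings$min_stretch_points) next
    i_min <- i0 - 1L + which.min(fs[i0:i1])
    # abrupt return: excursion must end within return_window of the
    # minimum; the smoothed trace lags the jump by half a window
    if (i1 - i_min > settings$return_window + settings$smooth_window %/% 2)
      next
    # locate the jump on the unsmoothed trace
    j_hi <- min(length(f) - 1L, i1 + settings$return_window)
    j_lo <- max(i0, i_min - settings$smooth_window)
    jumps <- f[(j_lo + 1L):(j_hi + 1L)] - f[j_lo:j_hi]
    j <- j_lo - 1L + which.max(jumps)
    if (max(jumps) < settings$threshold_mult * bl$sigma && bl$sigma > 0) next
    # jump height back to the local post-rupture baseline: immune to
    # baseline-extrapolation error (both sides share it)
    after <- seq(j + 1L, min(j + 10L, length(f)))
    rupture_force <- mean(f[after]) - f[j]
    if (!is.finite(rupture_force) || rupture_force <= 0) next
    # loading stiffness dF/dd from the final stretch against the piezo
    # axis (noise-free abscissa); this slope is k_eff of the tether +
    # cantilever series, from which k_PEG follows
    stretch <- seq(max(1L, j - settings$min_stretch_points + 1L), j)
    slope <- tryCatch(stats::lm.fit(cbind(1, d[stretch]),
                                    f[stretch])$coefficients[2],
                      error = function(e) NA_real_)
    rupture_sep <- d[j] + f[j] / curve$k_c
    k_slope <- if (is.finite(slope) && slope < 0)
      min(abs(unname(slope)), 0.99 * curve$k_c) else NA_real_
    k_peg <- if (is.finite(k_slope))
      1 / (1 / k_slope - 1 / curve$k_c) else NA_real_
    k_eff <- if (is.finite(k_peg))
      effective_spring_constant(k_peg, curve$k_c) else NA_real_
    lr <- if (is.finite(k_eff)) loading_rate(k_eff, curve$velocity) else NA_real_
    accepted <- is.finite(k_peg) &&
      rupture_sep >= settings$separation_window[1] &&
      rupture_sep <= settings$separation_window[2]
    out <- rbind(out, data.frame(
      curve_id = curve$curve_id, velocity_nm_s = curve$velocity,
      rupture_force_pN = rupture_force, rupture_separation_nm = rupture_sep,
      k_peg_pN_nm = k_peg, k_eff_pN_nm = k_eff, loading_rate_pN_s = lr,
      baseline_sigma_pN = bl$sigma, accepted = accepted))
  }
  out
}

#' Detect events across a curve ensemble
#'
#' Applies [detect_events()] to every curve and binds the candidate
#' events into one table.
#'
#' @param curves A `force_curve_set` or list of `force_curve` objects.
#' @param settings A [detection_settings()].
#' @return The combined events data.frame (see [detect_events()]).
#' @export
analyze_curves <- function(curves, settings = detection_settings()) {
  if (inherits(curves, "force_curve_set")) curves <- curves$curves
  if (length(curves) == 0) stop_input("no curves to analyze")
  do.call(rbind, c(list(.empty_events()),
                   lapply(curves, detect_events, settings = settings)))
}
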