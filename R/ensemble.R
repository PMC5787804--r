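# Ensemble-level statistics per condition and pulling velocity: binding
# probability, the empirical probability density of unbinding forces
# (mean of unit-area Gaussian kernels, one per event, width set by the
# measurement uncertainty), the most probable unbinding force F* from a
# Gaussian fit to that density, loading-rate moments, and two-sample
# comparisons with the field's significance-star convention.

#' Binding probability of a curve ensemble
#'
#' Fraction of force curves showing at least one accepted (specific)
#' unbinding event, with its binomial standard error
#' `sqrt(p (1 - p) / n)`.
#'
#' @param curves A `force_curve_set` or list of `force_curve` objects.
#' @param events Events table from [analyze_curves()].
#' @return List with `probability`, `se`, `n_curves`, `n_bound`.
#' @export
binding_probability <- function(curves, events) {
  if (inherits(curves, "force_curve_set")) curves <- curves$curves
  n <- length(curves)
  if (n == 0) stop_input("empty curve set")
  ids <- vapply(curves, function(cv) cv$curve_id, character(1))
  if (nrow(events) > 0 && !all(events$curve_id %in% ids))
    stop_input("events reference curves outside the supplied set")
  bound_ids <- unique(events$curve_id[events$accepted])
  p <- length(bound_ids) / n
  list(probability = p, se = sqrt(p * (1 - p) / n),
       n_curves = n, n_bound = length(bound_ids))
}

#' Select the specific event per curve
#'
#' Keeps accepted events only and, where a curve yields several, the one
#' at the largest rupture separation inside the window — with a single
#' tether the farthest rupture is the specific one.
#'
#' @param events Events table from [analyze_curves()].
#' @return Filtered events table, at most one row per curve.
#' @export
specific_events <- function(events) {
  ev <- events[events$accepted & is.finite(events$rupture_force_pN), ,
               drop = FALSE]
  if (nrow(ev) <= 1) return(ev)
  ord <- order(ev$curve_id, -ev$rupture_separation_nm)
  ev <- ev[ord, , drop = FALSE]
  ev[!duplicated(ev$curve_id), , drop = FALSE]
}

#' Empirical probability density of unbinding forces
#'
#' Mean of unit-area Gaussian kernels centred on the observed rupture
#' forces, each with width equal to that event's force uncertainty
#' (a single bandwidth may be given instead). Evaluated on a uniform
#' force grid spanning `[0, max force + 4 sigma]` and renormalised to
#' unit trapezoidal area over the grid. This measurement-error-width
#' estimate resolves the most probable force better than a histogram.
#'
#' @param forces Rupture forces in pN (>= 1 value).
#' @param sigma Per-event kernel widths in pN (recycled; default 5).
#' @param grid_step Force grid spacing, pN.
#' @param grid Optional explicit force grid (overrides `grid_step`).
#' @return An object of class `force_pdf`: list with `force` (grid, pN),
#'   `density` (1/pN) and `n` (number of events).
#' @export
construct_pdf <- function(forces, sigma = 5, grid_step = 0.1, grid = NULL) {
  if (length(forces) < 1 || any(!is.finite(forces)))
    stop_input("`forces` must contain at least one finite value")
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    stop_input("kernel widths must be positive")
  sigma <- rep_len(sigma, length(forces))
  if (is.null(grid))
    grid <- seq(0, max(forces) + 4 * max(sigma), by = grid_step)
  dens <- rowMeans(vapply(
    seq_along(forces),
    function(i) stats::dnorm(grid, forces[i], sigma[i]),
    numeric(length(grid))))
  area <- .trapz(grid, dens)
  if (area <= 0) stop_numeric("degenerate pdf (zero area)")
  structure(list(force = grid, density = dens / area, n = length(forces)),
            class = "force_pdf")
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.force_pdf <- function(x, ...) {
  cat(sprintf("<force_pdf> %d events, grid [0, %.4g] pN, mode %.4g pN\n",
              x$n, max(x$force), x$force[which.max(x$density)]))
  invisible(x)
}

#' Most probable unbinding force from a pdf
#'
#' Fits a Gaussian to the main mode of an empirical force pdf (the
#' window within +/- 2 initial widths of the grid argmax, the initial
#' width taken from the mode's half-maximum span) by nonlinear least
#' squares. Returns the fitted centre as F*, the fitted width, and the
#' centre's standard error from the fit covariance. If the fit fails the
#' grid argmax is returned with `converged = FALSE`.
#'
#' @param pdf A `force_pdf` from [construct_pdf()].
#' @return List with `f_star` (pN), `width` (pN), `f_star_se` (pN) and
#'   `converged` (logical).
#' @export
fit_most_probable_force <- function(pdf) {
  if (!inherits(pdf, "force_pdf")) stop_input("`pdf` must be a force_pdf")
  x <- pdf$force; y <- pdf$density
  i0 <- which.max(y)
  half <- y[i0] / 2
  # contiguous half-maximum span around the argmax -> initial width
  lo <- i0; while (lo > 1L && y[lo - 1L] >= half) lo <- lo - 1L
  hi <- i0; while (hi < length(y) && y[hi + 1L] >= half) hi <- hi + 1L
  w0 <- max((x[hi] - x[lo]) / 2.355, 2 * (x[2] - x[1]))
  win <- x >= x[i0] - 2 * w0 & x <= x[i0] + 2 * w0
  df <- data.frame(x = x[win], y = y[win])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * w^2)), data = df,
                      start = list(a = y[i0], mu = x[i0], w = w0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(f_star = x[i0], width = w0, f_star_se = NA_real_,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["mu"]],
                 error = function(e) NA_real_)
  list(f_star = unname(cf[["mu"]]), width = abs(unname(cf[["w"]])),
       f_star_se = se, converged = TRUE)
}

#' Summarise one pulling-velocity group
#'
#' Assembles the per-velocity ensemble statistics feeding the dynamic
#' force spectrum: number of curves and accepted events, binding
#' probability (fraction of curves with a specific event), the empirical
#' force pdf and its Gaussian-fitted most probable force, and the mean
#' and standard deviation of the per-event loading rates. The F*
#' standard error reported for the fit combines the pdf-fit covariance
#' with the mode's sampling error (fitted width / sqrt(n events)),
#' whichever is larger.
#'
#' @param curves Curves of one velocity (`force_curve_set` or list; other
#'   velocities are ignored when `velocity` is given).
#' @param events Events table from [analyze_curves()].
#' @param velocity Pulling velocity to summarise, nm/s.
#' @param kernel_sigma Optional fixed kernel width override, pN; by
#'   default each event uses its curve's baseline noise sigma.
#' @return An object of class `velocity_summary`.
#' @export
summarize_group <- function(curves, events, velocity,
                            kernel_sigma = NULL) {
  if (inherits(curves, "force_curve_set")) curves <- curves$curves
  vsel <- vapply(curves, function(cv) cv$velocity, numeric(1)) == velocity
  curves <- curves[vsel]
  if (length(curves) == 0) stop_input("no curves at velocity %g", velocity)
  events <- events[events$velocity_nm_s == velocity, , drop = FALSE]
  bp <- binding_probability(curves, events)
  ev <- specific_events(events)
  out <- list(velocity = velocity, n_curves = length(curves),
              n_accepted_events = nrow(ev),
              binding_probability = bp$probability,
              binding_probability_se = bp$se,
              pdf = NULL, f_star = NA_real_, f_star_se = NA_real_,
              f_star_width = NA_real_,
              mean_loading_rate = NA_real_, sd_loading_rate = NA_real_)
  if (nrow(ev) > 0) {
    sig <- if (is.null(kernel_sigma)) {
      s <- ev$baseline_sigma_pN
      ifelse(is.finite(s) & s > 0, s, 5)
    } else kernel_sigma
    pdf <- construct_pdf(ev$rupture_force_pN, sigma = sig)
    mp <- fit_most_probable_force(pdf)
    out$pdf <- pdf
    out$f_star <- mp$f_star
    out$f_star_width <- mp$width
    sampling_se <- mp$width / sqrt(nrow(ev))
    out$f_star_se <- max(mp$f_star_se, sampling_se, na.rm = TRUE)
    out$mean_loading_rate <- mean(ev$loading_rate_pN_s)
    out$sd_loading_rate <- stats::sd(ev$loading_rate_pN_s)
    if (nrow(ev) == 1) out$sd_loading_rate <- 0
  }
  structure(out, class = "velocity_summary")
}

#' @export
print.velocity_summary <- function(x, ...) {
  cat(sprintf(
    "<velocity_summary> v = %g nm/s: %d curves, %d events, BP %.3f +/- %.3f\n",
    x$velocity, x$n_curves, x$n_accepted_events,
    x$binding_probability, x$binding_probability_se))
  if (is.finite(x$f_star))
    cat(sprintf("  F* = %.2f +/- %.2f pN; loading rate %.3g +/- %.3g pN/s\n",
                x$f_star, x$f_star_se,
                x$mean_loading_rate, x$sd_loading_rate))
  invisible(x)
}

#' Summarise every pulling velocity of an ensemble
#'
#' @param curves A `force_curve_set` or list of `force_curve` objects.
#' @param events Events table from [analyze_curves()].
#' @param kernel_sigma Optional fixed kernel width, pN.
#' @return List of [summarize_group()] results, ordered by velocity.
#' @export
summarize_velocities <- function(curves, events, kernel_sigma = NULL) {
  if (inherits(curves, "force_curve_set")) curves <- curves$curves
  vels <- sort(unique(vapply(curves, function(cv) cv$velocity, numeric(1))))
  lapply(vels, function(v)
    summarize_group(curves, events, v, kernel_sigma = kernel_sigma))
}

#' Two-sample comparison (Student's t test)
#'
#' Two-sided two-sample t test (equal variances by default, Welch behind
#' a flag) with the significance-star convention
#' `p < 0.05 -> *`, `p < 0.01 -> **`, `p < 0.001 -> ***`, else `n.s.`.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return List with `statistic`, `p_value`, `significance_label`.
#' @export
compare_samples <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop_input("both samples need at least 2 values")
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, significance_label = "n.s."))
    stop_input("degenerate samples: zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  p <- tt$p.value
  label <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "n.s."
  list(statistic = unname(tt$statistic), p_value = p,
       significance_label = label)
}
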