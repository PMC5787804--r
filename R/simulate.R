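# Synthetic force-distance curve generator. Emulates the measurement:
# MSCT-class cantilevers (nominal 0.03 N/m = 30 pN/nm), PEG-tethered
# peptide-peptide bonds rupturing at tens of pN, pulling velocities
# 50-8000 nm/s (loading rates ~1e2-1e5 pN/s), per-curve specific-binding
# probabilities in the 5-25% range, >= 1000 curves per condition.
#
# Bound retractions are generated by stepping the piezo outward and
# applying the per-step rupture hazard 1 - exp(-k(F) dt) with the Bell
# rate evaluated on the series-elasticity force profile, so the nonlinear
# FJC loading is honoured exactly rather than assuming a constant rate.

#' Simulation configuration
#'
#' Full generative description of a synthetic force-spectroscopy
#' experiment. Defaults reproduce the study conditions the package is
#' designed around: six log-spaced pulling velocities in 50-8000 nm/s,
#' 1000 curves per velocity, a 13% per-curve specific-binding probability,
#' a 30 pN/nm cantilever and room temperature. Instrument noise (5 pN),
#' sampling step (0.2 nm) and the nonspecific-adhesion probability (5%)
#' are realistic fixture choices where no measured value exists.
#'
#' @param velocities Pulling velocities in nm/s.
#' @param curves_per_velocity Number of curves per velocity.
#' @param p_bind Per-curve probability that a specific tether is formed.
#' @param p_nonspecific Per-curve probability of a short-range (< 5 nm)
#'   contact-adhesion artifact.
#' @param bell [bell_parameters()] of the probed bond.
#' @param linker [linker_parameters()] of the PEG tether.
#' @param k_c Cantilever spring constant, pN/nm.
#' @param noise_sigma Gaussian force noise per sample, pN.
#' @param tilt Residual baseline slope, pN/nm.
#' @param sample_step Piezo sampling step, nm.
#' @param max_distance Retraction range beyond contact, nm (> Lc).
#' @param force_limit Approach contact force limit, pN.
#' @param temperature Temperature, K.
#' @param seed Integer seed making the ensemble fully reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(velocities = round(exp(seq(log(50), log(8000),
                                                         length.out = 6))),
                              curves_per_velocity = 1000,
                              p_bind = 0.13,
                              p_nonspecific = 0.05,
                              bell = bell_parameters(k_off = 0.1, x_beta = 0.5),
                              linker = linker_parameters(),
                              k_c = 30,
                              noise_sigma = 5,
                              tilt = 0,
                              sample_step = 0.2,
                              max_distance = 30,
                              force_limit = 100,
                              temperature = 298,
                              seed = 1L) {
  if (!is.numeric(velocities) || length(velocities) < 1L ||
      any(!is.finite(velocities)) || any(velocities <= 0))
    stop_input("`velocities` must be positive pulling velocities (nm/s)")
  check_positive_scalar(curves_per_velocity, "curves_per_velocity")
  if (!is.numeric(p_bind) || p_bind < 0 || p_bind > 1)
    stop_input("`p_bind` must lie in [0, 1]")
  if (!is.numeric(p_nonspecific) || p_nonspecific < 0 || p_nonspecific > 1)
    stop_input("`p_nonspecific` must lie in [0, 1]")
  if (!inherits(bell, "bell_parameters"))
    stop_input("`bell` must be a bell_parameters object")
  if (!inherits(linker, "linker_parameters"))
    stop_input("`linker` must be a linker_parameters object")
  check_positive_scalar(k_c, "k_c")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_input("`noise_sigma` must be >= 0")
  check_positive_scalar(sample_step, "sample_step")
  check_positive_scalar(max_distance, "max_distance")
  if (max_distance <= linker$contour_length)
    stop_input("`max_distance` (%g nm) must exceed the linker contour length (%g nm)",
               max_distance, linker$contour_length)
  check_positive_scalar(force_limit, "force_limit")
  structure(
    list(velocities = as.numeric(velocities),
         curves_per_velocity = as.integer(curves_per_velocity),
         p_bind = p_bind, p_nonspecific = p_nonspecific,
         bell = bell, linker = linker, k_c = k_c,
         noise_sigma = noise_sigma, tilt = tilt,
         sample_step = sample_step, max_distance = max_distance,
         force_limit = force_limit, temperature = temperature,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  velocities : %s nm/s\n", paste(signif(x$velocities, 4),
                                                collapse = ", ")))
  cat(sprintf("  curves/vel : %d   p_bind %.3g   p_nonspecific %.3g\n",
              x$curves_per_velocity, x$p_bind, x$p_nonspecific))
  cat(sprintf("  bond       : k_off %g 1/s, x_beta %g nm; tether Lc %g nm, lk %g nm\n",
              x$bell$k_off, x$bell$x_beta,
              x$linker$contour_length, x$linker$kuhn_length))
  cat(sprintf("  instrument : k_c %g pN/nm, noise %g pN, step %g nm, seed %d\n",
              x$k_c, x$noise_sigma, x$sample_step, x$seed))
  invisible(x)
}

# Tether force profile over the positive-separation part of the piezo
# grid. Expensive part of the simulation; shared across curves.
.tether_profile <- function(cfg, ctx) {
  d <- seq(cfg$sample_step, cfg$max_distance, by = cfg$sample_step)
  reach <- fjc_extension(500, cfg$linker, ctx) + 500 / cfg$k_c
  solvable <- d < reach - 1e-6
  f <- numeric(length(d))
  f[solvable] <- solve_force_at_separation(d[solvable], cfg$linker, cfg$k_c, ctx)
  f[!solvable] <- NA_real_
  list(distance = d, force = f)
}

#' Simulate one force-distance curve
#'
#' Generates one approach/retract cycle. The approach shows a flat
#' baseline and a linear repulsive contact ramp up to the force limit.
#' With probability `p_bind` the retract carries a specific tether whose
#' force follows the tether+cantilever series elasticity; rupture occurs
#' stochastically with per-step hazard `1 - exp(-k(F) dt)`,
#' `dt = sample_step / velocity`. Optional nonspecific adhesion adds a
#' short-range (< 5 nm) triangular attractive spike of 20-80 pN. Gaussian
#' noise and a linear tilt are added to both traces. Attractive forces
#' are negative in the stored traces; ground truth records positive
#' rupture magnitudes.
#'
#' Uses the current RNG state; [simulate_ensemble()] manages per-curve
#' seeds for reproducibility.
#'
#' @param cfg A [simulation_config()].
#' @param velocity Pulling velocity in nm/s (one of `cfg$velocities`).
#' @param curve_id Identifier string stored with the curve.
#' @param profile Optional precomputed tether force profile (internal).
#' @return An object of class `force_curve`: fields `curve_id`, `piezo`
#'   (nm, strictly increasing; negative values are in contact),
#'   `trace_force`/`retrace_force` (pN), `velocity`, `k_c`, `sample_step`,
#'   `temperature` and a `ground_truth` list (`bound`, `nonspecific`,
#'   `truncated`, `rupture_force` pN, `rupture_separation` nm — tether
#'   extension at rupture, `loading_rate` pN/s).
#' @export
simulate_curve <- function(cfg, velocity, curve_id = "curve",
                           profile = NULL) {
  if (!inherits(cfg, "simulation_config"))
    stop_input("`cfg` must be a simulation_config")
  if (!velocity %in% cfg$velocities)
    stop_input("`velocity` %g is not one of cfg$velocities", velocity)
  ctx <- thermal_context(cfg$temperature)
  if (is.null(profile)) profile <- .tether_profile(cfg, ctx)

  contact_depth <- cfg$force_limit / cfg$k_c
  n_contact <- ceiling(contact_depth / cfg$sample_step)
  d_contact <- -rev(seq_len(n_contact)) * cfg$sample_step
  piezo <- c(d_contact, 0, profile$distance)
  contact_force <- pmin(pmax(-piezo, 0) * cfg$k_c, cfg$force_limit)

  trace <- contact_force
  retrace <- contact_force

  gt <- list(bound = FALSE, nonspecific = FALSE, truncated = FALSE,
             rupture_force = NA_real_, rupture_separation = NA_real_,
             loading_rate = NA_real_)

  bound <- stats::runif(1) < cfg$p_bind
  nonspec <- stats::runif(1) < cfg$p_nonspecific

  if (bound) {
    f <- profile$force                     # NA beyond the solvable range
    dt <- cfg$sample_step / velocity
    n <- length(f)
    usable <- which(is.finite(f))
    haz <- 1 - exp(-bell_rate(f[usable], cfg$bell, ctx) * dt)
    u <- stats::runif(length(usable))
    hit <- which(u < haz)
    if (length(hit) > 0) {
      i_rupt <- usable[hit[1]]
    } else {
      i_rupt <- usable[length(usable)]     # survived the pull: forced rupture
      gt$truncated <- TRUE
    }
    idx <- seq_len(n) + n_contact + 1L     # offset into the full piezo grid
    tether <- numeric(n)
    keep <- seq_len(i_rupt)
    tether[keep] <- -f[keep]
    retrace[idx] <- retrace[idx] + tether
    F_r <- f[i_rupt]
    gt$bound <- TRUE
    gt$rupture_force <- F_r
    gt$rupture_separation <- profile$distance[i_rupt] - F_r / cfg$k_c
    k_peg <- linker_stiffness(F_r, cfg$linker, ctx)
    gt$loading_rate <- effective_spring_constant(k_peg, cfg$k_c) * velocity
  }

  if (nonspec) {
    peak <- stats::runif(1, 20, 80)
    apex <- stats::runif(1, 1, 4)
    half <- min(apex, 5 - apex)
    spike <- -peak * pmax(0, 1 - abs(piezo - apex) / half)
    retrace <- retrace + spike
    gt$nonspecific <- TRUE
  }

  if (cfg$noise_sigma > 0) {
    trace <- trace + stats::rnorm(length(piezo), 0, cfg$noise_sigma)
    retrace <- retrace + stats::rnorm(length(piezo), 0, cfg$noise_sigma)
  }
  if (cfg$tilt != 0) {
    trace <- trace + cfg$tilt * piezo
    retrace <- retrace + cfg$tilt * piezo
  }

  structure(
    list(curve_id = curve_id, piezo = piezo, trace_force = trace,
         retrace_force = retrace, velocity = velocity, k_c = cfg$k_c,
         sample_step = cfg$sample_step, temperature = cfg$temperature,
         ground_truth = gt),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<force_curve> %s: %d samples, v = %g nm/s, k_c = %g pN/nm\n",
              x$curve_id, length(x$piezo), x$velocity, x$k_c))
  if (!is.null(gt))
    cat(sprintf("  ground truth: bound %s%s%s\n",
                gt$bound,
                if (isTRUE(gt$bound))
                  sprintf(" (%.1f pN at %.1f nm)", gt$rupture_force,
                          gt$rupture_separation) else "",
                if (isTRUE(gt$nonspecific)) ", nonspecific spike" else ""))
  invisible(x)
}

#' Simulate a force-curve ensemble
#'
#' Generates `curves_per_velocity` curves at every configured velocity.
#' Deterministic for a fixed `cfg$seed`: each curve draws from its own
#' seeded sub-stream, so curves are mutually independent and the ensemble
#' is reproducible curve-by-curve. The manifest records the configuration,
#' its provenance hash, per-velocity counts and the ground-truth event
#' table.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `force_curve_set`: list with `curves` (list
#'   of [simulate_curve()] results) and `manifest` (config echo, seed,
#'   config hash, per-velocity counts, ground-truth table).
#' @export
simulate_ensemble <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop_input("`cfg` must be a simulation_config")
  ctx <- thermal_context(cfg$temperature)
  profile <- .tether_profile(cfg, ctx)
  n_total <- length(cfg$velocities) * cfg$curves_per_velocity
  set.seed(cfg$seed)
  curve_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  curves <- vector("list", n_total)
  k <- 0L
  for (v in cfg$velocities) {
    for (j in seq_len(cfg$curves_per_velocity)) {
      k <- k + 1L
      set.seed(curve_seeds[k])
      curves[[k]] <- simulate_curve(
        cfg, v, curve_id = sprintf("v%06d_c%05d", round(v), j),
        profile = profile)
    }
  }
  gt <- do.call(rbind, lapply(curves, function(cv) {
    g <- cv$ground_truth
    data.frame(curve_id = cv$curve_id, velocity_nm_s = cv$velocity,
               bound = g$bound, nonspecific = g$nonspecific,
               truncated = g$truncated,
               rupture_force_pN = g$rupture_force,
               rupture_separation_nm = g$rupture_separation,
               loading_rate_pN_s = g$loading_rate)
  }))
  manifest <- list(
    config = as_config_list(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_curves = stats::setNames(
      rep(cfg$curves_per_velocity, length(cfg$velocities)),
      as.character(cfg$velocities)),
    ground_truth = gt
  )
  structure(list(curves = curves, manifest = manifest),
            class = "force_curve_set")
}

#' @export
print.force_curve_set <- function(x, ...) {
  cat(sprintf("<force_curve_set> %d curves, %d velocities, seed %d, config %s\n",
              length(x$curves), length(x$manifest$n_curves),
              x$manifest$seed, x$manifest$config_hash))
  invisible(x)
}
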