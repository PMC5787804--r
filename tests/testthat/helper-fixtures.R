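# Shared fixtures: canonical parameter set used throughout the suite and
# a hand-built noiseless bound curve whose rupture force is known exactly.

ctx298 <- thermal_context(298)
bell01 <- bell_parameters(k_off = 0.1, x_beta = 0.5)
fjc_default <- linker_parameters()

# Eq.-1 most probable force, written out independently of the package.
fstar_closed_form <- function(r, k_off = 0.1, x_beta = 0.5, kBT = 4.114334) {
  (kBT / x_beta) * log(x_beta * r / (kBT * k_off))
}

# Noiseless synthetic bound curve rupturing at (approximately) the
# requested force, assembled point by point from the series force
# balance rather than through the stochastic simulator.
make_noiseless_bound_curve <- function(rupture_force = 50, k_c = 30,
                                       step = 0.2, max_d = 30,
                                       velocity = 2000, offset = 0,
                                       linker = linker_parameters()) {
  d_pos <- seq(step, max_d, by = step)
  reach <- fjc_extension(500, linker, ctx298) + 500 / k_c
  f <- ifelse(d_pos < reach - 1e-6,
              suppressWarnings(solve_force_at_separation(
                pmin(d_pos, reach - 1e-3), linker, k_c, ctx298)), NA)
  j <- which(f >= rupture_force)[1]
  retrace <- numeric(length(d_pos))
  retrace[seq_len(j)] <- -f[seq_len(j)]
  n_contact <- 17L
  d_neg <- -rev(seq_len(n_contact)) * step
  piezo <- c(d_neg, 0, d_pos)
  contact <- pmax(-piezo, 0) * k_c
  curve <- structure(
    list(curve_id = "manual", piezo = piezo,
         trace_force = contact + offset,
         retrace_force = c(contact[seq_len(n_contact + 1L)],
                           retrace) + offset,
         velocity = velocity, k_c = k_c, sample_step = step,
         temperature = 298, ground_truth = NULL),
    class = "force_curve")
  attr(curve, "true_rupture_force") <- f[j]
  attr(curve, "true_rupture_separation") <- d_pos[j] - f[j] / k_c
  curve
}
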