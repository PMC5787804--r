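# Plain-text file formats tying the pipeline together.
#
# Curve files: one TSV per approach/retract cycle with "# key=value"
# header lines (curve_id, velocity_nm_s, k_c_pN_nm, sample_step_nm,
# temperature_K, plus gt_* ground-truth keys when synthetic), then a
# three-column table piezo_nm / trace_force_pN / retrace_force_pN.
# Attractive forces are stored NEGATIVE in curve files; events tables
# store POSITIVE rupture magnitudes — stated here once to prevent sign
# drift. Events/summary tables are CSV; fit reports are JSON; configs
# are YAML. Numeric round trips are lossless to better than 1e-9
# relative. Every artifact carries the config hash and seed.

.fmt_num <- function(x) sprintf("%.15g", x)

# 32-bit FNV-1a over a string; returned as 8 hex digits. Used only for
# config provenance stamps.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor and multiply in 16-bit halves: doubles cannot hold 32-bit
    # bitwise ops or the full 32x25-bit product directly
    lo <- bitwXor(h %% 65536, b); hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Configuration as a plain list
#'
#' Flattens a [simulation_config()] into the named list written to YAML
#' configs and manifests.
#'
#' @param cfg A [simulation_config()].
#' @return A named list of plain vectors.
#' @export
as_config_list <- function(cfg) {
  list(velocities = cfg$velocities,
       curves_per_velocity = cfg$curves_per_velocity,
       p_bind = cfg$p_bind, p_nonspecific = cfg$p_nonspecific,
       k_off = cfg$bell$k_off, x_beta = cfg$bell$x_beta,
       contour_length = cfg$linker$contour_length,
       kuhn_length = cfg$linker$kuhn_length,
       k_c = cfg$k_c, noise_sigma = cfg$noise_sigma, tilt = cfg$tilt,
       sample_step = cfg$sample_step, max_distance = cfg$max_distance,
       force_limit = cfg$force_limit, temperature = cfg$temperature,
       seed = cfg$seed)
}

#' Provenance hash of a configuration
#'
#' Short FNV-1a hash of the canonical flattened configuration, stamped
#' into manifests, events tables and fit reports.
#'
#' @param cfg A [simulation_config()].
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  lst <- as_config_list(cfg)
  .fnv1a(paste(names(lst),
               vapply(lst, function(v) paste(.fmt_num(as.numeric(v)),
                                             collapse = ","), character(1)),
               sep = "=", collapse = ";"))
}

#' Read a simulation configuration from YAML
#'
#' Reads the YAML file, validates it against the configuration schema
#' (every violation is reported, not only the first), fills defaults for
#' absent optional keys, and returns a [simulation_config()].
#' Required key: `velocities`. All other keys default as in
#' [simulation_config()].
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lst <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_input("%s: malformed YAML (%s)",
                                                 path, conditionMessage(e)))
  validate_config(lst, file = path)
}

#' Validate a configuration list
#'
#' @param lst Named list of configuration values.
#' @param file Name used in diagnostics.
#' @return A [simulation_config()] with defaults filled.
#' @export
validate_config <- function(lst, file = "config") {
  if (!is.list(lst)) stop_input("%s: configuration must be a mapping", file)
  known <- c("velocities", "curves_per_velocity", "p_bind", "p_nonspecific",
             "k_off", "x_beta", "contour_length", "kuhn_length", "k_c",
             "noise_sigma", "tilt", "sample_step", "max_distance",
             "force_limit", "temperature", "seed")
  problems <- character()
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0)
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(extra, collapse = ", ")))
  if (is.null(lst$velocities))
    problems <- c(problems, "missing required key: velocities")
  num_keys <- setdiff(known, "velocities")
  for (k in intersect(names(lst), num_keys))
    if (!is.numeric(lst[[k]]) || length(lst[[k]]) != 1L ||
        !is.finite(lst[[k]]))
      problems <- c(problems, sprintf("key `%s` must be a single number", k))
  if (!is.null(lst$velocities) &&
      (!is.numeric(lst$velocities) || any(!is.finite(lst$velocities)) ||
       any(lst$velocities <= 0)))
    problems <- c(problems, "key `velocities` must be positive numbers")
  for (k in c("p_bind", "p_nonspecific"))
    if (is.numeric(lst[[k]]) && length(lst[[k]]) == 1L &&
        (lst[[k]] < 0 || lst[[k]] > 1))
      problems <- c(problems, sprintf("key `%s` must lie in [0, 1]", k))
  if (length(problems) > 0)
    stop_input("%s: invalid configuration:\n  - %s", file,
               paste(problems, collapse = "\n  - "))
  args <- list(velocities = lst$velocities)
  direct <- c("curves_per_velocity", "p_bind", "p_nonspecific", "k_c",
              "noise_sigma", "tilt", "sample_step", "max_distance",
              "force_limit", "temperature", "seed")
  for (k in intersect(names(lst), direct)) args[[k]] <- lst[[k]]
  if (!is.null(lst$k_off) || !is.null(lst$x_beta))
    args$bell <- bell_parameters(
      k_off = if (is.null(lst$k_off)) 0.1 else lst$k_off,
      x_beta = if (is.null(lst$x_beta)) 0.5 else lst$x_beta)
  if (!is.null(lst$contour_length) || !is.null(lst$kuhn_length))
    args$linker <- linker_parameters(
      contour_length = if (is.null(lst$contour_length)) 10
                       else lst$contour_length,
      kuhn_length = if (is.null(lst$kuhn_length)) 0.7 else lst$kuhn_length)
  tryCatch(do.call(simulation_config, args),
           dfspec_domain_error = function(e)
             stop_input("%s: %s", file, conditionMessage(e)))
}

#' Write a configuration to YAML
#' @param cfg A [simulation_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(as_config_list(cfg), path)
  invisible(path)
}

#' Write one force curve to a TSV curve file
#'
#' @param curve A `force_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  gt <- curve$ground_truth
  hdr <- c(
    sprintf("# curve_id=%s", curve$curve_id),
    sprintf("# velocity_nm_s=%s", .fmt_num(curve$velocity)),
    sprintf("# k_c_pN_nm=%s", .fmt_num(curve$k_c)),
    sprintf("# sample_step_nm=%s", .fmt_num(curve$sample_step)),
    sprintf("# temperature_K=%s", .fmt_num(curve$temperature)))
  if (!is.null(gt)) {
    hdr <- c(hdr,
      sprintf("# gt_bound=%d", as.integer(gt$bound)),
      sprintf("# gt_nonspecific=%d", as.integer(gt$nonspecific)),
      sprintf("# gt_truncated=%d", as.integer(gt$truncated)),
      sprintf("# gt_rupture_force_pN=%s", .fmt_num(gt$rupture_force)),
      sprintf("# gt_rupture_separation_nm=%s", .fmt_num(gt$rupture_separation)),
      sprintf("# gt_loading_rate_pN_s=%s", .fmt_num(gt$loading_rate)))
  }
  body <- paste(.fmt_num(curve$piezo), .fmt_num(curve$trace_force),
                .fmt_num(curve$retrace_force), sep = "\t")
  writeLines(c(hdr, "piezo_nm\ttrace_force_pN\tretrace_force_pN", body), path)
  invisible(path)
}

#' Read a force curve file
#'
#' @param path Curve file path (format of [write_force_curve()]).
#' @return A `force_curve`.
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop_input("curve file not found: %s", path)
  lines <- readLines(path)
  is_hdr <- grepl("^# ", lines)
  n_hdr <- match(FALSE, is_hdr) - 1L
  if (is.na(n_hdr) || n_hdr < 1L)
    stop_input("%s: line 1: missing '# key=value' header", path)
  kv <- sub("^# ", "", lines[seq_len(n_hdr)])
  eq <- regexpr("=", kv, fixed = TRUE)
  bad <- which(eq < 1)
  if (length(bad) > 0)
    stop_input("%s: line %d: header is not key=value", path, bad[1])
  keys <- substr(kv, 1, eq - 1)
  vals <- substr(kv, eq + 1, nchar(kv))
  h <- stats::setNames(as.list(vals), keys)
  need <- c("curve_id", "velocity_nm_s", "k_c_pN_nm", "sample_step_nm",
            "temperature_K")
  miss <- setdiff(need, keys)
  if (length(miss) > 0)
    stop_input("%s: line %d: missing header key(s) %s", path, n_hdr,
               paste(miss, collapse = ", "))
  if (lines[n_hdr + 1L] != "piezo_nm\ttrace_force_pN\tretrace_force_pN")
    stop_input("%s: line %d: unexpected column header", path, n_hdr + 1L)
  tab <- tryCatch(
    utils::read.delim(text = lines[-seq_len(n_hdr + 1L)], header = FALSE,
                      col.names = c("p", "t", "r"),
                      colClasses = "numeric"),
    error = function(e) stop_input("%s: line %d: malformed numeric table (%s)",
                                   path, n_hdr + 2L, conditionMessage(e)))
  if (ncol(tab) != 3L || anyNA(tab) || any(!is.finite(as.matrix(tab))))
    stop_input("%s: line %d: malformed numeric table", path, n_hdr + 2L)
  gt <- NULL
  if ("gt_bound" %in% keys) {
    num <- function(k) suppressWarnings(as.numeric(h[[k]]))
    gt <- list(bound = num("gt_bound") == 1,
               nonspecific = num("gt_nonspecific") == 1,
               truncated = num("gt_truncated") == 1,
               rupture_force = num("gt_rupture_force_pN"),
               rupture_separation = num("gt_rupture_separation_nm"),
               loading_rate = num("gt_loading_rate_pN_s"))
  }
  structure(
    list(curve_id = h$curve_id,
         piezo = tab$p, trace_force = tab$t, retrace_force = tab$r,
         velocity = as.numeric(h$velocity_nm_s),
         k_c = as.numeric(h$k_c_pN_nm),
         sample_step = as.numeric(h$sample_step_nm),
         temperature = as.numeric(h$temperature_K),
         ground_truth = gt),
    class = "force_curve"
  )
}

#' Write a curve ensemble to a directory
#'
#' One TSV curve file per curve plus a `manifest.json` carrying the
#' configuration echo, seed, config hash, per-velocity counts and the
#' ground-truth event table.
#'
#' @param ensemble A `force_curve_set` from [simulate_ensemble()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_curve_set <- function(ensemble, dir) {
  if (!inherits(ensemble, "force_curve_set"))
    stop_input("`ensemble` must be a force_curve_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$curves))
    write_force_curve(ensemble$curves[[i]],
                      file.path(dir, sprintf("curve_%06d.tsv", i)))
  jsonlite::write_json(ensemble$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a curve directory
#'
#' @param dir Directory written by [write_curve_set()] (or containing
#'   any `*.tsv` curve files).
#' @return A `force_curve_set`; the manifest is `NULL` when absent.
#' @export
read_curve_set <- function(dir) {
  if (!dir.exists(dir)) stop_input("curve directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0)
    stop_input("%s: no curve files (*.tsv) found", dir)
  curves <- lapply(files, read_force_curve)
  mpath <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath,
                                                          simplifyVector = TRUE)
              else NULL
  structure(list(curves = curves, manifest = manifest),
            class = "force_curve_set")
}

#' Write / read an events table
#'
#' CSV with one row per candidate event; `accepted` stored as 0/1.
#'
#' @param events Events data.frame from [analyze_curves()].
#' @param path CSV path.
#' @return `path` / the events data.frame.
#' @export
write_events <- function(events, path) {
  ev <- events
  ev$accepted <- as.integer(ev$accepted)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_input("events file not found: %s", path)
  ev <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_input("%s: %s", path,
                                                conditionMessage(e)))
  need <- c("curve_id", "velocity_nm_s", "rupture_force_pN",
            "rupture_separation_nm", "k_peg_pN_nm", "k_eff_pN_nm",
            "loading_rate_pN_s", "accepted")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0)
    stop_input("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  ev$accepted <- ev$accepted == 1
  ev
}

#' Write / read per-velocity summaries
#'
#' The scalar fields of each [summarize_group()] result as one CSV row
#' per velocity; the pdf curves go to a separate long-format CSV via
#' [write_pdfs()].
#'
#' @param summaries List of `velocity_summary` objects.
#' @param path CSV path.
#' @return `path` / a data.frame of per-velocity rows.
#' @export
write_summaries <- function(summaries, path) {
  rows <- lapply(summaries, function(s)
    data.frame(velocity_nm_s = s$velocity, n_curves = s$n_curves,
               n_accepted_events = s$n_accepted_events,
               binding_probability = s$binding_probability,
               binding_probability_se = s$binding_probability_se,
               f_star_pN = s$f_star, f_star_se_pN = s$f_star_se,
               f_star_width_pN = s$f_star_width,
               mean_loading_rate_pN_s = s$mean_loading_rate,
               sd_loading_rate_pN_s = s$sd_loading_rate))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop_input("summary file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write pdf curves for every velocity group
#'
#' Long-format CSV: `velocity_nm_s`, `force_pN`, `density_per_pN`.
#'
#' @param summaries List of `velocity_summary` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_pdfs <- function(summaries, path) {
  rows <- lapply(summaries, function(s) {
    if (is.null(s$pdf)) return(NULL)
    data.frame(velocity_nm_s = s$velocity, force_pN = s$pdf$force,
               density_per_pN = s$pdf$density)
  })
  utils::write.csv(do.call(rbind, c(list(NULL), rows)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a Bell-Evans fit report (JSON)
#'
#' @param fit A [fit_bell_evans()] result.
#' @param path JSON path.
#' @param provenance Optional named list (e.g. seed, config_hash) echoed
#'   into the report.
#' @return `path` / the report list.
#' @export
write_fit <- function(fit, path, provenance = NULL) {
  report <- list(
    model = "bell_evans_single_barrier",
    x_beta_nm = fit$x_beta,
    x_beta_ci_nm = fit$x_beta_ci,
    k_off_per_s = fit$k_off,
    k_off_ci_per_s = fit$k_off_ci,
    slope_pN = fit$slope, intercept_pN = fit$intercept,
    covariance = as.vector(fit$cov),
    kBT_pN_nm = fit$ctx$kBT, temperature_K = fit$ctx$temperature,
    n_points = fit$n_points, level = fit$level,
    reduced_chisq = fit$reduced_chisq,
    points = fit$points,
    provenance = provenance)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop_input("fit report not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
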