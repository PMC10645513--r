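#' Run configuration
#'
#' Builds (or reads) the flat configuration used by the pipeline runners
#' [run_flow()], [run_transport()] and [run_reduced()]. All physical keys
#' carry unit suffixes (`bx_um`, `chi_max_um`, ...) to prevent unit bugs.
#' The plain-text file format is one `key = value` pair per line; `#`
#' starts a comment.
#'
#' @param ... Key–value overrides of the defaults.
#' @param file Optional path to a `key = value` text file (applied before
#'   `...`).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    bx_um = 110, bz_um = 270,
    solver = "exact",                 # "exact" | "lubrication"
    nmax = 14,
    slip = "drosophila",
    n_particles = 40,
    kernel_um = 7,
    n_seeds = 100,
    base_seed = 1,
    chi_max_um = 400, chi_step_um = 2, dchi_um = 0.5,
    cloud_radius_um = 60,
    Z0 = 60 / 270,
    snapshot_chi_um = c(0, 100, 159, 250, 400),
    eval_chi_um = numeric(0),
    out_dir = "."
  )
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop(sprintf("cannot parse config line '%s'", ln),
                               call. = FALSE)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      cfg[[key]] <- if (all(!is.na(num))) num else val
    }
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  structure(cfg, class = "run_config")
}

log_line <- function(log_con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

open_run_log <- function(out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".log"))
  con <- file(path, open = "wt")
  con
}

config_as_list <- function(cfg) {
  lapply(unclass(cfg), function(v) if (length(v) == 1) unname(v) else unname(v))
}

#' Run a flow computation and export the field
#'
#' Resolves the configured geometry and slip fixture, solves with the
#' requested backend, and writes the field CSV (`flow_field.csv`:
#' `r_um`, `z_um`, `u_r`, `u_z`, `psi`) plus, for the exact solver, the
#' coefficient JSON (`flow_coefficients.json`). Outputs are fully
#' deterministic for a given configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the flow object and output paths.
#' @export
run_flow <- function(config = run_config()) {
  g <- embryo_geometry(config$bx_um, config$bz_um)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- open_run_log(config$out_dir, "flow")
  on.exit(close(log))
  log_line(log, "geometry resolved: bx=%g um bz=%g um c=%.4f um tau0=%.6f",
           g$bx, g$bz, g$c, g$tau0)
  slip <- slip_fixture(config$slip, g)
  flow <- if (identical(config$solver, "lubrication")) {
    lubrication_flow(slip, g)
  } else {
    stokes_flow(slip, g, nmax = config$nmax)
  }
  if (inherits(flow, "stokes_flow")) {
    log_line(log, "series solved: nmax=%d boundary residuals %.2e / %.2e",
             flow$nmax, flow$residual_g, flow$residual_dg)
  } else {
    log_line(log, "lubrication solution assembled for slip '%s'", slip$name)
  }
  csv <- file.path(config$out_dir, "flow_field.csv")
  json <- file.path(config$out_dir, "flow_coefficients.json")
  export_flow_field(flow, csv,
                    json_path = if (inherits(flow, "stokes_flow")) json else NULL)
  log_line(log, "field written: %s", csv)
  invisible(list(flow = flow, csv = csv,
                 json = if (inherits(flow, "stokes_flow")) json else NULL))
}

#' Run a transport ensemble and export the homogeneity curve
#'
#' Advects the configured seeded ensemble, computes the kernel-based
#' homogeneity curve and writes `homogeneity.csv` (`chi_um`, `phi_mean`,
#' `phi_min`, `phi_max`) and `transport_summary.json` with `chi_star`,
#' the resolved configuration, and the normalized variance at any
#' requested `eval_chi_um` values (e.g. experimentally realized
#' \eqn{\chi}).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `homogeneity_curve` and output
#'   paths.
#' @export
run_transport <- function(config = run_config()) {
  g <- embryo_geometry(config$bx_um, config$bz_um)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- open_run_log(config$out_dir, "transport")
  on.exit(close(log))
  log_line(log, "geometry resolved: bx=%g um bz=%g um tau0=%.6f", g$bx, g$bz,
           g$tau0)
  slip <- slip_fixture(config$slip, g)
  flow <- stokes_flow(slip, g, nmax = config$nmax)
  log_line(log, "series solved: nmax=%d boundary residuals %.2e / %.2e",
           flow$nmax, flow$residual_g, flow$residual_dg)
  ens <- advect_ensemble(
    flow, n = config$n_particles, n_seeds = config$n_seeds,
    base_seed = config$base_seed,
    chi_grid = seq(0, config$chi_max_um, by = config$chi_step_um),
    dchi = config$dchi_um, radius = config$cloud_radius_um
  )
  log_line(log, "ensemble advected: %d seeds x %d tracers, %d projections",
           ens$n_seeds, ens$n, ens$n_projected)
  curve <- homogeneity_curve(ens, g, measure = "kernel",
                             bandwidth = config$kernel_um)
  csv <- file.path(config$out_dir, "homogeneity.csv")
  readr::write_csv(
    tibble::tibble(chi_um = curve$chi, phi_mean = curve$phi_mean,
                   phi_min = curve$phi_min, phi_max = curve$phi_max),
    csv
  )
  eval_chi <- config$eval_chi_um
  summary <- list(
    chi_star_um = chi_star(curve),
    R_um = config$kernel_um,
    N = config$n_particles,
    n_seeds = config$n_seeds,
    base_seed = config$base_seed,
    phi_at = if (length(eval_chi) > 0) {
      stats::setNames(as.list(curve_value_at(curve, eval_chi)),
                      paste0("chi_", eval_chi))
    } else NULL,
    config = config_as_list(config)
  )
  json <- file.path(config$out_dir, "transport_summary.json")
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_line(log, "chi_star = %.1f um; summary written: %s",
           chi_star(curve), json)
  invisible(list(curve = curve, csv = csv, json = json))
}

#' Run the reduced one-dimensional model and export snapshots
#'
#' Writes density snapshots `reduced_snapshots.csv` (`chi_um`, `Z`, `n`)
#' at the configured \eqn{\chi} values and `reduced_summary.json` with
#' `chi_star_1d`, `Z0` and `bz`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the snapshots, the variance curve and
#'   output paths.
#' @export
run_reduced <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- open_run_log(config$out_dir, "reduced")
  on.exit(close(log))
  bz <- config$bz_um
  Z0 <- config$Z0
  Zg <- seq(-1, 1, length.out = 2001)
  snaps <- purrr::map_dfr(config$snapshot_chi_um, function(chi) {
    tibble::tibble(chi_um = chi, Z = Zg,
                   n = reduced_density(Zg, T_from_chi(chi, bz), Z0 = Z0))
  })
  curve <- reduced_variance_curve(bz = bz, Z0 = Z0)
  csv <- file.path(config$out_dir, "reduced_snapshots.csv")
  readr::write_csv(snaps, csv)
  json <- file.path(config$out_dir, "reduced_summary.json")
  jsonlite::write_json(
    list(chi_star_1d_um = attr(curve, "chi_star"), Z0 = Z0, bz_um = bz,
         config = config_as_list(config)),
    json, auto_unbox = TRUE, digits = NA
  )
  log_line(log, "chi_star_1d = %.1f um; snapshots written: %s",
           attr(curve, "chi_star"), csv)
  invisible(list(snapshots = snaps, curve = curve, csv = csv, json = json))
}
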