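#' Read and validate a pipeline run configuration
#'
#' A run configuration is a flat list (or YAML file) with an integer
#' `seed`, an `output_dir`, and one block per requested stage:
#' `surface`, `probe`, `friction`, `contact_angle`, `model`. Unknown keys
#' anywhere are rejected — all offending keys are listed at once — and
#' referenced input files must exist before anything executes.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return the validated config list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- list(
    top = c("seed", "output_dir", "surface", "probe", "friction",
           "contact_angle", "model", "log_level"),
    surface = c("kind", "q", "q_h", "nx", "ny", "bond_length",
                "lattice_constant", "spacing", "decoration", "out", "format"),
    probe = c("q_values", "kind", "nx", "ny", "bond_length",
              "lattice_constant", "decoration", "n", "z_probe", "n_orient",
              "weighting", "cutoff"),
    friction = c("forces", "ou", "area", "temperature", "t_cutoff"),
    contact_angle = c("traj", "cap", "dr", "dz", "threshold_fraction",
                      "z_exclude", "z_contact"),
    model = c("data", "synthetic", "through_origin", "cutoff"))
  bad <- character(0)
  chk <- function(block, where) {
    extra <- setdiff(names(block), allowed[[where]])
    if (length(extra))
      bad <<- c(bad, paste0(if (where != "top") paste0(where, "$") else "",
                            extra))
  }
  chk(config, "top")
  for (st in intersect(names(config), names(allowed)[-1]))
    if (is.list(config[[st]])) chk(config[[st]], st)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (p in c(config$friction$forces, config$contact_angle$traj,
              config$model$data))
    if (!is.null(p) && !file.exists(p))
      stop("referenced input file does not exist: ", p)
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "."
  class(config) <- c("run_config", class(config))
  config
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

.pipeline_surface <- function(cfg, config, seed) {
  kind <- cfg$kind %||% "hexagonal"
  s <- switch(kind,
    hexagonal = build_hexagonal(cfg$nx %||% 8, cfg$ny %||% 5,
                                q = cfg$q %||% 0,
                                bond_length = cfg$bond_length %||% 0.142,
                                decoration = cfg$decoration %||% "para"),
    square = build_square(cfg$nx %||% 8, cfg$ny %||% 8, q = cfg$q %||% 0,
                          lattice_constant = cfg$lattice_constant %||% 0.25,
                          decoration = cfg$decoration %||% "checkerboard"),
    ch2 = build_ch2(cfg$nx %||% 8, cfg$ny %||% 8,
                    q_h = cfg$q_h %||% cfg$q %||% 0.06,
                    spacing = cfg$spacing %||% 0.25),
    stop("unknown surface kind '", kind, "'"))
  out <- file.path(config$output_dir, cfg$out %||% "surface.gro")
  write_structure(s, out, format = cfg$format %||% "auto")
  list(surface = s,
       result = list(path = out, sidecar = paste0(out, ".csv"),
                     n_atoms = nrow(s$atoms), net_charge_e = net_charge(s),
                     cell_nm = s$cell))
}

.pipeline_probe <- function(cfg, config, seed) {
  qs <- cfg$q_values %||% c(0.1, 0.2, 0.3)
  kind <- cfg$kind %||% "hexagonal"
  ngrid <- cfg$n %||% c(12, 12)
  recs <- lapply(qs, function(q) {
    s <- switch(kind,
      hexagonal = build_hexagonal(cfg$nx %||% 4, cfg$ny %||% 3, q = q,
                                  decoration = cfg$decoration %||% "para"),
      square = build_square(cfg$nx %||% 6, cfg$ny %||% 6, q = q,
                            decoration = cfg$decoration %||% "checkerboard"),
      stop("probe stage supports hexagonal or square lattices"))
    g <- probe_map(s, z_probe = cfg$z_probe %||% 0.35, n = ngrid,
                   n_orient = cfg$n_orient %||% 16,
                   weighting = cfg$weighting %||% "uniform",
                   cutoff = cfg$cutoff %||% 1.0)
    st <- map_stats(g, component = "coulomb")
    data.frame(q = q, var_E = st$var_E, mean_E = st$mean_E)
  })
  d <- do.call(rbind, recs)
  ex <- q_scaling_exponent(d, "var_E")
  list(result = list(per_q = d, q_exponent = ex$exponent,
                     q_exponent_se = ex$se))
}

.pipeline_friction <- function(cfg, config, seed) {
  area <- cfg$area %||% (6.395 * 6.816)
  temperature <- cfg$temperature %||% 300
  t_cutoff <- cfg$t_cutoff %||% 1.0
  if (!is.null(cfg$forces)) {
    fs <- read_force_csv(cfg$forces, area, temperature)
  } else {
    ou <- cfg$ou %||% list()
    fs <- gen_ou_force(n = ou$n %||% 200000, dt = ou$dt %||% 0.002,
                       tau = ou$tau %||% 0.2, sigma2 = ou$sigma2 %||% 25,
                       area = area, temperature = temperature, seed = seed)
  }
  fr <- friction_coefficient(fs, t_cutoff = t_cutoff)
  res <- list(lambda_Nsm3 = fr$lambda, t_cutoff_ps = t_cutoff,
              converged = fr$converged)
  if (is.null(cfg$forces)) {
    m <- fs$meta
    res$lambda_closed_form_Nsm3 <-
      ou_lambda_exact(m$sigma2, m$tau, area, temperature, t_cutoff)
  }
  res
}

.pipeline_contact_angle <- function(cfg, config, seed) {
  if (!is.null(cfg$traj)) {
    frames <- read_traj_xyz(cfg$traj)
  } else {
    cap <- cfg$cap %||% list()
    frames <- gen_droplet(theta_true = cap$theta %||% 90,
                          R = cap$R %||% 2.0,
                          n_samples = cap$n_samples %||% 45000,
                          n_frames = cap$n_frames %||% 50,
                          noise = cap$noise %||% 0, seed = seed)
  }
  ca <- contact_angle_from_frames(
    frames, dr = cfg$dr %||% 0.1, dz = cfg$dz %||% 0.05,
    threshold_fraction = cfg$threshold_fraction %||% 0.5,
    z_exclude = cfg$z_exclude %||% 0.8, z_contact = cfg$z_contact %||% 0)
  res <- list(theta_deg = ca$theta, radius_nm = ca$radius,
              residual_nm = ca$residual, n_points = ca$n_points)
  if (is.null(cfg$traj)) res$theta_true_deg <- attr(frames, "theta_true")
  res
}

.pipeline_model <- function(cfg, config, seed) {
  if (!is.null(cfg$data)) {
    d <- utils::read.csv(cfg$data)
    names(d)[names(d) == "varE_kJmol2"] <- "var_E"
    names(d)[names(d) == "lambda_Nsm3"] <- "lambda"
    names(d)[names(d) == "q_e"] <- "q"
  } else {
    syn <- cfg$synthetic %||% list()
    d <- gen_lambda_dataset(zeta_true = syn$zeta_true %||% 130,
                            noise = syn$noise %||% 0.05, seed = seed)
  }
  zf <- fit_zeta(d, through_origin = cfg$through_origin %||% TRUE,
                 cutoff = cfg$cutoff %||% 0.45)
  list(zeta = zf$zeta, r_squared = zf$r_squared, n_used = zf$n_used,
       n_excluded = length(zf$excluded), units = zf$units)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order (surface ->
#' probe maps -> friction -> contact angle -> model fit), logging
#' progress to stderr, and writes a versioned JSON report
#' (`report.json` in the output directory) embedding the config hash,
#' package version, seed and per-stage parameters, so every number is
#' traceable to config + seed. A failing stage stops the stages
#' downstream of it with a clear cause; identical config and seed give
#' identical reports (up to the timestamp).
#'
#' @param config a config list or YAML path, see [read_run_config()].
#' @param quiet suppress progress messages.
#' @return the report list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[surfriction] ", ...)
  runners <- list(surface = .pipeline_surface, probe = .pipeline_probe,
                  friction = .pipeline_friction,
                  contact_angle = .pipeline_contact_angle,
                  model = .pipeline_model)
  stages <- intersect(names(runners), names(config))
  report <- list(
    package = "surfriction",
    version = as.character(utils::packageVersion("surfriction")),
    config_hash = .config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list())
  failed <- NULL
  for (k in seq_along(stages)) {
    st <- stages[k]
    if (!is.null(failed)) {
      report$stages[[st]] <- list(status = "skipped",
                                  cause = paste0("upstream stage '", failed,
                                                 "' failed"))
      next
    }
    say("stage ", st, " ...")
    stage_seed <- config$seed + 101L * k
    out <- tryCatch({
      r <- runners[[st]](config[[st]], config, stage_seed)
      if (!is.null(r$result)) r <- r$result
      c(list(status = "ok", params = config[[st]], seed = stage_seed), r)
    }, error = function(e) {
      failed <<- st
      list(status = "error", cause = conditionMessage(e))
    })
    report$stages[[st]] <- out
    if (identical(out$status, "error"))
      say("stage ", st, " FAILED: ", out$cause)
  }
  path <- file.path(config$output_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  say("report written to ", path)
  invisible(report)
}
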