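# Pipeline layer: validated run configuration and staged execution
# (simulate -> wham / pucker / rc -> report), with provenance-stamped
# artifacts. The thin command-line wrapper in inst/cli/ringpmf.R maps
# these stages onto shell subcommands and exit codes.

config_schema <- list(
  output_dir = NULL, seed = NULL, temperature = NULL,
  surrogate = list(nodes_x = NULL, nodes_y = NULL, wall_k = NULL),
  umbrella = list(n_windows = NULL, rc_range = NULL, k = NULL, dt = NULL,
                  D = NULL, n_equil = NULL, n_prod = NULL),
  wham = list(bin_width = NULL, tol = NULL, max_iter = NULL),
  landmark_windows = list(reactant = NULL, product = NULL),
  regions = NULL,
  pucker_path = list(rc2 = NULL, Q = NULL, theta = NULL, phi = NULL,
                     angular_sd = NULL, amplitude_sd = NULL, sharpness = NULL),
  ring = list(radius = NULL, n_frames = NULL, rc2_range = NULL),
  inputs = list(manifest = NULL, trajectory = NULL, rc2_series = NULL,
                rc_specs = NULL, pmf = NULL, pmf_b = NULL))

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: the
#' landmark surrogate potential, the 42-window umbrella campaign, WHAM
#' settings, landmark search windows, itinerary regions and the
#' conformational path. Override any entry before passing the list to
#' [run_pipeline()].
#'
#' @param output_dir artifact directory.
#' @param seed master seed.
#' @return Nested named list (a valid run configuration).
#' @export
default_config <- function(output_dir = "ringpmf_out", seed = 1L) {
  list(
    output_dir = output_dir,
    seed = as.integer(seed),
    temperature = 300,
    surrogate = list(nodes_x = c(1.5, 2.17, 3.2), nodes_y = c(0, 19, 5),
                     wall_k = 100),
    umbrella = list(n_windows = 42L, rc_range = c(1.3, 3.5), k = 500,
                    dt = 0.1, D = 0.001, n_equil = 10000L, n_prod = 10000L),
    wham = list(bin_width = 0.02, tol = 1e-7, max_iter = 1e5),
    landmark_windows = list(reactant = c(1.3, 1.9), product = c(2.9, 3.5)),
    regions = list(reactant = c(1.5, 1.8), ts = c(2.0, 2.3),
                   product = c(2.4, 3.2)),
    pucker_path = list(rc2 = c(1.5, 2.17, 2.8), Q = c(0.57, 0.45, 0.57),
                       theta = c(90, 90, 0), phi = c(210, 120, 120),
                       angular_sd = 8, amplitude_sd = 0.03, sharpness = 12),
    ring = list(radius = 1.45, n_frames = 400L, rc2_range = c(1.4, 3.3)),
    inputs = list())
}

#' Validate a run configuration
#'
#' Checks the configuration against the known key schema; unknown keys at
#' any level are rejected (they usually indicate a typo that would
#' otherwise silently fall back to a default).
#'
#' @param config nested named list.
#' @return The config, invisibly, on success; otherwise a config error.
#' @export
validate_config <- function(config) {
  check <- function(cfg, schema, where) {
    if (is.null(names(cfg)) && length(cfg) > 0L)
      stop(errorCondition(paste0("config section '", where, "' must be named"),
           class = c("ringpmf_config_error", "ringpmf_error", "error")))
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown) > 0L)
      stop(errorCondition(
        paste0("unknown config key(s) at '", where, "': ",
               paste(unknown, collapse = ", ")),
        class = c("ringpmf_config_error", "ringpmf_error", "error")))
    for (nm in names(cfg))
      if (is.list(schema[[nm]]) && !is.null(schema[[nm]]))
        check(cfg[[nm]], schema[[nm]], paste0(where, "$", nm))
  }
  check(config, config_schema, "config")
  if (!is.null(config$seed) && !is.finite(as.numeric(config$seed)))
    stop(errorCondition("config$seed must be a finite number",
         class = c("ringpmf_config_error", "ringpmf_error", "error")))
  invisible(config)
}

cfg_merged <- function(config) {
  base <- default_config()
  merge2 <- function(b, o) {
    for (nm in names(o))
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(o[[nm]]))
        merge2(b[[nm]], o[[nm]]) else o[[nm]]
    b
  }
  merge2(base, config)
}

cfg_potential <- function(cfg)
  surrogate_potential(data.frame(x = cfg$surrogate$nodes_x,
                                 y = cfg$surrogate$nodes_y),
                      wall_k = cfg$surrogate$wall_k)

cfg_path <- function(cfg)
  pucker_path(data.frame(rc2 = cfg$pucker_path$rc2, Q = cfg$pucker_path$Q,
                         theta = cfg$pucker_path$theta,
                         phi = cfg$pucker_path$phi),
              angular_sd = cfg$pucker_path$angular_sd,
              amplitude_sd = cfg$pucker_path$amplitude_sd,
              sharpness = cfg$pucker_path$sharpness)

need_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(errorCondition(
      paste0("missing input for stage: ", what,
             if (!is.null(path)) paste0(" (", path, ")") else ""),
      class = c("ringpmf_input_error", "ringpmf_error", "error")))
  path
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ringpmf] ", fmt), ...))
}

#' Run a pipeline stage
#'
#' Executes one stage of the analysis pipeline and writes its artifacts
#' under `config$output_dir`, each stamped with a provenance header
#' (package version, config hash, seed). Stages:
#' \describe{
#'   \item{simulate}{generate the synthetic umbrella dataset (per-window
#'     sample TSVs + manifest), the ring trajectory (multi-frame XYZ) and
#'     its rc2 series.}
#'   \item{wham}{reconstruct the PMF from the window manifest; write
#'     `pmf.tsv` and `landmarks.json`.}
#'   \item{pucker}{puckering series and per-region itinerary summary for
#'     the ring trajectory; write `pucker_series.tsv`, `itinerary.tsv`.}
#'   \item{rc}{evaluate reaction-coordinate monitors from a JSON spec file
#'     on the trajectory; write `monitors.tsv`.}
#'   \item{report}{collect landmarks, per-region majorities and (when a
#'     second profile is configured) the two-profile spread into
#'     `report.json`.}
#' }
#'
#' @param config a configuration list (see [default_config()]); only
#'   overrides need to be present. Unknown keys are rejected.
#' @param subcommand one of `"simulate"`, `"wham"`, `"pucker"`, `"rc"`,
#'   `"report"`.
#' @param verbose emit progress messages (default `TRUE`).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = list(), subcommand, verbose = TRUE) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "wham", "pucker", "rc", "report"))
  validate_config(config)
  cfg <- cfg_merged(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific parameters only, not artifact locations
  hash <- config_hash(cfg[setdiff(names(cfg), c("output_dir", "inputs"))])
  prov <- provenance_lines(c(
    sprintf("# config-hash %s seed %d", hash, cfg$seed)))
  prov_list <- list(config_hash = hash, seed = cfg$seed,
                    version = as.character(utils::packageVersion("ringpmf")))
  out <- list()

  if (subcommand == "simulate") {
    pot <- cfg_potential(cfg)
    u <- cfg$umbrella
    log_stage(verbose, "simulate: %d windows over [%g, %g] A, k = %g, seed %d",
              u$n_windows, u$rc_range[1], u$rc_range[2], u$k, cfg$seed)
    wins <- generate_umbrella_dataset(pot, u$n_windows, u$rc_range, u$k,
                                      cfg$temperature, u$dt, u$D,
                                      u$n_equil, u$n_prod, seed = cfg$seed)
    wdir <- file.path(cfg$output_dir, "windows")
    dir.create(wdir, showWarnings = FALSE)
    files <- vapply(seq_along(wins), function(i) {
      f <- file.path(wdir, sprintf("window_%02d.tsv", i))
      write_window_tsv(wins[[i]], f, provenance = prov)
      f
    }, character(1))
    out$manifest <- write_window_manifest(files, file.path(wdir, "manifest.json"))
    p <- cfg_path(cfg)
    rc2 <- seq(cfg$ring$rc2_range[1], cfg$ring$rc2_range[2],
               length.out = cfg$ring$n_frames)
    frames <- generate_ring_trajectory(p, rc2, cfg$ring$radius,
                                       seed = cfg$seed + 1L)
    out$trajectory <- write_xyz(frames, file.path(cfg$output_dir, "ring_traj.xyz"))
    out$rc2_series <- write_table_tsv(
      data.frame(frame_index = seq_along(rc2) - 1L, rc2 = rc2),
      file.path(cfg$output_dir, "rc2_series.tsv"), provenance = prov)
  }

  if (subcommand == "wham") {
    mf <- cfg$inputs$manifest
    if (is.null(mf)) mf <- file.path(cfg$output_dir, "windows", "manifest.json")
    wins <- read_window_manifest(need_input(mf, "wham (window manifest)"))
    log_stage(verbose, "wham: %d windows, bin width %g A, tol %g",
              length(wins), cfg$wham$bin_width, cfg$wham$tol)
    prof <- wham(wins, cfg$wham$bin_width, cfg$temperature,
                 cfg$wham$tol, cfg$wham$max_iter)
    log_stage(verbose, "wham: converged in %d iterations (residual %.3g kT)",
              prof$iterations, prof$residual)
    out$pmf <- write_pmf_tsv(prof, file.path(cfg$output_dir, "pmf.tsv"),
                             provenance = prov)
    lm <- landmarks(prof, cfg$landmark_windows$reactant,
                    cfg$landmark_windows$product)
    out$landmarks <- write_landmarks_json(
      lm, file.path(cfg$output_dir, "landmarks.json"), provenance = prov_list)
  }

  if (subcommand == "pucker") {
    tr <- cfg$inputs$trajectory
    if (is.null(tr)) tr <- file.path(cfg$output_dir, "ring_traj.xyz")
    rs <- cfg$inputs$rc2_series
    if (is.null(rs)) rs <- file.path(cfg$output_dir, "rc2_series.tsv")
    frames <- read_xyz(need_input(tr, "pucker (ring trajectory)"))
    rc2 <- read_table_tsv(need_input(rs, "pucker (rc2 series)"))$rc2
    log_stage(verbose, "pucker: %d frames", length(frames))
    ps <- pucker_series(frames)
    ps$rc2 <- rc2
    out$pucker_series <- write_table_tsv(
      ps[, c("frame_index", "rc2", "Q", "theta", "phi", "q_x", "q_y",
             "conformer")],
      file.path(cfg$output_dir, "pucker_series.tsv"), provenance = prov)
    it <- itinerary(ps, rc2, cfg$regions)
    out$itinerary <- write_table_tsv(
      it$summary, file.path(cfg$output_dir, "itinerary.tsv"), provenance = prov)
  }

  if (subcommand == "rc") {
    tr <- need_input(cfg$inputs$trajectory, "rc (trajectory)")
    sp <- need_input(cfg$inputs$rc_specs, "rc (rc_specs JSON)")
    frames <- if (grepl("\\.pdb$", tr, ignore.case = TRUE))
      read_pdb_frames(tr) else read_xyz(tr)
    specs <- read_rc_specs(sp)
    log_stage(verbose, "rc: %d frames x %d monitors", length(frames), length(specs))
    out$monitors <- write_table_tsv(
      monitor_series(frames, specs),
      file.path(cfg$output_dir, "monitors.tsv"), provenance = prov)
  }

  if (subcommand == "report") {
    pf <- cfg$inputs$pmf
    if (is.null(pf)) pf <- file.path(cfg$output_dir, "pmf.tsv")
    prof <- read_pmf_tsv(need_input(pf, "report (pmf)"))
    lm <- landmarks(prof, cfg$landmark_windows$reactant,
                    cfg$landmark_windows$product)
    rep <- list(landmarks = list(
      reactant_min = lm$reactant_min, ts_pos = lm$ts_pos,
      product_min = lm$product_min, barrier = lm$barrier,
      delta_g = lm$delta_g))
    itf <- file.path(cfg$output_dir, "itinerary.tsv")
    if (file.exists(itf)) {
      it <- read_table_tsv(itf)
      rep$regions <- stats::setNames(as.list(it$majority), it$region)
    }
    if (!is.null(cfg$inputs$pmf_b)) {
      prof_b <- read_pmf_tsv(need_input(cfg$inputs$pmf_b, "report (pmf_b)"))
      rep$profile_sd <- profile_sd(prof, prof_b,
                                   range = c(lm$ts_pos, lm$product_min))
    }
    rep$provenance <- prov_list
    out$report <- file.path(cfg$output_dir, "report.json")
    jsonlite::write_json(rep, out$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  log_stage(verbose, "%s: wrote %s", subcommand,
            paste(unlist(out), collapse = ", "))
  invisible(out)
}
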