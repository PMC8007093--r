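#' Load and validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML/JSON file holding one).
#' Recognized blocks — all atom indices 1-based:
#' \describe{
#'   \item{trajectory}{`path`, `format` (`xyz`/`pdb`/`auto`), `stride`,
#'     `molecules` (atoms per molecule, e.g. `c(8, 8)`).}
#'   \item{synthetic}{instead of `trajectory`: `n_frames`, `seed`,
#'     `amplitude`, `kappa` — generates the default six-state mixture via
#'     [make_trajectory()].}
#'   \item{cvs}{list of CV specs for [cv_timeseries()].}
#'   \item{hbonds}{`donor_heavy`, `donor_hydrogens` (list), `acceptors`,
#'     `distance`, `angle`, `group_by`.}
#'   \item{association}{`molA`, `molB`, `threshold` (Angstrom).}
#'   \item{cluster}{`k`, `seed`, optional `weights`, `columns`.}
#'   \item{shell}{`radius` (Angstrom), `solute` (molecule ids).}
#'   \item{spectra}{`sticks` (CSV path; structure ids `cluster_<i>` map to
#'     clusters), `bandwidth`, `scale` (factor or region table),
#'     `grid = c(from, to, by)`, `weighting` (`"population"` or
#'     `"boltzmann"`), `temperature`, and optionally `monomer_sticks`,
#'     `dimer_sticks`, `K`, `c`, `dimer_normalization` for equilibrium
#'     mixing.}
#' }
#'
#' @param config named list, or path to a YAML/JSON file.
#' @return validated config (class `voa_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$trajectory) && is.null(config$synthetic))
    stop("config needs a `trajectory` or `synthetic` block")
  if (is.null(config$cluster$k)) stop("config needs cluster$k")
  if (config$cluster$k < 1L) stop("cluster$k must be positive")
  if (is.null(config$cluster$seed)) config$cluster$seed <- 1L
  for (p in c("stride")) {
    v <- config$trajectory[[p]]
    if (!is.null(v) && v < 1) stop("trajectory$", p, " must be >= 1")
  }
  if (!is.null(config$shell) && config$shell$radius <= 0)
    stop("shell$radius must be > 0")
  class(config) <- c("voa_config", "list")
  config
}

load_pipeline_trajectory <- function(config) {
  if (!is.null(config$trajectory)) {
    tr <- config$trajectory
    mol <- if (!is.null(tr$molecules))
      rep(seq_along(tr$molecules), times = tr$molecules) else NULL
    read_trajectory(tr$path,
                    format = if (is.null(tr$format)) "auto" else tr$format,
                    stride = if (is.null(tr$stride)) 1L else tr$stride,
                    mol = mol)
  } else {
    sy <- config$synthetic
    states <- default_states_6(kappa = if (is.null(sy$kappa)) 50 else sy$kappa)
    make_trajectory(states, n_frames = sy$n_frames,
                    seed = if (is.null(sy$seed)) 1L else sy$seed,
                    amplitude = if (is.null(sy$amplitude)) 40 else sy$amplitude
                    )$trajectory
  }
}

default_cv_specs <- list(
  list(name = "P_theta", type = "pucker_phase", atoms = 1:5),
  list(name = "oh_torsion", type = "torsion", atoms = c(7L, 6L, 2L, 1L)))

#' Run the full trajectory-to-spectra pipeline
#'
#' Executes the configured stages in order — trajectory input, collective
#' variables, hydrogen-bond occupancy, monomer/dimer association,
#' k-medoids clustering with medoid export, and spectral assembly — and
#' writes every stage artifact under `outdir` with deterministic names.
#' Rerunning with the same config and seed reproduces byte-identical CSVs.
#'
#' Artifacts: `cvs.csv`, `cluster_table.csv`, `assignments.csv`,
#' `medoid_XX.xyz`, `association.csv`, `composite_*.csv` (+ `.json`
#' provenance sidecars), `report.json`, `config.json`.
#'
#' @param config a [pipeline_config()] (list or file path).
#' @param outdir output directory (created).
#' @param verbose log stage timings to stderr (results never go there).
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  config <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[voamd] stage %-12s %6.2f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  traj <- stage("input", load_pipeline_trajectory(config))
  report$n_frames <- n_frames(traj)
  report$n_atoms <- n_atoms(traj)

  cv_specs <- if (is.null(config$cvs)) default_cv_specs else config$cvs
  cvs <- stage("cvs", cv_timeseries(traj, cv_specs))
  write_cv_csv(cvs, file.path(outdir, "cvs.csv"))

  if (!is.null(config$hbonds)) {
    hb <- config$hbonds
    occ <- stage("hbonds", hbond_occupancy(
      traj, donor_set(hb$donor_heavy, hb$donor_hydrogens), hb$acceptors,
      hbond_criteria(distance = if (is.null(hb$distance)) 3.0 else hb$distance,
                     angle = if (is.null(hb$angle)) 30 else hb$angle),
      group_by = if (is.null(hb$group_by)) "all" else hb$group_by))
    report$hbond_occupancy <- as.list(occ$occupancy)
  }

  if (!is.null(config$association)) {
    as_cfg <- config$association
    hb <- config$hbonds
    if (is.null(hb)) stop("association stage needs an `hbonds` block for donors/acceptors")
    states <- stage("association", assign_association_state(
      traj, as_cfg$molA, as_cfg$molB,
      donor_set(hb$donor_heavy, hb$donor_hydrogens), hb$acceptors,
      threshold = if (is.null(as_cfg$threshold)) 4.0 else as_cfg$threshold))
    utils::write.csv(states, file.path(outdir, "association.csv"),
                     row.names = FALSE, quote = FALSE)
    report$dimer_fraction <- attr(states, "dimer_fraction")
  }

  # drop frames with undefined CVs before clustering, keeping the map back
  keep <- stats::complete.cases(as.data.frame(cvs))
  cvs_ok <- cvs[keep, , drop = FALSE]
  attr(cvs_ok, "periodic") <- attr(cvs, "periodic")
  class(cvs_ok) <- class(cvs)
  model <- stage("cluster", kmedoids(
    cvs_ok, k = config$cluster$k, seed = config$cluster$seed,
    weights = config$cluster$weights, columns = config$cluster$columns))
  write_cluster_outputs(model, outdir, traj = traj,
                        shell_radius = config$shell$radius,
                        solute = config$shell$solute)
  report$populations <- model$populations
  report$cluster_table <- cluster_table(model)

  if (!is.null(config$spectra)) {
    sp <- config$spectra
    bw <- if (is.null(sp$bandwidth)) 6 else sp$bandwidth
    sc <- if (is.null(sp$scale)) 1 else sp$scale
    grid <- if (!is.null(sp$grid))
      wavenumber_grid(sp$grid[1L], sp$grid[2L],
                      if (length(sp$grid) > 2L) sp$grid[3L] else 1) else NULL
    assemble <- function(sticks, weights_from) {
      specs <- lapply(sticks, broaden, bandwidth = bw, scale = sc, grid = grid)
      w <- if (identical(weights_from, "boltzmann")) {
        en <- vapply(sticks, `[[`, 0, "energy")
        boltzmann_weights(en, temperature =
                            if (is.null(sp$temperature)) 300 else sp$temperature)
      } else {
        ids <- names(sticks)
        cl <- suppressWarnings(as.integer(sub("^cluster_", "", ids)))
        if (anyNA(cl)) rep(1 / length(sticks), length(sticks))
        else model$populations[cl] / sum(model$populations[cl])
      }
      weighted_average(specs, w)
    }
    weighting <- if (is.null(sp$weighting)) "population" else sp$weighting
    if (!is.null(sp$sticks)) {
      sticks <- stage("spectra", read_sticks_csv(sp$sticks))
      comp <- stage("spectra", assemble(sticks, weighting))
      write_spectrum_csv(comp, file.path(outdir, "composite_ensemble.csv"))
      report$spectra <- "composite_ensemble.csv"
    }
    if (!is.null(sp$monomer_sticks) && !is.null(sp$dimer_sticks)) {
      mono <- stage("spectra",
                    assemble(read_sticks_csv(sp$monomer_sticks), weighting))
      dime <- stage("spectra",
                    assemble(read_sticks_csv(sp$dimer_sticks), weighting))
      if (is.null(sp$K) || is.null(sp$c))
        stop("equilibrium mixing needs spectra$K and spectra$c")
      mix <- stage("spectra", mix_monomer_dimer(
        mono, dime, K = sp$K, c = sp$c,
        dimer_normalization = sp$dimer_normalization))
      write_spectrum_csv(mono, file.path(outdir, "composite_monomer.csv"))
      write_spectrum_csv(dime, file.path(outdir, "composite_dimer.csv"))
      write_spectrum_csv(mix, file.path(outdir, "composite_mixed.csv"))
      report$equilibrium <- list(K = sp$K, c = sp$c,
                                 monomer_fraction =
                                   equilibrium_fractions(sp$K, sp$c)$monomer_fraction)
    }
  }

  cfg_out <- unclass(config)
  jsonlite::write_json(cfg_out, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
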