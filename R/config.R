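#' Assemble and validate a run configuration
#'
#' A run configuration bundles driver, model and (optionally) glycolysis
#' parameters with the simulation protocol settings. All omitted fields take
#' the published defaults; every sub-object is validated on construction.
#'
#' @param driver Named list of [driver_params()] fields.
#' @param model Named list of [model_params()] fields.
#' @param glycolysis Named list of [glycolysis_params()] fields, or
#'   \code{NULL} for the core (algebraic glycolytic pool) model.
#' @param init Initial pool state \code{c(p1, p2, p3)}.
#' @param p0_init Initial glycolytic level for the extended model.
#' @param n_periods,n_discard,dt_out,tol Simulation protocol settings.
#' @return A list of class \code{"dam_config"}.
#' @export
dam_config <- function(driver = list(), model = list(), glycolysis = NULL,
                       init = default_init(), p0_init = 0.29,
                       n_periods = 10, n_discard = 5,
                       dt_out = NULL, tol = 1e-10) {
  dp <- do.call(driver_params, check_known_keys(driver, driver_params,
                                                "driver"))
  mp <- do.call(model_params, check_known_keys(model, model_params,
                                               "model"))
  gp <- if (is.null(glycolysis)) NULL else {
    do.call(glycolysis_params,
            check_known_keys(glycolysis, glycolysis_params, "glycolysis"))
  }
  init <- check_pool_state(unlist(init))
  if (is.null(dt_out)) dt_out <- dp$T0 / 1000
  if (n_periods < 1 || n_discard < 0 || n_periods < n_discard + 1) {
    stop("need n_periods >= n_discard + 1 >= 1", call. = FALSE)
  }
  if (dt_out <= 0 || tol <= 0) {
    stop("`dt_out` and `tol` must be positive", call. = FALSE)
  }
  structure(list(driver = dp, model = mp, glycolysis = gp, init = init,
                 p0_init = p0_init, n_periods = n_periods,
                 n_discard = n_discard, dt_out = dt_out, tol = tol),
            class = "dam_config")
}

check_known_keys <- function(x, constructor, what) {
  if (length(x) == 0) return(list())
  known <- names(formals(constructor))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0 || is.null(names(x)) || any(names(x) == "")) {
    stop("unknown ", what, " key(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are \code{driver}, \code{model}, \code{glycolysis},
#' \code{init}, \code{p0_init}, \code{n_periods}, \code{n_discard},
#' \code{dt_out}, \code{tol}; any unknown key, at any level, is an error
#' naming the key. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A validated \code{dam_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(dam_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(dam_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param cfg A \code{dam_config}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dam_config"))
  out <- list(
    driver = unclass(cfg$driver),
    model = unclass(cfg$model),
    init = as.list(cfg$init),
    p0_init = cfg$p0_init,
    n_periods = cfg$n_periods, n_discard = cfg$n_discard,
    dt_out = cfg$dt_out, tol = cfg$tol
  )
  if (!is.null(cfg$glycolysis)) out$glycolysis <- unclass(cfg$glycolysis)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' Changes iff any effective parameter value changes; stamped into result
#' sidecars so outputs are traceable to their configuration.
#'
#' @param cfg A \code{dam_config}.
#' @return A character hash.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "dam_config"))
  canon <- rapply(unclass(cfg), function(x) signif(as.numeric(x), 15),
                  classes = "ANY", how = "list")
  rlang::hash(canon)
}

#' Run a configuration
#'
#' Dispatches to [simulate_dam()] or [simulate_dam_extended()] depending on
#' whether the configuration carries glycolysis parameters.
#'
#' @param cfg A \code{dam_config}.
#' @return A \code{dam_trajectory}.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "dam_config"))
  if (is.null(cfg$glycolysis)) {
    simulate_dam(cfg$model, cfg$driver, cfg$init, cfg$n_periods,
                 cfg$dt_out, cfg$tol)
  } else {
    simulate_dam_extended(cfg$model, cfg$driver, cfg$glycolysis, cfg$init,
                          cfg$p0_init, cfg$n_periods, cfg$dt_out, cfg$tol)
  }
}

#' Write a trajectory as delimited text
#'
#' Columns \code{t,p0,p1,p2,p3,ca,atp,nadh,j01,j21,j12,j13,j32} in CSV. A
#' JSON sidecar (same path with extension \code{.json}) records the
#' amplitude summary and, when supplied, the configuration hash.
#'
#' @param traj A \code{dam_trajectory}.
#' @param path Output CSV path.
#' @param cfg Optional \code{dam_config} used to produce the trajectory.
#' @param n_discard Burn-in periods for the sidecar amplitude summary.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path, cfg = NULL, n_discard = 5) {
  cols <- c("t", "p0", "p1", "p2", "p3", "ca", "atp", "nadh",
            "j01", "j21", "j12", "j13", "j32")
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  amps <- tryCatch(periodic_amplitudes(traj, n_discard = n_discard),
                   error = function(e) NULL)
  sidecar <- list(
    amplitudes = if (is.null(amps)) NULL else as.data.frame(amps),
    config_hash = if (is.null(cfg)) NULL else config_hash(cfg)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0(".json")
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A tibble (without parameter attributes).
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a sweep table as delimited text
#'
#' One row per grid value; the nested per-pool amplitude summaries go to a
#' JSON sidecar.
#'
#' @param result A \code{dam_sweep}.
#' @param path Output CSV path.
#' @param cfg Optional \code{dam_config}.
#' @return The path, invisibly.
#' @export
write_sweep <- function(result, path, cfg = NULL) {
  flat <- as.data.frame(dplyr::select(result, -"amplitudes"))
  utils::write.csv(flat, path, row.names = FALSE)
  sidecar <- list(
    param = attr(result, "param"),
    amplitudes = purrr::map(result$amplitudes, function(a) {
      if (is.null(a)) NULL else as.data.frame(a)
    }),
    config_hash = if (is.null(cfg)) NULL else config_hash(cfg)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Export the driver signals as delimited text
#'
#' Header \code{t,ca,atp,nadh}; all series dimensionless.
#'
#' @param dp A [driver_params()] object.
#' @param t_grid Time grid.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_driver_trace <- function(dp, t_grid, path) {
  utils::write.csv(as.data.frame(driver_trace(dp, t_grid)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Generate the default fixture files
#'
#' Emits the default driver trace and a down-sampled reference trajectory of
#' the default run into \code{dir}, for use as small plain-text test
#' fixtures.
#'
#' @param dir Output directory (created if missing).
#' @param dt Grid spacing of the emitted files (default 0.01, coarse enough
#'   to keep fixtures small).
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, dt = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dp <- driver_params()
  drv <- file.path(dir, "driver_trace.csv")
  write_driver_trace(dp, seq(0, 2 * dp$T0, by = dt), drv)
  traj <- simulate_dam(n_periods = 7, dt_out = dt)
  ref <- file.path(dir, "reference_trajectory.csv")
  write_trajectory(traj, ref)
  invisible(c(drv, ref))
}

#' Published per-pool oscillation amplitudes
#'
#' The reported final-period oscillation spans of the four pools under the
#' default parameters, used as the comparison column by
#' [report_amplitudes()] and by the regression tests.
#'
#' @return A tibble with columns \code{pool} and \code{reference}.
#' @export
dam_reference_amplitudes <- function() {
  tibble::tibble(
    pool = c("p0", "p1", "p2", "p3"),
    reference = c(0.20, 0.22, 0.16, 0.18)
  )
}

#' Compare simulated amplitudes with the published values
#'
#' @param amps A \code{dam_amplitudes} table (or a \code{dam_trajectory},
#'   which is summarised first).
#' @param tolerance Absolute tolerance of the comparison (default 0.01).
#' @return A tibble with columns \code{pool}, \code{amplitude},
#'   \code{reference}, \code{pass}.
#' @export
report_amplitudes <- function(amps, tolerance = 0.01) {
  if (inherits(amps, "dam_trajectory")) amps <- periodic_amplitudes(amps)
  out <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(amps), "pool", "amplitude"),
    dam_reference_amplitudes(), by = "pool"
  )
  dplyr::mutate(out, pass = abs(.data$amplitude - .data$reference) <=
                  tolerance)
}
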