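#' Parameter and phase-offset sweeps
#'
#' Each sweep re-runs the default simulation protocol over a grid of one
#' quantity and collects, per grid value, the final-period amplitude summary,
#' extremum phases and qualitative flags:
#' \describe{
#'   \item{\code{bounded}}{all pool series finite and within the conserved
#'     total,}
#'   \item{\code{periodic}}{every pool closes on itself over the final
#'     period to 1e-3 (the [periodic_amplitudes()] criterion),}
#'   \item{\code{n_sign_changes}}{number of sign changes of \eqn{dP_1/dt}
#'     per period (2 for a simple oxidative/cataplerotic alternation).}
#' }
#' Rows for grid values where the solver fails are kept and flagged rather
#' than aborting the sweep. Amplitude columns (\code{amp_p0} ...
#' \code{amp_p3}, \code{tmax_p1}, \code{tmin_p1}) are reported from the
#' final period even when the periodicity flag is off (e.g. a monotone
#' drift), so limiting cases remain inspectable; the full per-pool summary
#' sits in the \code{amplitudes} list-column.
#'
#' \code{sweep_k32()} varies the GABA-shunt rate constant;
#' \code{sweep_tau_nadh()} varies the phase offset of the redox proxy
#' relative to ATP; \code{sweep_tau_atp()} varies the phase offset of ATP
#' (and NADH with it) relative to the calcium pulse onset.
#'
#' @param grid Strictly increasing grid of parameter values; defaults
#'   bracket the qualitative regimes (\code{c(0, 0.25, 0.5, 1, 2, 4)} for
#'   the rate constant, \code{c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2) * T0}
#'   for the phase offsets).
#' @param mp,dp Base model and driver parameters.
#' @param init Initial pool state.
#' @param n_periods,n_discard,dt_out,tol Simulation protocol settings, as in
#'   [simulate_dam()] / [periodic_amplitudes()].
#' @return A tibble of class \code{"dam_sweep"}, one row per grid value,
#'   with attribute \code{param} naming the swept quantity.
#' @seealso [simulate_dam()], [periodic_amplitudes()]
#' @export
#' @examples
#' sw <- sweep_k32(c(0.5, 1, 2), n_periods = 8)
#' sw[, c("value", "periodic", "amp_p1")]
sweep_k32 <- function(grid = c(0, 0.25, 0.5, 1, 2, 4),
                      mp = model_params(), dp = driver_params(),
                      init = default_init(), n_periods = 10, n_discard = 5,
                      dt_out = dp$T0 / 1000, tol = 1e-10) {
  check_grid(grid, min = 0)
  run_sweep(grid, "k32", mp, dp, init, n_periods, n_discard, dt_out, tol,
            function(v, mp, dp) {
              mp$k32 <- v
              list(mp = mp, dp = dp)
            })
}

#' @rdname sweep_k32
#' @export
sweep_tau_nadh <- function(grid = c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2) *
                             dp$T0,
                           mp = model_params(), dp = driver_params(),
                           init = default_init(), n_periods = 10,
                           n_discard = 5, dt_out = dp$T0 / 1000,
                           tol = 1e-10) {
  check_grid(grid, min = -dp$T0 / 2, max = dp$T0, name = "tau_nadh")
  run_sweep(grid, "tau_nadh", mp, dp, init, n_periods, n_discard, dt_out,
            tol,
            function(v, mp, dp) {
              dp$tau_nadh <- v
              list(mp = mp, dp = dp)
            })
}

#' @rdname sweep_k32
#' @export
sweep_tau_atp <- function(grid = c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2) *
                            dp$T0,
                          mp = model_params(), dp = driver_params(),
                          init = default_init(), n_periods = 10,
                          n_discard = 5, dt_out = dp$T0 / 1000,
                          tol = 1e-10) {
  check_grid(grid, min = -dp$T0 / 2, max = dp$T0, name = "tau_atp")
  run_sweep(grid, "tau_atp", mp, dp, init, n_periods, n_discard, dt_out,
            tol,
            function(v, mp, dp) {
              dp$tau_atp <- v
              list(mp = mp, dp = dp)
            })
}

check_grid <- function(grid, min = -Inf, max = Inf, name = "grid") {
  if (!is.numeric(grid) || length(grid) < 1 || any(!is.finite(grid))) {
    stop("`grid` must be finite numeric", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (any(grid < min) || any(grid > max)) {
    stop(name, " grid values must lie in [", min, ", ", max, "]",
         call. = FALSE)
  }
  invisible(grid)
}

run_sweep <- function(grid, param, mp, dp, init, n_periods, n_discard,
                      dt_out, tol, apply_value) {
  total <- sum(check_pool_state(init))
  rows <- purrr::map_dfr(grid, function(v) {
    pars <- apply_value(v, mp, dp)
    res <- tryCatch(
      simulate_dam(pars$mp, pars$dp, init, n_periods, dt_out, tol),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(
        param = param, value = v, ok = FALSE,
        bounded = NA, periodic = NA, n_sign_changes = NA_integer_,
        amp_p0 = NA_real_, amp_p1 = NA_real_, amp_p2 = NA_real_,
        amp_p3 = NA_real_, tmax_p1 = NA_real_, tmin_p1 = NA_real_,
        amplitudes = list(NULL), message = conditionMessage(res)
      ))
    }
    T0 <- pars$dp$T0
    win <- final_period(res, T0)
    periodic <- all(vapply(c("p0", "p1", "p2", "p3"), function(pool) {
      abs(win[[pool]][nrow(win)] - win[[pool]][1]) < 1e-3
    }, logical(1)))
    bounded <- all(is.finite(as.matrix(win[, c("p0", "p1", "p2", "p3")]))) &&
      max(win$p1, win$p2, win$p3) <= total + 1e-6
    amps <- amplitude_table(win, T0)
    ann <- suppressWarnings(annotate_phases(res, T0))
    tibble::tibble(
      param = param, value = v, ok = TRUE,
      bounded = bounded, periodic = periodic,
      n_sign_changes = attr(ann, "n_sign_changes"),
      amp_p0 = amps$amplitude[amps$pool == "p0"],
      amp_p1 = amps$amplitude[amps$pool == "p1"],
      amp_p2 = amps$amplitude[amps$pool == "p2"],
      amp_p3 = amps$amplitude[amps$pool == "p3"],
      tmax_p1 = amps$t_max[amps$pool == "p1"],
      tmin_p1 = amps$t_min[amps$pool == "p1"],
      amplitudes = list(amps), message = NA_character_
    )
  })
  structure(rows, class = c("dam_sweep", class(rows)), param = param,
            n_periods = n_periods, n_discard = n_discard)
}
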