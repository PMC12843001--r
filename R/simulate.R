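#' Simulate the four-pool model
#'
#' Integrates the driven pool system over \code{n_periods} forcing periods
#' with an adaptive stiff-capable solver (lsoda), restarted at every branch
#' boundary of the piecewise calcium driver so the discontinuity never
#' degrades the integration order. The calcium driver is solved jointly with
#' the pools; ATP and NADH are evaluated in closed form. Time zero is the
#' onset of the calcium pulse.
#'
#' @param mp A [model_params()] object.
#' @param dp A [driver_params()] object.
#' @param init Initial pool state \code{c(p1, p2, p3)}; default
#'   [default_init()].
#' @param n_periods Number of forcing periods to simulate (default 10).
#' @param dt_out Output grid spacing (default \code{T0/1000}); integration is
#'   adaptive internally, the solution is reported on this grid.
#' @param tol Solver relative and absolute tolerance (default 1e-10).
#' @return A tibble of class \code{"dam_trajectory"} with columns
#'   \code{t, p0, p1, p2, p3, ca, atp, nadh, j01, j21, j12, j13, j32}.
#'   The parameter objects are carried as attributes.
#' @seealso [periodic_amplitudes()], [annotate_phases()], [flux_trace()],
#'   [simulate_dam_extended()]
#' @export
#' @examples
#' traj <- simulate_dam(n_periods = 6)
#' periodic_amplitudes(traj)
simulate_dam <- function(mp = model_params(), dp = driver_params(),
                         init = default_init(), n_periods = 10,
                         dt_out = dp$T0 / 1000, tol = 1e-10) {
  init <- check_pool_state(init)
  if (n_periods < 1) stop("`n_periods` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)

  t_grid <- seq(0, n_periods * dp$T0, by = dt_out)
  y0 <- c(ca = dp$ca_init, init)
  sol <- integrate_piecewise(
    y0 = y0, t_grid = t_grid, p = dp, tol = tol,
    rhs = function(t, y, branch) {
      atp <- atp_norm(t, dp)
      nadh <- atp_norm(t + dp$tau_nadh, dp)
      p0 <- mp$k0_p0 + mp$k0A * atp
      list(pool_rates_raw(y, t, branch, mp, dp, nadh, p0))
    }
  )
  traj <- assemble_trajectory(sol, mp, dp, p0_dynamic = FALSE)
  check_conservation(traj, sum(init))
  structure(traj,
            class = c("dam_trajectory", class(traj)),
            model_params = mp, driver_params = dp, init = init,
            n_periods = n_periods, dt_out = dt_out, tol = tol,
            extended = FALSE)
}

# rates of (ca, [p0,] p1, p2, p3) for a fixed driver branch; no validation,
# called from inside the integrator
pool_rates_raw <- function(y, t, branch, mp, dp, nadh, p0, j0 = NULL) {
  ca <- y[[1]]
  n <- length(y)
  p1 <- y[[n - 2]]; p2 <- y[[n - 1]]; p3 <- y[[n]]
  j01 <- mp$k01 * ca * p2 * p0
  j12 <- mp$k12 * p1 * nadh^2
  j13 <- mp$k13 * p1 * nadh^2
  j32 <- mp$k32 * p3 * (1 - nadh)
  dca <- branch_ca_rate(ca, branch, dp)
  dpools <- c(j01 - j12 - j13, j12 - j01 + j32, j13 - j32)
  if (is.null(j0)) c(dca, dpools) else c(dca, j0 - j01, dpools)
}

assemble_trajectory <- function(sol, mp, dp, p0_dynamic) {
  t <- sol[, "time"]
  atp <- atp_norm(t, dp)
  nadh <- nadh_norm(t, dp)
  p0 <- if (p0_dynamic) sol[, "p0"] else p0_level(atp, mp)
  fl <- dam_fluxes(sol[, "ca"], atp, nadh,
                   sol[, "p1"], sol[, "p2"], sol[, "p3"], mp, p0 = p0)
  tibble::tibble(
    t = t, p0 = unname(p0),
    p1 = sol[, "p1"], p2 = sol[, "p2"], p3 = sol[, "p3"],
    ca = sol[, "ca"], atp = atp, nadh = nadh,
    j01 = fl$j01, j21 = fl$j21, j12 = fl$j12, j13 = fl$j13, j32 = fl$j32
  )
}

check_conservation <- function(traj, total, limit = 1e-4) {
  drift <- max(abs(traj$p1 + traj$p2 + traj$p3 - total))
  if (drift > limit) {
    stop("carbon conservation drift ", signif(drift, 3),
         " exceeds ", limit, "; tighten `tol`", call. = FALSE)
  }
  invisible(drift)
}

#' Per-pool oscillation amplitudes on the attained periodic orbit
#'
#' Extracts, for each pool, the max minus min over the final full forcing
#' period together with the phase positions (in \eqn{[0, T_0)}) of the
#' extrema. Errors if the trajectory is too short or if any pool fails the
#' periodicity check \eqn{|x(t_{end}) - x(t_{end} - T_0)| < 10^{-3}}
#' (transient not yet decayed).
#'
#' @param traj A \code{dam_trajectory} from [simulate_dam()] or
#'   [simulate_dam_extended()].
#' @param T0 Forcing period; defaults to the period stored in the
#'   trajectory's driver parameters.
#' @param n_discard Number of burn-in periods that must precede the analysed
#'   period (default 5).
#' @return A tibble of class \code{"dam_amplitudes"} with one row per pool
#'   (\code{p0}--\code{p3}) and columns \code{pool}, \code{amplitude},
#'   \code{t_max}, \code{t_min}.
#' @export
periodic_amplitudes <- function(traj, T0 = NULL, n_discard = 5) {
  if (is.null(T0)) T0 <- attr(traj, "driver_params")$T0
  if (is.null(T0)) stop("supply `T0` for trajectories without stored driver ",
                        "parameters", call. = FALSE)
  t_end <- max(traj$t)
  if (t_end < (n_discard + 1) * T0 - 1e-9) {
    stop("trajectory must span at least n_discard + 1 = ", n_discard + 1,
         " periods", call. = FALSE)
  }
  win <- final_period(traj, T0)
  for (pool in c("p0", "p1", "p2", "p3")) {
    gap <- abs(win[[pool]][nrow(win)] - win[[pool]][1])
    if (gap >= 1e-3) {
      stop("pool `", pool, "` is not periodic to 1e-3 over the final period ",
           "(gap ", signif(gap, 3), "); transient has not decayed",
           call. = FALSE)
    }
  }
  out <- amplitude_table(win, T0)
  structure(out, class = c("dam_amplitudes", class(out)), T0 = T0)
}

final_period <- function(traj, T0) {
  t_end <- max(traj$t)
  dplyr::filter(traj, .data$t >= t_end - T0 - 1e-12)
}

# max-min and extremum phases per pool over a one-period window; no
# periodicity requirement (used by sweeps to report non-periodic rows too)
amplitude_table <- function(win, T0) {
  t0 <- win$t[1]
  purrr::map_dfr(c("p0", "p1", "p2", "p3"), function(pool) {
    x <- win[[pool]]
    tibble::tibble(
      pool = pool,
      amplitude = max(x) - min(x),
      t_max = (win$t[which.max(x)] - t0) %% T0,
      t_min = (win$t[which.min(x)] - t0) %% T0
    )
  })
}

#' Label oxidative and cataplerotic phases of the cycle
#'
#' Partitions the final forcing period into intervals of net filling
#' (\code{mito_ox}, \eqn{dP_1/dt > 0}: calcium-stimulated oxidative inflow
#' dominates) and net emptying (\code{mito_cat}, \eqn{dP_1/dt < 0}:
#' cataplerotic export dominates) of the right-TCA pool. The sign of
#' \eqn{dP_1/dt = J_{21} - J_{12} - J_{13}} is the package's operational
#' definition of the phase boundary. More than two sign changes per period
#' (possible with shifted drivers) triggers a warning, not an error. A
#' steady trajectory (all rates numerically zero) yields zero rows.
#'
#' @inheritParams periodic_amplitudes
#' @return A tibble of class \code{"dam_phases"} with columns \code{label},
#'   \code{start}, \code{end} (phase positions in \eqn{[0, T_0]}), plus an
#'   attribute \code{n_sign_changes}.
#' @export
annotate_phases <- function(traj, T0 = NULL) {
  if (is.null(T0)) T0 <- attr(traj, "driver_params")$T0
  win <- final_period(traj, T0)
  rate <- win$j21 - win$j12 - win$j13
  phase <- (win$t - win$t[1])
  out <- tibble::tibble(label = character(), start = numeric(),
                        end = numeric())
  if (max(abs(rate)) < 1e-8) {
    return(structure(out, class = c("dam_phases", class(out)),
                     n_sign_changes = 0L, T0 = T0))
  }
  lab <- ifelse(rate > 0, "mito_ox", "mito_cat")
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- tibble::tibble(
    label = runs$values,
    start = phase[starts],
    end = c(phase[ends[-length(ends)] + 1L], T0)
  )
  n_changes <- length(runs$values) - 1L +
    as.integer(runs$values[1] != runs$values[length(runs$values)])
  if (n_changes > 2L) {
    warning("dP1/dt changes sign ", n_changes,
            " times in one period; phase annotation may be fragmented",
            call. = FALSE)
  }
  structure(out, class = c("dam_phases", class(out)),
            n_sign_changes = n_changes, T0 = T0)
}

#' Recompute the flux vector along a trajectory
#'
#' Re-evaluates all five fluxes from the stored pool and driver series,
#' independent of the values the integrator emitted; useful as a consistency
#' oracle.
#'
#' @param traj A \code{dam_trajectory}.
#' @param mp Model parameters; defaults to those stored in the trajectory.
#' @return A tibble with columns \code{t, j01, j21, j12, j13, j32}.
#' @export
flux_trace <- function(traj, mp = NULL) {
  if (is.null(mp)) mp <- attr(traj, "model_params")
  fl <- dam_fluxes(traj$ca, traj$atp, traj$nadh,
                   traj$p1, traj$p2, traj$p3, mp, p0 = traj$p0)
  dplyr::bind_cols(tibble::tibble(t = traj$t), fl)
}
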