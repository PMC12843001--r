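#' Normalized ATP waveform
#'
#' Evaluates the prescribed sinusoidal energy signal
#' \eqn{ATP(t) = A_0 + A_1 (1 + \cos(2\pi (t + \tau_{ATP}) / T_0))}.
#' With the defaults the waveform spans exactly [0, 1], peaking at the onset
#' of each calcium pulse (t = 0 mod T0) and reaching its minimum half a
#' period later.
#'
#' @param t Time (vectorized), dimensionless.
#' @param p A [driver_params()] object.
#' @return Numeric vector of ATP levels in \eqn{[A_0, A_0 + 2 A_1]}.
#' @export
#' @examples
#' atp_norm(seq(0, 1, by = 0.25), driver_params())
atp_norm <- function(t, p = driver_params()) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric", call. = FALSE)
  }
  p$A0 + p$A1 * (1 + cos(2 * pi * (t + p$tau_atp) / p$T0))
}

#' Normalized NADH (redox) proxy
#'
#' The redox signal is the ATP waveform shifted by \code{tau_nadh}:
#' \eqn{NADH(t) = ATP(t + \tau_{NADH})}. With \code{tau_nadh = 0} the two
#' signals are identical, reflecting tight coupling of the energy and redox
#' states through oxidative phosphorylation; a positive offset makes NADH
#' lead ATP.
#'
#' @inheritParams atp_norm
#' @return Numeric vector of NADH levels in [0, 1] for default amplitudes.
#' @export
nadh_norm <- function(t, p = driver_params()) {
  atp_norm(t + p$tau_nadh, p)
}

#' Right-hand side of the calcium driver ODE
#'
#' The pulsatile calcium signal obeys a piecewise-linear relaxation ODE with
#' three branches per period, selected by \code{t mod T0} (right-continuous
#' at the switch times):
#' \deqn{dCa/dt = k_0 (1 - Ca) \ \mathrm{on}\ [0, t_1),\quad
#'       -k_1 (1 - Ca) \ \mathrm{on}\ [t_1, t_2),\quad
#'       -k_2 \, Ca \ \mathrm{on}\ [t_2, T_0).}
#'
#' @param ca Calcium level (vectorized with \code{t}).
#' @param t Time.
#' @param p A [driver_params()] object.
#' @return The branch rate at each time point.
#' @export
#' @examples
#' ca_rhs(0, 0.1, driver_params())   # fast rise: 22
#' ca_rhs(1, 0.7, driver_params())   # decay branch: -10
ca_rhs <- function(ca, t, p = driver_params()) {
  if (any(!is.finite(ca)) || any(!is.finite(t))) {
    stop("`ca` and `t` must be finite", call. = FALSE)
  }
  tt <- t %% p$T0
  b <- ca_branch(tt, p)
  rate <- numeric(length(b))
  rate[b == 1L] <- p$k0_ca * (1 - ca[b == 1L])
  rate[b == 2L] <- -p$k1_ca * (1 - ca[b == 2L])
  rate[b == 3L] <- -p$k2_ca * ca[b == 3L]
  rate
}

# branch index for phase time tt in [0, T0)
ca_branch <- function(tt, p) {
  ifelse(tt < p$t1, 1L, ifelse(tt < p$t2, 2L, 3L))
}

# breakpoints of the piecewise driver within [from, to]
ca_breakpoints <- function(from, to, p) {
  k <- seq(floor(from / p$T0) - 1, ceiling(to / p$T0) + 1)
  bp <- sort(unique(c(outer(k * p$T0, c(0, p$t1, p$t2), `+`))))
  bp[bp > from + 1e-12 & bp < to - 1e-12]
}

#' Solve the calcium driver ODE on a time grid
#'
#' Integrates the piecewise relaxation ODE with an adaptive stiff-capable
#' solver, restarted at every branch switch so that the discontinuous
#' right-hand side never crosses an integration step. With the default rates
#' (22, 15, 10) transients collapse within one period and the solution is
#' periodic to well below 1e-4 afterwards.
#'
#' @param p A [driver_params()] object.
#' @param t_grid Strictly increasing time grid.
#' @param tol Relative/absolute integration tolerance (default 1e-10).
#' @return A tibble with columns \code{t} and \code{ca}.
#' @export
#' @examples
#' ca <- solve_ca(driver_params(), seq(0, 2, by = 0.001))
#' range(ca$ca)
solve_ca <- function(p = driver_params(), t_grid, tol = 1e-10) {
  sol <- integrate_piecewise(
    y0 = c(ca = p$ca_init), t_grid = t_grid, p = p, tol = tol,
    rhs = function(t, y, branch) {
      list(branch_ca_rate(y[["ca"]], branch, p))
    }
  )
  tibble::tibble(t = sol[, "time"], ca = sol[, "ca"])
}

# smooth per-branch calcium rate (branch fixed, no mod-time test)
branch_ca_rate <- function(ca, branch, p) {
  switch(branch,
         p$k0_ca * (1 - ca),
         -p$k1_ca * (1 - ca),
         -p$k2_ca * ca)
}

# Integrate an ODE whose RHS is smooth within each branch of the calcium
# driver, restarting lsoda at every branch boundary. `rhs(t, y, branch)`
# must return list(dy). Returns the deSolve matrix restricted to t_grid.
integrate_piecewise <- function(y0, t_grid, p, rhs, tol = 1e-10) {
  if (any(diff(t_grid) <= 0)) {
    stop("`t_grid` must be strictly increasing", call. = FALSE)
  }
  from <- t_grid[1]
  to <- t_grid[length(t_grid)]
  cuts <- c(from, ca_breakpoints(from, to, p), to)
  y <- y0
  out <- matrix(numeric(0), ncol = length(y0) + 1,
                dimnames = list(NULL, c("time", names(y0))))
  grid_done <- 0L
  for (i in seq_len(length(cuts) - 1)) {
    a <- cuts[i]; b <- cuts[i + 1]
    branch <- ca_branch(((a + b) / 2) %% p$T0, p)
    inside <- t_grid[t_grid > a + 1e-13 & t_grid < b - 1e-13]
    times <- unique(c(a, inside, b))
    seg <- deSolve::lsoda(
      y = y, times = times, parms = NULL,
      func = function(t, y, parms) rhs(t, y, branch),
      rtol = tol, atol = tol
    )
    if (attr(seg, "istate")[1] < 0) {
      stop("ODE solver failed on [", signif(a, 6), ", ", signif(b, 6),
           "]: istate = ", attr(seg, "istate")[1], call. = FALSE)
    }
    keep <- seg[, "time"] %in% t_grid |
      vapply(seg[, "time"], function(tt) any(abs(tt - t_grid) < 1e-12),
             logical(1))
    out <- rbind(out, unclass(seg)[keep, , drop = FALSE])
    y <- seg[nrow(seg), -1]
    names(y) <- names(y0)
  }
  # de-duplicate grid points that coincide with segment ends
  out <- out[!duplicated(round(out[, "time"], 12)), , drop = FALSE]
  stopifnot(nrow(out) == length(t_grid))
  out
}

#' Tabulate the driver signals on a grid
#'
#' Convenience wrapper producing all three forcing signals at once:
#' numerically integrated calcium plus the closed-form ATP and NADH
#' waveforms.
#'
#' @inheritParams solve_ca
#' @return A tibble with columns \code{t}, \code{ca}, \code{atp},
#'   \code{nadh}.
#' @export
driver_trace <- function(p = driver_params(), t_grid, tol = 1e-10) {
  sol <- solve_ca(p, t_grid, tol = tol)
  tibble::tibble(
    t = sol$t,
    ca = sol$ca,
    atp = atp_norm(sol$t, p),
    nadh = nadh_norm(sol$t, p)
  )
}
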