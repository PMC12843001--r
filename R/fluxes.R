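#' Algebraic glycolytic pool level
#'
#' In the core model the glycolytic pool (FBP/PEP) is slaved to the energy
#' state: \eqn{P_0 = k_{0,p0} + k_{0A} \cdot ATP}. With defaults it spans
#' [0.1, 0.3] as ATP spans [0, 1].
#'
#' @param atp ATP level in [0, 1] (vectorized).
#' @param p A [model_params()] object.
#' @return Glycolytic pool level.
#' @export
p0_level <- function(atp, p = model_params()) {
  check_unit_interval(atp, "atp")
  p$k0_p0 + p$k0A * atp
}

#' Pyruvate-dehydrogenase inflow flux
#'
#' Calcium-stimulated carbon entry into the right-TCA pool:
#' \eqn{J_{01} = k_{01} \, Ca \, P_2 \, P_0}. Citrate synthase consumes one
#' oxaloacetate (from the left-TCA pool) per acetyl-CoA, so the companion
#' flux \eqn{J_{21}} equals \eqn{J_{01}} identically; use [flux_j21()] for
#' the alias.
#'
#' @param ca Calcium level (>= 0).
#' @param p2 Left-TCA pool level (>= 0).
#' @param p0 Glycolytic pool level (>= 0).
#' @param p A [model_params()] object.
#' @return Non-negative flux.
#' @export
flux_j01 <- function(ca, p2, p0, p = model_params()) {
  check_nonneg(ca, "ca"); check_nonneg(p2, "p2"); check_nonneg(p0, "p0")
  p$k01 * ca * p2 * p0
}

#' @rdname flux_j01
#' @export
flux_j21 <- function(ca, p2, p0, p = model_params()) {
  flux_j01(ca, p2, p0, p)
}

#' Citrate--malate exchange flux
#'
#' Redox-gated cataplerotic redistribution from the right- to the left-TCA
#' pool: \eqn{J_{12} = k_{12} \, P_1 \, NADH^2}. The quadratic redox
#' dependence acts as a switch favouring citrate export under highly reduced
#' conditions.
#'
#' @param p1 Right-TCA pool level (>= 0).
#' @param nadh Redox proxy in [0, 1].
#' @param p A [model_params()] object.
#' @return Non-negative flux.
#' @export
flux_j12 <- function(p1, nadh, p = model_params()) {
  check_nonneg(p1, "p1"); check_unit_interval(nadh, "nadh")
  p$k12 * p1 * nadh^2
}

#' GABA-replenishing cataplerotic flux
#'
#' Redox-gated carbon transfer from the right-TCA pool to the GABA pool via
#' alpha-ketoglutarate, glutamate and C4 counter-transport:
#' \eqn{J_{13} = k_{13} \, P_1 \, NADH^2}.
#'
#' @inheritParams flux_j12
#' @return Non-negative flux.
#' @export
flux_j13 <- function(p1, nadh, p = model_params()) {
  check_nonneg(p1, "p1"); check_unit_interval(nadh, "nadh")
  p$k13 * p1 * nadh^2
}

#' GABA-shunt anaplerotic flux
#'
#' Carbon entry into the left-TCA pool from the GABA reservoir via
#' succinate, inhibited by the reduced state:
#' \eqn{J_{32} = k_{32} \, P_3 \, (1 - NADH)}; fully blocked at NADH = 1.
#'
#' @param p3 GABA pool level (>= 0).
#' @inheritParams flux_j12
#' @return Non-negative flux.
#' @export
flux_j32 <- function(p3, nadh, p = model_params()) {
  check_nonneg(p3, "p3"); check_unit_interval(nadh, "nadh")
  p$k32 * p3 * (1 - nadh)
}

#' All five inter-pool fluxes at once
#'
#' Evaluates the full flux vector from pool levels and driver signals.
#' When \code{p0} is \code{NULL} (the core model) the glycolytic level is the
#' algebraic function [p0_level()] of ATP; pass a dynamic \code{p0} for the
#' extended model.
#'
#' @param ca,atp,nadh Driver levels (vectorized together).
#' @param p1,p2,p3 Pool levels.
#' @param p A [model_params()] object.
#' @param p0 Optional dynamic glycolytic pool level.
#' @return A tibble with columns \code{j01}, \code{j21}, \code{j12},
#'   \code{j13}, \code{j32}.
#' @export
dam_fluxes <- function(ca, atp, nadh, p1, p2, p3, p = model_params(),
                       p0 = NULL) {
  if (is.null(p0)) p0 <- p0_level(atp, p)
  j01 <- flux_j01(ca, p2, p0, p)
  tibble::tibble(
    j01 = j01,
    j21 = j01,
    j12 = flux_j12(p1, nadh, p),
    j13 = flux_j13(p1, nadh, p),
    j32 = flux_j32(p3, nadh, p)
  )
}

#' Pool balance equations
#'
#' Net rates of the three dynamic pools given the current state and driver
#' levels:
#' \deqn{dP_1/dt = J_{21} - J_{12} - J_{13},\quad
#'       dP_2/dt = J_{12} - J_{21} + J_{32},\quad
#'       dP_3/dt = J_{13} - J_{32}.}
#' The three rates telescope to zero: total carbon in \eqn{P_1 + P_2 + P_3}
#' is conserved, making the system quasi-closed (fully oxidized carbon
#' leaves as CO2 and is not tracked).
#'
#' @param state Named numeric vector \code{c(p1, p2, p3)}, non-negative.
#' @param t Time at which the ATP/NADH waveforms are evaluated.
#' @param mp A [model_params()] object.
#' @param dp A [driver_params()] object.
#' @param ca Calcium level at time \code{t} (supply from [solve_ca()] or an
#'   integrator's own calcium state).
#' @return Named numeric vector \code{c(dp1, dp2, dp3)} summing to zero.
#' @export
#' @examples
#' dp <- driver_params()
#' ca0 <- solve_ca(dp, c(0, 1e-6))$ca[1]
#' dam_rhs(default_init(), t = 0, mp = model_params(), dp = dp, ca = ca0)
dam_rhs <- function(state, t, mp = model_params(), dp = driver_params(), ca) {
  state <- check_pool_state(state)
  fl <- dam_fluxes(ca, atp_norm(t, dp), nadh_norm(t, dp),
                   state[["p1"]], state[["p2"]], state[["p3"]], mp)
  c(dp1 = fl$j21 - fl$j12 - fl$j13,
    dp2 = fl$j12 - fl$j21 + fl$j32,
    dp3 = fl$j13 - fl$j32)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", name, "` must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}

check_unit_interval <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1 + 1e-12)) {
    stop("`", name, "` must lie in [0, 1]; out-of-range values indicate a ",
         "misconfigured driver", call. = FALSE)
  }
  invisible(x)
}
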