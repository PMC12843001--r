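#' Parameters of the calcium and ATP forcing signals
#'
#' Constructs the parameter set for the two prescribed, dimensionless input
#' waveforms that drive the pool model: a pulsatile calcium signal defined by
#' a three-branch piecewise relaxation ODE, and a sinusoidal ATP signal
#' \eqn{ATP(t) = A_0 + A_1 (1 + \cos(2\pi t / T_0))}. The normalized redox
#' proxy NADH is the ATP waveform evaluated at \code{t + tau_nadh}, so with
#' the default offsets ATP and NADH are identical and both peak at the onset
#' of the calcium pulse (t = 0 mod T0), anti-phase with the calcium plateau.
#'
#' @param k0_ca Rise rate of the calcium pulse on the first branch
#'   (dimensionless, default 22).
#' @param k1_ca Rate constant of the second branch, \eqn{-k_1 (1 - Ca)}
#'   (default 15).
#' @param k2_ca Decay rate of the third branch, \eqn{-k_2 Ca} (default 10).
#' @param t1,t2 Branch switch times within one period; \eqn{0 < t_1 < t_2 < T_0}
#'   (defaults 0.25 and 0.5).
#' @param T0 Oscillation period in dimensionless time (default 1).
#' @param A0 ATP baseline offset (default 0).
#' @param A1 ATP half-amplitude; the waveform spans \eqn{[A_0, A_0 + 2 A_1]}
#'   (default 0.5).
#' @param tau_nadh Phase offset of the NADH proxy relative to ATP; positive
#'   values make NADH lead (default 0).
#' @param tau_atp Phase offset of the ATP (and hence NADH) waveform relative
#'   to the onset of the calcium pulse; positive values make ATP lead
#'   (default 0).
#' @param ca_init Initial calcium level in [0, 1] (default 0).
#'
#' @return A list of class \code{"driver_params"}.
#' @seealso [atp_norm()], [nadh_norm()], [solve_ca()]
#' @export
#' @examples
#' dp <- driver_params()
#' atp_norm(c(0, 0.25, 0.5), dp)
driver_params <- function(k0_ca = 22, k1_ca = 15, k2_ca = 10,
                          t1 = 0.25, t2 = 0.5, T0 = 1,
                          A0 = 0, A1 = 0.5,
                          tau_nadh = 0, tau_atp = 0, ca_init = 0) {
  p <- list(
    k0_ca = k0_ca, k1_ca = k1_ca, k2_ca = k2_ca,
    t1 = t1, t2 = t2, T0 = T0, A0 = A0, A1 = A1,
    tau_nadh = tau_nadh, tau_atp = tau_atp, ca_init = ca_init
  )
  validate_driver_params(p)
  structure(p, class = "driver_params")
}

validate_driver_params <- function(p) {
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("driver parameter `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$T0 <= 0) stop("`T0` must be positive", call. = FALSE)
  if (!(p$t1 > 0 && p$t1 < p$t2 && p$t2 < p$T0)) {
    stop("branch times must satisfy 0 < t1 < t2 < T0", call. = FALSE)
  }
  for (nm in c("k0_ca", "k1_ca", "k2_ca", "A0", "A1")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be non-negative", call. = FALSE)
  }
  if (p$A0 + 2 * p$A1 > 1 + 1e-12) {
    stop("A0 + 2*A1 must not exceed 1 (ATP waveform must stay in [0, 1])",
         call. = FALSE)
  }
  if (p$ca_init < 0 || p$ca_init > 1) {
    stop("`ca_init` must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Rate constants of the inter-pool fluxes
#'
#' Constructs the kinetic parameter set of the four-pool model. Defaults are
#' the published constants. The glycolytic pool level is the algebraic
#' function \eqn{P_0 = k_{0,p0} + k_{0A} \cdot ATP}; the five fluxes are
#' pure power-law products (no saturation):
#' \deqn{J_{01} = k_{01} \, Ca \, P_2 \, P_0, \qquad J_{21} = J_{01},}
#' \deqn{J_{12} = k_{12} \, P_1 \, NADH^2, \qquad
#'       J_{13} = k_{13} \, P_1 \, NADH^2, \qquad
#'       J_{32} = k_{32} \, P_3 \, (1 - NADH).}
#'
#' @param k0_p0 Offset of the glycolytic pool level (default 0.1).
#' @param k0A ATP coefficient of the glycolytic pool level (default 0.2).
#' @param k01 Rate constant of the pyruvate-dehydrogenase inflow (default 7).
#' @param k12 Rate constant of the citrate--malate exchange (default 1).
#' @param k13 Rate constant of the GABA-replenishing cataplerotic flux
#'   (default 2).
#' @param k32 Rate constant of the GABA-shunt anaplerotic flux (default 1).
#'
#' @return A list of class \code{"model_params"}.
#' @seealso [dam_fluxes()], [simulate_dam()]
#' @export
model_params <- function(k0_p0 = 0.1, k0A = 0.2, k01 = 7,
                         k12 = 1, k13 = 2, k32 = 1) {
  p <- list(k0_p0 = k0_p0, k0A = k0A, k01 = k01,
            k12 = k12, k13 = k13, k32 = k32)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("model parameter `", nm, "` must be a single finite non-negative ",
           "number", call. = FALSE)
    }
  }
  invisible(p)
}

#' Parameters of the regulated glycolytic influx
#'
#' Parameter set for the extended model in which the glycolytic pool is a
#' dynamic state fed by a phosphofructokinase-regulated influx
#' \deqn{J_0 = s \cdot \frac{1}{1 + \alpha_{ATP} ATP^{n}} \cdot
#'       \frac{1}{1 + \alpha_{Cit} P_1^{n}} \cdot
#'       \frac{P_0^{m}}{\beta^{m} + P_0^{m}},}
#' combining ATP inhibition, citrate inhibition (with \eqn{P_1} as the
#' citrate proxy) and positive feedback of the product FBP on its own
#' production. This functional form is the package's own phenomenological
#' formulation of the verbal regulatory scheme; see the methods vignette.
#' Setting \code{beta_fbp = 0} removes the positive-feedback factor
#' (it becomes identically 1).
#'
#' Defaults were chosen so that the dynamic glycolytic pool oscillates over
#' the same [0.1, 0.3] band the algebraic core model prescribes and shows
#' the asymmetric slow-rise/fast-fall waveform; see the methods vignette
#' for the tuning rationale.
#'
#' @param j0_scale Influx scale \eqn{s} (default 1.2).
#' @param alpha_atp Strength of ATP inhibition (default 4).
#' @param alpha_cit Strength of citrate inhibition via \eqn{P_1} (default 2).
#' @param beta_fbp Half-activation level of the FBP positive feedback;
#'   0 disables the factor (default 0.1).
#' @param n_atp,n_cit Hill exponents of the two inhibition factors
#'   (default 2).
#' @param m_fbp Hill exponent of the FBP activation factor (default 2).
#'
#' @return A list of class \code{"glycolysis_params"}.
#' @seealso [flux_j0()], [simulate_dam_extended()]
#' @export
glycolysis_params <- function(j0_scale = 1.2, alpha_atp = 4, alpha_cit = 2,
                              beta_fbp = 0.1, n_atp = 2, n_cit = 2,
                              m_fbp = 2) {
  p <- list(j0_scale = j0_scale, alpha_atp = alpha_atp,
            alpha_cit = alpha_cit, beta_fbp = beta_fbp,
            n_atp = n_atp, n_cit = n_cit, m_fbp = m_fbp)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("glycolysis parameter `", nm, "` must be a single finite ",
           "non-negative number", call. = FALSE)
    }
  }
  structure(p, class = "glycolysis_params")
}

#' Default initial pool state
#'
#' The published initial condition of the three dynamic pools:
#' \eqn{P_1 = 0.4}, \eqn{P_2 = 0.6}, \eqn{P_3 = 0.5} (total carbon 1.5).
#'
#' @return A named numeric vector \code{c(p1, p2, p3)}.
#' @export
default_init <- function() {
  c(p1 = 0.4, p2 = 0.6, p3 = 0.5)
}

check_pool_state <- function(init) {
  if (!is.numeric(init) || length(init) != 3L || any(!is.finite(init))) {
    stop("`init` must be three finite numbers (p1, p2, p3)", call. = FALSE)
  }
  if (any(init < 0)) stop("pool levels must be non-negative", call. = FALSE)
  if (is.null(names(init))) names(init) <- c("p1", "p2", "p3")
  init[c("p1", "p2", "p3")]
}
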