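#' Muscle map
#'
#' Assignment of the 24 dorsal and 24 ventral body-wall muscles to the seven
#' repeating neural units and to the lateral elements they overlap. Each unit
#' innervates three muscles per side except the end units: unit 1 drives
#' muscles 1-4 and unit 7 drives muscles 20-24, so all 24 muscles are covered.
#' Muscle m spans a block of adjacent segments (overlapping its neighbours)
#' with per-element weights proportional to overlap and normalized to sum to
#' one. The anterior-posterior gradient of neuromuscular efficacy is
#' `gamma_m = 0.7 * (1 - (m - 1) * F / M)` with `M = 24` and `F` the evolved
#' gain, so `gamma_1 = 0.7` always and the gradient is strictly decreasing
#' for `F > 0`.
#'
#' @param gain_F anterior-posterior gain in \[0, 1\].
#' @param config a [wcpg_config()].
#' @return a `wcpg_musclemap` list: `n_per_side`, `gamma`, `muscle_unit`
#'   (unit index per muscle), and per-side weight matrices `WmD`, `WmV`
#'   (muscles x segments).
#' @export
muscle_map <- function(gain_F, config = wcpg_config()) {
  m <- config$muscle
  M <- as.integer(m$n_per_side)
  n_seg <- as.integer(config$body$n_seg)
  gamma <- m$gamma0 * (1 - ((seq_len(M) - 1) * gain_F) / M)
  if (any(gamma <= 0))
    stop("muscle efficacy gradient must stay positive (gain_F too large)")

  muscle_unit <- c(rep(1L, 4L), rep(2:6, each = 3L), rep(7L, 5L))
  stopifnot(length(muscle_unit) == M)

  # muscle m covers `span` adjacent segments, stride 2, clipped at the tail
  span <- as.integer(m$span_segments)
  Wm <- matrix(0, M, n_seg)
  for (i in seq_len(M)) {
    s0 <- (i - 1L) * 2L + 1L
    segs <- s0:min(n_seg, s0 + span - 1L)
    Wm[i, segs] <- 1 / length(segs)
  }
  structure(list(n_per_side = M, gamma = gamma, muscle_unit = muscle_unit,
                 WmD = Wm, WmV = Wm, gain_F = gain_F),
            class = c("wcpg_musclemap", "list"))
}

#' Neuron-to-muscle drive matrix
#'
#' Encodes the muscle input equation `I_m^k = sum_{i in N^k} gamma_m q_i S_i`
#' as a (neurons x 48) matrix so that `I = t(Mdrv) %*% S`. The dorsal set
#' N^D is {AS, DA, DB, DD} and the ventral set N^V is {VD, VA, VB} of the
#' innervating unit; D-class entries carry negative sign (GABAergic).
#' Columns 1-24 are dorsal muscles, 25-48 ventral.
#'
#' @param wiring a [build_circuit()] wiring (provides signed NMJ weights).
#' @param map a [muscle_map()].
#' @param nmj_off optional per-neuron logical; `TRUE` zeroes that neuron's
#'   neuromuscular junction while leaving its dynamics intact.
#' @return matrix (`wiring$n` x `2 * map$n_per_side`).
#' @export
muscle_drive_matrix <- function(wiring, map, nmj_off = NULL) {
  M <- map$n_per_side
  if (max(map$muscle_unit) > wiring$n_units)
    stop("muscle map references unit ", max(map$muscle_unit),
         " but the wiring has only ", wiring$n_units)
  q <- wiring$nmj
  if (!is.null(nmj_off)) q[nmj_off] <- 0
  dorsal <- wiring$class %in% dorsal_classes()
  Mdrv <- matrix(0, wiring$n, 2L * M)
  for (mu in seq_len(M)) {
    u <- map$muscle_unit[mu]
    sel_d <- which(wiring$unit == u & dorsal)
    sel_v <- which(wiring$unit == u & !dorsal)
    Mdrv[sel_d, mu] <- map$gamma[mu] * q[sel_d]
    Mdrv[sel_v, M + mu] <- map$gamma[mu] * q[sel_v]
  }
  Mdrv
}

#' Muscle input from neural outputs
#'
#' @param S per-neuron synaptic outputs.
#' @param wiring a [build_circuit()] wiring.
#' @param map a [muscle_map()].
#' @param nmj_off optional per-neuron logical NMJ suppression mask.
#' @return numeric vector of 48 drives, dorsal muscles first.
#' @export
muscle_input <- function(S, wiring, map, nmj_off = NULL) {
  drv <- as.vector(crossprod(muscle_drive_matrix(wiring, map, nmj_off), S))
  names(drv) <- c(paste0("D", seq_len(map$n_per_side)),
                  paste0("V", seq_len(map$n_per_side)))
  drv
}

#' Leaky-integrator muscle activation update
#'
#' `dA/dt = (I - A) / tau_M` with tau_M = 100 ms, advanced one Euler step.
#'
#' @param A current activations.
#' @param I muscle drives.
#' @param dt step, s.
#' @param tau_m muscle time constant, s.
#' @return updated activations.
#' @export
muscle_activation_step <- function(A, I, dt, tau_m = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  A + dt / tau_m * (I - A)
}

#' Hill-type force-length factor
#'
#' Parabolic around the element rest length, zero beyond `width` strain:
#' `FL = max(0, 1 - ((l/l0 - 1)/width)^2)`.
#'
#' @param ratio element length over rest length.
#' @param width strain half-width of the parabola.
#' @return factor in \[0, 1\].
#' @export
force_length <- function(ratio, width = 0.5) {
  pmax(0, 1 - ((ratio - 1) / width)^2)
}

#' Hill-type force-velocity factor
#'
#' Hyperbolic decline with shortening strain rate (zero force at `vmax`),
#' mild saturating enhancement when lengthening.
#'
#' @param shorten_rate shortening strain rate, 1/s (positive = shortening).
#' @param vmax strain rate at which active force vanishes.
#' @param hill curvature of the shortening hyperbola.
#' @param cap upper bound of the lengthening enhancement.
#' @return non-negative factor, 1 at zero velocity.
#' @export
force_velocity <- function(shorten_rate, vmax = 4, hill = 2, cap = 1.5) {
  s <- shorten_rate / vmax
  out <- ifelse(s >= 0,
                pmax(0, (1 - pmin(s, 1)) / (1 + hill * pmin(s, 1))),
                pmin(cap, 1 + 0.5 * pmin(-s, 1)))
  out
}

#' Active muscle force on a lateral element
#'
#' `F = Fmax * A * FL(l/l0) * FV(shortening rate) * weight`; positive values
#' contract the element. Dorsal and ventral sides are independent.
#'
#' @param A muscle activation (unitless; may be negative for tone below
#'   rest, which produces an expansive force).
#' @param element_length current element length, mm.
#' @param element_velocity element lengthening rate dl/dt, mm/s.
#' @param rest_length element rest length, mm.
#' @param weight muscle-to-element overlap weight.
#' @param geometry a [body_geometry()] (Hill constants and Fmax).
#' @return force in kg*mm/s^2.
#' @export
muscle_force <- function(A, element_length, element_velocity, rest_length,
                         weight = 1, geometry = body_geometry()) {
  geometry$f_max * A * weight *
    force_length(element_length / rest_length, geometry$fl_width) *
    force_velocity(-element_velocity / rest_length, geometry$fv_vmax,
                   geometry$fv_hill, geometry$fv_cap)
}
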