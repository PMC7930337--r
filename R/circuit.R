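#' Synaptic output function
#'
#' Logistic sigmoid `1 / (1 + exp(-x))`: the steady-state synaptic activity of
#' a neuron as a function of its (bias-shifted) membrane potential. Strictly
#' increasing, saturating at 0 and 1.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build the ventral nerve cord wiring
#'
#' Instantiates `n_units` identical repeating units of the seven motorneuron
#' classes and wires them with the intraunit chemical synapses and gap
#' junction, the self-connections, and the interunit connections
#' (DB->DD+1, VA+1->DD chemical; DA-AS+1, VB-DB+1, AS-VA+1 electrical).
#' Interunit edges that would reference a unit beyond the chain ends are
#' dropped (no wraparound). The gap table is kept exactly symmetric.
#'
#' @param params `wcpg_params` from [decode_genotype()] (only `class_params`
#'   and `connectome` are used).
#' @param connectome optional connectome list overriding `params$connectome`.
#' @param n_units number of repeating units (7 for the full cord).
#' @param connection_scale optional named numeric vector of multipliers
#'   applied to individual evolved connections, e.g.
#'   `c(g_VB_DBp1 = 0, AS_to_VD = 0)`. Used for ablation and overexpression
#'   experiments; names follow [genotype_layout()] slots.
#' @param extra_gaps optional list of additional electrical channels, each
#'   `list(from, to, offset, g)`: class `from` of unit u coupled to class `to`
#'   of unit u+offset with conductance `g` (used by the B-class gap junction
#'   overexpression experiment).
#' @return a `wcpg_wiring` list: `n_units`, `n`, `class`, `unit`, `label`,
#'   chemical weight table `W` (entry `W[j, i]` is the synapse j -> i,
#'   self-connections on the diagonal), symmetric gap table `G`, `tau`,
#'   `theta`, and signed NMJ weights `nmj`.
#' @export
build_circuit <- function(params, connectome = NULL, n_units = 7,
                          connection_scale = NULL, extra_gaps = NULL) {
  if (n_units < 1) stop("n_units must be >= 1")
  con <- if (is.null(connectome)) params$connectome else connectome
  cp <- params$class_params
  cl <- neuron_classes()
  cp <- cp[match(cl, cp$class), ]
  n <- 7L * n_units
  unit <- rep(seq_len(n_units), each = 7L)
  klass <- rep(cl, n_units)
  idx <- function(class, u) (u - 1L) * 7L + match(class, cl)

  sc <- function(name) {
    if (!is.null(connection_scale) && name %in% names(connection_scale))
      connection_scale[[name]] else 1
  }

  W <- matrix(0, n, n)
  G <- matrix(0, n, n)
  for (u in seq_len(n_units)) {
    for (p in intraunit_chem_pairs()) {
      nm <- chem_pair_name(p)
      W[idx(p[1], u), idx(p[2], u)] <-
        W[idx(p[1], u), idx(p[2], u)] + con$chem_intra[[nm]] * sc(nm)
    }
    for (k in seq_len(7))                       # self-connections
      W[idx(cl[k], u), idx(cl[k], u)] <- cp$w_self[k]
    gvd <- con$gap_intra[["g_VD_DD"]] * sc("g_VD_DD")
    G[idx("VD", u), idx("DD", u)] <- G[idx("VD", u), idx("DD", u)] + gvd
    G[idx("DD", u), idx("VD", u)] <- G[idx("DD", u), idx("VD", u)] + gvd
    if (u < n_units) {
      W[idx("DB", u), idx("DD", u + 1L)] <-
        con$chem_inter[["DB_to_DDp1"]] * sc("DB_to_DDp1")
      W[idx("VA", u + 1L), idx("DD", u)] <-
        con$chem_inter[["VAp1_to_DD"]] * sc("VAp1_to_DD")
      inter_gap <- list(c("DA", "AS", "g_DA_ASp1"),
                        c("VB", "DB", "g_VB_DBp1"),
                        c("AS", "VA", "g_AS_VAp1"))
      for (gj in inter_gap) {
        g <- con$gap_inter[[gj[3]]] * sc(gj[3])
        a <- idx(gj[1], u); b <- idx(gj[2], u + 1L)
        G[a, b] <- G[a, b] + g
        G[b, a] <- G[b, a] + g
      }
    }
  }
  if (!is.null(extra_gaps)) {
    for (eg in extra_gaps) {
      for (u in seq_len(n_units)) {
        v <- u + eg$offset
        if (v < 1 || v > n_units) next
        a <- idx(eg$from, u); b <- idx(eg$to, v)
        G[a, b] <- G[a, b] + eg$g
        G[b, a] <- G[b, a] + eg$g
      }
    }
  }
  if (any(G < 0)) stop("gap junction conductances must be non-negative")

  structure(list(
    n_units = as.integer(n_units), n = n, class = klass, unit = unit,
    label = paste0(klass, unit), W = W, G = G,
    tau = rep(cp$tau, n_units), theta = rep(cp$bias, n_units),
    nmj = rep(cp$nmj_q * cp$nmj_sign, n_units)),
    class = c("wcpg_wiring", "list"))
}

#' @export
print.wcpg_wiring <- function(x, ...) {
  cat(sprintf("wormCPG wiring: %d units, %d neurons, %d chemical edges, %d gap channels\n",
              x$n_units, x$n, sum(x$W != 0), sum(x$G != 0) / 2))
  invisible(x)
}

# slim single-unit wiring straight from a normalized vector: the hot path of
# the stage-1 search (no data.frames). Class indices: AS1 DA2 DB3 DD4 VD5 VA6
# VB7; chem slots 29..37 follow intraunit_chem_pairs() order.
unit_wiring_quick <- function(v, rt) {
  real <- rt[, "lo"] + (v + 1) / 2 * (rt[, "hi"] - rt[, "lo"])
  W <- matrix(0, 7, 7)
  diag(W) <- real[15:21]
  pre <- c(1L, 1L, 2L, 3L, 5L, 5L, 2L, 7L, 6L)
  post <- c(2L, 5L, 3L, 1L, 6L, 7L, 4L, 4L, 4L)
  W[cbind(pre, post)] <- real[29:37]
  G <- matrix(0, 7, 7)
  G[5, 4] <- G[4, 5] <- real[38]
  list(W = W, G = G, tau = real[8:14], theta = real[1:7])
}

#' Circuit state
#'
#' Membrane potentials (relative to rest, so the default initial state is
#' all-zero) plus the per-neuron masks: `silenced` clamps a neuron at rest
#' with zero synaptic output and disconnects its gap junctions; `nmj_off`
#' suppresses its neuromuscular junction only, leaving the dynamics intact.
#'
#' @param wiring a `wcpg_wiring`.
#' @param V initial potentials (scalar or length-n vector).
#' @return a `wcpg_state` list.
#' @export
circuit_state <- function(wiring, V = 0) {
  n <- wiring$n
  V <- rep_len(V, n)
  structure(list(V = V, silenced = rep(FALSE, n), nmj_off = rep(FALSE, n)),
            class = c("wcpg_state", "list"))
}

#' One Forward-Euler update of the circuit
#'
#' Reference (pure R) implementation of
#' `tau_i dV_i/dt = -V_i + sum_j w_ji sigma(V_j + theta_j)
#'  + sum_j g_ji (V_j - V_i) + I_i`.
#' Long simulations use the identical compiled loop via
#' [simulate_circuit()].
#'
#' @param state a [circuit_state()].
#' @param wiring a `wcpg_wiring`.
#' @param external_input per-neuron external input (recycled).
#' @param dt time step in seconds (default 0.5 ms). A warning is raised when
#'   `dt >= 2 * min(tau)`, the Euler stability bound for the leak term.
#' @return the updated state.
#' @export
neural_step <- function(state, wiring, external_input = 0, dt = 5e-4) {
  if (dt <= 0) stop("dt must be positive")
  if (dt >= 2 * min(wiring$tau))
    warning("dt >= 2 * min(tau): Forward Euler may be unstable")
  V <- state$V
  off <- state$silenced
  S <- ifelse(off, 0, sigmoid(V + wiring$theta))
  chem <- as.vector(crossprod(wiring$W, S))
  Gm <- wiring$G
  if (any(off)) Gm[off, ] <- Gm[, off] <- 0
  gap <- as.vector(crossprod(Gm, V)) - colSums(Gm) * V
  inp <- chem + gap + rep_len(external_input, wiring$n)
  Vnew <- V + dt / wiring$tau * (-V + inp)
  Vnew[off] <- 0
  state$V <- Vnew
  state
}

#' Synaptic outputs of a state
#'
#' @param state a [circuit_state()].
#' @param wiring a `wcpg_wiring`.
#' @return vector of outputs in (0, 1); exactly 0 for silenced neurons.
#' @export
synaptic_output <- function(state, wiring) {
  ifelse(state$silenced, 0, sigmoid(state$V + wiring$theta))
}

#' Integrate a circuit and record traces
#'
#' Compiled Forward-Euler integration at `dt` with recording every
#' `record_stride` steps.
#'
#' @param wiring a `wcpg_wiring`.
#' @param duration simulated time, s.
#' @param dt neural step, s.
#' @param state0 optional initial [circuit_state()]; defaults to rest.
#' @param tonic per-neuron constant external input.
#' @param record_stride record every this many steps.
#' @return a `wcpg_trace` with `time`, matrices `V` and `S` (rows = samples,
#'   columns = neurons, labelled), and metadata.
#' @export
simulate_circuit <- function(wiring, duration, dt = 5e-4, state0 = NULL,
                             tonic = 0, record_stride = 10L) {
  if (is.null(state0)) state0 <- circuit_state(wiring)
  n_steps <- round(duration / dt)
  res <- simulate_circuit_cpp(wiring$W, wiring$G, wiring$tau, wiring$theta,
                              state0$V, state0$silenced,
                              rep_len(tonic, wiring$n), dt,
                              as.integer(n_steps), as.integer(record_stride))
  if (any(!is.finite(res$V_final)))
    stop("simulation error: non-finite neural state")
  res$S <- sigmoid(sweep(res$V, 2, wiring$theta, "+"))
  if (any(state0$silenced)) res$S[, state0$silenced] <- 0
  colnames(res$V) <- colnames(res$S) <- wiring$label
  structure(list(time = res$time, V = res$V, S = res$S,
                 V_final = res$V_final, dt = dt * record_stride,
                 n_units = wiring$n_units, class = wiring$class,
                 unit = wiring$unit, label = wiring$label),
            class = c("wcpg_trace", "list"))
}

#' @export
print.wcpg_trace <- function(x, ...) {
  cat(sprintf("wormCPG trace: %d samples at %.3g ms (%.3g s), %d neurons%s\n",
              length(x$time), x$dt * 1000, max(x$time), ncol(x$S),
              if (!is.null(x$x)) sprintf(", body midline with %d rods", ncol(x$x))
              else ""))
  invisible(x)
}

#' Extract one neuron's output trace
#'
#' @param trace a `wcpg_trace`.
#' @param class class label, e.g. `"DB"`.
#' @param unit unit number.
#' @param what `"S"` (synaptic output) or `"V"` (potential).
#' @return numeric vector.
#' @export
neuron_trace <- function(trace, class, unit = 1, what = c("S", "V")) {
  what <- match.arg(what)
  col <- which(trace$class == class & trace$unit == unit)
  if (length(col) != 1) stop("no neuron ", class, unit, " in this trace")
  trace[[what]][, col]
}

#' Run one isolated neural unit
#'
#' Stage-1 protocol: a single seven-neuron unit (no body, no interunit
#' connections) integrated from rest.
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param duration simulated seconds (default from config).
#' @param transient seconds discarded from the start of the returned trace.
#' @param record_stride recording stride in neural steps.
#' @return a `wcpg_trace` restricted to the post-transient window.
#' @export
run_isolated_unit <- function(genotype, config = wcpg_config(),
                              duration = config$simulation$duration,
                              transient = config$simulation$transient,
                              record_stride = config$simulation$record_stride) {
  params <- decode_genotype(genotype, config)
  wiring <- build_circuit(params, n_units = 1)
  tr <- simulate_circuit(wiring, duration, dt = config$simulation$dt_neural,
                         record_stride = record_stride)
  trace_window(tr, from = transient)
}

#' Restrict a trace to a time window
#'
#' @param trace a `wcpg_trace`.
#' @param from,to window bounds in seconds (defaults: whole trace).
#' @return the windowed trace.
#' @export
trace_window <- function(trace, from = -Inf, to = Inf) {
  keep <- trace$time > from & trace$time <= to
  for (nm in c("V", "S", "A", "x", "y"))
    if (!is.null(trace[[nm]])) trace[[nm]] <- trace[[nm]][keep, , drop = FALSE]
  trace$time <- trace$time[keep]
  trace
}
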