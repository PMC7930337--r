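#' Estimate the dominant frequency of a rhythmic trace
#'
#' Primary estimator: mean interval between rising crossings of the signal
#' mean (with linear interpolation of the crossing times). A spectral
#' estimate (FFT peak) is available as a cross-check. Signals with fewer
#' than two rising crossings, or with negligible amplitude, return 0 with
#' attribute `oscillatory = FALSE`.
#'
#' @param x numeric trace.
#' @param dt sampling interval, s.
#' @param method `"crossing"` (default) or `"spectral"`.
#' @param min_amplitude amplitude (max - min) below which the trace is
#'   treated as non-oscillatory.
#' @return frequency in Hz with attribute `oscillatory`.
#' @export
estimate_frequency <- function(x, dt, method = c("crossing", "spectral"),
                               min_amplitude = 1e-6) {
  method <- match.arg(method)
  flagged <- function(f, osc) { attr(f, "oscillatory") <- osc; f }
  if (any(!is.finite(x))) return(flagged(0, FALSE))
  if (diff(range(x)) < min_amplitude) return(flagged(0, FALSE))
  if (method == "spectral") {
    n <- length(x)
    xc <- x - mean(x)
    sp <- Mod(fft(xc))[seq_len(floor(n / 2))]
    k <- which.max(sp)
    return(flagged((k - 1) / (n * dt), k > 1))
  }
  y <- x - mean(x)
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  if (length(up) < 2) return(flagged(0, FALSE))
  # linear interpolation of each crossing time
  tc <- up - y[up] / (y[up + 1] - y[up])
  flagged(1 / (mean(diff(tc)) * dt), TRUE)
}

#' Rhythmic-pattern fitness of the B-class motorneurons (stage 1)
#'
#' Product over the DB and VB outputs of an amplitude term and a frequency
#' term. The amplitude term is the total variation of the output over the
#' window normalized by `4 * A * f_a * T` (the total variation of a sinusoid
#' of amplitude A at the target frequency), capped at 1; A = 0.5 is the
#' amplitude threshold. The frequency term is `1 - |f_j - f_a| / f_a`,
#' floored at 0, with f_a = 0.44 Hz the bending frequency of crawling worms.
#'
#' @param S_DB,S_VB output traces of the DB and VB neurons.
#' @param dt sampling interval, s.
#' @param constants list with `amp_threshold` and `freq_target` (defaults
#'   from [wcpg_config()]).
#' @return fitness in \[0, 1\].
#' @export
fitness_F1 <- function(S_DB, S_VB, dt,
                       constants = wcpg_config()$fitness) {
  if (any(!is.finite(S_DB)) || any(!is.finite(S_VB))) return(0)
  A <- constants$amp_threshold
  fa <- constants$freq_target
  term <- function(s) {
    T_ <- (length(s) - 1) * dt
    if (T_ <= 0) return(0)
    amp <- min(1, sum(abs(diff(s))) / (4 * A * fa * T_))
    f <- estimate_frequency(s, dt)
    freq <- max(0, 1 - abs(f - fa) / fa)
    amp * freq
  }
  term(S_DB) * term(S_VB)
}

#' Stage-1 fitness of a trace
#'
#' [fitness_F1()] applied to the DB and VB outputs of each unit in the trace,
#' averaged over units.
#'
#' @param trace a `wcpg_trace` (isolated unit or embodied), already windowed
#'   past the transient.
#' @param constants fitness constants.
#' @return fitness in \[0, 1\].
#' @export
f1_from_trace <- function(trace, constants = wcpg_config()$fitness) {
  units <- unique(trace$unit)
  mean(vapply(units, function(u) {
    fitness_F1(neuron_trace(trace, "DB", u), neuron_trace(trace, "VB", u),
               trace$dt, constants)
  }, numeric(1)))
}

#' Forward-velocity fitness (stage 2)
#'
#' `F2 = 1 - |V - V_a| / V_a`, floored at 0, with V_a = 0.22 mm/s the mean
#' forward velocity of the worm on agar.
#'
#' @param velocity mean forward velocity in mm/s, or a `wcpg_trace` from
#'   which [mean_velocity()] is computed.
#' @param constants list with `vel_target`.
#' @return fitness in \[0, 1\].
#' @export
fitness_F2 <- function(velocity, constants = wcpg_config()$fitness) {
  if (inherits(velocity, "wcpg_trace")) velocity <- mean_velocity(velocity)
  max(0, 1 - abs(velocity - constants$vel_target) / constants$vel_target)
}

#' Locomotion performance of a genotype under manipulations
#'
#' Runs the embodied model and scores the post-transient forward velocity
#' with [fitness_F2()]. The common currency of the ablation and
#' coordination analyses.
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param masks optional [circuit_masks()].
#' @param duration,transient evaluation window, s.
#' @return list with `velocity` (mm/s) and `performance` (F2).
#' @export
locomotion_performance <- function(genotype, config = wcpg_config(),
                                   masks = NULL,
                                   duration = config$simulation$duration,
                                   transient = config$simulation$transient) {
  tr <- run_embodied(genotype, config, masks = masks, duration = duration)
  v <- mean_velocity(trace_window(tr, from = transient))
  list(velocity = v, performance = fitness_F2(v, config$fitness))
}
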