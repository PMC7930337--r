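#' Curvature kymograph from midline postures
#'
#' Signed local curvature along the body for every frame. Curvature at an
#' interior midline point is the turning rate of the tangent angle with
#' arclength, smoothed with a moving-average window along the body. The sign
#' convention is dorsal-positive: with the worm initially heading along +x
#' and its dorsal side towards +y, bending towards the dorsal side gives
#' positive curvature.
#'
#' @param x,y matrices (frames x points) of midline coordinates, head first;
#'   or a `wcpg_trace` passed as `x` (its `time` is carried over).
#' @param time optional time stamps.
#' @param smooth_window odd moving-average width in body points (1 = none).
#' @return a `wcpg_kymograph`: `curvature` matrix (frames x interior points,
#'   1/mm), `body_coord` (head->tail in \[0, 1\]), `time`.
#' @export
curvature_kymograph <- function(x, y = NULL, time = NULL, smooth_window = 5) {
  if (inherits(x, "wcpg_trace")) {
    time <- x$time
    y <- x$y
    x <- x$x
  }
  if (ncol(x) < 3) stop("need at least 3 midline points per frame")
  n <- ncol(x)
  dx <- x[, -1, drop = FALSE] - x[, -n, drop = FALSE]
  dy <- y[, -1, drop = FALSE] - y[, -n, drop = FALSE]
  ds <- sqrt(dx^2 + dy^2)
  if (any(ds <= 0)) stop("degenerate midline: coincident points")
  ang <- atan2(dy, dx)
  dang <- ang[, -1, drop = FALSE] - ang[, -(n - 1), drop = FALSE]
  dang <- (dang + pi) %% (2 * pi) - pi   # unwrap
  seglen <- (ds[, -1, drop = FALSE] + ds[, -(n - 1), drop = FALSE]) / 2
  curv <- dang / seglen
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    curv <- t(apply(curv, 1, function(r)
      stats::filter(r, k, sides = 2)))
    # shrink to the valid (non-NA) interior
    keep <- colSums(is.na(curv)) == 0
    curv <- curv[, keep, drop = FALSE]
    bc <- seq(0, 1, length.out = n - 2)[keep]
  } else {
    bc <- seq(0, 1, length.out = n - 2)
  }
  structure(list(curvature = curv, body_coord = bc,
                 time = if (is.null(time)) seq_len(nrow(curv)) else time),
            class = c("wcpg_kymograph", "list"))
}

#' @export
print.wcpg_kymograph <- function(x, ...) {
  cat(sprintf("wormCPG kymograph: %d frames x %d body points, |curvature| up to %.2f /mm\n",
              nrow(x$curvature), ncol(x$curvature), max(abs(x$curvature))))
  invisible(x)
}

#' Dominant body wavelength of the curvature wave
#'
#' Per frame, the spatial wavelength is estimated as twice the mean spacing
#' between zero crossings of the curvature profile (linear interpolation),
#' averaged over frames; an FFT estimate over the padded profile is
#' available as a cross-check. The locomotion filter accepts wavelengths in
#' 0.4-0.9 body lengths.
#'
#' @param kym a [curvature_kymograph()].
#' @param method `"crossing"` (default) or `"spectral"`.
#' @return wavelength in body lengths, with attributes `pass` (in
#'   \[0.4, 0.9\]) and `oscillatory`.
#' @export
body_wavelength <- function(kym, method = c("crossing", "spectral")) {
  method <- match.arg(method)
  prof <- kym$curvature
  span <- diff(range(kym$body_coord))   # fraction of body covered
  m <- ncol(prof)
  est <- apply(prof, 1, function(r) {
    if (diff(range(r)) < 1e-9) return(NA_real_)
    if (method == "spectral") {
      pad <- c(r - mean(r), rep(0, 7 * m))
      sp <- Mod(fft(pad))[seq_len(4 * m)]
      k <- which.max(sp[-1])
      return(span * length(pad) / (k * m))
    }
    # curvature is signed around zero; do not demean (a partial period
    # would shift the crossings)
    s <- which(r[-m] * r[-1] < 0)
    if (length(s) < 2) return(NA_real_)
    tc <- s - r[s] / (r[s + 1] - r[s])
    2 * mean(diff(tc)) * span / (m - 1)
  })
  ok <- is.finite(est)
  if (!any(ok)) {
    out <- 0
    attr(out, "oscillatory") <- FALSE
    attr(out, "pass") <- FALSE
    return(out)
  }
  out <- mean(est[ok])
  attr(out, "oscillatory") <- TRUE
  attr(out, "pass") <- out >= 0.4 - 1e-6 && out <= 0.9 + 1e-6
  out
}

#' Anterior-posterior curvature profile slope
#'
#' Mean absolute curvature per body coordinate, fitted with a least-squares
#' line head to tail. Worms bend more near the head: the filter requires a
#' negative slope.
#'
#' @param kym a [curvature_kymograph()].
#' @return list with `slope` (per body length), `intercept`, `pass`.
#' @export
ap_curvature_slope <- function(kym) {
  prof <- colMeans(abs(kym$curvature))
  fit <- lm(prof ~ kym$body_coord)
  slope <- unname(coef(fit)[2])
  list(slope = slope, intercept = unname(coef(fit)[1]), pass = slope < 0)
}

#' Radius of curvature of the center-of-mass trajectory
#'
#' Algebraic (Kasa) circle fit to the COM path. Straight paths give an
#' effectively infinite radius. The filter requires a radius above 1 mm
#' (trajectories as straight as real crawling worms).
#'
#' @param com_path matrix (samples x 2), mm.
#' @param min_path_length flag the path as stationary below this length, mm.
#' @return radius in mm (possibly `Inf`) with attributes `pass` and
#'   `stationary`.
#' @export
trajectory_curvature_radius <- function(com_path, min_path_length = 0.05) {
  p <- as.matrix(com_path)
  steps <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (sum(steps) < min_path_length) {
    out <- 0
    attr(out, "stationary") <- TRUE
    attr(out, "pass") <- FALSE
    return(out)
  }
  x <- p[, 1] - mean(p[, 1]); y <- p[, 2] - mean(p[, 2])
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  r <- if (is.null(sol)) Inf else {
    cx <- sol[1] / 2; cy <- sol[2] / 2
    sqrt(cx^2 + cy^2 + sol[3])
  }
  # numerically huge radii are reported as straight
  if (!is.finite(r) || r > 1e3) r <- Inf
  out <- r
  attr(out, "stationary") <- FALSE
  attr(out, "pass") <- r > 1
  out
}

#' A/B-class neuromuscular junction ablation filter
#'
#' Runs the embodied model with the B-class NMJs zeroed and with the A-class
#' NMJs zeroed. Forward locomotion must depend on the B-class input and not
#' on the A-class input: pass iff velocity without A-class NMJs exceeds 20%
#' of the target velocity and velocity without B-class NMJs falls below 20%.
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param duration,transient evaluation window, s.
#' @return list with `velocity_without_A`, `velocity_without_B` (as fractions
#'   of the target velocity), and `pass`.
#' @export
nmj_ablation_filter <- function(genotype, config = wcpg_config(),
                                duration = config$simulation$duration,
                                transient = config$simulation$transient) {
  va <- locomotion_performance(
    genotype, config, circuit_masks(nmj_off_classes = c("DA", "VA")),
    duration, transient)$velocity
  vb <- locomotion_performance(
    genotype, config, circuit_masks(nmj_off_classes = c("DB", "VB")),
    duration, transient)$velocity
  Va <- config$fitness$vel_target
  list(velocity_without_A = va / Va, velocity_without_B = vb / Va,
       pass = (va > 0.2 * Va) && (vb < 0.2 * Va))
}

#' Apply all three ensemble filters to a solution
#'
#' NMJ-class dependence, body curvature (wavelength and anterior-posterior
#' profile), and trajectory straightness.
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param duration,transient evaluation window, s.
#' @return a `wcpg_filter_report` list with per-criterion results and
#'   `pass_all`.
#' @export
filter_report <- function(genotype, config = wcpg_config(),
                          duration = config$simulation$duration,
                          transient = config$simulation$transient) {
  tr <- trace_window(run_embodied(genotype, config, duration = duration),
                     from = transient)
  kym <- curvature_kymograph(tr)
  wl <- body_wavelength(kym)
  ap <- ap_curvature_slope(kym)
  rad <- trajectory_curvature_radius(com_path(tr))
  nmj <- nmj_ablation_filter(genotype, config, duration, transient)
  structure(list(
    nmj = nmj, wavelength = as.numeric(wl), wavelength_pass = attr(wl, "pass"),
    ap_slope = ap$slope, ap_pass = ap$pass,
    trajectory_radius = as.numeric(rad), trajectory_pass = attr(rad, "pass"),
    velocity = mean_velocity(tr),
    pass_all = nmj$pass && attr(wl, "pass") && ap$pass && attr(rad, "pass")),
    class = c("wcpg_filter_report", "list"))
}

#' @export
print.wcpg_filter_report <- function(x, ...) {
  cat("wormCPG filter report\n")
  cat(sprintf("  velocity: %.3f mm/s\n", x$velocity))
  cat(sprintf("  NMJ: v(-A) = %.2f Va, v(-B) = %.2f Va -> %s\n",
              x$nmj$velocity_without_A, x$nmj$velocity_without_B,
              if (x$nmj$pass) "pass" else "FAIL"))
  cat(sprintf("  wavelength: %.2f L -> %s\n", x$wavelength,
              if (x$wavelength_pass) "pass" else "FAIL"))
  cat(sprintf("  A-P curvature slope: %.3f -> %s\n", x$ap_slope,
              if (x$ap_pass) "pass" else "FAIL"))
  cat(sprintf("  trajectory radius: %.2f mm -> %s\n", x$trajectory_radius,
              if (x$trajectory_pass) "pass" else "FAIL"))
  cat(sprintf("  overall: %s\n", if (x$pass_all) "PASS" else "FAIL"))
  invisible(x)
}

body_thirds <- function(body_coord) {
  cut(body_coord, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
      labels = c("head", "mid", "tail"))
}

#' Bending amplitude per body third
#'
#' Peak-to-peak curvature over the window at each body point, summed within
#' the head, midbody and tail thirds.
#'
#' @param kym a [curvature_kymograph()].
#' @return named numeric vector (head, mid, tail).
#' @export
bending_amplitude <- function(kym) {
  p2p <- apply(kym$curvature, 2, function(c) diff(range(c)))
  tapply(p2p, body_thirds(kym$body_coord), sum)
}

#' Regional paralysis experiment
#'
#' Reproduces the anterior/midbody paralysis protocols: silence a range of
#' neural units either at the neurons (clamped, zero output) or at their
#' neuromuscular junctions (muscles inactivated, dynamics intact), and
#' measure the bending amplitude per body third against the unperturbed run.
#'
#' @param genotype a [genotype()].
#' @param region integer range of units to silence (within 1-7).
#' @param mode `"neurons"` or `"nmj"`.
#' @param config a [wcpg_config()].
#' @param duration,transient evaluation window, s.
#' @return list with `amplitude`, `baseline` (named head/mid/tail) and
#'   `ratio`.
#' @export
region_silencing_experiment <- function(genotype, region,
                                        mode = c("neurons", "nmj"),
                                        config = wcpg_config(),
                                        duration = config$simulation$duration,
                                        transient = config$simulation$transient) {
  mode <- match.arg(mode)
  if (length(region) && (min(region) < 1 || max(region) > 7))
    stop("region must lie within units 1..7")
  masks <- if (!length(region)) NULL
           else if (mode == "neurons") circuit_masks(silence_units = region)
           else circuit_masks(nmj_off_units = region)
  run_amp <- function(m) {
    tr <- trace_window(run_embodied(genotype, config, masks = m,
                                    duration = duration), from = transient)
    bending_amplitude(curvature_kymograph(tr))
  }
  base <- run_amp(NULL)
  amp <- if (is.null(masks)) base else run_amp(masks)
  list(amplitude = amp, baseline = base, ratio = amp / base)
}

#' B-class gap junction overexpression sweep
#'
#' Scales the electrical coupling between B-class motorneurons of adjacent
#' units (the evolved VB-DB+1 channel plus DB-DB+1 and VB-VB+1 channels
#' added at the scaled strength) and records speed and bending per body
#' third at each factor. Strong coupling synchronizes the pattern
#' generators and destroys the traveling wave.
#'
#' @param genotype a [genotype()].
#' @param factors overexpression factors (>= 1; 1 = unmodified).
#' @param config a [wcpg_config()].
#' @param duration,transient evaluation window, s.
#' @return data.frame with `factor`, `speed` (mm/s), and bending amplitude
#'   per third.
#' @export
gj_overexpression_sweep <- function(genotype, factors = c(1, 2, 4, 8),
                                    config = wcpg_config(),
                                    duration = config$simulation$duration,
                                    transient = config$simulation$transient) {
  if (any(factors < 1)) stop("overexpression factors must be >= 1")
  rows <- lapply(factors, function(f) {
    tr <- trace_window(
      run_embodied(genotype, config, masks = circuit_masks(gj_B_factor = f),
                   duration = duration), from = transient)
    amp <- bending_amplitude(curvature_kymograph(tr))
    data.frame(factor = f, speed = mean_velocity(tr), head = amp[["head"]],
               mid = amp[["mid"]], tail = amp[["tail"]])
  })
  do.call(rbind, rows)
}

subcircuit_members <- function(name) {
  switch(name,
         "AS-DA-DB" = c("AS", "DA", "DB"),
         "VD-VA-DD" = c("VD", "VA", "DD"),
         "VD-VB-DD" = c("VD", "VB", "DD"),
         stop("unknown subcircuit: ", name))
}

#' Intrinsic oscillation score of a subcircuit
#'
#' Isolates one of the three recurrently connected triples of the unit
#' (AS-DA-DB, VD-VA-DD, VD-VB-DD), keeping only the connections among its
#' members, and tests whether it can generate rhythmic patterns. Because
#' isolation removes synaptic drive, each neuron receives a compensatory
#' tonic input swept on a grid around the mean drive it lost (estimated from
#' a baseline run of the full unit). The score is the maximum over the grid
#' of the time-averaged |dS/dt| over the members, normalized by the total
#' variation rate of a full-range square wave at the target bending
#' frequency and capped at 1; grid points that settle to a fixed point
#' score 0.
#'
#' @param genotype a [genotype()].
#' @param subcircuit one of `"AS-DA-DB"`, `"VD-VA-DD"`, `"VD-VB-DD"`.
#' @param config a [wcpg_config()].
#' @param grid_points tonic grid points per neuron.
#' @param grid_span half-width of the tonic sweep (potential units).
#' @param duration,transient per-grid-point simulation window, s.
#' @return score in \[0, 1\] with attribute `best_tonic`.
#' @export
subcircuit_oscillation_score <- function(genotype, subcircuit,
                                         config = wcpg_config(),
                                         grid_points = 9, grid_span = 5,
                                         duration = 10, transient = 2) {
  members <- subcircuit_members(subcircuit)
  params <- decode_genotype(genotype, config)
  wiring <- build_circuit(params, n_units = 1)
  keep <- match(members, neuron_classes())
  # mean synaptic drive lost by isolation, from a baseline full-unit run
  base <- run_isolated_unit(genotype, config, duration = duration,
                            transient = transient)
  Sbar <- colMeans(base$S)
  lost <- vapply(keep, function(i) {
    drop_idx <- setdiff(seq_len(7), keep)
    sum(wiring$W[drop_idx, i] * Sbar[drop_idx])
  }, numeric(1))

  sub <- list(n_units = 1L, n = length(keep),
              class = wiring$class[keep], unit = wiring$unit[keep],
              label = wiring$label[keep],
              W = wiring$W[keep, keep, drop = FALSE],
              G = wiring$G[keep, keep, drop = FALSE],
              tau = wiring$tau[keep], theta = wiring$theta[keep],
              nmj = wiring$nmj[keep])
  class(sub) <- c("wcpg_wiring", "list")

  offsets <- seq(-grid_span, grid_span, length.out = grid_points)
  fa <- config$fitness$freq_target
  norm_rate <- 2 * fa   # total-variation rate of a 0-1 square wave at fa
  best <- 0
  best_tonic <- lost
  grid <- expand.grid(o1 = offsets, o2 = offsets, o3 = offsets)
  for (r in seq_len(nrow(grid))) {
    tonic <- lost + as.numeric(grid[r, ])
    tr <- simulate_circuit(sub, duration = duration,
                           dt = config$simulation$dt_neural, tonic = tonic,
                           record_stride = config$simulation$record_stride)
    tr <- trace_window(tr, from = transient)
    # a trajectory still relaxing to a fixed point is not an oscillation:
    # judge on the final quarter of the window
    tail_win <- trace_window(tr, from = max(tr$time) - duration / 4)
    if (max(apply(tail_win$S, 2, function(s) diff(range(s)))) < 1e-4) next
    rate <- mean(colSums(abs(diff(tr$S)))) / (max(tr$time) - min(tr$time))
    score <- min(1, rate / norm_rate)
    if (score > best) { best <- score; best_tonic <- tonic }
  }
  attr(best, "best_tonic") <- best_tonic
  best
}

#' Necessity and sufficiency of the interunit connections
#'
#' For each of the five interunit connections (2 chemical, 3 electrical):
#' the necessity score is the locomotion performance with that connection
#' ablated; the sufficiency score is the performance with only that
#' connection retained. A connection is classed necessary when its ablation
#' drops performance below `threshold` x baseline, and sufficient when it
#' alone preserves at least `threshold` x baseline. Solutions are
#' categorized as "simple" (some connection both necessary and sufficient),
#' "redundant" (sufficient connections exist but none is necessary) or
#' "complex" (none sufficient).
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param duration,transient evaluation window, s.
#' @param threshold fraction of baseline performance counting as coordinated.
#' @return a `wcpg_coordination` list: `baseline`, data.frame `connections`
#'   (necessity, sufficiency, flags) and `category`.
#' @export
interunit_necessity_sufficiency <- function(genotype, config = wcpg_config(),
                                            duration = config$simulation$duration,
                                            transient = config$simulation$transient,
                                            threshold = 0.5) {
  cons <- interunit_connection_names()
  perf <- function(masks)
    locomotion_performance(genotype, config, masks, duration,
                           transient)$performance
  baseline <- perf(NULL)
  nec <- vapply(cons, function(cn)
    perf(circuit_masks(drop_connections = cn)), numeric(1))
  suf <- vapply(cons, function(cn)
    perf(circuit_masks(keep_only_interunit = cn)), numeric(1))
  necessary <- nec < threshold * baseline
  sufficient <- suf >= threshold * baseline
  category <- if (any(necessary & sufficient)) "simple"
              else if (any(sufficient)) "redundant"
              else "complex"
  structure(list(
    baseline = baseline,
    connections = data.frame(connection = cons, necessity = nec,
                             sufficiency = suf, necessary = necessary,
                             sufficient = sufficient, row.names = NULL),
    category = category),
    class = c("wcpg_coordination", "list"))
}

#' @export
print.wcpg_coordination <- function(x, ...) {
  cat(sprintf("wormCPG interunit coordination: baseline performance %.3f, category '%s'\n",
              x$baseline, x$category))
  print(x$connections, row.names = FALSE)
  invisible(x)
}

#' Phase shift between two rhythmic traces
#'
#' The phase marker of each cycle is the midpoint time between the maximum
#' and the minimum of dS/dt within that cycle; the shift is the marker
#' difference over the shared period, in degrees, averaged circularly over
#' cycles and reported in (-180, 180]. Positive values mean `a` leads `b`.
#'
#' @param trace_a,trace_b numeric traces sampled at `dt`.
#' @param dt sampling interval, s.
#' @return phase shift in degrees.
#' @export
phase_shift <- function(trace_a, trace_b, dt) {
  fa <- estimate_frequency(trace_a, dt)
  fb <- estimate_frequency(trace_b, dt)
  if (!attr(fa, "oscillatory") || !attr(fb, "oscillatory"))
    stop("phase_shift requires oscillatory traces")
  if (abs(fa - fb) / max(fa, fb) > 0.1)
    stop(sprintf("frequency mismatch beyond 10%%: %.3f vs %.3f Hz", fa, fb))
  period <- 1 / mean(c(fa, fb))
  ma <- cycle_markers(trace_a, dt)
  mb <- cycle_markers(trace_b, dt)
  if (!length(ma) || !length(mb)) stop("could not locate rhythmic cycles")
  # for each marker of a, phase relative to the nearest marker of b
  shifts <- vapply(ma, function(t) {
    d <- (t - mb) / period * 360
    d <- (d + 180) %% 360 - 180
    d[which.min(abs(d))]
  }, numeric(1))
  ang <- shifts * pi / 180
  (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi + 180 - 1e-9) %% 360 -
    180 + 1e-9
}

# per-cycle phase markers: midpoint between the times of max and min dS/dt
cycle_markers <- function(x, dt) {
  y <- x - mean(x)
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  if (length(up) < 2) return(numeric(0))
  dS <- diff(x) / dt
  out <- numeric(0)
  for (k in seq_len(length(up) - 1)) {
    i0 <- up[k]; i1 <- up[k + 1] - 1
    if (i1 - i0 < 3) next
    seg <- dS[i0:min(i1, length(dS))]
    tmax <- (i0 + which.max(seg) - 1) * dt
    tmin <- (i0 + which.min(seg) - 1) * dt
    out <- c(out, (tmax + tmin) / 2)
  }
  out
}

#' Entrainment analysis of the neural chain
#'
#' Tests the directionality of interunit coordination. The full 7-unit
#' circuit (no body) is run to a steady rhythm; at a reference time the
#' state of the perturbed end unit is replaced with its own state from a
#' quarter, half, etc. period earlier (a pure phase shift on the same limit
#' cycle); the run then continues and each unit's asymptotic phase shift
#' relative to the unperturbed continuation is measured on its DB output.
#'
#' @param genotype a [genotype()].
#' @param perturbed_unit 1 (anterior-most) or 7 (posterior-most).
#' @param phase_shift_deg imposed phase shift in degrees.
#' @param config a [wcpg_config()].
#' @param settle seconds simulated before the perturbation.
#' @param measure_window seconds simulated after the perturbation; the last
#'   half is used for the phase measurement.
#' @return numeric vector of 7 adopted phase shifts (degrees) per unit.
#' @export
entrainment_analysis <- function(genotype, perturbed_unit, phase_shift_deg,
                                 config = wcpg_config(), settle = 20,
                                 measure_window = 20) {
  if (!perturbed_unit %in% c(1, 7))
    stop("perturbed_unit must be 1 or 7")
  params <- decode_genotype(genotype, config)
  wiring <- build_circuit(params, n_units = 7)
  dt <- config$simulation$dt_neural
  stride <- 1L   # need dense sampling to pick a shifted state
  base <- simulate_circuit(wiring, duration = settle, dt = dt,
                           record_stride = stride)
  fr <- estimate_frequency(neuron_trace(base, "DB", 4), base$dt)
  if (!attr(fr, "oscillatory")) stop("solution is not steadily oscillating")
  period <- 1 / fr

  n_back <- round((phase_shift_deg / 360) * period / base$dt)
  last <- nrow(base$V)
  Vpert <- base$V_final
  cols <- which(base$unit == perturbed_unit)
  src <- ((last - n_back - 1) %% last) + 1
  Vpert[cols] <- base$V[src, cols]

  st_ctrl <- circuit_state(wiring, V = base$V_final)
  st_pert <- circuit_state(wiring, V = Vpert)
  rec <- config$simulation$record_stride
  ctrl <- simulate_circuit(wiring, duration = measure_window, dt = dt,
                           state0 = st_ctrl, record_stride = rec)
  pert <- simulate_circuit(wiring, duration = measure_window, dt = dt,
                           state0 = st_pert, record_stride = rec)
  from <- measure_window / 2
  ctrl <- trace_window(ctrl, from = from)
  pert <- trace_window(pert, from = from)
  vapply(1:7, function(u) {
    phase_shift(neuron_trace(pert, "DB", u), neuron_trace(ctrl, "DB", u),
                ctrl$dt)
  }, numeric(1))
}
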