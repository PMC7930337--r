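#' Experimental manipulation masks
#'
#' Describes the manipulations applied to an embodied simulation, matching
#' the experimental protocols: silencing whole neural units (clamping their
#' neurons at rest with zero output), suppressing neuromuscular junctions by
#' class and/or by unit, removing individual evolved connections, keeping
#' only one interunit connection, and scaling the B-class interunit gap
#' junctions (overexpression).
#'
#' @param silence_units integer units (1-7) whose neurons are silenced.
#' @param silence_classes class labels silenced in every unit.
#' @param nmj_off_classes class labels whose NMJs are zeroed (e.g. `"DB"`;
#'   use `c("DA","VA")` for the A-class, `c("DB","VB")` for the B-class).
#' @param nmj_off_units units whose neurons' NMJs are all zeroed
#'   (muscle paralysis of a body region).
#' @param drop_connections connection slot names (see [genotype_layout()])
#'   removed from the wiring, e.g. `"g_VB_DBp1"` or `"AS_to_VD"`.
#' @param keep_only_interunit if non-`NULL`, the name of the single interunit
#'   connection retained; the other four are removed.
#' @param gj_B_factor B-class gap junction overexpression factor (>= 1).
#'   Factor 1 leaves the wiring untouched; larger values scale the evolved
#'   VB-DB+1 conductance by the factor and add DB-DB+1 and VB-VB+1 channels
#'   at conductance `(factor - 1) * g(VB-DB+1)`.
#' @return a `wcpg_masks` list.
#' @export
circuit_masks <- function(silence_units = NULL, silence_classes = NULL,
                          nmj_off_classes = NULL, nmj_off_units = NULL,
                          drop_connections = NULL, keep_only_interunit = NULL,
                          gj_B_factor = 1) {
  if (gj_B_factor < 1) stop("gj_B_factor must be >= 1")
  structure(list(silence_units = silence_units,
                 silence_classes = silence_classes,
                 nmj_off_classes = nmj_off_classes,
                 nmj_off_units = nmj_off_units,
                 drop_connections = drop_connections,
                 keep_only_interunit = keep_only_interunit,
                 gj_B_factor = gj_B_factor),
            class = c("wcpg_masks", "list"))
}

interunit_connection_names <- function() {
  c("DB_to_DDp1", "VAp1_to_DD", "g_DA_ASp1", "g_VB_DBp1", "g_AS_VAp1")
}

# resolve masks into (wiring, silenced, nmj_off) for a given decoded genotype
apply_masks <- function(params, n_units, masks) {
  if (is.null(masks)) masks <- circuit_masks()
  scale <- NULL
  extra <- NULL
  if (!is.null(masks$drop_connections)) {
    scale <- c(scale, stats::setNames(rep(0, length(masks$drop_connections)),
                                      masks$drop_connections))
  }
  if (!is.null(masks$keep_only_interunit)) {
    drop <- setdiff(interunit_connection_names(), masks$keep_only_interunit)
    scale <- c(scale, stats::setNames(rep(0, length(drop)), drop))
  }
  if (masks$gj_B_factor > 1) {
    g_base <- params$connectome$gap_inter[["g_VB_DBp1"]]
    scale <- c(scale, c(g_VB_DBp1 = masks$gj_B_factor))
    g_add <- (masks$gj_B_factor - 1) * g_base
    extra <- list(list(from = "DB", to = "DB", offset = 1L, g = g_add),
                  list(from = "VB", to = "VB", offset = 1L, g = g_add))
  }
  wiring <- build_circuit(params, n_units = n_units,
                          connection_scale = scale, extra_gaps = extra)
  silenced <- rep(FALSE, wiring$n)
  if (!is.null(masks$silence_units))
    silenced <- silenced | wiring$unit %in% masks$silence_units
  if (!is.null(masks$silence_classes))
    silenced <- silenced | wiring$class %in% masks$silence_classes
  nmj_off <- rep(FALSE, wiring$n)
  if (!is.null(masks$nmj_off_classes))
    nmj_off <- nmj_off | wiring$class %in% masks$nmj_off_classes
  if (!is.null(masks$nmj_off_units))
    nmj_off <- nmj_off | wiring$unit %in% masks$nmj_off_units
  list(wiring = wiring, silenced = silenced, nmj_off = nmj_off)
}

#' Run the embodied neuromechanical model
#'
#' Couples the seven-unit circuit, the muscles and the body in the clocked
#' loop: per neural step (0.5 ms) one circuit update and one muscle
#' activation update, then five body substeps (0.1 ms) with frozen
#' activations. The worm starts at rest (V = 0, A = 0, straight posture).
#' Identical inputs give bit-identical traces.
#'
#' @param genotype a [genotype()].
#' @param config a [wcpg_config()].
#' @param masks optional [circuit_masks()].
#' @param duration simulated seconds.
#' @param record_stride recording stride in neural steps.
#' @param check_overlap warn if the midline self-intersects (extreme
#'   genotypes can self-cross; contact is not modelled).
#' @return a `wcpg_trace` with neural outputs `S`, muscle activations `A`,
#'   midline coordinates `x`, `y` (rows = samples, columns = rods) and
#'   `time`. The transient is not discarded here; use [trace_window()].
#' @export
run_embodied <- function(genotype, config = wcpg_config(), masks = NULL,
                         duration = config$simulation$duration,
                         record_stride = config$simulation$record_stride,
                         check_overlap = FALSE) {
  params <- decode_genotype(genotype, config)
  mk <- apply_masks(params, n_units = 7, masks)
  geometry <- body_geometry(config)
  map <- muscle_map(params$gain_F, config)
  Mdrv <- muscle_drive_matrix(mk$wiring, map, nmj_off = mk$nmj_off)
  rest <- body_rest_state(geometry)

  dt_n <- config$simulation$dt_neural
  substeps <- round(dt_n / config$simulation$dt_body)
  if (abs(substeps * config$simulation$dt_body - dt_n) > 1e-12)
    stop("dt_neural must be an integer multiple of dt_body")
  n_macro <- round(duration / dt_n)

  res <- do.call(embodied_run_cpp, c(
    list(W = mk$wiring$W, G = mk$wiring$G, tau = mk$wiring$tau,
         theta = mk$wiring$theta, V0 = rep(0, mk$wiring$n),
         silenced = mk$silenced, tonic = rep(0, mk$wiring$n),
         Mdrv = Mdrv, tauM = config$muscle$tau_m,
         WmD = map$WmD, WmV = map$WmV), geom_args(geometry),
    list(x0 = rest$x, y0 = rest$y, phi0 = rest$phi, dt_neural = dt_n,
         substeps = as.integer(substeps), n_macro = as.integer(n_macro),
         record_stride = as.integer(record_stride))))
  if (any(!is.finite(res$x[nrow(res$x), ])))
    stop("simulation error: non-finite body state at end of run")
  colnames(res$S) <- mk$wiring$label
  tr <- structure(list(
    time = res$time, S = res$S, A = res$A, x = res$x, y = res$y,
    dt = dt_n * record_stride, n_units = mk$wiring$n_units,
    class = mk$wiring$class, unit = mk$wiring$unit,
    label = mk$wiring$label, body_length = geometry$length),
    class = c("wcpg_trace", "list"))
  if (check_overlap && midline_self_overlap(tr, geometry))
    warning("body midline self-intersects during the run")
  tr
}

# coarse geometric self-crossing check on subsampled frames
midline_self_overlap <- function(trace, geometry) {
  idx <- unique(round(seq(1, nrow(trace$x), length.out = 25)))
  thr <- 2 * mean(geometry$w)
  for (i in idx) {
    px <- trace$x[i, ]; py <- trace$y[i, ]
    n <- length(px)
    for (a in seq_len(n - 8)) {
      d2 <- (px[(a + 8):n] - px[a])^2 + (py[(a + 8):n] - py[a])^2
      if (any(d2 < thr^2)) return(TRUE)
    }
  }
  FALSE
}

#' Center-of-mass path of an embodied trace
#'
#' @param trace a `wcpg_trace` from [run_embodied()].
#' @return matrix (samples x 2) of the mean rod-center position.
#' @export
com_path <- function(trace) {
  if (is.null(trace$x)) stop("trace has no body data")
  cbind(x = rowMeans(trace$x), y = rowMeans(trace$y))
}

#' Mean forward speed of an embodied trace
#'
#' Net center-of-mass displacement projected on the mean heading (equal to
#' the net displacement magnitude) divided by the window duration, so pure
#' spinning or side-to-side wiggle scores ~0.
#'
#' @param trace a `wcpg_trace`, usually already windowed past the transient.
#' @return speed in mm/s.
#' @export
mean_velocity <- function(trace) {
  com <- com_path(trace)
  dur <- trace$time[nrow(com)] - trace$time[1]
  disp <- com[nrow(com), ] - com[1, ]
  sqrt(sum(disp^2)) / dur
}
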