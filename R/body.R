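#' Degrees of freedom of the segmented body
#'
#' Each of the `n_seg + 1` bounding rods carries two translational and one
#' rotational degree of freedom.
#'
#' @param n_seg number of body segments (>= 1).
#' @return `3 * (n_seg + 1)`.
#' @export
#' @examples
#' dof_count(50) # 153
dof_count <- function(n_seg) {
  if (!is.numeric(n_seg) || n_seg < 1 || n_seg != round(n_seg))
    stop("n_seg must be a positive integer")
  3L * (as.integer(n_seg) + 1L)
}

#' Body geometry
#'
#' Builds the rod-and-spring geometry from the configuration: a ~1 mm body of
#' `n_seg` variable-width segments. Half-widths taper towards head and tail
#' following `w(u) = w_max * sin(acos((2u - 1) / shape))` over the normalized
#' body coordinate u in \[0, 1\]; rest lengths of lateral and diagonal
#' elements are derived from the straight rest posture, which is therefore an
#' exact equilibrium.
#'
#' @param config a [wcpg_config()].
#' @return a `wcpg_geometry` list with widths, rest lengths, stiffness and
#'   damping vectors, drag coefficients and Hill-curve constants.
#' @export
body_geometry <- function(config = wcpg_config()) {
  b <- config$body
  n_seg <- as.integer(b$n_seg)
  n_rod <- n_seg + 1L
  u <- seq(0, 1, length.out = n_rod)
  w <- b$half_width_max * sin(acos((2 * u - 1) / b$width_shape))
  ds <- b$length / n_seg
  dw <- diff(w)
  l0_lat <- sqrt(ds^2 + dw^2)
  l0_diag <- sqrt(ds^2 + (w[-n_rod] + w[-1])^2)
  m <- config$muscle
  structure(list(
    n_seg = n_seg, n_rod = n_rod, length = b$length, w = w,
    l0_lat = l0_lat, l0_diag = l0_diag,
    k_lat = rep(b$k_lateral, n_seg), c_lat = rep(b$c_lateral, n_seg),
    k_diag = rep(b$k_diagonal, n_seg), c_diag = rep(b$c_diagonal, n_seg),
    drag_par = b$drag_par, drag_perp = b$drag_perp,
    c_rot = b$drag_perp * w^2 / 3,
    f_max = m$f_max, fl_width = m$fl_width, fv_vmax = m$fv_vmax,
    fv_hill = m$fv_hill, fv_cap = m$fv_cap),
    class = c("wcpg_geometry", "list"))
}

#' @export
print.wcpg_geometry <- function(x, ...) {
  cat(sprintf("wormCPG body geometry: %d segments (%d rods, %d DOF), %.2f mm long\n",
              x$n_seg, x$n_rod, dof_count(x$n_seg), x$length))
  invisible(x)
}

#' Straight rest posture
#'
#' Rod centers along the x axis, rods transverse (phi = pi/2, dorsal side
#' towards +y), all velocities zero. By construction this state is an exact
#' equilibrium of the passive body.
#'
#' @param geometry a [body_geometry()].
#' @return a `wcpg_body_state` list of x, y, phi and their velocities.
#' @export
body_rest_state <- function(geometry) {
  n_rod <- geometry$n_rod
  structure(list(
    x = seq(0, geometry$length, length.out = n_rod),
    y = rep(0, n_rod), phi = rep(pi / 2, n_rod),
    vx = rep(0, n_rod), vy = rep(0, n_rod), vphi = rep(0, n_rod)),
    class = c("wcpg_body_state", "list"))
}

geom_args <- function(g) {
  list(n_seg = g$n_seg, w = g$w, l0_lat = g$l0_lat, l0_diag = g$l0_diag,
       k_lat = g$k_lat, c_lat = g$c_lat, k_diag = g$k_diag, c_diag = g$c_diag,
       Cpar = g$drag_par, Cperp = g$drag_perp, c_rot = g$c_rot,
       Fmax = g$f_max, fl_width = g$fl_width, fv_vmax = g$fv_vmax,
       fv_hill = g$fv_hill, fv_cap = g$fv_cap)
}

#' Internal forces and torques
#'
#' Damped-spring forces of every lateral and diagonal element (plus active
#' muscle contraction if drives are given), resolved to per-rod generalized
#' forces. Damping is evaluated against the velocities stored in the state.
#'
#' @param state a `wcpg_body_state`.
#' @param geometry a [body_geometry()].
#' @param driveD,driveV per-segment dorsal/ventral muscle drives (default 0).
#' @return matrix (`n_rod` x 3) of force x, force y, torque.
#' @export
internal_forces <- function(state, geometry, driveD = 0, driveV = 0) {
  ga <- geom_args(geometry)
  do.call(body_internal_forces_cpp, c(
    list(x = state$x, y = state$y, phi = state$phi, vx = state$vx,
         vy = state$vy, vphi = state$vphi), ga,
    list(driveD = rep_len(driveD, geometry$n_seg),
         driveV = rep_len(driveV, geometry$n_seg))))
}

#' Drag forces of the agar environment
#'
#' Linear anisotropic drag per rod, `F = -C_par v_t - C_perp v_n`, where the
#' tangential direction is along the body midline (perpendicular to the rod)
#' and the normal direction is lateral slip along the rod axis, plus a
#' rotational drag torque `-c_rot * dphi/dt`.
#'
#' @param state a `wcpg_body_state`.
#' @param geometry a [body_geometry()] (provides the coefficients).
#' @return matrix (`n_rod` x 3) of drag force x, y and torque.
#' @export
drag_forces <- function(state, geometry) {
  d <- cbind(cos(state$phi), sin(state$phi))    # rod axis (lateral slip)
  t_ <- cbind(-d[, 2], d[, 1])                  # midline tangent
  v <- cbind(state$vx, state$vy)
  vt <- rowSums(v * t_)
  vn <- rowSums(v * d)
  f <- -geometry$drag_par * vt * t_ - geometry$drag_perp * vn * d
  cbind(f, -geometry$c_rot * state$vphi)
}

#' Advance the body
#'
#' Overdamped update `C(x) v = F_internal + F_muscle` solved per step with
#' damping implicit in the velocities and, for the default semi-implicit
#' method, the elastic Jacobian treated implicitly (linearized backward
#' Euler). The explicit variant keeps the elastic forces at the current
#' state and serves as the convergence reference.
#'
#' @param state a `wcpg_body_state`.
#' @param geometry a [body_geometry()].
#' @param driveD,driveV per-segment muscle drives, held constant.
#' @param dt body step, s (default 0.1 ms).
#' @param n_steps number of steps to take.
#' @param record_stride if not `NULL`, also return the midline trajectory
#'   recorded every `record_stride` steps.
#' @param method `"semi_implicit"` (default) or `"explicit"`.
#' @return the updated state; with `record_stride`, attribute `trajectory`
#'   holds `time`, `x`, `y`, `phi` matrices.
#' @export
body_step <- function(state, geometry, driveD = 0, driveV = 0, dt = 1e-4,
                      n_steps = 1L, record_stride = NULL,
                      method = c("semi_implicit", "explicit")) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  stride <- if (is.null(record_stride)) as.integer(n_steps) else
    as.integer(record_stride)
  ga <- geom_args(geometry)
  res <- do.call(body_run_cpp, c(
    list(x0 = state$x, y0 = state$y, phi0 = state$phi, vx0 = state$vx,
         vy0 = state$vy, vphi0 = state$vphi), ga,
    list(driveD = rep_len(driveD, geometry$n_seg),
         driveV = rep_len(driveV, geometry$n_seg), dt = dt,
         n_steps = as.integer(n_steps), record_stride = stride,
         implicit = method == "semi_implicit")))
  out <- structure(res$state, class = c("wcpg_body_state", "list"))
  if (!is.null(record_stride))
    attr(out, "trajectory") <- res[c("time", "x", "y", "phi")]
  out
}

#' Body midline from a state
#'
#' @param state a `wcpg_body_state`.
#' @return matrix (`n_rod` x 2) of rod-center coordinates.
#' @export
body_midline <- function(state) cbind(x = state$x, y = state$y)
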