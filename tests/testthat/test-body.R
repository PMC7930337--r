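geo <- body_geometry(wcfg)

test_that("degree-of-freedom count is 3(n_seg + 1)", {
  expect_equal(dof_count(50), 153)
  expect_equal(dof_count(1), 6)
  expect_equal(dof_count(10), 33)
  expect_error(dof_count(0))
})

test_that("geometry is positive and tapers at head and tail", {
  expect_equal(geo$n_rod, 51)
  expect_true(all(geo$w > 0))
  expect_lt(geo$w[1], max(geo$w))
  expect_lt(geo$w[geo$n_rod], max(geo$w))
  expect_true(all(c(geo$k_lat, geo$c_lat, geo$k_diag, geo$c_diag) > 0))
  expect_equal(geo$drag_perp / geo$drag_par, 40)
})

test_that("the straight rest posture carries zero internal force", {
  st <- body_rest_state(geo)
  f <- internal_forces(st, geo)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("drag matches the agar coefficients in the local frame", {
  st <- body_rest_state(geo)
  f0 <- drag_forces(st, geo)
  expect_equal(max(abs(f0)), 0)
  # unit velocity along the midline (tangential): magnitude C_par
  st$vx <- rep(1, geo$n_rod)
  ft <- drag_forces(st, geo)
  expect_equal(ft[, 1], rep(-3.2e-3, geo$n_rod))
  expect_equal(ft[, 2], rep(0, geo$n_rod))
  # unit velocity along the rods (normal/lateral slip): magnitude C_perp
  st <- body_rest_state(geo)
  st$vy <- rep(1, geo$n_rod)
  fn <- drag_forces(st, geo)
  expect_equal(fn[, 2], rep(-128e-3, geo$n_rod))
  expect_equal(fn[, 1], rep(0, geo$n_rod))
})

perturbed_state <- function(seed = 1, scale = 0.002) {
  set.seed(seed)
  st <- body_rest_state(geo)
  st$x <- st$x + rnorm(geo$n_rod, 0, scale)
  st$y <- st$y + rnorm(geo$n_rod, 0, scale)
  st$phi <- st$phi + rnorm(geo$n_rod, 0, 0.05)
  st
}

test_that("internal forces balance (Newton's third law)", {
  st <- perturbed_state(2)
  f <- internal_forces(st, geo)
  expect_lt(max(abs(colSums(f[, 1:2]))), 1e-10)
  # total torque about the origin also vanishes
  tot <- sum(st$x * f[, 2] - st$y * f[, 1]) + sum(f[, 3])
  expect_lt(abs(tot), 1e-10)
})

test_that("internal forces are translation invariant and rotation equivariant", {
  st <- perturbed_state(3)
  f <- internal_forces(st, geo)
  st2 <- st
  st2$x <- st$x + 1.7; st2$y <- st$y - 0.4
  expect_equal(internal_forces(st2, geo), f, tolerance = 1e-10)
  a <- 0.73
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  st3 <- st
  xy <- cbind(st$x, st$y) %*% t(R)
  st3$x <- xy[, 1]; st3$y <- xy[, 2]; st3$phi <- st$phi + a
  f3 <- internal_forces(st3, geo)
  expect_equal(f3[, 1:2], f[, 1:2] %*% t(R), tolerance = 1e-9)
  expect_equal(f3[, 3], f[, 3], tolerance = 1e-9)
})

test_that("mirroring the body about its long axis mirrors all forces", {
  st <- perturbed_state(4)
  dD <- runif(geo$n_seg); dV <- runif(geo$n_seg)
  f <- internal_forces(st, geo, driveD = dD, driveV = dV)
  sm <- st
  sm$y <- -st$y; sm$phi <- pi - st$phi
  # mirroring swaps dorsal and ventral sides, hence the drives too
  fm <- internal_forces(sm, geo, driveD = dV, driveV = dD)
  expect_equal(fm[, 1], f[, 1], tolerance = 1e-9)
  expect_equal(fm[, 2], -f[, 2], tolerance = 1e-9)
  expect_equal(fm[, 3], -f[, 3], tolerance = 1e-9)
})

test_that("a degenerate element is flagged", {
  st <- body_rest_state(geo)
  # move rod 26 so that its dorsal endpoint coincides with rod 25's
  st$x[26] <- st$x[25]
  st$y[26] <- st$y[25] + geo$w[25] - geo$w[26]
  expect_error(internal_forces(st, geo), "degenerate")
})

test_that("the resting body does not move under the integrator", {
  st <- body_rest_state(geo)
  out <- body_step(st, geo, dt = 1e-4, n_steps = 5000)
  expect_lt(max(abs(out$x - st$x)), 1e-9)
  expect_lt(max(abs(out$y - st$y)), 1e-9)
})

test_that("a single-sided constant drive bends the body dorsally, monotonically", {
  dD <- rep(0, geo$n_seg); dD[10:20] <- 4
  st <- body_rest_state(geo)
  curv_at <- function(st) {
    k <- curvature_kymograph(matrix(st$x, 1), matrix(st$y, 1),
                             smooth_window = 1)
    mean(k$curvature[1, 10:20])
  }
  vals <- numeric(5)
  for (i in 1:5) {
    st <- body_step(st, geo, driveD = dD, dt = 1e-4, n_steps = 2000)
    vals[i] <- curv_at(st)
  }
  expect_true(all(vals > 0))            # dorsal-positive convention
  expect_true(all(diff(vals) > -1e-6))  # develops monotonically, saturating
})

test_that("semi-implicit trajectories converge to the explicit reference", {
  dD <- rep(0, geo$n_seg); dD[5:25] <- 3
  final_midline <- function(dt, method) {
    st <- body_step(body_rest_state(geo), geo, driveD = dD, dt = dt,
                    n_steps = round(0.5 / dt), method = method)
    body_midline(st)
  }
  ref <- final_midline(5e-6, "explicit")
  e1 <- max(abs(final_midline(1e-4, "semi_implicit") - ref))
  e2 <- max(abs(final_midline(5e-5, "semi_implicit") - ref))
  expect_lt(e2, 0.75 * e1)   # first-order in dt
  expect_lt(e1, 5e-3)        # and close to the reference (mm)
})

test_that("drag dissipates non-negative power along an actuated run", {
  dD <- rep(0, geo$n_seg); dD[5:25] <- 4
  st <- body_rest_state(geo)
  for (i in 1:20) {
    st <- body_step(st, geo, driveD = dD, dt = 1e-4, n_steps = 100)
    fd <- drag_forces(st, geo)
    power <- -sum(fd[, 1] * st$vx + fd[, 2] * st$vy + fd[, 3] * st$vphi)
    expect_gte(power, 0)
  }
})
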