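test_that("curvature of canonical midlines is recovered", {
  # straight line: zero everywhere
  x <- matrix(seq(0, 1, length.out = 51), 1)
  y <- matrix(0, 1, 51)
  k <- curvature_kymograph(x, y, smooth_window = 1)
  expect_lt(max(abs(k$curvature)), 1e-10)

  # circular arc of radius r: constant curvature 1/r, sign by orientation
  r <- 0.4
  th <- seq(0, pi, length.out = 51)
  ka <- curvature_kymograph(matrix(r * cos(th), 1), matrix(r * sin(th), 1),
                            smooth_window = 1)
  # counterclockwise arc: constant positive curvature 1/r
  expect_equal(ka$curvature[1, ], rep(1 / r, 49), tolerance = 1e-3)

  # sinusoidal midline: curvature ~ -y'' / (1 + y'^2)^(3/2)
  xs <- seq(0, 1, length.out = 201)
  a <- 0.03; lam <- 0.5
  ys <- a * sin(2 * pi * xs / lam)
  ks <- curvature_kymograph(matrix(xs, 1), matrix(ys, 1), smooth_window = 1)
  # compare at interior points against the analytic expression (arclength
  # spacing differs from x spacing; match by position)
  xin <- xs[2:200]
  analytic <- -a * (2 * pi / lam)^2 * sin(2 * pi * xin / lam) /
    (1 + (a * 2 * pi / lam * cos(2 * pi * xin / lam))^2)^1.5
  expect_lt(max(abs(ks$curvature[1, ] - analytic)), 0.01 * max(abs(analytic)))

  expect_error(curvature_kymograph(matrix(0, 1, 2), matrix(0, 1, 2)),
               "3 midline")
})

test_that("body wavelength is recovered from constructed traveling waves", {
  # accurate recovery across the filter range, including the boundaries
  for (wl in c(0.4, 0.6, 0.9)) {
    est <- body_wavelength(synthetic_kymograph(wavelength = wl))
    expect_equal(as.numeric(est), wl, tolerance = 0.05 * wl)
  }
  # clear pass/fail classification away from the boundaries
  for (wl in c(0.45, 0.6, 0.85))
    expect_true(attr(body_wavelength(synthetic_kymograph(wl)), "pass"))
  long <- body_wavelength(synthetic_kymograph(wavelength = 1.5))
  expect_equal(as.numeric(long), 1.5, tolerance = 0.12)
  expect_false(attr(long, "pass"))
  half <- body_wavelength(synthetic_kymograph(wavelength = 0.5))
  expect_equal(as.numeric(half), 0.5, tolerance = 0.025)
  # spectral cross-check agrees roughly (coarse bins at these scales)
  sp <- body_wavelength(synthetic_kymograph(wavelength = 0.6),
                        method = "spectral")
  expect_equal(as.numeric(sp), 0.6, tolerance = 0.12)
  flat <- synthetic_kymograph(wavelength = 0.6, amplitude = 0)
  expect_false(attr(body_wavelength(flat), "oscillatory"))
})

test_that("anterior-posterior curvature slope separates profiles", {
  dec <- ap_curvature_slope(synthetic_kymograph(0.6, amp_slope = -2))
  expect_lt(dec$slope, 0)
  expect_true(dec$pass)
  inc <- ap_curvature_slope(synthetic_kymograph(0.6, amp_slope = 2))
  expect_gt(inc$slope, 0)
  expect_false(inc$pass)
  unif <- ap_curvature_slope(synthetic_kymograph(0.6, amp_slope = 0))
  expect_lt(abs(unif$slope), 0.2)   # ~flat profile, tiny sampling residue
})

test_that("trajectory curvature radius separates straight from curved paths", {
  straight <- trajectory_curvature_radius(synthetic_com_path("straight"))
  expect_true(is.infinite(straight))
  expect_true(attr(straight, "pass"))

  c1 <- trajectory_curvature_radius(synthetic_com_path("circle", radius = 1))
  expect_equal(as.numeric(c1), 1, tolerance = 0.02)

  c05 <- trajectory_curvature_radius(synthetic_com_path("circle", radius = 0.5))
  expect_equal(as.numeric(c05), 0.5, tolerance = 0.02)
  expect_false(attr(c05, "pass"))

  c2 <- trajectory_curvature_radius(synthetic_com_path("circle", radius = 2))
  expect_true(attr(c2, "pass"))

  still <- trajectory_curvature_radius(matrix(0.1, 50, 2))
  expect_true(attr(still, "stationary"))
})

test_that("phase shift between constructed rhythms is measured in degrees", {
  dt <- 0.01
  t <- seq(dt, 40, by = dt)
  base <- 0.5 + 0.4 * sin(2 * pi * 0.44 * t)
  expect_equal(phase_shift(base, base, dt), 0, tolerance = 1)
  quarter <- 0.5 + 0.4 * sin(2 * pi * 0.44 * (t + 0.25 / 0.44))
  expect_equal(phase_shift(quarter, base, dt), 90, tolerance = 2)
  half <- 0.5 + 0.4 * sin(2 * pi * 0.44 * (t + 0.5 / 0.44))
  expect_equal(abs(phase_shift(half, base, dt)), 180, tolerance = 2)
  # antisymmetry modulo the reporting interval
  s1 <- phase_shift(quarter, base, dt)
  s2 <- phase_shift(base, quarter, dt)
  expect_equal((s1 + s2 + 180) %% 360 - 180, 0, tolerance = 2)
  # mismatched frequencies are refused
  other <- 0.5 + 0.4 * sin(2 * pi * 0.6 * t)
  expect_error(phase_shift(base, other, dt), "mismatch")
  expect_error(phase_shift(rep(0.5, 100), base, dt), "oscillatory")
})

test_that("a subcircuit with no internal weights cannot oscillate", {
  v <- rep(0, 44)
  v[15:21] <- -1   # strongly inhibitory self-weights, no oscillation
  v[29:37] <- 0    # chemical weights at range midpoint = 0
  sc <- subcircuit_oscillation_score(genotype(v), "AS-DA-DB", wcfg,
                                     grid_points = 3, grid_span = 3,
                                     duration = 8, transient = 4)
  expect_equal(as.numeric(sc), 0)
})

test_that("masking connections that are already zero reproduces baseline bits", {
  g <- unclass(rand_genotype(21))
  g["g_AS_VAp1"] <- -1   # decodes to conductance exactly 0
  g <- genotype(g)
  a <- run_embodied(g, wcfg, duration = 1)
  b <- run_embodied(g, wcfg,
                    masks = circuit_masks(drop_connections = "g_AS_VAp1"),
                    duration = 1)
  expect_identical(a$S, b$S)
  expect_identical(a$x, b$x)
})

test_that("gap-junction overexpression at factor 1 is the identity", {
  g <- rand_genotype(22)
  a <- run_embodied(g, wcfg, duration = 1)
  b <- run_embodied(g, wcfg, masks = circuit_masks(gj_B_factor = 1),
                    duration = 1)
  expect_identical(a$S, b$S)
})

test_that("entrainment propagates only through interunit connections", {
  g <- demo_genotype("oscillator")
  # a zero-degree perturbation leaves every unit's phase untouched
  sh0 <- entrainment_analysis(g, perturbed_unit = 1, phase_shift_deg = 0,
                              wcfg, settle = 15, measure_window = 15)
  expect_true(all(abs(sh0) < 3))
  # with all interunit connections removed the shift cannot propagate
  gd <- unclass(g)
  gd[c("DB_to_DDp1", "VAp1_to_DD")] <- 0      # chemical weights -> 0
  gd[c("g_DA_ASp1", "g_VB_DBp1", "g_AS_VAp1")] <- -1  # conductances -> 0
  shd <- entrainment_analysis(genotype(gd), perturbed_unit = 1,
                              phase_shift_deg = 120, wcfg,
                              settle = 15, measure_window = 15)
  expect_equal(shd[1], 120, tolerance = 10)   # the perturbed unit keeps it
  expect_true(all(abs(shd[2:7]) < 3))         # nobody else adopts it
})

test_that("the subcircuit score finds the dorsal oscillator in the fixture", {
  s <- subcircuit_oscillation_score(demo_genotype("oscillator"), "AS-DA-DB",
                                    wcfg, grid_points = 5, grid_span = 4,
                                    duration = 8, transient = 2)
  expect_gt(as.numeric(s), 0)
})

test_that("an empty silencing region reproduces the unperturbed amplitudes", {
  res <- region_silencing_experiment(demo_genotype("oscillator"),
                                     integer(0), "neurons", wcfg,
                                     duration = 6, transient = 2)
  expect_equal(res$amplitude, res$baseline)
  expect_error(region_silencing_experiment(rand_genotype(1), 8, "neurons"),
               "units 1..7")
})
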