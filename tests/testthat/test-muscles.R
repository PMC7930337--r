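test_that("the anterior-posterior efficacy gradient follows gamma_m", {
  for (F_ in c(0, 0.3, 1)) {
    map <- muscle_map(F_, wcfg)
    expect_equal(map$gamma[1], 0.7)                      # gamma_1 always 0.7
    expect_equal(map$gamma, 0.7 * (1 - ((1:24 - 1) * F_) / 24))
    if (F_ > 0) expect_true(all(diff(map$gamma) < 0))
    expect_true(all(map$gamma > 0))
  }
  map0 <- muscle_map(0, wcfg)
  expect_equal(map0$gamma, rep(0.7, 24))                 # no gradient at F = 0
})

test_that("the muscle map covers all muscles and normalizes element weights", {
  map <- muscle_map(0.5, wcfg)
  expect_equal(map$n_per_side, 24)
  expect_equal(as.integer(table(map$muscle_unit)), c(4L, 3L, 3L, 3L, 3L, 3L, 5L))
  expect_equal(rowSums(map$WmD), rep(1, 24))
  expect_equal(rowSums(map$WmV), rep(1, 24))
})

test_that("muscle input sums signed NMJ contributions of the innervating unit", {
  p <- decode_genotype(rand_genotype(9), wcfg)
  w <- build_circuit(p, n_units = 7)
  map <- muscle_map(p$gain_F, wcfg)
  expect_equal(unname(muscle_input(rep(0, w$n), w, map)), rep(0, 48))
  # only DD of unit 1 active: dorsal muscles of unit 1 get negative drive
  S <- rep(0, w$n)
  S[w$label == "DD1"] <- 1
  I <- muscle_input(S, w, map)
  m1 <- which(map$muscle_unit == 1)
  expect_true(all(I[m1] < 0))
  expect_true(all(I[-m1] == 0))
  # hand-check the magnitude for muscle 1: gamma_1 * (-q_DD)
  qDD <- p$class_params$nmj_q[p$class_params$class == "DD"]
  expect_equal(unname(I[1]), -map$gamma[1] * qDD)
  # NMJ suppression of DD removes exactly that contribution
  I2 <- muscle_input(S, w, map, nmj_off = w$label == "DD1")
  expect_equal(unname(I2), rep(0, 48))
})

test_that("muscle activation is a leaky integrator with tau_M = 100 ms", {
  A <- 0
  for (i in 1:200) A <- muscle_activation_step(A, 2, dt = 5e-4, tau_m = 0.1)
  expect_equal(A, 2 * (1 - exp(-1)), tolerance = 5e-3)   # t = tau_M
  expect_equal(muscle_activation_step(1.5, 1.5, dt = 5e-4), 1.5)
  # square-wave input: closed-form RC response at the end of each half-cycle
  A <- 0; dt <- 5e-4; half <- 0.25
  for (cycle in 1:3) {
    for (i in seq_len(half / dt)) A <- muscle_activation_step(A, 1, dt)
    hi <- A
    for (i in seq_len(half / dt)) A <- muscle_activation_step(A, 0, dt)
    lo <- A
  }
  a <- exp(-half / 0.1)
  hi_ss <- (1 - a) / (1 - a^2)   # steady-state top of the filtered wave
  expect_equal(hi, hi_ss, tolerance = 1e-2)
  expect_equal(lo, hi_ss * a, tolerance = 1e-2)
})

test_that("bounded drives pull activations into the same bounds", {
  set.seed(10)
  A <- 5   # start far outside [a, b]
  for (i in 1:6000) A <- muscle_activation_step(A, runif(1, -0.5, 1), 5e-4)
  expect_gte(A, -0.5)
  expect_lte(A, 1)
})

test_that("Hill factors behave as force-length and force-velocity curves", {
  expect_equal(force_length(1), 1)
  expect_equal(force_length(1.6, width = 0.5), 0)
  expect_lt(force_length(1.2), force_length(1.05))
  expect_equal(force_velocity(0), 1)
  v <- seq(0, 4, by = 0.5)
  expect_true(all(diff(force_velocity(v, vmax = 4)) < 0))
  expect_lt(force_velocity(3), 1)     # fast shortening < isometric
  expect_gte(force_velocity(-2), 1)   # lengthening enhancement, capped
  expect_lte(force_velocity(-100), 1.5)
})

test_that("muscle force follows A x FL x FV x weight", {
  geo <- body_geometry(wcfg)
  expect_equal(muscle_force(0, 0.02, 0, 0.02, 1, geo), 0)
  iso <- muscle_force(2, 0.02, 0, 0.02, 0.5, geo)
  expect_equal(iso, geo$f_max * 2 * 0.5)   # FL = FV = 1 at the optimum
  fast <- muscle_force(2, 0.02, -0.06, 0.02, 0.5, geo)  # rapid shortening
  expect_lt(fast, iso)
})
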