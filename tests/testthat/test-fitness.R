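test_that("frequency estimation recovers known rhythms", {
  dt <- 0.005
  t <- seq(dt, 60, by = dt)
  f_sin <- estimate_frequency(sin(2 * pi * 0.44 * t), dt)
  expect_equal(as.numeric(f_sin), 0.44, tolerance = 1e-3)
  expect_true(attr(f_sin, "oscillatory"))

  f_const <- estimate_frequency(rep(0.7, 1000), dt)
  expect_equal(as.numeric(f_const), 0)
  expect_false(attr(f_const, "oscillatory"))

  sq <- sign(sin(2 * pi * 1 * t))          # 1 Hz square wave
  expect_equal(as.numeric(estimate_frequency(sq, dt)), 1, tolerance = 1e-3)

  f_sp <- estimate_frequency(sin(2 * pi * 0.44 * t), dt, method = "spectral")
  expect_equal(as.numeric(f_sp), 0.44, tolerance = 0.02)
})

test_that("F1 algebra matches the rhythmic-pattern fitness", {
  dt <- 0.005
  t <- seq(0, 50, by = dt)
  s_thr <- 0.5 + 0.5 * sin(2 * pi * 0.44 * t)   # threshold amplitude at f_a
  expect_equal(fitness_F1(s_thr, s_thr, dt, wcfg$fitness), 1,
               tolerance = 1e-3)
  # constant traces carry no variation
  expect_equal(fitness_F1(rep(0.5, 1000), rep(0.5, 1000), dt), 0)
  # twice the target frequency zeroes the frequency term
  s2 <- 0.5 + 0.5 * sin(2 * pi * 0.88 * t)
  expect_equal(fitness_F1(s2, s2, dt, wcfg$fitness), 0)
  # invariant to an additive offset
  expect_equal(fitness_F1(s_thr + 0.2, s_thr, dt),
               fitness_F1(s_thr, s_thr, dt))
  # amplitude term caps at 1 for supra-threshold oscillations
  s_big <- 0.5 + 0.5 * sin(2 * pi * 0.44 * t)
  s_sup <- 0.5 + 0.45 * sin(2 * pi * 0.44 * t)
  expect_gte(fitness_F1(s_big, s_big, dt), fitness_F1(s_sup, s_sup, dt))
  expect_lte(fitness_F1(s_big, s_big, dt), 1)
})

test_that("F2 algebra matches the velocity fitness", {
  expect_equal(fitness_F2(0.22, wcfg$fitness), 1)
  expect_equal(fitness_F2(0, wcfg$fitness), 0)
  expect_equal(fitness_F2(0.44, wcfg$fitness), 0)
  expect_equal(fitness_F2(0.11, wcfg$fitness), 0.5)
  expect_equal(fitness_F2(1, wcfg$fitness), 0)   # floored at 0
})

test_that("the GA maximizes a sphere function and elitism is monotone", {
  ga <- list(pop_size = 40, generations = 80, mutation_sigma = 0.08,
             recomb_prob = 0.5, elitism = 1)
  res <- ga_run(function(v) 1 - sum(v^2) / length(v), n_params = 10,
                ga = ga, seed = 3)
  expect_gt(res$best_fitness, 0.9)
  expect_true(all(diff(res$history$best) >= 0))
})

test_that("a flat fitness landscape leaves best fitness constant", {
  ga <- list(pop_size = 10, generations = 15, mutation_sigma = 0.1,
             recomb_prob = 0.5, elitism = 1)
  res <- ga_run(function(v) 0.5, n_params = 5, ga = ga, seed = 1)
  expect_true(all(res$history$best == 0.5))
})

test_that("a throwing fitness function scores zero, not an error", {
  ga <- list(pop_size = 6, generations = 3, mutation_sigma = 0.1,
             recomb_prob = 0.5, elitism = 1)
  expect_message(
    res <- ga_run(function(v) if (v[1] > 0) stop("boom") else 0.3,
                  n_params = 3, ga = ga, seed = 2),
    "scoring 0")
  expect_true(all(res$fitness %in% c(0, 0.3)))
})
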