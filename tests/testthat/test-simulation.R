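test_that("identical inputs give bit-identical embodied traces", {
  g <- rand_genotype(12)
  a <- run_embodied(g, wcfg, duration = 1)
  b <- run_embodied(g, wcfg, duration = 1)
  expect_identical(a$S, b$S)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
})

test_that("a worm without neuromuscular junctions does not move", {
  tr <- run_embodied(zero_actuation_genotype(), wcfg, duration = 2)
  com <- com_path(tr)
  expect_lt(max(abs(sweep(com, 2, com[1, ]))), 1e-12)
})

test_that("silencing every neuron reproduces the zero-actuation run", {
  g <- rand_genotype(13)
  off <- run_embodied(g, wcfg, masks = circuit_masks(silence_units = 1:7),
                      duration = 1)
  expect_lt(max(abs(off$S)), 1e-15)
  rest <- body_rest_state(body_geometry(wcfg))
  expect_equal(off$x[nrow(off$x), ], rest$x, tolerance = 1e-12)
  expect_equal(off$y[nrow(off$y), ], rest$y, tolerance = 1e-12)
})

test_that("recording stride does not alter the dynamics", {
  g <- rand_genotype(14)
  a <- run_embodied(g, wcfg, duration = 1, record_stride = 10)
  b <- run_embodied(g, wcfg, duration = 1, record_stride = 5)
  sub <- seq(2, nrow(b$S), by = 2)
  expect_identical(a$S, b$S[sub, , drop = FALSE])
  expect_identical(a$x, b$x[sub, , drop = FALSE])
})

test_that("a dead circuit holds every output at sigma(theta)", {
  v <- rep(0, 44)
  # zero all chemical, self and gap weights; biases stay mid-range (0)
  v[15:21] <- 0
  g <- genotype(v)
  p <- decode_genotype(g, wcfg)
  w <- build_circuit(p, n_units = 1)
  w$W[] <- 0; w$G[] <- 0
  tr <- simulate_circuit(w, duration = 2)
  expect_lt(max(abs(sweep(tr$S, 2, sigmoid(w$theta)))), 1e-12)
})

test_that("dt_neural must be a multiple of dt_body", {
  bad <- wcpg_config(overrides = list(simulation = list(dt_body = 3e-4)))
  expect_error(run_embodied(rand_genotype(1), bad, duration = 0.1),
               "multiple")
})
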