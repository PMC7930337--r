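test_that("sigmoid has the symmetry and saturation of a synaptic output", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1) + sigmoid(-1), 1)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  x <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
})

test_that("genotype layout counts 28 class + 15 connection + 1 gain slots", {
  layout <- genotype_layout()
  expect_equal(nrow(layout), 44)
  expect_equal(sum(layout$kind %in% c("bias", "tau", "w_self", "nmj")), 28)
  expect_equal(sum(layout$kind %in% c("chem", "gap")), 15)
  expect_equal(sum(layout$kind == "gain_F"), 1)
})

test_that("all-zero genotype decodes to range midpoints", {
  p <- decode_genotype(genotype(rep(0, 44)), wcfg)
  rg <- wcfg$ranges
  expect_equal(p$class_params$bias, rep(mean(rg$bias), 7))
  expect_equal(p$class_params$tau, rep(mean(rg$tau), 7))
  expect_equal(p$class_params$nmj_q, rep(mean(rg$nmj), 7))
  expect_equal(unname(p$connectome$gap_intra), mean(rg$gap))
  expect_equal(p$gain_F, mean(rg$gain_F))
})

test_that("decoding rejects malformed genotypes", {
  expect_error(genotype(rep(0, 43)), "44")
  expect_error(decode_genotype(rep(0, 45)), "44")
  bad <- wcpg_config(overrides = list(ranges = list(gap = NULL)))
  expect_error(decode_genotype(genotype(rep(0, 44)), bad), "range")
})

test_that("decode then re-encode returns the original genotype", {
  for (s in c(1, 7, 23)) {
    g <- rand_genotype(s)
    g2 <- encode_genotype(decode_genotype(g, wcfg), wcfg)
    expect_equal(unclass(g2), unclass(g), tolerance = 1e-12)
  }
})

test_that("NMJ signs follow neurotransmitter identity", {
  p <- decode_genotype(rand_genotype(3), wcfg)
  signs <- with(p$class_params, stats::setNames(nmj_sign, class))
  expect_equal(unname(signs[c("DD", "VD")]), c(-1, -1))
  expect_equal(unname(signs[c("AS", "DA", "DB", "VA", "VB")]), rep(1, 5))
  expect_true(all(p$class_params$tau > 0))
})

test_that("build_circuit instantiates the right neurons and edges", {
  p <- decode_genotype(rand_genotype(4), wcfg)
  w7 <- build_circuit(p, n_units = 7)
  expect_equal(w7$n, 49)
  expect_equal(w7$G, t(w7$G))

  w1 <- build_circuit(p, n_units = 1)
  expect_equal(w1$n, 7)
  # no interunit edges in a single unit: 9 chem + 7 self, 1 gap (2 entries)
  expect_equal(sum(w1$W != 0), 16)
  expect_equal(sum(w1$G != 0), 2)

  w2 <- build_circuit(p, n_units = 2)
  inter_chem <- sum(w2$W != 0 & outer(w2$unit, w2$unit, "!="))
  inter_gap <- sum(w2$G != 0 & outer(w2$unit, w2$unit, "!=")) / 2
  expect_equal(inter_chem, 2)
  expect_equal(inter_gap, 3)

  expect_error(build_circuit(p, n_units = 0), "n_units")
})

test_that("an isolated leaky neuron decays exponentially", {
  p <- decode_genotype(genotype(rep(0, 44)), wcfg)
  w <- build_circuit(p, n_units = 1)
  w$W[] <- 0; w$G[] <- 0
  w$tau <- rep(1, 7); w$theta <- rep(0, 7)
  st <- circuit_state(w, V = 1)
  dt <- 5e-4
  for (i in 1:2000) st <- neural_step(st, w, dt = dt)   # t = 1 s
  expect_equal(st$V, rep(exp(-1), 7), tolerance = 1e-3)
})

test_that("a self-excited neuron settles on the root of V = w sigma(V + theta)", {
  p <- decode_genotype(genotype(rep(0, 44)), wcfg)
  w <- build_circuit(p, n_units = 1)
  w$W[] <- 0; w$G[] <- 0
  w$tau <- rep(0.2, 7); w$theta <- rep(0, 7)
  diag(w$W) <- 2   # w_self = 2 for every neuron
  target <- stats::uniroot(function(v) v - 2 * sigmoid(v), c(0.5, 3),
                           tol = 1e-12)$root   # independent oracle
  st <- circuit_state(w, V = 1)
  for (i in 1:20000) st <- neural_step(st, w, dt = 5e-4)
  expect_equal(st$V, rep(target, 7), tolerance = 1e-6)
})

test_that("a gap-junction pair equalizes at rate (1 + 2g) / tau", {
  p <- decode_genotype(genotype(rep(0, 44)), wcfg)
  w <- build_circuit(p, n_units = 1)
  w$W[] <- 0; w$G[] <- 0
  w$tau <- rep(1, 7); w$theta <- rep(0, 7)
  g <- 0.5
  w$G[1, 2] <- w$G[2, 1] <- g
  st <- circuit_state(w)
  st$V[1] <- 1; st$V[2] <- -1
  d0 <- st$V[1] - st$V[2]
  for (i in 1:2000) st <- neural_step(st, w, dt = 5e-4)  # t = 1 s
  expect_equal((st$V[1] - st$V[2]) / d0, exp(-(1 + 2 * g)), tolerance = 2e-3)
})

test_that("symmetric gap tables conserve total gap current", {
  set.seed(5)
  for (rep in 1:5) {
    p <- decode_genotype(rand_genotype(rep), wcfg)
    w <- build_circuit(p, n_units = 7)
    V <- rnorm(w$n)
    gap_in <- as.vector(crossprod(w$G, V)) - colSums(w$G) * V
    expect_lt(abs(sum(gap_in)), 1e-12)
  }
})

test_that("synaptic outputs stay inside (0, 1) along a whole trajectory", {
  p <- decode_genotype(rand_genotype(6), wcfg)
  tr <- simulate_circuit(build_circuit(p, n_units = 7), duration = 5)
  expect_true(all(tr$S > 0 & tr$S < 1))
})

test_that("the neural integrator converges at first order under dt halving", {
  g <- demo_genotype("oscillator")
  p <- decode_genotype(g, wcfg)
  w <- build_circuit(p, n_units = 1)
  run_at <- function(dt) {
    tr <- simulate_circuit(w, duration = 10, dt = dt,
                           record_stride = round(0.01 / dt))
    tr$V
  }
  v1 <- run_at(5e-4); v2 <- run_at(2.5e-4); v3 <- run_at(1.25e-4)
  e1 <- max(abs(v1 - v2))
  e2 <- max(abs(v2 - v3))
  expect_lt(e2, 0.8 * e1)       # error shrinks ~linearly with dt
  expect_lt(e1, 0.5)            # and is small on a 10 s trajectory
})

test_that("large steps trigger the Euler stability warning", {
  p <- decode_genotype(genotype(rep(0, 44)), wcfg)
  w <- build_circuit(p, n_units = 1)
  w$tau <- rep(0.01, 7)
  expect_warning(neural_step(circuit_state(w), w, dt = 0.05), "unstable")
})

test_that("silencing a neuron equals removing its outgoing edges", {
  p <- decode_genotype(rand_genotype(8), wcfg)
  w <- build_circuit(p, n_units = 2)
  target <- which(w$label == "AS1")
  st <- circuit_state(w)
  st$silenced[target] <- TRUE
  tr_masked <- simulate_circuit(w, duration = 3, state0 = st)

  w_cut <- w
  w_cut$W[target, ] <- 0
  w_cut$G[target, ] <- w_cut$G[, target] <- 0
  tr_cut <- simulate_circuit(w_cut, duration = 3)

  others <- setdiff(seq_len(w$n), target)
  expect_identical(tr_masked$V[, others], tr_cut$V[, others])
})
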