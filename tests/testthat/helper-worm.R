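# shared fixtures, built once per test run

wcfg <- wcpg_config()

# deterministic pseudo-random genotypes
rand_genotype <- function(seed) {
  set.seed(seed)
  genotype(runif(44, -1, 1))
}

# a genotype whose NMJ magnitudes are zero (no actuation)
zero_actuation_genotype <- function(seed = 11) {
  g <- unclass(rand_genotype(seed))
  g[grep("^nmj_", names(g))] <- -1   # maps to q = 0
  genotype(g)
}

# memoized embodied runs of the committed demo locomotor (they are the
# expensive part of the suite; several tests share the same conditions)
.demo_runs <- new.env(parent = emptyenv())

demo_run <- function(key = "base", masks = NULL, duration = 15) {
  id <- paste0(key, "@", duration)
  if (is.null(.demo_runs[[id]]))
    .demo_runs[[id]] <- run_embodied(demo_genotype("locomotor"), wcfg,
                                     masks = masks, duration = duration)
  .demo_runs[[id]]
}

demo_window <- function(key = "base", masks = NULL, duration = 15,
                        transient = 5) {
  trace_window(demo_run(key, masks, duration), from = transient)
}
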