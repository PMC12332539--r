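# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code from seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small three-level toy (65 / 640 / 8088 molecules) with lightly trained
# encoders: enough latent structure for mechanism tests, fast to build.
small_toy <- function() memo("small_toy", function() {
  toy <- make_toy_hierarchy(2L, 4L, 8L, seed = 7L)
  sys <- build_bo_system(toy$hierarchy, toy$oracle, encoder_seed = 3L,
                         hyper = list(encoder_hyperparams(epochs = 60L),
                                      encoder_hyperparams(epochs = 40L),
                                      encoder_hyperparams(epochs = 20L,
                                                          batch_size = 1024L)))
  list(toy = toy, sys = sys)
})

# Study-condition toy for the multi-level vs standard comparison: a
# 37,960-molecule high-resolution space so the matched budget covers only
# a fraction of a percent of it.
funnel_toy <- function() memo("funnel_toy", function() {
  toy <- make_toy_hierarchy(2L, 6L, 12L, seed = 7L)
  sys <- build_bo_system(toy$hierarchy, toy$oracle, encoder_seed = 3L,
                         hyper = list(encoder_hyperparams(epochs = 150L),
                                      encoder_hyperparams(epochs = 100L),
                                      encoder_hyperparams(epochs = 30L,
                                                          batch_size = 1024L)))
  list(toy = toy, sys = sys)
})

funnel_config <- function(bo_seed, cluster_seed = bo_seed + 10L,
                          total_budget = 80L) {
  run_config(n_init = 10L, total_budget = total_budget, sigma_n = 0.05,
             pool_cap = 300L,
             seeds = list(oracle = 1L, encoder = 3L,
                          cluster = cluster_seed, bo = bo_seed))
}

# A permuted copy of a molecule (relabels nodes by `perm`).
permute_molecule <- function(m, perm, bead_table) {
  inv <- order(perm)
  edges <- m$edges
  if (nrow(edges)) edges <- matrix(inv[edges], ncol = 2L)
  cg_molecule(m$level, m$node_types[perm], edges, bead_table = bead_table)
}
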