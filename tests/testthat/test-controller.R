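test_that("a multi-level run respects budget, level contract and
           deduplication", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 101L, total_budget = 45L)
  tr <- run_multilevel(cfg, st$sys)
  expect_s3_class(tr, "bo_trace")
  expect_lte(nrow(tr), 45L)
  expect_equal(tr$iteration, seq_len(nrow(tr)))
  # starts at the lowest resolution: prior then init phases at level 1
  expect_true(all(tr$level[tr$phase %in% c("prior", "init")] == 1L))
  expect_equal(tr$phase[1], "prior")
  # levels change only at logged transition events
  tt <- trace_transitions(tr)
  lv <- tr$level[tr$phase == "bo"]
  if (length(lv) > 1L) {
    changes <- sum(diff(lv) != 0)
    expect_lte(changes, nrow(tt))
  }
  # no molecule evaluated twice at the same level
  expect_false(anyDuplicated(tr[, c("canonical_key", "level")]) > 0)
  # cumulative best is the running minimum and non-increasing
  expect_equal(tr$cum_best, cummin(tr$y))
  expect_true(all(diff(tr$cum_best) <= 0))
})

test_that("identical seeds give byte-identical traces", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 77L, total_budget = 40L)
  t1 <- run_multilevel(cfg, st$sys)
  t2 <- run_multilevel(cfg, st$sys)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(trace_transitions(t1), trace_transitions(t2))
  cfg2 <- funnel_config(bo_seed = 78L, total_budget = 40L)
  t3 <- run_multilevel(cfg2, st$sys)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("the single-level baseline stays at the top resolution", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 55L, total_budget = 30L)
  tr <- run_single_level(cfg, st$sys)
  expect_true(all(tr$level == st$sys$d))
  expect_equal(nrow(trace_transitions(tr)), 0L)
  expect_true(all(diff(tr$cum_best) <= 0))
  expect_equal(nrow(tr), 30L)
})

test_that("budget below the mandatory initialization is rejected", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 1L, total_budget = 5L)
  expect_error(run_multilevel(cfg, st$sys), "budget")
})

test_that("every evaluated high-level molecule passed the restriction
           rule or its fallback", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 101L, total_budget = 45L)
  tr <- run_multilevel(cfg, st$sys)
  hi <- tr[tr$phase == "bo" & tr$level > 1L, ]
  if (nrow(hi)) {
    expect_true(all(!is.na(hi$pool_fallback)))
    expect_true(all(hi$pool_size >= 1L))
  }
})

test_that("the fast candidate pool agrees with the generic restriction
           path", {
  st <- small_toy()
  sys <- st$sys
  idx2 <- sys$indices[[2]]; idx1 <- sys$indices[[1]]
  land <- oracle_landscape(st$toy$oracle, idx1$space)
  sb <- seed_bead_prior(st$toy$oracle, st$toy$hierarchy, noisy = FALSE)
  f0 <- cgfunnel:::.space_f0(sb$prior, idx1$space)
  rows <- order(land$y)[1:10]
  lower <- gp_update(gp_surrogate(1, xi = 2, sigma_n = 0.05,
                                  prior_mean = function(Z) rep(0, nrow(Z))),
                     idx1$coords[rows, , drop = FALSE], land$y[rows],
                     keys = idx1$space$keys[rows], prior_vals = f0[rows])
  pool <- restrict_candidates(idx2, character(0), lower, idx1,
                              st$toy$hierarchy, switch_policy(),
                              pool_cap = 50)
  # generic path must rank by the same mapped posterior means it reports
  md <- cgfunnel:::.map_rows_down(idx2$space, pool$rows, st$toy$hierarchy,
                                  idx1)
  mu <- gp_posterior(lower, md$coords)$mean
  expect_equal(pool$prior_mu, mu, tolerance = 1e-9)
  expect_true(!is.unsorted(pool$prior_mu))
})

test_that("run configurations load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("levels: 3", "n_init: 12", "total_budget: 50",
               "error_threshold: 0.2", "consecutive_required: 2",
               "down_factor: 1.5", "sigma_n: 0.07", "pool_cap: 123",
               "mode: single", "alpha: 0.4",
               "seeds:", "  oracle: 4", "  bo: 9"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$n_init, 12L)
  expect_equal(cfg$total_budget, 50L)
  expect_equal(cfg$policy$error_threshold, 0.2)
  expect_equal(cfg$policy$consecutive_required, 2L)
  expect_equal(cfg$policy$down_factor, 1.5)
  expect_equal(cfg$sigma_n, 0.07)
  expect_equal(cfg$pool_cap, 123L)
  expect_equal(cfg$mode, "single")
  expect_equal(cfg$seeds$oracle, 4L)
  expect_equal(cfg$seeds$bo, 9L)
  expect_equal(cfg$seeds$cluster, 1L)  # default fills the gap
})

test_that("traces round-trip through CSV export", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 55L, total_budget = 30L)
  tr <- run_single_level(cfg, st$sys)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$y, tr$y)
})

test_that("encoder, surrogate and oracle state serialize round-trip", {
  st <- small_toy()
  idx1 <- st$sys$indices[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  save_encoder(idx1$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_encoder(path)
  m <- space_molecule(idx1$space, 1)
  expect_identical(encode(back, m), encode(idx1$model, m))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_embeddings_csv(idx1, csv)
  emb <- utils::read.csv(csv)
  expect_equal(nrow(emb), space_size(idx1$space))
  expect_equal(ncol(emb), 6L)
  sdir <- withr::local_tempdir()
  sur <- gp_update(gp_surrogate(1, xi = 2, sigma_n = 0.05),
                   idx1$coords[1:3, , drop = FALSE], c(1, 2, 3),
                   keys = idx1$space$keys[1:3], prior_vals = c(0, 0, 0))
  save_surrogate(sur, sdir)
  meta <- jsonlite::read_json(file.path(sdir, "surrogate.json"))
  expect_equal(meta$n_obs, 3L)
  ojson <- withr::local_tempfile(fileext = ".json")
  oracle_to_json(st$toy$oracle, ojson)
  replay <- jsonlite::read_json(ojson)
  rebuilt <- make_toy_hierarchy(2, 4, 8, seed = replay$seed - 1L)$oracle
  expect_identical(rebuilt$levels, st$toy$oracle$levels)
})
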