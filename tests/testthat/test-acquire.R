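test_that("expected improvement matches its limiting cases and
           monotonicities", {
  expect_equal(expected_improvement(1, 0, 0.5), 0)    # no improvement
  expect_equal(expected_improvement(-1, 0, 0), 1)     # deterministic gain
  # EI at mu = y*, sigma = 1 is phi(0)
  expect_equal(expected_improvement(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_error(expected_improvement(0, -1, 0), "nonnegative")
  # nonnegative, increasing in sigma at fixed mu < y*, sigma -> 0 limit
  mus <- seq(-2, 2, by = 0.5)
  for (mu in mus) {
    eis <- expected_improvement(rep(mu, 4), c(0.01, 0.1, 0.5, 2), 0.3)
    expect_true(all(eis >= 0))
    # nondecreasing in sigma (strictness is lost to underflow when the
    # improvement is many sigmas certain)
    if (mu < 0.3) {
      expect_true(all(diff(eis) >= 0))
      expect_gt(eis[4], eis[3])
    }
    expect_equal(expected_improvement(mu, 1e-9, 0.3), max(0.3 - mu, 0),
                 tolerance = 1e-6)
  }
})

test_that("weighted k-medoids picks the middle of a uniform segment and
           degenerates correctly", {
  Z <- matrix(0, 5, 2)
  Z[, 1] <- c(0, 1, 2, 3, 4)
  # brute force: the medoid minimizing the summed distance is the middle
  med <- cgfunnel:::.kmedoids_weighted(Z, rep(1, 5), 1, seed = 1,
                                       n_restarts = 5)
  expect_equal(med, 3L)
  # heavily weighting an endpoint moves the medoid there
  med_w <- cgfunnel:::.kmedoids_weighted(Z, c(100, 1, 1, 1, 1), 1,
                                         seed = 1, n_restarts = 5)
  expect_equal(med_w, 1L)
})

test_that("initialization points come from the space, are distinct and
           beat random subsets in weighted cost", {
  st <- small_toy()
  idx <- st$sys$indices[[1]]
  sb <- seed_bead_prior(st$toy$oracle, st$toy$hierarchy, noisy = FALSE)
  keys <- init_points(idx, sb$prior, 10, seed = 4)
  expect_equal(length(keys), 10L)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(keys %in% space_keys(idx$space)))
  # full-space request returns every molecule
  all_keys <- init_points(idx, sb$prior, space_size(idx$space), seed = 4)
  expect_setequal(all_keys, space_keys(idx$space))
  # weighted cost of the clustering never exceeds 100 random subsets
  w <- exp(-cgfunnel:::.space_f0(sb$prior, idx$space))
  cost <- function(rows) {
    D <- sqrt(cgfunnel:::cross_dist2(idx$coords,
                                     idx$coords[rows, , drop = FALSE]))
    sum(w * apply(D, 1, min))
  }
  chosen <- cost(match(keys, space_keys(idx$space)))
  set.seed(9)
  rand <- replicate(100, cost(sample(nrow(idx$coords), 10)))
  expect_lte(chosen, min(rand))
})

test_that("prior weights follow w = exp(-f0)", {
  prior <- bead_prior(c(A = log(2)))
  tab <- cgfunnel:::as_bead_table(
    data.frame(code = "A", chem_class = "A", size_class = "R",
               charge = 0L, level = 1L, parent_code = NA_character_,
               logp = 0, stringsAsFactors = FALSE), 1L)
  sp <- enumerate_molecules(tab, 1)
  expect_equal(exp(-cgfunnel:::.space_f0(prior, sp)), 0.5)
})

test_that("the up-switch needs the required consecutive sub-threshold
           errors", {
  pol <- switch_policy(0.12, 3L, 2)
  expect_true(should_level_up(c(0.10, 0.11, 0.08), pol))
  expect_false(should_level_up(c(0.10, 0.13, 0.08), pol))
  expect_false(should_level_up(c(0.05, 0.05), pol))
  expect_true(should_level_up(c(0.5, 0.4, 0.1, 0.11, 0.08), pol))
  expect_false(should_level_up(c(0.1, 0.11, 0.12), pol))  # strict <
})

test_that("the down-switch fires strictly beyond two lengthscales", {
  pol <- switch_policy(0.12, 3L, 2)
  ev <- rbind(rep(0, 5))
  far <- c(2.5, 0, 0, 0, 0)    # 2.5 xi away at xi = 1
  expect_true(should_level_down(far, ev, 1, pol))
  at_edge <- c(2, 0, 0, 0, 0)  # exactly 2 xi: strict inequality
  expect_false(should_level_down(at_edge, ev, 1, pol))
  expect_false(should_level_down(rep(0, 5), ev, 1, pol))
  expect_false(should_level_down(far, NULL, 1, pol))  # no history
})

test_that("candidate restriction keeps reliable promising molecules and
           never returns evaluated ones", {
  st <- small_toy()
  sys <- st$sys
  idx2 <- sys$indices[[2]]
  idx1 <- sys$indices[[1]]
  sb <- seed_bead_prior(st$toy$oracle, st$toy$hierarchy, noisy = FALSE)
  f0 <- cgfunnel:::.space_f0(sb$prior, idx1$space)
  # train the lower surrogate on a few molecules around the best f0 region
  rows <- order(f0)[1:8]
  land <- oracle_landscape(st$toy$oracle, idx1$space)
  lower <- gp_update(gp_surrogate(1, xi = 2, sigma_n = 0.05),
                     idx1$coords[rows, , drop = FALSE], land$y[rows],
                     keys = idx1$space$keys[rows],
                     prior_vals = f0[rows])
  evaluated <- space_keys(idx2$space)[1:5]
  pool <- restrict_candidates(idx2, evaluated, lower, idx1,
                              st$toy$hierarchy, switch_policy(),
                              pool_cap = 100)
  expect_true(length(pool$rows) > 0)
  expect_lte(length(pool$rows), 100)
  expect_false(any(pool$keys %in% evaluated))
  # brute-force check of the admissibility rule for every pool member
  md <- cgfunnel:::.map_rows_down(idx2$space, pool$rows,
                                  st$toy$hierarchy, idx1)
  mu <- gp_posterior(lower, md$coords)$mean
  dmin <- sqrt(apply(cgfunnel:::cross_dist2(md$coords, lower$X), 1, min))
  if (!pool$fallback) expect_true(all(mu < 0))
  expect_true(all(dmin <= 2 * lower$xi + 1e-9))
  expect_equal(pool$prior_mu, mu, tolerance = 1e-9)
})

test_that("selection maximizes EI with deterministic tie-breaking", {
  m <- gp_update(gp_surrogate(1, xi = 1, sigma_n = 0.05),
                 matrix(rep(0, 5), 1), y = -1, prior_vals = 0)
  coords <- rbind(c(0.5, 0, 0, 0, 0), c(3, 0, 0, 0, 0), c(0.2, 0, 0, 0, 0))
  pool <- cgfunnel:::new_candidate_pool(1, 1:3, c("b", "a", "c"), coords,
                                        prior_mu = rep(0, 3))
  sel <- select_next(m, pool)
  post <- gp_posterior(m, coords, prior_vals = rep(0, 3))
  ei <- expected_improvement(post$mean, sqrt(post$var), -1)
  expect_equal(sel$ei, max(ei), tolerance = 1e-12)
  expect_equal(sel$key, pool$keys[which.max(ei)])
  # pool of one returns that molecule
  single <- cgfunnel:::new_candidate_pool(1, 2L, "only",
                                          coords[2, , drop = FALSE],
                                          prior_mu = 0)
  expect_equal(select_next(m, single)$key, "only")
  # exact ties break lexicographically
  sym <- cgfunnel:::new_candidate_pool(
    1, 1:2, c("zzz", "aaa"),
    rbind(c(1, 0, 0, 0, 0), c(-1, 0, 0, 0, 0)), prior_mu = c(0, 0))
  expect_equal(select_next(m, sym)$key, "aaa")
})
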