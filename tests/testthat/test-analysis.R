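test_that("neighborhood size counts neighbors within alpha * xi", {
  # 1-D integer grid 0..9 with d = 2: ends have 2 neighbors at distance
  # <= 2... brute-force per point: 2,3,4,4,4,4,4,4,3,2 -> mean 3.4;
  # recompute directly as the reference
  pts <- matrix(0:9, ncol = 1)
  d <- 0.5 * 4
  ref <- mean(vapply(1:10, function(i)
    sum(abs(pts[i, 1] - pts[-i, 1]) <= d), 0))
  expect_equal(neighborhood_size(pts, xi = 4, alpha = 0.5), ref)
  # all points identical -> N - 1
  same <- matrix(1, 7, 3)
  expect_equal(neighborhood_size(same, xi = 1, alpha = 0.5), 6)
  # vanishing radius with distinct points -> 0
  expect_equal(neighborhood_size(pts, xi = 1e-9, alpha = 0.5), 0)
  expect_error(neighborhood_size(matrix(0, 0, 2), 1), "empty")
})

test_that("neighborhood size is monotone in alpha and xi", {
  set.seed(2)
  pts <- matrix(rnorm(200), 40, 5)
  sizes_a <- vapply(c(0.2, 0.5, 1, 2),
                    function(a) neighborhood_size(pts, 1, a), 0)
  sizes_x <- vapply(c(0.5, 1, 2, 4),
                    function(x) neighborhood_size(pts, x, 0.5), 0)
  expect_true(all(diff(sizes_a) >= 0))
  expect_true(all(diff(sizes_x) >= 0))
})

test_that("density projection scales by the space-size ratio", {
  expect_equal(project_neighborhood(10, 100, 100), 10)
  expect_equal(project_neighborhood(0, 50, 1e6), 0)
  # low-resolution neighborhood projected to the medium space
  proj <- project_neighborhood(249, count_closed_form(15, 4),
                               count_closed_form(45, 4))
  expect_equal(proj, 249 * 6742680 / 89960)
  expect_equal(round(proj / 100) * 100, 18700)
  expect_error(project_neighborhood(1, 0, 10), "positive")
})

test_that("independent lengthscale refits recover a known scale", {
  set.seed(6)
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(runif(200 * 5, 0, 3), 200, 5)
    K <- exp(-as.matrix(dist(X))^2 / (2 * 2^2)) + diag(0.05^2, 200)
    y <- drop(t(chol(K)) %*% rnorm(200))
    xi <- fit_lengthscale(X, y, sigma_n = 0.05)
    if (xi >= 1.4 && xi <= 2.8) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fit_independent_lengthscale delegates to the surrogate fit on
           the level subset", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 101L, total_budget = 45L)
  tr <- run_multilevel(cfg, st$sys)
  idx1 <- st$sys$indices[[1]]
  xi <- fit_independent_lengthscale(tr, 1, idx1, sigma_n = 0.05)
  sub <- tr[tr$level == 1, ]
  rows <- match(sub$canonical_key, idx1$space$keys)
  ref <- fit_lengthscale(idx1$coords[rows, , drop = FALSE], sub$y,
                         sigma_n = 0.05)
  expect_equal(xi, ref)
  expect_warning(
    fit_independent_lengthscale(tr[tr$level == 99, ], 99, idx1,
                                default = 3.3),
    "fewer")
})

test_that("LASSO rule extraction recovers a planted single-bead effect", {
  sp <- enumerate_molecules(build_bead_table(1), 3)
  keys <- space_keys(sp)
  # count C beads per molecule; keep a composition-diverse subset
  nC <- vapply(seq_len(space_size(sp)), function(i)
    sum(space_molecule(sp, i)$node_types == "C"), 0)
  set.seed(31)
  pick <- c(sample(which(nC == 0), 20), sample(which(nC == 1), 20),
            sample(which(nC == 2), 15), which(nC == 3))
  y <- -2 * nC[pick] + rnorm(length(pick), 0, 0.05)
  trace <- data.frame(canonical_key = keys[pick], level = 1L,
                      ddG = y - 0.01, y = y, stringsAsFactors = FALSE)
  index <- list(level = 1L, space = sp)
  rules <- extract_rules(trace, index, n_boot = 50, seed = 4)
  top <- rules[1, ]
  expect_equal(top$feature, "C")
  expect_equal(top$kind, "bead")
  expect_gte(top$coefficient, -2.3)
  expect_lte(top$coefficient, -1.7)
  expect_true(all(c("boot_sd", "count") %in% names(rules)))
})

test_that("rule extraction demands enough negative-ddG records", {
  sp <- enumerate_molecules(build_bead_table(1), 2)
  trace <- data.frame(canonical_key = space_keys(sp)[1:5], level = 1L,
                      ddG = -1, y = -1)
  expect_error(extract_rules(trace, list(level = 1L, space = sp)),
               "at least 10")
})

test_that("trace summaries align multi-level curves with the prior
           offset", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 101L, total_budget = 45L)
  tr <- run_multilevel(cfg, st$sys)
  ts <- run_single_level(cfg, st$sys)
  summ <- trace_summary(list(ml = tr, single = ts))
  expect_true(all(c("per_level", "curves", "best50") %in% names(summ)))
  # cumulative-best column is the running minimum
  ml_curve <- summ$curves[summ$curves$run == "ml", ]
  expect_true(all(diff(ml_curve$cum_best) <= 0))
  # multi-level evaluation index starts after the prior evaluations
  n_prior <- sum(tr$phase == "prior")
  expect_equal(min(ml_curve$eval_index), n_prior + 1L)
  expect_equal(min(summ$curves$eval_index[summ$curves$run == "single"]),
               1L)
  # degenerate single-record trace
  one <- tr[1, , drop = FALSE]
  class(one) <- class(tr)
  s1 <- trace_summary(list(x = one))
  expect_equal(s1$best50$y, tr$y[1])
  expect_equal(s1$per_level$min, tr$y[1])
})

test_that("the neighborhood report covers every level with projections", {
  st <- small_toy()
  cfg <- funnel_config(bo_seed = 101L, total_budget = 45L)
  tr <- run_multilevel(cfg, st$sys)
  rep_df <- neighborhood_report(tr, st$sys, alpha = 0.5, sigma_n = 0.05)
  expect_equal(rep_df$level, 1:3)
  expect_equal(rep_df$space_size,
               vapply(1:3, function(l) count_closed_form(
                 nrow(st$sys$hierarchy$tables[[l]])), 0))
  # projection of a level-1 neighborhood to level 3 follows the density
  # ratio
  if (!is.na(rep_df$neighborhood[1])) {
    expect_equal(rep_df$projected_from_l1[3],
                 rep_df$neighborhood[1] *
                   rep_df$space_size[3] / rep_df$space_size[1])
  }
})
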