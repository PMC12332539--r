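test_that("analytic gradients of the composite loss match numerical
           differentiation", {
  toy <- make_toy_hierarchy(2, 4, 8, seed = 7)
  sp <- enumerate_molecules(toy$hierarchy$tables[[3]], 4)
  fmap <- cgfunnel:::.make_fmap(sp$bead_table)
  layout <- cgfunnel:::.ae_out_layout(length(fmap$classes),
                                      length(fmap$sizes))
  hy <- encoder_hyperparams(hidden = 8L, dec_hidden = 10L,
                            weight_decay = 0)
  set.seed(42)
  p <- cgfunnel:::.ae_init_params(fmap$F, 8L, 10L, 5L, 2L, layout$n_out)
  idx <- c(1, 50, 300, 2000, 8000)  # node counts 1..4 represented
  batch <- cgfunnel:::.batch_from_packed(fmap, sp$tm[idx, , drop = FALSE],
                                         sp$adj[idx], sp$nn[idx])
  res <- cgfunnel:::.ae_loss_and_grads(p, batch, fmap, layout, hy)
  set.seed(1)
  dir <- lapply(p, function(w) {
    d <- rnorm(length(w))
    if (is.matrix(w)) matrix(d, nrow(w)) else d
  })
  analytic <- sum(mapply(function(g, d) sum(g * d), res$grads[names(p)],
                         dir[names(p)]))
  eps <- 1e-5
  pp <- mapply(function(w, d) w + eps * d, p, dir[names(p)],
               SIMPLIFY = FALSE)
  pm <- mapply(function(w, d) w - eps * d, p, dir[names(p)],
               SIMPLIFY = FALSE)
  num <- (cgfunnel:::.ae_loss_and_grads(pp, batch, fmap, layout, hy)$loss -
            cgfunnel:::.ae_loss_and_grads(pm, batch, fmap, layout,
                                          hy)$loss) / (2 * eps)
  expect_equal(analytic, num, tolerance = 1e-6)
})

test_that("encodings are permutation invariant, finite and 5-dimensional", {
  st <- small_toy()
  idx3 <- st$sys$indices[[3]]
  tab <- st$toy$hierarchy$tables[[3]]
  model <- idx3$model
  set.seed(8)
  for (i in sample(space_size(idx3$space), 20)) {
    m <- space_molecule(idx3$space, i)
    z <- encode(model, m)
    expect_equal(length(z), 5L)
    expect_true(all(is.finite(z)))
    n <- length(m$node_types)
    p <- sample(n)
    mp <- permute_molecule(m, p, tab)
    # bypass shared canonicalization: encode the permuted node order raw
    li <- model$fmap$ranks$to_rank[m$node_types[p]]
    tm <- matrix(0, 1, 4); tm[1, seq_len(n)] <- li
    inv <- order(p)
    edges <- m$edges
    if (nrow(edges)) edges <- matrix(inv[edges], ncol = 2L)
    zp <- drop(cgfunnel:::.encode_packed(model, tm,
                                         cgfunnel:::.edges_to_adj(edges),
                                         n))
    expect_equal(z, zp, tolerance = 1e-5)
    expect_equal(encode(model, mp), z, tolerance = 1e-5)
  }
  expect_error(encode(model, cg_molecule(1, "A",
                                         bead_table = st$toy$hierarchy$tables[[1]])),
               "level")
})

test_that("training is reproducible from the seed", {
  toy <- make_toy_hierarchy(2, 4, 8, seed = 7)
  sp <- enumerate_molecules(toy$hierarchy$tables[[1]], 4)
  hy <- encoder_hyperparams(epochs = 5L)
  m1 <- train_encoder(sp, seed = 12, hyper = hy)
  m2 <- train_encoder(sp, seed = 12, hyper = hy)
  expect_identical(m1$params, m2$params)
  m3 <- train_encoder(sp, seed = 13, hyper = hy)
  expect_false(identical(m1$params, m3$params))
})

test_that("the trained level-1 model reconstructs its space essentially
           exactly", {
  # complete low-resolution space of up-to-three-bead molecules: large
  # enough to be a real reconstruction task, small enough to train to
  # convergence at desk scale
  sp <- enumerate_molecules(build_bead_table(1), 3)
  model <- memo("l1_recon_model", function()
    train_encoder(sp, seed = 1,
                  hyper = encoder_hyperparams(epochs = 400L)))
  rate <- reconstruction_rate(model, sp)
  expect_gte(rate, 0.95)
  # no exact latent collisions across the space
  Z <- encode_space(model, sp)
  expect_true(all(is.finite(Z)))
  expect_false(anyDuplicated(round(Z, 8)) > 0)
})

test_that("latent neighborhoods are chemically organized (type multisets
           cluster)", {
  sp <- enumerate_molecules(build_bead_table(1), 3)
  model <- memo("l1_recon_model", function()
    train_encoder(sp, seed = 1,
                  hyper = encoder_hyperparams(epochs = 400L)))
  Z <- encode_space(model, sp)
  multiset <- vapply(seq_len(space_size(sp)), function(i)
    paste(sort(space_molecule(sp, i)$node_types), collapse = ","), "")
  set.seed(3)
  refs <- sample(nrow(Z), 300)
  d2 <- cgfunnel:::cross_dist2(Z[refs, , drop = FALSE], Z)
  same_nn <- vapply(seq_along(refs), function(j) {
    nn <- order(d2[j, ])[2:11]  # 10 nearest, self excluded
    mean(multiset[nn] == multiset[refs[j]])
  }, 0)
  rand_pairs <- mean(outer(multiset[refs], multiset[sample(nrow(Z), 300)],
                           "==") )
  expect_gt(mean(same_nn), rand_pairs)
})

test_that("the latent cross-map is exact on materialized molecules and
           collapses siblings", {
  st <- small_toy()
  sys <- st$sys
  idx2 <- sys$indices[[2]]; idx1 <- sys$indices[[1]]
  set.seed(5)
  for (i in sample(space_size(idx2$space), 10)) {
    m <- space_molecule(idx2$space, i)
    z <- encode(idx2$model, m)
    mapped <- latent_to_lower(z, idx2, idx1, st$toy$hierarchy)
    direct <- encode(idx1$model, map_molecule_down(m, st$toy$hierarchy))
    expect_equal(mapped, direct)
  }
  # two siblings with the same lower image map to the same point
  tab2 <- st$toy$hierarchy$tables[[2]]
  kids <- tab2$code[tab2$parent_code == tab2$parent_code[1]][1:2]
  z1 <- encode(idx2$model, cg_molecule(2, kids[1], bead_table = tab2))
  z2 <- encode(idx2$model, cg_molecule(2, kids[2], bead_table = tab2))
  expect_equal(latent_to_lower(z1, idx2, idx1, st$toy$hierarchy),
               latent_to_lower(z2, idx2, idx1, st$toy$hierarchy))
  # stability: a perturbation smaller than half the margin to the second
  # neighbor does not change the mapped image
  nn <- index_nearest(idx2, z1)
  d2 <- sqrt(cgfunnel:::cross_dist2(matrix(z1, 1), idx2$coords))
  margin <- sort(d2)[2] / 2
  zp <- z1 + c(margin * 0.9, 0, 0, 0, 0)
  expect_equal(latent_to_lower(zp, idx2, idx1, st$toy$hierarchy),
               latent_to_lower(z1, idx2, idx1, st$toy$hierarchy))
})
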