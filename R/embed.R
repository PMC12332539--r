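# Permutation-invariant graph autoencoder: a message-passing encoder maps a
# CG molecule to a 5-dimensional latent point; a fully connected decoder
# reconstructs node count, per-node categorical features (class, size,
# charge), the logP proxy and the adjacency mask. Training follows the
# regularized-autoencoder recipe: deterministic encoder, an L2 penalty on
# the latent codes and weight decay on the decoder. All forward/backward
# passes are written as dense matrix operations batched over molecules
# (graphs have at most four nodes, so message passing reduces to a handful
# of masked matrix products).

.CHARGES <- c(-1L, 0L, 1L)

# ---- feature map -----------------------------------------------------------

.make_fmap <- function(bead_table) {
  classes <- sort(unique(bead_table$chem_class))
  sizes <- sort(unique(bead_table$size_class))
  k <- nrow(bead_table)
  nc <- length(classes); ns <- length(sizes)
  F <- nc + ns + 3L + 1L
  lp_mu <- mean(bead_table$logp)
  lp_sd <- stats::sd(bead_table$logp)
  if (!is.finite(lp_sd) || lp_sd == 0) lp_sd <- 1
  TF <- matrix(0, k, F)
  TF[cbind(seq_len(k), match(bead_table$chem_class, classes))] <- 1
  TF[cbind(seq_len(k), nc + match(bead_table$size_class, sizes))] <- 1
  TF[cbind(seq_len(k), nc + ns + match(bead_table$charge, .CHARGES))] <- 1
  TF[, F] <- (bead_table$logp - lp_mu) / lp_sd
  ranks <- .code_ranks(bead_table)
  list(classes = classes, sizes = sizes, F = F, TF = TF,
       lp_mu = lp_mu, lp_sd = lp_sd,
       codes = bead_table$code,
       class_of = match(bead_table$chem_class, classes),
       size_of = match(bead_table$size_class, sizes),
       charge_of = match(bead_table$charge, .CHARGES),
       logp_std = (bead_table$logp - lp_mu) / lp_sd,
       row_of_rank = match(ranks$sorted, bead_table$code),
       ranks = ranks)
}

# Packed batch -> per-slot feature matrices, masks, adjacency columns.
# tm holds lexicographic type ranks (0 = absent slot).
.batch_from_packed <- function(fmap, tm, adj, nn) {
  B <- length(nn)
  X <- vector("list", 4L); mask <- matrix(0, B, 4L)
  for (i in 1:4) {
    pres <- tm[, i] > 0
    Xi <- matrix(0, B, fmap$F)
    if (any(pres)) Xi[pres, ] <- fmap$TF[fmap$row_of_rank[tm[pres, i]], ,
                                         drop = FALSE]
    X[[i]] <- Xi
    mask[, i] <- as.numeric(pres)
  }
  A6 <- matrix(0, B, 6L)
  for (b in 1:6) A6[, b] <- as.numeric(bitwAnd(adj, .PAIR_BIT[b]) > 0L)
  pairmask <- mask[, .PAIRS[, 1L]] * mask[, .PAIRS[, 2L]]
  rowidx <- matrix(0L, B, 4L)
  for (i in 1:4) rowidx[tm[, i] > 0, i] <- fmap$row_of_rank[tm[tm[, i] > 0, i]]
  list(X = X, mask = mask, A6 = A6, pairmask = pairmask, nn = nn,
       rowidx = rowidx)
}

# ---- parameters ------------------------------------------------------------

.ae_init_params <- function(F, hidden, dec_hidden, latent, rounds, n_out) {
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  p <- list(W0 = g(F, hidden), b0 = numeric(hidden))
  for (r in seq_len(rounds)) {
    p[[paste0("Ws", r)]] <- g(hidden, hidden)
    p[[paste0("Wn", r)]] <- g(hidden, hidden)
    p[[paste0("br", r)]] <- numeric(hidden)
  }
  p$Wz <- 0.3 * g(hidden, latent); p$bz <- numeric(latent)
  p$W1 <- g(latent, dec_hidden); p$c1 <- numeric(dec_hidden)
  p$W2 <- g(dec_hidden, dec_hidden); p$c2 <- numeric(dec_hidden)
  p$Wo <- 0.1 * g(dec_hidden, n_out); p$co <- numeric(n_out)
  p
}

# output layout: count logits (4) | per slot: class, size, charge, logp |
# adjacency logits (6)
.ae_out_layout <- function(nc, ns) {
  per_slot <- nc + ns + 3L + 1L
  list(n_out = 4L + 4L * per_slot + 6L, per_slot = per_slot,
       nc = nc, ns = ns,
       slot_off = 4L + (0:3) * per_slot,
       adj_off = 4L + 4L * per_slot)
}

.softmax <- function(L) {
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# ---- forward / backward ----------------------------------------------------

# Encoder forward on a batch; returns z plus cached activations.
.enc_forward <- function(p, batch, rounds) {
  H <- vector("list", rounds + 1L)
  P <- vector("list", rounds + 1L)
  Nc <- vector("list", rounds)
  H[[1]] <- vector("list", 4L); P[[1]] <- vector("list", 4L)
  for (i in 1:4) {
    Pi <- sweep(batch$X[[i]] %*% p$W0, 2L, p$b0, "+")
    P[[1]][[i]] <- Pi
    H[[1]][[i]] <- pmax(Pi, 0) * batch$mask[, i]
  }
  pair_col <- function(i, j) which(.PAIRS[, 1L] == min(i, j) &
                                   .PAIRS[, 2L] == max(i, j))
  for (r in seq_len(rounds)) {
    H[[r + 1L]] <- vector("list", 4L); P[[r + 1L]] <- vector("list", 4L)
    Nc[[r]] <- vector("list", 4L)
    Ws <- p[[paste0("Ws", r)]]; Wn <- p[[paste0("Wn", r)]]
    br <- p[[paste0("br", r)]]
    for (i in 1:4) {
      Ni <- 0
      for (j in 1:4) if (j != i)
        Ni <- Ni + H[[r]][[j]] * batch$A6[, pair_col(i, j)]
      if (is.numeric(Ni) && length(Ni) == 1L)
        Ni <- matrix(0, nrow(H[[r]][[i]]), ncol(H[[r]][[i]]))
      Nc[[r]][[i]] <- Ni
      Pi <- sweep(H[[r]][[i]] %*% Ws + Ni %*% Wn, 2L, br, "+")
      P[[r + 1L]][[i]] <- Pi
      H[[r + 1L]][[i]] <- pmax(Pi, 0) * batch$mask[, i]
    }
  }
  G <- H[[rounds + 1L]][[1L]] + H[[rounds + 1L]][[2L]] +
    H[[rounds + 1L]][[3L]] + H[[rounds + 1L]][[4L]]
  z <- sweep(G %*% p$Wz, 2L, p$bz, "+")
  list(z = z, G = G, H = H, P = P, Nc = Nc)
}

.dec_forward <- function(p, z) {
  Q1 <- sweep(z %*% p$W1, 2L, p$c1, "+"); D1 <- pmax(Q1, 0)
  Q2 <- sweep(D1 %*% p$W2, 2L, p$c2, "+"); D2 <- pmax(Q2, 0)
  O <- sweep(D2 %*% p$Wo, 2L, p$co, "+")
  list(O = O, Q1 = Q1, D1 = D1, Q2 = Q2, D2 = D2)
}

# Composite loss and gradients for one batch. Returns list(loss, grads,
# parts). Target node features are read from batch$rowidx via the fmap.
.ae_loss_and_grads <- function(p, batch, fmap, layout, hyper) {
  B <- length(batch$nn)
  rounds <- hyper$rounds
  enc <- .enc_forward(p, batch, rounds)
  dec <- .dec_forward(p, enc$z)
  O <- dec$O
  dO <- matrix(0, B, layout$n_out)
  parts <- c(count = 0, class = 0, size = 0, charge = 0, logp = 0, adj = 0)

  # node-count head
  Pc <- .softmax(O[, 1:4, drop = FALSE])
  Yc <- matrix(0, B, 4L); Yc[cbind(seq_len(B), batch$nn)] <- 1
  parts["count"] <- -sum(Yc * log(pmax(Pc, 1e-12))) / B
  dO[, 1:4] <- (Pc - Yc) / B

  # per-slot heads, masked by node presence
  nvalid <- max(1, sum(batch$mask))
  for (i in 1:4) {
    off <- layout$slot_off[i]
    m <- batch$mask[, i]
    pres <- m > 0
    ri <- batch$rowidx[, i]
    ce_head <- function(cols, tgt_of, nm) {
      L <- O[, off + cols, drop = FALSE]
      Pm <- .softmax(L)
      Y <- matrix(0, B, length(cols))
      Y[cbind(which(pres), tgt_of[ri[pres]])] <- 1
      parts[nm] <<- parts[nm] - sum(Y * log(pmax(Pm, 1e-12))) / nvalid
      dO[, off + cols] <<- dO[, off + cols] + (Pm - Y) * m / nvalid
    }
    ce_head(seq_len(layout$nc), fmap$class_of, "class")
    ce_head(layout$nc + seq_len(layout$ns), fmap$size_of, "size")
    ce_head(layout$nc + layout$ns + 1:3, fmap$charge_of, "charge")
    lp_col <- off + layout$per_slot
    tgt <- numeric(B); tgt[pres] <- fmap$logp_std[ri[pres]]
    resid <- (O[, lp_col] - tgt) * m
    parts["logp"] <- parts["logp"] + hyper$w_logp * sum(resid^2) / nvalid
    dO[, lp_col] <- dO[, lp_col] + hyper$w_logp * 2 * resid / nvalid
  }

  # adjacency head (binary cross-entropy with logits over valid pairs)
  npair <- max(1, sum(batch$pairmask))
  Ladj <- O[, layout$adj_off + 1:6, drop = FALSE]
  S <- 1 / (1 + exp(-Ladj))
  bce <- -(batch$A6 * log(pmax(S, 1e-12)) +
             (1 - batch$A6) * log(pmax(1 - S, 1e-12)))
  parts["adj"] <- sum(bce * batch$pairmask) / npair
  dO[, layout$adj_off + 1:6] <- (S - batch$A6) * batch$pairmask / npair

  loss <- sum(parts) + hyper$lambda_z * sum(enc$z^2) / B

  # ---- backward: decoder ----
  g <- list()
  g$Wo <- crossprod(dec$D2, dO) + hyper$weight_decay * p$Wo
  g$co <- colSums(dO)
  dD2 <- tcrossprod(dO, p$Wo)
  dQ2 <- dD2 * (dec$Q2 > 0)
  g$W2 <- crossprod(dec$D1, dQ2) + hyper$weight_decay * p$W2
  g$c2 <- colSums(dQ2)
  dD1 <- tcrossprod(dQ2, p$W2)
  dQ1 <- dD1 * (dec$Q1 > 0)
  g$W1 <- crossprod(enc$z, dQ1) + hyper$weight_decay * p$W1
  g$c1 <- colSums(dQ1)
  dz <- tcrossprod(dQ1, p$W1) + 2 * hyper$lambda_z * enc$z / B

  # ---- backward: encoder ----
  g$Wz <- crossprod(enc$G, dz)
  g$bz <- colSums(dz)
  dG <- tcrossprod(dz, p$Wz)
  dH <- lapply(1:4, function(i) dG)
  pair_col <- function(i, j) which(.PAIRS[, 1L] == min(i, j) &
                                   .PAIRS[, 2L] == max(i, j))
  for (r in rev(seq_len(rounds))) {
    Ws <- p[[paste0("Ws", r)]]; Wn <- p[[paste0("Wn", r)]]
    gWs <- 0; gWn <- 0; gbr <- 0
    dPWs <- vector("list", 4L); dPWn <- vector("list", 4L)
    for (i in 1:4) {
      dP <- dH[[i]] * (enc$P[[r + 1L]][[i]] > 0) * batch$mask[, i]
      gWs <- gWs + crossprod(enc$H[[r]][[i]], dP)
      gWn <- gWn + crossprod(enc$Nc[[r]][[i]], dP)
      gbr <- gbr + colSums(dP)
      dPWs[[i]] <- tcrossprod(dP, Ws)
      dPWn[[i]] <- tcrossprod(dP, Wn)
    }
    g[[paste0("Ws", r)]] <- gWs
    g[[paste0("Wn", r)]] <- gWn
    g[[paste0("br", r)]] <- gbr
    dH <- lapply(1:4, function(j) {
      acc <- dPWs[[j]]
      for (i in 1:4) if (i != j)
        acc <- acc + dPWn[[i]] * batch$A6[, pair_col(i, j)]
      acc
    })
  }
  gW0 <- 0; gb0 <- 0
  for (i in 1:4) {
    dP0 <- dH[[i]] * (enc$P[[1L]][[i]] > 0) * batch$mask[, i]
    gW0 <- gW0 + crossprod(batch$X[[i]], dP0)
    gb0 <- gb0 + colSums(dP0)
  }
  g$W0 <- gW0; g$b0 <- gb0
  list(loss = loss, grads = g, parts = parts, z = enc$z)
}

# ---- training --------------------------------------------------------------

#' Default autoencoder hyperparameters
#'
#' @param rounds Message-passing rounds in the encoder.
#' @param hidden Encoder hidden width.
#' @param dec_hidden Decoder hidden width.
#' @param latent Latent dimensionality (5 throughout this package).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param lambda_z L2 penalty on latent codes (RAE regularization).
#' @param weight_decay L2 weight decay on decoder weights.
#' @param w_logp Weight of the logP mean-squared-error term.
#' @return Named list of hyperparameters.
#' @export
encoder_hyperparams <- function(rounds = 2L, hidden = 64L, dec_hidden = 192L,
                                latent = 5L, epochs = 120L, batch_size = 512L,
                                lr = 3e-3, lambda_z = 1e-4,
                                weight_decay = 1e-6, w_logp = 1) {
  as.list(environment())
}

#' Train the graph autoencoder for one resolution
#'
#' Trains a regularized autoencoder on the molecules of a materialized
#' chemical space: a permutation-invariant message-passing encoder (sum
#' aggregation) to a 5-D latent space, and a fully connected decoder
#' reconstructing node count, per-node class/size/charge (cross-entropy),
#' logP (mean squared error) and the adjacency matrix (binary cross-entropy
#' with logits). Optimized with Adam; fully reproducible given `seed`.
#'
#' @param space A materialized `cg_space`.
#' @param seed Integer seed governing initialization and batch order.
#' @param hyper Hyperparameters from [encoder_hyperparams()].
#' @param verbose Print the loss every few epochs.
#' @return An `encoder_model` with the trained parameters, the feature map
#'   and the per-epoch loss history.
#' @export
train_encoder <- function(space, seed = 1L, hyper = encoder_hyperparams(),
                          verbose = FALSE) {
  N <- space_size(space)
  if (N == 0L) stop("empty chemical space", call. = FALSE)
  fmap <- .make_fmap(space$bead_table)
  layout <- .ae_out_layout(length(fmap$classes), length(fmap$sizes))
  history <- numeric(hyper$epochs)
  p <- NULL
  with_seed(seed, {
    p <- .ae_init_params(fmap$F, hyper$hidden, hyper$dec_hidden,
                         hyper$latent, hyper$rounds, layout$n_out)
    m1 <- lapply(p, function(w) w * 0); m2 <- m1
    t_step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, N, by = hyper$batch_size)) {
        idx <- ord[start:min(N, start + hyper$batch_size - 1L)]
        batch <- .batch_from_packed(fmap, space$tm[idx, , drop = FALSE],
                                    space$adj[idx], space$nn[idx])
        res <- .ae_loss_and_grads(p, batch, fmap, layout, hyper)
        t_step <- t_step + 1L
        for (nm in names(p)) {
          gr <- res$grads[[nm]]
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * gr
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * gr^2
          mhat <- m1[[nm]] / (1 - b1^t_step)
          vhat <- m2[[nm]] / (1 - b2^t_step)
          p[[nm]] <- p[[nm]] - hyper$lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + res$loss; nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose && (ep %% 10L == 0L || ep == 1L))
        message(sprintf("epoch %d loss %.4f", ep, history[ep]))
    }
  })
  structure(list(level = space$level, params = p, fmap = fmap,
                 layout = layout, hyper = hyper, seed = seed,
                 loss_history = history),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat("<encoder_model level", x$level, "latent", x$hyper$latent,
      "final loss", signif(utils::tail(x$loss_history, 1L), 4L), ">\n")
  invisible(x)
}

.encode_packed <- function(model, tm, adj, nn) {
  batch <- .batch_from_packed(model$fmap, tm, adj, nn)
  .enc_forward(model$params, batch, model$hyper$rounds)$z
}

#' Embed a molecule in latent space
#'
#' Deterministic and invariant to node permutations of the input graph.
#'
#' @param model A trained `encoder_model`.
#' @param molecule A `cg_molecule` at the model's level.
#' @return Numeric latent vector of length 5.
#' @export
encode <- function(model, molecule) {
  if (molecule$level != model$level)
    stop("molecule level does not match encoder level", call. = FALSE)
  li <- model$fmap$ranks$to_rank[molecule$node_types]
  if (anyNA(li)) stop("molecule types unknown to this encoder",
                      call. = FALSE)
  tm <- matrix(0, 1L, 4L); tm[1L, seq_along(li)] <- li
  drop(.encode_packed(model, tm, .edges_to_adj(molecule$edges),
                      length(li)))
}

#' Embed every molecule of a space
#'
#' @param model A trained `encoder_model`.
#' @param space A `cg_space` at the model's level.
#' @param batch_size Molecules per forward batch.
#' @return Numeric matrix (molecules x 5), rows aligned with
#'   [space_keys()].
#' @export
encode_space <- function(model, space, batch_size = 4096L) {
  N <- space_size(space)
  Z <- matrix(0, N, model$hyper$latent)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1L)
    Z[idx, ] <- .encode_packed(model, space$tm[idx, , drop = FALSE],
                               space$adj[idx], space$nn[idx])
  }
  Z
}

# Decode latent points to discrete graph predictions (argmax categorical
# heads, logP-nearest type within the (class, size, charge) cell,
# 0.5-thresholded adjacency).
.decode_z <- function(model, z) {
  p <- model$params; lay <- model$layout; fm <- model$fmap
  O <- .dec_forward(p, z)$O
  B <- nrow(z)
  nn_hat <- max.col(O[, 1:4, drop = FALSE], ties.method = "first")
  type_hat <- matrix(0L, B, 4L)
  for (i in 1:4) {
    off <- lay$slot_off[i]
    cl <- max.col(O[, off + seq_len(lay$nc), drop = FALSE], "first")
    sz <- max.col(O[, off + lay$nc + seq_len(lay$ns), drop = FALSE], "first")
    ch <- max.col(O[, off + lay$nc + lay$ns + 1:3, drop = FALSE], "first")
    lp <- O[, off + lay$per_slot]
    for (b in seq_len(B)) {
      if (i > nn_hat[b]) next
      cand <- which(fm$class_of == cl[b] & fm$size_of == sz[b] &
                      fm$charge_of == ch[b])
      if (!length(cand))
        cand <- which(fm$class_of == cl[b] & fm$size_of == sz[b])
      if (!length(cand)) cand <- seq_along(fm$codes)
      type_hat[b, i] <- cand[which.min(abs(fm$logp_std[cand] - lp[b]))]
    }
  }
  adj_hat <- integer(B)
  S <- 1 / (1 + exp(-O[, lay$adj_off + 1:6, drop = FALSE]))
  for (b in 1:6) {
    on <- S[, b] > 0.5 &
      .PAIRS[b, 1L] <= nn_hat & .PAIRS[b, 2L] <= nn_hat
    adj_hat[on] <- bitwOr(adj_hat[on], .PAIR_BIT[b])
  }
  list(nn = nn_hat, type_rows = type_hat, adj = adj_hat)
}

#' Exact-match graph reconstruction rate
#'
#' Fraction of molecules whose decoded graph (argmax node count and node
#' types, thresholded adjacency) reproduces the input exactly.
#'
#' @param model A trained `encoder_model`.
#' @param space A `cg_space` at the model's level.
#' @param idx Optional row subset to evaluate.
#' @param batch_size Molecules per batch.
#' @return Fraction in [0, 1].
#' @export
reconstruction_rate <- function(model, space, idx = NULL,
                                batch_size = 4096L) {
  if (is.null(idx)) idx <- seq_len(space_size(space))
  ok <- logical(length(idx))
  row_of_rank <- model$fmap$row_of_rank
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(length(idx), start + batch_size - 1L)]
    tm <- space$tm[sel, , drop = FALSE]
    z <- .encode_packed(model, tm, space$adj[sel], space$nn[sel])
    dec <- .decode_z(model, z)
    true_rows <- matrix(0L, length(sel), 4L)
    for (i in 1:4) {
      pres <- tm[, i] > 0
      true_rows[pres, i] <- row_of_rank[tm[pres, i]]
    }
    pred_rows <- dec$type_rows
    pred_rows[col(pred_rows) > dec$nn] <- 0L
    ok[start:(start + length(sel) - 1L)] <-
      dec$nn == space$nn[sel] &
      rowSums(pred_rows != true_rows) == 0L &
      dec$adj == space$adj[sel]
  }
  mean(ok)
}

# ---- latent index and cross-resolution mapping -----------------------------

#' Build a latent index for a materialized space
#'
#' Associates every molecule of `space` with its latent embedding and keeps
#' the encoder for on-demand encoding; supports nearest-neighbor queries
#' and the cross-resolution latent map.
#'
#' @param model A trained `encoder_model`.
#' @param space A `cg_space` at the model's level.
#' @return A `latent_index`.
#' @export
build_latent_index <- function(model, space) {
  structure(list(level = space$level, space = space, model = model,
                 coords = encode_space(model, space)),
            class = "latent_index")
}

#' @export
print.latent_index <- function(x, ...) {
  cat("<latent_index level", x$level, "with", nrow(x$coords), "points>\n")
  invisible(x)
}

#' Nearest indexed molecule to a latent point
#'
#' @param index A `latent_index`.
#' @param point Latent vector.
#' @return List with `i` (row), `key` and `dist`.
#' @export
index_nearest <- function(index, point) {
  if (!nrow(index$coords)) stop("empty latent index", call. = FALSE)
  d2 <- colSums((t(index$coords) - point)^2)
  i <- which.min(d2)
  list(i = i, key = index$space$keys[i], dist = sqrt(d2[i]))
}

#' Map a latent point to the next-lower resolution
#'
#' Implements the cross-resolution latent map g: the nearest materialized
#' molecule at the current level is mapped down the bead-type hierarchy and
#' re-encoded with the lower level's encoder. For a point that is the
#' embedding of an indexed molecule the map is exact by construction.
#'
#' @param point Latent vector at level `l`.
#' @param index_l `latent_index` at level `l`.
#' @param index_lower `latent_index` at level `l - 1` (supplies the lower
#'   encoder).
#' @param hierarchy A `bead_hierarchy`.
#' @return Latent vector at level `l - 1`.
#' @export
latent_to_lower <- function(point, index_l, index_lower,
                            hierarchy = standard_hierarchy()) {
  if (index_l$level <= 1L) stop("already at the lowest level", call. = FALSE)
  nn <- index_nearest(index_l, point)
  m <- space_molecule(index_l$space, nn$i)
  encode(index_lower$model, map_molecule_down(m, hierarchy))
}

# Vectorized molecule-level descent: map rows of a space down one level and
# return their lower-level canonical keys and latent coordinates.
.map_rows_down <- function(space, rows, hierarchy, index_lower) {
  lvl <- space$level
  tab <- hierarchy$tables[[lvl]]
  low_tab <- hierarchy$tables[[lvl - 1L]]
  low_ranks <- .code_ranks(low_tab)
  # rank at level l -> rank at level l-1 via parent codes
  parent_rank <- low_ranks$to_rank[
    tab$parent_code[match(space$ranks$sorted, tab$code)]]
  tm <- space$tm[rows, , drop = FALSE]
  tml <- tm
  tml[tm > 0] <- parent_rank[tm[tm > 0]]
  cf <- .canonical_form(tml, space$adj[rows], space$nn[rows],
                        length(low_ranks$sorted))
  codes <- matrix("", nrow(cf$tm), 4L)
  codes[cf$tm > 0] <- low_ranks$sorted[cf$tm[cf$tm > 0]]
  keys <- .key_strings(codes, cf$adj, space$nn[rows])
  Z <- .encode_packed(index_lower$model, cf$tm, cf$adj, space$nn[rows])
  list(keys = keys, coords = Z)
}

#' Save and load encoder checkpoints
#'
#' The checkpoint is a single RDS file accompanied by a JSON sidecar
#' recording level, seed, hyperparameters and the loss history, so a
#' checkpoint can be audited without loading it.
#'
#' @param model A trained `encoder_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_encoder <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(level = model$level, seed = model$seed,
                            hyper = model$hyper,
                            loss_history = model$loss_history),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "encoder_model"))
  model
}

#' Export embeddings as CSV
#'
#' One row per molecule: canonical key plus the five latent coordinates.
#'
#' @param index A `latent_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings_csv <- function(index, path) {
  df <- data.frame(canonical_key = index$space$keys, index$coords)
  names(df)[-1L] <- paste0("z", seq_len(ncol(index$coords)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
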