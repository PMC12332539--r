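# Expected-improvement acquisition over discrete candidate pools,
# weighted k-medoid initialization and the resolution-switching policy.

#' Expected improvement (minimization convention)
#'
#' `EI = (y* - mu) Phi(z) + sigma phi(z)` with `z = (y* - mu)/sigma`; for
#' `sigma = 0` it degenerates to `max(y* - mu, 0)`.
#'
#' @param mu Posterior mean(s), kcal/mol.
#' @param sigma Posterior standard deviation(s), >= 0.
#' @param y_star Incumbent best (lowest) observation.
#' @return Nonnegative EI value(s).
#' @export
expected_improvement <- function(mu, sigma, y_star) {
  if (any(sigma < 0)) stop("`sigma` must be nonnegative", call. = FALSE)
  out <- pmax(y_star - mu, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (y_star - mu[pos]) / sigma[pos]
    out[pos] <- (y_star - mu[pos]) * stats::pnorm(z) +
      sigma[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Resolution-switching policy
#'
#' @param error_threshold Prediction-error threshold (kcal/mol) below which
#'   evaluations count toward an up-switch.
#' @param consecutive_required Number of consecutive sub-threshold
#'   evaluations required to switch up.
#' @param down_factor Multiplier of the lengthscale in the down-switch
#'   distance criterion `||x* - x'|| > down_factor * xi_l`.
#' @return A `switch_policy`.
#' @export
switch_policy <- function(error_threshold = 0.12, consecutive_required = 3L,
                          down_factor = 2) {
  stopifnot(error_threshold > 0, consecutive_required >= 1L,
            down_factor > 0)
  structure(list(error_threshold = error_threshold,
                 consecutive_required = consecutive_required,
                 down_factor = down_factor),
            class = "switch_policy")
}

#' Should the optimization move one resolution up?
#'
#' True iff the last `consecutive_required` prediction errors all exist and
#' are strictly below the threshold.
#'
#' @param recent_errors Prediction errors (kcal/mol) at the current level,
#'   oldest first.
#' @param policy A `switch_policy`.
#' @return Logical.
#' @export
should_level_up <- function(recent_errors, policy = switch_policy()) {
  m <- policy$consecutive_required
  n <- length(recent_errors)
  if (n < m) return(FALSE)
  all(recent_errors[(n - m + 1L):n] < policy$error_threshold)
}

#' Should the optimization fall back one resolution?
#'
#' True iff the selected candidate is farther than `down_factor * xi_l`
#' (strictly) from every already-evaluated point at this level. With no
#' evaluated points yet the answer is `FALSE` (candidate admissibility
#' already guarantees proximity to lower-level knowledge).
#'
#' @param x_star Latent point of the selected candidate.
#' @param evaluated Matrix of already-evaluated latent points (rows).
#' @param xi Current level's lengthscale.
#' @param policy A `switch_policy`.
#' @return Logical.
#' @export
should_level_down <- function(x_star, evaluated, xi,
                              policy = switch_policy()) {
  if (is.null(evaluated) || NROW(evaluated) == 0L) return(FALSE)
  if (!is.matrix(evaluated)) evaluated <- matrix(evaluated, nrow = 1L)
  dmin <- sqrt(min(cross_dist2(matrix(x_star, nrow = 1L), evaluated)))
  dmin > policy$down_factor * xi
}

# ---- weighted k-medoids ----------------------------------------------------

# Alternating weighted k-medoids: assign points to the nearest medoid, then
# replace each medoid by the cluster member minimizing the weighted
# within-cluster distance sum; restart from random seeds and keep the best
# total cost. Exact per-cluster updates make the single-cluster case a
# brute-force minimizer.
.kmedoids_weighted <- function(Z, w, n, seed, n_restarts = 10L,
                               max_iter = 30L) {
  N <- nrow(Z)
  stopifnot(n <= N)
  if (n == N) return(seq_len(N))
  best <- NULL; best_cost <- Inf
  with_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      med <- sample.int(N, n)
      for (it in seq_len(max_iter)) {
        D <- cross_dist2(Z, Z[med, , drop = FALSE])
        assign_ <- max.col(-D, ties.method = "first")
        new_med <- med
        for (c in seq_len(n)) {
          members <- which(assign_ == c)
          if (!length(members)) next
          Dm <- sqrt(cross_dist2(Z[members, , drop = FALSE],
                                 Z[members, , drop = FALSE]))
          cost_m <- colSums(Dm * w[members])
          new_med[c] <- members[which.min(cost_m)]
        }
        if (identical(sort(new_med), sort(med))) { med <- new_med; break }
        med <- new_med
      }
      D <- sqrt(cross_dist2(Z, Z[med, , drop = FALSE]))
      cost <- sum(w * apply(D, 1L, min))
      if (cost < best_cost) { best_cost <- cost; best <- med }
    }
  })
  sort(best)
}

#' Select initialization molecules by weighted k-medoid clustering
#'
#' Clusters the embedded chemical space into `n` weighted k-medoids with
#' weights `w_i = exp(-f0(x_i))`, so regions the additive bead prior deems
#' promising attract medoids. Deterministic given `seed`.
#'
#' @param index A `latent_index` over the materialized space.
#' @param prior A `bead_prior` (or `NULL` for uniform weights).
#' @param n Number of initialization molecules.
#' @param seed Integer seed.
#' @param n_restarts Random restarts of the clustering.
#' @param max_points Spaces larger than this are subsampled (seeded) before
#'   clustering to bound the distance computations.
#' @return Character vector of `n` canonical keys.
#' @export
init_points <- function(index, prior, n, seed = 1L, n_restarts = 10L,
                        max_points = 5000L) {
  N <- nrow(index$coords)
  if (n > N) stop("requested more initialization points than molecules",
                  call. = FALSE)
  w <- if (is.null(prior)) rep(1, N) else exp(-.space_f0(prior, index$space))
  rows <- seq_len(N)
  if (N > max_points) {
    rows <- with_seed(seed + 1L, sample.int(N, max_points))
    rows <- sort(rows)
  }
  if (n == length(rows)) return(index$space$keys[rows])
  med <- .kmedoids_weighted(index$coords[rows, , drop = FALSE], w[rows], n,
                            seed, n_restarts = n_restarts)
  index$space$keys[rows[med]]
}

# ---- candidate pools -------------------------------------------------------

new_candidate_pool <- function(level, rows, keys, coords, prior_mu = NULL,
                               fallback = FALSE) {
  structure(list(level = level, rows = rows, keys = keys, coords = coords,
                 prior_mu = prior_mu, fallback = fallback),
            class = "candidate_pool")
}

#' All unevaluated molecules of an indexed space as a candidate pool
#'
#' @param index A `latent_index`.
#' @param evaluated_keys Canonical keys already evaluated at this level.
#' @return A `candidate_pool`.
#' @export
full_pool <- function(index, evaluated_keys = character(0)) {
  rows <- which(!(index$space$keys %in% evaluated_keys))
  new_candidate_pool(index$level, rows, index$space$keys[rows],
                     index$coords[rows, , drop = FALSE])
}

#' Restrict candidates to neighborhoods with promising lower-level priors
#'
#' A level-`l` molecule is admissible when its image in the lower latent
#' space (via the molecule-level hierarchy map) both (a) has negative
#' lower-level posterior mean and (b) lies within
#' `down_factor * xi_(l-1)` of an evaluated lower-level input, i.e. where
#' the prior is reliable. If no candidate satisfies both, admissibility
#' relaxes to (b) alone. The pool is truncated to `pool_cap` candidates by
#' ascending mapped posterior mean.
#'
#' @param index_l `latent_index` at level `l`.
#' @param evaluated_keys Keys already evaluated at level `l`.
#' @param lower Trained `gp_surrogate` at level `l - 1` (>= 1 observation).
#' @param index_lower `latent_index` at level `l - 1`.
#' @param hierarchy A `bead_hierarchy`.
#' @param policy A `switch_policy` (supplies `down_factor`).
#' @param pool_cap Maximum pool size.
#' @return A `candidate_pool`.
#' @export
restrict_candidates <- function(index_l, evaluated_keys, lower, index_lower,
                                hierarchy = standard_hierarchy(),
                                policy = switch_policy(),
                                pool_cap = 5000L) {
  if (!nrow(lower$X)) stop("lower-level surrogate has no training data",
                           call. = FALSE)
  rows <- which(!(index_l$space$keys %in% evaluated_keys))
  if (!length(rows))
    return(new_candidate_pool(index_l$level, integer(0), character(0),
                              matrix(0, 0L, ncol(index_l$coords))))
  md <- if (!is.null(index_l$down_coords))
    list(coords = index_l$down_coords[rows, , drop = FALSE])
  else .map_rows_down(index_l$space, rows, hierarchy, index_lower)
  post <- gp_posterior(lower, md$coords)
  dmin2 <- numeric(length(rows))
  chunk <- 4096L
  for (start in seq(1L, length(rows), by = chunk)) {
    sel <- start:min(length(rows), start + chunk - 1L)
    dmin2[sel] <- apply(cross_dist2(md$coords[sel, , drop = FALSE],
                                    lower$X), 1L, min)
  }
  reliable <- sqrt(dmin2) <= policy$down_factor * lower$xi
  adm <- post$mean < 0 & reliable
  fallback <- FALSE
  if (!any(adm)) { adm <- reliable; fallback <- TRUE }
  keep <- which(adm)
  keep <- keep[order(post$mean[keep])]
  if (length(keep) > pool_cap) keep <- keep[seq_len(pool_cap)]
  new_candidate_pool(index_l$level, rows[keep], index_l$space$keys[rows[keep]],
                     index_l$coords[rows[keep], , drop = FALSE],
                     prior_mu = post$mean[keep], fallback = fallback)
}

#' Select the next molecule by maximizing expected improvement
#'
#' Computes the GP posterior for every pool member and returns the EI
#' maximizer; ties are broken by lexicographic canonical key.
#'
#' @param model `gp_surrogate` at the pool's level.
#' @param pool A nonempty `candidate_pool`.
#' @param y_star Incumbent best; defaults to the minimum observation held
#'   by `model`.
#' @return List with `key`, `row` (index into the pool's space), `x`
#'   (latent point), `ei`, `mu`, `sigma`, `y_star`.
#' @export
select_next <- function(model, pool, y_star = NULL) {
  if (!length(pool$rows)) stop("candidate pool is empty", call. = FALSE)
  if (is.null(y_star)) {
    if (!length(model$y)) stop("no observations to define y*", call. = FALSE)
    y_star <- min(model$y)
  }
  post <- gp_posterior(model, pool$coords, prior_vals = pool$prior_mu)
  sigma <- sqrt(post$var)
  ei <- expected_improvement(post$mean, sigma, y_star)
  best <- which(ei == max(ei))
  if (length(best) > 1L) best <- best[order(pool$keys[best])[1L]]
  list(key = pool$keys[best], row = pool$rows[best],
       x = pool$coords[best, ], ei = ei[best], mu = post$mean[best],
       sigma = sigma[best], y_star = y_star)
}
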