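# Orchestration of the full multi-level BO loop and the single-level
# baseline: budget accounting, level transitions, surrogate bookkeeping and
# the run trace.

#' Run configuration
#'
#' @param levels Number of resolution levels (must match the system).
#' @param n_init Initialization molecules at the lowest resolution.
#' @param total_budget Total molecule evaluations, including the
#'   single-bead prior evaluations and the initialization.
#' @param error_threshold,consecutive_required,down_factor Switching policy
#'   (see [switch_policy()]).
#' @param sigma_n GP observation-noise standard deviation (kcal/mol).
#' @param pool_cap Maximum candidate-pool size per iteration at levels > 1.
#' @param level1_pool_cap Cap on the lowest-level pool (seeded subsample
#'   per iteration when the space is larger).
#' @param seeds Named list of integer seeds: `oracle` (energy tables),
#'   `encoder`, `cluster` (k-medoid init), `bo` (loop randomness).
#' @param mode `"multilevel"` or `"single"`.
#' @param alpha Neighborhood radius multiplier used by the analyses.
#' @param default_xi Lengthscale used before two distinct observations
#'   exist at a level; `NA` (the default) sets it per level to the median
#'   pairwise latent distance of the indexed space.
#' @return A `run_config`.
#' @export
run_config <- function(levels = 3L, n_init = 50L, total_budget = 327L,
                       error_threshold = 0.12, consecutive_required = 3L,
                       down_factor = 2, sigma_n = 0.1, pool_cap = 5000L,
                       level1_pool_cap = 20000L,
                       seeds = list(oracle = 1L, encoder = 1L, cluster = 1L,
                                    bo = 1L),
                       mode = c("multilevel", "single"), alpha = 0.5,
                       default_xi = NA_real_) {
  mode <- match.arg(mode)
  structure(list(levels = levels, n_init = n_init,
                 total_budget = total_budget,
                 policy = switch_policy(error_threshold,
                                        consecutive_required, down_factor),
                 sigma_n = sigma_n, pool_cap = pool_cap,
                 level1_pool_cap = level1_pool_cap, seeds = seeds,
                 mode = mode, alpha = alpha, default_xi = default_xi),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `levels`, `n_init`, `total_budget`, `error_threshold`,
#' `consecutive_required`, `down_factor`, `sigma_n`, `pool_cap`,
#' `seeds.{oracle,encoder,cluster,bo}`, `mode`, `alpha`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("levels", "n_init", "total_budget",
                        "error_threshold", "consecutive_required",
                        "down_factor", "sigma_n", "pool_cap",
                        "level1_pool_cap", "mode", "alpha"))]
  if (!is.null(y$seeds)) args$seeds <- utils::modifyList(
    list(oracle = 1L, encoder = 1L, cluster = 1L, bo = 1L), y$seeds)
  do.call(run_config, args)
}

#' Bundle spaces, encoders and an oracle into a runnable system
#'
#' Materializes (or subsamples) each level's chemical space, trains one
#' autoencoder per level and builds the latent indices the optimization
#' loop queries. Spaces whose exact size exceeds `max_materialize` are
#' represented by a seeded stratified subsample of `subsample_size`
#' molecules (the candidate index for such levels is the subsample).
#'
#' @param hierarchy A `bead_hierarchy`.
#' @param oracle An `oracle_spec` (or `csv_oracle`).
#' @param encoder_seed Seed for all encoder trainings.
#' @param hyper Autoencoder hyperparameters, or a list of one per level.
#' @param max_materialize Largest space that is enumerated exhaustively.
#' @param subsample_size Subsample size for larger spaces.
#' @param max_beads Molecule size limit.
#' @return A `bo_system`.
#' @export
build_bo_system <- function(hierarchy, oracle, encoder_seed = 1L,
                            hyper = encoder_hyperparams(),
                            max_materialize = 200000L,
                            subsample_size = 100000L, max_beads = 4L) {
  d <- hierarchy$n_levels
  per_level_hyper <- if (!is.null(hyper$epochs)) rep(list(hyper), d)
  else hyper
  indices <- vector("list", d)
  for (l in seq_len(d)) {
    tab <- hierarchy$tables[[l]]
    exact <- count_closed_form(nrow(tab), max_beads)
    space <- if (exact <= max_materialize)
      enumerate_molecules(tab, max_beads)
    else sample_molecules(tab, subsample_size, max_beads,
                          seed = encoder_seed + 100L * l)
    model <- train_encoder(space, seed = encoder_seed + l,
                           hyper = per_level_hyper[[l]])
    indices[[l]] <- build_latent_index(model, space)
    if (l > 1L) {
      md <- .map_rows_down(space, seq_len(space_size(space)), hierarchy,
                           indices[[l - 1L]])
      indices[[l]]$down_coords <- md$coords
      indices[[l]]$down_keys <- md$keys
      indices[[l]]$down_rows <- match(md$keys, indices[[l - 1L]]$space$keys)
    }
  }
  structure(list(hierarchy = hierarchy, oracle = oracle, indices = indices,
                 d = d), class = "bo_system")
}

#' @export
print.bo_system <- function(x, ...) {
  cat("<bo_system with", x$d, "levels;",
      paste(vapply(x$indices, function(i) nrow(i$coords), 0),
            collapse = "/"), "indexed molecules>\n")
  invisible(x)
}

.evaluate_any <- function(oracle, molecule) {
  if (inherits(oracle, "csv_oracle")) csv_evaluate(oracle, molecule)
  else oracle_evaluate(oracle, molecule)
}

.empty_trace_row <- function(rec, iteration, phase, level, extras = list()) {
  row <- cbind(data.frame(iteration = iteration, phase = phase,
                          stringsAsFactors = FALSE),
               rec,
               data.frame(ei = NA_real_, mu_pre = NA_real_,
                          sigma_pre = NA_real_, y_star = NA_real_,
                          pred_error = NA_real_, pool_size = NA_integer_,
                          pool_fallback = NA, event = ""))
  for (nm in names(extras)) row[[nm]] <- extras[[nm]]
  row
}

# Map latent points at level l to lower-level latent coordinates through
# the nearest indexed molecule (exact for indexed embeddings).
.latent_batch_to_lower <- function(X, index_l, index_lower, hierarchy,
                                   chunk = 1024L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  rows <- integer(nrow(X))
  for (start in seq(1L, nrow(X), by = chunk)) {
    sel <- start:min(nrow(X), start + chunk - 1L)
    d2 <- cross_dist2(X[sel, , drop = FALSE], index_l$coords)
    rows[sel] <- max.col(-d2, ties.method = "first")
  }
  if (!is.null(index_l$down_coords))
    return(index_l$down_coords[rows, , drop = FALSE])
  .map_rows_down(index_l$space, rows, hierarchy, index_lower)$coords
}

#' Run the multi-level Bayesian optimization
#'
#' Executes the full funnel: (1) evaluate every lowest-resolution bead as a
#' single-bead molecule to build the additive prior f0; (2) select `n_init`
#' initialization molecules by weighted k-medoid clustering and evaluate
#' them; (3) iterate expected-improvement acquisition with per-iteration
#' lengthscale refits, moving to a higher resolution when the GP
#' prediction error stays below the threshold for the required number of
#' consecutive evaluations, and falling back when the selected candidate is
#' too far from evaluated points. Each level's GP uses the mapped posterior
#' of the level below as its prior mean (the additive bead prior at the
#' lowest level). Stops when the budget is exhausted. Fully reproducible
#' from the seeds in `config`.
#'
#' @param config A `run_config`.
#' @param system A `bo_system`.
#' @return A `bo_trace`: a data frame of evaluation records (with
#'   acquisition diagnostics and a `cum_best` column) carrying the level
#'   transitions as attribute `transitions`.
#' @export
run_multilevel <- function(config, system) {
  d <- system$d
  if (config$levels != d)
    stop("config levels != system levels", call. = FALSE)
  k1 <- nrow(system$hierarchy$tables[[1L]])
  if (config$total_budget < config$n_init + k1)
    stop("budget smaller than mandatory initialization", call. = FALSE)
  st <- new.env(parent = emptyenv())
  rows <- list(); transitions <- list()
  it <- 0L
  xi0 <- vapply(system$indices, function(ix) {
    if (is.na(config$default_xi)) cloud_scale(ix$coords)
    else config$default_xi
  }, 0)

  with_seed(config$seeds$bo, {
    # (1) additive bead prior from single-bead evaluations
    sbp <- seed_bead_prior(system$oracle, system$hierarchy)
    prior <- sbp$prior
    for (r in seq_len(nrow(sbp$records))) {
      it <- it + 1L
      rows[[it]] <- .empty_trace_row(sbp$records[r, ], it, "prior", 1L)
    }
    idx1 <- system$indices[[1L]]
    prior_fn1 <- .bead_prior_mean_fn(prior, idx1)
    f0_all <- .space_f0(prior, idx1$space)

    # surrogates with chained prior means (held in `st` so closures always
    # see the current lower-level model)
    st$sur <- vector("list", d)
    st$sur[[1L]] <- gp_surrogate(1L, xi = xi0[1L],
                                 sigma_n = config$sigma_n,
                                 prior_mean = prior_fn1)
    if (d > 1L) for (l in 2:d) {
      local({
        ll <- l
        st$sur[[ll]] <- gp_surrogate(
          ll, xi = xi0[ll], sigma_n = config$sigma_n,
          prior_mean = function(Xq) {
            low <- .latent_batch_to_lower(Xq, system$indices[[ll]],
                                          system$indices[[ll - 1L]],
                                          system$hierarchy)
            gp_posterior(st$sur[[ll - 1L]], low)$mean
          })
      })
    }

    # include the single-bead evaluations as level-1 training data
    mono_rows <- match(sbp$records$canonical_key, idx1$space$keys)
    st$sur[[1L]] <- gp_update(st$sur[[1L]],
                              idx1$coords[mono_rows, , drop = FALSE],
                              sbp$records$y,
                              keys = sbp$records$canonical_key,
                              prior_vals = f0_all[mono_rows])
    errors <- rep(list(numeric(0)), d)
    exhausted <- rep(FALSE, d)
    fresh_evals <- 0L  # evaluations at the current level since arriving

    # (2) weighted k-medoid initialization at level 1
    init_keys <- init_points(idx1, prior, config$n_init,
                             seed = config$seeds$cluster)
    init_keys <- setdiff(init_keys, st$sur[[1L]]$keys)
    for (ky in init_keys) {
      if (it >= config$total_budget) break
      row_i <- match(ky, idx1$space$keys)
      rec <- .evaluate_any(system$oracle, space_molecule(idx1$space, row_i))
      it <- it + 1L
      rows[[it]] <- .empty_trace_row(rec, it, "init", 1L)
      st$sur[[1L]] <- gp_update(st$sur[[1L]],
                                idx1$coords[row_i, , drop = FALSE], rec$y,
                                keys = ky, prior_vals = f0_all[row_i])
    }

    # (3) acquisition loop
    l <- 1L
    stall <- 0L  # consecutive control-flow steps without an evaluation
    while (it < config$total_budget) {
      if (stall > 4L * d) break
      sur <- st$sur[[l]]
      # per-iteration lengthscale refit (fixed sigma_n); with very few
      # points the marginal likelihood is uninformative, so the refit
      # waits for five observations and is bounded around the latent scale
      if (nrow(sur$X) >= 5L && nrow(unique(sur$X)) >= 2L) {
        st$sur[[l]]$xi <- fit_lengthscale(
          sur$X, sur$y - sur$prior_at_X, sigma_n = config$sigma_n,
          bounds = c(xi0[l] / 8, 3 * xi0[l]), default = xi0[l])
        sur <- st$sur[[l]]
      }
      # posterior mean of surrogate `lv` at its own indexed molecules,
      # descending the cached hierarchy maps instead of latent NN search
      mu_chain <- function(lv, rows) {
        sur_lv <- st$sur[[lv]]
        base <- if (lv == 1L) f0_all[rows]
        else mu_chain(lv - 1L, system$indices[[lv]]$down_rows[rows])
        if (!nrow(sur_lv$X)) return(base)
        Xq <- system$indices[[lv]]$coords[rows, , drop = FALSE]
        K <- rbf_kernel(sur_lv$X, sur_lv$X, sur_lv$xi) +
          diag(sur_lv$sigma_n^2, nrow(sur_lv$X))
        alpha <- backsolve(ch <- .gp_chol(K),
                           forwardsolve(t(ch), sur_lv$y - sur_lv$prior_at_X))
        base + drop(rbf_kernel(Xq, sur_lv$X, sur_lv$xi) %*% alpha)
      }
      pool <- if (l == 1L) {
        po <- full_pool(idx1, sur$keys)
        if (length(po$rows) > config$level1_pool_cap) {
          keep <- sort(sample.int(length(po$rows), config$level1_pool_cap))
          po <- new_candidate_pool(1L, po$rows[keep], po$keys[keep],
                                   po$coords[keep, , drop = FALSE])
        }
        po$prior_mu <- f0_all[po$rows]
        po
      } else {
        idxl <- system$indices[[l]]
        cand <- which(!(idxl$space$keys %in% st$sur[[l]]$keys))
        rr <- idxl$down_rows[cand]
        if (anyNA(rr)) {
          pool_slow <- restrict_candidates(idxl, st$sur[[l]]$keys,
                                           st$sur[[l - 1L]],
                                           system$indices[[l - 1L]],
                                           system$hierarchy, config$policy,
                                           config$pool_cap)
          pool_slow
        } else {
          mu_low <- mu_chain(l - 1L, rr)
          P <- system$indices[[l - 1L]]$coords[rr, , drop = FALSE]
          dmin2 <- numeric(length(cand))
          for (start in seq(1L, length(cand), by = 4096L)) {
            sel <- start:min(length(cand), start + 4095L)
            dmin2[sel] <- apply(cross_dist2(P[sel, , drop = FALSE],
                                            st$sur[[l - 1L]]$X), 1L, min)
          }
          reliable <- sqrt(dmin2) <=
            config$policy$down_factor * st$sur[[l - 1L]]$xi
          adm <- mu_low < 0 & reliable
          fb <- FALSE
          if (!any(adm)) { adm <- reliable; fb <- TRUE }
          keep <- which(adm)
          keep <- keep[order(mu_low[keep])]
          if (length(keep) > config$pool_cap)
            keep <- keep[seq_len(config$pool_cap)]
          new_candidate_pool(l, cand[keep], idxl$space$keys[cand[keep]],
                             idxl$coords[cand[keep], , drop = FALSE],
                             prior_mu = mu_low[keep], fallback = fb)
        }
      }
      if (!length(pool$rows)) {
        exhausted[l] <- all(system$indices[[l]]$space$keys %in%
                              st$sur[[l]]$keys)
        new_l <- if (l < d) l + 1L else break
        transitions[[length(transitions) + 1L]] <-
          data.frame(iteration = it, from = l, to = new_l,
                     reason = "exhausted")
        l <- new_l
        fresh_evals <- 0L
        stall <- stall + 1L
        next
      }
      y_star <- if (length(sur$y)) min(sur$y)
      else min(unlist(lapply(st$sur, function(s) s$y)))
      sel <- select_next(sur, pool, y_star = y_star)
      # a down-switch into a fully evaluated level would stall the run;
      # in that case the candidate is evaluated at the current level
      if (l > 1L && !exhausted[l - 1L] &&
          should_level_down(sel$x, sur$X, sur$xi, config$policy)) {
        transitions[[length(transitions) + 1L]] <-
          data.frame(iteration = it, from = l, to = l - 1L,
                     reason = "down")
        l <- l - 1L
        fresh_evals <- 0L
        stall <- stall + 1L
        next
      }
      mol <- space_molecule(system$indices[[l]]$space, sel$row)
      rec <- .evaluate_any(system$oracle, mol)
      err <- abs(sel$mu - rec$y)
      errors[[l]] <- c(errors[[l]], err)
      it <- it + 1L
      stall <- 0L
      fresh_evals <- fresh_evals + 1L
      rows[[it]] <- .empty_trace_row(
        rec, it, "bo", l,
        extras = list(ei = sel$ei, mu_pre = sel$mu, sigma_pre = sel$sigma,
                      y_star = sel$y_star, pred_error = err,
                      pool_size = length(pool$rows),
                      pool_fallback = isTRUE(pool$fallback)))
      st$sur[[l]] <- gp_update(st$sur[[l]], matrix(sel$x, nrow = 1L),
                               rec$y, keys = sel$key,
                               prior_vals = if (!is.null(pool$prior_mu))
                                 pool$prior_mu[match(sel$key, pool$keys)]
                               else NULL)
      if (l < d && fresh_evals >= 1L &&
          should_level_up(errors[[l]], config$policy)) {
        transitions[[length(transitions) + 1L]] <-
          data.frame(iteration = it, from = l, to = l + 1L, reason = "up")
        l <- l + 1L
        fresh_evals <- 0L
      }
    }
  })
  .finish_trace(rows, transitions, config, "multilevel", st)
}

#' Run standard single-level Bayesian optimization
#'
#' Plain BO at the highest resolution only: zero-mean GP prior, uniform
#' (unweighted) k-medoid initialization with the same number of points, the
#' same EI acquisition and the same total evaluation budget as the
#' multi-level run. Serves as the baseline comparison.
#'
#' @param config A `run_config`.
#' @param system A `bo_system`.
#' @return A `bo_trace` without level transitions.
#' @export
run_single_level <- function(config, system) {
  d <- system$d
  idx <- system$indices[[d]]
  st <- new.env(parent = emptyenv())
  rows <- list(); it <- 0L
  xi0 <- if (is.na(config$default_xi)) cloud_scale(idx$coords)
  else config$default_xi
  with_seed(config$seeds$bo, {
    st$sur <- list(gp_surrogate(d, xi = xi0,
                                sigma_n = config$sigma_n))
    init_keys <- init_points(idx, NULL, config$n_init,
                             seed = config$seeds$cluster)
    for (ky in init_keys) {
      if (it >= config$total_budget) break
      row_i <- match(ky, idx$space$keys)
      rec <- .evaluate_any(system$oracle, space_molecule(idx$space, row_i))
      it <- it + 1L
      rows[[it]] <- .empty_trace_row(rec, it, "init", d)
      st$sur[[1L]] <- gp_update(st$sur[[1L]],
                                idx$coords[row_i, , drop = FALSE], rec$y,
                                keys = ky, prior_vals = 0)
    }
    while (it < config$total_budget) {
      sur <- st$sur[[1L]]
      if (nrow(sur$X) >= 5L && nrow(unique(sur$X)) >= 2L) {
        st$sur[[1L]]$xi <- fit_lengthscale(
          sur$X, sur$y - sur$prior_at_X, sigma_n = config$sigma_n,
          bounds = c(xi0 / 8, 3 * xi0), default = xi0)
        sur <- st$sur[[1L]]
      }
      pool <- full_pool(idx, sur$keys)
      if (!length(pool$rows)) break
      if (length(pool$rows) > config$pool_cap) {
        keep <- sort(sample.int(length(pool$rows), config$pool_cap))
        pool <- new_candidate_pool(d, pool$rows[keep], pool$keys[keep],
                                   pool$coords[keep, , drop = FALSE])
      }
      pool$prior_mu <- rep(0, length(pool$rows))
      sel <- select_next(sur, pool)
      mol <- space_molecule(idx$space, sel$row)
      rec <- .evaluate_any(system$oracle, mol)
      it <- it + 1L
      rows[[it]] <- .empty_trace_row(
        rec, it, "bo", d,
        extras = list(ei = sel$ei, mu_pre = sel$mu, sigma_pre = sel$sigma,
                      y_star = sel$y_star,
                      pred_error = abs(sel$mu - rec$y),
                      pool_size = length(pool$rows),
                      pool_fallback = FALSE))
      st$sur[[1L]] <- gp_update(st$sur[[1L]], matrix(sel$x, nrow = 1L),
                                rec$y, keys = sel$key, prior_vals = 0)
    }
  })
  .finish_trace(rows, list(), config, "single", st)
}

.finish_trace <- function(rows, transitions, config, mode, st) {
  tr <- do.call(rbind, rows)
  tr$cum_best <- cummin(tr$y)
  attr(tr, "transitions") <- if (length(transitions))
    do.call(rbind, transitions)
  else data.frame(iteration = integer(0), from = integer(0),
                  to = integer(0), reason = character(0))
  attr(tr, "mode") <- mode
  attr(tr, "config") <- config
  attr(tr, "surrogates") <- st$sur
  class(tr) <- c("bo_trace", "data.frame")
  tr
}

#' Level-transition events of a run
#'
#' @param trace A `bo_trace`.
#' @return Data frame with columns `iteration`, `from`, `to`, `reason`.
#' @export
trace_transitions <- function(trace) attr(trace, "transitions")

#' Write a run trace to CSV
#'
#' @param trace A `bo_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
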