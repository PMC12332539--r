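# Post-hoc analyses: chemical-neighborhood sizes from fitted lengthscales,
# density projection of neighborhoods across resolutions, LASSO design-rule
# extraction with bootstrap uncertainties, and trace summaries.

#' Mean chemical-neighborhood size
#'
#' The average, over reference points, of the number of other points within
#' Euclidean distance `alpha * xi` (self excluded). The lengthscale of an
#' RBF kernel fitted to evaluated molecules measures how far information
#' about one molecule carries, so this count is an intrinsic neighborhood
#' size of the latent landscape.
#'
#' @param points Matrix of latent points (rows).
#' @param xi Fitted lengthscale (> 0).
#' @param alpha Radius multiplier (default 0.5).
#' @return Mean neighbor count.
#' @export
neighborhood_size <- function(points, xi, alpha = 0.5) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  if (!nrow(points)) stop("empty point set", call. = FALSE)
  stopifnot(xi > 0, alpha > 0)
  d2 <- cross_dist2(points, points)
  mean(rowSums(d2 <= (alpha * xi)^2) - 1)
}

#' Project a neighborhood size to another resolution
#'
#' Scales a neighborhood count by the ratio of total space sizes, i.e.
#' assumes comparable average molecule density in each latent space.
#'
#' @param size_from Neighborhood size at the source resolution.
#' @param N_from,N_to Total space sizes at the source and target
#'   resolutions.
#' @return Projected neighborhood size.
#' @export
project_neighborhood <- function(size_from, N_from, N_to) {
  if (N_from <= 0) stop("`N_from` must be positive", call. = FALSE)
  size_from * (N_to / N_from)
}

#' Independent per-level lengthscale from a run trace
#'
#' Refits the RBF lengthscale to the evaluated molecules of one level with
#' a zero-mean GP (no lower-resolution prior), so the estimate is not
#' biased by information borrowed from other levels.
#'
#' @param trace A `bo_trace`.
#' @param level Resolution level to extract.
#' @param index The `latent_index` of that level (supplies coordinates).
#' @param sigma_n Fixed noise standard deviation.
#' @param default Lengthscale returned (with a warning) when fewer than two
#'   evaluations exist at the level.
#' @return Fitted lengthscale.
#' @export
fit_independent_lengthscale <- function(trace, level, index, sigma_n = 0.1,
                                        default = 1) {
  sub <- trace[trace$level == level, ]
  if (nrow(sub) < 2L) {
    warning("fewer than two evaluations at level ", level,
            "; returning default", call. = FALSE)
    return(default)
  }
  rows <- match(sub$canonical_key, index$space$keys)
  keep <- !is.na(rows)
  X <- index$coords[rows[keep], , drop = FALSE]
  fit_lengthscale(X, sub$y[keep], sigma_n = sigma_n, default = default)
}

# Count features: one column per bead type and one per unordered bonded
# type pair occurring in the molecules.
.rule_features <- function(molecules) {
  single <- sort(unique(unlist(lapply(molecules, `[[`, "node_types"))))
  pair_of <- function(m) {
    if (!nrow(m$edges)) return(character(0))
    apply(m$edges, 1L, function(e) {
      paste(sort(m$node_types[e]), collapse = "~")
    })
  }
  pairs <- sort(unique(unlist(lapply(molecules, pair_of))))
  feats <- c(single, pairs)
  M <- matrix(0, length(molecules), length(feats),
              dimnames = list(NULL, feats))
  for (i in seq_along(molecules)) {
    tb <- table(molecules[[i]]$node_types)
    M[i, names(tb)] <- as.numeric(tb)
    pb <- table(pair_of(molecules[[i]]))
    if (length(pb)) M[i, names(pb)] <- as.numeric(pb)
  }
  list(M = M, n_single = length(single))
}

#' Extract design rules by LASSO regression
#'
#' Builds count features (single bead types; unordered bonded bead-type
#' pairs) over the evaluated molecules with `ddG < 0`, fits an
#' L1-regularized linear regression of the objective on the features with
#' the penalty chosen by cross-validation, and bootstraps the coefficients
#' for uncertainties. Features are ranked by absolute coefficient.
#'
#' @param trace A `bo_trace` (or any `eval_record` data frame).
#' @param index A `latent_index` whose space contains the evaluated
#'   molecules (supplies their graphs).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Optional: restrict to records of one level (default: the
#'   level of `index`).
#' @return Data frame of `feature_rule`s: `feature`, `kind`
#'   (`"bead"`/`"pair"`), `coefficient`, `boot_sd`, `count` (molecules
#'   containing the feature), sorted by `|coefficient|` descending.
#' @export
extract_rules <- function(trace, index, n_boot = 100L, seed = 1L,
                          level = index$level) {
  sub <- trace[trace$level == level & !is.na(trace$ddG) & trace$ddG < 0, ]
  sub <- sub[!duplicated(sub$canonical_key), ]
  if (nrow(sub) < 10L)
    stop("need at least 10 records with ddG < 0", call. = FALSE)
  mols <- lapply(sub$canonical_key,
                 function(k) space_molecule(index$space, k))
  ft <- .rule_features(mols)
  y <- sub$y
  X <- ft$M
  keep_col <- colSums(X != 0) > 0
  X <- X[, keep_col, drop = FALSE]
  if (ncol(X) < 2L)
    stop("need at least two distinct features", call. = FALSE)
  coefs <- with_seed(seed, {
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5L,
                            standardize = FALSE)
    lam <- cv$lambda.min
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam,
                          standardize = FALSE)
    beta <- as.numeric(fit$beta)
    boots <- matrix(0, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      ii <- sample.int(nrow(X), replace = TRUE)
      bf <- tryCatch(glmnet::glmnet(X[ii, , drop = FALSE], y[ii],
                                    alpha = 1, lambda = lam,
                                    standardize = FALSE),
                     error = function(e) NULL)
      if (!is.null(bf)) boots[b, ] <- as.numeric(bf$beta)
    }
    list(beta = beta, sd = apply(boots, 2L, stats::sd))
  })
  out <- data.frame(feature = colnames(X),
                    kind = ifelse(grepl("~", colnames(X), fixed = TRUE),
                                  "pair", "bead"),
                    coefficient = coefs$beta,
                    boot_sd = coefs$sd,
                    count = colSums(X > 0),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Summarize one or more run traces
#'
#' Produces per-level objective distributions, cumulative-best curves
#' aligned on evaluation index (initialization excluded; for multi-level
#' runs the index is offset by the number of prior evaluations, so curves
#' of multi-level and standard runs are comparable), and a kernel-density
#' summary of each run's best 50 objective values.
#'
#' @param traces A `bo_trace` or list of them (optionally named).
#' @return List with data frames `per_level` (level, n, mean, median, min),
#'   `curves` (run, eval_index, cum_best) and `best50` (run, y).
#' @export
trace_summary <- function(traces) {
  if (inherits(traces, "bo_trace")) traces <- list(run1 = traces)
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  if (is.null(names(traces)))
    names(traces) <- paste0("run", seq_along(traces))
  per_level <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    agg <- lapply(split(tr$y, tr$level), function(v) {
      data.frame(n = length(v), mean = mean(v), median = stats::median(v),
                 min = min(v))
    })
    cbind(run = nm, level = as.integer(names(agg)), do.call(rbind, agg),
          row.names = NULL)
  }))
  curves <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    n_prior <- sum(tr$phase == "prior")
    post <- tr[tr$phase == "bo", , drop = FALSE]
    if (!nrow(post)) return(NULL)
    data.frame(run = nm,
               eval_index = n_prior + seq_len(nrow(post)),
               cum_best = post$cum_best, level = post$level,
               stringsAsFactors = FALSE)
  }))
  best50 <- do.call(rbind, lapply(names(traces), function(nm) {
    v <- sort(traces[[nm]]$y)
    data.frame(run = nm, y = utils::head(v, 50L),
               stringsAsFactors = FALSE)
  }))
  list(per_level = per_level, curves = curves, best50 = best50)
}

#' Full neighborhood report for a run
#'
#' For each level: the independently refitted lengthscale, the mean
#' neighborhood size among evaluated molecules at radius `alpha * xi`, the
#' total space size, and the projections of lower-level neighborhoods to
#' higher resolutions by density scaling.
#'
#' @param trace A `bo_trace`.
#' @param system The `bo_system` of the run.
#' @param alpha Radius multiplier.
#' @param sigma_n Noise standard deviation for the refits.
#' @return Data frame, one row per level, with projection columns.
#' @export
neighborhood_report <- function(trace, system, alpha = 0.5, sigma_n = 0.1) {
  d <- system$d
  N <- vapply(seq_len(d), function(l)
    count_closed_form(nrow(system$hierarchy$tables[[l]])), 0)
  out <- lapply(seq_len(d), function(l) {
    idx <- system$indices[[l]]
    xi <- tryCatch(fit_independent_lengthscale(trace, l, idx,
                                               sigma_n = sigma_n),
                   warning = function(w) NA_real_)
    sub <- trace[trace$level == l, ]
    rows <- match(sub$canonical_key, idx$space$keys)
    rows <- rows[!is.na(rows)]
    size <- if (!is.na(xi) && length(rows) > 1L)
      neighborhood_size(idx$coords[rows, , drop = FALSE], xi, alpha)
    else NA_real_
    data.frame(level = l, xi = xi, n_evaluated = length(rows),
               neighborhood = size, space_size = N[l])
  })
  rep_df <- do.call(rbind, out)
  for (l2 in seq_len(d)) for (l1 in seq_len(l2 - 1L)) {
    col <- paste0("projected_from_l", l1)
    if (!col %in% names(rep_df)) rep_df[[col]] <- NA_real_
    rep_df[[col]][l2] <- project_neighborhood(rep_df$neighborhood[l1],
                                              N[l1], N[l2])
  }
  rep_df
}
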