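# Gaussian-process regression with a squared-exponential kernel over the
# latent space. Each resolution level carries its own GP whose prior mean
# is the mapped posterior of the next-lower level (delta learning); at the
# lowest level the prior is the additive single-bead model f0.

#' Squared-exponential (RBF) kernel
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 xi^2))` with unit signal variance.
#'
#' @param X1,X2 Matrices of latent points (rows) or single vectors.
#' @param xi Positive lengthscale (latent units).
#' @return Kernel matrix `nrow(X1)` x `nrow(X2)`.
#' @export
rbf_kernel <- function(X1, X2, xi) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0)
    stop("lengthscale `xi` must be a positive scalar", call. = FALSE)
  if (!is.matrix(X1)) X1 <- matrix(X1, nrow = 1L)
  if (!is.matrix(X2)) X2 <- matrix(X2, nrow = 1L)
  exp(-cross_dist2(X1, X2) / (2 * xi^2))
}

#' Create a level surrogate
#'
#' @param level Resolution level the surrogate models.
#' @param xi RBF lengthscale.
#' @param sigma_n Observation-noise standard deviation (kcal/mol), fixed
#'   (not optimized).
#' @param prior_mean Function mapping a matrix of latent points to prior
#'   mean values; defaults to the zero mean. For delta learning pass the
#'   mapped lower-level posterior mean; at level 1 pass the additive bead
#'   prior.
#' @return A `gp_surrogate` with empty training data.
#' @export
gp_surrogate <- function(level, xi = 1, sigma_n = 0.1,
                         prior_mean = function(X) numeric(nrow(X))) {
  stopifnot(xi > 0, sigma_n >= 0)
  structure(list(level = level, xi = xi, sigma_n = sigma_n,
                 prior_mean = prior_mean,
                 X = matrix(numeric(0), 0L, 0L), y = numeric(0),
                 prior_at_X = numeric(0), keys = character(0)),
            class = "gp_surrogate")
}

#' Add observations to a surrogate
#'
#' @param model A `gp_surrogate`.
#' @param X Matrix of latent points (rows) or a single vector.
#' @param y Observed objective values.
#' @param keys Optional canonical keys for bookkeeping.
#' @param prior_vals Optional precomputed prior-mean values at `X`
#'   (otherwise `prior_mean` is called once here and cached).
#' @return The updated `gp_surrogate`.
#' @export
gp_update <- function(model, X, y, keys = NULL, prior_vals = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  stopifnot(nrow(X) == length(y))
  if (is.null(prior_vals)) prior_vals <- model$prior_mean(X)
  model$X <- if (nrow(model$X)) rbind(model$X, X) else X
  model$y <- c(model$y, y)
  model$prior_at_X <- c(model$prior_at_X, prior_vals)
  model$keys <- c(model$keys, if (is.null(keys)) rep(NA_character_,
                                                     length(y)) else keys)
  model
}

.gp_chol <- function(K) {
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(K + diag(1e-8, nrow(K))), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance matrix singular beyond jitter", call. = FALSE)
  }
  ch
}

#' GP posterior mean and variance
#'
#' Exact conditioning: `mu(x) = m(x) + k(x, X) K^-1 (y - m(X))` and
#' `sigma^2(x) = k(x, x) - k(x, X) K^-1 k(X, x)` with
#' `K = k(X, X) + sigma_n^2 I`. With no training data the prior
#' `(m(x), 1)` is returned. Negative variances from round-off are clipped
#' at zero.
#'
#' @param model A `gp_surrogate`.
#' @param Xq Query points (matrix rows or single vector).
#' @param prior_vals Optional precomputed prior-mean values at `Xq`.
#' @return List with numeric vectors `mean` and `var`.
#' @export
gp_posterior <- function(model, Xq, prior_vals = NULL) {
  if (!is.matrix(Xq)) Xq <- matrix(Xq, nrow = 1L)
  m_q <- if (is.null(prior_vals)) model$prior_mean(Xq) else prior_vals
  if (!nrow(model$X)) return(list(mean = m_q, var = rep(1, nrow(Xq))))
  K <- rbf_kernel(model$X, model$X, model$xi) +
    diag(model$sigma_n^2, nrow(model$X))
  ch <- .gp_chol(K)
  r <- model$y - model$prior_at_X
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  Ks <- rbf_kernel(Xq, model$X, model$xi)
  mu <- m_q + drop(Ks %*% alpha)
  V <- forwardsolve(t(ch), t(Ks))
  s2 <- 1 - colSums(V^2)
  s2[s2 < 0] <- 0
  list(mean = mu, var = s2)
}

# log marginal likelihood of residuals r under K(xi) + sigma_n^2 I
.gp_log_marginal <- function(X, r, xi, sigma_n) {
  K <- rbf_kernel(X, X, xi) + diag(sigma_n^2, nrow(X))
  ch <- tryCatch(.gp_chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * sum(r * alpha) - sum(log(diag(ch))) -
    0.5 * length(r) * log(2 * pi)
}

#' Fit the RBF lengthscale by marginal likelihood
#'
#' Maximizes the GP log marginal likelihood of the prior-mean residuals
#' over a log-spaced grid on [0.01, 100] followed by golden-section
#' refinement; `sigma_n` stays fixed. Deterministic.
#'
#' @param X Training latent points (matrix rows).
#' @param y Observations.
#' @param prior_mean Prior mean function (as in [gp_surrogate()]).
#' @param sigma_n Fixed noise standard deviation.
#' @param bounds Search bounds for the lengthscale.
#' @param default Returned (with a warning) when fewer than two distinct
#'   points are available.
#' @param grid_n Number of initial grid points.
#' @return Fitted lengthscale.
#' @export
fit_lengthscale <- function(X, y, prior_mean = function(X) numeric(nrow(X)),
                            sigma_n = 0.1, bounds = c(0.01, 100),
                            default = 1, grid_n = 25L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) < 2L || nrow(unique(X)) < 2L) {
    warning("fewer than two distinct training points; returning default ",
            "lengthscale", call. = FALSE)
    return(default)
  }
  r <- y - prior_mean(X)
  obj <- function(lxi) .gp_log_marginal(X, r, exp(lxi), sigma_n)
  grid <- seq(log(bounds[1L]), log(bounds[2L]), length.out = grid_n)
  vals <- vapply(grid, obj, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- obj(c1); f2 <- obj(c2)
  for (it in 1:40) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- obj(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- obj(c1)
    }
    if (abs(b - a) < 1e-4) break
  }
  exp((a + b) / 2)
}

#' Additive single-bead prior
#'
#' Stores one objective value per lowest-resolution bead type; a molecule's
#' prior value is the sum of its beads' values (the additivity assumption
#' behind the f0 model).
#'
#' @param values Named numeric vector: names are level-1 bead codes.
#' @return A `bead_prior`.
#' @export
bead_prior <- function(values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(list(values = values), class = "bead_prior")
}

#' Evaluate the additive bead prior for a molecule
#'
#' @param molecule A `cg_molecule` at the lowest level.
#' @param prior A `bead_prior`.
#' @return Sum of the per-bead values (with multiplicity), kcal/mol.
#' @export
bead_prior_value <- function(molecule, prior) {
  v <- prior$values[molecule$node_types]
  if (anyNA(v))
    stop("bead type(s) missing from prior: ",
         paste(setdiff(molecule$node_types, names(prior$values)),
               collapse = ", "), call. = FALSE)
  sum(v)
}

# Vectorized f0 over all molecules of an indexed space.
.space_f0 <- function(prior, space) {
  vr <- prior$values[space$ranks$sorted]
  f0 <- numeric(space_size(space))
  for (i in 1:4) {
    pres <- space$tm[, i] > 0
    f0[pres] <- f0[pres] + vr[space$tm[pres, i]]
  }
  if (anyNA(f0)) stop("bead type(s) missing from prior", call. = FALSE)
  f0
}

# Prior mean function over latent points for level 1: nearest indexed
# molecule's f0 value (exact for embeddings of materialized molecules).
# Queries are chunked to bound the distance-matrix memory.
.bead_prior_mean_fn <- function(prior, index, chunk = 128L) {
  f0 <- .space_f0(prior, index$space)
  function(Xq) {
    if (!is.matrix(Xq)) Xq <- matrix(Xq, nrow = 1L)
    out <- numeric(nrow(Xq))
    for (start in seq(1L, nrow(Xq), by = chunk)) {
      sel <- start:min(nrow(Xq), start + chunk - 1L)
      d2 <- cross_dist2(Xq[sel, , drop = FALSE], index$coords)
      out[sel] <- f0[max.col(-d2, ties.method = "first")]
    }
    out
  }
}

#' Serialize surrogate state for resumable runs
#'
#' Writes the kernel settings as JSON and the training data (latent
#' coordinates, observations, keys) as CSV. The prior-mean function is not
#' serialized; on resume it is reconstructed from the system.
#'
#' @param model A `gp_surrogate`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_surrogate <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(level = model$level, xi = model$xi,
                            sigma_n = model$sigma_n,
                            n_obs = length(model$y)),
                       file.path(dir, "surrogate.json"),
                       auto_unbox = TRUE, digits = NA)
  df <- data.frame(canonical_key = model$keys, y = model$y,
                   prior = model$prior_at_X)
  if (nrow(model$X)) {
    X <- as.data.frame(model$X)
    names(X) <- paste0("x", seq_len(ncol(X)))
    df <- cbind(df, X)
  }
  utils::write.csv(df, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  invisible(dir)
}
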