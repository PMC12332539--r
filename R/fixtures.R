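# Deterministic miniature hierarchies and oracles for fast experiments and
# tests: small enough that the global optimum of the highest-resolution
# space is computable by exhaustive evaluation.

#' Build a toy bead hierarchy with a matching synthetic oracle
#'
#' Creates a balanced `k1 -> k2 -> k3` bead-type tree with a single bead
#' size (size classes are exercised only by the full tables): level-1 types
#' are chemical classes `A`, `B`, ..., each splitting into equally many
#' children per level. Hydrophobicity proxies are spread across classes
#' (class `A` most hydrophobic) with seeded within-class jitter, and
#' lower-level values are child averages, as in the full hierarchy. The
#' companion oracle is built on the level-3 table with child-averaged
#' energetics, so levels are mutually consistent.
#'
#' @param k1,k2,k3 Type counts per level; `k2` must divide into equal
#'   groups over `k1` and `k3` over `k2`.
#' @param seed Integer seed for logP jitter and oracle tables.
#' @param sigma_obs Oracle observation noise (kcal/mol).
#' @param coupling_sd Oracle pairwise-coupling scale.
#' @param node_sd Per-type scatter of the oracle at the highest resolution;
#'   the toy default is deliberately rough so that the high-resolution
#'   landscape has the complexity the funnel strategy is designed for.
#' @return List with `hierarchy` (a `bead_hierarchy`) and `oracle` (an
#'   `oracle_spec`).
#' @export
make_toy_hierarchy <- function(k1 = 2L, k2 = 4L, k3 = 8L, seed = 1L,
                               sigma_obs = 0.05, coupling_sd = 0.05,
                               node_sd = 0.4) {
  if (k1 > k2 || k2 > k3 || k2 %% k1 != 0L || k3 %% k2 != 0L)
    stop("need k1 <= k2 <= k3 with k2 divisible by k1 and k3 by k2",
         call. = FALSE)
  g12 <- k2 %/% k1; g23 <- k3 %/% k2
  classes <- LETTERS[seq_len(k1)]
  base <- seq(1.5, -1.5, length.out = k1)
  t1 <- data.frame(code = classes, chem_class = classes, size_class = "R",
                   charge = 0L, level = 1L, parent_code = NA_character_,
                   logp = NA_real_, stringsAsFactors = FALSE)
  rows2 <- list(); rows3 <- list()
  # Within-class spread comparable to the class separation, so the
  # embedding can resolve sibling types from the logP node feature, while
  # absolute logP differences stay small enough that siblings remain
  # energetically similar (the hierarchy stays informative).
  lp3 <- with_seed(seed, {
    jitter <- stats::rnorm(k3, 0, 0.15)
    spread <- rep(seq(-1.2, 1.2, length.out = g12 * g23), k1)
    rep(base, each = g12 * g23) + spread + jitter
  })
  i3 <- 0L
  for (ci in seq_len(k1)) {
    for (j in seq_len(g12)) {
      l2code <- paste0(classes[ci], j)
      rows2[[length(rows2) + 1L]] <- data.frame(
        code = l2code, chem_class = classes[ci], size_class = "R",
        charge = 0L, level = 2L, parent_code = classes[ci],
        logp = NA_real_, stringsAsFactors = FALSE)
      for (m in seq_len(g23)) {
        i3 <- i3 + 1L
        rows3[[length(rows3) + 1L]] <- data.frame(
          code = paste0(l2code, letters[m]), chem_class = classes[ci],
          size_class = "R", charge = 0L, level = 3L, parent_code = l2code,
          logp = lp3[i3], stringsAsFactors = FALSE)
      }
    }
  }
  t3 <- do.call(rbind, rows3); t2 <- do.call(rbind, rows2)
  t2$logp <- vapply(t2$code,
                    function(cd) mean(t3$logp[t3$parent_code == cd]), 0)
  t1$logp <- vapply(t1$code,
                    function(cd) mean(t2$logp[t2$parent_code == cd]), 0)
  hierarchy <- new_bead_hierarchy(list(as_bead_table(t1, 1L),
                                       as_bead_table(t2, 2L),
                                       as_bead_table(t3, 3L)))
  list(hierarchy = hierarchy,
       oracle = oracle_spec(hierarchy, seed = seed + 1L,
                            sigma_obs = sigma_obs,
                            coupling_sd = coupling_sd,
                            node_sd = node_sd))
}

#' Exhaustive noiseless objective landscape of a small space
#'
#' Evaluates every molecule of a materialized space with the noiseless
#' oracle; used to locate toy global optima by brute force.
#'
#' @param spec An `oracle_spec`.
#' @param space A `cg_space`.
#' @return Data frame with `canonical_key` and the noiseless `y`.
#' @export
oracle_landscape <- function(spec, space) {
  ys <- vapply(seq_len(space_size(space)), function(i) {
    oracle_evaluate(spec, space_molecule(space, i), noisy = FALSE)$y
  }, 0)
  data.frame(canonical_key = space_keys(space), y = ys,
             stringsAsFactors = FALSE)
}
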