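# Free-energy scoring arithmetic and the seeded synthetic oracle standing
# in for the MD thermodynamic-integration evaluations. Each molecule gets
# four positional free energies (kcal/mol): at the ternary-bilayer center,
# at the interface, in bulk water and at the center of a pure DLiPC
# bilayer. The optimization target is ddG = dG_center - dG_DLiPC combined
# with a nonnegative localization penalty S.

#' Does a molecule insert into the bilayer?
#'
#' A molecule is treated as inserting when the bilayer center is strictly
#' favored over water; ties count as non-inserting. Non-inserting molecules
#' skip the interface and DLiPC evaluations.
#'
#' @param dG_center,dG_water Free energies, kcal/mol.
#' @return Logical.
#' @export
is_inserting <- function(dG_center, dG_water) {
  dG_center < dG_water
}

#' Free-energy score of a molecule
#'
#' Computes `ddG = dG_center - dG_DLiPC`, the localization penalty
#' `S = w_a max(dG_center - dG_interface, 0) + w_b max(dG_interface -
#' dG_water, 0)` (zero exactly for center-localizing molecules, positive
#' when the interface or water is preferred) and the objective
#' `y = min(ddG, 0) + S`. For non-inserting molecules evaluated through the
#' shortcut (interface and DLiPC absent), `S` reduces to the only available
#' penalty term `w_a max(dG_center - dG_water, 0)` and `y = S`.
#'
#' @param dG_center,dG_interface,dG_water,dG_dlipc Free energies, kcal/mol;
#'   `dG_interface` and `dG_dlipc` may be `NA` only for non-inserting
#'   molecules.
#' @param w_a,w_b Nonnegative penalty weights.
#' @return List with `ddG`, `S`, `y`.
#' @export
score_free_energies <- function(dG_center, dG_interface, dG_water, dG_dlipc,
                                w_a = 1, w_b = 1) {
  if (!is.finite(dG_center) || !is.finite(dG_water))
    stop("dG_center and dG_water must be finite", call. = FALSE)
  if (!is.finite(dG_dlipc) || !is.finite(dG_interface)) {
    if (is_inserting(dG_center, dG_water))
      stop("the non-inserting shortcut (absent dG_interface/dG_DLiPC) is ",
           "only valid when the molecule does not insert", call. = FALSE)
    S <- w_a * max(dG_center - dG_water, 0)
    return(list(ddG = NA_real_, S = S, y = S))
  }
  ddG <- dG_center - dG_dlipc
  S <- w_a * max(dG_center - dG_interface, 0) +
    w_b * max(dG_interface - dG_water, 0)
  list(ddG = ddG, S = S, y = min(ddG, 0) + S)
}

# ---- synthetic oracle ------------------------------------------------------

#' Build a synthetic free-energy oracle
#'
#' Constructs seeded per-type energy contributions at the highest
#' resolution of `hierarchy` and derives lower-resolution tables by
#' child-averaging, so the oracle is consistent across resolutions in the
#' same way the reduced force fields are. Contributions correlate with the
#' hydrophobicity proxy: hydrophobic types favor the bilayer center and the
#' DLiPC phase (negative ddG), hydrophilic types favor water. Molecules get
#' approximately bead-additive energies with small pairwise edge couplings
#' and Gaussian observation noise.
#'
#' @param hierarchy A `bead_hierarchy`.
#' @param seed Integer seed for the energy tables (same seed, same tables).
#' @param sigma_obs Observation-noise standard deviation (kcal/mol).
#' @param coupling_sd Standard deviation of the pairwise edge couplings.
#' @param node_sd Per-type scatter around the hydrophobicity trend at the
#'   highest resolution. Larger values make the high-resolution landscape
#'   rougher while lower resolutions stay smooth (scatter averages out
#'   over siblings), mirroring the varying smoothness across
#'   coarse-graining resolutions.
#' @param w_a,w_b Penalty weights passed to [score_free_energies()].
#' @return An `oracle_spec`.
#' @export
oracle_spec <- function(hierarchy = standard_hierarchy(), seed = 1L,
                        sigma_obs = 0.1, coupling_sd = 0.05,
                        node_sd = 0.05, w_a = 1, w_b = 1) {
  L <- hierarchy$n_levels
  top <- hierarchy$tables[[L]]
  k <- nrow(top)
  positions <- c("center", "interface", "water", "dlipc")
  # Coefficients set so that 1-4-bead molecules span roughly -1.5 to +3
  # kcal/mol in ddG, matching the magnitude of the free-energy differences
  # the optimization is designed around. Per-type scatter is centered
  # within sibling groups, so it averages out exactly under
  # coarse-graining: the low-resolution landscape follows the smooth
  # hydrophobicity trend while higher resolutions are progressively
  # rougher -- the smoothness hierarchy the funnel strategy relies on.
  grp_top <- if (L > 1L) top$parent_code else rep("all", k)
  lp_mid <- if (L > 1L) {
    mid <- hierarchy$tables[[L - 1L]]
    mid$logp[match(top$parent_code, mid$code)]
  } else top$logp
  lp_base <- if (L > 2L) {
    mid <- hierarchy$tables[[L - 1L]]
    base <- hierarchy$tables[[L - 2L]]
    base$logp[match(mid$parent_code[match(top$parent_code, mid$code)],
                    base$code)]
  } else lp_mid
  # Per-type deviation from the hydrophobicity trend, structured by
  # resolution: the top level carries rough scatter centered within its
  # sibling groups (so it averages out one level down); the intermediate
  # level carries a smooth refinement proportional to how far its types
  # sit from their class mean (which averages out at the lowest level).
  # The low-resolution landscape is therefore the smooth trend alone, the
  # intermediate one adds a smooth learnable correction, and the top one
  # is genuinely rugged.
  grp_base <- if (L > 2L) {
    mid <- hierarchy$tables[[L - 1L]]
    mid$parent_code[match(top$parent_code, mid$code)]
  } else grp_top
  deviation <- function(sd_top) {
    e3 <- stats::rnorm(k, 0, sd_top)
    e3 <- e3 - stats::ave(e3, grp_top)
    beta <- stats::rnorm(1L, 0, 0.05)
    dev <- e3 + beta * (lp_mid - lp_base)
    if (L > 2L) {
      # mid-resolution group scatter, centered within the lowest-level
      # classes: the intermediate landscape is moderately rough while the
      # low-resolution one still follows the pure trend
      u <- unique(grp_top)
      e2 <- stats::rnorm(length(u), 0, 0.35 * sd_top)[match(grp_top, u)]
      e2 <- e2 - stats::ave(e2, grp_base)
      dev <- dev + e2
    }
    dev
  }
  node <- with_seed(seed, {
    lp <- top$logp
    # center and water share their scatter so the insertion decision
    # (center vs water) follows the smooth trend at every resolution;
    # ruggedness enters through the DLiPC offset and the interface term
    e_cw <- deviation(node_sd)
    center <- -0.10 * lp + e_cw
    water <- 0.08 * lp + e_cw
    interface <- 0.4 * center + 0.4 * water + deviation(0.8 * node_sd)
    gamma <- 0.07 * pmax(lp, 0) + deviation(node_sd)
    cbind(center = center, interface = interface, water = water,
          dlipc = center + gamma)
  })
  rownames(node) <- top$code
  coup <- with_seed(seed + 1L, {
    lapply(stats::setNames(positions, positions), function(pos) {
      M <- matrix(stats::rnorm(k * k, 0, coupling_sd), k, k)
      M <- (M + t(M)) / 2
      dimnames(M) <- list(top$code, top$code)
      M
    })
  })
  levels <- vector("list", L)
  levels[[L]] <- list(node = node, coup = coup)
  for (l in rev(seq_len(L - 1L))) {
    hi_tab <- hierarchy$tables[[l + 1L]]
    lo_tab <- hierarchy$tables[[l]]
    Mb <- matrix(0, nrow(hi_tab), nrow(lo_tab),
                 dimnames = list(hi_tab$code, lo_tab$code))
    Mb[cbind(seq_len(nrow(hi_tab)),
             match(hi_tab$parent_code, lo_tab$code))] <- 1
    Mn <- sweep(Mb, 2L, colSums(Mb), "/")
    hi <- levels[[l + 1L]]
    levels[[l]] <- list(node = crossprod(Mn, hi$node),
                        coup = lapply(hi$coup,
                                      function(C) crossprod(Mn, C %*% Mn)))
    rownames(levels[[l]]$node) <- lo_tab$code
  }
  structure(list(hierarchy = hierarchy, seed = seed, sigma_obs = sigma_obs,
                 coupling_sd = coupling_sd, node_sd = node_sd, w_a = w_a,
                 w_b = w_b, levels = levels),
            class = "oracle_spec")
}

#' @export
print.oracle_spec <- function(x, ...) {
  cat("<oracle_spec seed", x$seed, "sigma_obs", x$sigma_obs, "levels",
      length(x$levels), ">\n")
  invisible(x)
}

# Noiseless positional free energies of a molecule under the oracle.
.oracle_noiseless <- function(spec, molecule) {
  tabs <- spec$levels[[molecule$level]]
  g <- colSums(tabs$node[molecule$node_types, , drop = FALSE])
  if (nrow(molecule$edges)) {
    for (r in seq_len(nrow(molecule$edges))) {
      u <- molecule$node_types[molecule$edges[r, 1L]]
      v <- molecule$node_types[molecule$edges[r, 2L]]
      g <- g + vapply(tabs$coup, function(C) C[u, v], 0)
    }
  }
  g
}

#' Evaluate a molecule with the synthetic oracle
#'
#' Each positional free energy is the sum of per-bead contributions plus
#' pairwise edge couplings plus Gaussian observation noise (drawn from the
#' current RNG stream). Non-inserting molecules -- judged on the noiseless
#' center/water values -- skip the interface and DLiPC positions, which are
#' reported as `NA`.
#'
#' @param spec An `oracle_spec`.
#' @param molecule A `cg_molecule` at any level of the oracle's hierarchy.
#' @param noisy Set `FALSE` for the noiseless values.
#' @return A one-row data frame (`eval_record`) with the four free
#'   energies, `ddG`, `S`, the objective `y` and an `inserting` flag.
#' @export
oracle_evaluate <- function(spec, molecule, noisy = TRUE) {
  if (is.null(spec$levels[[molecule$level]]))
    stop("oracle has no tables for level ", molecule$level, call. = FALSE)
  if (!all(molecule$node_types %in% rownames(spec$levels[[
    molecule$level]]$node)))
    stop("unknown bead type for this oracle", call. = FALSE)
  g <- .oracle_noiseless(spec, molecule)
  ins <- is_inserting(g[["center"]], g[["water"]])
  sd_obs <- if (noisy) spec$sigma_obs else 0
  noise <- if (sd_obs > 0) stats::rnorm(4L, 0, sd_obs) else rep(0, 4L)
  gc_ <- g[["center"]] + noise[1L]
  gw <- g[["water"]] + noise[3L]
  if (ins) {
    gi <- g[["interface"]] + noise[2L]
    gd <- g[["dlipc"]] + noise[4L]
    sc <- score_free_energies(gc_, gi, gw, gd, spec$w_a, spec$w_b)
  } else {
    # shortcut path: judged on noiseless values, so the noisy center/water
    # pair may not satisfy the strict non-insertion inequality
    gi <- NA_real_; gd <- NA_real_
    S <- spec$w_a * max(gc_ - gw, 0)
    sc <- list(ddG = NA_real_, S = S, y = S)
  }
  data.frame(canonical_key = molecule$canonical_key,
             level = molecule$level,
             n_beads = length(molecule$node_types),
             dG_center = gc_, dG_interface = gi, dG_water = gw,
             dG_dlipc = gd, ddG = sc$ddG, S = sc$S, y = sc$y,
             inserting = ins, stringsAsFactors = FALSE)
}

#' Seed the additive bead prior from single-bead evaluations
#'
#' Evaluates every lowest-resolution single-bead molecule through the
#' oracle and stores the observed objectives as the additive prior f0.
#' These evaluations count toward the optimization budget.
#'
#' @param spec An `oracle_spec`.
#' @param hierarchy The oracle's bead hierarchy.
#' @param noisy Passed to [oracle_evaluate()].
#' @return List with `prior` (a [bead_prior()]) and `records` (one row per
#'   bead type).
#' @export
seed_bead_prior <- function(spec, hierarchy = spec$hierarchy, noisy = TRUE) {
  tab <- hierarchy$tables[[1L]]
  recs <- lapply(tab$code, function(cd) {
    oracle_evaluate(spec, cg_molecule(1L, cd, bead_table = tab),
                    noisy = noisy)
  })
  records <- do.call(rbind, recs)
  vals <- stats::setNames(records$y, tab$code)
  list(prior = bead_prior(vals), records = records)
}

#' Oracle backed by user-supplied free energies
#'
#' Replaces the synthetic oracle with a CSV of observed values: columns
#' `canonical_key`, `dG_center`, `dG_interface`, `dG_water`, `dG_dlipc`
#' (the latter two may be empty for non-inserting molecules). Molecules
#' absent from the table raise an error at evaluation time.
#'
#' @param path CSV file path.
#' @param w_a,w_b Penalty weights.
#' @return A `csv_oracle`.
#' @export
csv_oracle <- function(path, w_a = 1, w_b = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("canonical_key", "dG_center", "dG_interface", "dG_water",
            "dG_dlipc")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(table = df, w_a = w_a, w_b = w_b), class = "csv_oracle")
}

#' Evaluate a molecule against a user-supplied free-energy table
#'
#' @param spec A `csv_oracle`.
#' @param molecule A `cg_molecule`.
#' @return An `eval_record` row as in [oracle_evaluate()].
#' @export
csv_evaluate <- function(spec, molecule) {
  i <- match(molecule$canonical_key, spec$table$canonical_key)
  if (is.na(i))
    stop("no observation for molecule ", molecule$canonical_key,
         call. = FALSE)
  row <- spec$table[i, ]
  sc <- score_free_energies(row$dG_center, row$dG_interface, row$dG_water,
                            row$dG_dlipc, spec$w_a, spec$w_b)
  data.frame(canonical_key = molecule$canonical_key,
             level = molecule$level,
             n_beads = length(molecule$node_types),
             dG_center = row$dG_center, dG_interface = row$dG_interface,
             dG_water = row$dG_water, dG_dlipc = row$dG_dlipc,
             ddG = sc$ddG, S = sc$S, y = sc$y,
             inserting = is_inserting(row$dG_center, row$dG_water),
             stringsAsFactors = FALSE)
}

#' Serialize an oracle for exact replay
#'
#' Records the seed and scale parameters that deterministically rebuild
#' the oracle's energy tables (the tables themselves are derived data).
#'
#' @param spec An `oracle_spec`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
oracle_to_json <- function(spec, path) {
  jsonlite::write_json(list(seed = spec$seed, sigma_obs = spec$sigma_obs,
                            coupling_sd = spec$coupling_sd,
                            node_sd = spec$node_sd,
                            w_a = spec$w_a, w_b = spec$w_b,
                            n_levels = length(spec$levels)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
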