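# Enumeration, canonicalization and counting of CG molecules: connected
# vertex-typed simple graphs of one to four beads.
#
# Internals use a packed integer encoding: node types as lexicographic ranks
# of their codes (so numeric order equals code order) and the adjacency as a
# 6-bit mask over the node pairs (1,2),(1,3),(1,4),(2,3),(2,4),(3,4).
# Canonicalization takes the minimum packed value over all node
# permutations, which is exact and cheap for graphs of at most four nodes.

.PAIRS <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                c(2L, 3L), c(2L, 4L), c(3L, 4L))
.PAIR_BIT <- c(1L, 2L, 4L, 8L, 16L, 32L)

.chem_cache <- new.env(parent = emptyenv())

# all permutations of 1..n
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p + (p >= i)
    cbind(rep(i, nrow(q)), q)
  }))
}

# permutations of 1..4 fixing slots > n, plus a 64-entry adjacency remap
# table per permutation: remap[adj + 1] is the mask after relabeling nodes
# so that new slot a holds old node q[a].
.perm_set <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.chem_cache[[key]])) return(.chem_cache[[key]])
  qs <- .perms(n)
  if (n < 4L) qs <- cbind(qs, matrix(rep((n + 1L):4L, each = nrow(qs)),
                                     nrow(qs)))
  remaps <- lapply(seq_len(nrow(qs)), function(r) {
    q <- qs[r, ]
    vapply(0:63, function(adj) {
      out <- 0L
      for (b in 1:6) {
        i <- q[.PAIRS[b, 1L]]; j <- q[.PAIRS[b, 2L]]
        bit <- .PAIR_BIT[which(.PAIRS[, 1L] == min(i, j) &
                               .PAIRS[, 2L] == max(i, j))]
        if (bitwAnd(adj, bit) > 0L) out <- bitwOr(out, .PAIR_BIT[b])
      }
      out
    }, 0L)
  })
  .chem_cache[[key]] <- list(perms = qs, remaps = remaps)
  .chem_cache[[key]]
}

# The connected unlabeled simple graphs on 1..4 nodes, with automorphism
# groups found by brute force over node permutations.
.shapes <- function() {
  if (!is.null(.chem_cache$shapes)) return(.chem_cache$shapes)
  e <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  defs <- list(
    list(n = 1L, edges = matrix(integer(0), 0L, 2L)),          # vertex
    list(n = 2L, edges = e(1, 2)),                             # edge
    list(n = 3L, edges = e(1, 2, 2, 3)),                       # path-3
    list(n = 3L, edges = e(1, 2, 2, 3, 1, 3)),                 # triangle
    list(n = 4L, edges = e(1, 2, 2, 3, 3, 4)),                 # path-4
    list(n = 4L, edges = e(1, 2, 1, 3, 1, 4)),                 # star
    list(n = 4L, edges = e(1, 2, 2, 3, 3, 4, 1, 4)),           # cycle-4
    list(n = 4L, edges = e(1, 2, 2, 3, 1, 3, 3, 4)),           # paw
    list(n = 4L, edges = e(1, 2, 2, 3, 1, 3, 1, 4, 2, 4)),     # diamond
    list(n = 4L, edges = e(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4))# K4
  )
  shapes <- lapply(defs, function(d) {
    adj <- .edges_to_adj(d$edges)
    ps <- .perm_set(d$n)
    aut <- which(vapply(seq_along(ps$remaps),
                        function(r) ps$remaps[[r]][adj + 1L] == adj, TRUE))
    cycles <- vapply(aut, function(r) {
      q <- ps$perms[r, seq_len(d$n)]
      seen <- rep(FALSE, d$n); cyc <- 0L
      for (i in seq_len(d$n)) if (!seen[i]) {
        cyc <- cyc + 1L; j <- i
        while (!seen[j]) { seen[j] <- TRUE; j <- q[j] }
      }
      cyc
    }, 0L)
    list(n = d$n, edges = d$edges, adj = adj, aut_idx = aut,
         aut_cycles = cycles)
  })
  .chem_cache$shapes <- shapes
  shapes
}

.edges_to_adj <- function(edges) {
  adj <- 0L
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- min(edges[r, ]); j <- max(edges[r, ])
    b <- which(.PAIRS[, 1L] == i & .PAIRS[, 2L] == j)
    if (!length(b)) stop("invalid edge (", i, ",", j, ")")
    adj <- bitwOr(adj, .PAIR_BIT[b])
  }
  adj
}

.adj_to_edges <- function(adj) {
  .PAIRS[bitwAnd(adj, .PAIR_BIT) > 0L, , drop = FALSE]
}

.adj_connected <- function(adj, n) {
  if (n == 1L) return(TRUE)
  E <- .adj_to_edges(adj)
  reach <- rep(FALSE, n); reach[1L] <- TRUE
  repeat {
    grew <- FALSE
    if (nrow(E)) for (r in seq_len(nrow(E))) {
      a <- E[r, 1L]; b <- E[r, 2L]
      if (reach[a] != reach[b]) { reach[a] <- reach[b] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  all(reach[seq_len(n)])
}

# Vectorized canonical form. `tm`: N x 4 matrix of lexicographic type ranks
# (0 = absent slot); `adj`: integer masks; `nn`: node counts. Returns the
# canonicalized tm and adj (minimum packed code over all permutations).
.canonical_form <- function(tm, adj, nn, n_ranks) {
  B <- n_ranks + 1
  N <- length(nn)
  out_tm <- tm; out_adj <- adj
  pack <- function(t4, a) (((t4[, 1L] * B + t4[, 2L]) * B + t4[, 3L]) * B +
                             t4[, 4L]) * 64 + a
  for (n in sort(unique(nn))) {
    rows <- which(nn == n)
    ps <- .perm_set(n)
    tmn <- tm[rows, , drop = FALSE]; adjn <- adj[rows]
    best <- rep(Inf, length(rows)); bestq <- rep(1L, length(rows))
    for (r in seq_len(nrow(ps$perms))) {
      q <- ps$perms[r, ]
      code <- pack(tmn[, q, drop = FALSE], ps$remaps[[r]][adjn + 1L])
      upd <- code < best
      best[upd] <- code[upd]; bestq[upd] <- r
    }
    for (r in unique(bestq)) {
      sel <- bestq == r
      q <- ps$perms[r, ]
      out_tm[rows[sel], ] <- tmn[sel, q, drop = FALSE]
      out_adj[rows[sel]] <- ps$remaps[[r]][adjn[sel] + 1L]
    }
  }
  list(tm = out_tm, adj = out_adj)
}

.key_strings <- function(codes_mat, adj, nn) {
  type_part <- apply(codes_mat, 1L, function(z) paste(z[nzchar(z)],
                                                      collapse = ","))
  edge_part <- vapply(adj, function(a) {
    E <- .adj_to_edges(a)
    if (!nrow(E)) return("")
    paste(paste0(E[, 1L], "-", E[, 2L]), collapse = ";")
  }, "")
  paste0(type_part, "|", edge_part)
}

#' Create a CG molecule
#'
#' A CG molecule is a connected vertex-typed simple graph of one to four
#' beads. The constructor validates the structure, canonicalizes the node
#' order and attaches a canonical key that is identical for all isomorphic
#' relabelings.
#'
#' @param level Resolution level of the bead types.
#' @param node_types Character vector of 1--4 bead codes.
#' @param edges Two-column integer matrix of node-index pairs (may have zero
#'   rows for a single bead).
#' @param bead_table The `bead_table` the codes belong to; defaults to the
#'   standard table at `level`.
#' @return An object of class `cg_molecule` with fields `level`,
#'   `node_types`, `edges` and `canonical_key`.
#' @export
cg_molecule <- function(level, node_types, edges = matrix(integer(0), 0L, 2L),
                        bead_table = build_bead_table(level)) {
  n <- length(node_types)
  if (n < 1L || n > 4L) stop("molecule must have 1..4 beads", call. = FALSE)
  if (!is.matrix(edges)) edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) && (any(edges < 1L) || any(edges > n)))
    stop("edge endpoint outside node range", call. = FALSE)
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed", call. = FALSE)
  ranks <- .code_ranks(bead_table)
  li <- ranks$to_rank[node_types]
  if (anyNA(li))
    stop("unknown bead code(s): ",
         paste(node_types[is.na(li)], collapse = ", "), call. = FALSE)
  adj <- .edges_to_adj(edges)
  if (!.adj_connected(adj, n)) stop("molecule graph must be connected",
                                    call. = FALSE)
  tm <- matrix(0, 1L, 4L); tm[1L, seq_len(n)] <- li
  cf <- .canonical_form(tm, adj, n, length(ranks$sorted))
  codes <- matrix("", 1L, 4L)
  codes[cf$tm > 0] <- ranks$sorted[cf$tm[cf$tm > 0]]
  structure(list(level = level,
                 node_types = codes[1L, seq_len(n)],
                 edges = .adj_to_edges(cf$adj),
                 canonical_key = .key_strings(codes, cf$adj, n)),
            class = "cg_molecule")
}

.code_ranks <- function(bead_table) {
  sorted <- sort(bead_table$code, method = "radix")
  list(sorted = sorted,
       to_rank = stats::setNames(seq_along(sorted), sorted))
}

#' Canonical key of a CG molecule
#'
#' Two molecules have equal keys if and only if they are isomorphic as
#' vertex-typed graphs. Keys are computed by minimizing a serialized
#' (type sequence, edge set) encoding over all node permutations.
#'
#' @param molecule A `cg_molecule`.
#' @return A character scalar.
#' @export
canonical_key <- function(molecule) {
  stopifnot(inherits(molecule, "cg_molecule"))
  molecule$canonical_key
}

#' @export
print.cg_molecule <- function(x, ...) {
  cat("<cg_molecule level", x$level, "key", x$canonical_key, ">\n")
  invisible(x)
}

#' Enumerate all CG molecules of a chemical space
#'
#' Generates exactly one representative per isomorphism class of connected
#' vertex-typed simple graphs with up to `max_beads` nodes over the types in
#' `bead_table`. The result is deterministic: molecules are sorted by node
#' count and canonical key.
#'
#' @param bead_table A `bead_table` supplying the type alphabet.
#' @param max_beads Maximum number of beads (1--4).
#' @return A `cg_space` object holding the materialized molecules in packed
#'   form; see [space_size()], [space_molecule()] and [space_keys()].
#' @export
enumerate_molecules <- function(bead_table, max_beads = 4L) {
  if (max_beads < 1L) stop("`max_beads` must be >= 1", call. = FALSE)
  if (max_beads > 4L)
    stop("`max_beads` > 4 is unsupported: constant-bond-length and ",
         "no-angle assumptions only hold for small molecules", call. = FALSE)
  ranks <- .code_ranks(bead_table)
  k <- length(ranks$sorted)
  tms <- list(); adjs <- list(); nns <- list()
  for (sh in .shapes()) {
    n <- sh$n
    if (n > max_beads) next
    combos <- as.matrix(do.call(expand.grid,
                                rep(list(seq_len(k)), n)))[, n:1, drop = FALSE]
    storage.mode(combos) <- "double"
    tm <- cbind(combos, matrix(0, nrow(combos), 4L - n))
    cf <- .canonical_form(tm, rep(sh$adj, nrow(tm)), rep(n, nrow(tm)), k)
    keep <- !duplicated(
      (((cf$tm[, 1L] * (k + 1) + cf$tm[, 2L]) * (k + 1) + cf$tm[, 3L]) *
         (k + 1) + cf$tm[, 4L]) * 64 + cf$adj)
    tms[[length(tms) + 1L]] <- cf$tm[keep, , drop = FALSE]
    adjs[[length(adjs) + 1L]] <- cf$adj[keep]
    nns[[length(nns) + 1L]] <- rep(n, sum(keep))
  }
  tm <- do.call(rbind, tms); adj <- unlist(adjs); nn <- unlist(nns)
  codes <- matrix("", nrow(tm), 4L)
  codes[tm > 0] <- ranks$sorted[tm[tm > 0]]
  keys <- .key_strings(codes, adj, nn)
  ord <- order(nn, keys, method = "radix")
  new_cg_space(attr(bead_table, "level"), bead_table,
               tm[ord, , drop = FALSE], adj[ord], nn[ord], keys[ord])
}

new_cg_space <- function(level, bead_table, tm, adj, nn, keys) {
  if (anyDuplicated(keys)) stop("duplicate canonical keys in space")
  ranks <- .code_ranks(bead_table)
  structure(list(level = level, bead_table = bead_table, ranks = ranks,
                 tm = tm, adj = adj, nn = nn, keys = keys),
            class = "cg_space")
}

#' @export
print.cg_space <- function(x, ...) {
  cat("<cg_space level", x$level, "with", length(x$keys), "molecules>\n")
  invisible(x)
}

#' Number of molecules in a materialized space
#' @param space A `cg_space`.
#' @return Integer count.
#' @export
space_size <- function(space) length(space$keys)

#' Canonical keys of a materialized space
#' @param space A `cg_space`.
#' @return Character vector in deterministic stream order.
#' @export
space_keys <- function(space) space$keys

#' Extract one molecule from a space
#' @param space A `cg_space`.
#' @param i Row index or canonical key.
#' @return A `cg_molecule`.
#' @export
space_molecule <- function(space, i) {
  if (is.character(i)) {
    i <- match(i, space$keys)
    if (is.na(i)) stop("key not found in space", call. = FALSE)
  }
  n <- space$nn[i]
  li <- space$tm[i, seq_len(n)]
  structure(list(level = space$level,
                 node_types = space$ranks$sorted[li],
                 edges = .adj_to_edges(space$adj[i]),
                 canonical_key = space$keys[i]),
            class = "cg_molecule")
}

#' Closed-form count of a chemical space
#'
#' Counts isomorphism classes of connected vertex-typed simple graphs with
#' up to `max_beads` nodes over an alphabet of `k_types` types, by Burnside
#' orbit counting over the automorphism group of each connected graph shape
#' (vertex; edge; path-3 and triangle; path-4, star, cycle-4, triangle with
#' pendant, diamond and the complete graph on four nodes).
#'
#' @param k_types Number of available bead types (>= 1).
#' @param max_beads Maximum number of beads (1--4).
#' @return Exact count as a double (all values here are far below 2^53).
#' @export
count_closed_form <- function(k_types, max_beads = 4L) {
  if (k_types < 1L || max_beads < 1L || max_beads > 4L)
    stop("invalid arguments: need k_types >= 1 and 1 <= max_beads <= 4",
         call. = FALSE)
  total <- 0
  for (sh in .shapes()) {
    if (sh$n > max_beads) next
    total <- total + sum(k_types^sh$aut_cycles) / length(sh$aut_idx)
  }
  total
}

#' Map a molecule to the next-lower resolution
#'
#' Keeps the topology and replaces each node type by its parent type; the
#' result is canonicalized at the lower level. The map is many-to-one:
#' sibling types collapse.
#'
#' @param molecule A `cg_molecule` with `level > 1`.
#' @param hierarchy A `bead_hierarchy`; defaults to [standard_hierarchy()].
#' @return A `cg_molecule` at `level - 1`.
#' @export
map_molecule_down <- function(molecule, hierarchy = standard_hierarchy()) {
  l <- molecule$level
  if (l <= 1L) stop("molecule is already at the lowest level", call. = FALSE)
  cg_molecule(l - 1L, map_type_down(molecule$node_types, l, hierarchy),
              molecule$edges, bead_table = hierarchy$tables[[l - 1L]])
}

#' All higher-resolution preimages of a molecule
#'
#' Enumerates the level `l + 1` molecules that map down to `molecule`: same
#' topology, each node type replaced by any child of its current type,
#' deduplicated up to isomorphism.
#'
#' @param molecule A `cg_molecule` at level `l < ` number of levels.
#' @param hierarchy A `bead_hierarchy`.
#' @return List of `cg_molecule`s at level `l + 1`.
#' @export
molecule_preimages <- function(molecule, hierarchy = standard_hierarchy()) {
  l <- molecule$level
  if (l >= hierarchy$n_levels)
    stop("molecule is already at the highest level", call. = FALSE)
  child_tab <- hierarchy$tables[[l + 1L]]
  kids <- lapply(molecule$node_types,
                 function(cd) child_tab$code[child_tab$parent_code == cd])
  combos <- do.call(expand.grid, c(kids, stringsAsFactors = FALSE))
  seen <- character(0); out <- list()
  for (r in seq_len(nrow(combos))) {
    m <- cg_molecule(l + 1L, as.character(unlist(combos[r, ])),
                     molecule$edges, bead_table = child_tab)
    if (!(m$canonical_key %in% seen)) {
      seen <- c(seen, m$canonical_key)
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Draw a stratified sample of molecules without materializing the space
#'
#' Samples isomorphism classes by drawing a graph shape (with probability
#' proportional to the exact number of classes of that shape) and uniform
#' node types, canonicalizing and deduplicating. Intended for candidate
#' pools at resolutions whose full space is too large to materialize.
#'
#' @param bead_table A `bead_table`.
#' @param n_samples Number of distinct molecules to return.
#' @param max_beads Maximum number of beads (1--4).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `cg_space` holding the sampled molecules.
#' @export
sample_molecules <- function(bead_table, n_samples, max_beads = 4L,
                             seed = 1L) {
  ranks <- .code_ranks(bead_table)
  k <- length(ranks$sorted)
  total <- count_closed_form(k, max_beads)
  if (n_samples >= total) {
    sp <- enumerate_molecules(bead_table, max_beads)
    return(sp)
  }
  shapes <- Filter(function(s) s$n <= max_beads, .shapes())
  wts <- vapply(shapes, function(s) sum(k^s$aut_cycles) / length(s$aut_idx), 0)
  tm_acc <- NULL; adj_acc <- integer(0); nn_acc <- integer(0)
  keys_acc <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (length(keys_acc) < n_samples && tries < 50L) {
      tries <- tries + 1L
      m <- 2L * (n_samples - length(keys_acc))
      si <- sample.int(length(shapes), m, replace = TRUE, prob = wts)
      for (sidx in unique(si)) {
        sh <- shapes[[sidx]]
        cnt <- sum(si == sidx)
        tm <- matrix(0, cnt, 4L)
        tm[, seq_len(sh$n)] <- sample.int(k, cnt * sh$n, replace = TRUE)
        cf <- .canonical_form(tm, rep(sh$adj, cnt), rep(sh$n, cnt), k)
        codes <- matrix("", cnt, 4L)
        codes[cf$tm > 0] <- ranks$sorted[cf$tm[cf$tm > 0]]
        keys <- .key_strings(codes, cf$adj, rep(sh$n, cnt))
        new <- !(keys %in% keys_acc) & !duplicated(keys)
        if (any(new)) {
          tm_acc <- rbind(tm_acc, cf$tm[new, , drop = FALSE])
          adj_acc <- c(adj_acc, cf$adj[new])
          nn_acc <- c(nn_acc, rep(sh$n, sum(new)))
          keys_acc <- c(keys_acc, keys[new])
        }
      }
    }
  })
  keep <- seq_len(min(n_samples, length(keys_acc)))
  ord <- order(nn_acc[keep], keys_acc[keep], method = "radix")
  new_cg_space(attr(bead_table, "level"), bead_table,
               tm_acc[keep, , drop = FALSE][ord, , drop = FALSE],
               adj_acc[keep][ord], nn_acc[keep][ord], keys_acc[keep][ord])
}

#' Serialize molecules as JSONL
#'
#' Writes one JSON record per molecule with fields `level`, `node_types`,
#' `edges` and `canonical_key`.
#'
#' @param space A `cg_space`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_molecules_jsonl <- function(space, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(space$keys)) {
    m <- space_molecule(space, i)
    writeLines(jsonlite::toJSON(list(level = m$level,
                                     node_types = m$node_types,
                                     edges = m$edges,
                                     canonical_key = m$canonical_key),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
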