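# Bead-type tables for the three coarse-graining resolutions and the
# parent maps linking them.

.bead_cache <- new.env(parent = emptyenv())

#' Construct a bead-type table
#'
#' Builds the bead-type table for one of the three coarse-graining
#' resolutions. The high-resolution table (level 3) follows the Martini-style
#' palette restricted to chemical classes Q (charged), P (polar), N
#' (intermediate), C (apolar) and X (halo), each available in three bead
#' sizes: regular (no prefix), small (`S`) and tiny (`T`). Per size this
#' yields P1--P6, N1--N6, C1--C6, X1--X4 and Q1--Q5 split by charge sign,
#' i.e. 32 types per size and 96 in total. Lower resolutions merge adjacent
#' polarity bands (level 2, 45 types) and finally collapse each class to a
#' single type per size (level 1, 15 types). Every type at level `l > 1`
#' carries the code of its unique level `l - 1` parent, so the three tables
#' form a 96 -> 45 -> 15 tree.
#'
#' Each type carries a unitless octanol--water partition proxy (`logp`),
#' linear in the polarity index within a class (C most hydrophobic, Q least)
#' and attenuated for smaller beads. Lower-level values are the arithmetic
#' means of the children's values, mirroring the interaction averaging that
#' defines the reduced-resolution force fields.
#'
#' @param level Integer resolution level: 1 (low, 15 types), 2 (medium, 45)
#'   or 3 (high, 96).
#' @return A `bead_table`: a data frame with columns `code`, `chem_class`,
#'   `size_class`, `charge`, `level`, `parent_code` and `logp`, one row per
#'   bead type.
#' @examples
#' nrow(build_bead_table(3))  # 96
#' @export
build_bead_table <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !(level %in% 1:3))
    stop("`level` must be 1, 2 or 3", call. = FALSE)
  standard_hierarchy()$tables[[level]]
}

#' The standard three-level bead hierarchy
#'
#' Returns the packaged 96/45/15 bead-type hierarchy as a `bead_hierarchy`
#' object: a list with element `tables`, the per-level [build_bead_table()]
#' data frames indexed by level. The object is built once and cached.
#'
#' @return A `bead_hierarchy` object with three levels.
#' @export
standard_hierarchy <- function() {
  if (!is.null(.bead_cache$std)) return(.bead_cache$std)
  .bead_cache$std <- build_standard_hierarchy()
  .bead_cache$std
}

# logp proxy: per-class base value minus a fixed slope per polarity step,
# scaled down for S/T beads. Only the ordering and the within-class
# monotonicity matter downstream; the constants are packaged conventions.
.logp_base <- c(C = 4.5, X = 2.5, N = 1.0, P = -1.0, Q = -3.0)
.logp_slope <- 0.4
.size_scale <- c(R = 1.0, S = 0.8, T = 0.6)

build_standard_hierarchy <- function() {
  sizes <- c("R", "S", "T")
  pfx <- c(R = "", S = "S", T = "T")
  cls_idx <- list(P = 1:6, N = 1:6, C = 1:6, X = 1:4, Q = 1:5)
  grp <- list(P = list(1:2, 3:4, 5:6), N = list(1:2, 3:4, 5:6),
              C = list(1:2, 3:4, 5:6), X = list(1:2, 3:4),
              Q = list(1:2, 3:5))
  grp_label <- function(idx) paste0(min(idx), "-", max(idx))

  rows3 <- list(); rows2 <- list(); rows1 <- list()
  for (s in sizes) {
    for (cl in names(cls_idx)) {
      signs <- if (cl == "Q") c(1L, -1L) else 0L
      sgn_chr <- function(sg) if (sg == 0L) "" else if (sg > 0L) "+" else "-"
      # level 1: one type per class and size
      rows1[[length(rows1) + 1L]] <- data.frame(
        code = paste0(pfx[s], cl), chem_class = cl, size_class = s,
        charge = 0L, level = 1L, parent_code = NA_character_,
        logp = NA_real_, stringsAsFactors = FALSE)
      for (sg in signs) {
        # level 2: merged polarity bands
        for (g in grp[[cl]]) {
          l2code <- paste0(pfx[s], cl, ":", grp_label(g), sgn_chr(sg))
          rows2[[length(rows2) + 1L]] <- data.frame(
            code = l2code, chem_class = cl, size_class = s,
            charge = sg, level = 2L, parent_code = paste0(pfx[s], cl),
            logp = NA_real_, stringsAsFactors = FALSE)
          # level 3: individual polarity bands
          for (i in g) {
            rows3[[length(rows3) + 1L]] <- data.frame(
              code = paste0(pfx[s], cl, i, sgn_chr(sg)), chem_class = cl,
              size_class = s, charge = sg, level = 3L, parent_code = l2code,
              logp = .size_scale[[s]] *
                (.logp_base[[cl]] - .logp_slope * (i - 1)),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  t3 <- do.call(rbind, rows3); t2 <- do.call(rbind, rows2)
  t1 <- do.call(rbind, rows1)
  t2$logp <- vapply(t2$code,
                    function(cd) mean(t3$logp[t3$parent_code == cd]), 0)
  t1$logp <- vapply(t1$code,
                    function(cd) mean(t2$logp[t2$parent_code == cd]), 0)
  new_bead_hierarchy(list(as_bead_table(t1, 1L), as_bead_table(t2, 2L),
                          as_bead_table(t3, 3L)))
}

as_bead_table <- function(df, level) {
  rownames(df) <- NULL
  stopifnot(!anyDuplicated(df$code), all(is.finite(df$logp)),
            all(df$charge == 0L | df$chem_class == "Q"))
  structure(df, class = c("bead_table", "data.frame"), level = level,
            per_size_count = nrow(df) / length(unique(df$size_class)))
}

new_bead_hierarchy <- function(tables) {
  for (l in seq_along(tables)) {
    stopifnot(inherits(tables[[l]], "bead_table"))
    if (l > 1L) {
      miss <- setdiff(tables[[l]]$parent_code, tables[[l - 1L]]$code)
      if (length(miss))
        stop("parent codes missing from level ", l - 1L, ": ",
             paste(miss, collapse = ", "))
    }
  }
  structure(list(tables = tables, n_levels = length(tables)),
            class = "bead_hierarchy")
}

#' Map a bead type to the next-lower resolution
#'
#' Every bead type at level `l > 1` has exactly one parent at level `l - 1`;
#' this returns its code. Composing the map across levels walks the full
#' hierarchy (e.g. `C4 -> C:3-4 -> C`).
#'
#' @param code Bead-type code at `from_level`.
#' @param from_level Level of `code`; must be greater than 1.
#' @param hierarchy A `bead_hierarchy`; defaults to [standard_hierarchy()].
#' @return The parent bead code at `from_level - 1`.
#' @export
map_type_down <- function(code, from_level, hierarchy = standard_hierarchy()) {
  if (from_level <= 1L || from_level > hierarchy$n_levels)
    stop("`from_level` must be in 2..", hierarchy$n_levels, call. = FALSE)
  tab <- hierarchy$tables[[from_level]]
  i <- match(code, tab$code)
  if (anyNA(i))
    stop("unknown bead code(s) at level ", from_level, ": ",
         paste(code[is.na(i)], collapse = ", "), call. = FALSE)
  tab$parent_code[i]
}

#' Export a bead table as TSV
#'
#' @param table A `bead_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bead_table_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
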