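#' Construct a taxonomy from child-parent edges
#'
#' A taxonomy is a single-rooted, level-labelled tree of concept codes.
#' Levels are numbered from 1 at the root, so a node's level equals the
#' number of nodes on its path to the root (inclusive) and also its count
#' of subsumers (ancestors-or-self).
#'
#' @param child character vector of child codes.
#' @param parent character vector of parent codes, same length; the root is
#'   given with parent `"-"` (or may appear only on the parent side).
#' @return an object of class `taxonomy` with components `codes`, `parent`
#'   (integer index, `NA` at the root), `level`, `root` (index), `children`
#'   (list of integer vectors), `anc` (n x L integer matrix, ancestor index
#'   at each level, `NA` above a node's own level), `n_leaves` (leaf counts
#'   per subtree) and cached information-content vectors.
#' @keywords internal
new_taxonomy <- function(child, parent) {
  stopifnot(length(child) == length(parent))
  child <- as.character(child)
  parent <- as.character(parent)
  bad <- !nzchar(child) | grepl("[[:space:]]", child) |
    (!nzchar(parent) | grepl("[[:space:]]", parent))
  if (any(bad)) {
    stop("invalid code token in edge row(s): ", paste(which(bad), collapse = ", "))
  }
  if (anyDuplicated(child)) {
    stop("duplicate child row(s) for code(s): ",
         paste(unique(child[duplicated(child)]), collapse = ", "))
  }

  root_rows <- parent == "-"
  declared_root <- unique(child[root_rows])
  child <- child[!root_rows]
  parent <- parent[!root_rows]

  # roots: declared ones plus parents that never appear as a child
  implicit_root <- setdiff(parent, child)
  roots <- unique(c(declared_root, implicit_root))
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ",
         if (length(roots)) paste(roots, collapse = ", ") else "none (cycle?)")
  }
  root_code <- roots

  codes <- unique(c(root_code, child, parent))
  n <- length(codes)
  idx <- seq_len(n)
  names(idx) <- codes

  parent_idx <- rep(NA_integer_, n)
  parent_idx[idx[child]] <- idx[parent]
  root <- idx[[root_code]]

  # levels by breadth-first traversal from the root; detects cycles and
  # orphan components (nodes never reached)
  level <- rep(NA_integer_, n)
  level[root] <- 1L
  children <- split(idx[child], parent_idx[idx[child]])
  children_list <- vector("list", n)
  children_list[as.integer(names(children))] <- children
  frontier <- root
  while (length(frontier)) {
    kids <- unlist(children_list[frontier], use.names = FALSE)
    if (!length(kids)) break
    level[kids] <- level[parent_idx[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(level)) {
    stop("cycle or orphan subgraph detected involving node(s): ",
         paste(utils::head(codes[is.na(level)], 5L), collapse = ", "))
  }

  L <- max(level)
  # ancestor-at-level matrix: anc[i, l] is i's ancestor at level l (or NA)
  anc <- matrix(NA_integer_, n, L)
  anc[cbind(idx, level)] <- idx
  ord <- order(level) # parents before children
  for (i in ord[-1L]) {
    p <- parent_idx[i]
    anc[i, seq_len(level[i] - 1L)] <- anc[p, seq_len(level[i] - 1L)]
  }

  # leaf counts per subtree, bottom-up
  is_leaf <- lengths(children_list) == 0L
  n_leaves <- as.integer(is_leaf)
  for (i in rev(ord)) {
    p <- parent_idx[i]
    if (!is.na(p)) n_leaves[p] <- n_leaves[p] + n_leaves[i]
  }

  t <- structure(
    list(codes = codes, parent = parent_idx, level = level, root = root,
         children = children_list, anc = anc, n_leaves = n_leaves,
         n_levels = L),
    class = "taxonomy")
  # IC caches (cheap to precompute once; see ic())
  t$ic_path <- as.numeric(level)
  t$ic_ontology <- -log((n_leaves / level + 1) / (n_leaves[root] + 1))
  t
}

#' Load a taxonomy from an edge-list file
#'
#' The file is UTF-8, tab- or comma-delimited, two columns `child,parent`;
#' lines starting with `#` are ignored; the root may be declared by a row
#' whose parent field is `-`, or implied by appearing only as a parent.
#'
#' @param path path to the edge-list file.
#' @return a [taxonomy][new_taxonomy] object.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tROOT", "B\tROOT", "A1\tA"), tf)
#' tx <- load_edge_list(tf)
#' taxonomy_level(tx, "A1")  # 3
load_edge_list <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty edge list: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed edge row(s) in ", path, " (expected two columns)")
  }
  m <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  new_taxonomy(m[, 1L], m[, 2L])
}

#' Serialize a taxonomy back to an edge list
#'
#' Inverse of [load_edge_list()]: writes one `child<TAB>parent` row per
#' non-root node plus a `root<TAB>-` declaration row.
#'
#' @param t a taxonomy.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(t, path) {
  stopifnot(inherits(t, "taxonomy"))
  non_root <- which(!is.na(t$parent))
  rows <- c(paste0(t$codes[t$root], "\t-"),
            paste0(t$codes[non_root], "\t", t$codes[t$parent[non_root]]))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

# resolve codes to indices, with a helpful error
.tax_index <- function(t, codes) {
  i <- match(codes, t$codes)
  if (anyNA(i)) {
    stop("unknown code(s) not in taxonomy: ",
         paste(unique(codes[is.na(i)]), collapse = ", "))
  }
  i
}

#' Derive an ICD-10-style hierarchy from code strings
#'
#' Reconstructs the five-level scheme (virtual root, chapter, three-character
#' category, four-or-five-character subcategory, full expansion code) from
#' the lexical structure of the codes alone. Intermediate nodes are
#' synthesized from prefixes: chapter = first letter, category = first three
#' characters, subcategory = first five characters (`"X99.9"`), expansion =
#' the full string. Codes lacking deeper characters attach at their deepest
#' derivable level, so mixed-granularity inputs (a bare `"M06"` next to
#' `"I00.x01"`) are legal.
#'
#' @param codes character vector of ICD-10-style codes
#'   (letter + two digits, optional `"."` + up to three more characters).
#' @param root code string used for the virtual root (default `"ROOT"`).
#' @return a [taxonomy][new_taxonomy]; every input code is a node.
#' @export
#' @examples
#' tx <- derive_icd10_hierarchy(c("M06.9", "I00.x01"))
#' taxonomy_level(tx, "M06.9")   # 4 (subcategory)
#' taxonomy_level(tx, "I00.x01") # 5 (expansion)
derive_icd10_hierarchy <- function(codes, root = "ROOT") {
  codes <- unique(as.character(codes))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[A-Za-z0-9]{1,3})?$", codes)
  if (any(!ok)) {
    stop("code(s) not matching the ICD-10 lexical pattern: ",
         paste(codes[!ok], collapse = ", "))
  }
  child <- root
  parent <- "-"
  add_edge <- function(c_, p_) {
    child <<- c(child, c_)
    parent <<- c(parent, p_)
  }
  seen <- character(0)
  for (code in codes) {
    # prefix chain from chapter down to the code's own depth
    chain <- substr(code, 1L, 1L)                       # chapter
    if (nchar(code) >= 3L) chain <- c(chain, substr(code, 1L, 3L))
    if (nchar(code) >= 5L) chain <- c(chain, substr(code, 1L, 5L))
    if (nchar(code) > 5L) chain <- c(chain, code)
    chain <- unique(chain)
    prev <- root
    for (node in chain) {
      if (!(node %in% seen)) {
        add_edge(node, prev)
        seen <- c(seen, node)
      }
      prev <- node
    }
  }
  new_taxonomy(child, parent)
}

#' Structural queries on a taxonomy
#'
#' `taxonomy_level()` is the 1-based level (root = 1). `lca()` is the least
#' common ancestor, the deepest node that is an ancestor-or-self of both
#' arguments. `leaves_count()` is the number of leaves in the subtree rooted
#' at a node (a leaf counts itself). `subsumers_count()` is the number of
#' ancestors including the node itself, which in a tree equals the level.
#'
#' @param t a taxonomy.
#' @param a,b concept code strings (vectorised; recycled to common length
#'   for `lca`).
#' @return `lca()` returns code strings; the others return integers.
#' @export
lca <- function(t, a, b) {
  stopifnot(inherits(t, "taxonomy"))
  i <- .tax_index(t, a)
  j <- .tax_index(t, b)
  k <- pmin(t$level[i], t$level[j])
  out <- integer(max(length(i), length(j)))
  i <- rep_len(i, length(out)); j <- rep_len(j, length(out))
  k <- rep_len(k, length(out))
  for (q in seq_along(out)) {
    ai <- t$anc[i[q], seq_len(k[q])]
    aj <- t$anc[j[q], seq_len(k[q])]
    out[q] <- ai[max(which(ai == aj))]
  }
  t$codes[out]
}

#' @rdname lca
#' @export
taxonomy_level <- function(t, a) {
  stopifnot(inherits(t, "taxonomy"))
  t$level[.tax_index(t, a)]
}

#' @rdname lca
#' @export
leaves_count <- function(t, a) {
  stopifnot(inherits(t, "taxonomy"))
  t$n_leaves[.tax_index(t, a)]
}

#' @rdname lca
#' @export
subsumers_count <- function(t, a) {
  stopifnot(inherits(t, "taxonomy"))
  t$level[.tax_index(t, a)]
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", length(x$codes), " nodes, ", x$n_levels,
      " levels, root '", x$codes[x$root], "', ",
      x$n_leaves[x$root], " leaves\n", sep = "")
  invisible(x)
}

# pairwise LCA *levels* (and node indices) between two code index vectors,
# fully vectorised across the |A| x |B| grid: for each level, mark where the
# ancestor-at-level matches, then take the deepest all-prefix match.
.lca_grid <- function(t, i, j) {
  L <- t$n_levels
  common <- matrix(TRUE, length(i), length(j))
  lev <- matrix(0L, length(i), length(j))
  for (l in seq_len(L)) {
    ai <- t$anc[i, l]
    aj <- t$anc[j, l]
    eq <- outer(ai, aj, `==`)
    eq[is.na(eq)] <- FALSE
    common <- common & eq
    lev[common] <- l
  }
  node <- matrix(t$anc[cbind(rep(i, times = length(j)),
                             as.vector(lev))],
                 length(i), length(j))
  list(level = lev, node = node)
}
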