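#' Distance between two sets of taxonomy concepts
#'
#' Eight set-level distance measures between code sets `A` and `B`. The
#' first four work on exact-match overlap only; the other four aggregate
#' code-level distances (see [concept_distance()]):
#'
#' * `"dice"`: `1 - 2|A∩B| / (|A|+|B|)`
#' * `"jaccard"`: `1 - |A∩B| / |A∪B|`
#' * `"cosine"`: `1 - |A∩B| / sqrt(|A||B|)`
#' * `"overlap"`: `1 - |A∩B| / min(|A|,|B|)`
#' * `"closest_pair"`: average, over every code of either set, of the
#'   distance to its nearest code in the other set.
#' * `"nonshared_avg"`: for codes outside the intersection, the mean
#'   distance to the whole other set, summed and divided by `|A∪B|`.
#' * `"allpairs_avg"`: the plain mean over the full `|A| x |B|` grid of
#'   pairwise distances. Note this is NOT zero at `A == A` (it is the mean
#'   pairwise distance within the set).
#' * `"bipartite"`: minimum weighted bipartite matching. Each code may be
#'   used in at most one matched pair; the Hungarian algorithm finds the
#'   matching of size `min(|A|,|B|)` with the smallest summed distance, and
#'   the result is that total divided by the number of matched edges, so it
#'   stays in \[0,1\] and is comparable across set sizes. Surplus codes of
#'   the larger set are deliberately ignored: the matching keeps the most
#'   similar pairs and discards the redundant rest, which is what makes it
#'   robust when the two sets are large or unbalanced, where plain averages
#'   get diluted by the many dissimilar pairs.
#'
#' Duplicate codes are collapsed to a set before computation. Empty sets are
#' an error (no convention for them is defined, and a silent default would
#' corrupt parameter sweeps).
#'
#' @param t a taxonomy.
#' @param A,B character vectors of concept codes (treated as sets).
#' @param ss_method one of the eight method names above.
#' @param ic_method,cs_method,alpha,beta code-level configuration, ignored
#'   by the four overlap-family methods.
#' @param cost optional precomputed code-level distance matrix with
#'   dimnames covering all codes of `A` and `B` (rows/cols indexed by code);
#'   when supplied, `ic_method`/`cs_method` are not consulted.
#' @return a single numeric distance in \[0,1\].
#' @export
#' @examples
#' tx <- toy5_taxonomy()
#' set_distance(tx, c("A1a1", "A1b"), "A1a2", ss_method = "bipartite",
#'              cs_method = "wu")  # 0.2
set_distance <- function(t, A, B,
                         ss_method = c("bipartite", "closest_pair",
                                       "nonshared_avg", "allpairs_avg",
                                       "dice", "jaccard", "cosine", "overlap"),
                         ic_method = c("path", "ontology"),
                         cs_method = c("wu", "li", "simplified", "binary"),
                         alpha = 0.2, beta = 0.6, cost = NULL) {
  ss_method <- match.arg(ss_method)
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  if (!length(A) || !length(B)) {
    stop("set distance is undefined for empty code sets")
  }

  if (ss_method %in% c("dice", "jaccard", "cosine", "overlap")) {
    nab <- length(intersect(A, B))
    return(switch(ss_method,
      dice    = 1 - 2 * nab / (length(A) + length(B)),
      jaccard = 1 - nab / length(union(A, B)),
      cosine  = 1 - nab / sqrt(length(A) * length(B)),
      overlap = 1 - nab / min(length(A), length(B))))
  }

  if (is.null(cost)) {
    ic_method <- match.arg(ic_method)
    cs_method <- match.arg(cs_method)
    d <- concept_distance_matrix(t, A, B, ic_method = ic_method,
                                 cs_method = cs_method,
                                 alpha = alpha, beta = beta)
  } else {
    d <- cost[A, B, drop = FALSE]
  }

  switch(ss_method,
    closest_pair = {
      (sum(apply(d, 1L, min)) + sum(apply(d, 2L, min))) / (length(A) + length(B))
    },
    nonshared_avg = {
      a_only <- setdiff(A, B)
      b_only <- setdiff(B, A)
      s <- 0
      if (length(a_only)) s <- s + sum(rowMeans(d[a_only, , drop = FALSE]))
      if (length(b_only)) s <- s + sum(colMeans(d[, b_only, drop = FALSE]))
      s / length(union(A, B))
    },
    allpairs_avg = mean(d),
    bipartite = {
      hungarian_min_matching(d)$total / min(length(A), length(B))
    })
}
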