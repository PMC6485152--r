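#' Code-level distance between two taxonomy concepts
#'
#' Four pairwise distance formulas over concepts `a`, `b` with least common
#' ancestor `c`. Although the literature calls these "similarities", every
#' formula here returns 0 for maximal resemblance, so this package uniformly
#' calls them distances.
#'
#' * `"binary"`: 0 if `a == b` (exact, case-sensitive string match), else 1.
#'   Needs no IC.
#' * `"wu"`: `1 - 2*IC(c) / (IC(a) + IC(b))`, the information-theoretic
#'   ratio form.
#' * `"li"`: `1 - exp(-alpha * (IC(a)+IC(b)-2*IC(c))) * tanh(beta * IC(c))`.
#'   The first factor decays as `a` and `b` separate from their LCA; the
#'   second saturates with the LCA's depth. Note the sign convention: the
#'   exponent is negative in the separation term, so that the product stays
#'   in \[0,1\] and decreases with separation (some printed statements of
#'   this formula carry a positive exponent, which would leave \[0,1\] and
#'   invert the ranking). Defaults `alpha = 0.2`, `beta = 0.6` from the
#'   benchmark calibration of the original formulation; they are taken as
#'   given, not re-tuned. Note `li` is NOT zero at identity:
#'   `d(a,a) = 1 - tanh(beta*IC(a))` — a property of the formula, not a bug.
#' * `"simplified"`: `(IC(l) - IC(c)) / IC(l)` where `IC(l)` is the IC of a
#'   deepest-level node, computed here as the maximum IC over all nodes
#'   (equal to the total level count under path IC). A simplified form of
#'   `"wu"` valid when both concepts sit at the deepest level.
#'
#' @param t a taxonomy.
#' @param a,b concept code strings (vectorised, recycled).
#' @param ic_method `"path"` or `"ontology"`.
#' @param cs_method one of `"binary"`, `"wu"`, `"li"`, `"simplified"`.
#' @param alpha,beta positive reals, used by `"li"` only.
#' @return numeric vector of distances in \[0,1\].
#' @export
#' @examples
#' tx <- toy5_taxonomy()
#' concept_distance(tx, "A1a1", "A1a2", cs_method = "wu")          # 0.2
#' concept_distance(tx, "A1a1", "B1a", cs_method = "wu")           # 7/9
#' concept_distance(tx, "A1a1", "A1a2", cs_method = "li")          # ~0.3406
concept_distance <- function(t, a, b,
                             ic_method = c("path", "ontology"),
                             cs_method = c("wu", "li", "simplified", "binary"),
                             alpha = 0.2, beta = 0.6) {
  stopifnot(inherits(t, "taxonomy"))
  ic_method <- match.arg(ic_method)
  cs_method <- match.arg(cs_method)
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (cs_method == "binary") {
    return(as.numeric(a != b))
  }
  i <- .tax_index(t, a)
  j <- .tax_index(t, b)
  c_idx <- mapply(function(ii, jj) {
    k <- min(t$level[ii], t$level[jj])
    ai <- t$anc[ii, seq_len(k)]
    aj <- t$anc[jj, seq_len(k)]
    ai[max(which(ai == aj))]
  }, i, j)
  .cs_from_ic(t, .ic_idx(t, i, ic_method), .ic_idx(t, j, ic_method),
              .ic_idx(t, c_idx, ic_method),
              identical = i == j, ic_method = ic_method,
              cs_method = cs_method, alpha = alpha, beta = beta)
}

# core CS formulas on IC values (vectorised); `identical` flags a == b so
# the 0/0 case of "wu" at the root resolves to the identity distance 0.
.cs_from_ic <- function(t, ic_a, ic_b, ic_c, identical, ic_method,
                        cs_method, alpha = 0.2, beta = 0.6) {
  switch(cs_method,
    wu = {
      denom <- ic_a + ic_b
      if (any(denom == 0 & !identical)) {
        stop("IC(a) + IC(b) is zero for a non-identical pair; ",
             "exclude the virtual root from code sets")
      }
      out <- ifelse(identical, 0, 1 - 2 * ic_c / denom)
      # identity always exact zero, even for identical non-root nodes
      out[identical] <- 0
      out
    },
    li = {
      stopifnot(alpha > 0, beta > 0)
      delta <- ic_a + ic_b - 2 * ic_c
      1 - exp(-alpha * delta) * tanh(beta * ic_c)
    },
    simplified = {
      ic_l <- max(if (ic_method == "path") t$ic_path else t$ic_ontology)
      if (ic_l <= 0) {
        stop("degenerate taxonomy: maximum IC is not positive, ",
             "the simplified distance is undefined")
      }
      (ic_l - ic_c) / ic_l
    },
    stop("unknown cs_method: ", cs_method)
  )
}

#' Full pairwise code-level distance matrix
#'
#' Computes the distance between every code of `codes_a` and every code of
#' `codes_b` in one vectorised pass (the least common ancestors of the whole
#' grid are found level-by-level rather than pair-by-pair). This is the
#' workhorse behind all set-level distances and the prototype scores;
#' computing it once over the distinct codes of a cohort amortises the cost
#' of the more expensive IC method.
#'
#' @inheritParams concept_distance
#' @param codes_a,codes_b character vectors of codes; `codes_b` defaults to
#'   `codes_a` (symmetric matrix with zero diagonal except under `"li"`).
#' @return numeric matrix `length(codes_a)` x `length(codes_b)` with
#'   dimnames set to the codes.
#' @export
concept_distance_matrix <- function(t, codes_a, codes_b = codes_a,
                                    ic_method = c("path", "ontology"),
                                    cs_method = c("wu", "li", "simplified", "binary"),
                                    alpha = 0.2, beta = 0.6) {
  stopifnot(inherits(t, "taxonomy"))
  ic_method <- match.arg(ic_method)
  cs_method <- match.arg(cs_method)
  codes_a <- as.character(codes_a)
  codes_b <- as.character(codes_b)
  if (cs_method == "binary") {
    m <- 1 - outer(codes_a, codes_b, `==`)
    dimnames(m) <- list(codes_a, codes_b)
    return(m)
  }
  i <- .tax_index(t, codes_a)
  j <- .tax_index(t, codes_b)
  g <- .lca_grid(t, i, j)
  ic_a <- matrix(.ic_idx(t, i, ic_method), length(i), length(j))
  ic_b <- matrix(.ic_idx(t, j, ic_method), length(i), length(j), byrow = TRUE)
  ic_c <- matrix(.ic_idx(t, as.vector(g$node), ic_method), length(i), length(j))
  idm <- outer(i, j, `==`)
  m <- .cs_from_ic(t, ic_a, ic_b, ic_c, identical = idm,
                   ic_method = ic_method, cs_method = cs_method,
                   alpha = alpha, beta = beta)
  m <- matrix(m, length(i), length(j), dimnames = list(codes_a, codes_b))
  m
}
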