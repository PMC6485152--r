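#' Information content of taxonomy concepts
#'
#' Two information-theoretic IC definitions over a concept taxonomy:
#'
#' * `"path"`: the number of levels on the path from the node to the root,
#'   inclusive of both ends. The virtual root has IC 1, a chapter-level node
#'   IC 2, and a full five-level expansion code IC 5.
#' * `"ontology"`: the leaf/subsumer formulation
#'   \deqn{-\log\frac{|leaves(a)|/|subsumers(a)| + 1}{|leaves(r)| + 1}}
#'   which is 0 at the root and strictly increases along any root-to-leaf
#'   path. The logarithm is natural by default; the base cancels in
#'   ratio-form code distances and only rescales exponent-form ones.
#'
#' Both variants are precomputed at taxonomy construction, so lookups are
#' O(1) per code.
#'
#' @param t a taxonomy.
#' @param a character vector of concept codes.
#' @param method `"path"` or `"ontology"`.
#' @param log_base base of the logarithm for the ontology method
#'   (default `exp(1)`).
#' @return numeric vector of IC values.
#' @export
#' @examples
#' tx <- derive_icd10_hierarchy(c("M06.9", "I00.x01"))
#' ic(tx, c("ROOT", "M", "I00.x01"), method = "path")     # 1 2 5
#' ic(tx, "ROOT", method = "ontology")                    # 0
ic <- function(t, a, method = c("path", "ontology"), log_base = exp(1)) {
  stopifnot(inherits(t, "taxonomy"))
  method <- match.arg(method)
  i <- .tax_index(t, a)
  if (method == "path") {
    t$ic_path[i]
  } else {
    t$ic_ontology[i] / log(log_base)
  }
}

# IC values for node *indices* (internal fast path used by distance code)
.ic_idx <- function(t, i, method) {
  if (method == "path") t$ic_path[i] else t$ic_ontology[i]
}
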