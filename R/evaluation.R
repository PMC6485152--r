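#' The ten benchmark <IC, CS, SS> combinations
#'
#' The studied grid of algorithm combinations: path and ontology IC crossed
#' with the Wu-style code distance under all four CS-based set distances,
#' plus the Li and simplified code distances under bipartite matching.
#' Binary code distance and the four overlap-family set measures are not in
#' the preset (their limitations are established; they remain available to
#' [set_distance()] directly).
#'
#' @param preset name of the preset; only `"benchmark10"` is defined.
#' @return a data.frame with columns `name`, `ic_method`, `cs_method`,
#'   `ss_method`, `alpha`, `beta`.
#' @export
triple_preset <- function(preset = "benchmark10") {
  if (!identical(preset, "benchmark10")) stop("unknown preset: ", preset)
  ss4 <- c("closest_pair", "nonshared_avg", "allpairs_avg", "bipartite")
  ss_id <- c(closest_pair = 5L, nonshared_avg = 6L, allpairs_avg = 7L,
             bipartite = 8L)
  rows <- rbind(
    data.frame(ic_method = "path", cs_method = "wu", ss_method = ss4),
    data.frame(ic_method = "ontology", cs_method = "wu", ss_method = ss4),
    data.frame(ic_method = "path", cs_method = "li", ss_method = "bipartite"),
    data.frame(ic_method = "path", cs_method = "simplified",
               ss_method = "bipartite"))
  ic_id <- c(path = 1L, ontology = 2L)
  cs_id <- c(wu = 2L, li = 3L, simplified = 4L)
  rows$alpha <- 0.2
  rows$beta <- 0.6
  rows$name <- sprintf("<%d,%d,%d>", ic_id[rows$ic_method],
                       cs_id[rows$cs_method], ss_id[rows$ss_method])
  rows[, c("name", "ic_method", "cs_method", "ss_method", "alpha", "beta")]
}

# precision/recall/F from a confusion split; empty predicted-positive or
# empty actual-positive sets yield 0 rather than NaN
.prf <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  fscore <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn, n_test = tp + fp + fn + tn,
             precision = precision, recall = recall, fscore = fscore)
}

#' Evaluate a fitted classifier on a test cohort
#'
#' Predicts short/long HLOS for every test patient with
#' [predict.protoclass()] and scores the predictions against the observed
#' HLOS (gold standard: short = HLOS within the fitted short band,
#' by default 18 days or fewer). The positive class is short.
#'
#' @param object a fitted [protoclass()].
#' @param test test patient table.
#' @param k prototype size (defaults to the fitted `k`).
#' @return a one-row data.frame: `k`, confusion counts `tp,fp,fn,tn`,
#'   `n_test`, `precision`, `recall`, `fscore`.
#' @export
evaluate_hlos <- function(object, test, k = object$config$k) {
  test <- .check_patients(test)
  if (!nrow(test)) stop("empty test set")
  hlos_split <- max(object$strata$hlos_max[endsWith(object$strata$label, "short")])
  truth <- ifelse(test$hlos <= hlos_split, "short", "long")
  pred <- predict(object, test, k = k)
  out <- .prf(tp = sum(pred == "short" & truth == "short"),
              fp = sum(pred == "short" & truth == "long"),
              fn = sum(pred == "long" & truth == "short"),
              tn = sum(pred == "long" & truth == "long"))
  cbind(data.frame(k = k), out)
}

#' Sweep combinations and prototype sizes over a prediction task
#'
#' Fits one classifier per distinct (IC, CS) pair of `triples` (prototypes
#' depend only on the code-level configuration, so they are shared across
#' SS methods), then evaluates every triple at every prototype size in
#' `ks` on the test cohort.
#'
#' @param train,test patient tables.
#' @param taxonomy a taxonomy resolving all codes.
#' @param triples a data.frame as returned by [triple_preset()].
#' @param ks integer vector of prototype sizes (ascending).
#' @param strata see [hlos_strata()].
#' @param distinct passed to [protoclass()].
#' @return a tidy data.frame with one row per (triple, k):
#'   `triple`, `k`, `tp`, `fp`, `fn`, `tn`, `n_test`, `precision`,
#'   `recall`, `fscore`.
#' @export
hlos_sweep <- function(train, test, taxonomy, triples = triple_preset(),
                       ks = c(1, 5, 10, 20, 50), strata = hlos_strata(),
                       distinct = FALSE) {
  if (is.unsorted(ks, strictly = TRUE)) stop("ks must be strictly ascending")
  key <- paste(triples$ic_method, triples$cs_method, triples$alpha, triples$beta)
  fits <- list()
  out <- vector("list", nrow(triples) * length(ks))
  idx <- 0L
  for (r in seq_len(nrow(triples))) {
    if (is.null(fits[[key[r]]])) {
      fits[[key[r]]] <- protoclass(train, taxonomy, strata = strata,
                                   ic_method = triples$ic_method[r],
                                   cs_method = triples$cs_method[r],
                                   alpha = triples$alpha[r],
                                   beta = triples$beta[r],
                                   distinct = distinct)
    }
    fit <- fits[[key[r]]]
    fit$config$ss_method <- triples$ss_method[r]
    for (k in ks) {
      idx <- idx + 1L
      out[[idx]] <- cbind(data.frame(triple = triples$name[r]),
                          evaluate_hlos(fit, test, k = k))
    }
  }
  do.call(rbind, out)
}

#' Correlation between set-level methods across prototype sizes
#'
#' For each set-level method, traces the curve of distances between the
#' top-`k` code sets of two prototypes as `k` varies, then returns the
#' Pearson correlation matrix between the curves. A constant curve has no
#' defined correlation and yields `NA` against every other method.
#'
#' @param t a taxonomy.
#' @param proto_a,proto_b prototypes.
#' @param ks at least three prototype sizes.
#' @param ss_methods set-level methods to compare.
#' @inheritParams set_distance
#' @return a list with `curves` (matrix, rows = `ks`, columns = methods)
#'   and `correlation` (the methods x methods Pearson matrix).
#' @export
ss_correlation <- function(t, proto_a, proto_b, ks,
                           ss_methods = c("closest_pair", "nonshared_avg",
                                          "allpairs_avg", "bipartite"),
                           ic_method = "path", cs_method = "wu",
                           alpha = 0.2, beta = 0.6, cost = NULL) {
  if (length(ks) < 3L) stop("need at least three prototype sizes")
  curves <- sapply(ss_methods, function(ss) {
    vapply(ks, function(k) {
      set_distance(t, prototype_codes(proto_a, k), prototype_codes(proto_b, k),
                   ss_method = ss, ic_method = ic_method,
                   cs_method = cs_method, alpha = alpha, beta = beta,
                   cost = cost)
    }, numeric(1))
  })
  rownames(curves) <- ks
  constant <- apply(curves, 2L, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(curves))
  cm[constant, ] <- NA_real_
  cm[, constant] <- NA_real_
  diag(cm) <- 1
  list(curves = curves, correlation = cm)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Embeds a symmetric zero-diagonal distance matrix into `dims` dimensions
#' by classical (Torgerson) MDS: double-centre the squared distances and
#' keep the leading eigenvectors scaled by the square roots of their
#' eigenvalues. Deterministic up to sign and rotation; Euclidean distance
#' matrices are reproduced exactly at sufficient `dims`.
#'
#' @param dist square symmetric numeric matrix with zero diagonal.
#' @param dims embedding dimension (`n >= dims + 1`).
#' @return an `n x dims` coordinate matrix (row names preserved).
#' @export
mds_embed <- function(dist, dims = 2L) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || !isTRUE(all.equal(dist, t(dist)))) {
    stop("dist must be a square symmetric matrix")
  }
  if (any(diag(dist) != 0)) stop("dist must have a zero diagonal")
  if (nrow(dist) < dims + 1L) stop("need at least dims + 1 points")
  coords <- stats::cmdscale(stats::as.dist(dist), k = dims)
  if (ncol(coords) < dims) { # rank-deficient input: pad zero coordinates
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  coords
}
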