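#' Fit a nearest-prototype hospital length-of-stay classifier
#'
#' Builds, from a training cohort, one ranked diagnosis prototype per
#' age x HLOS stratum (see [build_prototype()]) and packages them with a
#' \verb{<IC, CS, SS>} distance configuration into a classifier: a new
#' patient is compared, within their own age band, against the short-HLOS
#' and the long-HLOS prototype, and assigned the label of the closer one.
#'
#' The positive class throughout is short HLOS (discharge within
#' `hlos_split` days). Exact distance ties are broken toward `"short"` (a
#' deterministic, documented bias; ties are flagged via a warning).
#'
#' @param patients training cohort: data.frame with columns `patient_id`,
#'   `age`, `hlos`, `codes` (list column or `";"`-joined strings).
#' @param taxonomy a [taxonomy][new_taxonomy] resolving every code.
#' @param strata stratification scheme, see [hlos_strata()].
#' @param ic_method `"path"` or `"ontology"` information content.
#' @param cs_method code-level distance: `"wu"`, `"li"`, `"simplified"`,
#'   or `"binary"`.
#' @param ss_method set-level distance used at prediction time, see
#'   [set_distance()].
#' @param alpha,beta parameters of the `"li"` code distance.
#' @param k default prototype size used by `predict` (top-k codes).
#' @param distinct score prototypes against distinct codes instead of
#'   occurrence multisets.
#' @return an object of class `protoclass` with components `prototypes`
#'   (named list, one per stratum), `taxonomy`, `strata`, `config`,
#'   `cost` (memoized code-distance matrix over the training codes) and
#'   `n_train`.
#' @seealso [predict.protoclass()], [evaluate_hlos()], [hlos_sweep()]
#' @export
#' @examples
#' tx <- gen_taxonomy(levels = 4, branching = c(3, 3, 3), seed = 1)
#' cohort <- gen_cohort(tx, n_per_stratum = c(40, 40, 20, 20), seed = 1)
#' sp <- split_cohort(cohort, train_fraction = 0.7, seed = 1)
#' fit <- protoclass(sp$train, tx, ss_method = "bipartite", k = 10)
#' pred <- predict(fit, sp$test)
#' table(pred, ifelse(sp$test$hlos <= 18, "short", "long"))
protoclass <- function(patients, taxonomy, strata = hlos_strata(),
                       ic_method = c("path", "ontology"),
                       cs_method = c("wu", "li", "simplified", "binary"),
                       ss_method = c("bipartite", "closest_pair",
                                     "nonshared_avg", "allpairs_avg",
                                     "dice", "jaccard", "cosine", "overlap"),
                       alpha = 0.2, beta = 0.6, k = 20, distinct = FALSE) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  ic_method <- match.arg(ic_method)
  cs_method <- match.arg(cs_method)
  ss_method <- match.arg(ss_method)
  patients <- stratify(.check_patients(patients), strata)
  assigned <- patients[!is.na(patients$stratum), ]
  if (!nrow(assigned)) stop("no training patient falls in any stratum")

  all_codes <- sort(unique(unlist(assigned$codes, use.names = FALSE)))
  .tax_index(taxonomy, all_codes) # validate early, with offenders named
  cost <- concept_distance_matrix(taxonomy, all_codes,
                                  ic_method = ic_method, cs_method = cs_method,
                                  alpha = alpha, beta = beta)

  prototypes <- lapply(strata$label, function(lab) {
    build_prototype(taxonomy, assigned, label = lab, k = Inf,
                    ic_method = ic_method, cs_method = cs_method,
                    alpha = alpha, beta = beta, distinct = distinct,
                    cost = cost)
  })
  names(prototypes) <- strata$label

  structure(
    list(prototypes = prototypes, taxonomy = taxonomy, strata = strata,
         config = list(ic_method = ic_method, cs_method = cs_method,
                       ss_method = ss_method, alpha = alpha, beta = beta,
                       k = k, distinct = distinct),
         cost = cost, n_train = nrow(assigned),
         call = match.call()),
    class = "protoclass")
}

# short/long prototype pair for one age band label prefix ("young"/"old")
.proto_pair <- function(object, age_band) {
  list(short = object$prototypes[[paste0(age_band, "_short")]],
       long = object$prototypes[[paste0(age_band, "_long")]])
}

# age band of each patient under the fitted strata ("young"/"old"/NA);
# prediction only needs the age axis, so HLOS bands are ignored here.
.age_band <- function(object, patients) {
  s <- object$strata
  band <- rep(NA_character_, nrow(patients))
  for (lab in c("young", "old")) {
    row <- s[s$label == paste0(lab, "_short"), ]
    in_band <- patients$age >= row$age_min & patients$age <= row$age_max
    band[in_band] <- lab
  }
  band
}

#' Predict short/long hospital stay for new patients
#'
#' Compares each patient's diagnosis set against the top-`k` codes of the
#' short- and long-HLOS prototypes of the patient's age band, under the
#' fitted \verb{<IC, CS, SS>} configuration, and returns the label of the
#' nearer prototype.
#'
#' @param object a fitted [protoclass()] object.
#' @param newdata patient table (`patient_id`, `age`, `hlos`, `codes`).
#' @param k prototype size (defaults to the fitted `k`).
#' @param type `"class"` for labels, `"distance"` for the two raw set
#'   distances per patient.
#' @param ... unused.
#' @return for `type = "class"`, a character vector in `{"short","long"}`;
#'   for `type = "distance"`, a data.frame with columns `d_short`, `d_long`.
#' @export
predict.protoclass <- function(object, newdata, k = object$config$k,
                               type = c("class", "distance"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  newdata <- .check_patients(newdata)
  band <- .age_band(object, newdata)
  if (anyNA(band)) {
    stop("patient(s) outside every age band: ",
         paste(newdata$patient_id[is.na(band)], collapse = ", "))
  }
  new_codes <- sort(unique(unlist(newdata$codes, use.names = FALSE)))
  .tax_index(object$taxonomy, new_codes)

  # extend the memoized cost matrix to cover unseen test codes
  pk <- unique(unlist(lapply(object$prototypes,
                             function(p) prototype_codes(p, min(k, nrow(p))))))
  all_codes <- union(new_codes, pk)
  missing <- setdiff(all_codes, rownames(object$cost))
  cost <- object$cost
  if (length(missing) || !all(all_codes %in% colnames(cost))) {
    cost <- concept_distance_matrix(object$taxonomy, all_codes,
                                    ic_method = cfg$ic_method,
                                    cs_method = cfg$cs_method,
                                    alpha = cfg$alpha, beta = cfg$beta)
  }

  d_short <- d_long <- numeric(nrow(newdata))
  for (b in unique(band)) {
    pp <- .proto_pair(object, b)
    ks <- min(k, nrow(pp$short))
    kl <- min(k, nrow(pp$long))
    cs_codes <- prototype_codes(pp$short, ks)
    cl_codes <- prototype_codes(pp$long, kl)
    for (i in which(band == b)) {
      d_short[i] <- set_distance(object$taxonomy, newdata$codes[[i]], cs_codes,
                                 ss_method = cfg$ss_method, cost = cost)
      d_long[i] <- set_distance(object$taxonomy, newdata$codes[[i]], cl_codes,
                                ss_method = cfg$ss_method, cost = cost)
    }
  }
  if (type == "distance") {
    return(data.frame(patient_id = newdata$patient_id,
                      d_short = d_short, d_long = d_long,
                      stringsAsFactors = FALSE))
  }
  ties <- d_short == d_long
  if (any(ties)) {
    warning(sum(ties), " exact distance tie(s) broken toward 'short'")
  }
  ifelse(d_short <= d_long, "short", "long")
}

#' @export
print.protoclass <- function(x, ...) {
  cfg <- x$config
  cat("Nearest-prototype HLOS classifier\n")
  cat("  config: IC=", cfg$ic_method, ", CS=", cfg$cs_method,
      if (cfg$cs_method == "li")
        paste0(" (alpha=", cfg$alpha, ", beta=", cfg$beta, ")"),
      ", SS=", cfg$ss_method, ", k=", cfg$k, "\n", sep = "")
  cat("  trained on ", x$n_train, " patients; prototypes: ",
      paste(sprintf("%s=%d", names(x$prototypes),
                    vapply(x$prototypes, nrow, 1L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.protoclass <- function(object, k = object$config$k, ...) {
  cfg <- object$config
  sep_k <- function(band) {
    pp <- .proto_pair(object, band)
    kk <- min(k, nrow(pp$short), nrow(pp$long))
    prototype_separation(object$taxonomy, pp$short, pp$long, kk,
                         cost = object$cost)
  }
  out <- list(config = cfg, n_train = object$n_train,
              prototype_sizes = vapply(object$prototypes, nrow, 1L),
              separation = c(young = sep_k("young"), old = sep_k("old")),
              k = k)
  class(out) <- "summary.protoclass"
  out
}

#' @export
print.summary.protoclass <- function(x, ...) {
  cat("Nearest-prototype HLOS classifier (", x$n_train, " training patients)\n",
      sep = "")
  cat("  prototype sizes: ",
      paste(sprintf("%s=%d", names(x$prototype_sizes), x$prototype_sizes),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  short-vs-long prototype separation at k=%d: young %.4f, old %.4f\n",
              x$k, x$separation[["young"]], x$separation[["old"]]))
  invisible(x)
}

#' Plot prototype separation against prototype size
#'
#' Draws, for each age band, the all-pairs average distance between the
#' short- and long-HLOS prototypes as a function of prototype size `k`.
#' Higher curves mean better-separated prototypes.
#'
#' @param x a fitted [protoclass()] object.
#' @param ks prototype sizes to evaluate.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of separations (rows = `ks`).
#' @export
plot.protoclass <- function(x, ks = seq(1, 50, by = 5), ...) {
  bands <- c("young", "old")
  sep <- sapply(bands, function(b) {
    pp <- .proto_pair(x, b)
    kmax <- min(nrow(pp$short), nrow(pp$long))
    vapply(pmin(ks, kmax), function(k)
      prototype_separation(x$taxonomy, pp$short, pp$long, k, cost = x$cost),
      numeric(1))
  })
  graphics::matplot(ks, sep, type = "l", lty = 1, col = c(2, 4),
                    xlab = "prototype size k",
                    ylab = "prototype separation (all-pairs avg distance)",
                    ...)
  graphics::legend("topright", legend = bands, lty = 1, col = c(2, 4), bty = "n")
  invisible(sep)
}
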