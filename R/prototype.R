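#' Default age x HLOS subpopulation strata
#'
#' The four pre-defined subpopulations: two age bands (18-50 years, 51+)
#' crossed with short (1-18 days) and long (19-50 days) hospital length of
#' stay. Labels are `young_short`, `old_short`, `young_long`, `old_long`.
#'
#' @param age_split last age (years) of the younger band (default 50).
#' @param hlos_split last HLOS (days) counted as short (default 18).
#' @param hlos_max upper bound of the long band (default 50).
#' @param age_max upper bound of the older band (default `Inf`).
#' @return a data.frame with columns `label`, `age_min`, `age_max`,
#'   `hlos_min`, `hlos_max`.
#' @export
hlos_strata <- function(age_split = 50, hlos_split = 18, hlos_max = 50,
                        age_max = Inf) {
  data.frame(
    label = c("young_short", "old_short", "young_long", "old_long"),
    age_min = c(18, age_split + 1, 18, age_split + 1),
    age_max = c(age_split, age_max, age_split, age_max),
    hlos_min = c(1, 1, hlos_split + 1, hlos_split + 1),
    hlos_max = c(hlos_split, hlos_split, hlos_max, hlos_max),
    stringsAsFactors = FALSE)
}

# validate a patient table: patient_id, age, hlos, codes (list or ";"-joined)
.check_patients <- function(patients) {
  need <- c("patient_id", "age", "hlos", "codes")
  if (!is.data.frame(patients) || !all(need %in% names(patients))) {
    stop("patients must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (!is.list(patients$codes)) {
    patients$codes <- strsplit(as.character(patients$codes), ";", fixed = TRUE)
  }
  patients$codes <- lapply(patients$codes, function(x) unique(x[nzchar(x)]))
  if (any(lengths(patients$codes) == 0L)) {
    stop("patient(s) with empty code set: ",
         paste(patients$patient_id[lengths(patients$codes) == 0L], collapse = ", "))
  }
  if (any(patients$hlos < 1)) stop("hlos must be >= 1 day")
  patients
}

#' Assign patients to age x HLOS strata
#'
#' Each patient is assigned to the unique stratum whose age and HLOS bands
#' both contain it, or left unassigned (label `NA`).
#'
#' @param patients a data.frame with columns `patient_id`, `age`, `hlos`,
#'   `codes` (list column, or `";"`-joined strings).
#' @param strata a strata table as from [hlos_strata()]; bands must be
#'   pairwise disjoint on the age x HLOS plane.
#' @return `patients` with a `stratum` column added.
#' @export
stratify <- function(patients, strata = hlos_strata()) {
  patients <- .check_patients(patients)
  lab <- rep(NA_character_, nrow(patients))
  hits <- integer(nrow(patients))
  for (s in seq_len(nrow(strata))) {
    in_s <- patients$age >= strata$age_min[s] & patients$age <= strata$age_max[s] &
      patients$hlos >= strata$hlos_min[s] & patients$hlos <= strata$hlos_max[s]
    hits <- hits + in_s
    lab[in_s] <- strata$label[s]
  }
  if (any(hits > 1L)) {
    stop("overlapping strata: patient(s) match more than one stratum")
  }
  patients$stratum <- lab
  patients
}

#' Prototype score of a diagnosis within a subpopulation
#'
#' The prototype score of a candidate code `d*` is the sum of its code-level
#' distances to every diagnosis occurrence `d` in the subpopulation's pooled
#' diagnosis list `D` (a multiset by default, so frequent diagnoses dominate
#' centrality; self-occurrences contribute the identity distance). The
#' smaller the summed distance, the more central — more prototypical — the
#' code.
#'
#' @param t a taxonomy.
#' @param d_star candidate code (scalar) or vector of candidates.
#' @param D character vector of diagnosis occurrences (multiset; keep
#'   duplicates).
#' @inheritParams set_distance
#' @return numeric vector of summed distances, one per candidate.
#' @export
#' @examples
#' tx <- toy5_taxonomy()
#' prototype_score(tx, "A1a1", c("A1a1", "A1a2", "A1b"), cs_method = "wu")
#' # 0 + 0.2 + 1/3 = 0.5333...
prototype_score <- function(t, d_star, D,
                            ic_method = c("path", "ontology"),
                            cs_method = c("wu", "li", "simplified", "binary"),
                            alpha = 0.2, beta = 0.6, cost = NULL) {
  if (!length(D)) stop("D must be a non-empty diagnosis list")
  d_star <- as.character(d_star)
  D <- as.character(D)
  distinct <- sort(unique(D)) # canonical order: scores do not depend on input order
  if (is.null(cost)) {
    ic_method <- match.arg(ic_method)
    cs_method <- match.arg(cs_method)
    d <- concept_distance_matrix(t, d_star, distinct, ic_method = ic_method,
                                 cs_method = cs_method, alpha = alpha, beta = beta)
  } else {
    d <- cost[d_star, distinct, drop = FALSE]
  }
  counts <- table(D)[distinct]
  as.numeric(d %*% as.numeric(counts))
}

#' Build a ranked subpopulation prototype
#'
#' Scores every distinct code occurring in the stratum against the stratum's
#' full diagnosis multiset with [prototype_score()], ranks ascending
#' (smallest summed distance first, ties broken lexicographically by code)
#' and truncates to the top `k`.
#'
#' @param t a taxonomy.
#' @param patients stratified patient table, or any patient table if
#'   `label` is `NULL` (then all rows are pooled).
#' @param label stratum label to pool, or `NULL` for all rows.
#' @param k prototype size cap (`Inf` keeps all codes).
#' @param distinct if `TRUE` score against the distinct code set instead of
#'   the occurrence multiset.
#' @inheritParams set_distance
#' @return an object of class `prototype`: a data.frame with columns `code`
#'   and `score` (ascending), with attributes `label` and `n_patients`.
#' @export
build_prototype <- function(t, patients, label = NULL, k = Inf,
                            ic_method = c("path", "ontology"),
                            cs_method = c("wu", "li", "simplified", "binary"),
                            alpha = 0.2, beta = 0.6, distinct = FALSE,
                            cost = NULL) {
  if (k < 1) stop("prototype size k must be >= 1")
  patients <- .check_patients(patients)
  if (!is.null(label)) {
    if (!"stratum" %in% names(patients)) {
      stop("patients must be stratified (see stratify()) to select a label")
    }
    patients <- patients[!is.na(patients$stratum) & patients$stratum == label, ]
  }
  if (!nrow(patients)) stop("empty stratum: ", if (is.null(label)) "<all>" else label)
  D <- unlist(patients$codes, use.names = FALSE)
  if (distinct) D <- unique(D)
  cand <- sort(unique(D))
  sc <- prototype_score(t, cand, D, ic_method = ic_method,
                        cs_method = cs_method, alpha = alpha, beta = beta,
                        cost = cost)
  ord <- order(sc, cand)
  out <- data.frame(code = cand[ord], score = sc[ord],
                    stringsAsFactors = FALSE)
  out <- utils::head(out, n = if (is.finite(k)) k else nrow(out))
  structure(out, label = label, n_patients = nrow(patients),
            class = c("prototype", "data.frame"))
}

#' Top-k codes of a prototype
#' @param p a prototype.
#' @param k number of leading codes.
#' @return character vector of the `k` most central codes.
#' @export
prototype_codes <- function(p, k = nrow(p)) {
  stopifnot(inherits(p, "prototype"))
  if (k > nrow(p)) stop("k = ", k, " exceeds prototype length ", nrow(p))
  p$code[seq_len(k)]
}

#' Separation between two prototypes at size k
#'
#' The all-pairs average code distance between the top-`k` code sets of two
#' prototypes. Larger values mean the prototypes are more distinctly
#' separated.
#'
#' @param t a taxonomy.
#' @param proto_a,proto_b prototypes (see [build_prototype()]).
#' @param k evaluation size, at most the length of both prototypes.
#' @inheritParams set_distance
#' @return numeric separation in \[0,1\].
#' @export
prototype_separation <- function(t, proto_a, proto_b, k,
                                 ic_method = c("path", "ontology"),
                                 cs_method = c("wu", "li", "simplified", "binary"),
                                 alpha = 0.2, beta = 0.6, cost = NULL) {
  set_distance(t, prototype_codes(proto_a, k), prototype_codes(proto_b, k),
               ss_method = "allpairs_avg", ic_method = ic_method,
               cs_method = cs_method, alpha = alpha, beta = beta, cost = cost)
}

#' Area under a separation-vs-size curve
#'
#' Trapezoidal area under a curve of separation values indexed by prototype
#' size `k`; used to compare code-level distance methods by how well their
#' prototypes separate across sizes.
#'
#' @param k strictly increasing numeric vector of prototype sizes.
#' @param separation separation values, same length.
#' @return the trapezoidal area (a single number).
#' @export
separation_auc <- function(k, separation) {
  if (length(k) < 2L || length(separation) != length(k)) {
    stop("need at least two (k, separation) points")
  }
  if (any(diff(k) <= 0)) stop("k must be strictly increasing")
  sum(diff(k) * (utils::head(separation, -1L) + utils::tail(separation, -1L)) / 2)
}

#' @export
print.prototype <- function(x, n = 10L, ...) {
  lab <- attr(x, "label")
  cat("<prototype", if (!is.null(lab)) paste0(" '", lab, "'"), "> ",
      nrow(x), " ranked codes from ", attr(x, "n_patients"),
      " patients\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}
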