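# run code under a locally seeded RNG, restoring global .Random.seed after
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' The TOY5 example taxonomy
#'
#' A fixed 11-node, 5-level taxonomy used throughout the documentation and
#' tests: two chapters `A` and `B`; `A` has children `A1` and the
#' mixed-granularity leaf `A2a`; `A1` has children `A1a` (with leaves
#' `A1a1`, `A1a2`) and `A1b`; `B` has the chain `B1` then leaf `B1a`.
#' Its five leaves are `A1a1`, `A1a2`, `A1b`, `A2a`, `B1a`.
#'
#' @return a [taxonomy][new_taxonomy].
#' @export
#' @examples
#' toy5_taxonomy()
toy5_taxonomy <- function() {
  new_taxonomy(
    child  = c("A", "B", "A1", "A2a", "A1a", "A1b", "A1a1", "A1a2", "B1", "B1a"),
    parent = c("root", "root", "A", "A", "A1", "A1", "A1a", "A1a", "B", "B1"))
}

#' Generate a synthetic taxonomy
#'
#' Builds a complete rooted tree with the requested per-level branching.
#' Codes are readable path strings (`"N3"`, `"N3.1"`, `"N3.1.2"`, ...), so
#' the branch structure is visible in the code itself. Deterministic; the
#' `seed` is accepted for interface symmetry with [gen_cohort()] but the
#' tree shape depends only on `levels` and `branching`.
#'
#' @param levels total level count including the root (>= 2).
#' @param branching integer vector of children per node at each level,
#'   length `levels - 1`.
#' @param seed unused (kept for a uniform generator interface).
#' @param root root code string.
#' @return a [taxonomy][new_taxonomy] with `prod(cumprod(branching))`
#'   guarded to at most 1e5 nodes.
#' @export
#' @examples
#' gen_taxonomy(levels = 5, branching = c(2, 2, 2, 2))  # 31 nodes
gen_taxonomy <- function(levels, branching, seed = NULL, root = "ROOT") {
  stopifnot(levels >= 2, length(branching) == levels - 1, all(branching >= 1))
  n_nodes <- 1 + sum(cumprod(branching))
  if (n_nodes > 1e5) {
    stop("requested taxonomy would have ", n_nodes, " nodes (guard: 1e5)")
  }
  child <- character(0)
  parent <- character(0)
  current <- root
  for (l in seq_len(levels - 1L)) {
    kids <- unlist(lapply(current, function(p) {
      if (p == root) paste0("N", seq_len(branching[l]))
      else paste0(p, ".", seq_len(branching[l]))
    }))
    child <- c(child, kids)
    parent <- c(parent, rep(current, each = branching[l]))
    current <- kids
  }
  new_taxonomy(child, parent)
}

# default code pools: group leaves by their level-2 branch, deal whole
# branches to four stratum cores plus one shared background pool
.default_pools <- function(t) {
  leaves <- which(t$n_leaves == 1L & t$level > 1L)
  branch <- t$anc[leaves, 2L]
  groups <- split(t$codes[leaves], branch)
  if (length(groups) < 5L) {
    stop("taxonomy needs at least 5 level-2 branches for default pools; ",
         "supply `pools` explicitly")
  }
  assign_to <- rep(1:5, length.out = length(groups))
  assign_to[5:length(groups)] <- 5L # all surplus branches into the background
  pooled <- lapply(1:5, function(g)
    unlist(groups[assign_to == g], use.names = FALSE))
  names(pooled) <- c("young_short", "old_short", "young_long", "old_long",
                     "background")
  pooled
}

#' Generate a synthetic patient cohort with subpopulation structure
#'
#' Emulates a cohort with two-way (age x HLOS) subpopulation structure over
#' overlapping diagnosis pools: each stratum owns a core pool of leaf codes
#' (by default, whole level-2 branches of the taxonomy, pairwise disjoint)
#' and all strata share a background pool. A patient draws a truncated-
#' Poisson number of distinct codes (minimum 1), a `core_fraction` share
#' from the stratum core and the rest from the background; age and HLOS are
#' sampled uniformly within the stratum's bands. With `core_fraction = 1`
#' and disjoint cores, strata share no codes; with `core_fraction = 0` the
#' strata are exchangeable.
#'
#' @param t a taxonomy.
#' @param n_per_stratum patient counts for `young_short`, `old_short`,
#'   `young_long`, `old_long` (default `c(283, 257, 82, 83)`).
#' @param codes_per_patient mean of the truncated Poisson code count
#'   (default 4).
#' @param core_fraction share of each patient's codes drawn from the
#'   stratum core pool (default 0.7).
#' @param pools named list with entries `young_short`, `old_short`,
#'   `young_long`, `old_long`, `background`, each a character vector of
#'   leaf codes; `NULL` for the default branch partition.
#' @param strata stratum bands, see [hlos_strata()]; ages in the open-ended
#'   older band are capped at `age_cap`.
#' @param age_cap maximum sampled age (default 90).
#' @param seed RNG seed (local to the call).
#' @return a patient data.frame: `patient_id`, `age`, `hlos`, `codes`
#'   (list column), `stratum`.
#' @export
gen_cohort <- function(t, n_per_stratum = c(283, 257, 82, 83),
                       codes_per_patient = 4, core_fraction = 0.7,
                       pools = NULL, strata = hlos_strata(), age_cap = 90,
                       seed = NULL) {
  stopifnot(inherits(t, "taxonomy"), length(n_per_stratum) == 4,
            core_fraction >= 0, core_fraction <= 1)
  if (is.null(pools)) pools <- .default_pools(t)
  need <- c("young_short", "old_short", "young_long", "old_long", "background")
  if (!all(need %in% names(pools))) {
    stop("pools must name: ", paste(need, collapse = ", "))
  }
  .tax_index(t, unique(unlist(pools)))
  .with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (s in seq_len(4L)) {
      lab <- strata$label[s]
      n <- n_per_stratum[s]
      if (n == 0L) next
      core <- pools[[lab]]
      bg <- pools$background
      amax <- min(strata$age_max[s], age_cap)
      for (p in seq_len(n)) {
        pid <- pid + 1L
        n_codes <- max(1L, stats::rpois(1L, codes_per_patient))
        n_codes <- min(n_codes, length(union(core, bg)))
        n_core <- min(round(core_fraction * n_codes), length(core))
        core_draw <- sample(core, n_core)
        bg_left <- setdiff(bg, core_draw) # pools may overlap; keep codes distinct
        n_bg <- min(n_codes - n_core, length(bg_left))
        codes <- c(core_draw, sample(bg_left, n_bg))
        rows[[pid]] <- list(
          patient_id = sprintf("P%04d", pid),
          age = sample(strata$age_min[s]:amax, 1L),
          hlos = sample(strata$hlos_min[s]:strata$hlos_max[s], 1L),
          codes = codes, stratum = lab)
      }
    }
    data.frame(
      patient_id = vapply(rows, `[[`, "", "patient_id"),
      age = vapply(rows, `[[`, 0L, "age"),
      hlos = vapply(rows, `[[`, 0L, "hlos"),
      codes = I(lapply(rows, `[[`, "codes")),
      stratum = vapply(rows, `[[`, "", "stratum"),
      stringsAsFactors = FALSE)
  })
}

#' Stratified train/test split of a cohort
#'
#' Splits patients into train and test sets, stratified by the age x HLOS
#' stratum so both sides keep the subpopulation proportions. Deterministic
#' given `seed`. A stratum with fewer than 2 patients goes entirely to the
#' training side, with a warning.
#'
#' @param patients a patient table (a `stratum` column is used if present,
#'   otherwise computed from `strata`).
#' @param train_fraction share of each stratum assigned to training,
#'   strictly between 0 and 1.
#' @param seed RNG seed (local to the call).
#' @param strata see [hlos_strata()].
#' @return a list with data.frames `train` and `test`.
#' @export
split_cohort <- function(patients, train_fraction = 0.7, seed = NULL,
                         strata = hlos_strata()) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!"stratum" %in% names(patients)) {
    patients <- stratify(patients, strata)
  }
  key <- ifelse(is.na(patients$stratum), "<unassigned>", patients$stratum)
  .with_seed(seed, {
    in_train <- logical(nrow(patients))
    for (s in unique(key)) {
      rows <- which(key == s)
      if (length(rows) < 2L) {
        warning("stratum '", s, "' has < 2 patients; all assigned to train")
        in_train[rows] <- TRUE
        next
      }
      n_tr <- round(train_fraction * length(rows))
      n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
      in_train[sample(rows, n_tr)] <- TRUE
    }
    list(train = patients[in_train, , drop = FALSE],
         test = patients[!in_train, , drop = FALSE])
  })
}
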