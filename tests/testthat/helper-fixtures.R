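# shared fixtures and independent oracles for the test suite

toy5 <- toy5_taxonomy()

# all permutations of 1..n (tiny n only)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# independent oracle: exhaustive minimum over all injective row->column
# assignments of size min(nrow, ncol)
brute_force_matching <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms_of(n)) {
      tot <- sum(cost[cbind(seq_len(n), cols[p])])
      if (tot < best) best <- tot
    }
  }
  best
}

# a mid-sized benchmark taxonomy shared by the synthetic-cohort tests:
# 5 levels, 6 chapters, 288 leaves
bench_taxonomy <- function() gen_taxonomy(levels = 5, branching = c(6, 4, 4, 3))

# pools reproducing the dilution scenario: four overlapping stratum cores
# (two sub-branches each of chapters N1/N2) whose codes also leak into the
# shared background, so prototypes of different strata converge as k grows
dilution_pools <- function(t) {
  lv <- t$codes[t$n_leaves == 1L & t$level > 1L]
  sub <- function(p) lv[startsWith(lv, paste0(p, "."))]
  cores <- list(young_short = c(sub("N1.1"), sub("N1.2")),
                old_short = c(sub("N2.1"), sub("N2.2")),
                young_long = c(sub("N1.3"), sub("N1.4")),
                old_long = c(sub("N2.3"), sub("N2.4")))
  c(cores, list(background = c(unlist(cores, use.names = FALSE),
                               sub("N5"), sub("N6"))))
}

# random non-empty leaf code set
random_code_set <- function(t, n_max = 6L) {
  lv <- t$codes[t$n_leaves == 1L & t$level > 1L]
  sample(lv, sample.int(n_max, 1L))
}

# tiny crafted cohort whose four prototypes are single known codes
crafted_cohort <- function(codes = list(young_short = "A1a2",
                                        old_short = "A1a2",
                                        young_long = "B1a",
                                        old_long = "B1a")) {
  data.frame(
    patient_id = paste0("C", 1:4),
    age = c(30, 70, 30, 70),
    hlos = c(5, 5, 30, 30),
    codes = I(unname(codes[c("young_short", "old_short",
                             "young_long", "old_long")])),
    stringsAsFactors = FALSE)
}
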