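# Independent oracles used across the suite: quadratic brute-force scans
# and exhaustive enumerations, deliberately naive and separate from the
# package's own code paths.

# quadratic interval-overlap scan (0-based half-open)
bf_overlap <- function(q, s) {
  out <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j] &&
          q$start[i] < s$end[j] && s$start[j] < q$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(q_idx = integer(0), s_idx = integer(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(q_idx = m[, 1], s_idx = m[, 2])
}

# quadratic cis-pair scan
bf_cis_pairs <- function(probes, snp_map, window) {
  out <- list()
  center <- floor((probes$start + probes$end) / 2)
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(snp_map))) {
      if (probes$chrom[i] == snp_map$chrom[j] &&
          abs(snp_map$pos[j] - center[i]) <= window) {
        out[[length(out) + 1L]] <- tibble::tibble(
          probe_id = probes$probe_id[i], snp_id = snp_map$snp_id[j])
      }
    }
  }
  dplyr::bind_rows(out)
}

# exhaustive optimal assignment of reference probes to pool probes in
# standardized (center, spread) space; tiny instances only
bf_optimal_assignment <- function(rs, ps, sc, ss) {
  r <- nrow(rs)
  m <- nrow(ps)
  cost <- outer(seq_len(r), seq_len(m), function(i, j) {
    sqrt(((rs$center[i] - ps$center[j]) / sc)^2 +
           ((rs$spread[i] - ps$spread[j]) / ss)^2)
  })
  best <- Inf
  best_assign <- NULL
  combos <- utils::combn(m, r, simplify = FALSE)
  perms <- all_permutations(r)
  for (cmb in combos) {
    for (k in seq_len(nrow(perms))) {
      idx <- cmb[perms[k, ]]
      tot <- sum(cost[cbind(seq_len(r), idx)])
      if (tot < best) {
        best <- tot
        best_assign <- idx
      }
    }
  }
  list(cost = best, assign = best_assign)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# a small default study specification used by many tests
small_spec <- function(seed = 1, ...) {
  simulation_spec(n_samples = 80, n_snps = 300, n_probes = 40,
                  n_effects = 6, effect_beta = 1.5, noise_sd = 1,
                  ld_block_size = 5, ld_decay = 0.7, seed = seed, ...)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
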