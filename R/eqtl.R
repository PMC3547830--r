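# Cis-eQTL mapping: pair enumeration, Spearman rank-correlation testing,
# permutation-based FDR, replication with allelic-direction checks, and
# transcript-class / tissue specificity.

#' Enumerate cis probe-SNP pairs
#'
#' All and only pairs on the same chromosome with
#' `|snp_pos - probe_center| <= window` (the boundary is included: a SNP
#' exactly `window` bp from the center is a cis pair).
#'
#' @param probes Tibble with `probe_id`, `chrom` and `center` (or
#'   `start`/`end`).
#' @param snp_map Tibble with `snp_id`, `chrom`, `pos` (0-based).
#' @param window Half-width of the cis window in bp (default 250 kb).
#' @return Tibble (`probe_id`, `snp_id`, `chrom`, `pos`, `distance`),
#'   sorted by probe then position; `distance = pos - center`, signed.
#' @export
enumerate_cis_pairs <- function(probes, snp_map, window = 250000) {
  probes <- add_probe_centers(as_tibble(probes))
  snp_map <- as_tibble(snp_map)
  out <- vector("list", 0L)
  for (ch in unique(probes$chrom)) {
    sm <- snp_map[snp_map$chrom == ch, , drop = FALSE]
    if (nrow(sm) == 0L) next
    sm <- sm[order(sm$pos), , drop = FALSE]
    pr <- probes[probes$chrom == ch, , drop = FALSE]
    lo <- findInterval(pr$center - window - 0.5, sm$pos) + 1L
    hi <- findInterval(pr$center + window + 0.5, sm$pos)
    cnt <- pmax(0L, hi - lo + 1L)
    if (sum(cnt) == 0L) next
    snp_idx <- sequence(cnt, from = lo)
    probe_row <- rep(seq_len(nrow(pr)), cnt)
    out[[ch]] <- tibble(
      probe_id = pr$probe_id[probe_row],
      snp_id = sm$snp_id[snp_idx],
      chrom = ch,
      pos = sm$pos[snp_idx],
      distance = sm$pos[snp_idx] - pr$center[probe_row])
  }
  if (length(out) == 0L) {
    return(tibble(probe_id = character(0), snp_id = character(0),
                  chrom = character(0), pos = double(0), distance = double(0)))
  }
  arrange(bind_rows(out), .data$probe_id, .data$pos)
}

# two-sided p from midrank Spearman rho via the t approximation with
# n - 2 df; clamped into (0, 1] so downstream logs and z-scores stay finite.
p_from_rho <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  tt <- abs(rho) * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

# signed standard-normal equivalent of a two-sided p
z_from_p <- function(p, rho) {
  qnorm(p / 2, lower.tail = FALSE) * sign(rho)
}

# all permutations of 1..n, one per row (n! x n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  nr <- nrow(sub)
  out <- matrix(0L, nrow = n * nr, ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nr + 1L):(i * nr)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nr)
  }
  out
}

spearman_exact_p <- function(rd, re, rho_obs) {
  n <- length(rd)
  sdv <- (rd - mean(rd)) / sqrt(sum((rd - mean(rd))^2))
  sev <- (re - mean(re)) / sqrt(sum((re - mean(re))^2))
  P <- all_perms(n)
  M <- matrix(sev[P], nrow(P))
  rho_all <- as.vector(M %*% sdv)
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

#' Spearman rank-correlation association test
#'
#' Tests a genotype dosage vector against an expression vector with the
#' midrank (average-rank) Spearman correlation. Missing entries are removed
#' pairwise. P values are two-sided: exact permutation enumeration for
#' `n_used < exact_below`, t approximation with `n_used - 2` df otherwise.
#' `z` is the signed standard-normal equivalent, its sign that of rho with
#' respect to the counted (alternate) allele.
#'
#' @param dosage Numeric vector of allele dosages (0/1/2, `NA` allowed).
#' @param expression Numeric vector, same length.
#' @param min_n Minimum samples after pairwise deletion.
#' @param min_genotype_count Minimum count in the smallest observed
#'   genotype group.
#' @param exact_below Sample size below which the exact permutation null is
#'   enumerated.
#' @return One-row tibble (`n_used`, `rho`, `p`, `z`, `status`); `status`
#'   is `"ok"` or a not-testable reason (`rho`, `p`, `z` then `NA`).
#'   Not-testable pairs are excluded from the multiple-testing universe by
#'   the callers.
#' @export
#' @examples
#' spearman_test(c(0, 0, 1, 1, 2, 2), c(1, 2, 3, 4, 5, 6),
#'               min_n = 4, min_genotype_count = 2)
spearman_test <- function(dosage, expression, min_n = 30,
                          min_genotype_count = 3, exact_below = 10) {
  if (length(dosage) != length(expression)) {
    linc_abort("`dosage` and `expression` must have equal length.",
               "linceqtl_param_error")
  }
  keep <- !is.na(dosage) & !is.na(expression)
  d <- dosage[keep]
  e <- expression[keep]
  n <- length(d)
  nt <- function(reason) tibble(n_used = n, rho = NA_real_, p = NA_real_,
                                z = NA_real_, status = reason)
  if (n < max(min_n, 3)) return(nt("insufficient_samples"))
  if (length(unique(d)) < 2L) return(nt("monomorphic"))
  if (min(table(d)) < min_genotype_count) return(nt("minor_genotype_group"))
  if (length(unique(e)) < 2L) return(nt("constant_expression"))
  rd <- rank(d)
  re <- rank(e)
  rho <- cor(rd, re)
  p <- if (n < exact_below) {
    spearman_exact_p(rd, re, rho)
  } else {
    p_from_rho(rho, n)
  }
  tibble(n_used = n, rho = rho, p = p, z = z_from_p(p, rho), status = "ok")
}

# Shared machinery for observed and permuted association scans. Ranks are
# computed once; permuting expression phenotypes relative to genotypes is a
# column permutation of the standardized rank matrix, so each of the 100
# permutations costs one crossproduct.
eqtl_engine <- function(expr, geno, pairs, min_n, min_genotype_count) {
  em <- as_intensity(expr)
  gm <- geno$dosage
  common <- intersect(colnames(em), rownames(gm))
  if (length(common) == 0L) {
    linc_abort("No samples shared between expression and genotypes.",
               "linceqtl_pipeline_error")
  }
  pairs <- as_tibble(pairs)
  known <- pairs$probe_id %in% rownames(em) & pairs$snp_id %in% colnames(gm)
  if (!all(known)) {
    inform(sprintf("%d pair(s) dropped: probe or SNP absent from the data.",
                   sum(!known)))
    pairs <- pairs[known, , drop = FALSE]
  }
  probes_u <- unique(pairs$probe_id)
  snps_u <- unique(pairs$snp_id)
  em <- em[probes_u, common, drop = FALSE]
  gm <- gm[common, snps_u, drop = FALSE]
  n <- length(common)
  has_na <- anyNA(em) || anyNA(gm)
  eng <- list(pairs = pairs, n = n, has_na = has_na,
              em = em, gm = gm, min_n = min_n,
              min_genotype_count = min_genotype_count)
  if (!has_na && nrow(pairs) > 0L && n >= 3L) {
    eng$E <- rank_rows_std(em)
    eng$G <- rank_cols_std(gm)
    eng$pi <- match(pairs$probe_id, probes_u)
    eng$si <- match(pairs$snp_id, snps_u)
    snp_ok <- apply(gm, 2L, function(v) {
      tab <- table(v)
      length(tab) >= 2L && min(tab) >= min_genotype_count
    })
    probe_ok <- !is.nan(eng$E[, 1L])
    eng$pair_ok <- snp_ok[eng$si] & probe_ok[eng$pi] & n >= min_n
  } else {
    eng$pair_ok <- rep(FALSE, nrow(pairs))
  }
  eng
}

# rho and p for every (testable) pair; `perm` permutes expression samples.
pair_stats <- function(eng, perm = NULL) {
  E <- eng$E
  if (!is.null(perm)) E <- E[, perm, drop = FALSE]
  R <- E %*% eng$G
  rho <- R[cbind(eng$pi, eng$si)]
  list(rho = rho, p = p_from_rho(rho, eng$n))
}

#' Map cis-eQTLs for a set of probe-SNP pairs
#'
#' Runs [spearman_test()] over every cis pair (vectorized through a rank
#' crossproduct when the data are complete, per-pair with pairwise deletion
#' otherwise) and returns one record per testable pair in deterministic
#' (probe, position) order. Pairs failing the sample-size, polymorphism or
#' minor-genotype-group rules are excluded from the testing universe and
#' counted in a message.
#'
#' @param expr An [expression_matrix()] (normalized) or matrix.
#' @param geno A [genotype_matrix()]; samples are intersected with the
#'   expression columns.
#' @param pairs Cis pairs from [enumerate_cis_pairs()].
#' @param min_n,min_genotype_count Testability rules, see [spearman_test()].
#' @param tissue Tissue label for the records; defaults to the label
#'   carried by `expr`.
#' @return Tibble of eQTL records: `tissue`, `probe_id`, `snp_id`,
#'   `chrom`, `pos`, `distance`, `n_used`, `rho`, `p`, `z`.
#' @export
map_cis_eqtls <- function(expr, geno, pairs, min_n = 30,
                          min_genotype_count = 3, tissue = NULL) {
  tissue <- tissue %||%
    (if (inherits(expr, "expression_matrix")) expr$tissue else NA_character_) %||%
    NA_character_
  eng <- eqtl_engine(expr, geno, pairs, min_n, min_genotype_count)
  pairs <- eng$pairs
  if (nrow(pairs) == 0L) {
    return(tibble(tissue = character(0), probe_id = character(0),
                  snp_id = character(0), chrom = character(0),
                  pos = double(0), distance = double(0), n_used = integer(0),
                  rho = double(0), p = double(0), z = double(0)))
  }
  if (!eng$has_na) {
    st <- pair_stats(eng)
    rec <- tibble(tissue = tissue,
                  probe_id = pairs$probe_id, snp_id = pairs$snp_id,
                  chrom = pairs$chrom %||% NA_character_,
                  pos = pairs$pos %||% NA_real_,
                  distance = pairs$distance %||% NA_real_,
                  n_used = eng$n, rho = st$rho, p = st$p,
                  z = z_from_p(st$p, st$rho))
    dropped <- sum(!eng$pair_ok)
    rec <- rec[eng$pair_ok, , drop = FALSE]
  } else {
    res <- pmap(list(pairs$probe_id, pairs$snp_id), function(pid, sid) {
      spearman_test(eng$gm[, sid], eng$em[pid, ],
                    min_n = min_n, min_genotype_count = min_genotype_count)
    })
    res <- bind_rows(res)
    rec <- bind_cols(tibble(tissue = tissue,
                            probe_id = pairs$probe_id, snp_id = pairs$snp_id,
                            chrom = pairs$chrom %||% NA_character_,
                            pos = pairs$pos %||% NA_real_,
                            distance = pairs$distance %||% NA_real_),
                     res)
    dropped <- sum(res$status != "ok")
    rec <- rec[res$status == "ok",
               c("tissue", "probe_id", "snp_id", "chrom", "pos", "distance",
                 "n_used", "rho", "p", "z")]
  }
  if (dropped > 0L) {
    inform(sprintf("%d pair(s) not testable (excluded from the multiple-testing universe).",
                   dropped))
  }
  arrange(rec, .data$probe_id, .data$pos, .data$snp_id)
}

#' Permutation-based FDR control for cis-eQTL records
#'
#' Estimates the null distribution of the test statistic by shuffling the
#' expression matrix's sample labels as whole columns `n_perm` times
#' (preserving probe-probe correlation) and re-running the association
#' scan. For `unit = "probe"` the statistic is each probe's minimum p over
#' its cis pairs; for `unit = "pair"` every pair p enters (the pooled
#' null). Estimated FDR at a candidate threshold t is
#' `mean over permutations of #(null units with p <= t) / max(1, #(observed
#' units with p <= t))`; the reported `p_threshold` is the largest observed
#' p with estimated FDR at or below `level` (a step function over observed
#' p values, no interpolation).
#'
#' @inheritParams map_cis_eqtls
#' @param n_perm Number of permutations (>= 10; the reference analysis
#'   used 100).
#' @param level Nominal FDR level.
#' @param unit `"probe"` (min-p per probe, the default) or `"pair"`.
#' @param seed Master seed; per-permutation seeds are derived by counter
#'   and recorded in the result.
#' @return A `linc_fdr` object: nominal level, `p_threshold`,
#'   significance-flagged `records` and `units` tibbles, the realized-FDR
#'   `curve`, observed/mean-null counts at the threshold, and the
#'   permutation seeds. An empty significant set (threshold 0) is a valid
#'   outcome, not an error. Use [tidy()] for records, [glance()] for the
#'   one-row summary.
#' @export
permutation_fdr <- function(expr, geno, pairs, n_perm = 100, level = 0.05,
                            unit = c("probe", "pair"), seed = 1,
                            min_n = 30, min_genotype_count = 3,
                            tissue = NULL) {
  unit <- match.arg(unit)
  if (n_perm < 10) {
    linc_abort("`n_perm` must be at least 10.", "linceqtl_param_error")
  }
  eng <- eqtl_engine(expr, geno, pairs, min_n, min_genotype_count)
  if (eng$has_na) {
    linc_abort("Permutation FDR requires complete dosage and expression data.",
               "linceqtl_param_error")
  }
  tissue <- tissue %||%
    (if (inherits(expr, "expression_matrix")) expr$tissue else NA_character_) %||%
    NA_character_
  records <- map_cis_eqtls(expr, geno, pairs, min_n = min_n,
                           min_genotype_count = min_genotype_count,
                           tissue = tissue)
  ok_pairs <- eng$pairs[eng$pair_ok, , drop = FALSE]
  probe_of <- ok_pairs$probe_id

  unit_stat <- function(p) {
    if (unit == "probe") {
      vapply(split(p, probe_of), min, numeric(1))
    } else {
      p
    }
  }
  st_obs <- pair_stats(eng)
  up <- unit_stat(st_obs$p[eng$pair_ok])

  perm_seeds <- vapply(seq_len(n_perm), function(b) {
    derive_seed(seed, paste0("perm:", b))
  }, integer(1))
  null_p <- numeric(0)
  for (b in seq_len(n_perm)) {
    withr::local_seed(perm_seeds[b])
    perm <- sample.int(eng$n)
    st <- pair_stats(eng, perm)
    null_p <- c(null_p, unit_stat(st$p[eng$pair_ok]))
  }
  null_sorted <- sort(null_p)

  if (length(up) == 0L) {
    curve <- tibble(threshold = double(0), n_observed = integer(0),
                    mean_null = double(0), est_fdr = double(0))
    p_threshold <- 0
  } else {
    tu <- sort(unique(up))
    up_sorted <- sort(up)
    n_obs <- findInterval(tu, up_sorted)
    mean_null <- findInterval(tu, null_sorted) / n_perm
    est <- mean_null / pmax(1, n_obs)
    curve <- tibble(threshold = tu, n_observed = n_obs,
                    mean_null = mean_null, est_fdr = est)
    p_threshold <- if (any(est <= level)) max(tu[est <= level]) else 0
  }

  if (unit == "probe") {
    units <- tibble(probe_id = names(up), p = unname(up),
                    significant = unname(up) <= p_threshold & p_threshold > 0)
    records$significant <- records$p <= p_threshold & p_threshold > 0 &
      records$probe_id %in% units$probe_id[units$significant]
  } else {
    units <- tibble(probe_id = records$probe_id, snp_id = records$snp_id,
                    p = records$p,
                    significant = records$p <= p_threshold & p_threshold > 0)
    records$significant <- units$significant
  }
  observed_count <- sum(units$significant)
  mean_null_count <- if (p_threshold > 0 && nrow(curve) > 0) {
    curve$mean_null[match(p_threshold, curve$threshold)]
  } else 0

  structure(list(
    level = level, unit = unit, n_perm = n_perm, seed = seed,
    perm_seeds = perm_seeds, p_threshold = p_threshold,
    observed_count = observed_count, mean_null_count = mean_null_count,
    units = units, records = records, curve = curve, tissue = tissue,
    n_samples = eng$n), class = "linc_fdr")
}

#' @export
print.linc_fdr <- function(x, ...) {
  cat(sprintf(paste0(
    "<linc_fdr> unit = %s, nominal FDR = %.3g, %d permutations\n",
    "  p threshold = %.4g; %d of %d units significant (mean null count %.2f)\n"),
    x$unit, x$level, x$n_perm, x$p_threshold, x$observed_count,
    nrow(x$units), x$mean_null_count))
  invisible(x)
}

#' @export
tidy.linc_fdr <- function(x, ...) x$records

#' @export
glance.linc_fdr <- function(x, ...) {
  tibble(unit = x$unit, level = x$level, n_perm = x$n_perm,
         n_samples = x$n_samples, p_threshold = x$p_threshold,
         n_units = nrow(x$units), n_significant_units = x$observed_count,
         n_significant_pairs = sum(x$records$significant),
         mean_null_count = x$mean_null_count)
}

#' Harmonize a genotype panel to a reference allele coding
#'
#' Aligns a second cohort's dosages to the reference cohort's counted
#' allele: SNPs with swapped ref/alt have dosage flipped to `2 - d` (and
#' downstream z signs therefore agree); SNPs whose alleles cannot be
#' reconciled are dropped with a warning.
#'
#' @param reference_map SNP map of the reference (discovery) cohort.
#' @param geno A [genotype_matrix()] to harmonize.
#' @return List: `geno` (harmonized) and `flips` tibble
#'   (`snp_id`, `action` in kept/flipped/dropped).
#' @export
harmonize_genotypes <- function(reference_map, geno) {
  map <- geno$snp_map
  m <- match(map$snp_id, reference_map$snp_id)
  action <- rep("kept", nrow(map))
  shared <- !is.na(m)
  same <- shared & map$ref == reference_map$ref[m] &
    map$alt == reference_map$alt[m]
  flip <- shared & map$ref == reference_map$alt[m] &
    map$alt == reference_map$ref[m]
  bad <- shared & !same & !flip
  action[flip] <- "flipped"
  action[bad] <- "dropped"
  d <- geno$dosage
  if (any(flip)) {
    d[, map$snp_id[flip]] <- 2L - d[, map$snp_id[flip]]
    tmp <- map$ref[flip]
    map$ref[flip] <- map$alt[flip]
    map$alt[flip] <- tmp
    if ("maf" %in% names(map)) map$maf[flip] <- 1 - map$maf[flip]
    inform(sprintf("%d SNP(s) flipped to the reference allele coding.",
                   sum(flip)))
  }
  if (any(bad)) {
    warn(sprintf("%d SNP(s) dropped: alleles irreconcilable with the reference.",
                 sum(bad)))
    d <- d[, !colnames(d) %in% map$snp_id[bad], drop = FALSE]
    map <- map[!bad, , drop = FALSE]
  }
  list(geno = genotype_matrix(d, map),
       flips = tibble(snp_id = geno$snp_map$snp_id, action = action))
}

#' Replicate discovery cis-eQTLs in an independent cohort
#'
#' Re-tests only the discovery-significant units in a replication cohort
#' (after harmonizing allele codings when the discovery genotype panel is
#' supplied), applies [permutation_fdr()] restricted to those units, and
#' reports the replication fraction plus, per replicated unit, the allelic
#' direction concordance `sign(z_discovery) * sign(z_replication)` for the
#' discovery top pair under the same counted allele.
#'
#' @param discovery A `linc_fdr` from the discovery cohort.
#' @param expr,geno Replication cohort expression and genotypes.
#' @param discovery_geno Optional discovery [genotype_matrix()] used to
#'   harmonize allele codings.
#' @param level,n_perm,seed,min_n,min_genotype_count Replication FDR
#'   settings.
#' @return A `linc_replication` object: per-unit `table`,
#'   `replication_fraction` (replicated / discovery-significant),
#'   `concordance_fraction` among replicated units, the replication
#'   `fdr`, and the allele `flips` log.
#' @export
replicate_eqtls <- function(discovery, expr, geno, discovery_geno = NULL,
                            level = 0.05, n_perm = 100, seed = 1,
                            min_n = 30, min_genotype_count = 3) {
  if (!inherits(discovery, "linc_fdr")) {
    linc_abort("`discovery` must be a linc_fdr object.", "linceqtl_param_error")
  }
  sig <- filter(discovery$records, .data$significant)
  flips <- NULL
  if (!is.null(discovery_geno)) {
    h <- harmonize_genotypes(discovery_geno$snp_map, geno)
    geno <- h$geno
    flips <- h$flips
  }
  if (nrow(sig) == 0L) {
    return(structure(list(table = tibble(), replication_fraction = NA_real_,
                          concordance_fraction = NA_real_, fdr = NULL,
                          flips = flips, level = level),
                     class = "linc_replication"))
  }
  pairs <- distinct(sig, .data$probe_id, .data$snp_id, .data$chrom,
                    .data$pos, .data$distance)
  fdr_rep <- permutation_fdr(expr, geno, pairs, n_perm = n_perm,
                             level = level, unit = discovery$unit,
                             seed = seed, min_n = min_n,
                             min_genotype_count = min_genotype_count)
  top_disc <- top_eqtl_per_probe(sig)
  rep_rec <- select(fdr_rep$records, "probe_id", "snp_id",
                    p_rep = "p", z_rep = "z")
  if (discovery$unit == "probe") {
    unit_sig <- select(fdr_rep$units, "probe_id", replicated = "significant")
    tab <- top_disc |>
      select("probe_id", "snp_id", p_disc = "p", z_disc = "z") |>
      left_join(rep_rec, by = c("probe_id", "snp_id")) |>
      left_join(unit_sig, by = "probe_id")
  } else {
    tab <- sig |>
      select("probe_id", "snp_id", p_disc = "p", z_disc = "z") |>
      left_join(rep_rec, by = c("probe_id", "snp_id")) |>
      left_join(select(fdr_rep$units, "probe_id", "snp_id",
                       replicated = "significant"),
                by = c("probe_id", "snp_id"))
  }
  tab$replicated[is.na(tab$replicated)] <- FALSE
  tab$concordant <- ifelse(tab$replicated & !is.na(tab$z_rep),
                           sign(tab$z_disc) * sign(tab$z_rep) > 0, NA)
  rep_frac <- mean(tab$replicated)
  conc <- tab$concordant[tab$replicated]
  structure(list(table = tab,
                 replication_fraction = rep_frac,
                 concordance_fraction = if (length(conc)) mean(conc, na.rm = TRUE) else NA_real_,
                 fdr = fdr_rep, flips = flips, level = level),
            class = "linc_replication")
}

#' @export
print.linc_replication <- function(x, ...) {
  cat(sprintf(paste0(
    "<linc_replication> %d discovery-significant unit(s): %.1f%% replicated",
    " at FDR %.2g; direction concordance %.1f%% among replicated\n"),
    nrow(x$table), 100 * x$replication_fraction, x$level,
    100 * x$concordance_fraction))
  invisible(x)
}

#' @export
tidy.linc_replication <- function(x, ...) x$table

#' @export
glance.linc_replication <- function(x, ...) {
  tibble(n_discovery = nrow(x$table),
         n_replicated = sum(x$table$replicated %||% logical(0)),
         replication_fraction = x$replication_fraction,
         concordance_fraction = x$concordance_fraction,
         level = x$level)
}

#' Strongest eQTL per probe
#'
#' Per probe, the record with the smallest p; ties broken by larger
#' `|rho|`, then smaller genomic position, then snp id — fully
#' deterministic.
#'
#' @param records eQTL record tibble (from [map_cis_eqtls()]).
#' @return One record per probe.
#' @export
top_eqtl_per_probe <- function(records) {
  if (nrow(records) == 0L) {
    linc_abort("`records` is empty.", "linceqtl_param_error")
  }
  records |>
    group_by(.data$probe_id) |>
    arrange(.data$p, desc(abs(.data$rho)), .data$pos, .data$snp_id,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Transcript-class specificity of lincRNA cis-eQTLs
#'
#' Labels each lincRNA top-eQTL SNP `lincRNA_specific` (no protein-coding
#' probe associated at the same significance threshold) or `shared`;
#' shared SNPs are further labelled same/opposite direction by
#' `sign(z_lincRNA) * sign(z_coding)` at the best coding record, and
#' flagged when they are also the strongest eQTL of some coding probe.
#'
#' @param linc_records Significant lincRNA eQTL records (typically
#'   `tidy(fdr)` filtered to significant).
#' @param coding_records Protein-coding eQTL records computed at the same
#'   threshold universe.
#' @param p_threshold The shared significance threshold (e.g.
#'   `fdr$p_threshold`).
#' @return Tibble, one row per lincRNA top eQTL: `probe_id`, `snp_id`,
#'   `p`, `z`, `specificity`, `coding_probe`, `p_coding`, `z_coding`,
#'   `direction`, `strongest_for_coding`; attributes `prop_specific` and
#'   `prop_opposite` summarize the proportions.
#' @export
specificity_analysis <- function(linc_records, coding_records, p_threshold) {
  top_linc <- top_eqtl_per_probe(linc_records)
  coding_sig <- filter(coding_records, .data$p <= p_threshold)
  best_coding <- if (nrow(coding_sig)) {
    coding_sig |>
      group_by(.data$snp_id) |>
      arrange(.data$p, desc(abs(.data$rho)), .data$probe_id,
              .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      select("snp_id", coding_probe = "probe_id", p_coding = "p",
             z_coding = "z")
  } else {
    tibble(snp_id = character(0), coding_probe = character(0),
           p_coding = double(0), z_coding = double(0))
  }
  strongest_snps <- if (nrow(coding_records)) {
    tc <- top_eqtl_per_probe(coding_records)
    tc$snp_id[tc$p <= p_threshold]
  } else character(0)
  out <- top_linc |>
    select("probe_id", "snp_id", "p", "z") |>
    left_join(best_coding, by = "snp_id") |>
    mutate(specificity = ifelse(is.na(.data$coding_probe),
                                "lincRNA_specific", "shared"),
           direction = ifelse(is.na(.data$z_coding), NA_character_,
                              ifelse(sign(.data$z) * sign(.data$z_coding) > 0,
                                     "same", "opposite")),
           strongest_for_coding = .data$snp_id %in% strongest_snps)
  shared <- out$specificity == "shared"
  attr(out, "prop_specific") <- mean(!shared)
  attr(out, "prop_opposite") <- if (any(shared)) {
    mean(out$direction[shared] == "opposite")
  } else NA_real_
  out
}

#' Tissue specificity of cis-eQTLs
#'
#' Compares per-tissue FDR results on common units (probes, or probe-SNP
#' pairs for `unit = "pair"`) and classifies each unit significant anywhere
#' as single-tissue, multi-tissue, or all-tissue. A Venn-style count per
#' tissue combination is attached as attribute `venn`.
#'
#' @param fdr_list Named list (>= 2) of `linc_fdr` objects, one per
#'   tissue, computed with the same unit.
#' @return Tibble: unit identifiers, `tissues` (list-column of tissues
#'   where significant), `n_tissues`, `class`.
#' @export
compare_tissues <- function(fdr_list) {
  if (length(fdr_list) < 2L || is.null(names(fdr_list))) {
    linc_abort("`fdr_list` must be a named list of at least two linc_fdr objects.",
               "linceqtl_param_error")
  }
  units <- unique(vapply(fdr_list, function(f) f$unit, character(1)))
  if (length(units) != 1L) {
    linc_abort("All FDR results must use the same unit.", "linceqtl_param_error")
  }
  unit <- units
  key_of <- function(f) {
    u <- filter(f$units, .data$significant)
    if (unit == "probe") u$probe_id else paste(u$probe_id, u$snp_id, sep = "::")
  }
  sets <- lapply(fdr_list, key_of)
  all_units <- sort(unique(unlist(sets)))
  n_tis <- length(fdr_list)
  if (length(all_units) == 0L) {
    out <- tibble(unit_id = character(0), tissues = list(),
                  n_tissues = integer(0), class = character(0))
    attr(out, "venn") <- tibble(tissue_set = character(0), n = integer(0))
    return(out)
  }
  tis <- lapply(all_units, function(u) {
    names(sets)[vapply(sets, function(s) u %in% s, logical(1))]
  })
  nt <- lengths(tis)
  out <- tibble(
    unit_id = all_units,
    tissues = tis,
    n_tissues = nt,
    class = ifelse(nt == n_tis, "all_tissue",
                   ifelse(nt == 1L, "single_tissue", "multi_tissue")))
  if (unit == "pair") {
    parts <- strsplit(all_units, "::", fixed = TRUE)
    out <- mutate(out,
                  probe_id = vapply(parts, `[`, character(1), 1L),
                  snp_id = vapply(parts, `[`, character(1), 2L),
                  .before = 1L)
  } else {
    out <- mutate(out, probe_id = all_units, .before = 1L)
  }
  combo <- vapply(tis, paste, character(1), collapse = "+")
  venn <- as_tibble(as.data.frame(table(tissue_set = combo),
                                  stringsAsFactors = FALSE))
  names(venn) <- c("tissue_set", "n")
  attr(out, "venn") <- venn
  out
}
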