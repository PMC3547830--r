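# Cis-pair enumeration, Spearman testing, permutation FDR, replication,
# specificity and tissue comparison.

test_that("cis-pair enumeration is boundary-inclusive and matches brute force", {
  probes <- tibble::tibble(probe_id = "p1", chrom = "chr1",
                           start = 999975, end = 1000025)  # center 1e6
  snp_map <- tibble::tibble(
    snp_id = c("edge", "out", "inside"), chrom = "chr1",
    pos = c(1250000, 1250001, 1e6))
  pairs <- enumerate_cis_pairs(probes, snp_map, window = 250000)
  expect_identical(sort(pairs$snp_id), c("edge", "inside"))
  expect_identical(pairs$distance[pairs$snp_id == "edge"], 250000)

  # probe with no SNP in its window yields zero pairs
  far <- tibble::tibble(probe_id = "p2", chrom = "chr1",
                        start = 9e6, end = 9e6 + 50)
  expect_identical(nrow(enumerate_cis_pairs(far, snp_map, 250000)), 0L)

  # random instance vs quadratic brute-force scan
  withr::local_seed(21)
  pr <- tibble::tibble(probe_id = sprintf("p%03d", 1:100),
                       chrom = sample(c("chr1", "chr2"), 100, TRUE),
                       start = sample.int(3e6, 100))
  pr$end <- pr$start + 50
  sm <- tibble::tibble(snp_id = sprintf("s%04d", 1:1000),
                       chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                       pos = sample.int(3e6, 1000))
  got <- enumerate_cis_pairs(pr, sm, window = 250000)
  bf <- bf_cis_pairs(pr, sm, 250000)
  expect_identical(
    dplyr::arrange(got[, c("probe_id", "snp_id")], probe_id, snp_id),
    dplyr::arrange(bf, probe_id, snp_id))
  # output ordering: by probe then position
  expect_false(is.unsorted(order(got$probe_id, got$pos)))
})

test_that("spearman_test matches exact and approximate oracles", {
  # perfect monotone association, no ties: rho exactly 1
  out <- spearman_test(c(10, 20, 30, 40, 50, 60), c(1, 2, 3, 4, 5, 6),
                       min_n = 4, min_genotype_count = 1)
  expect_equal(out$rho, 1)
  expect_identical(out$status, "ok")

  # tied dosages use midranks: rho below 1 and equal to Pearson on midranks
  tied <- spearman_test(c(0, 0, 1, 1, 2, 2), c(1, 2, 3, 4, 5, 6),
                        min_n = 4, min_genotype_count = 2)
  expect_lt(tied$rho, 1)
  expect_equal(tied$rho,
               cor(rank(c(0, 0, 1, 1, 2, 2)), rank(1:6)))
  expect_identical(tied$status, "ok")

  # exact enumeration agrees with cor.test's exact Spearman p (no ties in
  # expression): several parameterized cases
  withr::local_seed(22)
  for (n in c(6, 7, 8)) {
    for (rep in 1:3) {
      d <- sample(0:2, n, replace = TRUE)
      while (length(unique(d)) < 2) d <- sample(0:2, n, replace = TRUE)
      e <- rnorm(n)
      got <- spearman_test(d, e, min_n = 3, min_genotype_count = 1)
      ct <- suppressWarnings(cor.test(d, e, method = "spearman",
                                      exact = FALSE))
      expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
      # independent oracle: enumerate all permutations here, from scratch
      rd <- rank(d); re <- rank(e)
      sdv <- (rd - mean(rd)) / sqrt(sum((rd - mean(rd))^2))
      sev <- (re - mean(re)) / sqrt(sum((re - mean(re))^2))
      P <- all_permutations(n)
      rho_all <- as.vector(matrix(sev[P], nrow(P)) %*% sdv)
      p_oracle <- mean(abs(rho_all) >= abs(got$rho) - 1e-12)
      expect_equal(got$p, p_oracle, tolerance = 1e-12)
    }
  }

  # t-approximation path agrees with cor.test's asymptotic Spearman p
  withr::local_seed(23)
  d <- rbinom(100, 2, 0.4)
  e <- 0.3 * d + rnorm(100)
  got <- spearman_test(d, e)
  ct <- suppressWarnings(cor.test(d, e, method = "spearman", exact = FALSE))
  expect_equal(got$p, ct$p.value, tolerance = 1e-6)
  expect_equal(got$z, qnorm(got$p / 2, lower.tail = FALSE) * sign(got$rho))

  # not-testable sentinels
  expect_identical(spearman_test(rep(1, 40), rnorm(40))$status, "monomorphic")
  expect_identical(spearman_test(rbinom(40, 2, 0.5), rep(2, 40))$status,
                   "constant_expression")
  expect_identical(spearman_test(c(rep(0, 39), 1), rnorm(40))$status,
                   "minor_genotype_group")
  expect_identical(spearman_test(rbinom(10, 2, 0.5), rnorm(10))$status,
                   "insufficient_samples")

  # pairwise deletion of missing entries
  d2 <- c(rbinom(50, 2, 0.5), NA)
  e2 <- c(rnorm(50), 99)
  expect_identical(spearman_test(d2, e2)$n_used, 50L)
})

test_that("spearman results are invariant under monotone transforms of expression", {
  withr::local_seed(24)
  d <- rbinom(60, 2, 0.3)
  e <- 0.5 * d + rnorm(60)
  a <- spearman_test(d, e)
  b <- spearman_test(d, exp(e))
  cc <- spearman_test(d, 3 * e - 100)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)
  expect_equal(a[c("rho", "p", "z")], cc[c("rho", "p", "z")])
})

test_that("null p values are uniform under independence", {
  withr::local_seed(25)
  n_sim <- 400
  ps <- vapply(seq_len(n_sim), function(i) {
    d <- rbinom(100, 2, 0.4)
    e <- rnorm(100)
    spearman_test(d, e)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("map_cis_eqtls is deterministic, duplicates SNP columns faithfully, and finds planted effects", {
  spec <- small_spec(seed = 26)
  st <- simulate_study(spec)
  pairs <- enumerate_cis_pairs(st$probes, st$geno$snp_map, spec$window)
  rec <- suppressMessages(map_cis_eqtls(st$expression$blood, st$geno, pairs,
                                        min_n = 30))
  rec2 <- suppressMessages(map_cis_eqtls(st$expression$blood, st$geno, pairs,
                                         min_n = 30))
  expect_identical(rec, rec2)

  # the matrix fast path equals the per-pair spearman_test slow path
  idx <- seq(1, nrow(rec), length.out = 25)
  for (i in round(idx)) {
    s <- spearman_test(st$geno$dosage[, rec$snp_id[i]],
                       st$expression$blood$intensity[rec$probe_id[i], ],
                       min_n = 30)
    expect_equal(rec$rho[i], s$rho, tolerance = 1e-12)
    expect_equal(rec$p[i], s$p, tolerance = 1e-10)
  }

  # duplicated SNP column gives identical records for both copies
  g2 <- st$geno
  dup <- cbind(g2$dosage, copy = g2$dosage[, "snp00010"])
  colnames(dup)[ncol(dup)] <- "snp_copy"
  map2 <- dplyr::bind_rows(
    g2$snp_map,
    dplyr::mutate(g2$snp_map[g2$snp_map$snp_id == "snp00010", ],
                  snp_id = "snp_copy"))
  g2 <- genotype_matrix(dup, map2)
  pairs2 <- enumerate_cis_pairs(st$probes, g2$snp_map, spec$window)
  rec3 <- suppressMessages(map_cis_eqtls(st$expression$blood, g2, pairs2,
                                         min_n = 30))
  a <- rec3[rec3$snp_id == "snp00010", ]
  b <- rec3[rec3$snp_id == "snp_copy", ]
  expect_equal(a$rho, b$rho)
  expect_equal(a$p, b$p)

  # planted strong effect is the smallest p in its probe's window for
  # nearly all seeds
  hits <- vapply(1:10, function(sd) {
    sp <- simulation_spec(n_samples = 200, n_snps = 300, n_probes = 20,
                          n_effects = 1, effect_beta = 1, noise_sd = 1,
                          ld_decay = 0, maf_range = c(0.15, 0.5),
                          seed = 500 + sd)
    stx <- simulate_study(sp)
    px <- enumerate_cis_pairs(stx$probes, stx$geno$snp_map, sp$window)
    rx <- suppressMessages(map_cis_eqtls(stx$expression$blood, stx$geno, px))
    win <- rx[rx$probe_id == stx$effects$probe_id[1], ]
    best <- win$snp_id[which.min(win$p)]
    # accept the planted SNP or a perfect proxy of it
    prox <- suppressWarnings(find_proxies(stx$effects$snp_id[1], stx$geno,
                                          mode = "perfect"))$snp_id
    best %in% prox
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # empty sample intersection is a pipeline error
  em <- st$expression$blood$intensity
  colnames(em) <- paste0("X", colnames(em))
  expect_error(suppressMessages(map_cis_eqtls(em, st$geno, pairs)),
               class = "linceqtl_pipeline_error")
})

test_that("permutation FDR is deterministic, separates strong effects, and is monotone in level", {
  spec <- small_spec(seed = 27)
  st <- simulate_study(spec)
  pairs <- enumerate_cis_pairs(
    st$probes[st$probes$transcript_class == "lincRNA", ],
    st$geno$snp_map, spec$window)
  f1 <- suppressMessages(permutation_fdr(st$expression$blood, st$geno, pairs,
                                         n_perm = 30, seed = 4))
  f2 <- suppressMessages(permutation_fdr(st$expression$blood, st$geno, pairs,
                                         n_perm = 30, seed = 4))
  expect_identical(f1$p_threshold, f2$p_threshold)
  expect_identical(f1$units, f2$units)
  expect_identical(f1$records, f2$records)

  # an overwhelming effect is always flagged
  sp_big <- simulation_spec(n_samples = 100, n_snps = 100, n_probes = 10,
                            n_effects = 1, effect_beta = 5, noise_sd = 0.1,
                            maf_range = c(0.2, 0.5), seed = 28)
  stb <- simulate_study(sp_big)
  pb <- enumerate_cis_pairs(stb$probes, stb$geno$snp_map, sp_big$window)
  fb <- suppressMessages(permutation_fdr(stb$expression$blood, stb$geno, pb,
                                         n_perm = 20, seed = 1))
  expect_true(stb$effects$probe_id[1] %in%
                fb$units$probe_id[fb$units$significant])
  up <- fb$units$p[fb$units$probe_id == stb$effects$probe_id[1]]
  expect_gte(fb$p_threshold, up)

  # threshold monotone in the nominal level (same seed, same permutations)
  f01 <- suppressMessages(permutation_fdr(st$expression$blood, st$geno, pairs,
                                          n_perm = 30, level = 0.01, seed = 4))
  expect_lte(f01$p_threshold, f1$p_threshold)

  # estimated FDR formula on the curve: mean null count over observed count
  cur <- f1$curve
  expect_equal(cur$est_fdr, cur$mean_null / pmax(1, cur$n_observed))

  expect_error(suppressMessages(
    permutation_fdr(st$expression$blood, st$geno, pairs, n_perm = 5)),
    class = "linceqtl_param_error")
})

test_that("permutations shuffle whole sample columns and reproduce the null statistic", {
  spec <- small_spec(seed = 29)
  st <- simulate_study(spec)
  pairs <- enumerate_cis_pairs(st$probes, st$geno$snp_map, spec$window)
  f <- suppressMessages(permutation_fdr(st$expression$blood, st$geno, pairs,
                                        n_perm = 10, seed = 77))
  eng <- linceqtl:::eqtl_engine(st$expression$blood, st$geno, pairs, 30, 3)
  for (b in c(1L, 5L)) {
    perm <- withr::with_seed(f$perm_seeds[b], sample.int(eng$n))
    expect_identical(sort(perm), seq_len(eng$n))  # a true relabelling
    st_b <- linceqtl:::pair_stats(eng, perm)
    # cross-check one pair against a from-scratch spearman on permuted data
    i <- which(eng$pair_ok)[1]
    pid <- eng$pairs$probe_id[i]
    sid <- eng$pairs$snp_id[i]
    samples <- colnames(eng$em)
    s <- spearman_test(st$geno$dosage[samples, sid],
                       st$expression$blood$intensity[pid, samples[perm]],
                       min_n = 3, min_genotype_count = 1)
    expect_equal(st_b$rho[i], s$rho, tolerance = 1e-12)
  }
})

test_that("replication recovers direction concordance and survives allele flips", {
  # strong effects, independent replication cohort from the same process
  spec <- simulation_spec(n_samples = 150, n_snps = 400, n_probes = 40,
                          n_effects = 8, effect_beta = 2, noise_sd = 0.8,
                          ld_block_size = 5, seed = 30)
  disc <- simulate_study(spec)
  repl <- simulate_study(spec, cohort_seed = 3030)
  expect_identical(disc$geno$snp_map, repl$geno$snp_map)
  expect_false(identical(disc$geno$dosage, repl$geno$dosage))
  expect_identical(disc$effects, repl$effects)

  pairs <- enumerate_cis_pairs(disc$probes, disc$geno$snp_map, spec$window)
  fd <- suppressMessages(permutation_fdr(disc$expression$blood, disc$geno,
                                         pairs, n_perm = 30, seed = 1))
  expect_gt(fd$observed_count, 0)
  rr <- suppressMessages(replicate_eqtls(fd, repl$expression$blood, repl$geno,
                                         discovery_geno = disc$geno,
                                         n_perm = 30, seed = 2))
  expect_gt(rr$replication_fraction, 0.5)
  expect_equal(rr$concordance_fraction, 1)

  # flipping one SNP's allele encoding changes nothing after harmonization
  flip_snp <- disc$effects$snp_id[1]
  g3 <- repl$geno
  g3$dosage[, flip_snp] <- 2L - g3$dosage[, flip_snp]
  i <- match(flip_snp, g3$snp_map$snp_id)
  tmp <- g3$snp_map$ref[i]
  g3$snp_map$ref[i] <- g3$snp_map$alt[i]
  g3$snp_map$alt[i] <- tmp
  rr3 <- suppressMessages(replicate_eqtls(fd, repl$expression$blood, g3,
                                          discovery_geno = disc$geno,
                                          n_perm = 30, seed = 2))
  expect_identical(rr3$table$replicated, rr$table$replicated)
  expect_equal(rr3$table$z_rep, rr$table$z_rep, tolerance = 1e-10)
  expect_identical(rr3$flips$action[rr3$flips$snp_id == flip_snp], "flipped")
})

test_that("top-eQTL selection applies the deterministic tie-break cascade", {
  one <- tibble::tibble(tissue = "blood", probe_id = "p", snp_id = "a",
                        chrom = "chr1", pos = 10, distance = 0, n_used = 50,
                        rho = 0.4, p = 1e-5, z = 4.4)
  expect_identical(top_eqtl_per_probe(one)$snp_id, "a")

  two <- dplyr::bind_rows(one, dplyr::mutate(one, snp_id = "b", rho = 0.5,
                                             pos = 20))
  expect_identical(top_eqtl_per_probe(two)$snp_id, "b")  # same p, larger |rho|

  three <- dplyr::bind_rows(two, dplyr::mutate(one, snp_id = "c", rho = -0.5,
                                               pos = 5))
  expect_identical(top_eqtl_per_probe(three)$snp_id, "c") # |rho| tie, smaller pos

  # sort-oracle agreement on a random instance
  withr::local_seed(31)
  recs <- tibble::tibble(
    tissue = "blood",
    probe_id = sample(sprintf("p%02d", 1:20), 300, TRUE),
    snp_id = sprintf("s%03d", 1:300), chrom = "chr1",
    pos = sample.int(1e6, 300), distance = 0, n_used = 50,
    rho = round(runif(300, -1, 1), 2),
    p = round(10^-runif(300, 0, 6), 7), z = 0)
  got <- top_eqtl_per_probe(recs)
  oracle <- do.call(rbind, lapply(split(recs, recs$probe_id), function(g) {
    g[order(g$p, -abs(g$rho), g$pos, g$snp_id)[1], ]
  }))
  expect_identical(got$snp_id, oracle$snp_id)
})

test_that("specificity analysis classifies constructed shared and specific effects", {
  mk_rec <- function(probe, snp, p, z, rho = z / 10) {
    tibble::tibble(tissue = "blood", probe_id = probe, snp_id = snp,
                   chrom = "chr1", pos = match(snp, letters) * 100,
                   distance = 0, n_used = 100, rho = rho, p = p, z = z)
  }
  linc <- dplyr::bind_rows(
    mk_rec("L1", "a", 1e-8, 6), mk_rec("L2", "b", 1e-6, -5),
    mk_rec("L3", "c", 1e-7, 4))
  # coding expression independent of all SNPs: all lincRNA-specific
  coding_null <- mk_rec("C1", "d", 0.4, 0.8)
  s0 <- specificity_analysis(linc, coding_null, p_threshold = 1e-4)
  expect_identical(unique(s0$specificity), "lincRNA_specific")
  expect_equal(attr(s0, "prop_specific"), 1)

  # SNP 'a' drives lincRNA up and a coding gene down: shared, opposite
  coding <- dplyr::bind_rows(mk_rec("C1", "a", 1e-9, -7), coding_null)
  s1 <- specificity_analysis(linc, coding, p_threshold = 1e-4)
  expect_identical(s1$specificity[s1$snp_id == "a"], "shared")
  expect_identical(s1$direction[s1$snp_id == "a"], "opposite")
  expect_true(s1$strongest_for_coding[s1$snp_id == "a"])
  expect_equal(attr(s1, "prop_specific"), 2 / 3)
  expect_equal(attr(s1, "prop_opposite"), 1)
})

test_that("planted shared versus specific effects are recovered in proportion", {
  spec <- simulation_spec(n_samples = 200, n_snps = 600, n_probes = 80,
                          n_effects = 16, noise_sd = 0.8,
                          maf_range = c(0.2, 0.5),
                          ld_block_size = 5, seed = 33)
  st <- simulate_study(spec, n_shared = 4, target_class = "lincRNA",
                       beta = c(rep(2, 4), seq(0.5, 2, length.out = 12)))
  linc_ids <- st$probes$probe_id[st$probes$transcript_class == "lincRNA"]
  cod_ids <- st$probes$probe_id[st$probes$transcript_class == "protein_coding"]
  pl <- enumerate_cis_pairs(st$probes[st$probes$probe_id %in% linc_ids, ],
                            st$geno$snp_map, spec$window)
  pc <- enumerate_cis_pairs(st$probes[st$probes$probe_id %in% cod_ids, ],
                            st$geno$snp_map, spec$window)
  fd <- suppressMessages(permutation_fdr(st$expression$blood, st$geno, pl,
                                         n_perm = 30, seed = 1))
  crec <- suppressMessages(map_cis_eqtls(st$expression$blood, st$geno, pc))
  sig <- dplyr::filter(fd$records, significant)
  sp <- specificity_analysis(sig, crec, fd$p_threshold)
  truth_shared <- st$effects$snp_id[duplicated(st$effects$snp_id)]
  got_shared <- sp$snp_id[sp$specificity == "shared"]
  # planted shared SNPs (or their proxies) dominate the shared calls
  expect_gte(sum(sp$specificity == "shared"), 2)
  expect_lt(abs(attr(sp, "prop_specific") - 12 / 16), 0.25)
})

test_that("tissue comparison classifies planted tissue-restricted effects", {
  spec <- simulation_spec(
    n_samples = 140, n_snps = 300, n_probes = 30, n_effects = 0,
    effect_beta = 2.5, noise_sd = 0.7, ld_block_size = 5,
    maf_range = c(0.2, 0.5),
    tissues = c(blood = 140, SAT = 90, liver = 90), seed = 34)
  g <- simulate_genotypes(spec)
  probes <- make_probes(spec)
  ubi <- make_effects(spec, g, probes, n_effects = 2, beta = 2.5,
                      seed = 101)
  sat_only <- make_effects(spec, g, probes, n_effects = 2, beta = 2.5,
                           tissues_active = "SAT", seed = 202)
  sat_only <- dplyr::anti_join(sat_only, ubi, by = "probe_id")
  effects <- dplyr::bind_rows(ubi, sat_only)
  pairs <- enumerate_cis_pairs(probes, g$snp_map, spec$window)
  fdrs <- lapply(c("blood", "SAT", "liver"), function(ti) {
    e <- simulate_expression(g, spec, probes, effects, tissue = ti)
    suppressMessages(permutation_fdr(e, g, pairs, n_perm = 30, seed = 7,
                                     tissue = ti))
  })
  names(fdrs) <- c("blood", "SAT", "liver")
  tab <- compare_tissues(fdrs)

  for (pb in sat_only$probe_id) {
    row <- tab[tab$probe_id == pb, ]
    expect_identical(nrow(row), 1L)
    expect_identical(row$tissues[[1]], "SAT")
    expect_identical(row$class, "single_tissue")
  }
  for (pb in ubi$probe_id) {
    row <- tab[tab$probe_id == pb, ]
    expect_identical(row$class, "all_tissue")
  }

  # empty significant sets give an empty table
  null_f <- fdrs
  null_f$blood$units$significant <- FALSE
  null_f$SAT$units$significant <- FALSE
  null_f$liver$units$significant <- FALSE
  empty <- compare_tissues(null_f)
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(attr(empty, "venn")), 0L)
})
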