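# Normalization, PC correction, abundance comparison, control-probe
# selection.

named_matrix <- function(m) {
  dimnames(m) <- list(sprintf("p%03d", seq_len(nrow(m))),
                      sprintf("S%03d", seq_len(ncol(m))))
  m
}

test_that("quantile normalization equalizes column distributions and is idempotent", {
  m <- named_matrix(cbind(c(1, 2, 3), c(4, 5, 6)))
  q <- quantile_normalize(m)
  expect_equal(unname(sort(q[, 1])), c(2.5, 3.5, 4.5))
  expect_equal(unname(sort(q[, 2])), c(2.5, 3.5, 4.5))

  # already-identical columns are a fixed point
  m2 <- named_matrix(cbind(c(1, 5, 9), c(9, 1, 5)))
  q2 <- quantile_normalize(m2)
  expect_equal(unname(q2), unname(m2), ignore_attr = TRUE)

  # random matrix: all column distributions identical afterwards
  withr::local_seed(2)
  m3 <- named_matrix(matrix(rnorm(50 * 20), 50, 20))
  q3 <- quantile_normalize(m3)
  target <- sort(q3[, 1])
  for (j in 2:20) expect_equal(sort(q3[, j]), target, ignore_attr = TRUE)

  # idempotent within 1e-12
  expect_equal(quantile_normalize(q3), q3, tolerance = 1e-12)

  # constant column warning
  m4 <- named_matrix(cbind(c(1, 2, 3), c(7, 7, 7)))
  expect_warning(q4 <- quantile_normalize(m4), "identical")
  expect_equal(unname(q4[, 2]), rep(mean(sort(q4[, 1])), 3))

  # normalization state advances on the container
  spec <- small_spec(seed = 2)
  st <- simulate_study(spec)
  e <- suppressWarnings(quantile_normalize(st$expression$blood))
  expect_identical(e$normalization_state, "quantile")
})

test_that("log2 transform handles domains and offsets", {
  m <- named_matrix(matrix(c(8, 1, 2, 4, 16, 32), 2))
  expect_equal(unname(log2_transform(m)),
               unname(log2(m)), ignore_attr = TRUE)
  expect_equal(unname(log2_transform(named_matrix(matrix(c(2, 4, 16, 8), 2)))[1, 1]), 1)
  m_bad <- named_matrix(matrix(c(-1, 1, 2, 3), 2))
  expect_error(log2_transform(m_bad), class = "linceqtl_domain_error")
  expect_silent(log2_transform(m_bad, offset = 2))
})

test_that("principal-component removal is exact on constructed spectra and orthogonal", {
  # identity at k = 0
  withr::local_seed(5)
  m <- named_matrix(matrix(rnorm(200), 20, 10))
  expect_equal(remove_principal_components(m, 0), m, ignore_attr = TRUE)

  # rank-1 matrix, k = 1: residuals ~ 0
  u <- rnorm(20)
  v <- rnorm(10)
  r1 <- named_matrix(u %*% t(v))
  res1 <- remove_principal_components(r1, 1)
  expect_lt(max(abs(res1 - rowMeans(r1))) / max(abs(r1)), 1e-8)

  # constructed SVD: top-component variance share removed exactly
  qy <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  qv <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, -1] # _|_ 1
  d <- c(50, 8, 5, 3)
  M <- named_matrix(qy %*% diag(d) %*% t(qv))
  planted_share <- d[1]^2 / sum(d^2)
  res <- remove_principal_components(M, 1)
  resc <- res - rowMeans(res)
  Mc <- M - rowMeans(M)
  removed_share <- 1 - sum(resc^2) / sum(Mc^2)
  expect_equal(removed_share, planted_share, tolerance = 0.01)

  # residual orthogonal to the removed right singular vector
  sv <- svd(Mc)
  expect_lt(max(abs(resc %*% sv$v[, 1])), 1e-8)

  expect_error(remove_principal_components(m, 10),
               class = "linceqtl_param_error")
})

test_that("genetic-component protection retains dosage-driven structure", {
  spec <- small_spec(seed = 6)
  g <- simulate_genotypes(spec)
  withr::local_seed(7)
  snp <- g$dosage[, 10]
  m <- named_matrix(outer(rnorm(30, 1, 0.2), scale(snp)[, 1]) +
                      matrix(rnorm(30 * spec$n_samples, sd = 0.05), 30))
  colnames(m) <- rownames(g$dosage)
  protected <- suppressMessages(
    remove_principal_components(m, 1, protect_genetic = TRUE, geno = g))
  expect_equal(protected, m, ignore_attr = TRUE, tolerance = 1e-10)
  removed <- remove_principal_components(m, 1)
  expect_gt(max(abs(removed - m)), 0.1)
})

test_that("abundance comparison behaves at the null, under separation, and on generator truth", {
  withr::local_seed(8)
  base <- matrix(rnorm(20 * 30), 20, 30)
  m <- named_matrix(rbind(base, base))  # group B = relabelled copy of A
  a <- rownames(m)[1:20]
  b <- rownames(m)[21:40]
  out <- compare_abundance(m, a, b)
  expect_gt(out$p_mean, 0.9)
  expect_equal(out$mean_diff, 0)

  # pure shift: one-sided separation, near-minimal p for the group sizes
  m2 <- named_matrix(rbind(base, base + 1))
  out2 <- compare_abundance(m2, rownames(m2)[1:20], rownames(m2)[21:40])
  expect_lt(out2$p_mean, 1e-6)
  expect_equal(out2$mean_diff, -1)

  # generator truth: abundance_shift recovered within noise
  spec <- simulation_spec(n_samples = 100, n_snps = 100, n_probes = 200,
                          n_effects = 0, abundance_shift = 0.25, seed = 9)
  st <- simulate_study(spec)
  cls <- st$probes$transcript_class
  out3 <- compare_abundance(st$expression$blood$intensity,
                            st$probes$probe_id[cls == "protein_coding"],
                            st$probes$probe_id[cls == "lincRNA"])
  se <- spec$noise_sd / sqrt(sum(cls == "lincRNA") * spec$n_samples)
  expect_lt(abs(out3$mean_diff - 0.25), 6 * se + 0.01)

  expect_error(compare_abundance(m, a, a), class = "linceqtl_param_error")
  expect_error(compare_abundance(m, a[1], b),
               class = "linceqtl_insufficient_data_error")
})

test_that("matched-probe selection is exact on copies and near-optimal against enumeration", {
  # pool contains exact (mean, SD) copies of the reference probes
  withr::local_seed(10)
  ref_block <- matrix(rnorm(5 * 40, mean = rep(1:5, 40)), 5, 40)
  m <- named_matrix(rbind(ref_block, ref_block,
                          matrix(rnorm(10 * 40, mean = 20), 10, 40)))
  ref <- rownames(m)[1:5]
  pool <- rownames(m)[6:20]
  out <- select_matched_probes(ref, pool, m)
  expect_identical(nrow(out), 5L)
  expect_identical(anyDuplicated(out$matched), 0L)
  expect_equal(attr(out, "delta_center"), 0, tolerance = 1e-10)
  expect_equal(attr(out, "delta_spread"), 0, tolerance = 1e-10)

  # single reference probe takes its nearest pool neighbour
  m1 <- named_matrix(matrix(c(5, 5.2, 9, 1), 4, 10) +
                       matrix(rnorm(40, sd = 1e-3), 4, 10))
  out1 <- select_matched_probes(rownames(m1)[1], rownames(m1)[2:4], m1)
  expect_identical(out1$matched, rownames(m1)[2])

  # realistic pool 10x the reference: group mean delta within 0.05 units
  spec <- simulation_spec(n_samples = 60, n_snps = 50, n_probes = 220,
                          n_effects = 0, lincRNA_fraction = 0.09,
                          abundance_shift = 0, seed = 11)
  st <- simulate_study(spec)
  cls <- st$probes$transcript_class
  ref2 <- st$probes$probe_id[cls == "lincRNA"]
  pool2 <- st$probes$probe_id[cls == "protein_coding"]
  expect_gte(length(pool2), 10 * length(ref2))
  out2 <- select_matched_probes(ref2, pool2, st$expression$blood$intensity)
  expect_lt(abs(attr(out2, "delta_center")), 0.05)

  # tiny instance against the exhaustive optimal-assignment oracle
  withr::local_seed(12)
  mt <- named_matrix(matrix(rnorm(13 * 25, mean = rep(seq(0, 3, length.out = 13), 25)),
                            13, 25))
  ref3 <- rownames(mt)[1:5]
  pool3 <- rownames(mt)[6:13]
  out3 <- select_matched_probes(ref3, pool3, mt)
  rs <- linceqtl:::probe_stat(mt, ref3, "mean")
  ps <- linceqtl:::probe_stat(mt, pool3, "mean")
  sc <- sd(c(rs$center, ps$center))
  ss <- sd(c(rs$spread, ps$spread))
  opt <- bf_optimal_assignment(rs, ps, sc, ss)
  greedy_cost <- sum(out3$dist)
  expect_gte(greedy_cost, opt$cost - 1e-12)   # optimal is a lower bound
  expect_lt(greedy_cost, opt$cost + 2)        # and greedy stays close
  ms_opt <- linceqtl:::probe_stat(mt, ps$probe_id[opt$assign], "mean")
  delta_opt <- abs(mean(rs$center) - mean(ms_opt$center))
  expect_lt(abs(attr(out3, "delta_center")), max(0.05, delta_opt + 0.05))

  expect_error(select_matched_probes(ref3, pool3[1:2], mt),
               class = "linceqtl_matching_error")
  expect_error(select_matched_probes(ref3, c(ref3[1], pool3), mt),
               class = "linceqtl_param_error")
})

test_that("top-expressed selection is deterministic and matches a full sort", {
  m <- named_matrix(matrix(c(1, 1, 5, 5, 3, 3), 3, 2, byrow = TRUE))
  expect_identical(select_top_expressed(rownames(m), m, 2),
                   c("p002", "p003"))
  expect_identical(sort(select_top_expressed(rownames(m), m, 3)),
                   rownames(m))

  withr::local_seed(13)
  big <- matrix(rnorm(1e4 * 3), 1e4, 3)
  dimnames(big) <- list(sprintf("q%05d", seq_len(1e4)), c("a", "b", "c"))
  n <- 500
  got <- select_top_expressed(rownames(big), big, n)
  mu <- rowMeans(big)
  oracle <- names(sort(mu, decreasing = TRUE))[seq_len(n)]
  expect_identical(sort(got), sort(oracle))
  expect_error(select_top_expressed(rownames(m), m, 4),
               class = "linceqtl_param_error")
})
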