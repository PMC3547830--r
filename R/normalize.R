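# Expression normalization, covariate correction, abundance comparisons and
# control-probe selection.

#' Quantile-normalize sample columns
#'
#' Forces every sample column to the identical value multiset: the
#' across-sample mean of order statistics. Ties within a column receive the
#' mean of their target quantile values; probe and sample order are
#' preserved. Delegates to `limma::normalizeQuantiles(ties = TRUE)`, whose
#' behaviour matches this contract. Idempotent: applying it twice changes
#' nothing.
#'
#' @param x An [expression_matrix()] or bare probes-by-samples matrix.
#' @return Same container type, normalization state advanced to
#'   `"quantile"`. Columns with all-identical values collapse to the mean
#'   of the target vector, with a warning.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' rownames(m) <- paste0("p", 1:3)
#' quantile_normalize(m)
quantile_normalize <- function(x) {
  m <- as_intensity(x)
  const <- apply(m, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warn(sprintf("%d column(s) have all-identical values; they normalize to the target mean.",
                 sum(const)))
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  rewrap_expression(x, out, "quantile")
}

#' Log2-transform intensities
#'
#' @param x An [expression_matrix()] or matrix; values must be strictly
#'   positive after adding `offset`.
#' @param offset Constant added before taking logs (default 0).
#' @return Same container type, elementwise `log2(x + offset)`.
#' @export
log2_transform <- function(x, offset = 0) {
  m <- as_intensity(x) + offset
  if (any(m <= 0, na.rm = TRUE)) {
    linc_abort("Non-positive intensities; supply a positive `offset`.",
               "linceqtl_domain_error")
  }
  state <- if (inherits(x, "expression_matrix")) {
    paste0(x$normalization_state, "+log2")
  } else "log2"
  rewrap_expression(x, log2(m), state)
}

#' Remove leading principal components
#'
#' Subtracts the rank-`k` reconstruction of the row-centered matrix (SVD on
#' probes-by-samples), the usual correction for batch and global expression
#' structure before eQTL mapping. `k = 0` returns the input unchanged.
#' With `protect_genetic = TRUE` and a genotype matrix supplied, candidate
#' components whose sample scores correlate strongly with any SNP dosage
#' (max r-squared above `protect_r2`) are retained rather than removed, so
#' genetically driven expression structure survives the correction.
#'
#' @param x An [expression_matrix()] or matrix (should be normalized).
#' @param k Number of components to remove; must be `< min(dim(x))`.
#' @param protect_genetic Retain components associated with genotype?
#' @param geno A [genotype_matrix()], required when `protect_genetic`.
#' @param protect_r2 Max dosage r-squared above which a component is kept.
#' @return Same container type; residual matrix, state `"pc_corrected"`.
#' @export
remove_principal_components <- function(x, k, protect_genetic = FALSE,
                                        geno = NULL, protect_r2 = 0.1) {
  m <- as_intensity(x)
  if (!is_count(k + 1) || k < 0) {
    linc_abort("`k` must be a non-negative integer.", "linceqtl_param_error")
  }
  if (k >= min(dim(m))) {
    linc_abort("`k` must be smaller than both matrix dimensions.",
               "linceqtl_param_error")
  }
  if (k == 0) {
    return(rewrap_expression(x, m, "pc_corrected"))
  }
  mu <- rowMeans(m)
  mc <- m - mu
  sv <- svd(mc)
  drop_idx <- seq_len(k)
  if (protect_genetic) {
    if (is.null(geno)) {
      linc_abort("`protect_genetic` requires `geno`.", "linceqtl_param_error")
    }
    common <- intersect(colnames(m), rownames(geno$dosage))
    keep <- vapply(drop_idx, function(j) {
      scores <- sv$v[match(common, colnames(m)), j]
      r2 <- suppressWarnings(cor(scores, geno$dosage[common, ]))^2
      max(r2, na.rm = TRUE) > protect_r2
    }, logical(1))
    if (any(keep)) {
      inform(sprintf("Retaining %d genetically associated component(s).",
                     sum(keep)))
    }
    drop_idx <- drop_idx[!keep]
  }
  if (length(drop_idx) == 0L) {
    return(rewrap_expression(x, m, "pc_corrected"))
  }
  recon <- sv$u[, drop_idx, drop = FALSE] %*%
    (sv$d[drop_idx] * t(sv$v[, drop_idx, drop = FALSE]))
  out <- mc - recon + mu
  dimnames(out) <- dimnames(m)
  rewrap_expression(x, out, "pc_corrected")
}

#' Compare expression abundance between two probe sets
#'
#' Computes each probe's mean and variance across samples and contrasts the
#' two groups with two-sided Wilcoxon-Mann-Whitney tests (exact for small
#' groups without ties, normal approximation with tie correction
#' otherwise, as `stats::wilcox.test` provides).
#'
#' @param x An [expression_matrix()] or matrix.
#' @param group_a,group_b Disjoint character vectors of probe ids present
#'   in `x`, each of size >= 2.
#' @return One-row tibble: group sizes, per-group mean of probe means,
#'   their difference (`a - b`), W statistics and two-sided P values for
#'   the mean and variance comparisons.
#' @export
compare_abundance <- function(x, group_a, group_b) {
  m <- as_intensity(x)
  if (length(intersect(group_a, group_b))) {
    linc_abort("Probe groups must be disjoint.", "linceqtl_param_error")
  }
  miss <- setdiff(c(group_a, group_b), rownames(m))
  if (length(miss)) {
    linc_abort(sprintf("Probes not in the matrix: %s",
                       paste(head(miss, 5), collapse = ", ")),
               "linceqtl_param_error")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    linc_abort("Each group needs at least 2 probes.",
               "linceqtl_insufficient_data_error")
  }
  mean_a <- rowMeans(m[group_a, , drop = FALSE])
  mean_b <- rowMeans(m[group_b, , drop = FALSE])
  var_a <- apply(m[group_a, , drop = FALSE], 1L, var)
  var_b <- apply(m[group_b, , drop = FALSE], 1L, var)
  wm <- suppressWarnings(wilcox.test(mean_a, mean_b))
  wv <- suppressWarnings(wilcox.test(var_a, var_b))
  tibble(n_a = length(group_a), n_b = length(group_b),
         mean_a = mean(mean_a), mean_b = mean(mean_b),
         mean_diff = mean(mean_a) - mean(mean_b),
         w_mean = unname(wm$statistic), p_mean = wm$p.value,
         w_var = unname(wv$statistic), p_var = wv$p.value)
}

probe_stat <- function(m, ids, statistic) {
  sub <- m[ids, , drop = FALSE]
  ctr <- if (statistic == "median") {
    apply(sub, 1L, median)
  } else {
    rowMeans(sub)
  }
  tibble(probe_id = ids, center = unname(ctr),
         spread = apply(sub, 1L, sd))
}

#' Select expression-matched control probes
#'
#' Greedy without-replacement nearest-neighbour matching in standardized
#' (probe mean, probe SD) space: reference probes are processed in
#' probe-id order and each takes its closest still-unused pool probe. Used
#' to build a protein-coding control set with the same intensity
#' distribution as the lincRNA probes, isolating abundance effects on
#' eQTL detectability.
#'
#' @param reference Character vector of reference probe ids.
#' @param pool Character vector of candidate probe ids, disjoint from
#'   `reference`, with `length(pool) >= length(reference)`.
#' @param x An [expression_matrix()] or matrix containing all probes.
#' @param statistic `"mean"` (default) or `"median"` as the location
#'   statistic being matched alongside the SD.
#' @return Tibble (`reference`, `matched`, `dist`), one matched pool probe
#'   per reference probe, with attributes `delta_center` and
#'   `delta_spread`: group-level differences (reference - matched) of the
#'   location statistic and SD after matching.
#' @export
select_matched_probes <- function(reference, pool, x,
                                  statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  m <- as_intensity(x)
  if (length(intersect(reference, pool))) {
    linc_abort("`pool` must be disjoint from `reference`.",
               "linceqtl_param_error")
  }
  if (length(pool) < length(reference)) {
    linc_abort("Pool smaller than reference set; matching infeasible.",
               "linceqtl_matching_error")
  }
  rs <- probe_stat(m, reference, statistic)
  ps <- probe_stat(m, pool, statistic)
  sc <- sd(c(rs$center, ps$center))
  ss <- sd(c(rs$spread, ps$spread))
  sc <- if (is.na(sc) || sc == 0) 1 else sc
  ss <- if (is.na(ss) || ss == 0) 1 else ss
  ord <- order(rs$probe_id)
  avail <- rep(TRUE, nrow(ps))
  matched <- character(nrow(rs))
  dist <- numeric(nrow(rs))
  for (i in ord) {
    d2 <- ((rs$center[i] - ps$center) / sc)^2 +
      ((rs$spread[i] - ps$spread) / ss)^2
    d2[!avail] <- Inf
    j <- which.min(d2)
    avail[j] <- FALSE
    matched[i] <- ps$probe_id[j]
    dist[i] <- sqrt(d2[j])
  }
  out <- tibble(reference = rs$probe_id, matched = matched, dist = dist)
  ms <- probe_stat(m, matched, statistic)
  attr(out, "delta_center") <- mean(rs$center) - mean(ms$center)
  attr(out, "delta_spread") <- mean(rs$spread) - mean(ms$spread)
  out
}

#' Select the most abundantly expressed probes
#'
#' Top `n` probes of `pool` by per-probe mean intensity; ties broken by
#' probe id (lexicographic), fully deterministic.
#'
#' @param pool Character vector of candidate probe ids.
#' @param x An [expression_matrix()] or matrix.
#' @param n Number of probes to select (`n <= length(pool)`).
#' @return Character vector of `n` probe ids, most abundant first.
#' @export
select_top_expressed <- function(pool, x, n) {
  m <- as_intensity(x)
  if (n > length(pool)) {
    linc_abort("`n` exceeds the pool size.", "linceqtl_param_error")
  }
  mu <- rowMeans(m[pool, , drop = FALSE])
  pool[order(-mu, pool)][seq_len(n)]
}
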