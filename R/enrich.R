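# Regulatory-region enrichment of eQTL SNP sets: interval membership,
# fold enrichment against the panel background, and significance from a
# normal fit to log-transformed permutation enrichment scores.

#' SNP membership in an annotation track
#'
#' A SNP is in-track iff its position lies inside at least one interval
#' (0-based half-open: the interval start is in, the end is out).
#'
#' @param snp_map Tibble with `snp_id`, `chrom`, `pos` (0-based).
#' @param track Tibble of intervals (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()]; intervals may overlap.
#' @return Tibble (`snp_id`, `in_track`).
#' @export
snp_track_overlap <- function(snp_map, track) {
  snp_map <- as_tibble(snp_map)
  pts <- tibble(chrom = snp_map$chrom, start = snp_map$pos,
                end = snp_map$pos + 1)
  hit <- overlaps_by_chrom(pts, as_tibble(track))
  in_track <- rep(FALSE, nrow(snp_map))
  in_track[unique(hit$q_idx)] <- TRUE
  tibble(snp_id = snp_map$snp_id, in_track = in_track)
}

#' Fold enrichment of query SNP sets in a track
#'
#' `fold = (fraction of query sets hitting the track) / (fraction of
#' background SNPs in the track)`. A query set (an index SNP plus its
#' perfect proxies) hits when any of its members is in-track — one hit per
#' set, so linked proxies are not double-counted. The background is the
#' analysis SNP panel.
#'
#' @param query_sets List of character vectors of SNP ids (or a single
#'   character vector, treated as one-singleton-per-SNP sets).
#' @param snp_map Background SNP panel (`snp_id`, `chrom`, `pos`).
#' @param track Interval tibble.
#' @return One-row tibble: `fold`, `n_query`, `n_query_in_track`,
#'   `background_fraction`. Empty track gives fold 0 with a warning; an
#'   empty background fraction with in-track queries is the undefined
#'   sentinel `NA`.
#' @export
fold_enrichment <- function(query_sets, snp_map, track) {
  if (is.character(query_sets)) query_sets <- as.list(query_sets)
  if (length(query_sets) == 0L) {
    linc_abort("`query_sets` is empty.", "linceqtl_param_error")
  }
  track <- as_tibble(track)
  memb <- snp_track_overlap(snp_map, track)
  if (nrow(track) == 0L || sum(memb$in_track) == 0L) {
    if (nrow(track) == 0L) warn("Empty track: fold enrichment 0.")
    bg <- mean(memb$in_track)
  } else {
    bg <- mean(memb$in_track)
  }
  in_ids <- memb$snp_id[memb$in_track]
  hits <- vapply(query_sets, function(s) any(s %in% in_ids), logical(1))
  qf <- mean(hits)
  fold <- if (bg == 0) {
    if (qf == 0) NA_real_ else NA_real_  # undefined against empty background
  } else {
    qf / bg
  }
  if (nrow(track) == 0L) fold <- 0
  tibble(fold = fold, n_query = length(query_sets),
         n_query_in_track = sum(hits), background_fraction = bg)
}

# upper-tail p of log(fold) under a normal fitted by maximum likelihood to
# the log null folds; zero null folds are replaced by half the smallest
# positive fold before the log (recorded in the result).
enrichment_p <- function(observed_fold, null_folds) {
  zeros <- null_folds == 0
  replaced <- any(zeros)
  if (all(zeros)) {
    return(list(p = NA_real_, mean = NA_real_, sd = NA_real_,
                zero_replaced = TRUE))
  }
  if (replaced) {
    null_folds[zeros] <- min(null_folds[!zeros]) / 2
  }
  lf <- log(null_folds)
  mu <- mean(lf)
  sd_ml <- sqrt(mean((lf - mu)^2))
  if (sd_ml == 0) {
    return(list(p = NA_real_, mean = mu, sd = sd_ml, zero_replaced = replaced))
  }
  obs <- if (observed_fold <= 0) -Inf else log(observed_fold)
  list(p = pnorm(obs, mean = mu, sd = sd_ml, lower.tail = FALSE),
       mean = mu, sd = sd_ml, zero_replaced = replaced)
}

#' Permutation significance of regulatory enrichment
#'
#' Computes the observed fold enrichment of the top-`n_top` eQTL probes'
#' top SNPs (expanded by their perfect proxies, r-squared = 1) in a track,
#' then repeats the whole selection under `n_perm` permutations of the
#' expression sample labels: re-map associations, take the top `n_top`
#' probes by minimum p, their top SNPs and perfect proxies, and the fold
#' for each permuted set. One-sided significance is the upper-tail
#' probability of the log observed fold under a normal distribution fitted
#' to the `n_perm` log-transformed permutation enrichment scores.
#'
#' @inheritParams map_cis_eqtls
#' @param track Interval tibble (one annotation/cell-type track).
#' @param n_top Number of top probes whose eQTL SNPs form the query.
#' @param n_perm Number of permutations (the reference analysis used 100).
#' @param seed Master seed (per-permutation seeds derived by counter).
#' @param max_distance Perfect-proxy search radius in bp.
#' @param track_name Label carried into the result.
#' @return A `linc_enrichment` object: observed fold and query counts,
#'   null log-mean/SD, one-sided p, the vector of null folds and the
#'   observed fold's position among them (`rank_below` = permutations with
#'   a strictly smaller fold, `rank_ties` = equal folds). `NA` p with all
#'   null folds zero is the not-estimable sentinel.
#' @export
permutation_enrichment_significance <- function(expr, geno, pairs, track,
                                                n_top, n_perm = 100,
                                                seed = 1, max_distance = 500000,
                                                min_n = 30,
                                                min_genotype_count = 3,
                                                track_name = "track") {
  eng <- eqtl_engine(expr, geno, pairs, min_n, min_genotype_count)
  if (eng$has_na) {
    linc_abort("Enrichment permutation requires complete data.",
               "linceqtl_param_error")
  }
  ok <- eng$pair_ok
  pr <- eng$pairs[ok, , drop = FALSE]
  if (nrow(pr) == 0L) {
    linc_abort("No testable pairs.", "linceqtl_pipeline_error")
  }
  proxy_cache <- new.env(parent = emptyenv())
  proxies_of <- function(sid) {
    if (is.null(proxy_cache[[sid]])) {
      proxy_cache[[sid]] <- suppressWarnings(
        find_proxies(sid, geno, mode = "perfect",
                     max_distance = max_distance)$snp_id)
      if (length(proxy_cache[[sid]]) == 0L) proxy_cache[[sid]] <- sid
    }
    proxy_cache[[sid]]
  }
  groups <- split(seq_len(nrow(pr)), pr$probe_id)
  query_sets_for <- function(p, rho) {
    minp <- vapply(groups, function(ix) min(p[ix]), numeric(1))
    top_probes <- names(sort(minp))[seq_len(min(n_top, length(minp)))]
    lapply(top_probes, function(pb) {
      ix <- groups[[pb]]
      o <- ix[order(p[ix], -abs(rho[ix]), pr$pos[ix], pr$snp_id[ix])][1L]
      proxies_of(pr$snp_id[o])
    })
  }
  st <- pair_stats(eng)
  obs_sets <- query_sets_for(st$p[ok], st$rho[ok])
  obs <- fold_enrichment(obs_sets, geno$snp_map, track)

  null_folds <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    withr::local_seed(derive_seed(seed, paste0("enrich-perm:", b)))
    perm <- sample.int(eng$n)
    stb <- pair_stats(eng, perm)
    sets <- query_sets_for(stb$p[ok], stb$rho[ok])
    fb <- fold_enrichment(sets, geno$snp_map, track)$fold
    null_folds[b] <- ifelse(is.na(fb), 0, fb)
  }
  fit <- enrichment_p(obs$fold, null_folds)
  structure(list(
    track = track_name, fold = obs$fold, n_query = obs$n_query,
    n_query_in_track = obs$n_query_in_track,
    background_fraction = obs$background_fraction,
    null_log_mean = fit$mean, null_log_sd = fit$sd,
    p_one_sided = fit$p, zero_replaced = fit$zero_replaced,
    null_folds = null_folds,
    rank_below = sum(null_folds < obs$fold),
    rank_ties = sum(null_folds == obs$fold),
    n_perm = n_perm, n_top = n_top, seed = seed), class = "linc_enrichment")
}

#' @export
print.linc_enrichment <- function(x, ...) {
  cat(sprintf(paste0(
    "<linc_enrichment> %s: fold = %.3g (%d/%d query sets in track, ",
    "background %.3g)\n  null log-mean %.3g, log-SD %.3g; one-sided p = %.4g\n"),
    x$track, x$fold, x$n_query_in_track, x$n_query, x$background_fraction,
    x$null_log_mean, x$null_log_sd, x$p_one_sided))
  invisible(x)
}

#' @export
tidy.linc_enrichment <- function(x, ...) {
  tibble(permutation = seq_along(x$null_folds), fold = x$null_folds)
}

#' @export
glance.linc_enrichment <- function(x, ...) {
  tibble(track = x$track, fold = x$fold, n_query = x$n_query,
         n_query_in_track = x$n_query_in_track,
         background_fraction = x$background_fraction,
         null_log_mean = x$null_log_mean, null_log_sd = x$null_log_sd,
         p_one_sided = x$p_one_sided, n_perm = x$n_perm, n_top = x$n_top)
}
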