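# Pairwise LD from dosages, proxy-SNP search, and GWAS-catalog
# intersection of eQTL SNPs.

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors after pairwise
#' deletion of missing entries — the composite (genotypic) LD measure
#' appropriate for unphased genotypes. Symmetric in its arguments.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` (undefined-LD sentinel, with a
#'   warning) when either vector is monomorphic after deletion.
#' @export
#' @examples
#' ld_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) {
    linc_abort("Dosage vectors must have equal length.", "linceqtl_param_error")
  }
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[keep]
  b <- dosage_b[keep]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    warn("Monomorphic input: LD undefined.")
    return(NA_real_)
  }
  cor(a, b)^2
}

#' Find LD proxies of an index SNP
#'
#' Scans SNPs within `max_distance` bp of the index SNP and keeps those
#' whose composite r-squared with the index reaches the threshold. Two
#' modes: `"threshold"` (default cut 0.8; boundary inclusion controlled by
#' `strict`, default inclusive) and `"perfect"` (r-squared equal to 1
#' within 1e-12). The index SNP is always part of its own proxy set with
#' r-squared 1.
#'
#' @param index_snp SNP id present in `geno`.
#' @param geno A [genotype_matrix()].
#' @param threshold r-squared cut for `mode = "threshold"`.
#' @param max_distance Search radius in bp.
#' @param mode `"threshold"` or `"perfect"`.
#' @param strict If `TRUE`, require r-squared strictly above `threshold`.
#' @return Tibble (`index_snp`, `snp_id`, `r2`), the proxy set; empty with
#'   a warning when the index SNP is monomorphic.
#' @export
find_proxies <- function(index_snp, geno, threshold = 0.8,
                         max_distance = 500000,
                         mode = c("threshold", "perfect"), strict = FALSE) {
  mode <- match.arg(mode)
  map <- geno$snp_map
  i <- match(index_snp, map$snp_id)
  if (is.na(i)) {
    linc_abort(sprintf("Index SNP '%s' not in the panel.", index_snp),
               "linceqtl_param_error")
  }
  x <- geno$dosage[, index_snp]
  if (length(unique(x[!is.na(x)])) < 2L) {
    warn(sprintf("Index SNP '%s' is monomorphic; empty proxy set.", index_snp))
    return(tibble(index_snp = character(0), snp_id = character(0),
                  r2 = double(0)))
  }
  cand <- which(map$chrom == map$chrom[i] &
                  abs(map$pos - map$pos[i]) <= max_distance)
  r2 <- suppressWarnings(
    as.vector(cor(x, geno$dosage[, cand, drop = FALSE],
                  use = "pairwise.complete.obs"))^2)
  r2[cand == i] <- 1
  keep <- if (mode == "perfect") {
    !is.na(r2) & r2 >= 1 - 1e-12
  } else if (strict) {
    !is.na(r2) & r2 > threshold
  } else {
    !is.na(r2) & r2 >= threshold
  }
  keep[cand == i] <- TRUE
  tibble(index_snp = index_snp,
         snp_id = map$snp_id[cand[keep]],
         r2 = r2[keep])
}

#' Intersect top eQTL SNPs (plus LD proxies) with a GWAS catalog
#'
#' For each top eQTL SNP, expands to its proxy set at `r2_threshold` and
#' reports one row per (eQTL SNP, GWAS hit) where the trait-associated SNP
#' is the eQTL SNP itself or one of its proxies. The catalog is filtered
#' to reported P below `gwas_p_threshold` first. Catalog SNPs absent from
#' the genotype panel can only match by identity (logged). When coding
#' eQTL records and a significance threshold are supplied, each row is
#' flagged for whether the eQTL SNP also affects any protein-coding probe.
#'
#' @param top_records Top eQTL records (one per probe, e.g.
#'   [top_eqtl_per_probe()] output; must carry `probe_id`, `snp_id`, `p`
#'   and optionally `tissue`).
#' @param geno A [genotype_matrix()] serving as the LD reference panel.
#' @param catalog GWAS catalog tibble (`snp_id`, `trait`, `p_reported`,
#'   optionally `source_version`).
#' @param r2_threshold Proxy r-squared cut.
#' @param gwas_p_threshold Catalog inclusion threshold on reported P
#'   (strictly below).
#' @param max_distance Proxy search radius in bp.
#' @param strict Boundary handling of the r-squared cut, see
#'   [find_proxies()].
#' @param coding_records,p_threshold Optional protein-coding eQTL records
#'   and the shared significance threshold for the `affects_coding` flag.
#' @return Trait-eQTL tibble: `snp_id` (eQTL), `eqtl_p`, `probe_id`,
#'   `tissue`, `proxy_snp`, `r2`, `trait`, `gwas_p`, `affects_coding`;
#'   attribute `source_version` when the catalog carries one.
#' @export
intersect_gwas <- function(top_records, geno, catalog, r2_threshold = 0.8,
                           gwas_p_threshold = 9.9e-6, max_distance = 500000,
                           strict = FALSE, coding_records = NULL,
                           p_threshold = NULL) {
  catalog <- filter(as_tibble(catalog), .data$p_reported < gwas_p_threshold)
  absent <- setdiff(unique(catalog$snp_id), geno$snp_map$snp_id)
  if (length(absent)) {
    inform(sprintf("%d catalog SNP(s) absent from the genotype panel; matched by identity only.",
                   length(absent)))
  }
  coding_snps <- if (!is.null(coding_records) && !is.null(p_threshold)) {
    unique(coding_records$snp_id[coding_records$p <= p_threshold])
  }
  rows <- pmap(list(top_records$snp_id, top_records$p,
                    top_records$probe_id,
                    top_records$tissue %||% rep(NA_character_, nrow(top_records))),
               function(sid, pp, pid, tis) {
    if (sid %in% geno$snp_map$snp_id) {
      prox <- suppressWarnings(
        find_proxies(sid, geno, threshold = r2_threshold,
                     max_distance = max_distance, strict = strict))
    } else {
      prox <- tibble(index_snp = sid, snp_id = sid, r2 = 1)
    }
    hit <- inner_join(prox, catalog, by = "snp_id")
    if (nrow(hit) == 0L) return(NULL)
    tibble(snp_id = sid, eqtl_p = pp, probe_id = pid, tissue = tis,
           proxy_snp = hit$snp_id, r2 = hit$r2, trait = hit$trait,
           gwas_p = hit$p_reported,
           affects_coding = if (is.null(coding_snps)) NA else sid %in% coding_snps)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(snp_id = character(0), eqtl_p = double(0),
                  probe_id = character(0), tissue = character(0),
                  proxy_snp = character(0), r2 = double(0),
                  trait = character(0), gwas_p = double(0),
                  affects_coding = logical(0))
  }
  if ("source_version" %in% names(catalog) && nrow(catalog)) {
    attr(out, "source_version") <- catalog$source_version[1]
  }
  out
}
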