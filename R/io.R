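# Plain-text readers/writers for the pipeline's external formats.
#
# Conventions: genotype TSV has SNPs in rows and samples in columns; the SNP
# map TSV carries 1-based positions (converted to the package-internal
# 0-based convention on read); BED files are native 0-based half-open;
# expression TSV has probes in rows; the expression writer keeps the
# normalization state in a JSON sidecar next to the matrix.

#' Read/write a genotype matrix
#'
#' @param genotype_path TSV with column `snp_id` then one column per sample,
#'   values 0/1/2.
#' @param map_path TSV with `snp_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, optionally `maf`, `block`.
#' @return A [genotype_matrix()] (positions 0-based internally).
#' @export
read_genotype_matrix <- function(genotype_path, map_path) {
  g <- readr::read_tsv(genotype_path, show_col_types = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE)
  d <- t(as.matrix(g[, -1, drop = FALSE]))
  colnames(d) <- g$snp_id
  storage.mode(d) <- "integer"
  map$pos <- as.double(map$pos) - 1
  genotype_matrix(d, map)
}

#' @rdname read_genotype_matrix
#' @param geno A [genotype_matrix()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return (writer) Invisibly, the two paths written.
#' @export
write_genotype_matrix <- function(geno, dir, prefix = "genotypes") {
  gp <- file.path(dir, paste0(prefix, ".tsv"))
  mp <- file.path(dir, paste0(prefix, "_map.tsv"))
  gt <- as_tibble(t(geno$dosage))
  gt <- bind_cols(tibble(snp_id = colnames(geno$dosage)), gt)
  readr::write_tsv(gt, gp)
  map <- geno$snp_map
  map$pos <- map$pos + 1
  readr::write_tsv(map, mp)
  invisible(c(gp, mp))
}

#' Read/write an expression matrix with its probe map
#'
#' The writer stores the normalization state in `<path>.meta.json`; the
#' reader restores it (state `"raw"` when the sidecar is absent).
#'
#' @param path Expression TSV: column `probe_id` then one column per sample.
#' @param probe_map_path TSV with `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `center`, `transcript_class`,
#'   `gene_id`.
#' @param tissue Optional tissue label attached to the container.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, probe_map_path, tissue = NULL) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  probes <- readr::read_tsv(probe_map_path, show_col_types = FALSE)
  m <- as.matrix(e[, -1, drop = FALSE])
  rownames(m) <- e$probe_id
  meta_path <- paste0(path, ".meta.json")
  state <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$normalization_state
  } else "raw"
  expression_matrix(m, probes, normalization_state = state, tissue = tissue)
}

#' @rdname read_expression_matrix
#' @param x An [expression_matrix()].
#' @export
write_expression_matrix <- function(x, path) {
  m <- as_tibble(x$intensity)
  m <- bind_cols(tibble(probe_id = rownames(x$intensity)), m)
  readr::write_tsv(m, path)
  jsonlite::write_json(list(normalization_state = x$normalization_state),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read/write BED interval files
#'
#' Minimal BED support (3-6 columns, 0-based half-open, tab-separated,
#' no header), as used for annotation tracks and the lincRNA catalog.
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(x) <- cols[seq_len(ncol(x))]
  as_tibble(x)
}

#' @rdname read_bed
#' @param intervals Tibble with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a lincRNA catalog stored as exon-level BED
#'
#' One exon per line; the BED name field holds `transcript_id;gene_id`.
#'
#' @param path BED file.
#' @return Tibble: `transcript_id`, `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (one row per exon).
#' @export
read_lincrna_catalog <- function(path) {
  b <- read_bed(path)
  parts <- strsplit(b$name, ";", fixed = TRUE)
  tibble(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    chrom = b$chrom,
    strand = if ("strand" %in% names(b)) b$strand else "+",
    start = b$start, end = b$end)
}

#' Read a GWAS-catalog table
#'
#' @param path TSV with `snp_id`, `trait`, `p_reported` and optionally
#'   `source_version`.
#' @return Tibble of the catalog.
#' @export
read_gwas_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

# exon-level catalog rows for the synthetic lincRNA probes: exon 1 extends
# the probe interval, exon 2 sits 2 kb downstream, plus unprobed filler
# transcripts so the catalog is a superset of what the probes cover.
build_synthetic_catalog <- function(spec, probes) {
  linc <- probes[probes$transcript_class == "lincRNA", ]
  mk <- function(i, s, e, tid, gid, strand) {
    tibble(transcript_id = tid, gene_id = gid, chrom = "chr1",
           strand = strand,
           start = c(max(0, s - 100), e + 2000),
           end = c(e + 100, e + 2300))
  }
  rows <- pmap(list(seq_len(nrow(linc)), linc$start, linc$end,
                    sprintf("TCONS_%04d", seq_len(nrow(linc))),
                    linc$gene_id,
                    rep_len(c("+", "-"), nrow(linc))), mk)
  n_extra <- max(1L, ceiling(nrow(linc) / 5))
  starts <- round(seq(1000, spec$genome_size - 5000, length.out = n_extra))
  extra <- pmap(list(seq_len(n_extra), starts, starts + 400,
                     sprintf("TCONS_X%03d", seq_len(n_extra)),
                     sprintf("XLOC_X%03d", seq_len(n_extra)),
                     rep_len(c("+", "-"), n_extra)), mk)
  bind_rows(bind_rows(rows), bind_rows(extra))
}

# gene models for the synthetic protein-coding probes (two exons, alternate
# strands) used by classify_snp_location in the fixture pipeline.
build_synthetic_gene_models <- function(probes) {
  coding <- probes[probes$transcript_class == "protein_coding", ]
  n <- nrow(coding)
  strand <- rep_len(c("+", "-"), n)
  rows <- pmap(list(coding$start, coding$end, coding$gene_id, strand,
                    seq_len(n)), function(s, e, gid, st, i) {
    tibble(transcript_id = sprintf("TX_%04d", i), gene_id = gid,
           chrom = "chr1", strand = st,
           start = c(max(0, s - 50), e + 1500),
           end = c(e + 50, e + 1800))
  })
  bind_rows(rows)
}

catalog_to_bed <- function(catalog) {
  tibble(chrom = catalog$chrom, start = catalog$start, end = catalog$end,
         name = paste(catalog$transcript_id, catalog$gene_id, sep = ";"),
         score = 0L, strand = catalog$strand)
}

#' Write a complete synthetic fixture suite
#'
#' Generates one full study from `spec` and writes every file the pipeline
#' reads: genotype TSV + SNP map, one expression TSV (+ state sidecar) per
#' tissue, probe map, lincRNA catalog BED, protein-coding gene-model BED,
#' GWAS-catalog TSV (trait rows constructed on planted eQTL SNPs so the
#' intersection stage has known truth), one enhancer BED per synthetic cell
#' type, the planted-effect truth table and a manifest. Re-running with the
#' same spec (same seed) reproduces every file byte for byte.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Writable output directory (created if missing).
#' @param n_trait_snps Number of GWAS rows passing the catalog threshold;
#'   drawn from the planted eQTL SNPs.
#' @param n_gwas_background Extra catalog rows with reported P above the
#'   intersection threshold.
#' @param cell_types Names of the synthetic enhancer tracks.
#' @param n_enhancers,enhancer_width Number and mean width of enhancer
#'   intervals per track.
#' @return Manifest tibble (`file`, `n_rows`, `seed`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
make_fixture_suite <- function(spec, outdir, n_trait_snps = 12,
                               n_gwas_background = 20,
                               cell_types = c("K562", "GM12878"),
                               n_enhancers = 100, enhancer_width = 1000) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) linc_abort(sprintf("Cannot create '%s'.", outdir),
                        "linceqtl_io_error")
  }
  study <- simulate_study(spec)
  withr::local_seed(derive_seed(spec$seed, "fixtures"))

  paths <- character(0)
  rows <- integer(0)
  note <- function(p, n) {
    paths <<- c(paths, basename(p))
    rows <<- c(rows, as.integer(n))
  }

  gp <- write_genotype_matrix(study$geno, outdir)
  note(gp[1], spec$n_snps)
  note(gp[2], spec$n_snps)

  readr::write_tsv(study$probes, file.path(outdir, "probe_map.tsv"))
  note("probe_map.tsv", nrow(study$probes))

  for (ti in names(study$expression)) {
    p <- file.path(outdir, sprintf("expression_%s.tsv", ti))
    write_expression_matrix(study$expression[[ti]], p)
    note(p, spec$n_probes)
  }

  catalog <- build_synthetic_catalog(spec, study$probes)
  write_bed(catalog_to_bed(catalog), file.path(outdir, "lincrna_catalog.bed"))
  note("lincrna_catalog.bed", nrow(catalog))

  models <- build_synthetic_gene_models(study$probes)
  write_bed(catalog_to_bed(models), file.path(outdir, "coding_genes.bed"))
  note("coding_genes.bed", nrow(models))

  eff_snps <- unique(study$effects$snp_id)
  k <- min(n_trait_snps, length(eff_snps))
  trait_snps <- sort(sample(eff_snps, k))
  traits <- c("Mean platelet volume", "Body mass index", "Type 2 diabetes",
              "Coronary heart disease", "Parkinson's disease",
              "Thyroid volume", "Alcohol consumption", "Crohn's disease")
  other <- setdiff(study$geno$snp_map$snp_id, eff_snps)
  bg <- sort(sample(other, min(n_gwas_background, length(other))))
  gwas <- bind_rows(
    tibble(snp_id = trait_snps,
           trait = sample(traits, k, replace = TRUE),
           p_reported = 10^-runif(k, 8, 20)),
    tibble(snp_id = bg,
           trait = sample(traits, length(bg), replace = TRUE),
           p_reported = 10^-runif(length(bg), 1, 4.9)))
  gwas$source_version <- "synthetic-catalog-v1"
  readr::write_tsv(gwas, file.path(outdir, "gwas_catalog.tsv"))
  note("gwas_catalog.tsv", nrow(gwas))

  for (ct in cell_types) {
    starts <- sort(sample.int(spec$genome_size - 2 * enhancer_width,
                              n_enhancers))
    widths <- pmax(100, round(runif(n_enhancers, 0.5, 1.5) * enhancer_width))
    bed <- tibble(chrom = "chr1", start = as.double(starts),
                  end = as.double(starts + widths),
                  name = sprintf("enh_%s_%03d", ct, seq_len(n_enhancers)),
                  score = 0L, strand = ".")
    write_bed(bed, file.path(outdir, sprintf("enhancers_%s.bed", ct)))
    note(sprintf("enhancers_%s.bed", ct), n_enhancers)
  }

  truth <- study$effects
  truth$tissues_active <- vapply(truth$tissues_active, function(ta) {
    if (is.null(ta)) "" else paste(ta, collapse = ",")
  }, character(1))
  readr::write_tsv(truth, file.path(outdir, "effects_truth.tsv"))
  note("effects_truth.tsv", nrow(truth))

  manifest <- tibble(file = paths, n_rows = rows, seed = spec$seed)
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}
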