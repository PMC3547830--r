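#' Genotype dosage container
#'
#' Bundles a samples-by-SNPs dosage matrix (values 0/1/2, the count of the
#' alternate allele) with its SNP map. All genomic positions held internally
#' are 0-based; the on-disk SNP map uses 1-based positions and is converted
#' by [read_genotype_matrix()].
#'
#' @param dosage Integer matrix, samples in rows (named), SNPs in columns
#'   (named), values in `{0, 1, 2}` (or `NA`).
#' @param snp_map Tibble with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt` and optionally `maf`, `block`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `snp_map`.
#' @export
genotype_matrix <- function(dosage, snp_map) {
  if (!is.matrix(dosage)) {
    linc_abort("`dosage` must be a matrix (samples x SNPs).", "linceqtl_param_error")
  }
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    linc_abort("`dosage` must have sample row names and SNP column names.",
               "linceqtl_param_error")
  }
  snp_map <- as_tibble(snp_map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snp_map))) {
    linc_abort("`snp_map` must have columns snp_id, chrom, pos.",
               "linceqtl_param_error")
  }
  if (!setequal(colnames(dosage), snp_map$snp_id)) {
    linc_abort("SNP ids in `dosage` and `snp_map` disagree.", "linceqtl_param_error")
  }
  snp_map <- snp_map[match(colnames(dosage), snp_map$snp_id), , drop = FALSE]
  structure(list(dosage = dosage, snp_map = snp_map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs on %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$snp_map$chrom), collapse = ", ")))
  invisible(x)
}

#' Expression intensity container
#'
#' A probes-by-samples intensity matrix with its probe map and a
#' normalization-state tag. The state starts at `"raw"` and is advanced by
#' [quantile_normalize()], [log2_transform()] and
#' [remove_principal_components()].
#'
#' @param intensity Numeric matrix, probes in rows (named), samples in
#'   columns (named).
#' @param probes Tibble with at least `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open alignment interval); `center` and
#'   `transcript_class` are added/kept when present.
#' @param normalization_state Character scalar describing processing so far.
#' @param tissue Optional tissue label carried into eQTL records.
#' @param truth Optional planted-effect truth table (synthetic data only).
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensity, probes,
                              normalization_state = "raw",
                              tissue = NULL, truth = NULL) {
  if (!is.matrix(intensity) || is.null(rownames(intensity)) ||
      is.null(colnames(intensity))) {
    linc_abort("`intensity` must be a named matrix (probes x samples).",
               "linceqtl_param_error")
  }
  probes <- add_probe_centers(as_tibble(probes))
  if (!setequal(rownames(intensity), probes$probe_id)) {
    linc_abort("Probe ids in `intensity` and `probes` disagree.",
               "linceqtl_param_error")
  }
  probes <- probes[match(rownames(intensity), probes$probe_id), , drop = FALSE]
  structure(list(intensity = intensity, probes = probes,
                 normalization_state = normalization_state,
                 tissue = tissue, truth = truth),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples [%s]%s\n",
              nrow(x$intensity), ncol(x$intensity), x$normalization_state,
              if (is.null(x$tissue)) "" else paste0(" tissue=", x$tissue)))
  invisible(x)
}

# Accept either an expression_matrix or a bare matrix.
as_intensity <- function(x) {
  if (inherits(x, "expression_matrix")) x$intensity else as.matrix(x)
}

# Rebuild the same container type around a transformed matrix.
rewrap_expression <- function(x, m, state) {
  if (inherits(x, "expression_matrix")) {
    x$intensity <- m
    x$normalization_state <- state
    x
  } else {
    attr(m, "normalization_state") <- state
    m
  }
}
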