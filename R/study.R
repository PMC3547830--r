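# End-to-end study orchestration: annotation -> normalization -> per-tissue
# eQTL mapping with permutation FDR -> replication -> specificity ->
# GWAS intersection -> regulatory enrichment, with a JSON summary and a
# plain-text log of every seed and threshold.

#' Configure an end-to-end eQTL study
#'
#' Collects input paths and analysis constants. The defaults are the
#' reference analysis constants: 250 kb cis window, FDR 0.05 from 100
#' permutations at the probe level, proxies at r-squared >= 0.8, GWAS
#' catalog filter at reported P < 9.9e-6, TSS window 5 kb.
#'
#' @param genotypes,snp_map,probe_map,catalog Paths: genotype TSV, SNP map
#'   TSV (1-based positions), probe map TSV, lincRNA catalog BED.
#' @param expression Named character vector/list of expression TSV paths,
#'   one per tissue; the first is the discovery tissue.
#' @param coding_genes Optional protein-coding gene-model BED (enables SNP
#'   location classification).
#' @param gwas Optional GWAS catalog TSV.
#' @param tracks Optional named vector/list of annotation-track BED paths.
#' @param replication Optional list with `expression`, `genotypes`,
#'   `snp_map` paths for the replication cohort.
#' @param window,fdr_level,n_perm,unit,r2_proxy,strict_r2,gwas_p,tss_window
#'   Analysis constants (see the mapping and intersection functions).
#' @param min_n,min_genotype_count Testability rules.
#' @param n_top Query size for enrichment; defaults to the number of
#'   significant discovery probes.
#' @param quantile_normalize Apply [quantile_normalize()] to each tissue?
#' @param remove_pcs Number of principal components to remove (default 0).
#' @param seed Master seed for permutations.
#' @return A validated `study_config` list.
#' @export
study_config <- function(genotypes, snp_map, probe_map, expression, catalog,
                         coding_genes = NULL, gwas = NULL, tracks = NULL,
                         replication = NULL,
                         window = 250000, fdr_level = 0.05, n_perm = 100,
                         unit = "probe", r2_proxy = 0.8, strict_r2 = FALSE,
                         gwas_p = 9.9e-6, tss_window = 5000,
                         min_n = 30, min_genotype_count = 3, n_top = NULL,
                         quantile_normalize = TRUE, remove_pcs = 0,
                         seed = 1) {
  if (fdr_level <= 0 || fdr_level >= 1) {
    linc_abort("`fdr_level` must be in (0, 1).", "linceqtl_param_error")
  }
  if (r2_proxy < 0 || r2_proxy > 1) {
    linc_abort("`r2_proxy` must be in [0, 1].", "linceqtl_param_error")
  }
  if (gwas_p <= 0 || gwas_p >= 1) {
    linc_abort("`gwas_p` must be in (0, 1).", "linceqtl_param_error")
  }
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    linc_abort("`expression` must be named by tissue.", "linceqtl_param_error")
  }
  paths <- c(genotypes = genotypes, snp_map = snp_map, probe_map = probe_map,
             catalog = catalog, unlist(expression),
             coding_genes = coding_genes, gwas = gwas, unlist(tracks),
             unlist(replication))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    linc_abort(sprintf("Input file(s) not found: %s",
                       paste(missing, collapse = ", ")),
               "linceqtl_param_error")
  }
  structure(list(
    genotypes = genotypes, snp_map = snp_map, probe_map = probe_map,
    expression = as.list(expression), catalog = catalog,
    coding_genes = coding_genes, gwas = gwas,
    tracks = if (is.null(tracks)) NULL else as.list(tracks),
    replication = replication,
    window = window, fdr_level = fdr_level, n_perm = n_perm, unit = unit,
    r2_proxy = r2_proxy, strict_r2 = strict_r2, gwas_p = gwas_p,
    tss_window = tss_window, min_n = min_n,
    min_genotype_count = min_genotype_count, n_top = n_top,
    quantile_normalize = quantile_normalize, remove_pcs = remove_pcs,
    seed = seed), class = "study_config")
}

#' Convenience config for a fixture directory
#'
#' Builds a [study_config()] from the file layout written by
#' [make_fixture_suite()].
#'
#' @param dir Fixture directory.
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
fixture_config <- function(dir, ...) {
  expr_files <- list.files(dir, pattern = "^expression_.*\\.tsv$")
  tissues <- sub("^expression_(.*)\\.tsv$", "\\1", expr_files)
  expression <- setNames(file.path(dir, expr_files), tissues)
  if ("blood" %in% tissues) {
    expression <- expression[c("blood", setdiff(tissues, "blood"))]
  }
  track_files <- list.files(dir, pattern = "^enhancers_.*\\.bed$")
  tracks <- if (length(track_files)) {
    setNames(file.path(dir, track_files),
             sub("^enhancers_(.*)\\.bed$", "\\1", track_files))
  }
  gwas <- file.path(dir, "gwas_catalog.tsv")
  study_config(
    genotypes = file.path(dir, "genotypes.tsv"),
    snp_map = file.path(dir, "genotypes_map.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    expression = expression,
    catalog = file.path(dir, "lincrna_catalog.bed"),
    coding_genes = if (file.exists(file.path(dir, "coding_genes.bed"))) {
      file.path(dir, "coding_genes.bed")
    },
    gwas = if (file.exists(gwas)) gwas,
    tracks = tracks, ...)
}

#' Run the full cis-eQTL study
#'
#' Executes annotation, normalization, per-tissue cis-eQTL mapping with
#' permutation FDR, optional replication, transcript-class specificity,
#' tissue comparison, GWAS intersection and regulatory enrichment on the
#' configured inputs. Per-stage tables (TSV), a machine-readable
#' `summary.json`, an effective-config copy and a log carrying every seed
#' and threshold are written to `out_dir` when given; timings go to the
#' log only, so two runs with the same config and seed produce identical
#' summaries. A stage failure aborts with the stage name and cause;
#' partial outputs already written are retained.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory.
#' @return A `linc_study` object with all stage results and `summary`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (!inherits(config, "study_config")) {
    linc_abort("`config` must be a study_config.", "linceqtl_param_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character(0)
  t0 <- Sys.time()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%.1fs] %s",
                                       as.numeric(Sys.time() - t0, units = "secs"),
                                       sprintf(fmt, ...)))
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  stage <- function(name, code) {
    say("stage %s: start", name)
    tryCatch(code, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(log_lines, file.path(out_dir, "run.log"))
      }
      linc_abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                 "linceqtl_pipeline_error")
    })
  }

  say("seed = %d; window = %g; FDR level = %g; permutations = %d; unit = %s",
      config$seed, config$window, config$fdr_level, config$n_perm, config$unit)

  # ---- inputs -----------------------------------------------------------
  geno <- stage("read-genotypes", read_genotype_matrix(config$genotypes,
                                                       config$snp_map))
  probes_raw <- stage("read-probes",
                      readr::read_tsv(config$probe_map, show_col_types = FALSE))
  catalog <- stage("read-catalog", read_lincrna_catalog(config$catalog))

  # ---- annotation -------------------------------------------------------
  probes <- stage("annotation", {
    pr <- suppressMessages(map_probes_to_catalog(probes_raw, catalog))
    say("annotation: %d probes labelled lincRNA, %d protein_coding",
        sum(pr$transcript_class == "lincRNA"),
        sum(pr$transcript_class == "protein_coding"))
    pr
  })
  emit(mutate(probes, mapped_gene_ids = vapply(
    .data$mapped_gene_ids, paste, character(1), collapse = ",")),
    "probes_annotated")
  linc_probes <- probes$probe_id[probes$transcript_class == "lincRNA"]
  coding_probes <- probes$probe_id[probes$transcript_class == "protein_coding"]

  # ---- per-tissue expression + eQTL mapping -----------------------------
  tissues <- names(config$expression)
  discovery_tissue <- tissues[1]
  pairs_linc <- enumerate_cis_pairs(probes[probes$probe_id %in% linc_probes, ],
                                    geno$snp_map, window = config$window)
  fdr_by_tissue <- list()
  expr_by_tissue <- list()
  for (ti in tissues) {
    expr <- stage(paste0("expression-", ti), {
      e <- read_expression_matrix(config$expression[[ti]], config$probe_map,
                                  tissue = ti)
      if (config$quantile_normalize) e <- suppressWarnings(quantile_normalize(e))
      if (config$remove_pcs > 0) {
        e <- remove_principal_components(e, config$remove_pcs)
      }
      e
    })
    expr_by_tissue[[ti]] <- expr
    fdr_by_tissue[[ti]] <- stage(paste0("eqtl-", ti), {
      f <- suppressMessages(permutation_fdr(
        expr, geno, pairs_linc, n_perm = config$n_perm,
        level = config$fdr_level, unit = config$unit,
        seed = derive_seed(config$seed, paste0("tissue:", ti)),
        min_n = config$min_n,
        min_genotype_count = config$min_genotype_count, tissue = ti))
      say("eqtl %s: p threshold %.4g; %d significant unit(s), %d pair(s)",
          ti, f$p_threshold, f$observed_count, sum(f$records$significant))
      f
    })
    emit(fdr_by_tissue[[ti]]$records, paste0("eqtls_", ti))
    emit(filter(fdr_by_tissue[[ti]]$records, .data$significant),
         paste0("eqtls_significant_", ti))
  }
  fdr_disc <- fdr_by_tissue[[discovery_tissue]]
  sig_disc <- filter(fdr_disc$records, .data$significant)

  # ---- replication ------------------------------------------------------
  replication <- NULL
  if (!is.null(config$replication)) {
    replication <- stage("replication", {
      rg <- read_genotype_matrix(config$replication$genotypes,
                                 config$replication$snp_map)
      re <- read_expression_matrix(config$replication$expression,
                                   config$probe_map, tissue = "replication")
      if (config$quantile_normalize) re <- suppressWarnings(quantile_normalize(re))
      r <- suppressMessages(replicate_eqtls(
        fdr_disc, re, rg, discovery_geno = geno,
        level = config$fdr_level, n_perm = config$n_perm,
        seed = derive_seed(config$seed, "replication"),
        min_n = config$min_n,
        min_genotype_count = config$min_genotype_count))
      say("replication: %.1f%% replicated, %.1f%% concordant",
          100 * r$replication_fraction, 100 * r$concordance_fraction)
      r
    })
    emit(replication$table, "replication")
  }

  # ---- transcript-class specificity ------------------------------------
  specificity <- NULL
  if (nrow(sig_disc) > 0 && length(coding_probes) > 0) {
    specificity <- stage("specificity", {
      pairs_coding <- enumerate_cis_pairs(
        probes[probes$probe_id %in% coding_probes, ], geno$snp_map,
        window = config$window)
      coding_records <- suppressMessages(map_cis_eqtls(
        expr_by_tissue[[discovery_tissue]], geno, pairs_coding,
        min_n = config$min_n,
        min_genotype_count = config$min_genotype_count))
      s <- specificity_analysis(sig_disc, coding_records,
                                fdr_disc$p_threshold)
      say("specificity: %.1f%% lincRNA-specific of %d top eQTLs",
          100 * attr(s, "prop_specific"), nrow(s))
      s
    })
    emit(specificity, "specificity")
  }

  # ---- tissue comparison ------------------------------------------------
  tissue_table <- NULL
  if (length(tissues) >= 2) {
    tissue_table <- stage("tissue-comparison", compare_tissues(fdr_by_tissue))
    emit(mutate(tissue_table, tissues = vapply(
      .data$tissues, paste, character(1), collapse = ",")),
      "tissue_specificity")
  }

  # ---- SNP location + distance histogram -------------------------------
  locations <- NULL
  if (!is.null(config$coding_genes) && nrow(sig_disc) > 0) {
    locations <- stage("snp-location", {
      models <- read_lincrna_catalog(config$coding_genes)
      top <- top_eqtl_per_probe(sig_disc)
      suppressWarnings(classify_snp_location(
        tibble(snp_id = top$snp_id, chrom = top$chrom, pos = top$pos),
        models, tss_window = config$tss_window))
    })
    emit(locations, "snp_locations")
  }
  histogram <- NULL
  if (nrow(sig_disc) > 0) {
    histogram <- stage("distance-histogram",
                       distance_histogram(sig_disc, window = config$window))
    emit(histogram, "distance_histogram")
  }

  # ---- GWAS intersection ------------------------------------------------
  gwas_table <- NULL
  if (!is.null(config$gwas)) {
    gwas_table <- stage("gwas-intersection", {
      cat_tbl <- read_gwas_catalog(config$gwas)
      top_all <- bind_rows(lapply(fdr_by_tissue, function(f) {
        s <- filter(f$records, .data$significant)
        if (nrow(s)) top_eqtl_per_probe(s) else NULL
      }))
      if (nrow(top_all) == 0L) {
        tibble()
      } else {
        suppressMessages(intersect_gwas(
          top_all, geno, cat_tbl, r2_threshold = config$r2_proxy,
          gwas_p_threshold = config$gwas_p, strict = config$strict_r2))
      }
    })
    emit(gwas_table, "gwas_intersection")
  }

  # ---- enrichment -------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$tracks) && nrow(sig_disc) > 0) {
    n_top <- config$n_top %||% length(unique(sig_disc$probe_id))
    enrichment <- stage("enrichment", {
      res <- imap(config$tracks, function(path, nm) {
        permutation_enrichment_significance(
          expr_by_tissue[[discovery_tissue]], geno, pairs_linc,
          track = read_bed(path), n_top = n_top, n_perm = config$n_perm,
          seed = derive_seed(config$seed, paste0("enrich:", nm)),
          min_n = config$min_n,
          min_genotype_count = config$min_genotype_count, track_name = nm)
      })
      for (r in res) {
        say("enrichment %s: fold %.3g, p %.4g", r$track, r$fold, r$p_one_sided)
      }
      res
    })
    emit(bind_rows(lapply(enrichment, glance)), "enrichment")
  }

  # ---- summary ----------------------------------------------------------
  per_tissue <- lapply(fdr_by_tissue, function(f) {
    list(n_probes_tested = nrow(f$units),
         n_significant_probes = if (f$unit == "probe") f$observed_count
                                else length(unique(
                                  f$records$probe_id[f$records$significant])),
         n_significant_pairs = sum(f$records$significant),
         p_threshold = f$p_threshold)
  })
  summary <- list(
    seed = config$seed,
    tissues = tissues,
    n_lincRNA_probes = length(linc_probes),
    n_coding_probes = length(coding_probes),
    eqtl = per_tissue,
    replication = if (!is.null(replication)) list(
      replication_fraction = replication$replication_fraction,
      concordance_fraction = replication$concordance_fraction),
    specificity = if (!is.null(specificity)) list(
      n_top_eqtls = nrow(specificity),
      prop_lincRNA_specific = attr(specificity, "prop_specific"),
      n_shared = sum(specificity$specificity == "shared"),
      prop_opposite_direction = attr(specificity, "prop_opposite")),
    tissue_classes = if (!is.null(tissue_table)) as.list(
      table(factor(tissue_table$class,
                   levels = c("single_tissue", "multi_tissue", "all_tissue")))),
    gwas = if (!is.null(gwas_table)) list(
      n_rows = nrow(gwas_table),
      n_unique_eqtl_snps = length(unique(gwas_table$snp_id))),
    enrichment = if (!is.null(enrichment)) lapply(enrichment, function(r) {
      list(fold = r$fold, p_one_sided = r$p_one_sided)
    }))
  summary <- summary[!vapply(summary, is.null, logical(1))]

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         file.path(out_dir, "effective_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("done")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  structure(list(config = config, probes = probes, geno = geno,
                 fdr = fdr_by_tissue, replication = replication,
                 specificity = specificity, tissue_table = tissue_table,
                 locations = locations, histogram = histogram,
                 gwas = gwas_table, enrichment = enrichment,
                 summary = summary, log = log_lines),
            class = "linc_study")
}

#' @export
print.linc_study <- function(x, ...) {
  disc <- names(x$fdr)[1]
  cat(sprintf("<linc_study> tissues: %s\n", paste(names(x$fdr), collapse = ", ")))
  cat(sprintf("  discovery (%s): %d significant probe unit(s) at p <= %.4g\n",
              disc, x$fdr[[disc]]$observed_count, x$fdr[[disc]]$p_threshold))
  if (!is.null(x$replication)) {
    cat(sprintf("  replication: %.1f%% replicated, %.1f%% concordant\n",
                100 * x$replication$replication_fraction,
                100 * x$replication$concordance_fraction))
  }
  if (!is.null(x$specificity)) {
    cat(sprintf("  specificity: %.1f%% lincRNA-specific\n",
                100 * attr(x$specificity, "prop_specific")))
  }
  if (!is.null(x$gwas)) {
    cat(sprintf("  GWAS intersection: %d row(s)\n", nrow(x$gwas)))
  }
  invisible(x)
}

#' @export
glance.linc_study <- function(x, ...) {
  disc <- names(x$fdr)[1]
  tibble(
    discovery_tissue = disc,
    n_significant_probes = x$fdr[[disc]]$observed_count,
    n_significant_pairs = sum(x$fdr[[disc]]$records$significant),
    p_threshold = x$fdr[[disc]]$p_threshold,
    replication_fraction = if (!is.null(x$replication)) {
      x$replication$replication_fraction
    } else NA_real_,
    prop_lincRNA_specific = if (!is.null(x$specificity)) {
      attr(x$specificity, "prop_specific")
    } else NA_real_,
    n_gwas_rows = if (!is.null(x$gwas)) nrow(x$gwas) else NA_integer_)
}

#' Binned signed-distance distribution of cis-eQTLs
#'
#' Fractions of records falling into equal-width bins of the signed
#' probe-center-to-SNP distance over `[-window, window]`; fractions sum
#' to 1 over the retained records.
#'
#' @param records eQTL record tibble with a `distance` column.
#' @param window Cis-window half-width in bp.
#' @param n_bins Number of equal-width bins.
#' @return Tibble: `bin_start`, `bin_end`, `midpoint`, `n`, `fraction`.
#' @export
distance_histogram <- function(records, window = 250000, n_bins = 25) {
  d <- records$distance[abs(records$distance) <= window]
  if (length(d) == 0L) {
    linc_abort("No records within the window.", "linceqtl_param_error")
  }
  br <- seq(-window, window, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(d, br, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(idx, n_bins)
  tibble(bin_start = br[-length(br)], bin_end = br[-1],
         midpoint = (br[-length(br)] + br[-1]) / 2,
         n = cnt, fraction = cnt / sum(cnt))
}
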