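#' Specify a synthetic eQTL study
#'
#' Collects every parameter of the synthetic-data generator into one
#' validated object. The defaults describe the study conditions exercised
#' throughout the test suite: 200 samples, 2,000 SNPs in linkage blocks of
#' 10, 200 expression probes on one chromosome, 50 planted cis-effects of
#' 0.8 intensity units per allele copy against unit-SD noise, and lincRNA
#' probes sitting 0.25 intensity units below protein-coding probes
#' (mirroring the 6.67 vs 6.92 abundance gap seen on blood arrays).
#'
#' @param n_samples Number of individuals in the sample universe.
#' @param n_snps Number of SNPs.
#' @param n_probes Number of expression probes.
#' @param maf_range Length-2 numeric in (0, 0.5]: minor-allele-frequency
#'   range, one MAF drawn per LD block.
#' @param ld_block_size SNPs per LD block.
#' @param ld_decay Copy probability in `[0, 1)` of the block-copy LD model:
#'   within a block each SNP copies the previous SNP's dosage per sample
#'   with this probability, else redraws under Hardy-Weinberg. Population
#'   r-squared between SNPs `d` apart in a block is `ld_decay^(2 d)`.
#' @param n_effects Number of planted cis-effects (on lincRNA probes by
#'   default, see [make_effects()]).
#' @param effect_beta Planted effect size, intensity units per allele copy.
#' @param lincRNA_fraction Fraction of probes labelled lincRNA.
#' @param abundance_shift Intensity units separating the protein-coding and
#'   lincRNA class baselines (coding higher).
#' @param coding_baseline Baseline intensity of protein-coding probes.
#' @param noise_sd Gaussian noise SD, intensity units.
#' @param probe_length Probe alignment length in bp.
#' @param genome_size Chromosome length in bp; default `n_snps * 5000`.
#' @param tissues Named integer vector of tissue subset sizes; each subset
#'   is drawn from the same sample universe (multi-tissue designs share
#'   individuals). Default one tissue, `blood`, containing every sample.
#' @param window Cis-window half-width in bp (distance from probe center to
#'   SNP, inclusive).
#' @param seed Master seed; every generator call derives its own stream.
#'
#' @return A `simulation_spec` object (validated list).
#' @export
#' @examples
#' spec <- simulation_spec(n_samples = 50, n_snps = 100, n_probes = 20, seed = 1)
#' spec
simulation_spec <- function(n_samples = 200, n_snps = 2000, n_probes = 200,
                            maf_range = c(0.05, 0.5),
                            ld_block_size = 10, ld_decay = 0.8,
                            n_effects = 50, effect_beta = 0.8,
                            lincRNA_fraction = 0.5, abundance_shift = 0.25,
                            coding_baseline = 6.92, noise_sd = 1,
                            probe_length = 50, genome_size = NULL,
                            tissues = NULL, window = 250000, seed = 1) {
  for (nm in c("n_samples", "n_snps", "n_probes", "ld_block_size")) {
    if (!is_count(get(nm))) {
      linc_abort(sprintf("`%s` must be a positive integer.", nm),
                 "linceqtl_param_error")
    }
  }
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    linc_abort("`maf_range` must lie within (0, 0.5] with min <= max.",
               "linceqtl_param_error")
  }
  if (!is.numeric(ld_decay) || ld_decay < 0 || ld_decay >= 1) {
    linc_abort("`ld_decay` must be in [0, 1).", "linceqtl_param_error")
  }
  if (lincRNA_fraction < 0 || lincRNA_fraction > 1) {
    linc_abort("`lincRNA_fraction` must be in [0, 1].", "linceqtl_param_error")
  }
  if (noise_sd < 0 || abundance_shift < 0) {
    linc_abort("`noise_sd` and `abundance_shift` must be non-negative.",
               "linceqtl_param_error")
  }
  genome_size <- genome_size %||% (n_snps * 5000)
  if (genome_size < probe_length + 2) {
    linc_abort("`genome_size` too small for the probe length.",
               "linceqtl_param_error")
  }
  tissues <- tissues %||% c(blood = n_samples)
  if (is.null(names(tissues)) || any(!nzchar(names(tissues)))) {
    linc_abort("`tissues` must be a named vector of subset sizes.",
               "linceqtl_param_error")
  }
  if (any(tissues < 1) || any(tissues > n_samples)) {
    linc_abort("Every tissue subset must be within the sample universe.",
               "linceqtl_param_error")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_probes = as.integer(n_probes), maf_range = as.double(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_decay = as.double(ld_decay),
    n_effects = as.integer(n_effects), effect_beta = as.double(effect_beta),
    lincRNA_fraction = as.double(lincRNA_fraction),
    abundance_shift = as.double(abundance_shift),
    coding_baseline = as.double(coding_baseline),
    noise_sd = as.double(noise_sd), probe_length = as.integer(probe_length),
    genome_size = as.double(genome_size),
    tissues = setNames(as.integer(tissues), names(tissues)),
    window = as.double(window), seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_spec> %d samples, %d SNPs (blocks of %d, decay %.2f), ",
    "%d probes (%.0f%% lincRNA)\n  %d planted effects (beta = %.2f), ",
    "noise_sd = %.2f, tissues: %s, seed = %d\n"),
    x$n_samples, x$n_snps, x$ld_block_size, x$ld_decay, x$n_probes,
    100 * x$lincRNA_fraction, x$n_effects, x$effect_beta, x$noise_sd,
    paste(sprintf("%s(%d)", names(x$tissues), x$tissues), collapse = ", "),
    x$seed))
  invisible(x)
}

sample_ids <- function(spec) sprintf("S%04d", seq_len(spec$n_samples))

#' Tissue sample subsets
#'
#' Returns, for each tissue in the spec, the sample ids belonging to that
#' tissue. Subsets are drawn deterministically from the master seed, so the
#' same individuals are shared across tissues, as in multi-tissue designs
#' where all tissues come from one cohort.
#'
#' @param spec A [simulation_spec()].
#' @return Named list of character vectors of sample ids.
#' @export
tissue_samples <- function(spec) {
  ids <- sample_ids(spec)
  withr::local_seed(derive_seed(spec$seed, "tissues"))
  out <- lapply(seq_along(spec$tissues), function(i) {
    k <- spec$tissues[[i]]
    if (k == spec$n_samples) ids else sort(sample(ids, k))
  })
  setNames(out, names(spec$tissues))
}

#' Simulate genotype dosages with block LD structure
#'
#' Draws Hardy-Weinberg genotypes (dosage 0/1/2) for SNPs placed uniformly
#' along one chromosome and grouped into LD blocks. Every SNP in a block
#' shares the block's MAF; after the first SNP of a block, each sample's
#' dosage is copied from the previous SNP with probability `ld_decay`, else
#' redrawn, giving a population correlation of `ld_decay^d` between SNPs
#' `d` apart in the block and independence across blocks.
#'
#' The SNP map (positions, block MAFs, alleles) is drawn from the spec's
#' master seed alone, while dosages use `dosage_seed`; generating a second
#' cohort with a different `dosage_seed` therefore yields independent
#' genotypes on an identical SNP map, as needed for replication designs.
#'
#' @param spec A [simulation_spec()].
#' @param dosage_seed Seed for the dosage draws (default derived from the
#'   spec seed).
#' @return A [genotype_matrix()] whose `snp_map` carries `maf` and `block`.
#' @export
#' @examples
#' g <- simulate_genotypes(simulation_spec(n_samples = 40, n_snps = 60,
#'                                         n_probes = 10, seed = 3))
#' table(g$dosage[, 1])
simulate_genotypes <- function(spec,
                               dosage_seed = derive_seed(spec$seed, "genotypes")) {
  if (!inherits(spec, "simulation_spec")) {
    linc_abort("`spec` must be a simulation_spec.", "linceqtl_param_error")
  }
  ns <- spec$n_samples
  nm <- spec$n_snps
  withr::with_seed(derive_seed(spec$seed, "map"), {
    pos <- sort(sample.int(spec$genome_size, nm)) - 1
    n_blocks <- ceiling(nm / spec$ld_block_size)
    block <- rep(seq_len(n_blocks), each = spec$ld_block_size)[seq_len(nm)]
    block_maf <- runif(n_blocks, spec$maf_range[1], spec$maf_range[2])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nm, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
  })
  maf <- block_maf[block]

  withr::local_seed(dosage_seed)
  d <- matrix(0L, nrow = ns, ncol = nm)
  for (j in seq_len(nm)) {
    fresh <- rbinom(ns, 2L, maf[j])
    if (j > 1L && block[j] == block[j - 1L] && spec$ld_decay > 0) {
      keep <- rbinom(ns, 1L, spec$ld_decay) == 1L
      d[, j] <- ifelse(keep, d[, j - 1L], fresh)
    } else {
      d[, j] <- fresh
    }
  }
  snp_id <- sprintf("snp%05d", seq_len(nm))
  dimnames(d) <- list(sample_ids(spec), snp_id)
  genotype_matrix(d, tibble(
    snp_id = snp_id, chrom = "chr1", pos = as.double(pos),
    ref = ref, alt = alt, maf = maf, block = block))
}

#' Probe map for a synthetic study
#'
#' Places probes uniformly on the chromosome and labels each lincRNA or
#' protein_coding with probability `lincRNA_fraction`. Gene ids follow the
#' lincRNA-catalog style (`XLOC_*`) for lincRNA probes.
#'
#' @param spec A [simulation_spec()].
#' @return Tibble: `probe_id`, `chrom`, `start`, `end`, `center`,
#'   `transcript_class`, `gene_id` (0-based half-open intervals).
#' @export
make_probes <- function(spec) {
  withr::local_seed(derive_seed(spec$seed, "probes"))
  np <- spec$n_probes
  half <- floor(spec$probe_length / 2)
  lo <- half + 1
  hi <- spec$genome_size - spec$probe_length
  centers <- sort(sample(seq(lo, hi), np))
  start <- centers - half
  end <- start + spec$probe_length
  cls <- ifelse(runif(np) < spec$lincRNA_fraction, "lincRNA", "protein_coding")
  tibble(
    probe_id = sprintf("probe%04d", seq_len(np)),
    chrom = "chr1", start = as.double(start), end = as.double(end),
    center = floor((start + end) / 2),
    transcript_class = cls,
    gene_id = ifelse(cls == "lincRNA",
                     sprintf("XLOC_%04d", seq_len(np)),
                     sprintf("GENE_%04d", seq_len(np))))
}

#' Plant cis-effects
#'
#' Chooses `n_effects` distinct probes of `target_class` that have at least
#' one SNP within the cis window of their center and assigns each a random
#' such SNP with effect size `beta`. Optionally the first `n_shared` effects
#' are mirrored onto the nearest protein-coding probe within the window of
#' the same SNP (same or opposite direction), for transcript-class
#' specificity studies.
#'
#' @param spec A [simulation_spec()].
#' @param geno Output of [simulate_genotypes()].
#' @param probes Output of [make_probes()].
#' @param n_effects,beta Number and size of planted effects; default from
#'   the spec. `beta` may be a vector (recycled to `n_effects`) to plant a
#'   spread of effect sizes.
#' @param target_class Probe class receiving the effects.
#' @param n_shared How many effects are shared with a neighbouring
#'   protein-coding probe.
#' @param shared_sign `"random"`, `"same"` or `"opposite"` direction of the
#'   shared coding effect relative to the lincRNA effect.
#' @param tissues_active Character vector of tissue names in which the
#'   effects act, or `NULL` for all tissues.
#' @param seed Stream seed; defaults to a stream derived from the spec seed.
#'
#' @return Truth tibble: `probe_id`, `snp_id`, `beta`, `tissues_active`
#'   (list-column; `NULL` element = active everywhere).
#' @export
make_effects <- function(spec, geno, probes,
                         n_effects = spec$n_effects, beta = spec$effect_beta,
                         target_class = "lincRNA", n_shared = 0,
                         shared_sign = c("random", "same", "opposite"),
                         tissues_active = NULL,
                         seed = derive_seed(spec$seed, "effects")) {
  shared_sign <- match.arg(shared_sign)
  withr::local_seed(seed)
  probes <- add_probe_centers(probes)
  pos <- geno$snp_map$pos
  has_cis <- vapply(probes$center, function(cc) {
    any(abs(pos - cc) <= spec$window)
  }, logical(1))
  eligible <- probes[probes$transcript_class == target_class & has_cis, ]
  if (nrow(eligible) < n_effects) {
    linc_abort(sprintf(
      "Only %d %s probes have a cis SNP; cannot plant %d effects.",
      nrow(eligible), target_class, n_effects), "linceqtl_spec_error")
  }
  chosen <- eligible[sort(sample.int(nrow(eligible), n_effects)), ]
  snp_for <- vapply(chosen$center, function(cc) {
    ok <- which(abs(pos - cc) <= spec$window)
    ok[sample.int(length(ok), 1L)]
  }, integer(1))
  eff <- tibble(
    probe_id = chosen$probe_id,
    snp_id = geno$snp_map$snp_id[snp_for],
    beta = rep_len(beta, n_effects),
    tissues_active = rep(list(tissues_active), n_effects))
  if (n_shared > 0) {
    if (n_shared > n_effects) {
      linc_abort("`n_shared` cannot exceed `n_effects`.", "linceqtl_param_error")
    }
    coding <- probes[probes$transcript_class == "protein_coding", ]
    extra <- vector("list", n_shared)
    for (i in seq_len(n_shared)) {
      sp <- pos[snp_for[i]]
      dd <- abs(coding$center - sp)
      cand <- which(dd <= spec$window)
      if (length(cand) == 0L) {
        warn(sprintf("No protein-coding probe within the window of %s; shared effect skipped.",
                     eff$snp_id[i]))
        next
      }
      nearest <- cand[which.min(dd[cand])]
      sgn <- switch(shared_sign,
                    same = 1, opposite = -1,
                    random = sample(c(-1, 1), 1L))
      extra[[i]] <- tibble(probe_id = coding$probe_id[nearest],
                           snp_id = eff$snp_id[i], beta = eff$beta[i] * sgn,
                           tissues_active = list(tissues_active))
    }
    eff <- bind_rows(eff, bind_rows(extra))
  }
  eff
}

#' Simulate expression intensities with planted cis-effects
#'
#' Probe intensity = class baseline (lincRNA = coding baseline minus
#' `abundance_shift`) + `beta` x dosage for planted probe-SNP pairs active
#' in the tissue + Gaussian noise. The returned container carries the truth
#' table (with an `active` flag resolved for this tissue) for recovery
#' tests.
#'
#' @param geno A [genotype_matrix()] from [simulate_genotypes()].
#' @param spec The same [simulation_spec()].
#' @param probes Probe map, default [make_probes()] of the spec.
#' @param effects Truth tibble from [make_effects()], or `NULL` for no
#'   planted effects.
#' @param tissue Tissue name (must exist in `spec$tissues`); the expression
#'   matrix covers that tissue's sample subset.
#' @param noise_seed Seed for the noise draws; override to generate an
#'   independent cohort under the same planted truth.
#'
#' @return An [expression_matrix()] with `normalization_state = "raw"`.
#' @export
#' @examples
#' spec <- simulation_spec(n_samples = 60, n_snps = 100, n_probes = 20,
#'                         n_effects = 3, seed = 11)
#' g <- simulate_genotypes(spec)
#' pr <- make_probes(spec)
#' ef <- make_effects(spec, g, pr)
#' e <- simulate_expression(g, spec, pr, ef)
simulate_expression <- function(geno, spec, probes = make_probes(spec),
                                effects = NULL, tissue = "blood",
                                noise_seed = derive_seed(
                                  spec$seed, paste0("expression:", tissue))) {
  if (!tissue %in% names(spec$tissues)) {
    linc_abort(sprintf("Unknown tissue '%s'.", tissue), "linceqtl_param_error")
  }
  probes <- add_probe_centers(probes)
  samples <- tissue_samples(spec)[[tissue]]
  if (!all(samples %in% rownames(geno$dosage))) {
    linc_abort("Tissue samples missing from the genotype matrix.",
               "linceqtl_spec_error")
  }
  if (!is.null(effects)) {
    bad_p <- setdiff(effects$probe_id, probes$probe_id)
    bad_s <- setdiff(effects$snp_id, geno$snp_map$snp_id)
    if (length(bad_p) || length(bad_s)) {
      linc_abort(sprintf("Effects reference unknown probes/SNPs: %s",
                         paste(c(bad_p, bad_s), collapse = ", ")),
                 "linceqtl_spec_error")
    }
  }
  withr::local_seed(noise_seed)
  np <- nrow(probes)
  ns <- length(samples)
  baseline <- ifelse(probes$transcript_class == "lincRNA",
                     spec$coding_baseline - spec$abundance_shift,
                     spec$coding_baseline)
  m <- matrix(rnorm(np * ns, mean = 0, sd = spec$noise_sd), np, ns) + baseline
  dimnames(m) <- list(probes$probe_id, samples)
  truth <- NULL
  if (!is.null(effects) && nrow(effects) > 0) {
    active <- vapply(effects$tissues_active, function(ta) {
      is.null(ta) || tissue %in% ta
    }, logical(1))
    for (i in which(active)) {
      pid <- effects$probe_id[i]
      m[pid, ] <- m[pid, ] + effects$beta[i] * geno$dosage[samples, effects$snp_id[i]]
    }
    truth <- mutate(effects, active = active)
  }
  expression_matrix(m, probes, normalization_state = "raw",
                    tissue = tissue, truth = truth)
}

# one synthetic study in memory: genotypes, probes, effects, expression per
# tissue. Used by the fixture writer and convenient in tests.
#' Simulate a complete study in memory
#'
#' @inheritParams simulate_expression
#' @param spec A [simulation_spec()].
#' @param n_shared,target_class,tissues_active,beta Passed to
#'   [make_effects()].
#' @param cohort_seed When given, dosage and noise streams are derived from
#'   this seed instead of the spec seed, yielding an independent cohort
#'   (fresh genotypes and noise) on the same SNP map, probes and planted
#'   truth — the structure a replication cohort shares with discovery.
#' @return List: `spec`, `geno`, `probes`, `effects`, `expression` (named
#'   list of [expression_matrix()] per tissue).
#' @export
simulate_study <- function(spec, n_shared = 0, target_class = "lincRNA",
                           tissues_active = NULL, cohort_seed = NULL,
                           beta = spec$effect_beta) {
  base <- cohort_seed %||% spec$seed
  geno <- simulate_genotypes(spec,
                             dosage_seed = derive_seed(base, "genotypes"))
  probes <- make_probes(spec)
  effects <- if (spec$n_effects > 0) {
    make_effects(spec, geno, probes, beta = beta, n_shared = n_shared,
                 target_class = target_class, tissues_active = tissues_active)
  }
  expr <- lapply(names(spec$tissues), function(ti) {
    simulate_expression(geno, spec, probes, effects, tissue = ti,
                        noise_seed = derive_seed(base,
                                                 paste0("expression:", ti)))
  })
  list(spec = spec, geno = geno, probes = probes, effects = effects,
       expression = setNames(expr, names(spec$tissues)))
}
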