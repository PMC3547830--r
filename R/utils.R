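# internal helpers shared across modules

linc_abort <- function(message, class) {
  abort(message, class = c(class, "linceqtl_error"))
}

# Deterministic sub-seed derivation: one master seed per run, per-purpose
# streams derived by salting. Kept < 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, salt) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    linc_abort("`seed` must be a single finite number.", "linceqtl_param_error")
  }
  u <- utf8ToInt(salt)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.double(seed)) * 10007 + h) %% 2147483629)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Probe center: floor((start + end) / 2) of the 0-based half-open alignment
# interval. Rounding direction is a package convention.
add_probe_centers <- function(probes) {
  if (!"center" %in% names(probes)) {
    probes$center <- floor((probes$start + probes$end) / 2)
  }
  probes
}

# Midrank-standardized rows: each row ranked across columns, centered and
# scaled to unit sum of squares, so that crossprod of two such vectors is the
# Spearman (midrank) correlation. Constant rows come out as NaN and are
# treated as not testable downstream.
rank_rows_std <- function(m) {
  r <- t(apply(m, 1L, rank))
  if (nrow(m) == 1L) r <- matrix(r, nrow = 1L, dimnames = dimnames(m))
  r <- r - rowMeans(r)
  ss <- sqrt(rowSums(r^2))
  out <- r / ss
  dimnames(out) <- dimnames(m)
  out
}

rank_cols_std <- function(m) {
  t(rank_rows_std(t(m)))
}
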