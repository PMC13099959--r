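# Shared fixtures: libraries and profile sets are built in code at test
# time; nothing is read from disk.

# Full 153-genotype panel (built once; enumeration is deterministic).
full_library <- enumerate_library()

# Small 20-genotype library: wild type + the 19 substitutions at position 2.
small_library <- enumerate_library(variable_positions = 2)

# Flat (pH-insensitive) profiles with given efficiencies, in library order.
flat_profiles <- function(library, m) {
  ids <- library$variants$variant_id
  stopifnot(length(m) == length(ids))
  stats::setNames(
    lapply(m, function(mi) fitness_profile("flat", m_max = mi)), ids)
}

# Reduce a variant_library to its first n entries (keeps WT), for oracle
# tests on small frequency vectors.
subset_library <- function(library, n) {
  v <- library$variants[seq_len(n), , drop = FALSE]
  structure(list(variants = v,
                 barcode_index = stats::setNames(v$variant_id, v$barcode),
                 wt_peptide = library$wt_peptide),
            class = "variant_library")
}

# Independent Welch oracle: textbook statistic with Satterthwaite df,
# evaluated directly (kept free of stats::t.test, which backs the
# implementation).
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Brute-force BH oracle: sort, step-up, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}
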