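#' Convert counts to within-sample relative frequencies
#'
#' Normalizes each sample column by library size after adding a symmetric
#' pseudocount, so frequencies (and downstream log2 ratios) are defined for
#' zero-count genotypes: `f_ig = (n_ig + q) / sum_j (n_jg + q)`.
#'
#' @param counts A `count_table` or a genotype x sample matrix of
#'   non-negative counts.
#' @param pseudocount Pseudocount `q` >= 0 added to every cell (default 0.5).
#' @return Genotype x sample matrix of frequencies, columns summing to 1,
#'   with the pseudocount recorded as attribute `"pseudocount"`.
#' @export
to_frequencies <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  stopifnot(is.matrix(counts), all(counts >= 0), pseudocount >= 0)
  matched <- colSums(counts)
  if (any(matched == 0)) {
    stop("sample(s) with zero matched reads: ",
         paste(colnames(counts)[matched == 0], collapse = ", "))
  }
  x <- counts + pseudocount
  freq <- sweep(x, 2L, colSums(x), "/")
  attr(freq, "pseudocount") <- pseudocount
  freq
}

# Align two frequency matrices on shared genotypes and paired replicate
# columns (replicate k of the numerator condition against replicate k of
# the denominator).
.pair_columns <- function(num, den, pairing = NULL) {
  stopifnot(identical(rownames(num), rownames(den)))
  if (is.null(pairing)) {
    if (ncol(num) != ncol(den)) {
      stop("unpaired replicates: ", ncol(num), " vs ", ncol(den),
           " columns; supply an explicit pairing")
    }
    pairing <- cbind(seq_len(ncol(num)), seq_len(ncol(den)))
  }
  list(num = num[, pairing[, 1L], drop = FALSE],
       den = den[, pairing[, 2L], drop = FALSE])
}

#' Per-replicate log2 fold change between two frequency tables
#'
#' Selection is summarized per variant as
#' `log2FC = log2(f_end / f_start)`, computed within each biological
#' replicate (replicate k paired with replicate k), then reported as mean
#' and sd across replicates.
#'
#' @param freq_end,freq_start Genotype x replicate frequency matrices with
#'   identical genotype sets and strictly positive entries.
#' @param pairing Optional two-column matrix of (end, start) column index
#'   pairs; default pairs columns positionally.
#' @return List with `log2fc_replicates` (genotype x replicate matrix),
#'   `log2fc_mean` and `log2fc_sd` (named vectors).
#' @export
log2_fold_change <- function(freq_end, freq_start, pairing = NULL) {
  pr <- .pair_columns(freq_end, freq_start, pairing)
  if (any(pr$num <= 0) || any(pr$den <= 0)) {
    stop("frequencies must be strictly positive; ",
         "use a pseudocount upstream")
  }
  lfc <- log2(pr$num / pr$den)
  colnames(lfc) <- paste0("rep", seq_len(ncol(lfc)))
  list(log2fc_replicates = lfc,
       log2fc_mean = rowMeans(lfc),
       log2fc_sd = apply(lfc, 1L, stats::sd))
}

#' Welch's two-sample t test (unequal variances)
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom, as used for
#' all two-group comparisons. The degenerate case of two zero-variance
#' groups with equal means (identical constant groups) returns `t = 0`,
#' `p = 1`.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each group needs n >= 2 observations")
  }
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2L,
                  p = 1))
    }
    stop("zero variance in both groups with unequal means: ",
         "Welch statistic undefined")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Multiplicity adjustment of p-values
#'
#' Step-up Benjamini-Hochberg by default; Holm and Bonferroni available.
#' Input order is preserved and adjusted values are clipped to \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"`, `"holm"`, or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Volcano classification of enrichment results
#'
#' A variant is `enriched` when its mean log2 fold change is at least
#' `fc_threshold` (>= 4-fold by default) with adjusted p below `alpha`;
#' `depleted` symmetrically; otherwise `neutral`. The fold-change boundary
#' is inclusive.
#'
#' @param log2fc_mean Numeric vector of mean log2 fold changes.
#' @param adj_p Adjusted p-values, same length.
#' @param fc_threshold log2 fold-change cut (default 2, i.e. 4-fold).
#' @param alpha Significance cut on adjusted p (default 0.05).
#' @return Character vector in `{"enriched", "depleted", "neutral"}`.
#' @export
classify_volcano <- function(log2fc_mean, adj_p, fc_threshold = 2,
                             alpha = 0.05) {
  stopifnot(length(log2fc_mean) == length(adj_p))
  out <- rep("neutral", length(log2fc_mean))
  out[log2fc_mean >= fc_threshold & adj_p < alpha] <- "enriched"
  out[log2fc_mean <= -fc_threshold & adj_p < alpha] <- "depleted"
  out
}

#' Enrichment statistics for a test condition against a reference
#'
#' The headline statistic of the pooled screen. For each variant the
#' per-replicate log2 fold change of its frequency (test over reference) is
#' computed with replicate k paired to replicate k; significance comes from
#' a two-sided Welch t test of the per-replicate log2 frequencies in the
#' test condition against those in the reference; p-values are adjusted
#' across variants and classified on the volcano rule.
#'
#' Both the between-cycle selection summary (cycle T vs cycle 0/1 of the
#' same condition) and the between-condition contrast (condition vs the
#' reference pH at the same cycle; see [condition_contrast()]) use this
#' machinery.
#'
#' @param freq_test,freq_ref Genotype x replicate frequency matrices.
#' @param pairing Optional explicit replicate pairing (see
#'   [log2_fold_change()]).
#' @param fc_threshold,alpha Volcano thresholds (see [classify_volcano()]).
#' @param method Multiplicity adjustment method.
#' @return An `enrichment_result` data.frame: `variant_id`, one
#'   `log2fc_repK` column per replicate, `log2fc_mean`, `log2fc_sd`,
#'   `p_value`, `adj_p`, `class`.
#' @export
enrichment_results <- function(freq_test, freq_ref, pairing = NULL,
                               fc_threshold = 2, alpha = 0.05,
                               method = "BH") {
  lfc <- log2_fold_change(freq_test, freq_ref, pairing)
  pr <- .pair_columns(freq_test, freq_ref, pairing)
  ltest <- log2(pr$num)
  lref <- log2(pr$den)
  p <- vapply(seq_len(nrow(ltest)), function(i) {
    welch_t_test(ltest[i, ], lref[i, ])$p
  }, numeric(1))
  adj <- adjust_pvalues(p, method = method)
  res <- data.frame(variant_id = rownames(freq_test),
                    lfc$log2fc_replicates,
                    log2fc_mean = lfc$log2fc_mean,
                    log2fc_sd = lfc$log2fc_sd,
                    p_value = p,
                    adj_p = adj,
                    class = classify_volcano(lfc$log2fc_mean, adj,
                                             fc_threshold, alpha),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(res)[2:(1 + ncol(lfc$log2fc_replicates))] <-
    paste0("log2fc_", colnames(lfc$log2fc_replicates))
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Contrast variant frequencies between a condition and the reference pH
#'
#' pH effects are expressed relative to the reference condition (pH 5.5):
#' per variant and replicate, `log2(f_condition / f_reference)` at the same
#' cycle, with the reference in the denominator. This is
#' [enrichment_results()] with the reference condition as the baseline.
#'
#' @inheritParams enrichment_results
#' @param freq_condition Frequencies under the test condition.
#' @param freq_reference Frequencies under the reference condition.
#' @return An `enrichment_result` data.frame.
#' @export
condition_contrast <- function(freq_condition, freq_reference,
                               pairing = NULL, fc_threshold = 2,
                               alpha = 0.05, method = "BH") {
  enrichment_results(freq_condition, freq_reference, pairing,
                     fc_threshold, alpha, method)
}

#' Predict pooled frequencies from single-strain mating efficiencies
#'
#' Theoretical expectation for the pooled outcome after `cycles` rounds of
#' cell-autonomous selection:
#' `f_i(T) = f_i(0) m_i^T / sum_j f_j(0) m_j^T` (with `0^0 = 1`).
#'
#' @param f0 Initial frequency vector summing to 1.
#' @param m Mating-efficiency vector (>= 0), same length.
#' @param cycles Number of selection cycles (>= 0).
#' @return Predicted frequency vector summing to 1.
#' @export
predict_frequencies <- function(f0, m, cycles) {
  .assert_frequencies(f0)
  stopifnot(length(m) == length(f0), all(m >= 0), cycles >= 0)
  if (cycles == 0) return(f0)
  x <- f0 * m^cycles
  if (sum(x) <= 0) stop("population extinct: all efficiencies zero")
  x / sum(x)
}

#' Infer relative mating efficiencies from start and end frequencies
#'
#' Inverts the pooled predictor: `m_i = (fT_i / f0_i)^(1/cycles)`, rescaled
#' so the reference variant has efficiency 1.
#'
#' @param f0,fT Strictly positive frequency vectors (start, end).
#' @param cycles Number of selection cycles between them (>= 1).
#' @param reference_variant Name (or index) of the variant scaled to 1.
#' @return Named vector of relative efficiencies.
#' @export
infer_efficiencies <- function(f0, fT, cycles, reference_variant = "WT") {
  stopifnot(length(f0) == length(fT), cycles >= 1)
  if (any(f0 <= 0) || any(fT <= 0)) {
    stop("zero frequency encountered: apply a pseudocount upstream ",
         "(see to_frequencies)")
  }
  m_hat <- (fT / f0)^(1 / cycles)
  ref <- if (is.character(reference_variant)) {
    match(reference_variant, names(m_hat))
  } else {
    reference_variant
  }
  if (is.na(ref) || ref < 1 || ref > length(m_hat)) {
    stop("reference variant not found")
  }
  m_hat / m_hat[[ref]]
}

#' Compare observed and predicted frequencies
#'
#' Agreement between observed post-competition frequencies and predictions
#' from single-strain mating efficiencies, assessed with Pearson's r
#' (and R^2).
#'
#' @param observed,predicted Numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @return List with `observed`, `predicted`, `pearson_r`, `r_squared`.
#' @export
compare_observed_predicted <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3L) stop("need at least 3 paired values")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(observed, predicted, method = "pearson")
  list(observed = observed, predicted = predicted,
       pearson_r = r, r_squared = r^2)
}

#' Write enrichment results as TSV
#'
#' @param result An `enrichment_result` data.frame.
#' @param path TSV path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
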