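#' Microscopy mating rate from per-field cell counts
#'
#' Mating rate of a field scored for vegetative cells (V), zygotes (Z),
#' asci (A) and free spores (S):
#' `rate (%) = (2Z + 2A + 0.5S) * 100 / (V + 2Z + 2A + 0.5S)`.
#' Zygotes and asci each derive from two mated cells and a free spore is
#' weighted as half a cell, hence the coefficients.
#'
#' @param V,Z,A,S Non-negative integer counts (vectorized over fields).
#' @return Mating rate percentage in \[0, 100\].
#' @examples
#' mating_rate(V = 80, Z = 5, A = 5, S = 20)  # 27.27...
#' @export
mating_rate <- function(V, Z, A, S) {
  stopifnot(all(V >= 0), all(Z >= 0), all(A >= 0), all(S >= 0))
  total <- V + Z + A + S
  if (any(total == 0)) stop("unscorable field: all counts zero")
  mated <- 2 * Z + 2 * A + 0.5 * S
  mated * 100 / (V + mated)
}

#' Two-level aggregation of per-field mating rates
#'
#' Fields are averaged within each biological replicate first (to avoid
#' pseudoreplication); the replicate means are the downstream statistical
#' units and are summarized as mean and sd across replicates.
#'
#' @param field_rates List of numeric vectors, one per replicate (each the
#'   per-field rates of that replicate), or a single numeric vector for one
#'   replicate.
#' @return List with `replicate_means` (numeric vector), `mean`, and `sd`
#'   (`NA` with a single replicate).
#' @export
aggregate_fields <- function(field_rates) {
  if (is.numeric(field_rates)) field_rates <- list(field_rates)
  if (any(lengths(field_rates) == 0L)) {
    stop("empty replicate: every replicate needs >= 1 field")
  }
  rep_means <- vapply(field_rates, mean, numeric(1))
  list(replicate_means = rep_means,
       mean = mean(rep_means),
       sd = if (length(rep_means) > 1L) stats::sd(rep_means) else NA_real_)
}

#' Beta-galactosidase activity in Miller units
#'
#' `MU = (OD420 * 1000) / (V * t * OD600)` with reaction volume `V` in mL
#' and reaction time `t` in minutes; reports receptor-pathway activation in
#' the reporter assay.
#'
#' @param od420 Absorbance at 420 nm (>= 0).
#' @param od600 Culture absorbance at 600 nm (> 0).
#' @param volume_ml Reaction volume in mL (> 0).
#' @param time_min Reaction time in minutes (> 0).
#' @return Miller units (vectorized).
#' @examples
#' miller_units(od420 = 0.5, od600 = 5, volume_ml = 0.2, time_min = 30)
#' @export
miller_units <- function(od420, od600, volume_ml, time_min) {
  if (any(od600 <= 0) || any(volume_ml <= 0) || any(time_min <= 0)) {
    stop("od600, volume_ml and time_min must all be positive")
  }
  if (any(od420 < 0)) stop("od420 must be non-negative")
  (od420 * 1000) / (volume_ml * time_min * od600)
}

#' Lag time of a growth curve
#'
#' Time (minutes) at which a growth curve first reaches a defined OD600
#' threshold, linearly interpolated between the bracketing samples; 0 when
#' the curve starts at or above the threshold; `NA` when the threshold is
#' never attained ("not reached").
#'
#' @param times_min Strictly increasing time vector (minutes), length >= 2.
#' @param od600 OD600 measurements, same length.
#' @param threshold OD600 threshold (default 0.5).
#' @return Lag time in minutes, or `NA_real_` if not reached.
#' @export
lag_time <- function(times_min, od600, threshold = 0.5) {
  stopifnot(length(times_min) == length(od600), length(times_min) >= 2L)
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (od600[1L] >= threshold) return(0)
  hit <- which(od600 >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  j <- hit[1L]
  i <- j - 1L
  times_min[i] + (threshold - od600[i]) *
    (times_min[j] - times_min[i]) / (od600[j] - od600[i])
}

#' Mating-rate profile across a pH gradient
#'
#' Summarizes per-pH replicate mating rates as mean and sd and reports the
#' pH of maximal mean rate; ties on the maximum are broken toward the
#' lower pH.
#'
#' @param rates_by_pH Named list: names are pH values, elements numeric
#'   vectors of replicate rates (>= 2 pH levels).
#' @return List with `profile` (data.frame `pH`, `mean`, `sd`, `n`) and
#'   `argmax_pH`.
#' @export
ph_mating_profile <- function(rates_by_pH) {
  if (length(rates_by_pH) < 2L) stop("need >= 2 pH levels")
  ph <- as.numeric(names(rates_by_pH))
  if (any(is.na(ph))) stop("list names must be numeric pH values")
  ord <- order(ph)
  ph <- ph[ord]
  rates_by_pH <- rates_by_pH[ord]
  prof <- data.frame(
    pH = ph,
    mean = vapply(rates_by_pH, mean, numeric(1)),
    sd = vapply(rates_by_pH, function(x) {
      if (length(x) > 1L) stats::sd(x) else NA_real_
    }, numeric(1)),
    n = lengths(rates_by_pH),
    row.names = NULL)
  list(profile = prof, argmax_pH = ph[which.max(prof$mean)])
}

#' Multiplicative expectation for a double mutant's mating rate
#'
#' Null model for epistasis: if two substitutions act independently, their
#' combined effect is the product of their relative effects,
#' `expected = m_wt * (m_a / m_wt) * (m_b / m_wt)`, clipped to \[0, 100\].
#' Observed rates above this expectation indicate positive (buffering)
#' epistasis.
#'
#' @param m_a,m_b Single-mutant mating rates (percent, in \[0, 100\]).
#' @param m_wt Wild-type mating rate (percent, > 0).
#' @return Expected double-mutant mating rate (percent).
#' @export
expected_double <- function(m_a, m_b, m_wt) {
  stopifnot(all(m_a >= 0), all(m_a <= 100), all(m_b >= 0), all(m_b <= 100))
  if (any(m_wt <= 0)) stop("m_wt must be positive")
  pmin(pmax(m_wt * (m_a / m_wt) * (m_b / m_wt), 0), 100)
}

#' Classify rescue of a loss-of-function variant by a permissive partner
#'
#' A deleterious substitution is called rescued when its single-mutant
#' mating rate is near zero (below `null_floor`) while the double mutant
#' with the permissive partner reaches at least `rescue_min`. The default
#' floor (1%) and rescue threshold (3%) frame the restored range reported
#' for permissive-partner double mutants (roughly 3-9% from near-zero);
#' both are explicit conventions, configurable.
#'
#' @param single_rate Single-mutant mating rate (percent).
#' @param double_rate Double-mutant (with permissive partner) rate
#'   (percent).
#' @param null_floor Rate below which a single mutant counts as near-zero.
#' @param rescue_min Minimal double-mutant rate to call rescue.
#' @return `"rescued"` or `"not_rescued"` (vectorized).
#' @export
classify_rescue <- function(single_rate, double_rate, null_floor = 1,
                            rescue_min = 3) {
  stopifnot(all(single_rate >= 0), all(single_rate <= 100),
            all(double_rate >= 0), all(double_rate <= 100))
  ifelse(single_rate < null_floor & double_rate >= rescue_min,
         "rescued", "not_rescued")
}

#' Summarize a microscopy count table
#'
#' Convenience wrapper over [mating_rate()] and [aggregate_fields()] for a
#' long-format count table with columns
#' `genotype, condition, replicate, field, V, Z, A, S`.
#'
#' @param counts Data.frame in the long format above (e.g. from
#'   `read.delim`).
#' @return Data.frame with one row per genotype x condition:
#'   `genotype, condition, n_replicates, mean, sd`.
#' @export
summarize_mating_counts <- function(counts) {
  required <- c("genotype", "condition", "replicate", "field",
                "V", "Z", "A", "S")
  if (!all(required %in% names(counts))) {
    stop("count table must have columns: ", paste(required, collapse = ", "))
  }
  counts$rate <- mating_rate(counts$V, counts$Z, counts$A, counts$S)
  keys <- unique(counts[, c("genotype", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- counts[counts$genotype == keys$genotype[i] &
                    counts$condition == keys$condition[i], ]
    agg <- aggregate_fields(split(sub$rate, sub$replicate))
    data.frame(genotype = keys$genotype[i], condition = keys$condition[i],
               n_replicates = length(agg$replicate_means),
               mean = agg$mean, sd = agg$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
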