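---
title: "Models and methods behind matefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind matefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matefit)
```

# The experimental system

`matefit` analyses pooled competition assays of the fission-yeast mating
pheromone M-factor, a nine-residue farnesylated peptide (mature sequence
`YTPKVPYMC`). A panel of homothallic (*h90*) strains — the wild type plus
every single amino-acid substitution at the eight non-cysteine residues,
152 variants and 153 genotypes in all — is pooled at equal abundance and
put through repeated mating–germination cycles: mating and sporulation on
solid medium, ethanol killing of unmated vegetative cells, and spore
outgrowth in rich medium. Because only mated cells contribute spores to
the next cycle, a genotype's frequency trajectory integrates its mating
efficiency under the chosen condition (medium, pH, temperature). Genotype
abundance is read out by amplicon sequencing: each variant is identified
by the 24-bp stretch of the pheromone gene encoding the eight variable
residues, located immediately downstream of the constant `AAGAAT` motif in
75-bp reads.

The package provides the full desk side of this workflow: library
enumeration and barcoding, a forward simulator that generates FASTQ reads
with the statistical structure the analysis assumes, motif-anchored
demultiplexing, enrichment statistics, predictors linking pooled outcomes
to single-strain mating efficiencies, and the single-strain assay
formulas (microscopy mating rate, Miller units, growth lag) together with
the double-mutant buffering analysis.

# Selection model

Selection is modelled as cell-autonomous and multiplicative. If genotype
$i$ has frequency $f_i$ and mating efficiency $m_i \in [0,1]$ under the
current condition, one mating–germination cycle updates

$$f_i' = \frac{f_i\, m_i}{\sum_j f_j\, m_j},$$

so after $T$ deterministic cycles
$f_i(T) \propto f_i(0)\, m_i^T$. The cell-autonomy assumption rests on two
facts about the system: the *h90* background gives every genotype the same
receptor context (each clone alternates between producing and receiving
the pheromone), and *S. pombe* cannot mate using exogenous pheromone
alone, so a variant's success is primarily determined by its own
signalling capacity rather than by partner-choice dynamics. No
frequency-dependent pairing term is included.

The non-mating control regime (serial passage on rich medium without
ethanol selection) instead applies
$f_i' \propto f_i\, w_i^{g}$ with $w_i$ the vegetative relative fitness
per generation and $g$ the generations per passage (default 8, roughly the
outgrowth implied by diluting to a low density and growing to saturation
over two days). Germination and outgrowth between mating cycles are
treated as fitness-neutral; $w$ acts only in the non-mating regime.

Between cycles the population passes a bottleneck: frequencies are
resampled multinomially at `drift_cells` cells (default $1.53 \times
10^7$, i.e. $10^5$ cells per genotype at assembly). Setting
`drift_cells = NULL` gives the deterministic closed form, which the test
suite verifies to $10^{-12}$ relative error against independent evaluation
of $f_i(0) m_i^T$.

## pH-response profiles

Per-variant mating efficiency is a function of pH with three supported
shapes: flat ($m = m_{\max}$), alkaline-activated
($m = m_{\max}\,\mathrm{logistic}((\mathrm{pH} - \mathrm{pH}_{mid})/s)$),
and the mirrored acid-activated form. Presets encode the qualitative
classes seen in the panel:

* `WT-like` / `Y7W-like`: flat, $m_{\max} = 0.6$ — pH-insensitive, high
  efficiency.
* `P6H-like`: alkaline, $m_{\max} = 0.55$, midpoint pH 6.5, width 0.3 —
  near-sterile at the standard pH 5.5 ($m \approx 0.02$), about half of
  cells mating at pH $\ge 7.5$.
* `P6D-like`: acid, $m_{\max} = 0.65$, midpoint pH 5.2, width 0.45 —
  the highest efficiency of the panel at pH 4–5, more than two-fold above
  its own pH 5.5 level, and near-sterile at pH $\ge 6.5$.
* `T2Q-like`: flat $m_{\max} = 0.75$ with $w = 0.95$ — the
  antagonistic-pleiotropy class: better mating, slower vegetative growth
  (a prolonged lag phase in rich medium).
* `impaired`: flat $m_{\max} = 0.05$, for the C-terminal substitutions
  that lose most signalling activity; `dead`: $m = 0$.

These numbers are the simulator's ground truth, chosen once to reproduce
the qualitative phenotype classes; they are not fitted to any dataset.
`default_fitness_profiles()` assigns them across the 153-genotype panel;
`recapitulation_profiles()` builds the minimal contrast scenario (one
alkaline-activated variant, one acid-activated variant, 151 flat).

# Read simulation

Each sequenced sample draws genotype counts from one multinomial at the
population frequencies, then builds one 75-bp read per draw: random pad,
`AAGAAT` anchor, 24-nt barcode, random pad. The anchor offset is uniform
over all feasible positions, so downstream code must locate the motif
rather than slice at a fixed coordinate. Pads are rejection-sampled so
they never introduce a motif occurrence upstream of (or in addition to)
the intended anchor. Substitution errors are applied independently per
base at `error_rate` (default $10^{-3}$, a typical well-calibrated
short-read error rate); indels, PCR bias, paired ends and quality-score
variation are deliberately out of scope. Barcodes are built from a
deterministic one-codon-per-amino-acid table (high-usage *S. pombe*
codons, shipped as `extdata/spombe_codons.tsv`), giving each genotype a
unique 24-mer; variants differing at one residue differ in at most three
adjacent bases.

All randomness flows from a single root seed through deterministic
per-stage derived seeds, so identical configurations give byte-identical
FASTQ output. The hot loops (read assembly, exact demultiplexing) are
implemented in C++ via Rcpp and use R's RNG, preserving seed
reproducibility; deep samples are generated and counted in multinomial
chunks so memory stays flat at any depth.

# Demultiplexing

A read is assigned by taking the 24 bases following the *first* `AAGAAT`
occurrence and looking them up exactly in the library index. Reads
without the motif, with fewer than 24 downstream bases, or with an
unknown 24-mer count as `unmatched`; counts always satisfy
matched + unmatched = total. Exact matching is the default because
library barcodes can differ by a single nucleotide, so any mismatch
tolerance risks systematic misassignment; an optional Hamming-distance-1
rescue mode exists but reports its assignments separately and never
merges them into the exact counts. `N` bases match nothing. A
sequencing-depth floor (default 400,000 matched reads per sample) flags
shallow samples without dropping them.

## The barcode crosstalk floor

Exact matching has one unavoidable consequence worth knowing about. With
per-base error rate $e$, a read from genotype $j$ whose barcode is a
1-nt neighbour of genotype $i$'s converts into a perfect $i$ barcode with
probability $\approx e/3$ per neighbouring position. Summed over
neighbours, this puts a floor of roughly $10^{-5}$ (at $e = 10^{-3}$,
with a handful of abundant neighbours) under the observed frequency of
even a completely absent variant. The floor inflates the matched
fraction slightly above the error-free-window expectation $(1-e)^{30}$,
compresses very large negative log2 fold changes, and — most importantly
for inference — dominates the replicate-to-replicate variance of
absent variants' frequencies, because the converted counts are Poisson.
No exact-match pipeline can remove it (an error-converted read is
indistinguishable from a real one); the package's design response is the
depth analysis below.

# Enrichment statistics

Counts are converted to frequencies per sample with a symmetric
pseudocount (default 0.5) so that log-ratios are defined for zero-count
genotypes: $f_{ig} = (n_{ig} + q)/\sum_j (n_{jg} + q)$. Selection is
summarized per variant as
$\log_2(f_{end}/f_{start})$ within each biological replicate (replicate
$k$ paired with replicate $k$; no cross-pairing), then reported as mean
± sd across replicates. Condition effects are expressed the same way
against the reference condition (pH 5.5) at the same cycle, reference in
the denominator.

Biological replicates are the unit of inference throughout — microscopy
fields are averaged within a replicate before any test, and read counts
never enter a test directly. Significance per variant comes from a
two-sided Welch (unequal-variance) $t$ test comparing the per-replicate
$\log_2$ frequencies under the test condition against those under the
reference; with $n = 3$ replicates per group this leaves roughly 2–4
Satterthwaite degrees of freedom. P-values are adjusted across variants
with Benjamini–Hochberg by default (Holm and Bonferroni are available;
the adjustment method is a documented convention, as is BH itself). The
volcano rule calls a variant enriched when its mean log2 fold change is
at least 2 (i.e. $\ge$ 4-fold, boundary inclusive) with adjusted
$p < 0.05$, depleted symmetrically, otherwise neutral.

## Sequencing depth for the recapitulation experiment

The synthetic recapitulation check asks the pipeline to rediscover an
alkaline-activated variant at pH 7.0 vs 5.5 and an acid-activated variant
at pH 4.0 vs 5.5, with zero false enriched calls among 151 flat variants.
Its depth is a designed quantity. With only 1–2 true positives among 153
variants, the BH threshold at rank 1 is $0.05/153 \approx 3.3 \times
10^{-4}$; with $\approx 2$ degrees of freedom that requires
$|t| \gtrsim 40$. The limiting variance is the Poisson noise of the
focal variant's reference-condition counts, which sit at the crosstalk
floor ($\approx 10^{-5}$ of matched reads). Requiring the expected raw
$p$ to clear the threshold with a several-fold margin gives a
final-cycle depth of $1.2 \times 10^7$ reads per sample, which the
acceptance checks use; the default generator configuration keeps the
screen's own working depth of $4 \times 10^5$ reads per sample. Problem
sizes elsewhere: the closed-form equivalence suite uses panels of up to
10 genotypes over up to 10 cycles (100 seeded draws); demultiplexing
accuracy is measured at $10^5$ reads; mating-efficiency recovery at
$10^6$ reads per sample over 5 cycles.

# Predicting pooled outcomes from single-strain efficiencies

`predict_frequencies()` evaluates the closed form
$f_i(T) \propto f_i(0) m_i^T$ (with $0^0 = 1$), the theoretical
expectation for pooled outcomes given individually measured mating
efficiencies; `infer_efficiencies()` inverts it,
$\hat m_i = (f_T/f_0)^{1/T}$ rescaled to a reference variant (wild type
by default). Agreement between observed and predicted frequencies is
assessed with Pearson's $r$, reporting $R^2$. Inference degrades
gracefully with depth: a variant whose final frequency falls below about
$10^{-4}$ at $10^6$ reads carries fewer than ~100 reads and (because of
the $1/T$ root) still recovers its relative efficiency to a few percent,
but below the crosstalk floor the estimate reflects the floor, not the
variant.

# Single-strain assay formulas

* Mating rate (%) from microscopy counts of vegetative cells (V),
  zygotes (Z), asci (A) and free spores (S):
  $(2Z + 2A + 0.5S) \times 100 / (V + 2Z + 2A + 0.5S)$ — zygotes and asci
  each derive from two mated cells; a free spore weighs half a cell.
  Fields (nine per plate by convention) are averaged within a replicate
  first; replicate means are compared across genotypes.
* β-galactosidase reporter activity in Miller units:
  $(\mathrm{OD}_{420} \times 1000)/(V_{mL} \times t_{min} \times
  \mathrm{OD}_{600})$.
* Growth lag: the time a growth curve first reaches
  $\mathrm{OD}_{600} = 0.5$, linearly interpolated between bracketing
  samples, 0 if the curve starts above threshold, `NA` ("not reached") if
  it never attains it.
* pH profiles tabulate per-pH replicate means ± sd and report the argmax
  pH, ties broken toward the lower pH (a documented convention).

For the double-mutant buffering analysis, no quantitative epistasis
statistic is standard in this assay, so the package makes its conventions
explicit and configurable: the expected double-mutant rate under
independence is multiplicative,
$m_{ab} = m_{wt} (m_a/m_{wt})(m_b/m_{wt})$ clipped to [0, 100], and a
loss-of-function variant counts as rescued by a permissive partner when
its single-mutant rate is below 1% while the double mutant reaches at
least 3% — thresholds framing the "restored from near-zero to a few
percent" regime that motivates the analysis.

# What the simulator does and does not emulate

The generator reproduces the features the analysis actually relies on:
equal starting frequencies, cell-autonomous multiplicative selection,
multinomial bottlenecks and read sampling, the motif + barcode read
layout at random offsets, uniform substitution errors, and seedable
determinism. It does not emulate PCR amplification bias (a per-variant
multiplicative bias hook exists conceptually but is not modelled),
indels, quality-score structure, chimeric reads, mating-type switching
dynamics, diploid intermediates, or partner-choice/frequency-dependent
mating. Passing the synthetic checks therefore demonstrates that the
statistical machinery is correct under the stated model — not that real
screens are free of the biases above. In particular, real data can show
variant-specific technical biases that this model would not flag.

# Numerical and interface conventions

Frequencies are validated to sum to 1 within $10^{-9}$ on entry and
$10^{-12}$ in trajectories; extinction (all $f_i m_i = 0$) is an error,
not a silent NaN. The Welch test handles the degenerate case of two
constant equal groups ($t = 0$, $p = 1$) that arises when both conditions
sit at the pseudocount floor. All tables are TSV with headers (library,
sample manifest, counts with `unmatched`/`total_reads` rows, enrichment
results); FASTQ is four-line, optionally gzipped; configurations are
YAML with per-stage sections, overridable from the command line
(`section.key=value`), and every run writes a JSON manifest with the
config echo, seed, versions and input checksums. The variant naming uses
mature-peptide coordinates (`P6H`); precursor coordinates add a constant
offset of +30 (`mfm1-P36H`).

# Known limitations

* The crosstalk floor bounds how deep a depletion can be measured and
  adds variance to absent variants; depth must be budgeted for it.
* With three replicates the Welch test is heavy-tailed (df ≈ 2);
  genuinely significant calls need large effect sizes or tight
  replicate agreement, which is the regime the assay operates in.
* Exact matching discards all reads with any error in the 30-nt
  motif+barcode window (~3% at $e = 10^{-3}$); this costs depth, not
  accuracy.
* The multiplicative epistasis null and the rescue thresholds are
  conventions; conclusions sensitive to them should be checked across a
  range of thresholds.
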