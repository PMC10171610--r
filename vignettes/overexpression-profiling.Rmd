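---
title: "Methods: pooled overexpression profiling and knockout fitness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled overexpression profiling and knockout fitness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oeprof)
```

# The experimental design being modelled

A genome-wide pool of yeast strains, each overexpressing one gene from a
multicopy plasmid, competes through serial passages: the saturated culture
is diluted 1:250 into fresh (usually stressful) medium and regrown to
saturation, which corresponds to about `log2(250) ≈ 7.97` bulk doublings
per passage. Plasmid inserts are sequenced from the initial pool and after
n passages. A strain whose overexpressed gene improves fitness under the
stress increases its share of the pool multiplicatively every generation,
so after a few passages it dominates the reads. The analysis problem is to
turn read alignments into per-gene occupancies, decide which enrichments
are real, and quantify whether independent replicate cultures agree beyond
chance. A complementary design competes a barcoded knockout collection
across media (rich medium, salt, salt + calcium) and asks which knockouts
lose fitness condition-specifically.

# The competition model

Strain abundances evolve in two alternating steps per passage.

**Deterministic growth.** With per-strain relative fitness $w_i$ (1 =
neutral) and $g$ doublings per passage, the expected post-growth share of
strain $i$ is
$$s_i = \frac{n_i\,2^{g w_i}}{\sum_j n_j\,2^{g w_j}}.$$
Growth-to-stationary is modelled as exactly $g = \log_2(1/\text{dilution})$
bulk doublings — no lag or stationary-phase kinetics — because that is the
only generation accounting the passage design itself pins down, and the
sampling times are expressed in those units.

**Stochastic bottleneck.** The dilution carries `initial_cells` cells into
the next passage, drawn multinomially from the shares $s_i$. The real
bottleneck census is not reported for this kind of experiment, so
`initial_cells` is an explicit free parameter; the default $10^6$ keeps
genetic drift per passage (CV $\approx 1/\sqrt{n_i}$ per strain) small
relative to the selection differentials of interest ($w \ge 1.3$ produces
$>$ 5-fold enrichment per passage). Setting `initial_cells = Inf` switches
to expectation mode (no drift), which is what the closed-form tests use.

**Spontaneous adaptive mutants.** With `mutation_rate` $> 0$, each cell
founds, with that per-passage probability, a lineage carrying
$w_i + \texttt{mutation\_bonus}$ thereafter. This models the background
adaptation that produces replicate-specific sweeps unrelated to the
plasmid insert — the reason the analysis insists on replicate overlap.
Mutations are per-lineage fitness bonuses applied at passage boundaries,
not sequence-level events; that is sufficient to reproduce the confound's
statistical signature (a single replicate shows a convincing hit that no
other replicate reproduces).

**Sequencing.** Reads are a multinomial draw of `read_depth` reads with
weight $\propto$ abundance $\times\, e^{-\lambda L_i}$, where $L_i$ is the
insert length and $\lambda$ (`length_bias_rate`, per bp) reproduces the
empirical under-detection of long inserts. $\lambda = 0$ (the default)
gives unbiased sampling. The weights are rescaled relative to the shortest
insert before exponentiation so multi-kilobase inserts cannot underflow.

The generator emulates: the ~5,751-strain pool size, 1:250 passaging with
~8 generations per passage, per-strain fitness per condition, multinomial
bottleneck and sequencing noise, length-biased detection, and rare
adaptive mutants. It does **not** emulate: plasmid copy-number dynamics or
loss, sequence-level read structure (no FASTQ), chimeric alignments,
cross-contamination, or density-dependent growth. Passing synthetic
benchmarks therefore demonstrates the statistical machinery under the
model's assumptions, not robustness to every artefact of real long-read
screens.

# Quantification

Reads (BED intervals, 0-based half-open throughout) are assigned to insert
loci when they share a chromosome and the overlap covers at least half of
the **locus** length — the semantics of interval intersection with a
minimum fraction of the target feature. The threshold is inclusive
($\ge$), strand is ignored, and a read covering two adjacent loci at
$\ge 50\%$ each counts for both; such reads are rare for multi-kb insert
loci. Counts become occupancies in reads per million,
$\mathrm{RPM}_i = 10^6\, c_i / \sum_j c_j$, where the denominator is reads
assigned to any locus: the analysis universe is the insert set, not the
whole genome. A sample with no assigned reads is an error naming the
sample, not a silent zero.

The length-bias diagnostic reports the per-sample Pearson correlation
between insert length and read count, with a one-sided p-value for
negative correlation, and flags the result undefined (rather than
crashing) when lengths or counts are constant. No length *correction* of
fold changes is applied: because the same insert appears in numerator and
denominator, the fold change cancels any multiplicative, time-invariant
detection bias, and that cancellation is the method's own bias-reduction
step. A regression-based correction was considered and rejected as
unsupported by the described method.

# Hit calling

Per replicate, the fold change is
$\mathrm{FC}_{n,i} = \mathrm{RPM}_{n,i} / \mathrm{RPM}_{0,i}$. Genes with
zero baseline RPM have no defined fold change and are excluded from
testing rather than pseudocounted — the quantity of interest is enrichment
relative to the initial pool, which is undefined for a strain never
observed there. Genes dropping to zero get $\mathrm{FC} = 0$,
$\log_2\mathrm{FC} = -\infty$.

Each tested gene gets a 1-df Pearson chi-square on the 2×2 table
[[gene, others] before; [gene, others] after] — the composition that uses
exactly the before/after appearance ratio plus the count data. The exact
table composition is an adopted interpretation; Yates' correction is off
by default (all counts are large) and available as a sensitivity switch.
P-values are BH-adjusted **per replicate across its tested genes**, and a
hit requires $\log_2\mathrm{FC} \ge 5$ **and** FDR $\le 0.05$, both
inclusive. Numerically, chi-square tail probabilities are clamped at the
smallest positive double before adjustment: a selective sweep produces
statistics far past the point where the tail underflows to exactly zero,
and downstream code treats p-values as strictly positive.

A neutral pool cannot produce hits under these thresholds at realistic
depth: a 32-fold RPM rise from multinomial noise around hundreds of reads
per gene is effectively impossible, which the null-calibration tests
confirm (zero hits in ≥ 99/100 seeded neutral screens).

# Replicate overlap and diversity

The permutation test redraws each replicate's hit set uniformly without
replacement from the universe, preserving the per-replicate hit counts,
and compares the observed number of genes hit in exactly $k$ of $R$
replicates to the null distribution (one-sided, default 10,000
permutations). Categories are "exactly k", matching the 1/4 … 4/4
presentation of results; an "at least k" variant is available. The
universe defaults to the genes testable in that experiment (non-excluded),
since hits can only arise there; it is overridable. The p-value is the
plain exceedance proportion; when no permutation reaches the observed
count it is reported as an upper bound $< 1/n_\text{perm}$, with an
optional $(b+1)/(m+1)$ estimator. For $R = 2$ the exactly-2 null is
hypergeometric, which the tests use as a closed-form oracle; for null-drawn
hit sets the p-values are verified super-uniform over 500 simulated
datasets.

One subtlety: for *disjoint* hit sets the exactly-1 count sits at its
ceiling, so its p-value equals the null probability of complete
disjointness — close to 1 only when the universe dwarfs the hit sets. The
p = 1.00 seen for the exactly-1 category in well-powered screens arises
differently: strong multi-replicate overlap pushes the observed singleton
count *below* its null expectation, and the one-sided test returns 1. The
structured-hit-set test reproduces exactly this.

Pool diversity is tracked with the Gini–Simpson index
$D = 1 - \sum p_i^2$ (0 for one strain, $1 - 1/N$ at uniformity), which
declines monotonically in expectation through a sweep.

# Knockout fitness Z-scores

Per replicate, $x_i = \log_2(\mathrm{RPM}_{\text{after},i} /
\mathrm{RPM}_{\text{before},i})$ over genes detected in both samples, and
$z_i = (x_i - \bar x)/s_x$ with the sample (n−1) standard deviation. The
log-ratio is standardised rather than the raw ratio: the raw ratio is
heavy-tailed and produces asymmetric Z distributions inconsistent with the
near-symmetric ones this analysis expects; a raw-ratio switch exists.
Genes with zero counts in either sample are dropped from that replicate.
If all fold changes are equal the replicate is degenerate: all z = 0,
flagged, rather than an error.

The between-condition screen runs Welch's t-test per gene on the replicate
Z-vectors, implemented in closed form (Welch–Satterthwaite df) so it
vectorises across thousands of genes, BH-adjusts across genes, and passes
genes with FDR $\le 0.05$ and $\Delta Z = \bar z_A - \bar z_B \le -1$
(both inclusive). The magnitude filter matters: with triplicates the
t-test alone is noisy, and the $|\Delta Z| \ge 1$ requirement anchors the
screen to effects of at least one standard score. Classification into
Group I ($Z_{\mathrm{Na}} - Z_{\mathrm{YPD}} \ge 1$: slow in rich medium,
unchanged under salt) and Group II ($\le -1$: impaired under salt, rescued
by calcium) uses inclusive thresholds and can be restricted to a gene
subset (e.g. mitochondrial genes).

In the synthetic knockout screen, per-gene baseline fitness jitter
(`fitness_sd`, default 0.02) is drawn once per gene and shared across
conditions; planted effects are expressed in units of that jitter's
standard deviation (`effect_z`, default 2). Because the jitter is a gene
property, it cancels from between-condition contrasts, which is exactly
why the paired design detects condition-specific effects far smaller than
the gene-to-gene fitness spread.

# Growth rates

The growth rate (1/hour) is the OLS slope of $\log_2 \mathrm{OD}_{660}$
on time over readings with $0.125 \le \mathrm{OD} \le 0.500$, bounds
inclusive — the reciprocal of the mean doubling time. If noise carries the
culture through the window more than once, all in-window points are used.
A culture whose OD never strictly exceeds 0.125 within the first 48 h is
"not detected" (N.D); a detected culture with fewer than two in-window
points raises a distinct "insufficient window" error. The estimator is
exact on noiseless exponentials for any rate in [0.05, 2] /h and is
time-shift invariant; it is deliberately *not* invariant to rescaling the
OD axis, since the window is absolute.

# Problem sizes and runtime choices

The test suite runs everything at sizes a laptop handles in a couple of
minutes, chosen as the smallest scales at which each statistical claim is
still sharp: full 5,751-strain pools for the sweep and spike-recovery
benchmarks ($10^6$-cell bottlenecks, $10^6$ reads); 1,200-gene pools for
the 100-seed neutral-screen calibration; 600-gene knockout screens with
40 + 40 planted genes; 500 null datasets × 300 permutations for the
overlap super-uniformity check; 1,000 fuzzed instances (≤ 200 reads × 50
loci) for the interval-assignment oracle. Every stochastic operation takes
an explicit seed and restores the caller's RNG state.

# Known limitations

* The simulator's bottleneck census is a free parameter; inference about
  drift magnitude in real screens is outside scope.
* The chi-square composition (focal gene vs rest) is an interpretation of
  an ambiguous description; the sensitivity switch and the permutation
  machinery do not depend on it.
* Fold-change hit calling conditions on detection in the initial pool;
  genes absent there are unreportable by design.
* The knockout screen model plants additive fitness effects; epistasis,
  barcode swapping and PCR jackpots are not modelled.
* No multiple-pool normalisation beyond RPM is implemented; batch effects
  between pools must be handled by the replicate structure.
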