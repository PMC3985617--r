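---
title: "Models and methods behind dualmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dualmark` quantifies the engineering of dual selectable markers — genes
like *E. coli* `tolC` that support both a positive selection and a
counter-selection — for repeated selection/counter-selection cycling in
multiplex genome engineering. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

## 1. The per-cycle allele-conversion model

One CoS-MAGE cycle leaves each clone with a random subset of the `L`
targeted loci converted. `dualmark` models the *next* cycle's gains as an
independent, identically distributed draw from a per-cycle conversion
distribution, OR-ed onto the current genotype:

* conversions accumulate monotonically (an allele, once converted, never
  reverts — recombineering does not undo an edit at a converted locus);
* cycles are exchangeable (no cycle-to-cycle drift in recombination
  efficiency, no fitness differences among genotypes);
* no escape-mutation process is modelled inside the cycling simulator
  (escape is handled by the other modules).

Three distribution modes are available:

* `empirical_pattern` — resample whole observed clone-by-locus patterns
  from a genotyped single-cycle population. This preserves any locus
  correlation present in the data.
* `empirical_count` — resample only the per-clone conversion *counts* and
  place them uniformly among loci. This deliberately drops positional
  dependence between loci.
* `parametric_zib` — a zero-inflated binomial (ZIB) count distribution,
  again placed uniformly.

The count modes are the default because the uniform-placement assumption
("no positional dependence") is the minimal model when only population
summaries are available; whether a real population was resampled by
pattern or by count is unknowable from summaries alone, so both are
provided and neither is privileged in tests beyond their own contracts.

### ZIB calibration

Published single-cycle results are typically two numbers: the mean edits
per clone `m` and the unmodified fraction `P0`. A plain binomial on `L`
trials cannot match both (the printed pairs are over-dispersed: e.g.
`m = 2.87`, `P0 = 0.096` on `L = 10` implies a binomial `P0` of only
`(1 - 0.287)^10 ≈ 0.035`). The ZIB is the minimal two-parameter
extension: with probability `pi` a clone gains nothing, otherwise its
count is Binomial(`L`, `p`). `fit_conversion_model()` solves

$$(1-\pi)Lp = m, \qquad \pi + (1-\pi)(1-p)^L = P_0$$

by eliminating `p` and bisecting on `pi` over `[0, 1 - m/L]`; the
residual of the zero-fraction equation is driven below `1e-8` (200
bisection steps, interval tolerance `1e-10`). The pair is feasible iff
`(1 - m/L)^L <= P0 <= 1 - m/L`; infeasible input raises an error naming
the violated bound. Degenerate input `m = 0` requires `P0 = 1` and
returns `pi = 1, p = 0`. A documented limitation: only the mean and the
zero mass are matched — the upper tail (clones with many edits per cycle)
is whatever the ZIB implies, and may deviate from an observed population.

`simulate_trajectory()` starts all-unconverted and records, per cycle,
the mean conversion count, the count histogram over `0..L`, and the
unmodified/fully-converted fractions. `apply_bottleneck()` subsamples
lineages without replacement, the sampling model for seeding a
counter-selection from a small inoculum: neutral in expectation
(hypergeometric) but diversity-collapsing in any one draw, which is why
small inocula often fix a single genotype.

All stochastic operations take explicit integer seeds (`withr::with_seed`
scoping; no global RNG state is disturbed), and `seed = NULL` means "use
the current stream" so composite simulations remain reproducible from a
single outer seed.

## 2. Growth-curve selection statistics

Kinetic selections are summarised by the first time a culture reaches
OD600 ≥ 0.4. `time_to_threshold()` interpolates linearly between the
bracketing readings — plate readers sample every few minutes, and real
crossing times are not on the sampling grid — and censors at the last
reading when the threshold is never reached.

The Normalized Selective Advantage of a selection is

$$\mathrm{NSA} = 1 - \frac{t^{RS}\,(t^{CNS}/t^{RNS})}{t^{CS}}$$

a ratio of ratios: the selective-media growth advantage of recombinants
over controls, normalised by the nonselective-media ratio to cancel
inoculum differences. It is scale-invariant (multiplying all four times
by a constant changes nothing), bounded above by 1, exactly 0 when the
selective and nonselective ratios coincide, and → 1 when controls never
grow in selection. Censored times enter at the horizon and set a flag:
when `t_CS` is censored the reported NSA is a conservative *lower bound*
on the true value.

Normalized Culture Time scores a candidate escape oligo between two
controls measured in the same counter-selection:

$$\mathrm{NCT} = \frac{t_{oligo} - t_{positive}}{t_{mock} - t_{positive}}$$

The affine normalisation was chosen because it reproduces every
qualitative anchor of the screen: exactly 0 when the oligo behaves like
the marker-knockout positive control, exactly 1 when it behaves like the
mock recombination, and values slightly outside `[0, 1]` are possible
(and observed in practice) when a culture grows faster than the knockout
or slower than the mock. The causal call threshold is 0.6 with a
borderline band `[0.6, 1)`; both are tunable. Degenerate controls
(`t_mock = t_positive`) are a hard error rather than a silent NaN.

`growth_delay()` is the paired difference of threshold times between
selective and nonselective cultures of the same clone, with an explicit
"No Growth" flag when the selective culture never crosses within its
window, and an optional conversion to doublings given a doubling time.
No growth-model fitting (logistic/Gompertz parameters) is attempted —
threshold times are the field's reporting unit here. OD smoothing is off
by default; `smooth_curve()` offers a window-3 moving median for spike
removal only.

## 3. Escape-frequency estimation

A plating experiment is `colonies / cells_plated`. Two reporting modes:

* **Single plating**: exact Clopper–Pearson 95% interval via the beta
  quantile form. At escape frequencies down to `1e-11`, colony counts are
  0 or 1 and Wald/normal intervals are meaningless; the exact interval
  still produces an informative upper bound (`≈ 3.69/N` at zero
  colonies).
* **Replicates**: mean of per-replicate frequencies ± SEM
  (`sd/sqrt(n)`), the convention for multi-replicate platings; a single
  replicate flags its undefined SEM instead of fabricating one.

`fold_reduction()` is a plain ratio of frequencies (with a lower bound
from the improved condition's upper confidence limit when its point
estimate is zero), and is transitive by construction. Reports round to 2
significant figures via `format_frequency()`. Under mechanistic
independence of two counter-selection agents, escaping both requires
escaping each, so `predicted_joint_escape()` multiplies the single-agent
frequencies and, given an observed joint frequency, reports the
observed/predicted deviation factor — departures from 1 quantify
non-independence.

No fluctuation analysis (Luria–Delbrück) is attempted: platings measure
escape *frequencies*, not mutation *rates*.

## 4. Diagnosing escape mutations from re-sequenced clones

The diagnosis pipeline consumes variant calls (a VCF v4.x subset per
clone), a single-chromosome reference FASTA, and a TSV gene table
(`name, start, end, strand, essential`). Coordinates are 1-based
inclusive at every interface (VCF convention); genome bins are half-open
from coordinate 0, with a boundary position falling in the right-hand
bin. Gene models must be disjoint with CDS lengths divisible by 3;
violations are errors naming the locus.

### Effect classification

`classify_cohort()` assigns each call to the gene that fully contains it
(anything else is `intergenic`) and classifies by codon arithmetic on the
coding strand (reverse complement for minus-strand genes), bacterial
genetic code (NCBI table 11). Precedence:

1. `start_lost` — the variant leaves the first codon outside the
   initiation set {ATG, GTG, TTG}. A substitution mapping one valid start
   onto another is *synonymous* (both initiate as Met). The rarer table-11
   starts (ATT/ATC/ATA/CTG) are not treated as valid initiation codons.
2. indels: `frameshift` if the net length change is not a multiple of 3,
   else `inframe_indel`;
3. `stop_gained`, then `stop_lost`, then `nonsynonymous`, then
   `synonymous` for substitutions, decided on the affected codon(s).

`start_lost`, `frameshift` and `stop_gained` count as loss of function
(LoF). The whole classifier is verified against an independent
translate-and-diff oracle (reconstruct the full mutant CDS, translate
both with Biostrings, derive the category from the protein difference and
length change) over tens of thousands of random SNVs, anchored indels and
short multi-base substitutions — the two routes must agree exactly.

One known caveat is deliberately *not* modelled: a premature stop early
in a CDS can be rescued by a downstream in-frame ATG, so a `stop_gained`
in the first quarter of a gene is weaker LoF evidence than the category
suggests. Modelling reinitiation would require expression data the
pipeline does not consume.

### Ancestral filtering, tallies and enrichment

Variants carried by more than half of the clones (`threshold_fraction =
0.5`, configurable) are strain-background, not escape-selected: a
variant present in ~55% of clones is far likelier to be a partially
fixed ancestral allele than an independently recurrent escape mutation.
They are reported separately and removed from causal analysis.

`tally_genes()` reports, per gene, Distinct Mutations (unique
`(pos, ref, alt)` keys), Total Mutations (distinct × incidence = number
of calls), genomes hit, and the LoF fraction of distinct mutations.
`gene_enrichment()` compares each gene's share of the scope's total
mutations against the share expected from coding length alone
(`length / total length`), with a one-sided exact binomial p-value and
Benjamini–Hochberg adjustment across the scope. The paper-style ranking
(distinct, then total, then LoF fraction, descending) is kept as the
primary ordering, with the test supplying calibrated evidence on top of
it; under a uniform-per-bp passenger null the p-values are approximately
uniform, which is verified in the test suite. `cohort_hit_fraction()`
gives the fraction of clones with at least one retained mutation in a
candidate gene set, and lists the complement — the clones whose escape
must use some rarer mechanism.

### Duplication-site selection

Duplicating the uptake operon protects against LoF escape only while both
copies persist. A single crossover between identical copies loops out one
arc of the circular chromosome, so `select_duplication_sites()` accepts a
candidate insertion point only if *each* of the two arcs between the
candidate and the source locus contains at least one essential gene —
then neither loop-out yields a viable cell. Candidates inside annotated
genes are rejected with the gene named.

## 5. What the synthetic data emulates — and what it does not

`gen_reference()` builds a circular genome of alternating-strand ORFs
with random spacers; every CDS translates to a stop-free, Met-led
protein, so classification on it is well-posed.

`gen_escape_clones()` emulates the structure of an escape cohort:

* each clone carries, with probability `causal_hit_prob` (default 0.93,
  matching a cohort where ~93% of clones had an uptake-operon hit), one
  causal mutation in a causal gene chosen proportionally to coding
  length; it is a LoF type with probability `causal_lof_bias` (default
  0.75, bracketing observed per-gene LoF fractions of ~0.63–0.87),
  otherwise a nonsynonymous SNV;
* Poisson(`passenger_rate`) passenger SNVs per clone, uniform per bp
  genome-wide — exactly the null hypothesis the enrichment test assumes,
  which is what makes null calibration on generated cohorts meaningful.
  The default rate of 30/clone reflects a mismatch-repair-deficient
  hypermutator background at full genome scale (~4.6 Mb); on the small
  toy genomes used in tests the rate is scaled to preserve either per-bp
  density or per-gene burden, stated per test;
* a fixed set of `ancestral_variants` SNVs (default 21) shared by every
  clone, placed outside causal genes so a positional collision cannot
  silently delete a planted causal mutation.

Frameshifts are generated as 1-bp deletions mid-gene, premature stops by
scanning for a codon one substitution away from TAA/TAG/TGA, start
losses by mutating the second base of the start codon (no single-base
change of A\[CGT\]G is a valid start).

`gen_growth_quartet()` produces the four curves feeding NSA from an
exponential-growth model with lag, OD saturation and Gaussian reading
noise. One parameterisation decision deserves emphasis:
**`resistant_fraction` is the escape fraction of the control
population** under the counter-selective agent — the quantity the
selection is trying to minimise. The control-selective culture grows
from a Binomial(`n0`, `resistant_fraction`) founder draw (expectation
optionally, for deterministic tests); the recombinant-selective culture
grows from `n0 * recombinant_fraction` (default 1). This is the reading
under which the quartet behaves like the assay: full escape
(`resistant_fraction = 1`) gives NSA ≈ 0, and a fraction so low that no
escaper lands in the inoculum leaves the control curve censored at the
horizon, pushing the NSA lower bound toward 1. An inoculum expectation
below one cell produces no growth — fractional founder cells do not
grow. Defaults: `n0 = 1e6` cells, doubling time 30 min, lag 60 min,
carrying OD 1.2, `od_per_cell = 1e-9` (OD 1 ≈ 1e9 cells/ml), noise SD
0.005 OD, horizon 2880 min (a 48-h kinetic course), 10-min sampling.

`gen_plating()` draws colony counts as Poisson(`f · N`): with `f·N`
small and `N` up to 1e10, the Poisson and binomial are indistinguishable
and the Poisson is cheap.

What passing tests on these generators does **not** show about real
data: no sequencing error or coverage model (variant calls are taken as
given), no oligo- or locus-specific conversion variance, no fitness
differences among genotypes, no over-dispersion of the passenger burden
beyond Poisson, and no structural variants. Conclusions about those
failure modes need real cohorts.

## 6. Numerical choices and test problem sizes

* Bisection tolerance `1e-10` on `pi`, residual guard `1e-8`; weights
  must sum to 1 within `1e-9`.
* Ties in enrichment ranking break by distinct, then total, then LoF
  fraction; equal on all three preserves input order.
* Degenerate inputs are errors, not NaNs: empty populations, non-monotone
  time vectors, `t_mock = t_positive`, zero baseline frequencies,
  mixed-agent pooling, out-of-range gene models, REF mismatches (with the
  position named).
* Test problem sizes were chosen to make Monte-Carlo tolerances sharp at
  interactive runtimes: 10 000 lineages for calibration round-trips
  (3-standard-error bands), 20 000 lineages against the exact L = 3
  enumeration oracle, 10 000 random variants against the translation
  oracle, 2 000 platings per frequency for interval coverage, ~25
  cohorts of 40 genes × 450 codons at passenger rate 120 for the
  enrichment null (per-gene expected counts near 280 keep exact-test
  discreteness well below the Kolmogorov–Smirnov 1% critical distance),
  and 40 seeds of a 12-gene genome for causal-gene recovery.

## 7. Known limitations

* The ZIB matches only the mean and zero mass of a cycle; multi-edit
  tail probabilities are unconstrained.
* Pattern mode preserves locus correlations but cannot extrapolate
  beyond observed patterns; count mode does the opposite.
* NSA from censored control cultures is a lower bound, not an estimate.
* The NCT normalisation is one defensible affine choice; other
  monotone normalisations would preserve the 0/1 anchors.
* The classifier evaluates one variant at a time: two same-clone variants
  in one codon are classified marginally, not jointly.
* The enrichment test conditions on the scope's total mutation count;
  it does not model clone-level correlation (e.g. one hypermutable clone
  contributing many passengers to one gene).
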