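---
title: "The bilateral-tumor repertoire model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bilateral-tumor repertoire model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bilatrep` analyzes bulk TCR-beta clone tables from a bilateral mouse
tumor design: the same tumor line grafted on both flanks, with the left
and right tumors (each cut into two fragments) and the left and right
tumor-draining lymph nodes (dLNs, CD44hi-sorted) sequenced per mouse.
This vignette explains the statistics the package computes, the model
behind its synthetic-data generator, the parameters that matter, and the
numerical and design choices a maintainer should know about.

## Clone definition and bookkeeping

A clone (clonotype) is the triple (TRBV segment, TRBJ segment, CDR3
nucleotide sequence); equality is exact textual equality of the three
fields after uppercasing the CDR3. All ingestion paths merge duplicate
keys by summing read counts, drop zero-count records, and recompute
frequencies as count over total reads — a file's frequency column is
never trusted, which protects downstream statistics from upstream
rounding. "Detected" always means at least one read after normalization.

Depth normalization follows the six-reads-per-cell convention: each
sample is downsampled without replacement (multivariate hypergeometric
over clones — reads are physical sequencing reads) to `6 × cell_count`
reads. A multinomial mode exists for simulation parity. Every stochastic
operation takes an explicit seed and restores the caller's RNG state, so
there is no hidden global state anywhere in the package; reruns are
byte-identical.

By default the read total of a sample must not be below its target;
`on_excess = "keep"` downgrades this to a logged warning and passes the
sample through unchanged, which is the pragmatic choice for shallow
samples whose depth already equals the target by construction.

## Repertoire indices

* **Clonality** is one minus Pielou evenness,
  $1 - H/\ln n$ with $H = -\sum_i p_i \ln p_i$ (natural logs). It is
  undefined below two clones and the package treats that as an error
  rather than returning a sentinel. Clonality is invariant under clone
  relabeling and uniform count scaling, which the test suite checks.
* **Morisita-Horn similarity** is computed from frequencies (the
  count-based and frequency-based forms are algebraically identical);
  values are clamped to [0, 1] against floating-point drift.
* **Overlap frequency**: the published one-line definition — the
  geometric mean of the frequencies within each sample — does not fix
  whether the geometric mean is taken per clone and then summed, or taken
  on the per-sample shared totals. The package defaults to the
  geometric mean of totals, $\sqrt{(\sum_A)(\sum_B)}$, and exposes
  `sum_of_geomeans` as an option; for highly similar samples the two
  nearly coincide (for identical samples both give 1), so figure-level
  conclusions are insensitive to the choice. Both are reported by
  `overlap()` objects.
* **V/J usage** is read-frequency weighted. PCA is centered but not
  variance-scaled (all features share the frequency scale), computed by
  SVD via `prcomp`; the union segment vocabulary is built across samples
  with absent segments entered as 0 rather than dropped. Because PCA
  signs are arbitrary, each component is oriented so its
  largest-magnitude loading is positive, making coordinates reproducible
  across runs and sample orders. Whether V and J usage should be analyzed
  separately or as one concatenated feature vector is genuinely open; the
  `space` argument (`"v"`, `"j"`, `"v_and_j"`, default concatenated)
  leaves it to the analyst.
* **Variance decomposition of clonality** across mice is an ordinary
  one-way ANOVA (between/within sums of squares, df, F, p); with four
  mice contributing left and right tumors the design gives df 3 between
  and 4 within. All-identical input makes F undefined and is reported as
  `NA` with a note, not an error.
* **Group tests** are two-sided Student's t: pooled variance for
  unpaired comparisons (matching the labeled test of common graphing
  software; Welch available via a flag), paired for ipsi/contra designs.
  Degenerate constant inputs with zero mean difference return t = 0,
  p = 1 instead of erroring, so symmetry fixtures behave.

## Differential clone expansion

For two samples with library-preparation cell counts $N_A$, $N_B$, every
clone in the union of key spaces (clones absent on one side enter at
frequency 0) is tested on the 2×2 table
$[\hat c_A, N_A - \hat c_A; \hat c_B, N_B - \hat c_B]$, where
$\hat c = \mathrm{round}(N \cdot p)$ is the estimated cell count
(half-up rounding — deterministic and unbiased over uniform frequency
grids; the rounding convention is not fixed by the published definition).
The two-sided Fisher exact p sums hypergeometric probabilities not
exceeding that of the observed table (the minimum-likelihood convention
of the common reference implementations, stated explicitly because
two-sided Fisher definitions vary). The implementation enumerates the
hypergeometric support directly with `dhyper`, which vectorizes cheaply
over clone universes of thousands of tables; `stats::fisher.test` serves
as an independent cross-check in the tests, alongside a `choose()`-based
full-enumeration oracle.

Fold change is computed on frequencies, not estimated counts; a clone
absent on one side has infinite fold change and passes the fold-change
criterion, so presence/absence calls rest on the q-value alone — this is
what "including clones detected only at one time point" requires. A clone
is labeled expanded at q < 0.01 and fold change > 2 (both thresholds are
arguments and echoed in the result metadata).

q-values default to Storey's method: $\hat\pi_0(\lambda)$ on the grid
0.05–0.95 (step 0.05), smoothed with a df-3 cubic smoothing spline and
evaluated at the grid maximum, then applied multiplicatively to
Benjamini-Hochberg step-up values. Below 50 p-values, or when the
$\pi_0$ estimate is non-positive, the method falls back to plain BH
(π0 = 1); the method actually used is always recorded. Forcing π0 = 1
reproduces BH exactly, which the tests assert.

## The synthetic generator

The generator encodes the proportional-infiltration picture: clones are
primed in the dLNs, mix in circulation, and seed both tumors evenly in
proportion to their circulating frequencies; dLN priming, not tumor
seeding, is what differs between sides. Per mouse:

1. **Priming.** Each of `n_reactive_clones` (500) tumor-reactive clones
   is primed in both dLNs with probability `p_dual_priming` (0.5), else
   on one side (left/right equally). Latent clonal expansions are
   log-normal with log-sd `expansion_lognormal_sigma` (2.0); for
   dual-primed clones the left/right log expansions share a Gaussian
   component giving log-scale Pearson correlation
   `dln_expansion_correlation` (0.4).
2. **dLN samples.** Each CD44hi dLN is the primed reactive clones plus
   `n_bystander_dln_clones` (20,000) private non-tumor-associated clones
   with log-normal masses, at their raw latent masses (no rescaling),
   read-sampled to `reads_factor × cells_per_dln_sample` (6 × 10,000)
   reads by multinomial draw. Bystander dLN clones never enter tumors —
   they model the antigen-experienced but tumor-irrelevant majority that
   dilutes left-right dLN overlap.
3. **Circulation.** Each reactive clone's circulating mass is the sum of
   its two dLN latent outputs.
4. **Tumors.** Each tumor receives every circulating clone at its
   circulating mass times a per-clone in-situ expansion factor shared by
   both tumors (log-normal, `tumor_insitu_shared_sigma` = 1.0) times
   per-tumor log-normal noise (`tumor_insitu_noise_sigma` = 0.3), plus
   `n_bystander_tumor_clones` (5,000) private local clones. Bystander
   masses are scaled so reactive clones hold
   `tumor_reactive_mass_fraction` (0.80) of the latent tumor mass — the
   single knob encoding how strongly in-situ expansion amplifies
   infiltrating tumor-reactive clones over passengers, calibrated to the
   reported ~80% share of reads carried by clones overlapping between
   bilateral tumors.
5. **Fragments.** Each tumor splits into two fragments via per-clone,
   per-fragment log-normal noise (`fragment_noise_sigma` = 0.15), each
   read-sampled to 6 × 10,000 reads.

Clone keys draw V segments from a per-mouse Dirichlet
(`v_usage_concentration` = 2), so V/J usage clusters by mouse in PCA; J
segments are uniform; CDR3s are in-frame concatenations of the 61 sense
codons (lengths 30–45 nt), so all emitted clones are productive, with the
amino-acid CDR3 given by standard-code translation. A
`public_clone_fraction` (0.01) of keys is drawn from a shared
cross-mouse pool of `n_public_pool` (1,000) keys, producing the weak
between-mouse sharing seen in real repertoires.

### Calibration and what the defaults produce

The priming and correlation defaults (0.5, 0.4) are calibration choices,
not measurements: no quantitative priming-sharing or
expansion-correlation values are available to fit, so they are set to
reproduce the reported left-right overlap levels within dLN-tumor
overlapping repertoires (~40% frequency-weighted, 20–40% by clone count)
through a specific mechanism — the share of dual-primed mass (2/3 at
p = 0.5) attenuated by finite-depth detection of the partner clone in the
opposite dLN, which is strong because reactive clones hold only a small
natural share of CD44hi dLN reads. Likewise `tumor_reactive_mass_fraction
= 0.80` directly encodes the reported ~80% within-mouse tumor overlap.
`tumor_insitu_shared_sigma = 1.0` decorrelates tumor frequencies from dLN
frequencies (shared between tumors, so it does not separate left from
right).

With all defaults (4 mice, 60,000 reads per sample), dataset-level
summaries land at: within-mouse tumor-tumor overlap frequency ~80%;
between-mouse tumor overlap and Morisita-Horn near zero; whole-dLN
left-right overlap ~1%; left-right share within dLN-tumor overlapping
repertoires ~35–55% across seeds (mean ~45%). One fragility is
documented deliberately: the *minimum* over four mice of the
within-mouse tumor Morisita-Horn fluctuates between ~0.78 and ~0.93
across seeds, because per-tumor in-situ noise (σ = 0.3) acting on a
repertoire whose top clone holds 15–25% of reads occasionally moves a
single dominant clone enough to pull one mouse below 0.9. The mean
within-mouse similarity is robustly high; the minimum is not a stable
statistic at n = 4, and the acceptance checks report it honestly rather
than tuning noise parameters down.

### What the generator does and does not emulate

It reproduces: private per-mouse key spaces with weak public sharing,
heavy-tailed clonal expansion (top-10 clones carrying a majority of
reads at 6 × 10⁴ depth), partial left-right priming overlap, proportional
infiltration with in-situ noise, fragment-level heterogeneity smaller
than between-mouse differences, and exact 6-reads-per-cell sampling. It
does not attempt: V(D)J recombination realism or germline-aware CDR3s,
thymic selection, TCR-alpha chains, UMI/error structure, or
treatment-induced repertoire changes. Passing tests on synthetic data
therefore establish the correctness and internal consistency of the
statistics and the qualitative structure of the bilateral design, not
biological conclusions about any real dataset.

## Numerical choices, degenerate inputs, tie-breaks

* Rank classes (top 10, 11–20, 21–40, 41–100, others) order clones by
  count descending with ties broken by CDR3nt, then V, then J —
  breakdowns are identical across runs regardless of input order.
* Empty repertoires are an error state for every statistic; the one
  deliberate exception is the dLN-tumor overlap filter, which returns an
  empty (flagged) repertoire when the intersection is empty.
* Frequencies must sum to 1 within 1e-9 after any construction;
  read/write round-trips preserve counts exactly and frequencies to
  1e-12 (frequencies are written at full precision and recomputed from
  counts on read).
* Fisher p-values use the customary `(1 + 1e-7)` relative tolerance when
  comparing table probabilities, guarding against ties lost to floating
  point.
* Between-mouse overlap values follow the one-value-per-ordered-mouse-
  pair convention (n × (n−1) values for n mice) computed on per-mouse
  pooled tumors, matching the reported group sizes (within mice n = 4,
  between mice n = 4 × 3 for four mice).
* The left-right share within dLN-tumor overlapping (OL) repertoires is
  computed on frequencies renormalized within each OL set (shared mass
  over total OL mass, combined as a geometric mean). The OL repertoire
  object itself keeps whole-dLN frequencies by default — it is a subset
  of the dLN distribution — with renormalization available via a flag;
  the share statistic is only meaningful on the renormalized scale.
  Scatter-plot correlations over shared clones are Pearson's r of log10
  frequencies (a linear-scale r is also reported); the log-scale choice
  matches how such data are plotted and is invariant to the
  renormalization constant.

## Problem sizes used in tests

The shipped test suite exercises the full 4-mouse default configuration
(24 samples, 60,000 reads each) for dataset-level acceptance summaries,
averaged over three replicate datasets to damp Monte-Carlo noise, and a
reduced 2-mouse configuration (120 reactive clones, ~4,800 reads per
sample) for pipeline mechanics and parameter-recovery grids (5 parameter
points × 10 replicates). Exhaustive Fisher-oracle equivalence runs over
all 2×2 tables with row sums ≤ 15 plus 1,000 randomized tables with
margins up to 50 cross-checked against `stats::fisher.test`.

## Known limitations

* The Storey π0 spline is the standard smoother but can be unstable for
  small or pathological p-value sets; the BH fallback (recorded in the
  output) is the guardrail.
* `downsample` draws sequential conditional hypergeometrics in R; for
  repertoires of ~10⁵ clones this is linear and fast enough, but a
  compiled implementation would be the next step for much larger data.
* The generator's bystander clones are compartment-private; real
  repertoires share some bystanders across compartments and mice beyond
  the public-pool mechanism.
* `within_between_mouse` requires exactly one left and one right sample
  per mouse (pool fragments first); designs with replicates per side
  need manual pair construction.
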