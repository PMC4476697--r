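---
title: "mitosignal: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitosignal: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models each
module implements, the tunable parameters and why their defaults are what
they are, what the synthetic generators emulate (and deliberately do not),
the numerical choices, and the limits of what the passing test suite
demonstrates.

## The problem

After traumatic brain injury, mitochondrial damage-associated molecular
patterns — including mtDNA itself — reach the circulation and the relative
mtDNA content of peripheral whole blood rises within hours. If that rise
tracks the injured brain's bioenergetic state, a blood draw could stand in
for measurements (ex-vivo tissue respirometry) that are otherwise
impossible to obtain longitudinally. The pipeline therefore spans four
methodologically unrelated layers — comparative genomics for assay design,
qPCR quantification, oxygraph signal processing, and small-sample
statistics — and the package's central design decision is that **every layer
is validated against truth-known synthetic data and an independent oracle**,
because the primary data of such studies (raw Ct values, oxygraph records,
per-animal values) are typically not deposited.

## NUMT screening

Nuclear genomes contain NUMTs: old, partially diverged insertions of mtDNA.
A qPCR assay meant to count mitochondrial genomes must avoid them, so the
screen asks, for every window of the circular mitochondrial genome, how
similar its best nuclear match is.

**Model.** Windows of `window` bases (default 100) at starts every `step`
bases (default 10) are compared, ungapped and full-length, against both
strands of every nuclear contig. Candidate alignments are found by exact
k-mer seeding (`k = 15`); each seed's diagonal is scored by the exact
fraction of matching bases over the whole window. A window is *NUMT-like*
when its best identity reaches `identity_threshold` (default 0.80). Unique
regions are the maximal stretches of the circle **not covered by any
NUMT-like window** — the complement-of-coverage rule. This matters at NUMT
edges: a window that straddles a NUMT boundary can itself be below
threshold, but the union-of-unique-windows rule would then let reported
regions brush into the NUMT by up to `window − step` bases. Taking the
complement of NUMT-like coverage instead guarantees that no returned region
overlaps any region of nuclear similarity.

**Defaults.** `window = 100` is close to qPCR amplicon scale;
`identity_threshold = 0.80` keeps NUMTs of up to ~20% divergence excluded
while random 100-mers in a 200-kb contig stay near 0.4; at 2% divergence a
NUMT window contains mismatches every ~50 bases on average, so 15-mer seeds
are effectively always found. All parameters are exposed.

**Numerical and boundary choices.**

* The mitochondrial genome is treated as circular by extension with the
  first `window − 1` bases; output coordinates are always 0-based half-open
  within `[0, L)`, and a unique region spanning the origin is emitted as two
  rows flagged `origin_wrap`.
* Rotating the mitochondrial sequence by a multiple of `step` rotates the
  unique coverage set exactly (property-tested); rotations that break the
  window-start grid can shift region edges by up to one step, which is a
  property of the grid, not of the screen.
* `max_nuclear_identity` is the best *seeded* identity among windows
  starting inside the region: a lower bound that equals the true optimum
  wherever it matters (above-threshold windows always carry seeds at the
  divergences of interest) and roughly the random background elsewhere.
* An empty nuclear genome returns the whole mitochondrial genome as one
  region — documented behaviour, not an error.

**Oracle.** The test suite recomputes every window's best identity with a
seed-free O(n·m) diagonal sweep and re-derives the regions independently;
implementation and oracle must agree exactly on instances up to tens of
kilobases (validation used 1.5–2.5 kb mitochondrial / 6–10 kb nuclear
instances with planted NUMTs at 0–5% divergence, plus the 16.5 kb / 200 kb
default scale in the pipeline tests).

## Melting temperature and primer design

Because primer picking is implemented in-package, a melting-temperature
model is needed. `melting_temperature()` uses the unified nearest-neighbor
thermodynamic parameters of Allawi & SantaLucia (1997), duplex initiation
terms per terminal base pair, the entropic monovalent-salt correction
ΔS′ = ΔS + 0.368·(N−1)·ln[Na⁺], and Tm = 1000·ΔH / (ΔS′ + R·ln(CT/4)) −
273.15 for a non-self-complementary duplex at total strand concentration
CT (defaults: 50 mM Na⁺, 0.25 µM oligo). The implementation was validated
to within hundredths of a degree against an independent implementation of
the same parameter set, and those values are frozen in the tests. Under
these conditions the bundled reference assay primers melt at ≈ 55.5–56.7 °C,
which is why the default acceptance window is 55–66 °C with a ranking
target of 60 °C.

`design_primer_pairs()` enumerates every forward primer, reverse primer
(reverse complement of a downstream tract), and forward-strand hydrolysis
probe satisfying:

| parameter | default | note |
|---|---|---|
| primer length | 25–30 nt | the assay family's specificity constraint |
| primer GC | 0.30–0.70 | |
| primer Tm | 55–66 °C (target 60) | at the Tm model's defaults |
| amplicon | 60–200 bp | forward start to reverse end |
| probe | 18–25 nt, GC 0.30–0.70 | strictly between the primers |

Pairs are ranked by the transparent penalty
|Tm_f − Tm_r| + |Tm_f − target| + |Tm_r − target| + 5(|GC_f − 0.5| + |GC_r − 0.5|),
with ties broken on (penalty, forward start) for reproducibility. A probe is
required by default; with 25-nt primers this makes the effective minimum
amplicon 25 + 18 + 25 = 68 bp, so the nominal amplicon floor of 60 bp is
reachable only with `probe = FALSE`. Probe Tm is matched to the primer mean
rather than the +10 °C hydrolysis-probe rule, because the reference assays'
printed probes are short (19–21 nt) and cooler than their primers. Two caps
keep the quadratic enumeration bounded: `max_pairs` (candidate thinning
with a warning) and `max_report` (only the top-ranked pairs get probes and
are returned). An empty result is a valid outcome — a homopolymeric region
fails the GC constraint. The two bundled COI assays share primers and
differ only in probe; the package therefore treats an assay as a
(primer pair, probe) combination.

`check_specificity()` is deliberately exhaustive rather than seeded: every
offset of every contig, both strands, full-length identity, plus a
`perfect_3prime_match` flag for sites matching the primer's five
3′-terminal bases exactly at ≥ 90% full-length identity — the configuration
most likely to misprime.

## Comparative-Ct quantification

The comparative-Ct model: per sample and target,
ΔCt = Ct_target − Ct_normalizer; against the calibrator,
ΔΔCt = ΔCt − ΔCt_cal; RQ = E^−ΔΔCt with amplification efficiency E = 2
(perfect doubling — the assays run under universal cycling conditions;
E is exposed as a configuration hook but efficiency estimation is out of
scope). Consequences used as tests: RQ is invariant under any constant
shift of a sample's Ct values; the calibrator's own RQ is identically 1;
one cycle of ΔΔCt is exactly a factor of 2.

Choices where the method leaves room:

* **Calibrator** (`"auto"` default): the per-gene mean ΔCt of all
  pre-injury samples, so pre-injury RQ centres near 1; an explicit
  reference sample id can be supplied instead (the synthetic generator
  always emits one, named `calibrator`).
* **Replicates**: exactly three per cell; cells with replicate SD above
  0.5 cycles are flagged, never dropped — auditability over automation.
* **Pooling**: group summaries are mean ± SEM with sample SD (n − 1);
  each gene × animal contributes one value, so a group of 4 animals × 3
  genes pools n = 12. A single value has SEM defined as 0.
* **Reference table**: the bundled `rq_reference_summary()` ships per-gene
  group means (with SEM and group sizes) from a porcine TBI cohort measured
  with this assay design. Pooling them weighted by group size yields
  0.8403 → 0.84 pre-injury (n = 39), 2.0667 → 2.07 (diffuse, 6 h) and
  1.35 (focal, 25 h). The same arithmetic gives 2.36 for the diffuse 25 h
  group where 2.37 was published — a rounding-level discrepancy we report
  as computed rather than resolve.

## Respirometry

The trace model is a closed respirometry chamber: O2 concentration falls
linearly at rate flux × sample_conc / 1000 µM/s within each SUIT phase
(flux in pmol O2·s⁻¹·mg⁻¹, sample concentration in mg/ml — at the standard
1 mg/ml, a flux of 80 is a slope of −0.080 µM/s). Calibration is two-point
linear with the medium's solubility factor (default 0.92 relative to pure
water at 37 °C); the air-saturation concentration is a required input, not
a constant, because it depends on barometric pressure and temperature.

**Flux.** J(t) = −d[O2]/dt · 1000 / sample_conc, derivative from a local
quadratic Savitzky–Golay fit over `smooth_window` seconds (default 21 s at
1 Hz) — robust to µM-level sensor noise; plain central differences are kept
as a fallback mode for oracle checks. Negative fluxes (reoxygenation
artifacts) are reported, never clipped.

**Phases.** Titration events open phases; the analysis window starts
`equilibration_s` (default 60 s) after the titration to exclude injection
and stirring transients, which the generator makes real by adding a
decaying positive spike (default 5 µM, τ = 10 s) at every titration. An
emptied window warns rather than silently dropping the phase; records
before the first titration form a `baseline` phase.

**Steady state.** Within a phase, the reported flux is the mean over the
`window_s`-second sub-window minimizing the rolling SD of the flux series —
the most stable plateau — with that SD reported as `stability`. This
resists both early-phase drift and titration spikes. The constructor
default of 30 s suits short phases; the package's own validation uses
600-s phases sampled at 1 Hz with 300–400 s plateau windows, where the
slope-estimation noise at 0.5 µM sensor noise is small enough that the
median recovery error over a 10–150 pmol·s⁻¹·mg⁻¹ × 0–0.5 µM grid stays
well under 2%, and the recovered RCR at the reference levels
(OXPHOS 82.6, LEAK 13.97 → RCR 5.91) is within 3%.

**Profile.** OXPHOS(CI+CII) (State 3, after succinate with NADH-linked
substrates and ADP) over LEAK(CI+CII) (State 4o, after oligomycin) gives
RCR, the coupling index. Missing states stay `NA`; a non-positive LEAK
leaves RCR undefined with an explicit flag. Which titrations precede
succinate varies between protocols, so the phase plan is data/configuration,
not code.

## Cohort statistics

All tests are two-sided with p-values formed by doubling the smaller tail,
capped at 1 (the convention of the common analysis software this layer
mirrors).

* **Wilcoxon signed-rank** (paired pre/post): exact mode builds the null of
  the positive-rank sum over all 2^m sign assignments by
  generating-function convolution — algebraically identical to literal
  enumeration, and still exact with midranks under ties. Zero differences
  follow the Pratt rule by default (rank them, drop their sign
  contribution), which is the conservative choice for discrete RQ deltas; a
  drop-zeros option exists. The normal approximation (tie-adjusted
  variance, continuity correction) serves m > 25.
* **Mann-Whitney U**: exact mode uses the classic two-sample combinatorial
  recursion without ties and full label permutation with midranks when ties
  are present (falling back to the tie-corrected normal approximation
  beyond `max_enum` splits, with the method recorded in the result).
* **RM-ANOVA across genes**: one-way repeated-measures
  F = MS_gene / MS_(gene×animal), no sphericity correction (mirroring the
  original analysis convention), missing cells an error rather than
  imputed. The degenerate all-equal case returns F = 0, p = 1 rather than
  0/0.
* **Pearson correlation**: product-moment r with the t-distribution
  p-value; |r| = 1 handled as the p → 0 limit; slope and intercept reported
  for plotting.
* **No multiple-testing correction** is applied anywhere, matching the
  analysis convention this package models; all raw p-values are reported
  with that caveat.

The association layer fixes the sign convention in the type itself:
delta_resp = sham mean − post-injury value (a *deficit*, positive when
respiration is below sham), recomputed rather than stored, so a positive r
always means larger blood-mtDNA increases with larger cerebral deficits and
no figure can silently flip sign. One respiration endpoint per run is
enforced.

Exactness claims are property-tested: both exact tests equal literal
full-enumeration oracles (all 2^m sign vectors; all C(N, n1) splits) on
random instances up to n = 12 including ties and zeros, and the exact
Wilcoxon's empirical size at n = 12 over 10,000 null simulations falls in
[0.03, 0.07] — the discreteness-aware band around the nominal 0.05.

## What the generators emulate — and what they do not

The generators' defaults are the study conditions the package models:
three mitochondrial targets against a nuclear 16S normalizer, triplicates,
group sizes of 4–5 animals, group mean RQ levels taken from the bundled
reference table, OXPHOS/LEAK reference fluxes 82.6/13.97 pmol·s⁻¹·mg⁻¹ at
1 mg/ml and 37 °C with solubility factor 0.92. Where no published value
exists the defaults were chosen once as instrument-plausible: replicate Ct
SD 0.15 cycles and animal-level log2-RQ SD 0.25 (typical TaqMan triplicate
scatter and biological spread), sensor noise 0.2 µM at 1 Hz, 5 µM titration
spikes, 16.5 kb mitochondrial genome, 200 kb nuclear contig.

Deliberate simplifications: NUMTs are substitution-only (no indels), which
keeps the brute-force oracle exact; animal-level RQ variation is
log2-normal (ΔΔCt is linear in log2 space, so this matches the assay's
error structure) and drawn independently per animal × gene × timepoint;
cohort (ΔRQ, Δresp) pairs are bivariate normal; amplification efficiency is
exactly 2; oxygraph noise is white and Gaussian. Real data have gapped
NUMTs, correlated gene responses within an animal, plate and batch effects,
efficiency below 2, and autocorrelated sensor drift. Passing tests
therefore demonstrate that the *analysis layer* is correct under its stated
model, not that the model exhausts real-data behaviour.

## Problem sizes used in validation

Oracle-equivalence screens run on 1.5–2.5 kb mitochondrial / 5–10 kb
nuclear instances (the seed-free oracle is O(n·m)); the pipeline tests use
the full 16.5 kb / 30–200 kb scale. Statistical properties use 500-seed
Monte Carlo at n = 200 for correlation recovery (|bias| < 0.02) and 10,000
null simulations for test size. These sizes are the package's choices for a
thorough-but-quick default test run; all scale up by parameter.

## Known limitations

* The screen is ungapped: a NUMT with indels would be caught only via its
  intact flanks. Chromosome-scale assemblies want a dedicated aligner.
* `max_nuclear_identity` is a seeded lower bound away from NUMTs.
* No primer-dimer or cross-assay interaction checks; no multiplexing.
* Absolute (standard-curve) quantification, efficiency estimation from
  amplification curves, and plate-batch correction are out of scope.
* The respirometry layer analyzes recorded traces; it does not correct for
  chamber back-diffusion or instrument-specific artifacts beyond the
  equilibration exclusion.
* Exact-test enumeration is limited to m ≤ 25 non-zero pairs (Wilcoxon) and
  moderate split counts (Mann-Whitney); beyond that the normal
  approximation is used and labelled.
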