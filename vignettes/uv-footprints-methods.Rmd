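---
title: "Models and methods: UV damage, repair and mutation footprints at TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: UV damage, repair and mutation footprints at TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

uvfootprint asks a single-nucleotide-resolution question: at which
positions inside a transcription factor's binding sites does protein
binding change (i) the formation of UV photolesions — cyclobutane
pyrimidine dimers (CPDs) and 6–4 photoproducts (6–4 PPs) — (ii) their
repair, and (iii) the downstream C>T mutation burden, relative to what
the local DNA sequence alone would predict?  This vignette describes
the statistical models, the tunable parameters, the synthetic data
the package tests itself on, and the numerical choices made where the
design was genuinely open.

## The sequence-context Poisson model of damage formation

UV photolesions form only at dipyrimidines (TT, TC, CT, CC read 5'→3'
on the damaged strand), and their formation frequency depends strongly
on flanking sequence.  The package models the count at each
dipyrimidine locus as an independent Poisson draw whose rate depends on
the hexanucleotide context NNYYNN centered on the dipyrimidine:

* `estimate_context_rates()` tallies, over a background region set,
  the occurrences $k_n$ of each of the 1,024 pyrimidine-centered
  hexanucleotides $n$ and the damages observed at them, giving a rate
  $r_n$ = damages / occurrences per hexamer.  The expected damage over
  $k$ occurrences is $\lambda_n = r_n k$.
* `expected_profile()` uses the additivity of independent Poisson
  variables: the expected count at one motif-relative position and
  strand of a site set is the sum of the context rates at that position
  across sites.  Observed counts are aggregated by
  `observed_profile()` in motif coordinates (position 0 at the motif
  center, `floor(L/2)` from the 5' end; a dipyrimidine is indexed by
  the lower of its two motif coordinates, the "i/i+1" convention;
  minus-strand sites are flipped so profiles superpose).

The background region set for formation models should be accessible,
intergenic DNA: accessibility because damage maps are compared within
open chromatin, intergenic because transcription-coupled repair and
transcription-associated structure would otherwise contaminate the
rates.  `build_accessible_regions()` implements the curation used
throughout: the top 50% of peaks by signal, 150-bp windows centered on
peak summits, genic intervals subtracted.

`ks_poisson_check()` verifies the per-locus Poisson assumption per
hexamer.  Damage files omit zero-count loci, so zeros are
reconstructed from the occurrence enumeration before comparing the
empirical count distribution to Poisson($\hat\lambda$).  The standard
continuous-sample KS formula degenerates on counts (the statistic
jumps to $F(0)$ at the zero atom), so the statistic is computed
atom-wise on the integer support and the Kolmogorov asymptotic p-value
is reported; for discrete data it is conservative, which the function
logs.

## Flank scaling

Local covariates shared by a cluster's sites — nucleosome positioning,
co-factors, residual chromatin structure — shift damage levels
coherently without being binding effects.  Before testing,
`flank_scale()` multiplies the model expectation by the mean
observed/expected ratio over the flanking positions outside the
binding-site span (motif ± 5 bp, within the ±40 bp window), separately
per profile strand and per motif half (clusters can have asymmetric
flanks, e.g. palindromic content or one-sided co-factors).  The split
is at the motif center with the center column assigned to the left
half; positions with zero expectation are skipped; a strand-half with
no usable flank position falls back to factor 1 with a warning.  The
flank definition (everything in the window outside motif ± `span_pad`)
is configurable.

## The per-position test, its direction convention, and correction

`poisson_position_test()` compares the observed count $X$ with the
scaled expectation $\lambda'$ per (position, strand) cell:
$z = (X-\lambda')/\sqrt{\lambda'}$, direction = sign$(X-\lambda')$, and
a one-sided inclusive tail $P(\mathrm{Pois}(\lambda') \ge X)$ for
enrichment or $P(\le X)$ for depletion.  Benjamini–Hochberg correction
is applied jointly over all cells of one cluster's window; clusters are
corrected independently.  Cells with $\lambda' = 0$ but $X > 0$ are
flagged `model_gap` and excluded from correction.  The CPD threshold
is q < 0.05; 6–4 PP analyses reuse the identical machinery with their
own rate table and the more conservative q < 0.01, because
UVDE-seq-style maps carry more background.

One property of this convention deserves emphasis: because the tested
tail is chosen from the data, each null cell gets two chances, and the
raw exceedance $P(p < \alpha)$ under the null is close to $2\alpha$
(each directional tail alone is a valid, slightly conservative
p-value; simulation at study scale gives ≈ 0.075 at $\alpha = 0.05$).
The package deliberately reproduces this directional convention rather
than doubling the tail; it is how the significance calls are defined,
the BH correction operates on these p-values, and the naked-DNA filter
(below) absorbs part of the residual false-positive load.  Users who
need strictly level-$\alpha$ raw p-values should double the tail
probability themselves.  Null z-scores are well calibrated (mean ≈ 0,
SD ≈ 1 in study-scale simulations).

Two orthogonal guards complete the formation analysis:

* `shuffle_null_test()` rebuilds the null empirically by reassigning
  every damage record (with its count) to a uniformly drawn locus of
  the same tetranucleotide (NYYN) class within the background regions.
  Per-cell empirical p-values use the $(1+k)/(1+n)$ convention.  The
  resampling is realized exactly but efficiently: destinations of one
  class's records are multinomial over that class's loci, so per-cell
  iteration counts are drawn with `rmultinom()` over (cells +
  elsewhere) instead of per record — distributionally identical, two
  orders of magnitude faster, and verified against a per-record
  brute-force oracle in the test suite.  Note that with $m$ testable
  cells the smallest attainable BH q is $m/(n_{iter}+1)$; at least
  2,000 iterations are needed before q < 0.05 is reachable in an 81 ×
  2 cell window.
* `naked_dna_filter()` demotes calls that replicate, same position and
  direction, in naked irradiated DNA: those are sequence-intrinsic
  photoreactivity, not TF binding.  Demoted cells stay in the output
  labelled `sequence-intrinsic`; opposite-direction replication is
  kept but flagged.

Binding-strength stratification (`stratify_by_strength()`) splits a
cluster into motif-score tiers of equal size (remainder to the top
tiers, ties broken by genomic order); true binding effects should
weaken monotonically toward the weak tier, which is a property test in
the suite.

## Repair: bootstrap conditioned on burden and context

Repair efficiency depends on the tetranucleotide context NYYN.
`repair_efficiency_by_context()` estimates per-context survival
$s_c = t/0h$ (and efficiency $1-s_c$) over accessible intergenic
background, flagging contexts under a configurable initial-count floor.
`bootstrap_unrepaired_test()` asks whether a position retains more
unrepaired damage than its initial burden and composition predict: the
0h count of each (position, strand) cell is decomposed into per-NYYN
counts $n_c$, and each of the (default 10,000) bootstrap draws is
$\sum_c \mathrm{Binomial}(n_c, s_c)$ — a null conditioned on both the
initial amount of damage and its sequence composition.  The null is
flank-scaled exactly as in the formation analysis, the empirical
one-sided p-value for elevated remaining damage uses $(1+k)/(1+n)$,
and BH runs across the ±30 bp window (narrower than formation, since
repair signal is noisier and compute grows with the window).  A
locus-resampling kernel (draw background loci of the class weighted by
initial counts, Bernoulli per-lesion survival from their observed
ratios) is available via `kernel = "locus"` for sensitivity analysis;
the two kernels agree closely on simulated data.

Library normalization between timepoints is off by default
(`norm_factor = 1`, i.e. inputs assumed depth-normalized) and settable
as a scalar; results should always be reported alongside the
normalization used.  `context_efficiency_comparison()` contrasts a
position's NYYN composition (efficiencies replicated by composition
counts) against all usable contexts with a two-sided Mann–Whitney U.

## Mutations: projection, shuffle null, concordance

`project_mutations()` converts the initial CPD map into the C>T
profile it would cause if every CPD-dimerized cytosine were mutated:
each C inside a damaged dipyrimidine contributes the lesion count at
its own position (a CC lesion projects a two-position tandem; TT
projects nothing); strands are aggregated.  The projection satisfies
an exact conservation identity (total projected = $\sum$ count × #C in
the dipyrimidine) that the acceptance suite checks.

`actual_mutation_profile()` maps pyrimidine-strand C>T events
(reference C>T and G>A) into motif coordinates, counting recurrent
mutations per occurrence (a unique-locus mode exists).
`trinucleotide_shuffle_test()` is the damage shuffle with classes
given by the pyrimidine-strand NCN trinucleotide of each cytosine and
flank scaling of the null mean per motif half.
`concordance()` regresses actual on projected counts by OLS across
window positions, standardizes residuals, flags positions with
|z| > 2.58 as discordant (these are candidates for repair- or
selection-driven departures from formation), and computes a
randomized baseline by correlating the projected profile against the
actual profiles of 5 random other clusters;
`concordance_group_test()` contrasts matched and randomized
correlations across clusters by Mann–Whitney.

## Structural photoreactivity geometry

For predicted TF–DNA complexes the package computes, per dipyrimidine
step: `d22` (distance between the two C5–C6 bond midpoints — the bond
pair that closes the cyclobutane ring of a CPD), `d64` (5' C5 to the
3' base's C4-attached acceptor, O4 for thymine and N4 for cytosine —
the atoms joined in a 6–4 PP), stacking overlap (ring atoms only,
projected into the mean base plane whose normal is the normalized sum
of the two base-plane normals; convex polygon intersection via
Sutherland–Hodgman clipping), base-pair and base-step parameters, and
the sugar pseudorotation phase with its pucker label
(36° windows, C3'-endo at P = 0).

Frames are fitted by reflection-free least-squares (Kabsch)
superposition of packaged idealized planar ring geometries (regular
polygons with aromatic bond lengths, origin at the ring centroid, x
through the glycosidic nitrogen).  Pair and step parameters use the
symmetric mid-frame scheme: the relative rotation is halved to define
the mid-frame, translations are expressed in it (shift/slide/rise;
shear/stretch/stagger for pairs after flipping the complementary
base's frame about x), and the rotation vector components about the
mid-frame axes give tilt/roll/twist (buckle/propeller/opening).  This
construction is exactly invertible, and the suite verifies an ideal
helix round-trip to 1e-6 and rigid-motion invariance of every output
to 1e-9.  Absolute conventions (e.g. where the frame origin sits)
follow this package's own standard bases, so values can differ by
small constants from other implementations; comparisons between bound
and unbound states, which is what `compare_states()` reports
(medians, fold changes, two-sided Mann–Whitney p, optional reactive-
range flags), are unaffected.  Reactivity thresholds are configuration
values with no defaults.  The interbase angle is computed as
$\sqrt{\mathrm{propeller}^2+\mathrm{buckle}^2}$.

Structure input follows the standard quality gates: per-residue mean
confidence (pLDDT in the temperature-factor field) must be ≥ 70 for
every DNA residue after trimming 3 bp from each chain end, where
predicted termini are systematically unreliable.

## The synthetic-data generator

Every stage is tested against `synthesize_study()` /
`simulate_damage()` / `simulate_repair()` / `simulate_mutations()`
fixtures with known truth:

* Hexamer truth rates are a dinucleotide base rate (TT 0.10, TC 0.06,
  CT 0.03, CC 0.015 damages per occurrence — TT-dominant, mean ≈ 0.05
  per dipyrimidine, the scale of a deeply sequenced damage map) times
  a seeded lognormal flank modifier (σ = 0.35), giving the strong
  flank dependence real maps show without copying any published table.
* Repair truth is per-NYYN survival at the later timepoint,
  logit-normal around 0.45 (σ = 0.6); the repair acceptance study uses
  mean 0.4, σ = 0.3 so that a 2× planted survival multiplier stays
  below 1.  Mutation truth is per-NCN per-sample C>T probability,
  higher for 5'-pyrimidine contexts.
* Sites are planted as exact consensus (or PWM draws) at jittered
  regular spacing, centered in 150-bp accessible windows, both strands
  equally, scored by the native log-odds scanner.  Effects are planted
  per (motif position, strand) as formation-rate or survival
  multipliers, optionally scaled with motif score.
* A study consists of motif-free accessible background chromosomes
  (6 Mb by default) plus one chromosome per cluster.  The background
  matters: context rates are estimated once over all accessible DNA,
  and with 2,000 planted sites a motif-interior hexamer would draw
  ~90% of its occurrences from the planted sites themselves if the
  windows were the only accessible sequence — the rate table would
  absorb the planted effect.  A 6 Mb background keeps the self-
  contribution near 15%, matching the real-data regime in which any
  single TF is a minority of every k-mer's genome-wide occurrences.
  The residual self-masking is visible and realistic: a 3× planted
  effect is recovered at observed/expected ≈ 2.2 rather than 3.

What the fixtures do not emulate: mappability and read-level noise,
blacklist artifacts, chromatin-feature covariates beyond the region
set (the flank-scaling target), correlated damage at overlapping
dipyrimidines, inter-sample mutation burden heterogeneity, and real
motif redundancy.  Green tests therefore demonstrate the statistical
machinery — calibration, power on planted effects at realistic scale,
exact identities — not performance on any real dataset.

## Problem sizes and determinism

All randomness flows from one master seed through named substreams
(`substream_seed()`), so stages are independently reproducible and
fixture bundles are byte-identical under a fixed seed.  The simulation
scales used by the test suite and the acceptance script — 50 clusters ×
2,000 sites for null calibration, 20 damage-realization seeds for
recovery and repair power on one synthesized study genome, 2,000
shuffle iterations, 10,000 bootstrap draws — were chosen as the
smallest sizes at which the tested properties are stable across seeds.
Empirical p-values use $(1+k)/(1+n)$ and can never be zero; BH q-values
are reported alongside raw p throughout.

## Known limitations

* The directional one-sided convention's ≈ 2α raw-p behaviour,
  discussed above.
* Hexamer rates require deep maps; uncovered k-mers contribute zero
  expectation (flagged), which slightly deflates expected profiles in
  shallow data.
* The repair bootstrap conditions on the observed 0h counts and treats
  background survival as known; background survival uncertainty is not
  propagated (it is negligible at the default background sizes).
* Geometry absolute values are convention-dependent (own standard
  bases); only within-package comparisons are meaningful.
* The mmCIF reader covers the `_atom_site` loop of predicted-model
  files, not the full mmCIF grammar.
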