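---
title: "Detecting intramolecular covariation, coevolving site pairs and correlated family evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intramolecular covariation, coevolving site pairs and correlated family evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscan)
```

coevoscan implements three complementary ways of asking whether parts of a
protein system evolve together, at three scales: pairs of alignment columns
within one protein (physicochemical covariation), pairs of sites within or
between proteins (correlated evolutionary rates with compensatory-substitution
analysis), and whole protein or domain families (mirrortree correlation of
evolutionary distance matrices). The motivating system is the
insulin/insulin-receptor axis, where the C-peptide — the linker excised from
proinsulin during maturation — shows coevolutionary signal despite its high
sequence variability; but every function is generic over any set of aligned
protein families with matched species.

All three engines consume pre-aligned FASTA (`read_alignment()`); alignment
construction is deliberately out of scope. Sites are reported in the residue
numbering of a designated ungapped reference record (`build_column_map()`),
and named domains — for human preproinsulin, the shipped default is signal
peptide 1–24, B chain 25–54, C-peptide 57–87, A chain 90–110, with the
dibasic processing sites 55–56 and 88–89 excluded as in the UniProt chain
annotation — can be sliced out with `slice_domain()`. When a whole set of
adjacent domains must partition every alignment column, columns that are gaps
in the reference between two domains go to the preceding domain
(`extend_right = TRUE`), a deterministic convention.

## Physicochemical covariation between columns

Each alignment column is mapped to a numeric vector through a property scale;
the shipped defaults are residue volume (Zamyatnin, Å³), Kyte–Doolittle
hydropathy, Grantham polarity, Bhaskaran–Ponnuswamy average flexibility and
residue molecular weight, all replaceable by two-column TSV tables. Gaps and
`X` are missing data, masked pairwise.

Sequences in an ortholog alignment are redundant to varying degrees, so each
record receives a Vingron–Argos weight proportional to its summed mismatch
distance to all other records; weights sum to one and near-duplicates are
down-weighted. The covariation statistic for a column pair is the weighted
product-moment correlation of the two property vectors, with weights
renormalised over the jointly unmasked records. A column enters the scan only
if it carries at least `variability_min = 3` distinct residues (counting
residues, not distinct property values — the stricter and simpler reading,
exposed as a flag). Significance uses the two-sided critical value of the
product-moment correlation at `confidence = 0.99`, with degrees of freedom
`n_eff − 2` where `n_eff = 1 / sum(w²)` is the effective sample size of the
renormalised joint weights: duplicating a sequence therefore cannot
manufacture significance. Correlated positions are clustered by average
linkage on similarity `r` and cut at `cutoff = 0.55`; the merge tree is
exported as Newick with the merge correlation as node labels. A
domain-by-domain contingency table of significant pairs, split by sign,
summarises where covariation concentrates.

A caveat this package measures rather than hides: the critical-value test
assumes exchangeable sequences. On exchangeable data it is exactly calibrated
(the unit suite verifies a ~1% significant-pair rate at 99% confidence), but
orthologs are related by a tree, and shared ancestry inflates the false-positive
rate of *any* per-pair correlation test — on tree-structured
independent-site simulations the empirical rate runs near 10%. Sequence
weighting does not remove this; only tree-aware methods can, and those are
out of scope here. Significant covariation pairs on real ortholog data are
therefore best read as a ranking, not as a calibrated error rate.

## CAPS-style coevolving site pairs

For every sequence pair (i, j) and column c the engine scores the observed
residue pair with BLOSUM62 and corrects for the pair's divergence time
t(i, j), the Poisson-corrected amino-acid distance (`divergence_times()`);
identical (t = 0) and saturated (p = 1) pairs are excluded rather than
floored — θ is undefined there and any ε floor would be arbitrary.
`caps_profile()` exposes the classical descriptors θ = B/t and
D = (θ − θ̄)². The scan statistic, however, is the correlation of
*time-corrected score residuals*: scores are first normalised as
B′(a, b) = B(a, b) − [B(a, a) + B(b, b)]/2 (zero for any conserved pair,
negative in proportion to the severity of a substitution) and then the
per-column trend in t is removed by quadratic regression, leaving residuals
that covary between two columns exactly when substitutions co-occur in the
same sequence pairs beyond what divergence predicts. The raw ratio θ is kept
as a descriptor but not correlated, because its 1/t factor is common to all
columns: profiles of two unrelated, well-conserved columns correlate near
1.0 through shared divergence structure alone, which would swamp any true
signal. Identical residue patterns still give r_coev = 1 under the residual
statistic, whatever the tree.

Significance comes from `n_resample = 1000` null draws at `alpha = 0.05`,
with two constructions. The default draws random distinct usable column
pairs from the observed alignment: under column independence the tested
pairs are themselves draws from this null, so the test is self-calibrating
even though the sequences share a phylogeny (false-positive rate ≈ α on
simulated independent sites). The alternative (`null_method =
"permutation"`) permutes residues within columns before pairing; it is more
powerful but destroys the shared-tree structure that real null columns
retain, and measures ~3–5× α false positives on tree-structured data — use
it only when the extra power is worth the anticonservativeness. A pair must
also clear `min_R = 0.1`. Significant pairs form coevolution groups as
connected components; a group exceeding 5% of the protein length
(`group_cap`) is flagged, not truncated.

Compensation is assessed per significant pair: for each included sequence
pair, the signed property difference p(aᵢ) − p(aⱼ) is computed at both sites
(fixed global record-pair orientation — compensation is directional, and
reversing the record order flips both vectors jointly, leaving r unchanged)
and the two difference vectors are correlated, for hydropathy and for
molecular weight. Because the n(n−1)/2 sequence pairs are not independent
observations, the critical value uses the number of *sequences* as the
effective sample size; non-significant compensation values are reported as
"No" in the output table, mirroring the conventional CAPS report layout.

The intermolecular scan restricts both families to their shared species (an
explicit identifier map is supported; there is no fuzzy matching), computes
divergence times per molecule, and tests every usable column of one family
against every usable column of the other. At the 12-species scale of the
motivating study the scan has little power, and a significant fraction near
α — background level — is the expected honest outcome.

## Mirrortree correlation of distance matrices

`distance_matrix()` builds the Poisson-corrected distance matrix
d = −ln(1 − p) of a family, under pairwise deletion by default (complete
deletion is a flag for sensitivity analysis; the two coincide on gap-free
alignments). `mirrortree_r()` aligns two matrices by species identifier and
returns the product-moment correlation over the N(N−1)/2 upper-triangle
entries (row-major, i < j — the order is documented for reproducibility of
intermediate dumps but cannot affect r). `correlation_table()` assembles the
full ligand-forms × receptor-forms table, appends a negative-control family
as an extra row and column, adds per-ligand means over the receptor rows,
and flags any ligand/receptor pair that fails to exceed both of its control
pairings. Distances are computed on domain slices of the family alignment
(not re-aligned sub-sequences): slicing preserves the columns and therefore
the species-pair comparability.

## The synthetic-data generator

Every statistical property of the engines is exercised on data with known
ground truth, generated in code. Topologies are Yule-distributed (uniform
pair joining — the same labelled-topology law as a Yule process) with
i.i.d. exponential branch lengths of mean 0.1 expected substitutions per
site, a depth at which vertebrate-ortholog-like divergences (pairwise p
roughly 0.2–0.6) arise for the default rate of 1 substitution per site per
unit branch length. Sites evolve by a Poisson process with uniform
replacement among the 20 residues — deliberately not an empirical matrix,
so that null calibration stays interpretable.

A planted compensatory pair holds the two sites to a fixed constraint: the
pair's ancestral property sum (volume by default, tolerance 10 Å³). Each
substitution at the first site triggers, with probability ρ, a compensatory
draw at the second restricted to residues restoring the constraint; the
second site's own substitutions are likewise constraint-respecting with
probability ρ. At ρ = 1 with a tight tolerance the property sum is conserved
along every branch; at ρ = 0 the pair takes, verbatim, the independent-sites
code path. Anchoring compensation to the ancestral sum (rather than the
current, drifting sum) is what makes the planted pair a *persistent*
constraint — a drifting target decays into independence within a few
uncompensated events and no longer emulates a compensating residue pair.
When no residue lies within tolerance of the required value the nearest
residue is used and the event is counted (`n_widened`).

For family pairs, each branch receives a log-normal rate multiplier
(sdlog 0.6 — moderate, realistic rate heterogeneity); family B's multiplier
is m_B = m_A^s · exp((1 − s)·ε) with independent ε, so s = 1 shares rates
exactly and s = 0 makes them independent while preserving the marginal law.
Mean mirrortree correlation rises monotonically in s (about 0.72 at s = 0 —
the shared-topology baseline — to about 0.98 at s = 1 for 12 taxa and 300
columns), bracketing the range a real ligand/receptor pair and an unrelated
control exhibit.

What the generator does *not* emulate: indels (outputs are gap-free),
empirical amino-acid exchangeabilities, site-rate heterogeneity within a
family, and alignment error. Passing tests on these simulations therefore
demonstrate the statistics' behaviour under idealised evolution; on real
alignments, gap handling and misalignment add noise the tests do not probe.

## Problem sizes, numerics and degenerate inputs

The calibration and power suites use 32 taxa × 60 columns with 20 replicates
(coupling ρ ∈ {0, 0.5, 0.9}), and the rate-share comparison uses 12 taxa ×
300 columns with 100 replicates — sizes chosen to estimate rates to a few
percent while keeping a full run in minutes on one core. Ties at the null
quantile are accepted as significant (relevant only in tiny alignments where
the quantile saturates at 1). Weighted correlations clamp to [−1, 1] against
floating-point overshoot. Zero-variance columns are skipped, never errors;
an alignment with no testable column yields an empty result with a warning.
Pipeline runs (`run_pipeline()`) derive one sub-seed per analysis from the
global seed and the analysis name, so adding an analysis block never
perturbs the others, and rerunning an unchanged config reproduces its output
files byte for byte.

## Known limitations

* Phylogenetic autocorrelation inflates the covariation test's false-positive
  rate on real ortholog data (see above); treat its output as a ranking.
* The CAPS-style residual statistic corrects divergence-time trends per
  column but, like all pair-based statistics without ancestral
  reconstruction, retains some shared-branch background; its default null
  absorbs that background at the cost of power near the detection floor.
* Compensation correlations test property differences over non-independent
  sequence pairs; the sequence-count degrees of freedom are a conservative
  patch, not an exact distribution.
* Mirrortree correlations inherit the shared-topology baseline (r ≈ 0.7–0.8
  even for unrelated families on the same species tree); only the comparison
  against a control pairing, not the absolute r, carries evidence.
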