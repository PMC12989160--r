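---
title: "Classifying driver and passenger missense mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver and passenger missense mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missdriver)
```

## The problem and the data model

Somatic missense mutations in cancer genomes divide into *drivers*, which
confer a selective growth advantage, and neutral *passengers*. `missdriver`
implements a per-cancer-type classification pipeline over three information
layers: the protein sequence around the mutated residue, a predicted
three-dimensional structure of the protein, and the amino-acid contact
network derived from that structure.

The canonical record is one substitution: protein id, 1-based position,
wild-type and mutant residue, cancer type, tumour sample count and a label
in `{driver, passenger, unknown}`. Positions are 1-based everywhere in the
user-facing API — matching mutation nomenclature such as R175H — and
converted to 0-based offsets only inside window arithmetic. When a label
is not curated, `label_by_recurrence()` promotes records observed in at
least 3 tumour samples to drivers; that recurrence threshold is the
standard operational driver definition for somatic mutation corpora and is
the package default. Existing passenger labels are never overwritten by
recurrence.

## Mutation-preference statistics

For substitution $i \to j$, with $n_{ijD}$ occurrences among $N_D$ drivers
and $n_{ijP}$ among $N_P$ passengers, the preference of each class is
$n_{ij}/N$ and the driver-vs-passenger odds ratio is

$$\mathrm{OR}_{ij} = \frac{n_{ijD}/N_D}{n_{ijP}/N_P}.$$

Zero cells are reported as *flags* rather than numbers
(`driver_unique`, `passenger_unique`, `absent`): substitutions unique to
one class are a biologically meaningful category, and smoothing them away
at the reporting stage would hide it. Pseudocounts are used only where
odds become model features (below). Motif and substitution preferences are
called *driver* at odds $\ge 1.2$ and *passenger* at $\le 0.8$, both
boundaries inclusive; anything between is *neither*. Per-type driver
frequencies carry Wilson score intervals (default 95 %), and
residue-composition differences between classes are tested with Fisher's
exact test (two-sided, by summation of hypergeometric probabilities not
exceeding the observed one).

## Sequence features

*Property changes.* For each per-residue property table $P$ (AAindex1
format), the feature is $\Delta P = P(\text{mut}) - P(\text{wt})$,
antisymmetric by construction. The reference configuration uses a large
curated list of physical, chemical, energetic and conformational
parameters (152 in the original setting); the package treats the list as
configuration loaded from AAindex-format files — a small demonstration
set of five canonical indices ships in `inst/extdata/` — because a
hard-coded list would make the property set unauditable.

*Substitution matrices and contact potentials.* Each configured AAindex2
matrix contributes its $(\text{wt}, \text{mut})$ cell. Each AAindex3
pairwise contact potential $CP$ contributes three neighbour terms:
$CP(\text{left}, \text{mut}) - CP(\text{left}, \text{wt})$, the analogous
right-neighbour difference, and $CP(\text{left}, \text{right})$ for the
flanking pair itself. At a sequence terminus the affected component is
*missing*, never silently zero — a terminal mutation has no left
neighbour, and recording 0 would fabricate a neutral measurement.

*Window composition.* The 20 residues are partitioned into six side-chain
classes (aliphatic GAVLIP, sulfur CM, aromatic FWY, polar STNQ, positive
KRH, negative DE — a partition covering all 20 exactly once; the exact
partition is configuration since several conventions exist) and the
residues in a 13-residue window (6 per side, mutation site excluded,
truncated at termini) are counted per class.

*Gapped motif odds.* Seven pattern families combine the mutation site with
neighbouring residues at various gaps: site+right and left+site at gap 0,
site+right at gaps 3 and 4, left+site at gap 3, the adjacent tripeptide,
and a gapped tripeptide (left, site, right at gap 3). The families are
offset vectors in configuration — the display patterns observed in real
corpora (e.g. `C**R**`, `S**R*L`) motivate gaps up to 4, but no canonical
published set exists, so the package fixes a default and lets users
replace it. For each family the odds ratio of each concrete motif between
driver and passenger *training* sites is stored with a Haldane–Anscombe
pseudocount of 0.5 (protecting against zero passenger counts, which would
otherwise produce infinite feature values), and the feature of a mutation
is the stored odds of its realised motif. Motifs unseen in training — and
sites whose family offsets leave the sequence — score exactly 1
(odds-neutral), so prediction never extrapolates from unobserved patterns.

*PSSM and track features.* From a PSI-BLAST position-specific scoring
matrix: the mean log-odds score over the 13-residue window (each position
scored by its own native-residue column), the difference
$\mathrm{score}(\text{pos}, \text{mut}) - \mathrm{score}(\text{pos},
\text{wt})$, and the wild-type site score. Conservation tracks (18 in the
reference configuration, as produced by multi-method conservation servers)
and one disorder track each contribute the site value and the window mean;
missing values are excluded from means and a fully missing window yields a
missing feature.

## Structure features

Structures are AlphaFold-style predicted models; the per-residue pLDDT
confidence lives in the B-factor column and is read as the mean over the
residue's atoms (identical to the per-residue value for genuine AlphaFold
files). Multi-chain files are not modelled (AlphaFold monomers are
single-chain); the first chain is used with a warning.

*Solvent accessibility.* SASA uses Shrake–Rupley quadrature: each atom is
inflated by the probe radius (1.4 Å, a water molecule), sampled with a
deterministic golden-spiral lattice (default 960 points per atom), and
points falling inside any neighbouring inflated atom are discarded. Atom
radii come from a standard van der Waals table by element. Points exactly
on a neighbour's sphere (possible only for degenerate coincident atoms)
are credited to the lower-indexed atom, so exact duplicates do not double
count. Relative ASA divides by the theoretical per-residue maxima of Tien
et al. (2013), clipped to $[0, 1]$. DSSP output files can be ingested
instead, overriding computed ASA and providing secondary structure; the
8-state DSSP code collapses to 3 states by the common convention
{H,G,I}→H, {E,B}→E, rest→C.

*Residue depth* is the distance from the residue's heavy-atom centroid to
the nearest solvent-accessible surface point retained by the quadrature.
This surface-point definition was chosen over alternatives because it
reuses the SASA machinery, needs no extra dependency, and has closed-form
degenerate cases (an isolated residue has depth at most one atomic-plus-
probe radius) that make it testable.

*Contacts.* A residue's contact count is the number of other residues with
at least one atom pair within 7 Å, excluding immediate sequence
neighbours (|Δindex| ≤ 1): backbone-bonded neighbours are always within
any reasonable cutoff and would add a constant, uninformative offset.
When several structural models exist for one protein, every feature is
averaged per residue across models; residues present in only some models
average over those containing them and are flagged.

## Network features

The amino-acid contact network has residues as nodes and an edge between
residues with at least one atom pair within 7 Å, weighted by the number
of such atom pairs (no adjacency exclusion here — the network layer
represents the raw contact topology). Four centralities of the mutated
residue are computed: normalised closeness (reciprocal of the mean
shortest-path length over reachable residues), betweenness normalised by
$(n-1)(n-2)/2$, eigenvector centrality, and weighted degree. The named
centrality trio is closeness/betweenness/eigenvector; weighted degree is
the conventional fourth companion in amino-acid network analyses and is
documented as such. Shortest paths use unit edge lengths by default
(weights affect eigenvector centrality and degree only); reciprocal-weight
path lengths are available as an option since either convention is
defensible. Eigenvector centrality is computed by power iteration
(tolerance $10^{-9}$, cap $10^4$, deterministic all-ones start, result
scaled to maximum 1) on the adjacency shifted by $\sigma I$ with $\sigma$
the maximum row sum: the shift leaves eigenvectors unchanged while making
the dominant eigenvalue strictly largest in magnitude, so the iteration
also converges on bipartite graphs, where $\lambda_{\min} =
-\lambda_{\max}$ defeats the unshifted iteration. Closeness and
betweenness are delegated to `igraph` and cross-checked in the test suite
against an independent brute-force oracle (Floyd–Warshall distances plus
exhaustive shortest-path enumeration, and a dense eigen-solve).

## The classifier

Features are min-max normalised to $[0, 1]$ per column using training
minima/maxima; one-hot secondary-structure columns pass through; constant
columns map to 0; test values outside the training range are clipped with
a warning. Missing cells are imputed with training-column medians — an
explicit policy, applied before normalisation, never silent. Univariate
select-K-best ranks features by ANOVA F (or mutual information /
chi-squared) with ties broken deterministically by column name; a K sweep
over a grid (classically up to 50) picks the K maximising mean
cross-validated balanced accuracy, smallest K on ties.

The classifier is a feed-forward network: 1–5 ReLU hidden layers,
He-normal initialisation, and a single sigmoid output unit. A two-way
softmax head and a tied-transpose output layer are algebraically
equivalent or strictly less general than this form, so the package
implements the standard untied single-sigmoid architecture. Training is
mini-batch SGD with momentum, L2 weight decay and binary cross-entropy;
early stopping monitors the loss on a stratified validation split
(default 10 % of the training rows) and restores the best-epoch weights.
Defaults — two hidden layers of 64 and 32 units, learning rate 0.01,
momentum 0.9, L2 $10^{-4}$, batch 32, at most 500 epochs, patience 10 —
are ordinary values for tabular data of this width; published per-type
architectures report only tuning ranges, so these are the package's own
defaults and everything is exposed in `mlp_config()`. The decision
threshold is 0.5 with the boundary mapped to the driver class. No over- or
under-sampling is applied to class imbalance; the evaluation metrics
(balanced accuracy, MCC) are imbalance-aware instead.

Evaluation: stratified 80:20 splits (largest-remainder rounding, class
proportions within one record of global), protein-grouped splits that
keep every protein entirely on one side (mutations of one protein are
correlated, and row-level splits would leak), and stratified 10-fold
cross-validation with the imputer, scaler, feature selection and model
all refitted inside each training fold. Metrics are the standard
confusion-table set — sensitivity, specificity, accuracy, balanced
accuracy, MCC (defined as 0 when a denominator factor vanishes) — plus
ROC-AUC by trapezoidal integration (equal to the normalised Mann–Whitney
statistic, ties at half credit) and PR-AUC by step integration. Because
it is ambiguous whether a cross-validated AUC should be averaged per fold
or pooled, `kfold_cv()` reports both.

## The synthetic-fixture generator

Real corpora require licensed mutation databases and large structure
downloads, so the package ships a deterministic generator that emulates
the *shapes* of all inputs: random sequences from a configurable residue
frequency table; idealised α-helical structures (rise 1.5 Å, 100° per
residue, consecutive Cα–Cα distances ≈ 3.8 Å) with backbone and Cβ atoms,
optional Gaussian jitter and a synthetic pLDDT profile; PSSM profiles
with conserved native columns; correlated conservation tracks and an
anti-correlated disorder track around a latent per-residue profile; and
mutation tables whose driver sites are drawn preferentially at
high-conservation positions with sample counts ≥ 3 (passengers ≤ 2), so
recurrence labelling reproduces the intended labels exactly. The default
driver:passenger ratio is 2:1, inside the band observed in real per-type
corpora. Everything is written to disk in the real file formats, so every
end-to-end test also exercises the parsers.

What the generator does *not* emulate: realistic folds, evolutionary
covariation between positions, residue-composition biases of real
proteomes, or the long-tailed recurrence distributions of real tumour
data. Passing tests therefore demonstrate that the machinery is correct
and leak-free under known signal, not that any particular accuracy will
transfer to real corpora.

## Numerical choices and problem sizes

The test suite and the acceptance script run at desk scale by design:
SASA quadrature uses 60–240 points per atom in pipelines (the analytic
single-sphere check uses the full 960 and agrees within 1 %); the
planted-signal recovery uses 2 000 mutations with 40 features, 5 of them
planted at effect size $d = 2$, where the pipeline reaches mean 10-fold
balanced accuracy above 0.95 and recovers all planted features, while
label-shuffled controls stay within chance (0.45–0.55) under both row and
protein-grouped splits. Brute-force oracles (path enumeration for
betweenness, pairwise Mann–Whitney for AUC, hypergeometric enumeration
for Fisher) back every closed-form claim on small instances.

Known limitations: single-chain structures only; the FEATURE-style
microenvironment descriptors and interaction typing (H-bond vs salt
bridge) of full structural annotation stacks are out of scope; DSSP and
conservation/disorder predictors are ingested as files, not
re-implemented; and the shipped property/matrix lists are small
demonstration sets — production use should point the loaders at a full
AAindex installation.
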