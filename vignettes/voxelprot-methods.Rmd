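---
title: "Methods: downstream analysis of voxelated spatial FFPE proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of voxelated spatial FFPE proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelprot)
```

## The setting

A formalin-fixed paraffin-embedded (FFPE) tissue slide is cut into a grid
of *voxels* — physically dissected sub-regions, each processed as one
proteomic sample — and each voxel yields a label-free protein
quantitation. voxelprot implements the downstream computational layer of
such an experiment: digest quality control at the peptide level, an
open-search modification landscape, spatial-variability filtering of the
protein × voxel intensity matrix, weighted co-regulation networks around
seed proteins, and per-voxel summed intensity maps for annotated protein
sets. The default slide geometry throughout is a 4 × 5 grid of 20 voxels
with voxels 2, 5 and 8 excluded (a contamination scenario), leaving 17
analysis voxels.

Because the package is exercised without access to raw mass-spectrometry
data, it ships a first-class synthetic-data generator that emulates the
statistical structure of the real inputs and exports its ground truth, so
every estimator can be tested for parameter recovery.

## Digest quality control

Peptides are classified against a tryptic cleavage rule: cleavage
C-terminal to K/R, suppressed before proline (the default of the common
search engines; configurable off), with flanking residues `-` at protein
termini. A peptide conforming at both termini is *fully tryptic*, at
exactly one *semi-tryptic*, at neither *non-tryptic*. A *miscleaved*
peptide retains at least one internal, non-suppressed K/R site. Note the
asymmetry this implies: a lysine in front of a proline is internal but
was never cleavable, so it does not witness a missed cleavage.

The counting unit for all percentages is the unique peptide — a distinct
(sequence, modification-set) pair per voxel — rather than the
peptide-spectrum match. Spectral counts are kept per record and used only
by the rank-abundance module.

The K:R cleavage ratio is reported in two contexts: the peptide's own
C-terminal residue (protein C-terminal peptides excluded, their terminus
not being a cleavage event) and the residue immediately upstream of the
N-terminus (protein N-terminal peptides excluded). A zero denominator is
an error naming the context, not a silent `NaN`.

## Mass-shift landscape

Open searches report a delta mass per peptide. Observed shifts are binned
to a bundled monoisotopic catalog within a 0.01 Da tolerance; the catalog
is computed from standard atomic masses (H 1.00782503207, C 12 exactly,
N 14.0030740048, O 15.9949146196 Da):

| name | composition | shift (Da) |
|---|---|---|
| methylation | +CH2 | 14.0157 |
| oxidation/hydroxylation | +O | 15.9949 |
| formylation | +CO | 27.9949 |
| dihydroxy | +O2 | 31.9898 |
| acetylation | +C2H2O | 42.0106 |
| carbamidomethyl | +C2H3NO | 57.0215 |

Frequency tables count a peptide once per distinct shift it carries;
residue distributions weight multi-event peptides by 1/(number of
events) so percentages sum to 100. Both normalization statements are
property-tested. The exclusion list for the frequency table is taken
literally as configured (typically carbamidomethylation, methionine
oxidation and terminal acetylation, the modifications a closed search
already models); note that "C-terminal acetylation" in common usage most
likely denotes protein *N*-terminal acetylation — the catalog carries the
acetyl mass either way and the exclusion is by mass, so the distinction
does not change results.

The five-way stratification (tryptic/miscleaved × unmodified/modified,
with miscleaved-modified split into methyl-K and other) assigns every
unique peptide to exactly one category; fractions of the total sum to 1
to within 1e-12, and the conditional split within
miscleaved-and-modified is the diagnostic for methylation-coupled
miscleavage. A peptide carrying both a methyl-K and another modification
lands in the methyl-K category.

## Spatial matrix processing

The intensity matrix holds log2 intensities with missing values. The
processing order is: keep fully quantified rows (complete in every
voxel), quantile-normalize, then filter by spatial variability. SE here
is the standard error of the mean — the row's sample standard deviation
(n−1 denominator) divided by √(number of voxels) — and the default
cutoff is SE > 0.18, strict, so a protein exactly at the boundary is
dropped. The cutoff is a parameter, so a plain-SD convention is reachable
by rescaling (multiply the cutoff by √n). SE is computed on the log2
scale.

One genuine small-sample caveat, exposed by the synthetic tests and worth
stating: quantile normalization assumes most proteins are spatially flat,
so that forcing every voxel onto a common intensity distribution removes
technical, not biological, variation. On a matrix of a few dozen proteins
dominated by planted modules, the module signal *is* the column
distribution difference and quantile normalization removes it. The
pipeline therefore exposes `quantile_norm: false`; on realistically sized
matrices (hundreds of proteins, few of them spatially variable) the step
is benign and stays on by default.

## Co-regulation networks

Signed Pearson correlation between protein rows is mapped to a weighted
adjacency with a soft power: unsigned `a = |r|^β` (default β = 6) or
signed `a = ((1+r)/2)^β` (default β = 12), the weighted co-expression
convention. Unsigned is the default so that anti-correlated partners stay
adjacent to a seed, and the signed correlation matrix is always carried
alongside so inverse partners remain identifiable (`r ≤ −t`, default
t = 0.6). Since `x^β` is monotone on [0,1], neighborhood *rankings* in
unsigned mode do not depend on β; only thresholded selections do.

Topological overlap smooths the adjacency by shared neighbours:

TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),
k_i = Σ_{u≠i} a_iu,

with unit diagonal. Modules are average-linkage clusters of the
dissimilarity 1 − TOM cut at a fixed height (default 0.5); singletons get
the unassigned label "0". Seed neighborhoods default to the top 23
partners by adjacency, ties broken by ascending accession for
determinism. The threshold selection rule's direction is configurable
(`≥ t` or `≤ t`) because published neighborhood cutoffs have been stated
in both directions; top-k ranking is the default.

## Term maps and enrichment

A term map is the per-voxel summed intensity of an annotated protein
set. The default sums on the linear scale (2^x back-transform from log2)
because summing log intensities has no physical meaning; a log2-scale sum
is available behind a flag for comparison. Maps are rendered as SVG
choropleths over the voxel polygons: min → dark blue rgb(0,0,139), max →
dark red rgb(139,0,0), linear in between, excluded voxels grey. An
all-equal map renders mid-ramp (0.5) everywhere rather than dividing by
a zero range. Enrichment of a protein set against a local annotation
table is an upper-tail hypergeometric test with Benjamini–Hochberg
adjustment — a deliberate local stand-in for web-service enrichment,
whose p-values depend on the service's database version and are not
reproduced here.

## The synthetic-data generator

**Intensities.** The generative model is
`x_pv = μ_p + λ_p · s_m(p)(v) + ε_pv`, ε ~ N(0, σ²) iid, with all
proteins sharing the baseline μ (default 20 log2 units), module members
carrying loading ±λ on their module's spatial profile, and background
proteins λ = 0. Profiles: *gradient* is linear in retained-voxel index
(0 to 1); *hotspot* is 1 on a centre voxel and decays as exp(−grid
distance); *uniform* is constant. Defaults: 2 modules × 10 proteins +
30 background, 20% of module members anti-correlated, σ = 0.1, 10%
missing completely at random outside the fully-quantified core (the
module proteins, by default). The loading default λ = 4 log2 units is
chosen so that planted members are "spatially changed" in the sense of
the SE > 0.18 convention — over 17 voxels that cutoff demands a spatial
SD of ≈ 0.74, and a gradient profile has SD ≈ 0.32λ. At σ = 0 the model
is a closed form, which the tests exploit for exact recovery checks.

**Peptides.** Records are drawn with replacement from the 0-missed
tryptic digest (length 7–35) of a supplied FASTA; the default synthetic
proteome (200 × 400 residues, human-like composition) yields a pool of
roughly 6500 peptides, keeping repeated draws of one peptide within one
voxel rare — this matters because the QC estimators count unique
peptides per voxel, and a small pool would inflate rate estimates by
collapsing duplicated unmodified peptides. Planting order: missed
cleavage (probability `p_misclv`, merging a fragment with its
neighbour), modifications (per entry, a Binomial(n, p) number of events;
target residues sampled from the entry's weights; each event placed on a
uniformly chosen occurrence in a uniformly chosen eligible peptide not
yet carrying that shift — this two-stage scheme keeps both the
peptide-level frequency and the residue distribution unbiased), lysine
methylation with miscleavage coupling (a methylated C-terminal K escapes
cleavage with probability `methyl_misclv_coupling`, default 0.9, merging
the peptide rightward so the methyl-K becomes internal), then
semi-tryptic trimming (1–3 residues off one terminus, validated to yield
a semi-tryptic classification without clipping planted events or the
miscleavage junction; if no valid trim exists the peptide stays
tryptic). Digest defaults (2% semi-tryptic, 11% base miscleavage,
oxidation 6% mostly on proline, dihydroxy 3%, formylation 1% on lysine,
methylation 3% on lysine) reproduce the QC levels characteristic of
well-behaved FFPE digests.

Ground truth is recorded by construction and the construction is guarded
(trim validation, junction guards) so that ground-truth category counts
always equal exhaustive re-classification of the emitted table — an
invariant under test.

**Randomness.** Each generator call seeds one global stream and consumes
it in a fixed, documented field order (intensities: noise matrix then
missingness mask; peptides: draws, miscleavage, modifications, coupling,
trims, voxels, spectral counts). Partial regeneration is impossible;
bit-identical reproducibility is total.

**What the generator does not emulate.** Correlated (intensity-dependent)
missingness, peptide-to-protein roll-up noise, shared peptides between
proteins, retention-time or spectral artifacts, and realistic protein
abundance ranges (all proteins share one baseline). Passing recovery
tests therefore demonstrates estimator correctness under a clean
generative model, not robustness to every artifact of real data.

## Numerical choices and degenerate inputs

Problem sizes in the test-suite simulations: n = 5000 peptides for
binomial 3σ recovery of digest parameters; 50 × 17 intensity matrices for
network recovery; ≤ 30 nodes where matrices are compared against
brute-force triple-loop oracles (tolerance 1e-12). Ties are broken by
ascending accession everywhere a ranking is emitted. Zero-variance rows
or columns are errors naming the offender (they have no defined
correlation), empty voxel groups are dropped with a warning, an empty
retained set after SE filtering is allowed, and an empty conditional
stratification table is a value, not an error. The miscleavage-rate
recovery check sets the methylation probability to zero, since the
methylation-miscleavage coupling deliberately adds miscleavage beyond
`p_misclv`.

## Pipeline

`run_pipeline()` executes qc → rank → spatial → network → termmap from a
strict-schema YAML config (unknown keys rejected; defaults: SE cutoff
0.18, top-k 23, unsigned β = 6). With `simulate: true` the inputs come
from the bundled synthetic conditions (overridable under the `sim:`
key), and every run writes a manifest with per-file MD5 hashes — the
same config and seed reproduce identical hashes. A thin command-line
wrapper is installed under `exec/voxelprot.R`.

```{r example, eval = FALSE}
cfg <- system.file("extdata", "demo_run.yaml", package = "voxelprot")
man <- run_pipeline(cfg)
names(man$files)
```

## Known limitations

Dataset-scale results of any particular study (total identification
counts, specific seed networks, web-service FDR values) depend on raw
data and database versions and are outside what this package recomputes;
the package reproduces the *methods* and verifies them on synthetic
ground truth. Quantile normalization is distribution-destroying on
module-dominated small matrices (see above). The hypergeometric
enrichment ignores annotation-term dependence, as the standard
over-representation test does.
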