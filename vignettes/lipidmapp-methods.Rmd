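---
title: "Methods: in-silico lipid libraries, spectral annotation and metabolite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico lipid libraries, spectral annotation and metabolite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmapp)
```

lipidmapp implements a multi-platform metabolomics analysis chain for
comparing cell types — here a mouse embryonic fibroblast line (m15), mouse
embryonic stem cells (mESC) and induced pluripotent stem cells (iPSC) —
from tandem-MS lipid annotation through multivariate fingerprinting,
univariate differential statistics and metabolite-network mapping. This
vignette documents the models, the tunable parameters and their defaults,
the numerical choices, and what the packaged synthetic scenario does and
does not establish.

## In-silico lipid MS/MS library

Lipid species are modeled as a class backbone plus acyl chain
contributions. Each class has a fixed backbone elemental formula, e.g.
glycerophosphocholine (C8H20NO6P) for PC, glycerophosphoethanolamine
(C5H14NO6P) for PE, glycerol for TG/DG, carnitine for acylcarnitines, and
a fixed d18:1 sphingoid base for SM (reported lipid totals at class C:DB
resolution do not constrain the sphingoid base, so one is fixed by
convention). Each esterified chain with `c` carbons and `d` double bonds
contributes the fatty acid minus water (C_c H_{2c-2d-2} O). Plasmenyl
(plasmalogen) species carry an O-alk-1-enyl chain at sn-1: relative to the
diacyl species of the same C:DB the formula loses one oxygen, and the
vinyl-ether double bond is implicit rather than counted — the LipidMaps
"P-" convention. Plasmanyl (O-alkyl) species are not modeled.

Monoisotopic masses are computed from atomic masses hard-coded to six
decimals (IUPAC 2021), so the library requires no network access and mass
arithmetic is testable to 1e-4 Da. Protonated precursors add the proton
mass (1.007276 Da), sodiated precursors the Na+ cation mass; the default
enumerates `[M+H]+` only, matching positive-ion-mode acquisition, with
`[M+Na]+` available per class in the configuration.

Enumeration covers, per class, every unordered chain multiset from a
configurable pool. The default pool is the common even-chain fatty acids
14:0, 16:0, 16:1, 18:0, 18:1, 18:2, 18:3, 20:4 and 22:6 — a deliberate
config choice, since no specific enumeration pool is canonical. For
plasmenyl classes the sn-1 ether position is chemically distinct from the
sn-2 acyl position, so ordered (ether, acyl) pairs are enumerated. Output
order is deterministic: class, total carbons, total double bonds,
lexicographic chains.

Fragmentation rules are fixed intensity templates per class, not learned
spectra: annotation matches identities, not quantitative intensities. For
protonated choline lipids the dominant ion is the phosphocholine head
group at m/z 184.0733 (template intensity 999), with the precursor kept
at 500 and per-chain neutral losses of the free fatty acid and its ketene
at 100. PE-family species lose the phosphoethanolamine head (141.0191
Da), PS the phosphoserine head, acylcarnitines show the m/z 85.0284
marker, TG/DG show fatty-acid losses. The 999/500/100 template is
configurable via `predict_fragments(intensity_template=)`.

## Spectral annotation

Candidate filtering uses the accurate-mass rule: a library precursor is a
candidate only if its m/z error is strictly below `tol_mDa`, default 1.5
mDa, the tolerance appropriate for an accurate-mass QTOF. Ion traps
acquire at roughly unit resolution, so a 500 mDa default is suggested for
them; neither value is a claim about any particular instrument. The
instrument model also encodes the one-third mass exclusion rule: an ion
trap cannot retain fragments below ~precursor/3, which removes the m/z
184 choline head group for typical phospholipid precursors — the
structural reason QTOF spectra discriminate head groups better.

Fragment similarity is the cosine of square-root-transformed intensity
vectors (the NIST-style dot-product convention) over peaks paired
greedily by nearest m/z within `frag_tol_Da` (default 0.01 Da QTOF, 0.5
Da ion trap), each peak participating in at most one pair; unmatched
peaks of either spectrum enter as zero-matched dimensions. Greedy rather
than optimal assignment is standard practice and deterministic; at 0.01
Da tolerance the difference is negligible. Candidates rank by score, then
absolute precursor error, then name — a fully deterministic order. The
default `min_score` of 0.5 stands in for the manual confirmation step a
human curator would apply; it is the main sensitivity/precision dial.

## Feature tables and normalization

Intensity tables are samples × features with group labels and a platform
tag. Missing values are encoded as `NA`, never zero (zeros would bias
fold changes); statistics drop missing values pairwise. Normalization
divides each sample by its total intensity so samples compare on relative
composition; it is idempotent and invariant to per-sample rescaling, and
is applied per platform before merging since total ion current is not
comparable across instruments. Merging concatenates features over the
shared samples with platform-qualified feature ids; features measured on
several platforms are kept separate so they can be checked for
concordance (`cross_platform_concordance`, per-feature Pearson r) rather
than silently averaged.

## Ordination

PCA is mean-centered (unit-variance scaling optional and off by default,
as the inputs are already relative compositions) with a deterministic
sign convention: the largest-magnitude loading of each component is
positive. PLS-DA regresses the centered group-indicator matrix on the
centered intensities via NIPALS with X deflation, tolerance 1e-10, at
most 500 iterations per component; two components are extracted by
default, matching a two-dimensional score plot. Group separation is
quantified as the mean silhouette width on the first two score
components — a scalar that turns "the groups form distinct clusters"
into an assertable quantity.

## Differential statistics

Per feature, the omnibus one-way ANOVA F across all cell types gives the
p-value; the pairwise fold change is the ratio of group means of
normalized intensities and the percent difference is `(fold - 1) * 100`.
Direction is `up`/`down` only when the raw ANOVA p is below alpha = 0.05.
No multiple-testing correction is applied by default — a deliberate
faithful-reproduction choice matching analyses that report raw ANOVA
p-values at p < 0.05 — and a Benjamini-Hochberg option
(`adjust = "BH"`) is available for users who want FDR control. Using the
omnibus p rather than pairwise t-tests for the direction call is an
interpretation; it matches a single significance column per feature.

## Metabolite network

Nodes are metabolites with structural fingerprints; edges are of two
types. Chemical-similarity edges connect pairs whose Tanimoto coefficient
on the 0–1000 integer scale is strictly greater than 700 (the threshold
is literal: 700 itself does not connect). Biochemical edges connect pairs
listed in a reaction-pair table (KEGG RPAIR-shaped: substrate–product
pairs of enzymatic reactions), regardless of similarity; a pair may carry
both edge types. All pairs above threshold are connected — the original
MetaMapp tool adds similarity edges more selectively to connect
components, a divergence documented here. The packaged reaction-pair
table is a small synthetic stand-in; users substitute a full RPAIR
export.

Fingerprints are fixed-length bit sets. They may be supplied precomputed
(0/1 strings in the metadata TSV) — the primary path, and the one the
synthetic scenario uses — or computed from SMILES as hashed atom-pair
substructure fingerprints (ChemmineR atom pairs folded to 1024 bits).
The hashed fingerprint is this package's own construction in the spirit
of substructure-key fingerprints; it is not the PubChem 881-key
dictionary, and Tanimoto values from different fingerprint definitions
are not interchangeable — hence the escape hatch for precomputed keys.

Node attributes encode the differential results: red (`up`) when p <
alpha and fold > 1, blue (`down`) when p < alpha and fold < 1, white
otherwise, "not measured" for nodes without statistics. Node size is
`s_min + k * |log2 fold|` clamped to `[s_min, s_max]` — the log scale
keeps a doubling and a halving the same size, since "scales with fold
change" is otherwise unparameterized. Exports are GraphML (lossless for
node/edge sets and attributes; integer NA scores are written as -1
sentinels because GraphML has no integer NA) and SIF plus a
node-attribute TSV for Cytoscape. Layout is left to Cytoscape.

## The synthetic scenario: what it emulates and what it does not

`stemcell_scenario()` packages the study design: three cell types with 3
replicates for the direct-infusion lipid fingerprint and 6 replicates for
the chromatography platforms; multiplicative log-normal noise
(`sigma = sqrt(log(1 + cv^2))`, keeping intensities positive, the
standard MS noise model) with default CVs of 10% for direct infusion and
5% for chromatography — a plausible instrument-class ordering chosen
once, not an empirical claim, since true replicate CVs for such data are
unreported. Effects embed the qualitative biology: polyunsaturated PCs
(three or more double bonds) elevated in pluripotent cells with PC 36:3
at +53% in mESC; 1–3 double-bond PEs reduced with PE 36:3 at −33%;
amino acids down in pluripotent cells and lower still in iPSC; lyso
species lowest in iPSC; sphingomyelins, carbohydrates, citric-acid-cycle
members and free fatty acids unchanged. The mESC–iPSC contrasts are
deliberately much smaller than either type's contrast with m15, so that
unsupervised PCA separates fibroblasts from pluripotent cells while the
two pluripotent types overlap and only supervised PLS-DA resolves them —
the fingerprint structure the pipeline is meant to detect. An abundant
unchanged lipid pool dominates each sample's total intensity, so
total-intensity normalization distorts embedded ratios by under 1%
(expected group totals differ by ~0.6%); this mirrors the real-data
assumption that overall composition is roughly stable.

Spectra are simulated from library entries with Gaussian precursor jitter
(default SD 0.5 mDa), Gaussian fragment jitter (SD 0.005 Da), log-normal
intensity noise (CV 0.2) and i.i.d. fragment dropout (10%), with truth
labels written to a sidecar so recovery can be scored without leaking
truth into the analysis path.

What passing tests on this generator do *not* show: the noise is i.i.d.
log-normal with no ion suppression, no isobaric overlap beyond what the
enumerated library itself contains, no retention-time information, no
batch or drift structure, and fingerprints for synthetic metabolites are
class-templated bit sets rather than real chemistry. Results on real
data depend on exactly those omitted features.

## Numerical and evaluation choices

- Atomic masses to six decimals bound formula-mass error well below the
  1e-4 Da test tolerance; the test suite checks against an independently
  entered higher-precision table.
- The precursor filter uses strict inequality; widening the tolerance
  can only add candidates (monotonicity is tested).
- Annotation tie-breaks (equal scores) resolve by precursor error then
  name, so outputs are reproducible across runs and platforms.
- Degenerate inputs are rejected, not patched: all-zero samples in
  normalization, all-identical values or zero within-group variance in
  ANOVA, empty-vs-empty peak lists in similarity, two empty fingerprints
  in Tanimoto, zero-variance features in concordance (flagged `NA`).
- Problem sizes in the tests are desk-scale by design: the 543-entry
  default library, 500 simulated spectra for recovery, 200-node networks
  against a brute-force all-pairs oracle, 1000 null simulations for the
  ANOVA type-I rate.
- Effect-size recovery is evaluated as the mean estimate over 25
  independently seeded simulated experiments at the study design (n = 6
  per group, 5% CV): a single experiment of that size estimates a +53%
  effect with a standard error near 3 percentage points, so replicated
  evaluation measures estimator accuracy rather than one noise draw.
  This is also what `scripts/acceptance.R` reports.

## Known limitations

Fragment intensities are templates, so scores are dominated by peak
identity; negative ion mode, oxidized and odd-chain lipids, isotope
patterns, chimeric spectra and decoy-based FDR are out of scope.
PLS-DA components are not cross-validated — with more features than
samples a supervised projection will separate any labeling to some
degree, which is why the permutation check in the test suite exists and
why silhouette values from PLS-DA scores should never be read as
evidence of class difference on their own.
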