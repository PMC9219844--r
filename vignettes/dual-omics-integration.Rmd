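---
title: "Dual-omics EC-level integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-omics EC-level integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted LC–MS metabolomics and RNA-seq transcriptomics each produce a
list of dysregulated entities — features and genes — that live in different
identifier spaces. This package integrates the two layers where they
naturally meet: the Enzyme Commission (EC) code. Significant metabolites are
mapped to the enzymes that produce or consume them (compound → EC, keyed by
CAS registry number or compound name); significant genes are mapped through
their protein-domain families (gene → PFAM → EC, keeping only associations
at a chosen confidence tier, "gold" by default). A metabolic reaction whose
EC appears in **both** sets carries dual, mutually independent evidence of
dysregulation — the central output of the pipeline. Reactions are classified
as `transcript_only`, `metabolite_only`, or `both`, and exported as an iPath
selection file (green / blue / bold black edges respectively).

# The metabolite layer

## Mass arithmetic

All identification rests on monoisotopic mass arithmetic. A molecular
formula in Hill notation is parsed to element counts and summed over IUPAC
monoisotopic atomic masses (`element_masses()`, carbon exactly 12). An
adduct observed in positive-mode ESI has

$$ m/z \;=\; \frac{M + \Delta}{z} $$

where $\Delta$ is the electron-corrected mass shift (e.g. $+1.007276$ u for
M+H, $+22.989218$ u for M+Na) and $z$ the charge. Eight standard
positive-mode adducts are packaged: M+H, M+Na, M+NH3 (ammonium), M+K,
M−H2O, M−NH3, M+2H, M+H+Na. Annotation accepts every (compound, adduct)
pair whose theoretical m/z lies within a relative tolerance of the observed
value, sorted by |ppm error| with ties broken by adduct priority (protonated
first, doubly charged last) and then compound name. The default tolerance is
**10 ppm**: the packaged reference observations agree with theory to ≤ 5 ppm
wherever they are internally consistent at all, and a lock-mass calibrated
qTOF instrument is specified to < 2 ppm, so 10 ppm is conservative without
being promiscuous.

The packaged registry (`load_registry()`) carries ~30 named reference
metabolites with formula, CAS, KEGG, EC links and pathway memberships. Each
catalogued (compound, adduct, m/z) observation carries two flags computed
once by brute force over the full annotation grid: `verified` (within 10 ppm
of its stated adduct — 28 of 35 rows) and `ambiguous` (another compound ties
or beats it in |ppm|, so rank-1 identity rests on tie-breaks, e.g. the
isobaric resolvin E1 / 5S-hydroperoxy-18R-hydroxy-eicosapentaenoate pair).
Unverified rows are retained for transparency but excluded from accuracy
claims.

## Differential abundance

Retention-time alignment follows the peak-group idea: features matched
across runs by m/z (single-linkage within tolerance) that occur once per run
in most runs become anchors; each run is corrected by a monotone
piecewise-linear interpolation of anchor offsets toward the cross-run median
retention time, with retention times outside the anchor range left
unchanged. Technical replicate runs are then averaged (arithmetic mean) into
biological samples before testing — matching the averaging contract of the
emulated acquisition design.

Per feature, a two-sided Welch t-test is applied to
$\log_2(\text{intensity} + \text{pseudo})$ with pseudo-intensity 1.0 (zeros
are real in MS data). Benjamini–Hochberg adjustment produces q-values. Two
significance tiers are used downstream: q < 0.05 for the differential
tables, and a stricter raw p < 0.001 tier for the metabolite → EC step and
pathway scoring. Fold-changes are displayed in the signed convention
(+r for increases, −1/r for decreases, |value| ≥ 1).

Degenerate inputs are resolved by convention: equal constant groups give
p = 1; unequal constant groups give p = 0; groups with fewer than two values
give p = NA (flagged) while the fold-change is still reported.

# The transcript layer

The differential-expression stage is a deliberately simple, documented
stand-in — not a reimplementation of a negative-binomial GLM engine.
Counts are normalized by median-of-ratios size factors (per sample, the
median ratio of counts to the gene-wise geometric-mean reference, excluding
genes with any zero), then tested per gene by the same Welch-on-logs /
BH machinery as the metabolite layer, with pseudo-count 1. Its operating
characteristics are validated only against synthetic ground truth: FDR is
controlled (log-normal noise makes the t-test on logs exact, and
negative-binomial counts behave well in simulation), and sensitivity at the
per-gene p < 0.05 level exceeds 0.9 for planted |log2FC| ≥ 2 at n = 3/3 and
dispersion 0.05. With three samples per group the Welch test has ~4 degrees
of freedom, which bounds how small its p-values can get; after BH selection
at q < 0.05 over thousands of genes, sensitivity necessarily drops
(~0.4–0.6 under the same conditions), concentrated in low-count genes. That
is an inherent property of an unmoderated two-sample test at n = 3 and the
main reason a production analysis would use a shrinkage-based engine; the
integration layer, not the DE engine, is the contribution here.

# Pathway activity

Pathway scoring conditions on the annotatable mass space: the universe is
the set of rank-1 annotated features, membership is by rank-1 compound. Each
pathway gets (i) a two-sided Fisher exact p from the 2×2
significant × membership table and (ii) an empirical p: B random
"significant" sets of the observed size are drawn from the universe
(resampling feature ids, preserving annotation structure), and

$$ p_{\text{emp}} = \frac{1 + \#\{b : \text{hits}_b \ge \text{hits}_{\text{obs}}\}}{B + 1}, $$

never exactly zero by the add-one rule. Note the empirical p is one-sided
(enrichment) while the Fisher p is two-sided; the two agree in rank on
enriched pathways (Spearman ≈ 0.97 in simulation) and deliberately diverge
on depleted ones. Pathway direction is summarized as the mean signed
fold-change of the significant member features (all members when none are
significant). Default B = 999; every permutation flows from the single
pipeline seed.

# The synthetic-data generator

The generator plants a complete, known truth so that every downstream stage
is testable offline. It emulates:

* a 2-group × 3-biological-replicate design with technical triplicate LC–MS
  runs (averaged by the pipeline);
* compounds emitted as 1–3 co-eluting adduct features (primary M+H at
  relative abundance 1.0, secondaries 0.3 / 0.1, retention jitter
  sd 0.01 min);
* planted differential compounds (fraction 0.2) with multiplicative
  fold-changes uniform in [4, 32], random direction;
* log-normal intensity noise (sd 0.3 on the natural-log scale) around
  base intensities log-uniform in [1e5, 1e7];
* Gaussian mass error with sd ppm/3 truncated at ±2 ppm (lock-mass
  accuracy), applied once per feature;
* per-run linear retention warps (slope ~ N(1, 0.01), offset
  ~ N(0, 0.05 min)) over a two-cluster retention model (hydrophilic
  mean 1.5 min, hydrophobic mean 8 min, 14-min run);
* negative-binomial counts (dispersion 0.05) with gene means log-uniform
  in [2, 2000] and planted DE genes (fraction 0.1, |log2FC| in [2, 4]);
* a coupled EC topology: 60% of the differential compounds' ECs are also
  assigned, at gold tier, to planted DE genes — each such EC to 2–4
  distinct carrier genes, reflecting that PFAM→EC associations are
  many-to-many and enzyme families contain multiple co-regulated paralogs.
  The planted dual-evidence overlap is the intersection of the two
  constructed layer sets, by definition.

What it does **not** emulate: raw spectra (peak picking is upstream of this
package), isotope patterns, in-source fragmentation beyond the packaged
neutral losses, batch effects, intensity-dependent variance, dropout, or
library-size imbalance. Passing tests therefore demonstrate correctness of
the pipeline's algebra and calibration of its statistics under a clean
generative model — not robustness to every artifact of real acquisitions.

# Numerical choices and tie-breaks

* Mass comparisons: ppm error is always relative to the theoretical m/z;
  additivity and adduct round-trips hold to 1e-9 u.
* Annotation search uses an m/z-sorted index with binary search; its
  contract is exact equality with a brute-force scan, which the tests
  enforce.
* Anchor maps enforce monotonicity by a cumulative-maximum pass over anchor
  targets before interpolation.
* EC comparison is exact string match on four fields; partial codes
  (`1.3.1.-`) are parsed but never match at overlap time.
* Adduct-group chaining breaks when the retention gap between consecutive
  members exceeds the co-elution window (default 0.2 min, an order of
  magnitude above the observed ~0.05 min spread of same-compound adducts).

# Problem sizes used in validation

The test suite simulates at reduced but representative sizes, chosen as the
package's own validation design: zero-noise exactness at 20 compounds;
empirical FDR of the metabolite layer over 200 simulated datasets of 30
compounds; EC-overlap recovery at the full default design (100 compounds,
2000 genes) over 50 seeds, asserting mean Jaccard ≥ 0.7 against planted
truth; permutation-null calibration over 500 null draws at B = 199,
asserting a rejection rate of 0.05 ± 0.02 at the 0.05 level.

# Known limitations

* The DE stand-in's power at n = 3 is well below that of moderated or
  GLM-based engines; reported per-gene statistics are not comparable to
  theirs.
* Annotation is rank-1 by mass alone; isobaric compounds are resolved only
  by the documented tie-break order, and isomers are not disambiguated.
* The compound registry and mapping tables are offline fixtures at toy
  scale; a production analysis would swap in full database exports behind
  the same file contracts.
* Pathway direction is a mean of signed fold-changes, which can mask mixed
  up/down pathways; inspect member-level tables for such cases.
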