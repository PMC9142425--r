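---
title: "PFAS suspect screening and isotope-dilution quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PFAS suspect screening and isotope-dilution quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroscreen)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) in complex environmental
matrices — here, biosolids destined for land application — are monitored
two ways at once from a single negative-mode LC-HRMS run: a *targeted*
analysis quantifies a fixed panel against isotopically labelled
surrogates, and a *suspect screen* matches every remaining feature
against a large formula library to flag PFAS the panel misses. This
package implements both halves and the exact-mass arithmetic they share.

## Exact-mass model

All masses derive from a bundled table of monoisotopic masses (most
abundant isotope, NIST/CIAAW values, shipped as plain text so it can be
checked independently). Two ion conventions cover negative-mode PFAS
work:

* deprotonated molecule: $m/z = M - m(\mathrm{H}) + m(e^-)$;
* intact fragment anion: $m/z = m(\text{fragment}) + m(e^-)$.

The electron mass (0.000549 Da) is deliberately included. On small
fragments it is worth several ppm — for C$_2$F$_5^-$ its neglect moves
the theoretical mass from 9.5 ppm to about 14 ppm away from the observed
118.9937, i.e. outside the $\pm 10$ ppm annotation rule the workflow
itself imposes. Tests pin this down as a discriminating case.

Mass defect is $m - \operatorname{round}(m)$ (nearest integer, result in
$(-0.5, 0.5]$), computed on the **observed precursor m/z**. Whether to
use the neutral or ionic mass is genuinely open — the convention here
reproduces both printed reference defects (0.0546 and 0.1337) from the
ionic values, so the ionic convention is adopted. The Kendrick transform
uses $KM = m \cdot \mathrm{nominal}/\mathrm{exact}$ with integer nominal
masses summed per element (CF$_2 \to 50$).

## Screening decision procedure

A feature becomes a reported candidate when it passes, in order: blank
subtraction, precursor match, fragment evidence, mass-defect rule, and
confidence-level assignment. The tunable parameters, with defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| precursor tolerance | 5 | ppm | Orbitrap full-scan accuracy at R = 70k |
| fragment tolerance | 10 | ppm | ddMS² at R = 17.5k is less accurate |
| retention-time tolerance | 0.2 | min | reference-standard confirmation window |
| mass-defect window | [−0.25, 0.1] | amu | halogenated-molecule range |
| `min_fragments` | 1 | count | see below |
| homolog series minimum | 3 | members | two points always align |
| KMD grouping tolerance | 0.002 | — | ~2 mDa, above transform jitter at 10 ppm |

**Fragment-count entry rule.** The headline screening criterion is often
phrased as "more than one supporting fragment", but the per-level
definitions require only *one* diagnostic fragment, and two kinds of
legitimate detections would be lost under the stricter count: compounds
whose confirmation rests on reference-standard spectra rather than
generic rules, and weaker-but-real single-fragment level-3 candidates.
The default entry rule is therefore the per-level one (`min_fragments =
1`, counting any evidence-bearing fragment: rule annotation,
reference-standard or library match); the stricter count is one
configuration flag away.

**Confidence levels.** Level 1 needs a reference standard (retention
time within tolerance *and* shared fragmentation); 2a a local
spectral-library record sharing at least two fragments; 2b at least one
*structure-specific* annotation with a unique-structure isomer set; 3 the
same evidence but structural ambiguity — more than one isomer in the
matched set, or only class-generic annotations (a CF$_3^-$ ion supports
"fluoroalkyl chain", not one positional isomer). All shipped alkyl-chain
and neutral-loss rules are class-generic; the 6:2 fluorotelomer-phosphate
chain fragment is marked structure-specific because ether cleavage pins
down the chain. Retention time plays no role below level 1: predicted
retention is out of scope, so only standards justify a time constraint.

**Tie-break.** An observed fragment matching two rules takes the smaller
absolute ppm error, and carries at most one annotation.

**Homologous series.** Features are sorted by KMD and grouped by
single-linkage at the grouping tolerance; within a group, members whose
rounded Kendrick masses agree modulo the base nominal mass (50) form a
series. Single-linkage can chain in principle; at realistic feature
densities and a 0.002 tolerance this is negligible, and the length-3
minimum suppresses chance pairs.

## Quantification model

Isotope dilution: response ratio $r = A/A_{IS}$, calibrated as
$r = a + b\,c$ by ordinary least squares (`stats::lm`). Equal matrix
suppression of analyte and surrogate cancels in $r$ — the tests verify
both the cancellation and parameter recovery (median absolute relative
error under 2% across 1–250 ng/g with 1% area noise).

Detection limits follow the blank-statistics formulas
$LOD = (S_b + 3\sigma_b)/b$ and $LOQ = (S_b + 10\sigma_b)/b$ where
$\sigma_b$ is the standard deviation of blank-replicate signals — the
only reading under which a zero mean blank signal still yields a
positive LOD. Three adjustments sit on top:

* **blank-adjusted LOQ** $= \max(LOQ,\ 3 \times c_{blank})$: all printed
  reference pairs (4.2 → 278.1 at blank 92.7; 1.5 → 9.9 at 3.3;
  3.3 → 9.0 at 3.0) satisfy the $3\times$ form exactly;
* **recovery-adjusted LOQ** $= LOQ / \text{recovery}$ when recovery
  < 60% — the simplest loss correction, applied as a separate optional
  operation because it is ambiguous whether published LOQs are pre- or
  post-adjustment;
* negative back-calculations floor at zero with a flag.

Labels: `n.d.` below LOD; `n.r.` when a blank-contaminated analyte fails
the $3\times$ rule or the adjusted LOQ; `<LOQ` between the limits with a
clean blank; numeric otherwise. Σ PFAS sums quantified means only — the
choice that makes the group totals reproducible from the per-analyte
values, and that keeps the total invariant to the presence of
non-quantified labels.

## What the simulator emulates — and what it does not

`generate_targeted_fixture()` reproduces the study design: triplicate
WAS/PS/blank groups, replicate heterogeneity as multiplicative
log-normal spread (8% WAS, 45% PS — concentrations are positive, and the
drier PS matrix plausibly carries contaminant hot spots), blank
contamination for the five blank-detected analytes, and a 1–250 ng/g
calibration. Replicate factors are rescaled so each group's empirical
mean equals its target exactly: the fixture's purpose is to test the
decision logic at the reported operating point, not to propagate
sampling noise into the reporting layer. Measurement (area) noise
defaults to zero with a knob (`area_rsd`); calibration noise likewise.
True concentrations for label-only entries are conventions documented in
the generator: `<LOQ` entries sit at the LOD–LOQ midpoint, `n.r.`
entries at 60% of the $3\times$-blank threshold.

`generate_suspect_fixture()` injects the seven screening compounds at
their observed precursor m/z, retention times and annotated fragment
lists. Two precursors are not reported anywhere and are reconstructed
(fragment + CO$_2$ neutral-loss mass for the glutamic-acid ester; the
theoretical [M−H]$^-$ for the phosphonic acid); retention times not
reported (5:3 FTCA, the glutamic ester) are arbitrary documented values,
and the tests use only relative retention matching. Fragment intensities
are a decreasing geometric profile — intensities carry no evidence in
this workflow. Decoys cover each rejection path: an FTOH (blacklisted
class), a 20 ppm mass decoy, blank-contamination peaks, and 30 random
matrix peaks with out-of-window defects and no MS².

What passing these fixtures does **not** show: robustness to retention
drift, isotope envelopes, in-source fragmentation, co-eluting isobars at
sub-tolerance separation, chromatographic tailing, or intensity
nonlinearity. The mzML path uses an intentionally simple greedy centroid
clustering (weighted-mean m/z, apex retention time, summed area) —
adequate for well-separated synthetic peaks, not a replacement for a
production peak picker; the CSV feature-table route is the canonical
tested input.

## Numerical choices and degenerate inputs

* Formulas are Hill notation; carbon-free formulas canonicalize
  alphabetically (`PO3` → `O3P`). Charges are never encoded in formulas.
* Salt curation strips exactly one Na/K and adds one H; multi-counterion
  formulas are removed outright (no published procedure exists; one
  substitution covers the common case and is idempotent).
* Blank matching aggregates blank replicates by their mean area before
  the $3\times$ comparison (the aggregation is unstated in the source
  workflow; the mean is the natural replicate summary) and reuses the
  identification windows (5 ppm, 0.2 min).
* Hydrogen-free formulas cannot be deprotonated: their theoretical
  [M−H]$^-$ is `NA` and they never match precursors.
* A missing surrogate area is a per-analyte error record, not a crash;
  an empty blank set downgrades blank subtraction to a warning and
  pass-through.
* Degenerate calibration (fewer than three distinct levels) is an error;
  a noiseless calibration line is legal and fits with $R^2 = 1$.

## Problem sizes used in the test suite

The suite runs the full screening fixture (87 features, 40 suspects,
5 seeds), a 1,000-decoy false-positive check, 200-sample quantification
recovery, 50-formula mass-oracle comparisons and the mzML round trips in
about ten seconds; these sizes were chosen as the smallest that still
exercise every decision path and give the property checks real
statistical content.

## Known limitations

Single-charge negative-mode chemistry only; no adducts beyond [M−H]$^-$,
no isotope-pattern scoring, no retention-time prediction, no
structure elucidation from SMILES (carried as opaque metadata), no
remote spectral-database queries (level 2a is a local-file comparison),
and semi-quantification of suspects is a single-point response factor
flagged as such. The bundled 40-entry suspect list is a synthetic
fixture in the shape of the EPA PFAS Master List schema; real screens
should load a current list via `read_suspect_list()`.
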