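---
title: "Evaluating fish lipid nutritional quality from fatty-acid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fish lipid nutritional quality from fatty-acid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidqual)
```

## The problem

Gas-chromatography surveys of fish report each fatty acid as a percent of
the total fatty-acid peak area (FAME area-percent). Those composition
vectors, together with crude lipid content and the species' trophic level,
are the raw material for a standard set of nutritional-quality questions:
how much of the fat is saturated versus polyunsaturated, how much of the
health-relevant long-chain omega-3 mass (EPA, DPA, DHA) a species carries,
and how its lipid profile scores on the dietary quality indices used in
food science. lipidqual implements that full analysis chain for
species-mean composition tables, with a 22-species estuarine survey
included as plain-text data.

## Data model

A **profile** is one species' named vector of percent values over
fatty-acid labels of the form `C<carbons>:<double bonds>` with an optional
omega suffix `n-<series>`. Labels are parsed structurally, so
classification never relies on a lookup of known acids: zero double bonds
is saturated (SFA), one is monounsaturated (MUFA), two or more is
polyunsaturated (PUFA). Not-detected entries ("ND" in the source tables)
are stored as zero and flagged, which makes them behave as absent mass in
every sum.

Two details of published tables need explicit handling:

* **Truncated labels.** The packaged survey prints the EPA row once as
  `C20:5n-` (the series digit lost in typesetting). A fixed two-entry
  alias table — not a fuzzy parser — maps such known variants to their
  canonical labels, so the correction is deterministic and auditable.
* **The series-less `C22:4`.** The survey lists `C22:4` among the PUFAs
  without an omega annotation. Its printed omega-6 range (maximum 8.31%)
  only reproduces when `C22:4` is *excluded* from the omega-6 sum, while
  its printed n-6/n-3 ratios (e.g. 0.49 for *Mugil cephalus*) only
  reproduce when it is *included* (as adrenic acid, C22:4 n-6). The data
  are internally inconsistent on this point, so the package records the
  ambiguity instead of resolving it: `omega_membership()` takes a
  `convention` argument, `"default"` counting `C22:4` as n-6 (the choice
  under which the index-level results reproduce) and `"strict"` counting
  only explicit annotations. All downstream stages thread the convention
  through.

Profiles are kept exactly as printed and never re-normalized to 100%,
because every published result lives on the as-printed scale; the
identified total (~82–96% in the survey) is reported alongside the class
sums.

## The five quality indices

With class sums SFA, MUFA, and the omega sums n-3 and n-6 (percent of
total fatty acids), and individual acids referred to by label:

* n-6/n-3 ratio = n-6 / n-3 (dietary guidance favours values below 4);
* P/S ratio = PUFA / SFA (values below 0.45 are considered undesirable);
* IA (index of atherogenicity, Ulbricht–Southgate)
  = (C12:0 + 4·C14:0 + C16:0) / (MUFA + n-6 + n-3);
* IT (index of thrombogenicity, Ulbricht–Southgate)
  = (C14:0 + C16:0 + C18:0) /
    (0.5·MUFA + 0.5·n-6 + 3·n-3 + n-3/n-6);
* HH (hypocholesterolemic/hypercholesterolemic ratio, Santos-Silva)
  = (C18:1n-9 + C18:2n-6 + C20:4n-6 + C18:3n-3 + C20:5n-3 + C22:5n-3 +
     C22:6n-3) / (C14:0 + C16:0).

Lower IA and IT, and higher HH and P/S, are favourable. Acids missing
from a profile contribute zero (C12:0 is below the reporting threshold in
the packaged survey, so its IA term vanishes there).

Two structural notes. First, the IT numerator is the plain three-term sum
of the saturates — source texts sometimes garble the parenthesization,
but the canonical Ulbricht–Southgate form is validated here by
reproducing the survey's printed per-species IT and its mean. Second,
four of the five indices are ratios of linear forms in the profile and
are exactly invariant under uniform rescaling; **IT is not**, because the
dimensionless n-3/n-6 term in its denominator does not scale. Shrinking a
profile uniformly strictly lowers IT. The effect is small at realistic
identified totals (rescaling a survey profile by 0.9 moves IT by ~1%) but
it is a real property of the published formula, and the test suite
asserts the true behaviour rather than a false invariance.

Degenerate inputs raise errors instead of returning sentinel numbers
(`NaN`, `Inf`), so a pathological synthetic profile cannot silently
contaminate a dataset-level mean. The one precedence rule: a zero IT
numerator (no C14:0/C16:0/C18:0 at all) returns 0 before the omega-6
check, since the index is unambiguously zero regardless of the diverging
ratio term.

## Lipid-content categories

Crude lipid (g per 100 g wet weight) maps to the four Ackman classes:
lean (< 2%), low fat (2–4%), medium fat (4–8%), high fat (> 8%). The
published bounds do not state which side is closed; here the boundaries
resolve as lean `[0, 2)`, low `[2, 4)`, medium `[4, 8]`, high `(8, ∞)` —
a choice consistent with the survey's published counts (11 medium, 7 low,
4 lean, 0 high), though no survey species sits exactly on a boundary, so
the convention is recorded rather than empirically forced.

## Statistical stages

* **Survey summary** (`class_means()`): across-species mean and sample SD
  (n − 1) of the class sums and of EPA, DPA, DHA. The analysis unit is
  the species mean — the per-individual values behind published tables
  are generally unpublished — so n equals the species count (22 here).
* **Trophic correlation** (`trophic_correlation()`): Pearson r between a
  class sum and trophic level, two-sided p from the t transform with
  n − 2 df (delegated to `stats::cor.test`; an independent
  covariance-formula oracle checks it to 10 decimals in the tests).
  Trophic-level SDs are carried in the data model but ignored here — no
  errors-in-variables model is attempted. Because species means (not
  individuals) enter the correlation, recomputed r can differ a few
  hundredths from values published from raw data: the packaged survey
  gives r = −0.44 for PUFA vs trophic level where the original analysis
  printed −0.42. The package asserts its own recomputed value.
* **Lipid-category ANOVA** (`lipid_class_anova()`): one-way `stats::aov`
  of a class sum across the non-empty Ackman categories with Tukey HSD
  contrasts at α = 0.05. An exactly constant response is reported as
  F = 0, p = 1 rather than the 0/0 floating-point artifact.

## Clustering

Species are clustered hierarchically (`stats::hclust`, Euclidean
distance) on the five-index matrix. The indices live on different scales
(n-6/n-3 spans ~0.1–0.5 while HH spans ~0.6–1.4), so per-column
z-scoring is on by default; without it the widest column dominates the
distances. Linkage is selectable (complete by default, average and Ward
D2 available) because the original figure's settings are unstated; on the
packaged survey the complete-linkage 4-group cut reproduces the published
best-quality group membership exactly. Groups from the k-cut are
renumbered 1..k by increasing composite quality — mean z-score of the
favourable indices (HH, P/S) minus mean z-score of the unfavourable ones
(IA, IT, n-6/n-3) — so "group k" always reads as the nutritionally most
desirable cluster and the numbering is invariant to input row order.
Agglomeration in `hclust` is deterministic; equal-distance ties resolve
by the lowest cluster indices.

## The synthetic-data generator

`simulate_dataset()` exists so every pipeline stage is testable on data
with known ground truth. Its defaults emulate the packaged survey's
structure: 22 species × 10 individuals; trophic levels uniform on
[2.0, 4.5]; class sums around SFA 38.9 / MUFA 31.1 / PUFA 20.9 percent
(≈91% identified); lipid contents uniform on [0.5, 7.5] g/100 g; and a
within-species coefficient of variation of 8%, a typical replicate spread
for FAME area-percent data. Class mass is spread over the 26 survey
fatty-acid labels by proportions frozen once from the survey (C16:0
carries ~66% of the SFA mass, DHA ~41% and EPA ~32% of the omega-3
mass), so synthetic profiles look realistic without touching the fixture
at run time. Noise is multiplicative log-normal with mean exactly 1,
which keeps values non-negative without rejection sampling; the rare
profile whose total exceeds 100% (a ~3.7σ event at the default noise) is
rescaled onto the simplex boundary so profile invariants hold by
construction. Trophic-level effects enter as linear shifts of the PUFA
(and optionally omega-6) mass per trophic-level unit, centred mid-range;
the default slopes are zero, making the generator a null model whose
correlation-test size the suite verifies empirically (≈5% over 200
seeds), with sign recovery checked at slope −4%/level and cv 5%.

What the generator does *not* emulate: compositional closure beyond the
total cap (real class sums co-vary negatively because percentages
compete), species-level phylogenetic structure, seasonal or size
covariates, and ND censoring of trace acids. Passing tests therefore
demonstrate correctness of the pipeline's arithmetic and inference under
a clean, known data-generating process — not robustness to every
artifact of real survey data.

## Problem sizes and numerical choices

The test suite runs the full golden reproduction on the 22-species
fixture (sub-second per stage), 200-seed null and power simulations for
the correlation test, and short property loops (rescaling, round-trips,
permutations); the whole suite completes in well under two minutes on a
single CPU. All internal computation is double precision; published-value
comparisons round to the printed precision (2 dp for indices, 1 dp for
percentage shares) only at the comparison point. Two published values are
knowingly *not* asserted: the survey's IT minimum (printed 0.38 for
*Trypauchen vagina*; the species-mean recomputation gives 0.34 under
either C22:4 convention) and its abstract-level r = −0.42 — both appear
to derive from unpublished individual-level data, and the package asserts
its own recomputed values (0.34, and r ∈ [−0.50, −0.35]) instead.

## Worked example

```{r example}
ds <- load_study_fixture()
categorize_dataset(ds)

ind <- nutritional_indices(ds)
round(colMeans(ind[, -1]), 2)

trophic_correlation(ds, "pufa")

cl <- cluster_species(index_matrix(ind), k = 4)
names(cl$groups)[cl$groups == 4]
```

## Limitations

The package analyses species-mean area-percent tables; it does not model
absolute concentrations (mg/100 g), individual-fish variation beyond the
simulation module, cis/trans isomers, or lipid-class (phospholipid vs
triacylglycerol) partitioning. Index formulas are the standard published
forms; alternative literature indices (FLQ, NVI, unsaturation index) are
out of scope.
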