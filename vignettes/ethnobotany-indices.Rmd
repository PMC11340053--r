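---
title: "Consensus indices, knowledge comparisons and the synthetic survey model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus indices, knowledge comparisons and the synthetic survey model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoindices)
```

## The data model

Everything in this package reduces to one atomic datum, the **use report**:
informant *i* cites species *s* for ailment *a*. An `eb_dataset` bundles the
report table with informant demographics, species metadata and an
ailment-to-category map, and enforces three things at construction time:

1. **Referential integrity** — every report points at a known informant and
   species; violations are errors, not silent drops.
2. **Report-key uniqueness** — the key is the triple (informant, species,
   normalized ailment). An informant who mentions the same species–ailment
   pair twice, say once as fresh leaves and once as a dried decoction,
   contributes *one* use report; preparation and plant part are metadata.
   This convention is the only reading under which published per-species
   report counts we transcribe are arithmetically coherent, and duplicates
   are collapsed with a warning so the decision is visible.
3. **Ailment normalization** — case folded, trimmed, internal whitespace
   collapsed. Anything stronger (merging true synonyms, or deliberate
   spelling variants such as a "tung"/"lung" confusion in a source table)
   must arrive through an explicit synonym table; the package never merges
   distinct labels on its own, because silent merges change every consensus
   count downstream.

Counts are stratified by ethnic group. The group denominator `N_g` is the
number of informants *interviewed* in the group, not the number who cited
anything — a species nobody mentions has `UV = 0`, and a listed-but-uncited
species is legal and contributes zeros everywhere.

## The five indices

For species *s* in group *g*: `FC` = distinct citing informants, `UR` = use
reports, `NU` = distinct ailments. Always `FC ≤ UR` and `NU ≤ UR`, and UR
decomposes as the sum of per-ailment informant counts; the test suite checks
these identities against brute-force loops on randomly generated
micro-surveys.

**Use value.** `UV = UR / N_g`. The published tables we replay print UV per
group with `N_g = 63`; on the arithmetically consistent rows this
reproduces the printed value at printed precision exactly. A handful of
source rows contradict their own integer ingredients (the transcription
flags them in `uv_consistent`), and those are excluded from exact replay
rather than "fixed": the fixtures preserve what was printed.

**Informant consensus factor.** `ICF = (n_ur − n_t)/(n_ur − 1)` per ailment
category. The category layer is supplied by the `AilmentCategoryMap`; with
fewer than two reports the denominator vanishes and the function returns
`NA` with a warning rather than a number — an undefined consensus is a fact
about the data, not a zero. Bounds and both boundary cases (`ICF = 1` iff
one species, `ICF = 0` iff all species distinct) are property-tested.

**Fidelity level.** `FL = 100·N_s/FC_s` for one species–ailment pair.
`FL` is undefined (a domain error) when the species was never cited for the
ailment; returning 0 would conflate "never asked about" with "rejected".

**Relative popularity level.** The published one-sentence definition of RPL
does not reproduce its own printed values (the same species carries
different RPLs for different ailments in the source tables, and a few rows
break `ROP = RPL·FL` at printed precision), so the package separates two
modes honestly. The default *threshold* mode implements the classic
popular/unpopular rule: species with `FC` at or above half the group
maximum get `RPL = 1`, the rest `FC/(max FC/2)`; the threshold is exactly
`max/2` with no integer truncation, so ties at the threshold are popular.
The *supplied* mode is a validated pass-through used to replay printed
tables. The reproducible identity `ROP = RPL·FL` is asserted to machine
precision either way.

**Minimum-citation filter.** Indices are conventionally reported only for
species claimed by three or more informants; `min_citation_filter()` and
the `min_citations` arguments implement that, with `group = "all"` keeping
a species that clears the bar in any single group.

## Display conventions

All index values are computed and stored at full double precision. One
formatting layer (`format_index_table()`, `round_half_up()`) applies the
customary display rounding — UV 3 dp, ICF 2 dp, FL 2 dp, RPL 2 dp, ROP to
the nearest integer — rounding halves *away from zero*, which is how the
published tables we replay display `73.71 → 74`. Where a source table itself
rounded an exact half the other way (one ICF of 0.625 printed as 0.62),
replay tests compare at half-a-unit of printed precision instead of
imposing our convention on someone else's rounding. P-values print at 4
decimals floored at 0.0001; raw values are kept in the returned objects.

## Demographic comparisons

The response is the **knowledge score**: distinct species cited per
informant, zero for informants absent from the report table. Comparisons
are nonparametric — score distributions are discrete, skewed and tie-heavy:

- ≥3 levels: Kruskal–Wallis rank test with tie correction,
  `df = levels − 1`;
- 2 levels (gender in the emulated study): the two-sample Wilcoxon rank-sum
  test — the groups are independent informants, so the paired variant would
  be wrong;
- per-level summaries use the sample (n−1) standard deviation;
- degenerate inputs follow explicit contracts: empty levels are dropped
  with a warning, and if every score is identical the statistic is 0 and
  p = 1 (no evidence of difference), instead of the 0/0 the raw statistic
  would produce.

The age–knowledge association is a least-squares regression of score on
age, quadratic by default (`curvilinear = TRUE`) to capture the
rise-through-middle-age, fall-among-the-eldest shape; the quadratic is the
smallest polynomial with that shape and its R² is comparable across runs. A
LOESS curve would fit the bend equally well but has no comparable
variance-explained summary. Rank statistics are invariant under strictly
monotone transforms of the scores, and R² is invariant under score shifts —
both property-tested.

## The synthetic survey generator

The generator exists so every stage is testable end to end with no field
data. Its defaults encode the emulated study's printed summaries, and they
are study conditions, not tuning knobs:

| parameter | default | source of the default |
|---|---|---|
| groups | 3 × 63 informants | the study's stratification |
| age classes | 35–44, 45–54, 55–64, 65+ with weights 33/45/88/23 | printed class frequencies |
| ages within class | uniform integers; eldest class capped at 77 | stated 35–77 age range |
| knowledge curve | per-class Normal(mean, sd): 4.73 ± 0.94, 6.84 ± 1.74, 7.9 ± 1.72, 5.09 ± 1.47, rounded, clipped to [0, n_species] | printed class means ± SD |
| species pool | 189 species, selection weight ∝ rank⁻¹ | documented species count; Zipf skew is the standard citation-popularity model |
| ailments | 100, round-robin over 14 categories | printed ailment and category counts |
| repertoire | each species treats 1 + Poisson(2) ailments (≤ 8); a citing informant reports 1–3 of them | plausible ranges for the source's per-species use lists |
| demographics | gender 133/56, education 89/81/19, religion 101/13/75, occupation 155/23/11 | printed composition |

Randomness is Mersenne–Twister with rejection sampling for `sample()`,
seeded per stage (`seed` for informants, `seed + 1` for reports), so a
config plus seed determines the dataset byte for byte across platforms, and
the caller's RNG state is restored afterwards. The fast path
`simulate_knowledge_counts()` draws only the per-informant species counts;
`simulate_use_reports()` realises exactly those counts, so calibration
statistics computed on the fast path are distributed identically to the
full pipeline's.

**What the generator does and does not emulate.** It reproduces the
marginal structure the analysis consumes: group sizes, age-class knowledge
means and spreads, skewed species popularity, category structure. It does
not model informant-level correlation between demographics (e.g. education
confounded with age), healer specialisation (informants focused on one
disease category), shared cultural repertoires within groups, or
nonresponse. Passing tests therefore certify the *arithmetic and the
statistical procedures*, not any claim about real survey dynamics beyond
those marginals.

**Calibration.** With the per-class knowledge curve above, the
between-class share of score variance is ≈ 0.40, but a quadratic in
*continuous* age cannot recover all of it (ages are uniform within classes
and the class means are not exactly quadratic): across 200 seeds the
quadratic fit's R² has median ≈ 0.30, comfortably inside the
0.27–0.47 envelope the package asserts for the median. The envelope is a
property of the median, not of individual seeds — at n = 189 the sampling
SD of R² is ≈ 0.05, so no generator could hold 200 independent draws
inside a ±0.10 band, and a seed-wise assertion would be meaningless. We
considered smooth age curves through the class means (least-squares
quadratic, natural spline, piecewise-linear interpolations land the median
at 0.43, 0.40 and 0.27 respectively) and kept the per-class draw because it
is the model the class summaries actually state. The same emulated
conditions give the Kruskal–Wallis test essentially unit power at α = 0.05
(rejection rate 1.00 over 200 replicates) while a flat knowledge curve
holds its size (type-I rate within Monte-Carlo error of 0.05 over 1000
replicates). Popularity-rank recovery is asserted on the seed-averaged
citation frequencies (Spearman ρ ≥ 0.9 against the configured weights over
12 seeds at the default skew); per-seed rank correlations are bounded near
0.77 by tail-count noise at 189 informants under any Zipf exponent, so the
averaged form is the recoverable statement.

## Problem sizes and runtime

The test suite runs the full oracle-equivalence sweep on 100 random
micro-surveys (≤ 10 informants, ≤ 8 species — small enough that brute-force
loops are unambiguous), 1000 null replicates for test size, 200 replicates
each for power and the R² envelope, all at the study scale of 189
informants via the fast score path; the whole suite completes in about a
minute on one CPU. These sizes were chosen so the Monte-Carlo standard
errors are well inside the asserted tolerances.

## Known limitations

- The transcribed fixture tables inherit their source's defects: a few
  printed UV values contradict their own integer ingredients, two priority
  rows break `ROP = RPL·FL` at printed precision, one row lacks its FL and
  one its decimal point. All are flagged in the fixtures
  (`uv_consistent`, `note`) and excluded from exact replay; none are
  silently corrected.
- RPL in threshold mode depends only on FC, so it cannot reproduce sources
  that assign one species different RPLs per ailment; use supplied mode to
  replay such tables.
- Scientific names are opaque strings; there is no taxonomic resolution,
  and the species fixture carries name, family and voucher only.
- The demographic tests are marginal one-variable comparisons, matching
  standard survey practice; no multivariable or mixed models are fitted.
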