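# ethnoindices

Quantitative analysis of ethnobotanical surveys built on informant
**use reports** — one informant citing one plant species as a remedy for one
ailment. The package is aimed at ethnobotanists and ethnopharmacologists who
collect semi-structured interview data from traditional healers and need the
field's standard consensus and importance indices as transparent, auditable
arithmetic rather than spreadsheet formulas, together with the
socio-demographic knowledge comparisons that usually accompany them.

## The indices

With `N_g` informants in group *g*, and for each species its frequency of
citation `FC` (distinct citing informants), use-report count `UR` and
distinct-ailment count `NU`:

- **Use value**  `UV = UR / N_g` — the species' relative importance to the
  community.
- **Informant consensus factor**, per ailment category with `n_ur` use
  reports over `n_t` distinct species:
  `ICF = (n_ur − n_t) / (n_ur − 1)` — 1 when everyone agrees on one species,
  0 when every report names a different one, undefined for `n_ur < 2`.
- **Fidelity level**, for a species and one ailment cited by `N_s` of its
  `FC_s` citing informants: `FL = 100 · N_s / FC_s`.
- **Relative popularity level** `RPL ∈ [0, 1]`: species whose FC reaches half
  the group maximum are popular (`RPL = 1`); below that threshold
  `RPL = FC / (max FC / 2)`. A supplied mode replays externally given values.
- **Rank-order priority** `ROP = RPL · FL` — fidelity corrected for
  popularity, used to shortlist species for pharmacological follow-up.

Knowledge comparisons use each informant's **knowledge score** (distinct
species cited): Kruskal–Wallis across ≥3 demographic levels, the two-sample
Wilcoxon rank-sum test for two, and a least-squares regression of score on
age with an optional quadratic term for the curvilinear rise-and-fall of
knowledge with age.

A seeded synthetic survey generator (`sim_config()`, `simulate_study()`)
emulates a three-ethnic-group medicinal-plant survey — 3 × 63 informants aged
35–77, an age-dependent knowledge curve, a 189-species pool with Zipf-skewed
citation popularity, 100 ailments in 14 disease categories — so the whole
pipeline is testable without field data. Packaged fixtures
(`eb_fixture()`) transcribe the study's printed summary tables;
`reconstruct_uv_dataset()` and friends rebuild minimal datasets from printed
integer ingredients so published index values can be *recomputed*, not
assumed.

## Worked example

```r
library(ethnoindices)

ds <- simulate_study(sim_config(seed = 42))
ds
#> <eb_dataset>
#>   189 informants in 3 group(s): Gedeo, Oromo, Sidama
#>   189 species, 2096 use reports, 95 distinct ailments
#>   14 ailment categories

head(format_index_table(uv_table(ds, "Gedeo")), 4)
#>   species_id group    fc    ur    nu    uv
#> 1 sp001      Gedeo    46    89     3 1.41
#> 2 sp002      Gedeo    33    33     1 0.524
#> 3 sp003      Gedeo    24    50     3 0.794
#> 4 sp004      Gedeo    20    46     5 0.73
```

`sp001` was cited by 46 of the 63 Gedeo informants, contributing 89 use
reports over 3 ailments, hence `UV = 89/63 = 1.41`: the workhorse remedy of
that group. The same dataset flows into the consensus and demographic layers:

```r
format_index_table(icf_table(ds, "Sidama"))[1:3, ]
#>   category    group    nur    nt   icf
#> 1 category 01 Sidama    30    17  0.45
#> 2 category 02 Sidama    62    26  0.59
#> 3 category 03 Sidama    29    16  0.46

scores <- knowledge_scores(ds)
compare_groups(scores, ds$informants, "age")
#> <knowledge comparison by age>
#>   35-44                n =  41   4.78 +/- 0.76
#>   45-54                n =  42   7.12 +/- 1.94
#>   55-64                n =  79   7.99 +/- 1.81
#>   65+                  n =  27   5.22 +/- 1.19
#>   Kruskal-Wallis: statistic = 90.713, df = 3, p = 0.0001

age_knowledge_fit(scores, ds$informants)
#> <age-knowledge quadratic fit>
#>   coefficients: intercept = -19.64, linear = 0.9729, quadratic = -0.008629
#>   R-squared = 0.358
```

Middle-aged healers cite the most species and the quadratic term is negative:
knowledge rises through middle age and falls again among the eldest — about a
third of the variance in this simulated survey is carried by age alone.

Replaying a published value from its printed integer ingredients:

```r
ds38 <- reconstruct_uv_dataset(fc = 16, ur = 38, nu = 14, n_informants = 63)
round_half_up(use_value(ds38, "sp1", "Oromo")$uv, 3)
#> [1] 0.603
```

A thin command-line front end over the same functions ships in
`inst/cli/ethnosurvey` (subcommands `simulate`, `indices`, `demographics`,
`report`; results go to files, logs to stderr, exit codes 0/1/2).

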