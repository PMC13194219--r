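# trunkvoc

Analysis of constitutive and herbivore-induced volatile emissions from
tree trunks, measured longitudinally by enclosure sampling and thermal
desorption GC–MS.

Wood-boring pests such as the Asian longhorned beetle live hidden inside
the trunk for most of their life cycle, where visual detection performs
poorly. Infestation, however, changes the trunk's volatile emission
profile: some compounds appear de novo, others are strongly upregulated,
and even undamaged neighboring trees respond. `trunkvoc` turns the raw
outputs of such a study — deconvoluted component tables, an n-alkane
ladder, a compound library, calibration levels, and a study design — into
annotated, quantified, classified and temporally modelled emission
profiles. It is written for analytical chemists and chemical ecologists
running enclosure-sampling VOC studies on woody plants.

## What it computes

* **Retention-index annotation** — linear retention indices from the
  alkane ladder, LRI = 100·n + 100·(t − tₙ)/(tₙ₊₁ − tₙ), matched against
  a reference library within a configurable tolerance, with
  identification-tier bookkeeping (M/R/S).
* **Calibrated emission rates** — OLS calibration lines (free intercept),
  surrogate-standard quantification for compounds without authentic
  standards, normalization to bark surface and sampling time
  (ng dm⁻² h⁻¹), and median-based separation of trunk volatiles from
  ambient background air.
* **Classification** — detection-frequency filters (DF ≥ 10 % retention;
  DF ≥ 50 % per tree pre-stress for the constitutive core) and inclusive
  twofold rules assigning each compound to *constitutive*,
  *herbivore-induced*, *neighbor-induced*, *stress-induced* or
  *unclassified*, with symbolic ratio marks ("ApI", ">", "ALB") when
  sub-threshold detection makes a ratio undefined.
* **Temporal dynamics** — daily M ± SE aggregation of duplicate samples,
  nonlinear fitting of the four-parameter asymmetric peak function
  y = y₀ + A·e^(−e^(−z) − z + 1), z = (x − x_c)/w, Kendall τ_b
  correlation grouping of emission patterns, and Kruskal–Wallis + Dunn
  rank tests of emission differences between trees and phases.
* **Synthetic studies** — a generator that emulates a three-tree,
  three-phase, 188-day infestation experiment with planted compound
  classes, lognormal noise and detection censoring, so the whole pipeline
  is testable against ground truth without instrument data.

## Worked example

```r
library(trunkvoc)
study <- generate_study(default_study_config(seed = 1))
res <- run_pipeline(study)
table(res$classification$label)
#>     constitutive             hipv neighbor_induced   stress_induced
#>               30               14                6                4
#>     unclassified
#>                1
```

The pipeline retained 55 compounds after background separation and the
10 % detection-frequency filter. Thirty form the constitutive core
(detected in ≥ 50 % of pre-stress samples at every tree); the induced
compounds split into herbivore-, neighbor- and stress-induced classes.
One planted herbivore-induced compound lands on the wrong side of an
almost exactly twofold increase at this seed — the generator's noise
level intentionally keeps recovery near, but not trivially at, 100 %.

```r
head(res$induced_table[, c("compound", "label", "df_pct",
                           "ratio_I_vs_N", "ratio_pre_post")], 6)
#>          compound            label df_pct ratio_I_vs_N ratio_pre_post
#> 1  Benzyl alcohol   stress_induced    100       0.9678          3.779
#> 2 3-Methylbutanal   stress_induced    100       0.9264          3.085
#> 3         Styrene   stress_induced    100       0.9383          3.395
#> 4   Propylbenzene   stress_induced    100       0.9172          3.805
#> 5     2-Heptanone neighbor_induced     87                         ALB
#> 6        p-Cymene             hipv    100          ApI          6.323
```

Stress-induced compounds increased ~3–4-fold comparably at both
quarantine trees; p-cymene is exclusive to the infested tree ("ApI") with
a 6.3-fold post-exposure increase; 2-heptanone appeared de novo at the
neighbor ("ALB" mark). Temporal dynamics of an induced compound:

```r
em <- subset(res$emissions, compound == "p-Cymene" & tree_id == "ApI")
agg <- daily_aggregate(em$day, em$rate)
fit_extreme(agg$day, agg$mean)
#> 'Extreme' peak fit
#>   y0 = 0.3234, A = 8.357, xc = 43.75 days, w = 17.36 days
#>   n = 42, adj. R^2 = 0.95792
```

The fitted peak sits at day 44 — between the compound's two planted
emission pulses (days 34 and 60), with the dominant one weighted more
heavily — on a baseline of 0.32 ng dm⁻² h⁻¹.

A thin command-line front end is installed with the package
(`inst/scripts/trunkvoc`): `trunkvoc simulate --seed 1 --out study` and
`trunkvoc run-all --in study --out results`.

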