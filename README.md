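# scatniche

Dietary niche breadth and trophic level analysis from predator scats.

When an invasive prey species (here the armored catfish *Pterygoplichthys*,
a low-trophic-level detritivore) becomes abundant in a river, a native
predator such as the Neotropical river otter may concentrate its diet on
it. Two signatures of that shift can be read from scats: the diet becomes
less even across prey categories (niche breadth contracts), and the
predator feeds lower in the food web (its trophic level drops). `scatniche`
implements both lines of evidence — gross scat analysis of prey remains and
stable-isotope analysis of fecal matter — as a tested, reusable pipeline
for long-format scat records grouped by river and year.

## What it computes

**Occurrence tabulation.** For each river-year group and prey taxon: the
number of scats containing the taxon, the percentage of scats (%S, sums
above 100), and the taxon's share of all prey records (%R, sums to 100 and
serves as the diet-composition proportion downstream).

**Levin's niche breadth.** From diet proportions *p<sub>j</sub>*,

> B = 1 / Σ p<sub>j</sub>², &nbsp;&nbsp; B<sub>a</sub> = (B − 1) / (n − 1)

with *n* the number of recorded prey categories. B runs from 1 (specialist)
to *n* (even generalist); B<sub>a</sub> is its [0, 1] standardization
(conventionally > 0.6 generalist, < 0.4 specialist). Confidence intervals
resample scats (not records) with replacement, 1000 replicates by default,
and report empirical 2.5%/97.5% quantiles.

**Mao Tau accumulation curves.** The analytic expected prey richness in
*h* of *H* scats, τ(h) = S<sub>obs</sub> − Σ<sub>j</sub> α<sub>jh</sub>
S<sub>j</sub>, with the combinatorial coefficient α<sub>jh</sub> =
(H−h)!(H−j)! / ((H−h−j)! H!) evaluated in log-gamma space, plus a
scat-bootstrap band.

**Fractional trophic level.** FTL<sub>i</sub> = 1 + Σ<sub>j</sub>
FTL<sub>j</sub>·DC<sub>ij</sub>, the diet-weighted mean prey trophic level
plus one, using %R-based diet proportions and a prey trophic-level lookup
(taxa without a known FTL are excluded and proportions renormalized).
Bootstrap CIs as above. A trophic-enrichment-factor helper converts
between-group δ¹⁵N differences into trophic-level shifts (3.4‰ per level).

**Isotope statistics.** δ-notation, per-group variance of δ¹⁵N/δ¹³C as
isotopic niche width with Levene homoscedasticity tests (omnibus and
pairwise), a Shapiro–Wilk screen, two-factor river-by-year ANOVA
(sequential sums of squares, optional log transform of δ¹⁵N), and
Bonferroni-adjusted pairwise t tests (pooled or Welch by a
variance-driven policy).

**Synthetic data.** A diet-scenario generator (multinomial prey draws per
scat, `1 + Poisson` item counts) and a group-wise normal isotope generator,
with closed-form B<sub>a</sub>/FTL targets for parameter-recovery testing.
The package ships the published per-taxon record counts for five river-year
groups (285 scats, 734 records) expanded deterministically to scat level,
and a clearly labelled *synthetic* prey trophic-level reference.

## Worked example

```r
library(scatniche)
scats <- otter_diet_fixture()          # packaged record counts at scat level
nb <- niche_breadth_table(scats, n_boot = 1000, seed = 17)
nb[, c("river", "year", "B_a", "ci_low", "ci_high", "classification")]
```

```
      river year  B_a q2.5 q97.5        label
1     Mopan 2016 0.29 0.26  0.43   specialist
2    Pasion 2010 0.47 0.41  0.59 intermediate
3    Pasion 2015 0.18 0.18  0.29   specialist
4 San Pedro 2009 0.53 0.48  0.67 intermediate
5 San Pedro 2015 0.29 0.27  0.38   specialist
```

Both invaded rivers contract: San Pedro falls from 0.53 two years after
the invasion to 0.29 seven years after; Pasion from 0.47 to 0.18, the
sharpest specialization, with the armored catfish rising from 9.9% to
49.3% of that river's prey records. The trophic side tells the same story:

```r
ftl_table(scats, prey_reference_fixture(), n_boot = 1000, seed = 17)
```

```
      river year  FTL q2.5 q97.5
1     Mopan 2016 3.72 3.61  3.84
2    Pasion 2010 3.72 3.64  3.81
3    Pasion 2015 3.41 3.31  3.51
4 San Pedro 2009 3.64 3.57  3.73
5 San Pedro 2015 3.54 3.48  3.60
```

and `ftl_shift_from_d15N(2.78)` ≈ 0.82 converts the San Pedro mean-δ¹⁵N
drop into roughly 0.8 trophic levels. (FTL point values depend on the
packaged *synthetic* prey reference; treat them as illustrative, not as
field estimates.)

The numbered scripts under `analysis/` run the full workflow — input
construction, occurrence/niche, accumulation, trophic level, isotope
statistics — and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_occurrence_niche.R   # ... through 05
```

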