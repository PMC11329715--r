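# vipertherm

Thermal-ecology analysis of ectotherm thermoregulation, built around the
study design used for alpine vipers: thermal-gradient trials for preferred
body temperature, "grab and jab" field body temperatures, paired sun/shade
operative-temperature loggers, monthly climate grids under current and
future scenarios, and a population-level phylogeny. The package estimates
set-point temperature ranges, computes the classic thermoregulation index
suite, budgets annual activity-restriction hours under climate warming, and
tests for phylogenetic signal in population thermal traits — all runnable
end-to-end on a bundled, seeded synthetic-data generator, and equally on
real tables with the same schemas.

It is aimed at herpetologists and thermal ecophysiologists who want these
standard quantities computed reproducibly, with bootstrap uncertainty and
explicit, testable conventions for every rule the field usually leaves
implicit.

## The quantities

For an animal with body temperature *T*<sub>b</sub>, environmental operative
temperature *T*<sub>e</sub> (what a non-thermoregulating animal would
attain), and a laboratory-preferred set-point range
*T*<sub>set</sub> = \[*T*<sub>set,low</sub>, *T*<sub>set,up</sub>\]:

- **T<sub>p</sub>, T<sub>set</sub>** — a Gaussian kernel density is fitted
  to each individual's gradient readings, rescaled to \[0, 1\], and read on
  a fixed 15–45 °C grid at 0.05 °C steps: *T*<sub>p</sub> is the
  temperature at density 1, and the set-point bounds are the outermost
  half-maximum crossings (density = 0.5). An interquartile variant is
  available behind a flag.
- **d<sub>b</sub>** (accuracy) — mean deviation of *T*<sub>b</sub> from
  *T*<sub>set</sub> (0 inside the range, distance to the nearest bound
  outside); **d<sub>e</sub>** (habitat thermal quality) — the same for
  *T*<sub>e</sub> over the 06:00–20:00 activity window. Both with
  percentile-bootstrap 95 % CIs.
- **E = 1 − d<sub>b</sub>/d<sub>e</sub>** (Hertz effectiveness),
  **I = d<sub>e</sub> − d<sub>b</sub>** (Blouin-Demers & Weatherhead), and
  **E<sub>x</sub>** (thermal exploitation: share of records with
  *T*<sub>b</sub> in *T*<sub>set</sub> over records whose time-matched
  *T*<sub>e</sub> overlaps *T*<sub>set</sub>; unclamped, can exceed 1).
- **h<sub>r</sub>** (restriction time) — hours per year that hourly
  *T*<sub>e</sub>, synthesized from monthly climate means, strictly exceeds
  *T*<sub>set,up</sub>; compared across current and GCM × SSP scenario
  offsets.
- **Blomberg's K** (with permutation p) and **Pagel's λ** (by maximum
  likelihood with a likelihood-ratio test, λ searched up to the
  positive-definiteness limit, so values above 1 are admissible) on
  population *T*<sub>p</sub> over a Grafen-calibrated tree.

## Worked example

```r
library(vipertherm)
cfg <- pipeline_config(seed = 1, n_cells = 30, n_days = 4,
                       n_boot = 1000, n_perm = 199)
run <- run_pipeline(cfg)
print(run)
```

```
Thermoregulation indices by population
 population   t_p t_set_lower t_set_upper  d_b d_b_lo d_b_hi  d_e d_e_lo d_e_hi
         KU 29.05       26.70       33.10 0.48   0.12   0.94 3.83   3.65   4.01
         LA 29.25       22.30       32.55 0.00   0.00   0.00 1.34   1.23   1.45
         TO 30.00       27.75       32.65 0.33   0.13   0.58 4.56   4.36   4.76
         TY 28.65       25.70       32.10 0.22   0.11   0.34 3.22   3.04   3.38
         VA 27.80       24.45       30.65   NA     NA     NA 2.55   2.40   2.68
 e_hertz i_bdw  e_x n_tb n_te
    0.88  3.35 1.64   25 1344
    1.00  1.34 1.36   15 1344
    0.93  4.23 3.32   95 1344
    0.93  3.00 2.58  155 1344
      NA    NA   NA    0 1344

Annual activity-restriction time (h/year) by scenario
 scenario_id mean_h_r se_h_r mean_delta n_cells
     current   1026.9   93.2        0.0      30
    SSP1-2.6   1484.7   92.4      457.8      30
    SSP5-8.5   2101.9   94.3     1075.0      30

Phylogenetic signal (n = 5 tips): K = 0.910 (P = 0.380), lambda = 0.000 (P = 1.000)

Population statistics on 73 individuals
  SVL -> Tp (females):   b =   0.0137  P = 0.1921
  latitude -> Tp:        b =   1.1871  P = 0.0011
  ...
```

Reading it: each population row gives the pooled set-point estimate, then
accuracy and habitat quality with bootstrap CIs — KU's animals sit inside
their preferred range almost always (d<sub>b</sub> 0.48) while its habitat
deviates by ~3.8 °C on average, so E = 0.88 indicates careful
thermoregulation. The VA row is generated without body-temperature records,
so d<sub>b</sub>, E, I and E<sub>x</sub> are reported missing, not zero.
The budget block shows mean annual restricted hours rising from ~1000 under
current climate to ~2100 under the pessimistic pathway. With only five
population tips, neither signal statistic approaches significance.

Every synthetic table can be replaced by a real CSV with the same columns
(`run_pipeline(cfg, tables = list(spots = ..., otm = ...))`);
`validate_tables()` checks schemas, unit ranges, timestamp monotonicity and
logger cadence first. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

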