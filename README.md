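# pvstrat

Should a drug class be analysed separately in pharmacovigilance signal
detection? National spontaneous reporting systems pool Traditional
Chinese Medicine (TCM), Western medicine and biological products into one
database before disproportionality screening, yet a class with a
reporting profile of its own may be served badly by pooled analysis.
`pvstrat` implements a reference-based decision framework for that
question, aimed at pharmacovigilance analysts and methodologists working
with stratified spontaneous-report data.

## What it computes

1. **Ingest** — raw reports are split to one-drug-one-ADR records,
   "unknown" names dropped, records aggregated to drug–ADR pairs with
   occurrence counts, filtered to counts ≥ 3 and to drugs present in a
   reference database of known associations, and annotated known/unknown.
2. **Detection** — four disproportionality methods on the per-pair 2×2
   table (cells *a, b, c, d*, *N = a+b+c+d*): PRR
   `(a/(a+b))/(c/(c+d))` with the criterion {a ≥ 3, PRR ≥ 2, χ² ≥ 4};
   ROR `ad/bc` with {a ≥ 3, 95% CI lower bound > 1}; the MHRA composite
   criteria; and the BCPNN information component
   `IC = log2((a+0.5)/(E+0.5))`, `E = (a+b)(a+c)/N`, with {IC − 2·SD > 0}.
3. **Evaluation** — the total-sample and stratum runs are cross-tabulated
   over the stratum's pair universe into a fourfold table whose cells
   split by reference-known status, giving recall `R1 = (a1+b1)/K`,
   `R2 = (a1+c1)/K`, precision `P1 = (a1+b1)/(a+b)`, `P2 = (a1+c1)/(a+c)`
   and discrepancy `D = |b1−c1|/(b+c)`.
4. **Decision** — thresholds `Rt, Pt, Dt` (integer percents just above the
   mean per-method differences) feed a three-branch decision tree that
   returns **separation** or **non-separation** with its full decision
   path.

A seeded simulator generates multi-stratum reporting systems with planted
signals so every stage is testable, and the fourfold cells of a published
nationwide TCM worked example ship with the package.

## Worked example

```r
library(pvstrat)
td <- tcm_decision_table()
td$indicators_percent
#>   method    R1    R2    P1    P2    D
#> 1    PRR 72.41 71.69 27.10 26.94 0.92
#> 2   MHRA 61.69 60.72 27.89 27.69 1.18
#> 3     IC 38.19 36.75 42.15 46.21 4.72
print(td$decisions)
#> <threshold_set> Rt = 2%, Pt = 2%, Dt = 3%
#> <decision_outcome: PRR> verdict: separation
#>   R: difference 0.72% vs threshold 2% -> continue
#>   P: difference 0.16% vs threshold 2% -> continue
#>   D: difference 0.92% vs threshold 3% -> separation
#> ...
#> consensus: separation (3 separation : 0 non-separation)
```

Reading: in the TCM worked example the pooled run recalls slightly more
known signals (R1 > R2 by under 1%), the stratum run is as precise or
more precise (for IC, P2 − P1 = 4.06% > 2%), and no method crosses a
non-separation branch — every method concludes the TCM stratum should be
detected separately.

The same pipeline runs end to end on simulated data:

```r
cfg <- sim_config(n_reports = 6000, stratum_profile_shift = 0.9, seed = 1)
res <- run_pipeline(generate_reports(cfg), generate_reference(cfg),
                    out_dir = "results")
res$decisions$consensus
```

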