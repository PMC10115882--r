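# storgrowth

Soil microbial biomass is usually assumed to grow by cellular replication,
but microorganisms also grow by synthesizing intracellular carbon-storage
compounds — polyhydroxybutyrate (PHB, bacterial) and triacylglycerides
(TAG, bacterial and fungal) — which are hydrophobic and therefore invisible
to chloroform fumigation-extraction (CFE) and to DNA-based growth measures.
`storgrowth` implements the full quantitative accounting needed to
partition biomass growth into these two pathways from a multi-isotope
soil-microcosm experiment, for microbial ecologists and isotope
biogeochemists:

- **Replicative growth** from ¹⁸O incorporation into DNA: capsule ¹⁸O is
  corrected for extraction-kit oxygen using the DNA oxygen content (31% by
  mass), then a two-pool mixing model with 70% of new-DNA oxygen derived
  from soil water gives the fraction of newly synthesized DNA,
  `f_new = (A_DNA − A_nat) / (f_w·A_water + (1 − f_w)·A_nat − A_nat)`,
  which is multiplied by extractable microbial biomass C (MBC, from CFE)
  to obtain gross replicative growth in µg C g⁻¹ soil.
- **Storage growth** from ¹³C-labelled glucose: PHB (measured as its ethyl
  ester) and TAG fatty acids (measured as FAMEs) are corrected for
  derivatization carbon by C-weighted mass balance, then partitioned
  between the glucose endmember (3 at% ¹³C) and the unlabelled zero-C
  control with a two-pool mixing model,
  `f = (A_sample − A_background) / (A_source − A_background)`,
  always in atom-fraction space.
- **Supporting accounting**: CFE biomass (ΔDOC), ¹⁴C-traced glucose
  incorporation, CO₂ efflux rates and their glucose-derived share,
  first-order error propagation (quadrature of sds / relative sds),
  storage-to-biomass ratios and respiration-endurance hours.
- **Robust statistics** for n = 4 microcosm designs: Hodges–Lehmann shift
  estimates with exact Mann–Whitney confidence intervals,
  percentile-bootstrap pairwise median comparisons with Benjamini–Hochberg
  adjustment, Cohen's d, compact letter displays.
- **A synthetic microcosm generator** that forward-simulates the complete
  3 (glucose: 0/90/400 µg C g⁻¹) × 2 (±nutrients) × 2 (24/96 h) design
  with known ground truth, so every stage of the pipeline is testable
  without any external data.

## Worked example

```r
library(storgrowth)
b <- run_pipeline(seed = 1, B = 1000)   # simulate + account + statistics
subset(b$growth, timepoint_h == 96,
       c(treatment, dna_growth_c, labelled_storage_c, total_growth_c,
         extra_growth_pct, storage_mbc_ratio, endurance_h))
```

```
 treatment dna_growth_c labelled_storage_c total_growth_c extra_growth_pct storage_mbc_ratio endurance_h
        C0         5.44               0.00           5.44              0.0             0.252         114
    C0+ntr         6.88               0.00           6.88              0.0             0.197         107
      C400        19.05              33.64          52.70            176.6             0.490         349
  C400+ntr        42.32              12.33          54.65             29.1             0.239         175
       C90        18.52               5.67          24.19             30.6             0.230         142
   C90+ntr        24.29               4.63          28.91             19.0             0.210         128
```

Reading the 96 h row for the high-C, no-nutrient treatment (`C400`):
DNA-based (replicative) growth is 19.1 µg C g⁻¹, but another 33.6 µg C g⁻¹
of biomass growth went into glucose-derived PHB and TAG — 177% more growth
than the DNA-based method alone observes. The storage pool is 0.49 times
the extractable biomass and would sustain 349 h of basal respiration.
Under nutrient supplementation (`C400+ntr`) the allocation flips toward
replication (42.3 vs 12.3 µg C g⁻¹): PHB behaves as *surplus* storage
(stimulated by excess C, suppressed by nutrients) while TAG behaves as
*reserve* storage tracking replicative growth. `b$comparisons` holds the
pairwise bootstrap/Hodges–Lehmann statistics behind the letters in
`b$letters`; `b$qc` lists every clamp or flag raised during accounting.

The same run is available from the command line:

```sh
Rscript inst/scripts/storgrowth-cli.R simulate --out data/ --seed 1
Rscript inst/scripts/storgrowth-cli.R run --input data/ --out results/ --seed 1
```

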