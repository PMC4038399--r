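# holoscreen

Template-ligand virtual screening with thermal-shift validation, in R.

`holoscreen` is for computational chemists and assay scientists who want
to (a) rank a compound library against a protein target using **ligand
homology modeling** — the ligands bound in holo structures (or binding
databases) of the target's evolutionary relatives — and (b) analyze the
**differential scanning fluorimetry (DSF / thermal shift)** plates used
to validate the resulting short-list.

## What it computes

**Screening.** Holo templates, supplied as target–template residue
alignments, are ranked by the sum-of-pairs score
`SP = Σ BLOSUM62(a, b)` over aligned residues (with a >30%
sequence-identity exclusion for blind benchmarking). The bound ligands of
the top 100 templates become template ligands, and each library compound
is scored per evidence library by

```
mTC = w · mean_l TC(L_l, L_lib) + (1 − w) · max_l TC(L_l, L_lib),   w = 0.1
```

where TC is the Tanimoto coefficient of binary fingerprints (Open Babel
FP2 by default). Scores from multiple evidence libraries combine by
maximum; the library is ranked and the top 1% short-listed. Benchmarks
report the enrichment factor `EF_x = (#TP in top ⌈xN⌉)/(#TP · x)` and the
area under the accumulative curve (AUAC), with seeded random baselines.

**Thermal shifts.** Plate traces are control-subtracted,
replicate-averaged, and fit to the Boltzmann sigmoid
`I(T) = Imin + (Imax − Imin)/(1 + exp((Tm − T)/a))`. Curves are triaged
by the quality score Q (fitted amplitude over observed range) and a
transition counter (none / single / multi); single-transition curves
yield ΔTm, the van't Hoff enthalpy `ΔH = R·Tm²/a`, and the approximate
dissociation constant `K_D = [L] · exp(ΔH/R · (1/Tm − 1/T0))`.

Seeded generators (`simulate_library()`, `simulate_templates()`,
`simulate_plate()`) produce screening libraries with planted actives and
96-well melt plates with known truth, so the whole pipeline is testable
offline.

## Worked example

```r
library(holoscreen)

# --- screen a synthetic library with 10 planted actives ---
sim <- simulate_library(n_compounds = 1000, n_actives = 10,
                        bit_flip_prob = 0.02, seed = 7)
ev  <- evidence_library("pdb-holo", sim$template_ligands)
res <- rank_library(sim$library, ev, w = 0.1)
head(res, 5)
#>   rank        id mtc_pdb-holo combined
#> 1    1 cmpd00662        0.717    0.717
#> 2    2 cmpd00029        0.710    0.710
#> 3    3 cmpd00238        0.682    0.682
#> 4    4 cmpd00765        0.667    0.667
#> 5    5 cmpd00644        0.663    0.663

truth <- sim$truth$id[sim$truth$is_active]
enrichment_factor(res$id, truth, x = 0.01)   # 100: all actives in the top 1%
auac(res$id, truth)                          # 0.995

# --- analyze a simulated 96-well thermal-shift plate ---
plate <- simulate_plate(seed = 7)
an <- analyze_plate(plate_curves(plate$plate))
an$reference$t0                              # 55.01 C ligand-free midpoint
subset(an$ligands, hit)[1:3, c("ligand_id", "delta_tm", "q", "k_d")]
#>   ligand_id delta_tm     q      k_d
#> 1       L01     11.9 0.954 7.65e-08
#> 2       L08     11.8 0.991 8.18e-08
#> 3       L06     10.1 0.949 2.22e-07
```

All 10 planted actives rank in the top 10 (EF_0.01 = 100, its maximum),
and the plate analysis recovers every planted binder as a hit: a ligand
with a true +11.9 °C shift at 100 µM ligand maps to an estimated K_D of
~77 nM.

A command-line front end over the same functions lives in
`inst/cli/holoscreen.R`:

```sh
Rscript inst/cli/holoscreen.R screen --library lib.smi \
        --evidence pdb=template_ligands.smi --top 0.01 --out results/
Rscript inst/cli/holoscreen.R dsf --plate plate.csv --out dsf_results/
```

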