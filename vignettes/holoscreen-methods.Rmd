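---
title: "Template-ligand screening and thermal-shift analysis with holoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-ligand screening and thermal-shift analysis with holoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoscreen)
```

## The screening model

holoscreen implements ligand homology modeling (LHM) for virtual ligand
screening. The premise: evolutionarily related proteins bind overlapping
sets of ligands, so the ligands found bound in *holo* template structures
(or recorded in binding databases) of the target's distant relatives are
informative about what the target itself binds — even when no close
homolog or high-resolution target structure exists.

### Template ranking

Templates come with precomputed residue alignments to the target. Each
alignment is scored by the sum-of-pairs score

$$\mathrm{SP} = \sum_{\text{aligned } (a,b)} \mathrm{BLOSUM62}(a, b),$$

and templates are ranked by descending SP-score; the bound ligands of the
top 100 templates (default `n_top_templates`) form the template-ligand
set. Alignments are *inputs* here: producing them requires threading and
structure-alignment machinery that is deliberately outside this package,
which keeps the scoring core small, deterministic and fully testable. For
benchmark ("blind") mode, templates with sequence identity strictly above
30% to the target are excluded first; identity is computed as identities
over aligned-pair count, the only denominator derivable from the data the
package actually holds. Ties in SP-score are broken lexicographically by
template id so ranking is reproducible.

### Compound scoring: mTC

Every library compound is compared with every template ligand through the
Tanimoto coefficient (TC) of binary structure fingerprints, and scored
per evidence library as

$$mTC = w\,\frac{\sum_{l=1}^{N_{lg}} TC(L_l, L_{lib})}{N_{lg}}
      + (1-w)\,\max_{l} TC(L_l, L_{lib}), \qquad w = 0.1 .$$

The maximum term dominates by design: if any single template ligand is a
true ligand of the target, a close library analog of it should surface
regardless of how dissimilar the rest of the template-ligand set is. The
average term acts as a soft consensus prior. Independent screens are run
against each evidence library (canonically three: holo-structure ligands
plus two binding-database-derived sets) and a compound's combined score is
the **maximum** of its per-evidence mTC scores. The number of evidence
libraries is configuration, not method: the combination rule is what
matters.

### Fingerprints

No particular fingerprint is canonical for this approach; absolute TC
thresholds are always fingerprint-dependent. The default here is Open
Babel's FP2 via ChemmineR/ChemmineOB — a hashed linear-fragment
(path-based) fingerprint indexing paths of up to 7 bonds into 1024 bits —
because it is deterministic, fast, and available without a license. The
TC cutoffs used elsewhere in the package (0.7 for chemical-class
clustering, 0.9 for aggregator similarity) are honored as configurable
defaults with the caveat that their bite depends on the fingerprint
behind them.

### Evaluation

A benchmark screen is scored by the enrichment factor within the top
fraction $x$,

$$EF_x = \frac{\#\{\text{true positives in top } \lceil xN \rceil\}}
             {\#\{\text{true positives}\} \cdot x},$$

and by the area under the accumulative curve (AUAC) of true-positive
fraction versus screened fraction. A true positive is a known binder or
any library compound with TC exactly 1 to one (fingerprint-identical
compounds are indistinguishable to the screen). Conventions the package
fixes because the definitions leave them open: the top set has size
$\lceil xN \rceil$, matching the screening short-list rule, and AUAC is a
trapezoid over the full per-compound step curve anchored at (0,0) — under
which $EF_{0.01}$ spans 0–100, random ranking gives $EF \approx 1$ and
AUAC $\approx 0.5$, and a perfect screen approaches AUAC 1. The
random baseline is Monte-Carlo over seeded uniform permutations, reported
with its standard error.

```{r enrichment}
ranked <- sprintf("c%04d", 1:1000)
enrichment_factor(ranked, truth = ranked[1:10], x = 0.01)
random_baseline(10000, 100, x = 0.01, n_perm = 200, seed = 1)$ef_mean
```

## Thermal-shift (DSF) analysis

Screening short-lists are validated by differential scanning fluorimetry:
a dye fluoresces as it binds hydrophobic surface exposed during thermal
unfolding, so fluorescence rises through the melt. Ligand binding
stabilizes the folded state and shifts the melting midpoint $T_m$ upward.

### Curve processing

Wells are read from long-format CSV (25–74 °C at 1 °C per point in the
standard protocol; any uniform grid of ≥ 10 points is accepted).
Protein and protein–ligand wells are corrected by subtracting the matched
drug–dye control (falling back to the dye-only control), replicates
(minimum two) are averaged pointwise, and the mean curve is fit to the
Boltzmann sigmoid

$$I(T) = I_{min} + \frac{I_{max} - I_{min}}{1 + e^{(T_m - T)/a}} .$$

Numerical choices, all of which matter in the degenerate cases:

* **Truncation.** Points after the global intensity maximum are dropped
  before fitting: post-peak decay is aggregation of the unfolded state,
  outside the two-state model. This is standard DSF practice.
* **Initialization.** $I_{min}$/$I_{max}$ start at the means of the first
  and last deciles of the trace, $T_m$ at the half-amplitude crossing,
  $a$ at 1 °C; optimization is Levenberg–Marquardt (minpack.lm) with
  $a > 0$ and $T_m$ box-constrained to the observed window.
* **Convergence guards.** A fit is only accepted when the amplitude is
  positive, exceeds 4× the fit RMSE *and* 6× a robust noise scale taken
  from the full differenced trace (`mad(diff(I))/√2` — deliberately not
  the truncated-fit RMSE, which a short noise prefix can deflate), and
  the model traverses more than 80% of its amplitude inside the fitted
  window (rejecting noise ramps fit with huge $a$ or boundary $T_m$).
  Flat traces therefore return `converged = FALSE` rather than an error
  or a spurious midpoint; across 200 simulated flat noisy wells this
  rejects every one while accepting 100/100 genuine 2%-noise melts.

### Triage: Q score and transition counting

Each curve gets a quality score $Q$ = fitted amplitude / total observed
fluorescence range, clamped to [0, 1]: 1 is a clean full-range sigmoid, 0
means no transition. Multi-step unfolding is detected on the smoothed
(5-point moving average) first derivative: transitions are local maxima
above 25% of the strongest slope, above a noise floor of
3·mad(diff(I))/(step·√5), and at least 5 °C apart. Curves classified
`none` or `multi` are excluded from thermodynamic analysis, mirroring the
manual curation such experiments receive; the thresholds are exposed as
arguments. No hard Q cutoff is imposed on hits by default beyond a floor
of 0.1, since curve curation in practice is qualitative.

### Thermodynamics

From the reference (ligand-free) fit the van't Hoff unfolding enthalpy is
$\Delta H = R\,T_m^2/a$ (Kelvin, R = 1.987 cal mol⁻¹ K⁻¹) — this follows
from the Boltzmann model itself, since it implies
$\ln K_{unfold} = (T - T_m)/a$. Heat-capacity corrections are ignored
throughout. For a stabilized well the association constant at the shifted
midpoint is

$$K_L(T_m) = \frac{\exp\!\big[-\tfrac{\Delta H}{R}\big(\tfrac{1}{T_m} -
\tfrac{1}{T_0}\big)\big]}{[L]}, \qquad K_D = 1/K_L,$$

with $T_0$ the reference midpoint from the same plate and $[L]$ the total
ligand concentration (valid when ligand is in large excess over protein;
default 10⁻⁴ M, configurable per assay). With no shift, $K_D = [L]$
exactly; larger stabilizing shifts give smaller $K_D$.

A ligand is a **positive hit** when its curve converged to a single
transition with $Q \ge$ 0.1 and $\Delta T_m$ exceeds 3× the replicate
standard deviation of the reference $T_m$, floored at 0.5 °C. The floor
is this package's choice: with a 1 °C sampling grid, shifts below half a
degree are not meaningfully resolved, and with noiseless simulated
replicates the 3-sigma rule alone would degenerate to zero.

```{r dsf}
sim <- simulate_plate(seed = 42)
an <- analyze_plate(plate_curves(sim$plate))
head(merge(an$ligands, sim$truth)[, c("ligand_id", "class", "true_delta_tm",
                                      "delta_tm", "q", "hit")])
```

## What the generators emulate — and what they do not

`simulate_library()` plants actives as bit-flip-corrupted copies of
template-ligand fingerprints among random decoys drawn at the *same*
expected bit density, so similarity separation can only come from the
planted structure. It does not emulate real chemistry: no valence
constraints, no correlated substructure bits, no property-matched decoys.
Passing its recovery tests shows the scoring and ranking machinery is
correct, not that any fingerprint separates actives from decoys in a real
library.

`simulate_plate()` builds a 96-well layout (10 binders with shifts drawn
from 3–12 °C, 8 non-binders, 3 fluorescence-quenched flat wells, 2
two-transition wells; 2 replicates; matched dye and drug–dye controls)
with Gaussian noise at 2% of the melt amplitude and a plate-wide linear
drift that control subtraction cancels. Real instrument noise is neither
white nor homoscedastic, and real compound interference is richer than
"flat" or "two-step"; the generator's role is to give every pipeline
branch a case with known truth.

Test and benchmark problem sizes (1,000–10,000-compound libraries,
≤ 200-compound oracle comparisons, 100-curve fitting studies, 2,000
permutation baselines) were chosen so each check exercises the intended
regime at desk scale; all are parameters, not limits.

## Known limitations

* Template alignments, and hence SP-scores, are only as good as the
  upstream threading/structure pipeline that produced them.
* TC cutoffs are not transferable across fingerprint types; recalibrate
  0.7/0.9 if you change `fp_type`.
* The van't Hoff $K_D$ is an order-of-magnitude estimate: it ignores
  $\Delta C_p$, assumes two-state unfolding and ligand excess, and
  inherits the reference-fit enthalpy.
* Aggregator flagging is similarity-only; it cannot replace
  detergent-control experiments.
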