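---
title: "Modelling lung adenocarcinoma growth patterns with a compartmental cellular Potts model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lung adenocarcinoma growth patterns with a compartmental cellular Potts model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(luadmorph)
```

Lung adenocarcinoma (LUAD) is classified into five histologic growth
patterns — lepidic (LPA), acinar (APA), papillary (PPA), micropapillary
(MPA) and solid (SPA) — with different prognoses. `luadmorph` implements a
compartmental cellular Potts model (CPM) in which these architectures emerge
from a single base model of a columnar epithelial monolayer by changing a
handful of biophysical parameters: the cancer cells' growth rate, their
cell–cell contact energies (adhesion and apico-basal polarity), their death
rate, mucus secretion and stromal proliferation. The package also implements
the measurement side of such a study: contact-category scoring of the
simulated tissue, spheroid shape-index morphometrics on binary masks,
marker-positive pixel ratios, and pooled nearest-neighbour distance
statistics for 3D spot sets.

This vignette is the package's account of the model, its assumptions, the
parameters that matter, and the numerical choices behind the implementation.

## The Potts model

The tissue lives on a 2D square lattice (500×500 pixels at full scale, about
1 µm per pixel). Every lattice site carries a compartment id; compartments
are grouped into clusters (cells). The energy is

$$
H \;=\; \sum_{\langle i,j\rangle}
J\!\left(\tau_i,\tau_j\right)\,\bigl[\sigma_i \ne \sigma_j\bigr]
\;+\; \sum_{c} \lambda_c \left(v_c - V_c\right)^2 ,
$$

where the first sum runs over unordered neighbour pairs within the
neighbour order (order 3 by default, i.e. 12 neighbours per pixel), $\sigma$
is the compartment id, $\tau$ the label (cell type × compartment type), $J$
the contact energy per boundary unit, and the second sum constrains each
compartment's volume $v_c$ to its target $V_c$ with strength $\lambda_c$.
The medium (luminal space) is label 0 and has no volume constraint. No
surface (perimeter) constraint is used on any object.

Dynamics are Metropolis copy attempts: one Monte Carlo step (MCS) performs
`width × height` independent random picks of a target site and a random
neighbour as source; if their compartment ids differ the copy is accepted
with probability $\min(1, e^{-\Delta H/T})$ at Potts temperature $T = 10$.
One MCS represents approximately 2 hours of simulated time. Because copy
attempts are independent uniform picks with replacement (not a shuffled
sweep — the alternative reading of an MCS), runs are exactly reproducible
from the configuration and the RNG seed; behaviour hooks draw from the same
stream in a fixed order.

Fixed (no-flux) boundaries are the default: sites outside the lattice carry
no energy and no copy crosses the edge, so tissue cannot wrap; periodic
boundaries are available per configuration.

### Compartmental epithelial cells

Cancer and normal lung epithelial cells are *compartmental*: one cluster
made of apical, basal, lateral and cytosolic sub-compartments, encoding
apico-basal polarity. Columnar cells are nominally 10 pixels wide and 30
tall. Stromal cells (10×10), extracellular-matrix portions (5×5) and mucus
are single-compartment pseudo-cells.

Two contact-energy tables are kept: `external` between compartments of
different cells and `internal` between sub-compartments of the same cell.
All internal energies are 1 (cohesion). The published model deltas — e.g.
tumor-basal to stroma/matrix 3 (base) vs 30 (low adhesion), tumor-apical and
tumor-basal to the other tumor sub-compartments 40 (base) vs 10 (low
polarity) — are applied to the *external* table: polarity is maintained
because an apical surface that touches another cell's sub-compartments is
expensive, which keeps cells in a monolayer with apical facing the lumen.
(Applying the 40 internally would instead penalise a cell's own apical
resting on its own cytosol, which is unavoidable.)

The baseline matrix around those deltas is a declared package default, not a
literature claim: strong lateral–lateral adhesion (J = 2) binds the layer,
apical–medium J = 4 turns apical surfaces to the lumen, basal–stroma and
basal–matrix J = 3 anchor the layer, unlisted pairs are neutral at J = 16
and non-apical surfaces see the medium at J = 20. The full table ships as a
versioned JSON file (`inst/extdata/contact_energies_base.json`).

```{r energies}
J <- default_contact_energies()
contact_energy(J, "cancer.basal", "stromal.generic")
contact_energy(J, "cancer.apical", "cancer.cytosol")
```

### Volume constraints and the connectivity guard

$\lambda = 2$ for every volume-constrained compartment (a conventional scale
against $T = 10$; configurable). The presets enable a *connectivity guard*:
a copy attempt is rejected if it would split the overwritten compartment
locally (the compartment's pixels in the 8-neighbourhood ring must stay one
connected component), if it would seed a pixel not 8-adjacent to the gaining
compartment (order-3 copies could otherwise create satellites two pixels
away), or if it would remove the last pixel of a compartment whose target
volume is positive. The guard preserves the thin apical/basal/lateral strips
that fragment easily at $T = 10$; apoptotic compartments (target 0) may
still vanish. The raw engine without the guard is available
(`connectivity_guard = FALSE`), matching the plain CPM in which compartments
may fragment.

## Cell behaviours

Behaviour hooks fire once per MCS after the attempt sweep, in the order
growth → death → mucus secretion → stromal growth → mitosis (mitosis last so
daughters are consistent at snapshot time).

### Growth semantics

The published models quote dimensionless growth rates (0.03 base, 0.09 for
3× growth, 0.3 for 10× growth, 0.022 and 0.3 in the lepidic models, 0.02 for
growing stroma). The package interprets one unit of rate as **10 pixels of
target-volume increment per MCS** (one cell-width column of the nominal
columnar cell): each MCS every growing cell's target volume rises by
`rate × 10` pixels, distributed over its compartments pro-rata to their
current targets so the membrane sub-compartments grow with the cell.

Why this unit: with a division trigger at twice the birth volume
(~300 pixels), reading the rates as absolute pixels per MCS gives less than
one division in every published run length (rate × steps ≤ 180 pixels),
while reading them as fractions of the cell volume per MCS drives any
lattice to confluence within a few hundred MCS. The 10-pixel unit places
every published (rate, steps) combination in the regime the corresponding
figures show — a few division cycles for the base model over its run, an
order-of-magnitude faster cycle for the solid model. The nominal 24-hour
mitosis calibration (12 MCS) is treated as nominal, not enforced: absolute
cycle times are emergent from the rate and the tissue mechanics.

Two caps bound the growth pressure. The total target never exceeds 2.2× the
reference (birth) volume — just above the 2× division requirement, which the
actual volume approaches from below because boundary energies hold the
realised volume slightly under target. And the target never runs more than
50 pixels ahead of the actual volume, bounding the outward pressure at
$2\lambda \cdot 50 = 200$, above the largest contact energy (40) but finite:
slow-growing cells stay rate-limited and architecture-preserving, while
fast-growing cells saturate the pressure bound and push their neighbourhood
mechanically — which is exactly how the growth-rate presets differentiate.

### Contact inhibition

When enabled (second lepidic model), a cell touching any *other* cancer or
normal epithelial cell grows at 99.7% of its set rate
(`effective_growth_rate(0.3, TRUE, 0.997)` = 0.2991). The contact condition
follows the epithelial-contact reading (contact with stroma does not
inhibit). The mild factor mainly desynchronises division timing across
cells.

### Death

Each alive cluster of a type with a positive death rate enters apoptosis
independently each MCS (memoryless Bernoulli; cancer 0.00065 and normal
0.0001 in the first lepidic model, 0.002 and 0.001 in the second). Apoptosis
sets every compartment target to 0 so the Potts dynamics shrinks the cell;
clusters reaching zero volume are removed from the registries. Vacated
surface closes purely via the Potts dynamics — there is no explicit
wound-healing rule.

### Mitosis

A cluster divides when its actual volume (not its target — mechanics gate
division, so squeezed cells wait) reaches twice its birth volume. Epithelial
cells divide **in the plane of the layer**: the cut line through the centre
of mass runs along the cell's own apico-basal axis (apical centroid minus
basal centroid), so the daughters sit side by side, each spanning basal to
apical, and division lengthens the layer — the morphogenetic driver of
papilla formation by buckling. Each daughter is rebuilt with the four
polarity compartments by geometric reassignment along that axis (top band
apical, bottom band basal, side strips lateral, remainder cytosol, with band
sizes pro-rata to the parent's composition). Pseudo-cells split
perpendicular to their longest principal axis into two generic daughters.
Daughters are born at mechanical equilibrium — compartment targets reset to
actual birth volumes, reference volume set to the birth volume — which
discharges any pressure the parent had accumulated. Degenerate splits are
skipped and retried later.

### Mucus secretion and stromal proliferation

With the acinar behaviour enabled, each cancer cell accrues secretion credit
(default 0.05 pixels per cell per MCS — not a published value; fractional
credits accumulate) and whole credits convert medium pixels adjacent to its
apical boundary into mucus pseudo-cell pixels; once that boundary is
covered, the existing mucus plume extends instead. Creation events aggregate
into pseudo-cells of up to ~9 pixels. Mucus therefore only ever appears on
the luminal side.

With the papillary-v2 behaviour enabled, stromal and matrix clusters in
contact with cancer basal surfaces receive growth increments at rate 0.02
(same unit and caps as cell growth) and divide by the same mitosis rule —
stroma proliferates beneath the advancing cancer layer, keeping papillae
stroma-cored in long runs.

## Presets and initial conditions

`preset()` returns the eleven named configurations; all are deltas from the
base model (growth 0.03, the base contact energies, 4000 MCS, 10
replicates). `build_initial_epithelium()` constructs the published starting
state: a stromal bed (stromal cells interleaved with matrix pseudo-cells), a
single row of columnar epithelial cells spanning the lattice width with the
centred 5 cells cancerous, and lumen above. `build_initial_spheroid_mixture()`
builds the mixed-spheroid start: a disc of randomly interleaved cancer and
stromal cells (50:50, both growing at the same rate) in medium.

```{r preset}
preset("base_ppa")
```

### Desk scale

Full-scale runs (500×500, 4000–40000 MCS, 10 replicates) are supported but
slow. The package's standard desk scale — used by the test-suite
comparisons and the reproduction script — shrinks the lattice by 0.3
(150×150), cell geometry by 0.5 (5×15-pixel columnar cells: small enough for
tissue-level dynamics on the smaller lattice, large enough that the
sub-compartment strips stay robust at $T = 10$) and divides step counts by
4. The growth unit is rescaled by cell-area × step factor, which at these
factors leaves it unchanged, so each cell completes about the same number of
division cycles per run as at full scale.

```{r deskrun, eval = FALSE}
tr <- simulate_preset("base_ppa", seed = 1, scale = TRUE)
autoplot(tr$state)   # tissue view: cell types, apical/basal shading
autoplot(tr)         # category fractions over simulated time
glance(tr)
```

## Morphology metrics and subtype calls

Two clusters are neighbours when any of their pixels lie within the
neighbour order of each other; the medium counts as a neighbour label. Every
alive cancer cell receives exactly one of five connection categories:

1. touches both luminal space and stroma-or-mucus (the polarised monolayer
   configuration),
2. luminal space but no stromal side,
3. stromal side but no lumen,
4. no contact with any other cancer cell,
5. contact with cancer cells only.

Categories 4 and 5 take precedence (evaluated first), which makes the five
categories a partition — they would otherwise overlap textually. Contact
with normal epithelium counts toward the stromal (non-lumen) side, so a
cancer cell surrounded by normal epithelium and cancer falls into category
3. Both conventions are package decisions, declared here because the
original category definitions do not resolve them.

`category_fractions()` and `neighbor_count_histogram()` score a state;
`metrics_record()` bundles them with cell counts per type;
`aggregate_replicates()` produces the replicate-averaged mean ± SD tables
that mirror the published category and neighbour-count heatmaps
(`plot_metric_heatmap()` draws them). `classify_subtype()` applies a
rule-based call (papillary / micropapillary / solid / lepidic /
indeterminate) with explicit, tunable thresholds
(`subtype_thresholds()`: dominance ≥ 0.4 and ≥ 1.5× the runner-up, "high"
modal neighbour count ≥ 5, lepidic requires a near-monolayer cancer count);
the thresholds are package-declared values, not published ones.

## Quantification outside the simulator

### Spheroid shape index

For a spheroid mask with perimeter $P$ and area $A$, two radius estimates
$R_p = P/2\pi$ and $R_a = \sqrt{A/\pi}$ are normalised by $R_a$, giving
$nP = 2\pi\,R_p/R_a$ and $nA = \pi$; the structural-complexity index is

$$ \frac{nP}{nA} \;=\; \frac{P}{\sqrt{\pi A}}, $$

exactly 2 for an ideal circle, scale-invariant, and larger for
protrusion-bearing silhouettes. Area is the foreground pixel count. The
perimeter follows the traced 8-connected boundary contour with
corner-corrected chain-code weights (0.948 per axis move, 1.340 per
diagonal), which is unbiased for smooth shapes; the naive crack-edge count
(up to ~8% longer on diagonal boundaries) is available via
`method = "crack"`. Masks with several components reduce to the largest,
with a warning.

### Positive pixel ratios

`positive_ratio(marker, region)` is `|marker ∧ region| / |region|` — the
quantification used for proliferation (KI67) and apoptosis
(cleaved-Caspase-3) positive fractions within manually segmented tumour or
stroma regions of immunostained sections.

### 3D spot distances and pooled tests

`knn_mean_distances()` computes, for every 3D spot, the mean Euclidean
distance to its 9 nearest other spots (the spot itself excluded — the
convention adopted here), flagging spots above a 60 µm visualisation cutoff.
`pooled_stats()` pools spheroids the way the published comparisons do: the
total mean is the total sum of distances over the total spot count, and the
total SD comes from the total sum of squared deviations (sample convention,
$n - 1$). `two_sample_tests_from_totals()` computes the two-sample t
statistic (pooled-variance Student's form by default — the equal-variance
reading of the published method — Welch by flag) and the variance-ratio F
statistic (larger variance in the numerator, $n-1$ degrees of freedom each,
two-sided p as twice the smaller tail) from those totals alone.

```{r spots}
set.seed(1)
sp <- make_spots(n_points = 150, seed = 1)
u <- knn_mean_distances(sp$uniform, k = 9)
cl <- knn_mean_distances(sp$clustered, k = 9)
two_sample_tests_from_totals(pooled_stats(list(u = u$mean_distance)),
                             pooled_stats(list(c = cl$mean_distance)))
```

## Synthetic data

The generator module stands in for the study's raw data so every
quantification routine can be tested against known ground truth:

* `make_mask()` — smooth circle masks (like knockdown spheroids without
  protrusions) and cosine-modulated star masks with a controlled number of
  protrusions (like control spheroids); ground truth records the exact pixel
  area and protrusion count.
* `make_marker_pair()` — a region with exactly `round(fraction × size)`
  marker pixels, so `positive_ratio()` recovers the fraction identically.
* `make_spots()` — matched uniform-in-sphere and clustered 3D point sets
  (default: 4 Gaussian clusters of SD 15 µm plus 20% uniform background in a
  200 µm sphere, chosen to resemble confocal spot detections at the scale of
  a mixed spheroid). The clustered sets have a wider spread of per-spot
  nearest-neighbour means, which the pooled F test detects.

What these fixtures do *not* emulate: microscope noise, point-spread
functions, segmentation errors, uneven staining, or the detection step that
produces spots from raw fluorescence. Passing round-trip tests therefore
demonstrates correctness of the measurement code, not robustness to
real-world imaging artefacts.

## Numerical choices and degenerate inputs

* RNG: one seeded stream per simulation; the engine consumes it through the
  same generator as the R-level hooks, so trajectories are bit-reproducible
  from (configuration, seed).
* Copy attempts picking an off-lattice neighbour (fixed boundaries) or two
  sites of the same compartment count as rejected/null attempts.
* `delta_hamiltonian()` of a null move returns 0 with a flag.
* A missing contact-energy entry for a label pair present on the lattice is
  an error naming the pair; the shipped tables are complete.
* Mitosis of a cluster too small to furnish both daughters (fewer than 4
  pixels each for epithelial cells) is skipped and retried.
* Empty masks, empty regions, non-positive perimeter/area and spot sets
  smaller than k+1 are errors; multi-component masks reduce to the largest
  component with a warning.
* The t/F tails are computed with `lower.tail = FALSE` where appropriate to
  avoid cancellation in tiny p-values.

## Known limitations

* The engine's tissue growth is lumen-front-limited: cells gain volume
  mostly where they face the medium, so realised division rates saturate
  well below nominal for the fastest presets. At desk scale the solid-model
  runs (10× growth, one quarter of 600 MCS) complete only ~2 division
  cycles — enough to thicken and coarsen the layer (category 2/3 contacts,
  higher neighbour counts) but not to assemble the fully enclosed
  cancer-only cores that long runs (e.g. the first lepidic model over
  10000 desk MCS) do develop. Full-scale runs with the published step counts
  are the intended setting for solid-pattern reproduction.
* At desk scale the second lepidic model's cancer population frequently dies
  out: its high death rate (0.002/MCS) outpaces the crowded monolayer's
  realised division rate. The direction of the published contrast — fewer
  cancer–cancer contacts than the first lepidic model — is preserved, in the
  extreme.
* The supplementary parameter tables of the original study (exact baseline
  contact energies, λ values, mucus rates, scoring thresholds) are not
  printed in its main text; all such values here are declared package
  defaults, chosen once for mechanistic plausibility and documented above.
* 2D only; no chemotaxis or diffusion fields; no explicit cell-cycle model;
  no parameter-space sweeps or learned morphology clustering.
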