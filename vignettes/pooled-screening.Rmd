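---
title: "Multidimensional pooled BAC-library screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional pooled BAC-library screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacscreen)
```

## The problem

A BAC library with ~10× genome coverage holds tens of thousands of clones;
any locus of interest sits in on the order of ten of them. PCR-based
screening becomes tractable when the library is pooled so that each clone
is a member of exactly one pool per *dimension*, and a positive score in
every dimension triangulates the clone's coordinate. For an amphidiploid
genome (two progenitor genomes A and C), multiplexed SNP assays add a
twist: *intergenomic* SNPs distinguish the two homoeologous copies of a
gene in one reaction, so a single assay locates two loci — provided the
pool scoring can recognise pools containing one homoeolog, the other, or
both.

`bacscreen` implements the design, simulation, scoring, deconvolution and
audit layers of such a screening platform.

## The pooling design

The library (default: 216 plates × 384 wells = 82,944 clones) is arranged
in a cube: 36 layers of six plates in a 3 × 2 block grid, giving 48 cube
rows and 48 cube columns. A clone at cube position $(r, c, L)$ belongs to

$$\mathrm{PP}=L,\quad \mathrm{RP}=r,\quad \mathrm{CP}=c,\quad
\mathrm{DP}=(r+c)\bmod n_r,\quad \mathrm{SP}=(r+L)\bmod n_r,\quad
\mathrm{FP}=(c+L)\bmod n_c$$

with $n_r, n_c$ the cube row/column counts. Superpool dimensions use the
plate number: $\mathrm{SA}=\text{plate}\bmod 36$ (six plates per pool),
$\mathrm{SB}=\text{plate}\bmod 27$ (eight plates per pool),
$\mathrm{SG}=\text{plate}$ (single-plate pools).

**Why these formulas.** The historical six-axis scheme is described only
qualitatively in the screening literature; no closed formulas for the
diagonal, side and face axes are printed anywhere we could follow. The
modular forms above are fixed here because they satisfy every published
structural constraint — each dimension partitions the full clone set into
equal pools (36 × 2304 for PP, 48 × 1728 for the other five), the
$(\mathrm{RP}, \mathrm{CP}, \mathrm{PP})$ triple identifies a clone
uniquely, and the totals come out at 276 six-dimensional and 339
eight-dimension pools. The physical pools of the original platform may
have used different but equivalent axes. Similarly the SA/SB plate
groupings are fixed as *stride* groupings so that an SA pool is never
identical to a PP layer (which groups *consecutive* plates) — otherwise
SA would add no deconvolution information.

**Non-square cubes.** A classic "diagonal" presupposes a square cube, but
the modular formulas partition the clone set for *any* geometry: in
$(r+c)\bmod n_r$ the row coordinate spans the full residue ring for fixed
$c, L$, so every pool receives exactly $n_c \times \text{layers}$ clones.
We therefore allow non-square scaled geometries (the test suite uses an
8 × 6 × 4 cube of 192 clones for exhaustive checks) rather than rejecting
them. This is a deliberate deviation from a stricter reading under which
diagonal dimensions require $n_r = n_c$.

All coordinates are 0-based half-open internally; plates are 1-based and
wells "A1"-style only in files.

## The signal model

Each (pool, assay) record carries a normalized intensity $R \ge 0$ and a
normalized allele-frequency coordinate $\Theta \in [0,1]$. With $a$
effective carrier clones of allele 1 and $b$ of allele 2:

* $a + b = 0$: $R \sim \max(0,\, \mathcal N(\mu_0, \sigma_0))$ (residual
  fluorescence), $\Theta \sim \mathcal U(0,1)$ (undefined ratio — it never
  matters, because residual pools fail the $R$ threshold in expectation);
* $a + b > 0$: $R = R_{\max}\,(1 - e^{-\kappa (a+b)}) + \mathcal N(0, \sigma_0)$,
  $\Theta = \mathrm{clamp}\!\left(\frac{b}{a+b} + \mathcal N(0, \sigma_\Theta),\, 0, 1\right).$

The saturating-exponential intensity is one of many monotone saturating
forms consistent with the qualitative biology (clones are present in
unequal ratios in a pool; signal saturates with template amount); it is
fixed for reproducibility, and nothing downstream depends on its exact
shape — scoring only thresholds $R$.

### Defaults and what they emulate

| parameter | default | meaning |
|---|---|---|
| `r_residual_mean`, `r_residual_sd` | 0.05, 0.02 | residual intensity of empty pools, safely below the 0.2 threshold |
| `r_max`, `kappa` | 1.0, 1.0 | one carrier already gives $R \approx 0.63$ |
| `theta_sd` | 0.02 | Theta scatter of real pool data near the cluster cores |
| `dropout_prob` | 0.03 | per-clone per-assay representation failure |
| `weak_clones`, `weak_dropout_prob` | none, 0.5 | poorly growing clones escape detection often |
| `pool_fail_prob` | 0 | independent per-pool reaction failure (for controlled injection) |

Dropout is per-clone **per assay**: a dropped clone is absent from all of
its pools for that assay at once, modelling both weak growth and a clone
erroneously omitted during manual pooling. Consequently a pool carrying
$k$ clones of an allele is lost with probability $\approx p^k$ (verified
as a property test). The platform being emulated reported that ≈5.8% of
carrier pools escaped detection; with the 3% baseline dropout this
aggregate is reached when roughly 6% of carrier clones are "weak" at the
0.5 rate (e.g. `weak_clones` drawn as 6% of carriers). We leave
`weak_clones` empty by default rather than hard-wiring a fraction, since
it is an experiment-level property.

`pool_fail_prob` is *not* part of the emulated biology; it exists so that
a per-carrier-pool miss rate $f$ can be injected independently across
dimensions, making the recovery prediction $(1-f)^d$ across $d$ screened
dimensions testable. Per-clone dropout cannot produce this independence.

### What a green test does not establish

The simulator emulates residual fluorescence, saturation, Theta mixing,
dropout and cross-reactive (off-target) assays — with *independent*
Gaussian noise and *uniform* random locus placement. Real data have
correlated noise between assays of one oligo pool, plate-position
effects, unequal clone representation (insert-size and growth biases),
and loci clustered on few plates (library construction order). Green
tests establish the algorithms' correctness under the stated model, not
the field performance of the platform.

## Scoring

The threshold rule: $R < 0.2 \Rightarrow$ not scored; otherwise
$\Theta \le 0.05 \Rightarrow$ allele 1, $\Theta \ge 0.95 \Rightarrow$
allele 2, strictly between $\Rightarrow$ *both*. **Boundary semantics:**
$\Theta$ exactly 0.05 or 0.95 is a single-SNP call — the source
descriptions phrase the interval both ways, and we follow the
methods-style wording ("equal to or below / equal to or above" are the
single-SNP classes). This matters only for ties, which have measure zero
under the noise model but occur in boundary tests.

The clustering baseline (`cluster_baseline()`) stands in for proprietary
cluster-based callers: 1-D k-means on $\Theta$ of $R$-passing records,
up to three clusters mapped to calls by mean ordering
(lowest → allele 1, middle → both, highest → allele 2), with a
deterministic quantile initialisation. When both-allele pools'
$\Theta$ values intermingle with the single-allele clusters the baseline
misassigns them — the failure mode the threshold rule was designed
around. With fewer passing records than clusters (or a degenerate
partition) it falls back to the threshold rule with a warning. It is a
comparator, not a reproduction of any commercial algorithm.

`threshold_sweep()` re-scores and re-deconvolves under alternative
$\Theta$ windows; for nested windows the both-class count is
non-decreasing as the window widens (wider windows can only convert
single-SNP calls into both-calls, and both-calls count as positive for
either allele). For non-nested windows no monotonicity is guaranteed.
`fold_theta()` ($0.5 - |0.5 - \Theta|$) folds the two single-allele tails
together for diagnostics over many assays.

## Deconvolution

A coordinate is putative for an allele iff its pool is positive in
**every** screened dimension (a both-call is positive for either allele).
The implementation starts from the dimension whose positive pools cover
the fewest clones and filters by the remaining dimensions; the test suite
proves it identical to a brute-force scan over all coordinates,
exhaustively on the scaled cube and on 100 random screens at full scale.
Missing pool records are treated as negative with a warning — a scoring
failure in any dimension loses the coordinate, which is the dominant
false-negative mechanism of intersection decoding. An optional
`max_missing_dims` relaxation exists for diagnosis (about half of real
losses involve a single failed dimension) but is off by default.

Adding dimensions can only shrink the candidate set; the extra SA/SB or
single-plate dimensions exist to remove *shadow coordinates* —
non-carrier positions whose pools are all positive due to other carriers,
the combinatorial false positives that dominate when a locus has many
copies.

## Evaluation

`confirm()` reproduces the screening-summary arithmetic: confirmed =
putative ∩ known, with percentages of known and of putative, rounded to
one decimal (presentation convention); zero denominators give `NA`.
`audit_pools()` classifies every (pool, assay) pair:

* **consistent** — observed equals expected;
* **below_threshold** — a carrier pool not scored because $R < 0.2$;
* **both_for_single** — both-call where one allele was expected (never
  loses a coordinate; may inflate the putative list);
* **conflicting** — any call that removes a known coordinate from
  candidacy (single-allele call where the other allele or both was
  expected). A pool expected *both* but observed single is classified
  here, because the unobserved allele's coordinates lose that dimension —
  this resolves an ambiguity in the category description in favour of the
  omission-consequence reading;
* **unexpected_positive** — a positive pool with no known carrier.

The categories partition the audited pairs. `plate_filter()` implements
the two-step validation: only putative clones on plates that
independently test positive are carried to clone-level confirmation.

## Numerical and degenerate-input choices

* Theta is clamped to [0, 1] after noise; signal validation rejects
  records outside [0, 1] or with negative R rather than clamping.
* k-means ties in the baseline are broken by adding `1e-9 * rank` to the
  quantile centers, making the initialisation deterministic.
* `place_locus()` draws zero-truncated Poisson(10.6) copy numbers by
  default, matching the average locus representation of a 10× library.
* Empty candidate sets, empty signal tables and zero-copy placements are
  legal everywhere and covered by tests.
* Reruns under one seed are byte-identical (the whole pipeline consumes
  randomness only through R's RNG).

## Known limitations

* The diagonal/side/face axes and SA/SB groupings are *a* consistent
  realisation of the published pool counts, not necessarily the physical
  ones; designs from other realisations are isomorphic but not
  pool-for-pool identical.
* The clustering baseline is intentionally simple (1-D, fixed k); it is
  not a reimplementation of any vendor algorithm and should only be used
  as a comparator.
* The simulator does not model raw Cy3/Cy5 intensities, normalization, or
  assay designability; it starts from normalized (R, Theta) space.
* Field-scale recovery figures (e.g. ~80% of known coordinates) depend on
  unreleased genotyping data and are deliberately not asserted; the
  package instead verifies the mechanisms (threshold rule, intersection
  decoding, $(1-f)^d$ loss compounding) that explain them.
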