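---
title: "h33dyn: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{h33dyn: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h33dyn)
```

`h33dyn` analyses how the histone variant H3.3 is redistributed across the
genome while cells traverse a bifurcating fate transition — canonically,
OSKM-driven reprogramming of fibroblasts in which sorting (Thy-1 at days 6
and 9, SSEA-1 at days 12 and 16) separates a successful route ending in iPSCs
from an unsuccessful one. This vignette states the models and rules the
package implements, the parameters that matter, what the synthetic benchmark
does and does not emulate, and the choices made where the design was open.

## The experimental design as data

A *sample sheet* (tibble: `label`, `day`, `route`, `assay`) carries the
design. The default seven-point course is

```{r}
route_labels(design_reprogramming(), "successful")
route_labels(design_reprogramming(), "unsuccessful", include_shared = FALSE)
```

Day 0 and day 3 precede sorting and are `shared` by both routes; the
successful ordering runs through iPSC. The iPSC sample is given day 20 —
an arbitrary value larger than day 16 — only so that each route is totally
ordered; no computation uses the numeric gap. The three-point
transdifferentiation design (`design_transdiff()`: day 0, day 4, iHP) reuses
all machinery and simply has no unsuccessful branch, so route exclusivity is
undefined (`NA`) and no gene can be called a route-exclusive activator there.

All quantitative data are gene × sample tibbles (`gene_id` first column),
read and written as TSV at full decimal precision so file round trips are
exact.

## Region annotation

Coordinates are BED-style 0-based half-open throughout. The promoter of a
gene is the `promoter_bp = 3000` bases strictly upstream of its strand-aware
TSS, clamped at coordinate 0; the genebody is the full interval. A peak
overlapping any promoter window by ≥ 1 bp is a promoter peak; otherwise any
genebody overlap makes it a genebody peak; otherwise it is intergenic —
promoter precedence mirrors the convention of the standard annotation tools.
Competing genes within a category are resolved by smallest peak-to-TSS
distance, then lexicographic `gene_id`; this tie-break is a package choice
(exposed, not hard-wired into the rule) because annotation tools do not
document theirs. Peaks on chromosomes absent from the catalog downgrade to
intergenic with a warning rather than failing, keeping partial catalogs
usable. The implementation (a dplyr overlap join) is tested for exact
agreement with a per-base brute-force labeller on 1000 random peaks.

## Normalisation and presence calls

Tag counts are scaled to a common library of `scale = 1e7` tags
(`value × scale / library_size`); the 10⁷ constant is the familiar
tag-directory convention and is configurable. FPKM is the standard
`counts / ((length/10³)(library/10⁶))`. Heatmap matrices are per-row min–max
normalised to [0, 1]; constant rows map to all zeros (the only sensible
degenerate value once the range is empty).

A gene is *present* (enriched) in a sample when

\[(\mathrm{IP} + c)\,/\,(\mathrm{input} + c) \ge f \quad\text{and}\quad
\mathrm{IP}/(L/10^3) \ge d\]

with fold threshold `f = 2`, pseudocount `c = 1` on both numerator and
denominator (guarding zero input), and density floor `d = 0.5` normalised
tags/kb. The floor exists because a bare 2-over-1 ratio fires on nearly
empty genes; setting `min_density = 0` recovers the bare fold rule exactly.

## Onset rules

The core classification takes a boolean presence vector ordered along the
successful route, day 0 first:

* present at day 0 → **constitutive** (only genes that *start* displaying
  enrichment after day 0 can have an onset, so day-0-present genes never
  receive one, even if later lost);
* absent everywhere → **never**;
* absent at day 0 and at every point before some `t`, present from `t`
  through the end → **onset** at `t` (a "D-onwards" gene);
* anything else (gained-then-lost, gapped) → **unsustained**.

These four statuses partition the 2⁷ = 128 patterns of the default design
(and the 2³ of the transdifferentiation design); the test suite checks exact
equality with literal rule application on all 136.

Expression onset first requires FPKM ≤ 1 at day 0. The default
(`sustained = FALSE`) then takes the *first* post-day-0 point with FPKM > 1 —
the existential reading of "above threshold at any time-point". The
`sustained = TRUE` variant instead returns the first point from which
expression stays above threshold through the end, ignoring transient earlier
crossings; it deliberately differs from the deposition rule (which brands
gapped patterns unsustained) because a transient expression dip should delay,
not disqualify, an expression onset. Both readings are exposed and neither is
silently chosen; accessibility uses the sustained deposition-style rule, "in
a similar fashion" to H3.3.

*Route exclusivity* is absence at every sorted unsuccessful sample
(D6T⁺ … D16S⁻). Shared day-0/day-3 samples are excluded: they are the same
physical population on both routes and cannot carry route information. An
empty unsuccessful vector gives `NA`, never `TRUE`. *Precedence* compares
onset indices on the successful ordering: `lead = index(expression onset) −
index(deposition onset)`, positive for deposition-first; undefined whenever
either modality lacks a clean onset.

## Route-dependent clusters and differential expression

The upstream publication-grade DE step is a package call outside this
package's scope, and the cluster semantics depend only on the direction of
change, so DE is operationalised as an endpoint rule:
`log2FC = log2((end + 1)/(D0 + 1))` with the successful endpoint iPSC and the
unsuccessful endpoint D16S⁻, DE iff |log2FC(successful)| ≥ `lfc_min = 1`.
Clusters then follow the quadrant rules — I: down on both routes; II: down on
the successful route while the unsuccessful route is flat *or up*; III: up on
both; IV: up on the successful route while the unsuccessful is flat *or
down*. The unsuccessful-route threshold (same `lfc_min`) is the package's
declared operationalisation of "exclusively" versus "regardless of route";
genes unmeasured on the unsuccessful route stay unassigned. Negating all
fold changes maps I↔III and II↔IV, a symmetry the tests assert.

Heatmap row order is deterministic: cluster label first, then average-linkage
hierarchical clustering (Euclidean) of the *distinct* row patterns with
genes sorted by `gene_id` beforehand — so exact ties keep id order and the
result is invariant to input row permutation.

## Discovery

* **Top-N loss.** The ranking metric is the largest drop between consecutive
  successful-route time-points, floored at zero, with total loss (sum of all
  positive drops) and then `gene_id` as tie-breaks. The metric is a declared
  package choice: it operationalises "depleted at any time-point" while
  staying insensitive to the absolute level. `n = 250` by default.
* **Activators.** A gene must (1) have a deposition onset within the
  D6T⁻/D9T⁻/D12S⁺ window, (2) be route-exclusive, and (3) increase
  expression on the successful route exclusively (successful log2FC ≥ 1,
  unsuccessful |log2FC| < 1, reusing the DE rule for internal consistency).
* **Marker enrichment.** Upper-tail hypergeometric p per marker set,
  Benjamini–Hochberg across sets, score −log₁₀(adjusted p), significant at
  score ≥ 2. `phyper` and `p.adjust` do the arithmetic; the tests verify
  them against exhaustive draw enumeration (universe ≤ 20) and a hand-written
  step-up oracle.
* **Functional targets** are an exact two-set intersection with Venn region
  sizes (`tidy()` gives the table); which upstream definition of "losing
  H3.3" feeds it is left to the caller on purpose, since several are
  defensible.

## Profiles

Stepwise bedGraph coverage is stored with prefix integrals, so the sum of
signal over any window is exact, not sampled. Anchor profiles split
`[pos − flank, pos + flank)` into equal bins (minus-strand windows
reversed); the profile value is total bin signal over total covered bases,
which makes mass conservation — `Σ bin mean × width × n_anchors` equals the
per-base total — an identity checked against brute force on 100 random
fixtures. Windows crossing coordinate 0 are clamped and averaged over their
covered bases (with a counted warning) rather than dropping the anchor.
Genebody (metagene) profiles scale each gene to a fixed number of bins, the
fixed-bin convention of average-profile tools; the per-bp normalisation is
declared here rather than inferred from any external tool.

## The synthetic branching time course

The generator plants, per gene, a class — fibroblast (15%), mesenchymal
(10%), pluripotency (15%), epithelial (10%), housekeeping (10%), neutral
(40%) — with counts allocated by largest remainder so realised fractions
match configuration to rounding. Classes fix the trajectory templates:

* fibroblast/mesenchymal genes start enriched and expressed high and lose
  both along the successful route at a per-gene loss step, balanced across
  steps so the class-mean curve falls strictly at every transition; they
  retain H3.3 on the unsuccessful route. Cluster I genes also lose
  expression on the unsuccessful route, Cluster II genes keep it.
* pluripotency/epithelial genes gain H3.3 at a planted onset (uniform over
  D3–D12) and expression at onset + lead; a configured
  `deposition_lead_fraction` of onset genes (allocated exactly, not by coin
  flips, so the planted fraction is recoverable without sampling error) get
  lead 1–2 steps, the rest are simultaneous. Cluster III genes also rise on
  the unsuccessful route; epithelial genes always carry unsuccessful-route
  enrichment, which confines true activators to the pluripotency class.
* housekeeping genes are constitutively enriched and expressed; neutral
  genes are never either.

Expression templates use high = 3.8, low = 0.2 FPKM: with pseudocount 1 the
planted endpoint log2 fold changes are exactly ±2 and the levels straddle
the FPKM > 1 onset threshold. ChIP counts are negative binomial
(`size = 1/dispersion`) around `input mean × 4` where present and
`input mean × 1` where absent, with input mean 2 tags/kb × gene length —
chosen so that at zero noise the pseudocount-1 fold rule and the density
floor recover the planted pattern for every gene length in the 1–50 kb
log-uniform catalog. Counts are overdispersed NB because ChIP tags are;
no noise model is claimed from any external source.

Presence-flip noise ε flips each planted presence call independently
*before* count generation, so the perturbation is carried by the emitted
count matrices themselves and degrades recovery through the real enrichment
caller; flipping only a separate presence file would be invisible to the
pipeline. At ε = 0 and zero dispersion/log-sd the pipeline recovers 100% of
planted onsets, clusters, activators and the deposition-lead fraction — the
round trip is the generator's correctness oracle.

What the generator does **not** emulate: read-level artefacts (fragment
sizes, GC bias, mappability), peak-shape variation, replicate structure,
correlated noise across neighbouring genes, and partially-penetrant
trajectories. Passing recovery tests therefore demonstrates that the rules
are implemented exactly and are robust to independent noise of the stated
kinds — not that they would be equally accurate on real libraries.

## Determinism, problem sizes and limitations

Every sampling step sits under `withr::with_seed` with sub-seeds derived
from the configuration seed, so bundles are byte-identical across runs and
platforms; the pipeline itself is RNG-free, and every output file carries a
hash of the effective analysis parameters (paths excluded, so the same
configuration into different directories stays byte-identical). The test
suite and the acceptance script run at 400–1000 genes, 3 seeds per noise
level, 100 random fixtures for the profile and BH oracles, and 1000 random
peaks for the annotation oracle — sizes at which every check completes in
seconds while keeping binomial noise on recovery rates well below the
margins being asserted.

Known limitations: the endpoint DE rule ignores intermediate time-points and
replicates by design; onset calls are hard-thresholded (no smoothing or
change-point uncertainty); the marker-enrichment module expects user-supplied
GMT sets rather than any curated tissue panel; and peak calling itself is out
of scope — peaks are consumed, not produced.
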