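# h33dyn

Temporal analysis of histone-variant **H3.3** deposition along a bifurcating
cell-fate transition.

During OSKM-induced reprogramming of mouse embryonic fibroblasts, cells can be
sorted into a *successful* route (Thy-1⁻, later SSEA-1⁺, ending in iPSCs) and
an *unsuccessful* route (Thy-1⁺ / SSEA-1⁻). H3.3, the replication-independent
H3 variant deposited by Hira on active chromatin, is progressively removed
from fibroblast/mesenchymal genes and gained on pluripotency/epithelial genes
— and the gain tends to *precede* transcriptional activation. `h33dyn`
implements this analysis as a tested, deterministic pipeline over gene ×
sample matrices:

* **Region annotation** — strand-aware assignment of peaks to
  promoter (3 kb upstream of the TSS) > genebody > intergenic, with
  nearest-TSS tie-breaking.
* **Quantification** — library normalisation to 10⁷ tags, FPKM
  (`counts / ((L/10³)(N/10⁶))`), per-row min–max normalisation, and presence
  calls by fold-over-input: present iff
  `(IP + 1)/(input + 1) ≥ 2` and IP density ≥ 0.5 tags/kb.
* **Onset classification** — the "D-onwards" rule: a gene is a *D-onwards*
  gene when enrichment is absent at day 0 and every earlier point, then
  present from D through the end of the course; expression onset uses
  FPKM > 1 after a quiet day 0. Route exclusivity and
  deposition-versus-expression precedence (lead in time-point steps) build on
  these calls.
* **Route-dependent clustering** — endpoint log2 fold changes
  (pseudocount 1, |log2FC| ≥ 1) place DE genes in Cluster I (down both
  routes), II (down successful-only), III (up both), IV (up
  successful-only).
* **Discovery** — top-250 ranking by largest consecutive loss of genebody
  signal, functional-target (Venn) intersection, route-exclusive activator
  identification (onset in the D6–D12 window, never enriched on the
  unsuccessful route, expression up successful-only), and hypergeometric
  marker-set enrichment with Benjamini–Hochberg adjustment
  (score = −log₁₀ adjusted p, significant at ≥ 2).
* **Profiles** — exact binned average-enrichment profiles around anchors and
  metagene genebody profiles on stepwise (bedGraph) coverage, plus gene-set
  trajectories with standard errors.
* **Synthetic benchmark** — a deterministic generator of the full branching
  design (7-point reprogramming or 3-point transdifferentiation to iHPs)
  with planted classes, clusters, onsets and activators, used to validate
  every stage end-to-end.

Everything is tidyverse-native: functions take a tibble first and return
tibbles, results plot with `autoplot()`, and run objects support
`tidy()`/`glance()`.

## Worked example

Simulate a noise-free 1000-gene reprogramming course, run the full pipeline
on its file bundle, and inspect the result:

```r
library(h33dyn)

cfg <- simulation_config(n_genes = 1000, fpkm_log_sd = 0,
                         count_dispersion = 0, presence_flip = 0, seed = 42)
simulate_bundle(cfg, "bundle")
res <- run_all(run_config("bundle", "out"))
glance(res)
#> # A tibble: 1 × 10
#>   n_genes  n_de n_cluster_I n_cluster_II n_cluster_III n_cluster_IV n_onset
#>     <int> <int>       <int>        <int>         <int>        <int>   <int>
#> 1    1000   500         122          128           128          122     250
#>   n_deposition_first n_activators config_hash
#>                <int>        <int> <chr>
#> 1                200           59 e473a797a4f0a4de5f25dad349950f1b
```

Half the genes are differentially expressed between day 0 and iPSC and fall
into the four route-dependent clusters; 250 genes gain H3.3 with a clean
sustained onset, 200 of them before their expression onset (the generator's
80% deposition-lead fraction over the 250 onset genes), and 59 route-exclusive
activators are recovered. Per-gene calls line up with the planted truth:

```r
tidy(res)
#> # A tibble: 1,000 × 10
#>   gene_id cluster    h33_status h33_onset expr_status expr_onset route_exclusive
#>   <chr>   <fct>      <chr>      <chr>     <chr>       <chr>      <lgl>
#> 1 g0001   I          constitut… <NA>      constituti… <NA>       FALSE
#> 2 g0002   IV         onset      D12S+     onset       D16S+      TRUE
#> 3 g0003   unassigned never      <NA>      never       <NA>       TRUE
#> 4 g0004   II         constitut… <NA>      constituti… <NA>       FALSE
#> # ℹ 996 more rows
```

`g0002` is a typical activator: H3.3 arrives at D12 (SSEA-1⁺ cells),
expression follows at D16, and the gene is never enriched on the unsuccessful
route. The core rule is available directly:

```r
classify_onset(c(0, 0, 1, 1, 1, 1, 1),
               route_labels(design_reprogramming(), "successful"))
#> # A tibble: 1 × 2
#>   status onset_label
#>   <chr>  <chr>
#> 1 onset  D6T-
```

A thin CLI mirrors the stages (`simulate`, `annotate`, `quantify`,
`profiles`, `clusters`, `onset`, `discover`, `run-all`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "h33dyn.R", package = "h33dyn"))')
Rscript "$CLI" simulate --out bundle --n-genes 1000 --seed 42
Rscript "$CLI" run-all --input bundle --out out
```

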