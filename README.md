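# regatlas

Analysis toolkit for bulk RNA-seq expression atlases of energy-balance
brain regions, for researchers who want to ask: *where in the
appetite-regulating brain are my disease genes expressed, and do they fall
into coherent co-expression programs?*

The package re-implements, as a tested and reusable pipeline, the analysis
style used for regional brain atlases of obesity genetics: a gene ×
sample TPM matrix over hypothalamic, brainstem, cortical/limbic,
cerebellar and embryonic punches (plus embryonic stem-cell lines) is
summarized per disease gene list by

- **Regional frequency distributions.** For gene *g* and region *r* (TPM
  averaged over replicates), the frequency is
  `F(g, r) = 100 · TPM(g, r) / Σ_r' TPM(g, r')`, compiled per list as
  mean ± SEM, with all pairwise region contrasts tested by one-way ANOVA
  followed by pooled-variance t tests under the Benjamini–Krieger–
  Yekutieli two-stage adaptive FDR (both stages at level `q/(1+q)`).
- **Gene-set enrichment.** Region-vs-rest ranking by signal-to-noise
  `(μ_t − μ_o)/(σ_t + σ_o)` (SDs floored at `0.2·|μ|`), weighted
  running-sum enrichment score with hit increments `∝ |s|^p` and miss
  decrements `1/(N − N_h)`, gene-set permutation null, NES and
  Benjamini–Hochberg FDR; a target is flagged when ES > 0 and FDR < q.
- **Co-expression modules**, three ways: WGCNA-style (unsigned adjacency
  `|cor|^β`, soft threshold by scale-free fit with a silhouette fallback,
  topological overlap, static tree cut), hierarchical clustering
  (correlation distance, average linkage) and k-means with elbow-based k
  selection; partitions compared by the adjusted Rand index.
- **Module overrepresentation.** For a list with `x` genes among `y`
  total list memberships and a module of `z` genes containing `w` of the
  list, the score is `w / ((x/y)·z) − 1`: 0 under exact proportional
  allocation, −1 when the module has none of the list.
- **A synthetic atlas generator** that plants region markers,
  co-expression modules tied to region groups, a developmental-stage
  program and list enrichments with known ground truth, so every stage
  has a recovery test without any data download.

## Worked example

```r
library(regatlas)

set.seed(1)
atlas <- generate_atlas(atlas_config(n_genes = 600, seed = 1))
gl <- generate_gene_lists(atlas$truth,
  list(list(name = "monogenic", size = 25,
            target_group = "homeostatic", strength = 1.0),
       list(name = "background", size = 30)),
  rownames(atlas$matrix$values), seed = 2)

prof <- average_replicates(atlas$matrix)
ft   <- frequency_table(prof)
summ <- list_summary(ft, gl$lists$monogenic)
head(summ[order(-summ$mean), c("region", "group", "mean", "sem")], 3)
#>   region       group     mean      sem
#> 7    NTS homeostatic 10.73504 1.650998
#> 4    VMH homeostatic 10.67216 1.688508
#> 8    DVC homeostatic 10.61880 1.594223

res <- gsea_all(atlas$matrix, gl$lists, level = "group",
                n_perm = 1000, seed = 3, universe = "all")
subset(res, significant, c(target, list, es, nes, p_perm, fdr))
#>        target      list        es      nes      p_perm         fdr
#> 1 homeostatic monogenic 0.8557898 3.178004 0.000999001 0.000999001
```

The planted homeostatic list peaks in homeostatic regions (top mean
frequencies ~10.7% per region versus ~4.2% = 100/24 under uniformity)
and is the only (target, list) pair flagged by GSEA. Module detection
and overrepresentation continue the same session:

```r
uni  <- names(atlas$truth$module_of)
mods <- wgcna_modules(average_replicates(
  expr_matrix(atlas$matrix$values[uni, ], atlas$matrix$samples)))
mods
#> <module_assignment> wgcna: 240 genes, 6 modules (0 unassigned)
module_agreement(mods$modules, atlas$truth$module_of[uni])
#> [1] 1

ot <- overrepresentation_table(mods, gl$lists)
sub <- subset(ot, list == "monogenic")
sub[order(-sub$score), ][1:3, ]
#>   module      list  w  z percentage  x  y  score
#> 1      1 monogenic 15 40       37.5 15 27 -0.325
#> 2      2 monogenic  0 40        0.0 15 27 -1.000
#> 3      3 monogenic  0 40        0.0 15 27 -1.000
```

All six planted modules are recovered exactly (ARI = 1), and the planted
list's maximal overrepresentation score lands on the module sharing its
target group: all 15 of its clustered genes sit in module 1 (37.5% of
the module). Note the score's absolute level depends on the total
membership count y: with only two small lists y (27) is smaller than the
module size z (40), so even complete concentration cannot exceed
y/z − 1 < 0; with realistically many lists (y >> z, as in a five-list
disease panel) concentrated lists score strongly positive. The ranking
across modules — which is what the overrepresentation analysis reads —
is unaffected.

Every run is reproducible from a JSON config through the pipeline driver
(`run_pipeline("config.json")`) or the CLI
(`inst/cli/regatlas run --config config.json`), which writes stage TSVs,
a Newick sample dendrogram and a manifest with input checksums.

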