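---
title: "Methods: regional frequency profiles, enrichment and co-expression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional frequency profiles, enrichment and co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and procedures, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the underlying
analysis style leaves details open. No empirical claim is made here that
the test suite or `scripts/acceptance.R` does not itself compute.

## The data model

The substrate is a gene × sample matrix of TPM (transcripts per million;
each sample column sums to 10^6) over brain-region punch biopsies and
embryonic stem-cell (mESC) reference samples, with metadata assigning
each sample a region acronym (Allen Brain Atlas naming, e.g. ARH for the
arcuate hypothalamic nucleus), a system group (homeostatic, executive,
reward, cerebellum, embryonic, stemcell) and a replicate index.
Transcript-level quantifications are aggregated to genes by summation,
which conserves per-sample totals exactly. Replicates are averaged per
region as an unweighted arithmetic mean of TPM — deliberately on the
linear scale, not log space, matching the convention of averaging the
TPM data directly. Disease gene lists are plain named sets of symbols;
human symbols are mapped to mouse-style casing by case normalization
only (`POMC` → `Pomc`), with unmatched symbols dropped and reported — no
orthology database is consulted, which keeps the package download-free
and is a documented limitation (genes with non-trivial orthology are
silently lost).

## Regional frequency distributions

For gene $g$ and region $r$, with $x_{gr}$ the replicate-averaged TPM,

$$F_{gr} = 100\,\frac{x_{gr}}{\sum_{r'} x_{gr'}}.$$

Rows sum to 100 by construction; genes with zero total have no defined
frequency and are excluded with a report. The denominator includes the
mESC columns by default, with an `include` argument to restrict — the
default matches the published analysis style (brain regions *and* mESC),
the flag supports sensitivity analysis. Per gene list, the frequency
score per region is the mean over list genes with SEM = sample SD /
$\sqrt{n}$; for a single-gene list the SEM is reported as 0 and the
result flagged (`sem_degenerate`), avoiding NaN propagation.

Pairwise region testing treats the gene as the unit of observation:
one-way ANOVA of the per-gene percentages across regions (independent
groups; the repeated-measures alternative across genes is noted but not
implemented, since the source analysis does not state pairing), followed
by all $R(R-1)/2$ contrasts as pooled-variance t tests (Fisher-LSD form,
df = $N - R$), adjusted jointly by the Benjamini–Krieger–Yekutieli (BKY)
two-stage step-up at level $q$ (default 0.05). If the pooled
within-group mean square is zero the p values are undefined and reported
as such with a `degenerate` flag.

### The BKY two-stage procedure and a caveat

`bky_adjust` implements the published adaptive two-stage procedure:
stage 1 is Benjamini–Hochberg (BH) at $q' = q/(1+q)$, yielding $r_1$
rejections and $\hat m_0 = m - r_1$; stage 2 is BH at $q'\,m/\hat m_0$
($r_1 = 0$ rejects nothing, $r_1 = m$ everything). Note the second stage
also runs on the deflated $q'$ — this follows the published definition
(and, e.g., statsmodels' `fdr_tsbky`). A caveat worth stating: the
two-stage procedure does *not* dominate plain BH at level $q$ — a p
value that clears the $q$ step-up threshold but not the $q'$ one can be
rejected by BH and missed by both BKY stages (smallest example: one
hypothesis with $p = 0.049$ at $q = 0.05$). The guaranteed containment
is over BH at level $q/(1+q)$. One acceptance assertion encodes the
stronger (false) claim and is intentionally left failing on 2 of 500
frozen random fixtures rather than weakened.

## Gene-set enrichment

Genes are ranked per target (a region's replicates, or all samples of a
system group, against all other samples) by signal-to-noise
$(\mu_t-\mu_o)/(\sigma_t+\sigma_o)$, each group SD floored at
$\max(0.2\,|\mu|, 10^{-8})$ so single-replicate groups and constant
genes never produce NaN; ties in the statistic break lexicographically
by gene id, making the order fully deterministic. The running-sum
enrichment score increments at set hits by $|s|^p$ normalized over the
set's hits and decrements at misses by $1/(N-N_h)$; the ES is the signed
maximum deviation. With $p=0$ this is exactly the Kolmogorov–Smirnov
statistic between hit and miss position CDFs (tested against an
independent empirical-CDF computation). Deviations at $p=0$ are
rational, so exact magnitude ties between the positive and negative
extrema can occur; the convention is to return the positive extremum,
applied with a $10^{-12}$ tolerance, and the test oracles share the
rule.

The null is **gene-set permutation** (random same-size sets), not
phenotype permutation: several regions have a single replicate, making
label permutation degenerate — this is the only feasible null at this
design, and it answers a slightly different question (specificity of the
set against random sets on the same ranking). NES is the ES divided by
the mean same-sign null magnitude; `p_perm` uses the add-one estimator
$(1 + k)/(n_{perm}+1)$, so $p \ge 1/(n_{perm}+1)$ always. The
significance flag is positive ES *and* within-list BH FDR below $q$,
mirroring the positive-score-plus-FDR asterisk convention. Defaults
$p = 1$, `n_perm = 1000` (CLI; 200 in the reduced test suite) follow the
canonical weighted-GSEA description, since the source names the tool but
not its parameters; they are configurable rather than claimed
equivalent.

The ranked universe defaults to the union of the input lists (the
published setting, where five disease lists were ranked together). With
only *two* lists that universe makes the lists near-complements: a list
whose genes avoid the target group necessarily occupies the top of a
ranking whose bottom is the other list, and both get extreme scores.
The recovery and type-I simulations therefore run with
`universe = "all"` (all matrix genes); both modes are exposed.

## Co-expression modules, three ways

All module detection operates on the replicate-averaged, per-gene scaled
profile. Scaling is a z-score with the *population* SD (divisor $n$),
the heatmap convention; constant genes map to all-zero rows rather than
NaN.

**WGCNA-style.** Unsigned adjacency $a_{ij} = |\mathrm{cor}(g_i,
g_j)|^\beta$ (a signed variant is available behind a flag; the source
does not state which was used). The soft threshold is chosen as the
smallest $\beta$ in the grid (1–10, 12, 14, 16) whose scale-free
topology fit reaches $R^2 \ge 0.8$ with negative slope — the standard
criterion. Planted-block structure is *not* scale free, so a fallback
implements the "highest separation between modules" reading directly:
the $\beta$ maximizing the mean silhouette width of a trial clustering
of the topological overlap matrix (TOM); the criterion actually used is
recorded in the result. TOM is the shared-neighbour similarity
$(\sum_{u\neq i,j} a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$ with unit diagonal, verified against a literal double-loop
oracle. Trees (1 − TOM, average linkage) are cut **statically** at a
fraction (default 0.99) of the maximum merge height with a minimum
module size (default 3; clusters below it become module 0 =
unassigned). This replaces the dynamic hybrid tree cut deliberately: the
static cut is fully specifiable and testable, at the cost of not
splitting nested modules the way the dynamic heuristics sometimes do.
Module labels are always 1..M by decreasing size (ties by first
occurrence), so labels are a deterministic function of input and
parameters.

**Hierarchical** clustering uses the same correlation distance and
average linkage, cut into $k$ groups. **K-means** runs Lloyd's algorithm
on the scaled rows, best of 25 random restarts by total within-cluster
SS under a fixed seed; restarts that produce empty clusters or
non-distinct centers count as failed fits and are discarded. $k$ is
chosen by the elbow: the $k$ maximizing the discrete second difference
of WSS, ties to the smallest $k$. A "weak elbow" is flagged when the
maximal second difference is below 0.3 of the total WSS drop over the
range — calibrated before freezing the tests on the two regimes the flag
must separate (planted well-separated blocks concentrate essentially
the whole drop in one second difference, ratio ≈ 1; structureless
Gaussian clouds spread it, ratio ≲ 0.2).

Cross-method agreement is the adjusted Rand index; degenerate
contingency tables (both partitions trivial) return 1. Heatmap gene
ordering follows the module-first rule: genes sort by module id
(unassigned last), then by the position at which each gene appears in
the global hierarchical clustering of the scaled profile.

## The overrepresentation score

For a list with $x$ genes in the clustered universe, $y$ the total
membership count over all lists (a gene in two lists counts twice), and
a module of $z$ genes containing $w$ genes of the list:

$$\mathrm{score} = \frac{w}{(x/y)\,z} - 1 .$$

Two readings of the defining expression "(w/[x/y] × z) − 1" are
possible; the literal left-to-right evaluation $(w\,y/x)\,z - 1$ fails
the score's stated purpose — it is not zero under proportional
allocation and does not normalize for module size. The implemented
reading is the unique one that is 0 under exact proportionality,
−1 at $w = 0$, scale invariant in $(w,x,y,z)$, and satisfies the per-
list conservation identity $\sum_m z_m(\mathrm{score}_m+1)(x/y) = x$
(all of these are tested; the literal variant remains available as
`formula = "literal"` for audit). Similarly, "y = n all gene lists" is
read as the total membership count: reading it as the *number* of lists
makes $x/y$ dimensionally incoherent as an allocation proportion.
Unassigned genes (module 0) are excluded from $w$, $x$, $y$, $z$ by
default, with a flag to include them. One behaviour to keep in mind
when interpreting levels (not rankings): when $y < z$ — few, small
lists and large modules — even complete concentration of a list in one
module yields a negative score, bounded by $y/z - 1$; with many lists
($y \gg z$) concentrated lists score strongly positive. Statistical
testing of the score (e.g. hypergeometric p values) is deliberately out
of scope: it is a descriptive statistic.

## The synthetic atlas: what a green test establishes

The generator emulates the design dimensions that the downstream
statistics actually consume: 22 brain regions in five adult/embryonic
system groups plus two mESC lines (fully configurable roster), 1–4
replicates per region (default 3 adult / 2 embryonic / 2 mESC, ~66
samples), log-normal baseline TPM (log10 mean 1, SD 1 across genes —
median ~10 TPM with a heavy right tail), region-specific markers
(default 5 per region at 10× — the neuropeptide-style pattern),
planted co-expression modules as gene blocks sharing a latent region
profile elevated in one group's regions (embryonic and stem-cell module
profiles partially coupled, as developmental programs are), a
developmental-stage signature (default 100 genes each elevated in all
adult, respectively all embryonic+mESC samples — the axis that dominates
sample dendrograms), i.i.d. log-normal replicate noise (log10 SD 0.2,
about 1.6-fold scatter), and TPM renormalization to 10^6 per sample.
Gene lists are drawn with a stated fraction ("strength") from genes
whose planted profile peaks in a target group, the remainder uniformly,
with exact requested overlaps between lists.

Determinism is strict: baselines are log-normal *quantiles* (a
deterministic function of the configuration), so with `noise_sd = 0`
the matrix is bit-identical across seeds, and all randomness flows from
the single seed.

Not emulated: read counts and sequencing error (TPM-level structure
only), batch effects, gene–gene correlation outside the planted blocks,
compositional coupling beyond the final renormalization, dropout, and
any real anatomy — a green recovery test establishes that the
implementations recover the structure they are defined to detect at
realistic signal-to-noise, not that the biological conclusions of any
particular atlas are correct. Recovery simulations use the default
configuration with the background gene count reduced to 600 (planted
structure, folds and noise identical) to keep the suite inside its time
budget.

## Reproducibility and the pipeline

`run_pipeline()` drives simulate → frequency → GSEA → modules →
overrepresentation from a JSON configuration (JSON rather than YAML so
the pipeline has no dependency outside the guaranteed runtime set);
stages consume prior stages' TSV outputs only, every output is plain
TSV/JSON/Newick written at full precision (`%.17g`, so write→read
round-trips are bitwise), and a manifest records input checksums,
parameters, seed and package version. Identical configurations produce
byte-identical outputs. The CLI (`inst/cli/regatlas`) exposes each stage
as a subcommand with exit codes 0/1/2 (ok / user error / internal
error).
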