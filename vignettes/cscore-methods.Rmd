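---
title: "Concordance scoring of paired differential-expression contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance scoring of paired differential-expression contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscore)
library(dplyr)
```

## The problem

A common design in transcriptomics compares two related exposure groups
against one shared control — for example two clinical subgroups of the same
condition, each contrasted with healthy samples, within each cell type of a
single-nucleus experiment. The scientific question is then not only *which*
genes respond, but whether each gene responds the **same way** in both
comparisons (a shared response) or in **opposite directions** (a response
that differs between the subgroups). Thresholded overlap of two DEG lists
answers this only coarsely and inherits every arbitrary cut-off; `cscore`
instead scores concordance continuously, per feature, and attaches a
permutation significance to each score.

The same machinery applies unchanged to pathway-level inputs: a normalized
enrichment score (NES) with its adjusted p-value is consumed exactly like a
log2 fold change with its FDR.

## The statistic

Each feature carries an effect and an FDR in each contrast:
\((E_1, \mathrm{FDR}_1)\) and \((E_2, \mathrm{FDR}_2)\). Three ingredients
combine into the score.

**Significance weight.** Effects are discounted by how non-significant they
are:
\[
w(\mathrm{FDR}) =
\begin{cases}
1 & \mathrm{FDR} < 0.05\\[2pt]
\log_{10}(\mathrm{FDR}) / \log_{10}(0.05) & \mathrm{FDR} \ge 0.05
\end{cases}
\]
The two branches agree at 0.05 and the weight decays to 0 at
\(\mathrm{FDR} = 1\), so a large but unconvincing fold change contributes
little.

**Magnitude.** The weighted total response size:
\[
M = |E_1|\, w(\mathrm{FDR}_1) + |E_2|\, w(\mathrm{FDR}_2) .
\]

**Ratio.** Direction agreement, positive iff the effects share a sign:
\[
R = \begin{cases}
\dfrac{\max(|E_1|, |E_2|)}{|E_1 - E_2| + 1} & E_1 E_2 > 0\\[8pt]
-\dfrac{|E_1 - E_2|}{\max(|E_1|, |E_2|) + 1} & E_1 E_2 \le 0 .
\end{cases}
\]

The **C-score** is \(C = M \times R\). Positive values mean the feature
moved in the same direction in both comparisons (up in both or down in
both); negative values mean opposite directions; the absolute value grows
with the size and significance of the fold changes. A feature whose effect
is exactly zero has no direction, so its score is forced to exactly 0: by
default a single zero effect suffices (`zero_rule = "either"`), because the
discordant branch would otherwise label a \((0, e)\) feature "different".
The `"both"` variant is available for users who prefer the narrower
reading.

The absolute-value placement deserves a note: without \(|\cdot|\) around
the effects, a gene strongly *down* in both contrasts would receive a
negative magnitude and flip sign, contradicting the intended reading that
positive scores cover shared-down as well as shared-up responses. The
implementation therefore uses \(|E|\) throughout the magnitude and the
ratio numerators/denominators.

## Permutation significance

Significance is assessed against a null in which the pairing between the
two contrasts is destroyed while each contrast's own (effect, FDR) coupling
is preserved: every permutation shuffles the rows of contrast 1 and of
contrast 2 independently and rescores all features. The permuted scores of
all features and all permutations are **pooled** into one null
distribution — equivalently, the null is the distribution of
\(C(E_{1i}, \mathrm{FDR}_{1i}, E_{2j}, \mathrm{FDR}_{2j})\) over ordered
cross-pairs \((i, j)\). The pooled design is what makes the small-sample
rule coherent: with \(n\) features there are exactly \(n^2\) ordered
cross-pairs, and `exact = TRUE` enumerates them all. A per-feature null
(each feature compared only to its own permuted scores) is available via
`null = "per_gene"` for users who want the narrower conditioning.

For each feature the one-sided p-value is the pooled-null frequency of
scores strictly greater than a positive observed score, or strictly smaller
than a negative one; zero scores get p = 1. Ties count for neither tail, so
exact mode is reproducible bit for bit. Sampling defaults follow the size
rule: \(n^2\) permutations for tables of at most 200 features, 40 000
otherwise. Two finite-sample conventions are exposed:
`p_correction = "add_one"` (default) reports \((\#\{\text{more extreme}\} +
1)/(N + 1)\) so that no p-value is exactly 0, while `"raw_frequency"`
reports the literal frequency.

Because the test is one-sided *in the direction of the observed sign*, a
feature from a fully null table is rejected at level \(\alpha\) whenever it
lands in either extreme tail — the null rejection rate is about
\(2\alpha\) overall (about \(\alpha\) per tail), which the all-null
calibration test in the suite reproduces at \(\alpha = 0.05\).
Users who need a strictly level-\(\alpha\) family decision should halve
\(\alpha\) or filter on score sign first; classification in this package
keeps the field's convention of \(\alpha = 0.05\) one-sided.

Classification (`classify_patterns()`): `zero` if \(C = 0\);
`not_significant` if \(p \ge \alpha\); otherwise `shared_up` / `shared_down`
by the sign of the effects for positive scores, and `different` for
negative scores.

## The communication network

Given per-cell-type score tables and a ligand–receptor resource
(LIANA-style: pair name, ligand subunits, receptor subunits, complexes
joined by `_`), `build_ccc_network()` forms one directed edge per (sender
cell type, receiver cell type, ligand–receptor pair) tetramer: ligand
subunit C-scores are looked up in the sender's table, receptor subunit
scores in the receiver's, and the edge weight is their sum (`subunit_agg`
offers `mean`/`min` within each side for resources with large complexes).
The mean of the contributing genes' permutation p-values is attached to the
edge. An edge requires at least one found subunit on each side
(`require_all_subunits = TRUE` tightens this); self-edges are off by
default since the network maps signals *between* cell types; no
significance filter is applied unless `max_mean_p` is set.

Positive-weight edges form the *shared* subnetwork (interactions responding
concordantly in both contrasts), negative-weight edges the *different*
subnetwork. Degrees use **absolute** weights — the sum of \(|w|\) sent
(out-degree) or received (in-degree) per cell type — so that the
negative-weight subnetwork still yields positive, comparable degree
magnitudes. `rank_ccc_genes()` aggregates \(|w|\) per (cell type, gene) to
rank a cell type's dominant outgoing ligands or incoming receptors.

## The synthetic benchmark

`simulate_dual_contrast()` plants a known regulation class per gene —
`shared_up`, `shared_down`, `different` (opposite signs, which side is up
is random), `null` — with default proportions 5/5/5/85 % over 2 000 genes.
True absolute effects follow Normal(1.5, 0.3) truncated at 0 on the log2
scale, drawn independently per contrast; observed effects add
Normal(0, 0.25) noise; per-contrast p-values come from the corresponding
z-test and are BH-adjusted within contrast. These defaults represent a
moderately powered snRNA-seq DE setting: planted genes are individually
detectable (|effect|/SE ≈ 6) but the 15 % signal fraction keeps the pooled
null dominated by null–null cross-pairs.

The generator works directly on the (effect, FDR) scale rather than
simulating counts, because that pair is the entire interface the score
consumes; count-level realism (overdispersion, library-size variation,
dropout) would exercise the upstream DE model, which this package
deliberately does not contain. Passing recovery tests therefore
demonstrates that the scoring and testing machinery recovers planted
concordance structure from well-calibrated DE summaries — not that any
particular upstream DE caller is well calibrated on real counts.

With the default configuration and 40 000 permutations, the test suite
asserts pre-registered recovery bounds — precision ≥ 0.8 for called shared
and called different genes, per-class recall ≥ 0.5 — at full size in the
acceptance suite and on a 400-gene version in the unit suite; the observed
margins are far wider.

`simulate_lr_resource()` samples a toy resource (configurable complex
fraction) and `simulate_celltype_scores()` composes generator and scoring
per cell type with fixed seed offsets (generation: master seed + index;
permutation: master seed + 500 + index), so multi-cell-type fixtures are
reproducible from one integer.

## Numerical and design choices

- **Alignment.** Features present in only one contrast are excluded before
  scoring (the score needs both effects); `missing_as_zero = TRUE` keeps
  them with effect 0 / FDR 1, which the zero rule scores as 0. Features are
  sorted lexicographically (C locale) so results do not depend on input row
  order.
- **Tail counting.** Null tail counts use a sort + `findInterval()` pass
  per permutation, so the pooled null (up to 40 000 × n scores) is never
  materialised; memory stays O(n).
- **Degenerate inputs.** Tables with a single feature are rejected for
  permutation testing; empty intersections error at alignment; all-tied
  null pools yield p = 1/(N+1) under `add_one` (ties count for neither
  tail).
- **Exact small-sample statistics.** The Mann–Whitney test enumerates all
  \(\binom{n_1+n_2}{n_1}\) rank assignments and doubles the smaller tail
  (capped at 1); ties across groups are refused rather than approximated.
  The hypergeometric overlap test uses the upper-tail distribution function
  directly, which is stable at universe sizes in the tens of thousands.
- **Problem sizes.** The shipped tests run the full 2 000-gene, 40 000
  permutation recovery benchmark once and keep the remaining checks at
  12–500 genes, which exercises every code path with exhaustive oracles
  where those are feasible.

## Limitations

- The permutation null treats features as exchangeable within a contrast;
  correlated genes (co-regulation, shared pathways) make the pooled null
  anti-conservative in ways the synthetic generator (independent genes)
  does not probe.
- Edge weights sum C-scores over subunits without expression-level
  weighting; a ligand absent from the resource, or expressed but not tested
  in a contrast, simply contributes nothing.
- The network inherits the resource's coverage and the score tables'
  universe; degree comparisons across datasets are only meaningful with a
  common resource and gene universe.

## A worked example

```{r example}
sim <- simulate_dual_contrast(n_genes = 300, seed = 42)
res <- cscore_test(sim$contrasts, seed = 1)
glance(res)
res |> tidy() |> arrange(desc(c_score)) |> head(3)
```

```{r network}
sims <- simulate_celltype_scores(n_cell_types = 3, n_genes = 120, seed = 9)
scores <- lapply(sims, `[[`, "scores")
lr <- simulate_lr_resource(scores$CT1$feature, n_pairs = 15, seed = 9)
net <- build_ccc_network(scores, lr)
glance(net)
ccc_degrees(net)
```

```{r plot, fig.width = 5, fig.height = 4}
autoplot(res)
```
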