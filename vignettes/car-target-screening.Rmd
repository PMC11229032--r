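---
title: "Screening expression data for CAR therapy targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening expression data for CAR therapy targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartarget)
```

## The problem

Chimeric antigen receptor (CAR) cells kill any cell displaying their target
antigen, so a usable target must satisfy two constraints at once: high
*coverage* (most tumor cells express it, strongly) and high *specificity*
(healthy tissues do not). Because CARs only see the cell surface, the search
space is the surfaceome — genes whose products localize to the plasma
membrane (GO:0005886). `cartarget` implements the batch workflow for this
search over bulk RNA-seq expression: tumor cohorts (TCGA-shaped), healthy
tissue baselines (GTEx-shaped), and cancer cell line panels (DepMap-shaped),
all on the transcripts-per-million (TPM) scale.

## Cohort assembly

TCGA tumors carry few adjacent-normal samples, which starves a
tumor-versus-normal test of control observations. The standard remedy,
which `build_cohort()` implements, is to pool each tumor's adjacent normals
with the GTEx samples of the matching healthy tissue(s). The tumor-to-tissue
assignment is data, not code: a two-column map
(`inst/extdata/cohort_map_default.tsv` ships a conventional pairing for the
33 TCGA tumor codes) that users should review and may edit freely. Tumors
with no clean GTEx counterpart (e.g. head-and-neck, mesothelioma) map to an
empty tissue set, meaning adjacent normals alone form the control group.

Three expression encodings are supported and tracked explicitly: linear
TPM, $\log_2(\mathrm{TPM}+1)$ (the display scale), and the UCSC Xena RSEM
encoding $\log_2(\mathrm{TPM}+0.001)$. All statistics run on linear TPM or
on $\log_2(\mathrm{TPM}+1)$ as stated below; `convert_scale()` moves
between encodings, clamping the Xena back-transform at zero (its sentinel
for zero expression decodes to $2^{-9.9658}-0.001 \approx 0$, which can be
a hair negative in floating point).

## The differential screen

For each gene of the tested universe, with tumor group $T$ and control
group $C$ in TPM:

* **Fold change**: $\mathrm{FC} = \dfrac{\mathrm{med}(T) + \varepsilon}
  {\mathrm{med}(C) + \varepsilon}$ with pseudocount $\varepsilon = 0.01$
  TPM. Medians resist the heavy right tail of expression data; the
  symmetric pseudocount keeps the ratio finite at zero medians and
  preserves the reciprocal identity
  $\mathrm{FC}(T,C) \cdot \mathrm{FC}(C,T) = 1$.
* **log2 fold change**: $\mathrm{med}(\log_2(T+1)) -
  \mathrm{med}(\log_2(C+1))$. Note this is a difference of log-scale
  medians, *not* $\log_2$ of the FC ratio; the two differ for skewed
  distributions (for even group sizes the median interpolates, and the
  pseudocount enters only the ratio form).
* **Significance**: two-sided Mann–Whitney U. The test is rank-based, hence
  identical on TPM and any monotone transform of it. We use the exact null
  distribution when the smaller group has at most 8 observations and the
  pooled data are tie-free, otherwise the tie-corrected normal
  approximation with continuity correction — with cohort sizes in the tens
  to hundreds, the approximation regime is the one that matters.
* **Multiplicity**: Benjamini–Hochberg across the *entire* tested universe
  (every membrane gene screened in the call, typically ~5000), not merely
  the genes ultimately reported — adjusting only survivors would invalidate
  the false-discovery-rate guarantee. Significance means adjusted
  $p < 0.05$.

`screen_taa()` reports the significant genes passing the fold-change
threshold: `direction = "over"` (FC at or above the threshold) finds CAR
target candidates, `direction = "under"` (FC at or below the reciprocal)
finds candidates for NOT-gate veto antigens. Rows are sorted by decreasing
$|\mathrm{log2fc}|$ with ties broken alphabetically, and volcano
coordinates are attached ($y = -\log_{10}$ adjusted $p$, with the adjusted
$p$ floored at $10^{-300}$ so the coordinate stays finite).

The companion tools reuse the same primitives: `fc_table()` tabulates a
candidate's fold change across several tumors (selectivity);
`median_profile()` gives per-cohort group medians including metastatic
samples where present; `tissue_expression()` contrasts one gene's tumor
expression against every healthy tissue (the off-tumor toxicity check),
adjusting across the tissues of that call; `skcm_compare()` runs the three
pairwise tests among metastatic / primary / control for the one cohort
(melanoma) with enough metastatic samples, adjusting across the three
p-values. Metastatic samples are excluded from every other statistic —
their group sizes are too small for inference.

## Logic gates as coverage arithmetic

Dual-antigen CARs rescue imperfect single targets: AND (both required), OR
(either suffices), NOT (second antigen vetoes), IF-BETTER (second antigen
co-stimulates). Published practice assesses these visually;
`gate_feasibility()` formalizes the judgement as explicit per-sample
coverage arithmetic so it can be computed, tested, and tuned. A
`gate_config()` holds the thresholds: a gene is *on* in a sample at
`tau_on` TPM (default 10 — roughly where bulk expression reliably implies
surface protein), *absent* below `tau_off` (default 1), a gate needs tumor
coverage `c_min` (default 0.8) and tolerates per-tissue co-coverage at most
`s_max` (default 0.05). These defaults are deliberate, conservative
choices — there is no published numeric standard — and every analysis
reports the supporting fractions alongside the boolean verdicts so users
can apply their own cutoffs.

The rules, writing $f_T(\cdot)$ for a fraction of tumor samples and
$f_{ts}(\cdot)$ for a fraction within one normal tissue:

* AND viable iff $f_T(a \ge \tau_{on} \wedge b \ge \tau_{on}) \ge c_{min}$
  and every tissue has $f_{ts}(a \ge \tau_{on} \wedge b \ge \tau_{on}) \le
  s_{max}$.
* OR viable iff the same with either-above fractions.
* NOT ($a$ activating, $b$ vetoing) viable iff
  $f_T(a \ge \tau_{on} \wedge b < \tau_{off}) \ge c_{min}$ and every
  tissue where $f_{ts}(a \ge \tau_{on}) > s_{max}$ is protected by the
  veto: $f_{ts}(b \ge \tau_{off}) \ge 1 - s_{max}$.
* IF-BETTER viable iff AND failed *only* on tumor co-coverage (its tissue
  safety held), $a$ alone covers $\ge c_{min}$ of tumor samples, and $b$
  still co-occurs in at least $c_{min}/2$ of them. The $c_{min}/2$
  co-stimulation floor is this package's reading of "the second antigen
  helps often enough to matter"; it is exposed through `c_min` rather than
  a separate knob to keep the configuration small.

AND and OR are symmetric in the gene pair; NOT and IF-BETTER read the first
gene as the activating antigen. `pair_correlation()` supplies the
supporting view: per-sample paired expression with Pearson and Spearman
correlations per group, computed on $\log_2(\mathrm{TPM}+1)$ (Pearson on
raw TPM is dominated by the top expressors). A gene constant within a group
has no defined correlation and is reported as `NA`, never coerced to zero.

## Cell line panels

`select_cell_lines()` turns a validated target into a wet-lab panel: all
cell lines (optionally within one lineage) whose expression of the gene
passes a TPM threshold, sorted by expression. The boundary convention is
`above` $\equiv$ `>=` and `below` $\equiv$ `<`, so the two directions
always partition the panel. DepMap expression ships log2(TPM+1)-encoded;
declare the scale at load time and it is decoded before filtering.

## The synthetic generator

`simulate_cohort()` draws TCGA/GTEx-shaped data from a log-normal model:
per gene a baseline $b_g \sim U(0, 8)$ on the $\log_2(\mathrm{TPM}+1)$
scale (about 1–255 TPM, the range the tools exercise), per planted
(gene, group) pair a shift of $\log_2(\mathrm{FC})$, per sample Gaussian
noise with $\sigma = 0.25$, decoded as
$\mathrm{TPM} = \max(0,\, 2^{b_g + \mathrm{shift} + \epsilon} - 1)$.
The default study conditions — 40 tumor versus 40 pooled control samples,
$\sigma = 0.25$, planted fold changes of 4–16 — mirror the scale at which
the pooled-control design is meant to operate. At $\sigma = 0$ every
sample in a (gene, group) cell is identical, so medians and log2 fold
changes recover the planted values exactly and the ratio FC matches up to
the pseudocount. `simulate_celllines()` does the same for DepMap-shaped
panels, with planted entries setting exact TPM levels.

What the generator does *not* emulate: gene–gene covariance, library-size
and batch artifacts, multimodal (subtype) expression, and the
zero-inflation of lowly expressed genes. Tests passing on this generator
therefore demonstrate the statistical machinery — calibration under the
null, recovery of planted effects, invariances — not robustness to real
TCGA/GTEx messiness; conclusions about specific genes always require the
real matrices, which users supply to the same loaders.

## Numerical and design notes

* Tie policy: the Mann–Whitney exact path is used only on tie-free pooled
  data; with ties or larger groups the tie-corrected normal approximation
  applies. All pooled values identical yields $p = 1$ directly.
* Duplicate gene rows (and symbol collisions after Ensembl-to-symbol
  mapping) keep the row with the highest total linear expression — a
  deterministic dominant-transcript rule; dropped counts are recorded as
  attributes. Unmapped genes are dropped because the downstream surfaceome
  filter is symbol-keyed.
* Output tables freeze their sort orders and the CLI formats numerics at 6
  significant digits, so reruns are byte-identical.
* The screen refuses vacuous work: an empty gene-set intersection, a
  missing control group, or a fold-change threshold $\le 1$ are errors,
  not empty results.

Default problem sizes used by the test and acceptance workloads — 6000-gene
universes, 40/40 groups, 20 generator seeds — were chosen as the smallest
sizes at which the recall/FDR and calibration properties are measured with
useful precision.

## Worked example

```{r example}
spec <- cohort_spec(
  tumor_code = "SIM", n_genes = 500, n_primary = 40,
  n_adjacent_normal = 10, tissues = c(Colon = 30),
  planted = data.frame(gene = 1:2, target = "primary_tumor", fc = 16),
  sigma = 0.25, seed = 7)
sim <- simulate_cohort(spec)
cohort <- simulated_cohort(sim)
hits <- screen_taa(cohort, sim$gene_set, fc_threshold = 15)
hits[, c("gene", "fc", "log2fc", "p_value", "adj_p")]
```

Both planted antigens are recovered with fold changes near 16
($\mathrm{log2fc} \approx 4$) and nothing else passes.
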