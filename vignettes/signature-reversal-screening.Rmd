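---
title: "Signature-reversal screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscreen)
```

orthoscreen implements an in-silico screen that looks for compounds whose
post-perturbation transcriptomic signatures *mimic* a reference
differential-expression phenotype — for example a loss-of-function contrast
for a transcription factor such as MYC — and then nominates *combinations*
of such compounds whose effects are complementary rather than redundant.
This vignette explains the statistical machinery, the parameters that
matter, and the design decisions taken where more than one defensible choice
existed.

## The concordance model

Both sides of the comparison are reduced to trinary regulation calls.
Drug signatures arrive as replicate-averaged Z-scores (L1000 Level 5-style);
a gene is called +1 when `z >= 1`, -1 when `z <= -1`, 0 otherwise
(`binarize_zscores()`, boundary inclusive). The reference is built from a
differential-expression table with the rule `|log2FC| > 1` and `p <= 0.05`
(`build_reference()`; note the *strict* fold-change inequality — the
fold-change rule belongs to the RNA-seq contrast and the Z-score rule to
the drug platform, so each keeps its own boundary convention, with an
`inclusive` flag on the reference builder to align them when desired).

With reference calls $a$ and drug calls $b$ over a shared gene universe, the
overlap is $O = \{g : a_g \neq 0 \wedge b_g \neq 0\}$, the concordant subset
$C = \{g \in O : a_g = b_g\}$, the discordant subset $D = O \setminus C$,
and

$$\mathrm{NCR} = \frac{|C| - |D|}{|A|}, \qquad A = \{g : a_g \neq 0\}.$$

NCR is $+1$ only for a drug that reproduces every reference DEG call and
$-1$ only for one that flips them all. Because real drug platforms measure
fewer genes than an RNA-seq contrast, the two universes are intersected
before scoring and $|A|$ is recomputed inside the intersection; the number
of dropped reference DEGs is reported, since it silently changes the
denominator. Gene identifiers are treated as opaque case-sensitive strings —
no alias mapping is built in.

## Permutation null and multiple testing

Significance comes from relabelling the *drug* profile's calls uniformly at
random over the gene universe, preserving its up/down counts; the reference
is never permuted. The restriction of such a relabelling to the reference
DEG positions is a simple random sample without replacement from the
profile's multiset of calls, so the four overlap counts jointly follow a
sequential hypergeometric law. The implementation samples those counts
directly (`rhyper`) rather than materialising each permuted vector — the
distributions are identical (a test compares the fast null against the
explicit shuffle, which remains available as `permute_calls()`), and the
speed-up is what makes 1000 permutations per signature practical at screen
scale. P-values use the add-one convention $p = (1 + \#\{\mathrm{NCR}_\pi
\ge \mathrm{NCR}_\mathrm{obs}\})/(1 + n_\mathrm{perm})$, which avoids exact
zeros and keeps BH correction well defined. The test is one-sided (upper
tail) by default because screening interest is concordance with the
reference; a two-sided option exists.

Each signature's permutations run in an RNG substream derived from the
screen seed and a stable hash of the signature id, so results are invariant
to column order. BH correction (`bh_adjust()`, a thin wrapper over
`stats::p.adjust`) runs across signatures within a screen; in the
pathway-restricted screen each pathway is its own family, because pooling
across pathways would couple unrelated score distributions.

## Pathway-restricted screening and method agreement

`pathway_screen()` restricts the reference to each supplied gene set
(`restrict_reference()`) and recomputes the whole screen inside it, giving
each signature a multidimensional concordance profile. Selecting the
pathway collection itself is out of scope — the sets are an input (GMT).
Pathways whose restriction contains no reference DEGs are skipped with a
message rather than scored as 0/0.

Agreement between the full-profile and pathway-restricted enrichment labels
is summarised by `compare_methods()`: the sample odds ratio $ad/bc$ of the
2×2 table (with the Haldane–Anscombe 0.5 correction when a cell is zero,
flagged in the output) and a two-sided Fisher exact p-value. The sample OR
is reported — not the conditional MLE that `fisher.test()` estimates —
because that is the convention under which such overlap ORs are usually
printed.

## Compound-level enrichment

Replicate signatures are collapsed to compound calls GSEA-style: signatures
are ranked by NCR (ties by ascending p, then id — fully deterministic), and
each compound's replicates act as the member set of an unweighted
Kolmogorov–Smirnov running sum (+1/hits at members, −1/misses elsewhere),
whose signed maximum excursion is the enrichment score; on an exact tie
between the positive and negative extremes the positive one is reported.
The null reshuffles member *positions* over the ranked list, preserving the
replicate count — the standard positional null for a ranked-list statistic.
Since that null depends only on $(N, m)$, all compounds with the same
replicate count share one null distribution, each seeded from the screen
seed and $m$, keeping results invariant to compound order. NES divides the
observed score by the mean absolute null score of matching sign (a z-score
variant is available and recorded in the output metadata). A compound is
"enriched" when NES > 0 and BH-FDR ≤ 0.05.

The pathway-method label for a compound aggregates its per-pathway
enrichment calls; the default is enrichment in *any* pathway (the most
inclusive reading; `majority` and `all` are options, and the choice used is
part of the output). The recurrence filter then requires a compound to be
enriched under *both* methods in at least `min_lines` cell lines (default
3).

## Orthogonality and the drug network

For combination nomination, replicate profiles are first aggregated per
compound by the per-gene mode of their binarized calls, with ties resolved
to 0 (no majority direction means no call — conservative and stays in the
trinary alphabet). Aggregates are computed within one cell line at the
fixed screening condition; the cell line is a parameter.

The orthogonality score of a candidate against an anchor drug is

$$\mathrm{OS} = \sqrt{\mathrm{NCR}_\mathrm{target}^2 +
 (1 - \mathrm{NCR}_\mathrm{drug})^2},$$

where $\mathrm{NCR}_\mathrm{drug}$ uses the anchor's nonzero calls as the
reference set. OS is monotone increasing in $|\mathrm{NCR}_\mathrm{target}|$
and decreasing in $\mathrm{NCR}_\mathrm{drug}$, bounded by $\sqrt{5}$: high
for a compound that matches the target phenotype through genes the anchor
does not touch.

No published threshold defines when an OS counts as "orthogonality
enrichment", so the binary profile uses an explicit, recorded criterion:
candidate itself target-enriched AND OS strictly above the anchor's 75th
percentile across candidates (`os_quantile`, configurable). The binary
anchors × candidates matrix then yields pairwise Jaccard similarities
between the anchors' partner profiles (two all-zero profiles are defined as
similarity 1, with a message). The network keeps every edge with similarity
above `edge_threshold` (default 0 — weighted greedy modularity can
down-weight weak edges without discarding them), retains isolated nodes,
and is clustered with Clauset–Newman–Moore greedy modularity maximisation
on the edge weights. Vertices are sorted lexicographically before
clustering and the agglomeration is cut explicitly at its modularity
maximum (first maximum on ties), so the partition is deterministic;
community ids are relabelled by decreasing size, ties by smallest member
id, making outputs diff-stable. Betweenness uses unweighted hops by
default (no distance convention is implied by a similarity weight); a
`1/weight` option exists.

## The synthetic-screen generator

`screen_config()` fixes the study conditions the package is tested under:
978 landmark-style genes, a 728-gene reference DEG set (half up), 10 cell
lines × 200 compounds × 3 replicate signatures at 10 µM / 24 h, planted
antagonists copying 50% of the reference DEG calls concordantly and 10%
discordantly (expected NCR ≈ 0.4), a 30% background nonzero-call rate
(roughly the mass outside ±1 of a unit normal, and shared by null
compounds so the permutation null is exercised at matched sparsity), a TAS
drawn in [0.4, 1] for planted signatures with a 10% low-TAS decoy fraction
among null compounds, and additive Gaussian noise with sd 0.05. Planted
calls get Z magnitudes uniform in [1.2, 3], beyond the binarization
boundary with margin, so noise at sd ≤ 0.1 cannot flip them;
boundary-straddling inputs are exercised separately in the threshold tests.
Every generated object is reproducible from (config, seed), and each
generator emits a truth table that downstream tests read instead of
re-deriving expectations.

What the generator does *not* emulate: probe-level deconvolution error,
the correlation structure of inferred (non-landmark) genes, batch effects,
dose–response shapes, or the uneven compound coverage of real CMAP data.
Tests passing on synthetic screens therefore demonstrate the correctness
and calibration of the statistics, not the biological validity of any
particular hit list.

## Numerical choices and problem sizes

* Add-one permutation p-values; permutation-count resolution means the
  smallest attainable p is $1/(n_\mathrm{perm}+1)$ — with few compounds and
  few permutations BH-corrected q-values cannot fall below
  $n \cdot p_{\min} / \mathrm{rank}$, which is why the default is 1000
  permutations.
* Comparisons against permutation nulls use a $10^{-12}$ tolerance so
  float rounding cannot move an observation across its own null value.
* The running sum's terminal value is asserted to return to 0 within
  $10^{-12}$; the positive/negative extreme tie-break uses a $10^{-9}$
  tolerance (far below the smallest real gap $1/(m(N-m))$ at any realistic
  list size).
* Degenerate inputs error early and informatively: an empty DEG set, a
  filter that removes every signature, a pathway with no reference DEGs, an
  anchor with no nonzero calls, a member set covering the whole ranked
  list.
* Test and verification sizes were chosen to exercise the method at the
  scale it targets while remaining desk-reproducible: the calibration check
  uses 500 independent null profiles at 1000 permutations on the
  978/728-gene configuration; planted-recovery runs the full ten-line
  default screen; the bit-exact determinism check reruns a three-line,
  60-compound bundle end to end.

## Known limitations

* NCR is unweighted: a gene just past the threshold counts as much as one
  far beyond it; rank-based connectivity scores are deliberately out of
  scope.
* TAS is consumed as given, never computed from raw replicates; GCTX/HDF5
  binary inputs are not parsed (GCT 1.3 text and a TSV dialect are).
* The pathway-method "enriched" aggregation (any/majority/all) is a
  modelling choice, not an estimated quantity; conclusions that depend on
  it should be checked under more than one setting.
* The orthogonality-enrichment criterion is a screen-internal ranking
  device; it does not model pharmacological synergy (no Bliss/Loewe).

## A small worked run

```{r example, message = FALSE}
cfg <- screen_config(n_genes = 300, n_deg = 100, n_compounds = 60,
                     n_antagonists = 3, n_line_decoys = 2, n_cell_lines = 3,
                     seed = 1)
bundle <- simulate_multi_cell_line(cfg)
sets <- split(bundle$reference$deg_set, rep(1:4, length.out = 100))
names(sets) <- paste0("PWY", 1:4)
res <- run_full_screen(lapply(bundle$screens, `[[`, "matrix"),
                       bundle$reference, sets,
                       out_dir = file.path(tempdir(), "demo"),
                       n_perm = 1000, min_lines = 3, seed = 9)
dplyr::filter(res$recurrence, passes)
```

The recurrent hits are exactly the three planted pan-line antagonists;
`res$communities`, `res$centrality` and the TSVs under the output directory
carry the network stage.
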