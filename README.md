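# orthoscreen

Transcriptomic signature-reversal screening and drug-combination nomination
in R.

Given (a) a reference differential-expression profile — typically a
loss-of-function contrast for a transcriptional driver such as MYC — and
(b) a library of drug-induced signatures (LINCS L1000-style Level 5
replicate-averaged Z-scores with compound / cell line / dose / time / TAS
metadata), `orthoscreen` answers two questions:

1. **Which compounds mimic the reference phenotype?** Each signature is
   binarized into trinary regulation calls (`|z| >= 1`) and compared with
   the binarized reference (`|log2FC| > 1`, `p <= 0.05`) through the
   Normalized Concordance Ratio

   `NCR = (|C| - |D|) / |A|`

   where `A` is the reference DEG set, `O` the genes called nonzero in
   both profiles, `C ⊆ O` the sign-concordant genes and `D = O \ C`. NCR
   ranges from −1 (full reversal of the reference would score a mimic −1;
   a perfect mimic scores +1). Significance comes from a gene-label
   permutation null (up/down counts preserved, 1000 permutations, add-one
   p-values) with Benjamini–Hochberg correction; replicate signatures are
   collapsed to compound-level calls with an unweighted KS-style enrichment
   score and a positional permutation NES/FDR, optionally restricted to
   pathway gene sets, and hits are required to recur across cell lines
   under both the full-profile and the pathway method.

2. **Which pairs of such compounds are complementary?** For an anchor drug
   and a candidate, the orthogonality score

   `OS = sqrt(NCR_target² + (1 − NCR_drug)²)`

   is high when the candidate matches the reference phenotype through
   genes the anchor does not touch. Binary orthogonality-enrichment
   profiles feed a Jaccard-similarity network over compounds, clustered
   with greedy (Clauset–Newman–Moore) modularity maximisation, with
   betweenness/degree centrality and mechanism-of-action summaries per
   community.

A synthetic-screen generator (`screen_config()`, `simulate_reference()`,
`simulate_drug_matrix()`, `simulate_multi_cell_line()`,
`simulate_orthogonal_pair()`) plants antagonists, decoys, orthogonal pairs
and community blocks with known ground truth, so the entire pipeline is
testable without external downloads. I/O covers GCT 1.3 text, a TSV dialect
with sidecar metadata, reference-profile TSV and GMT.

## Worked example

```r
library(orthoscreen)

cfg <- screen_config(n_genes = 300, n_deg = 100, n_compounds = 60,
                     n_antagonists = 3, n_line_decoys = 2, n_cell_lines = 3,
                     seed = 1)
bundle <- simulate_multi_cell_line(cfg)
sets <- split(bundle$reference$deg_set, rep(1:4, length.out = 100))
names(sets) <- paste0("PWY", 1:4)

res <- run_full_screen(lapply(bundle$screens, `[[`, "matrix"),
                       bundle$reference, sets, out_dir = "demo",
                       n_perm = 1000, min_lines = 3, seed = 9)
dplyr::filter(res$recurrence, passes)
#> # A tibble: 3 × 4
#>   compound_id cell_lines_enriched n_enriched passes
#>   <chr>       <list>                   <int> <lgl>
#> 1 cmpd001     <chr [3]>                    3 TRUE
#> 2 cmpd002     <chr [3]>                    3 TRUE
#> 3 cmpd003     <chr [3]>                    3 TRUE
```

The three recurrent hits are exactly the three planted pan-line
antagonists; the two one-line decoys are rejected by the recurrence filter.
Per-line screen summaries are a `glance()` away:

```r
glance(res$per_line$CL1$concordance)
#> # A tibble: 1 × 6
#>   n_signatures n_ref_deg n_genes n_perm n_significant concordance_rate
#>          <int>     <int>   <int>  <dbl>         <int>            <dbl>
#> 1          162       100     300   1000            10           0.0617
```

`n_significant` counts signatures with NCR > 0 and FDR ≤ 0.05; the
concordance rate is their fraction of all screened signatures. The network
stage lands in `res$communities`, `res$centrality` and `res$network`
(igraph), with `plot_drug_network()` and `autoplot()` for figures, and every
stage table is written under `out_dir` as TSV with a config-hash/seed
header plus a `manifest.json`.

See `vignette("signature-reversal-screening")` for the model, the
permutation-null implementation, parameter defaults and design decisions.

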