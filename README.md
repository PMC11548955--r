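# omiclink

Mining associated gene–metabolite pairs from short longitudinal
transcriptome + metabolome studies.

## Who this is for

You profiled a tissue, culture or cohort at a handful of time points with
both RNA-seq (or any expression platform) and metabolomics, you care about
one metabolite, and you want a ranked list of candidate genes behind its
accumulation. Plain correlation handles this badly: transcription leads
metabolite accumulation by one or more sampling steps, and biological
systems are nonlinear, so the causal gene can correlate near zero with its
own product while hundreds of bystanders ride the shared developmental
trend. `omiclink` brings the time-series causality toolbox to this problem
and condenses it into one interpretable ranking.

## What it computes

For every gene *g* against the chosen target metabolite *m*:

1. **An association score** by one of seven estimators — Pearson, Spearman,
   cross-correlation function (lag-scanned Pearson), Granger causality
   (nested-OLS F-test, score = 1 − p), canonical correlation over a lag
   matrix, dynamic time warping similarity, or convergent cross-mapping
   (CCM). CCM treats the pair as a dynamical system: if *g* drives *m*,
   the delay embedding (shadow manifold) of *m* can reconstruct *g*, with
   skill ρ that *converges* (grows) as the library of embedded points
   expands.
2. **A fold change** f = log2 of the gene's normalized mean expression at
   the metabolite's **peak** time point versus the next sampled (decline)
   point, with median-of-ratios size factors and a pseudocount.
3. **The CAT score** — after min–max normalization across genes of the
   clamped score s and |f|, the vector magnitude √(s² + f²) ∈ [0, √2] —
   plus an optional rule-based annotation bonus (defaults: enzymes +0.2,
   unknown function +0.1). Genes sort by the final score; the top 100 are
   also emitted as a plain-text payload for downstream review, and a
   thresholded sub-list keeps genes with raw s ≥ 0.5 and |f| ≥ 1.

A Pearson network (|r| ≥ 0.8) among the metabolites, restricted to the
target's connected component, is written alongside.

Everything runs offline; a seeded synthetic-data module generates studies
with planted driver genes (negative-binomial counts, log-normal depth
factors, lagged saturating metabolite response) so the whole pipeline is
testable without any external data.

## Worked example

The package ships a small generated study (30 genes × 9 time points × 2
replicates, one planted driver, `inst/extdata/example/`):

```r
library(omiclink)
exdir <- system.file("extdata", "example", package = "omiclink")
cfg <- pipeline_config(target_metabolite = "target_met", method = "ccm",
                       max_lag = 1, seed = 7)
res <- run_pipeline(file.path(exdir, "expression.csv"),
                    file.path(exdir, "metabolites.csv"), cfg,
                    annotation = file.path(exdir, "annotation.tsv"),
                    outdir = tempfile())
head(res$ranking, 5)
```

```
  rank gene_id score best_lag log2fc cat_score bonus final_score
1    1    g001 0.930        1  2.021     1.380   0.2       1.580
2    2    g003 0.110        1  2.123     1.007   0.2       1.207
3    3    g028 0.807        1  1.309     1.060   0.0       1.060
4    4    g013 0.902        0 -0.201     0.973   0.0       0.973
5    5    g002 0.589        1 -0.467     0.666   0.2       0.866
```

The planted driver `g001` ranks first: its CCM score of 0.93 at lag 1 says
the metabolite's trajectory encodes the gene's history one sampling step
back, and its log2 FC of 2.02 says the gene drops ~4-fold right after the
metabolite's peak (time point 6 → 7) — exactly the shut-off signature of a
biosynthetic gene. `g013` correlates well but shows no expression change
around the peak; `g003` changes but barely associates; neither composite
beats the driver. The run directory also receives `ranked_table.csv`,
`network_edges.tsv`, `agent_payload.json`, `manifest.json` (config echo,
input hashes, warnings, timings) and four PNG plots.

Command-line equivalents:

```sh
Rscript inst/cli/omiclink.R simulate --outdir study --genes 100 --timepoints 13 --seed 1
Rscript inst/cli/omiclink.R run --expression study/expression.csv \
    --metabolites study/metabolites.csv --target target_met \
    --method ccm --lag 1 --outdir results
```

## Documentation

`vignettes/gene-metabolite-association.Rmd` describes the model and its
assumptions, every tunable parameter, what the synthetic generator does and
does not emulate, numerical edge-case policies, and known limitations.
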