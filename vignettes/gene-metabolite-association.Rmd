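---
title: "Mining gene–metabolite associations from short time courses"
author: "omiclink maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene–metabolite associations from short time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiclink)
```

## The problem

Longitudinal multi-omics designs — a transcriptome and a metabolome profiled
over the same handful of time points — are the natural setting for asking
*which gene drives the accumulation of this metabolite?* Plain correlation
answers a different question: it is blind to the lag between transcription
and metabolite accumulation, and it mistakes shared developmental trends for
mechanism. `omiclink` scores every gene against one user-chosen target
metabolite with a panel of seven estimators spanning linear/nonlinear and
lag-blind/lag-aware behavior, then folds the association together with the
gene's expression change around the metabolite's peak into a single
heuristic ranking statistic (the CAT score).

The package operates on two features × samples matrices (counts or
normalized intensities) whose samples are labeled by time point and
replicate, plus an optional free-text functional annotation table.

## Pipeline model

1. **Alignment and normalization.** Both matrices are restricted to their
   shared time points (≥ 3 required). Expression counts are depth-corrected
   with median-of-ratios size factors — sample $j$ gets
   $s_j = \mathrm{median}_{g \in \mathcal{R}}\; c_{gj} / (\prod_k c_{gk})^{1/m}$
   over the reference set $\mathcal{R}$ of genes positive in every sample —
   then replicates are averaged within each time point. In count mode the
   association estimators see $\log(1 + \bar c_{gt})$: correlation and
   state-space methods behave badly on the heavy right skew of raw counts
   (a 20-fold-induced gene's series is otherwise dominated by its two or
   three peak samples). Metabolite intensities are replicate-averaged as-is
   (there is no library-depth concept for them) and missing cells are
   linearly interpolated over the time index, up to one third missing.

2. **Association.** Each estimator maps the pair (gene series $x$, target
   series $y$) to a score:
   * *pearson*, *spearman* — the classical coefficients, lag-blind,
     in $[-1, 1]$.
   * *ccf* — Pearson between $x_{t-\ell}$ and $y_t$ scanned over
     $\ell = 0..L$ (the gene may only lead); the score is the value of
     maximal magnitude, smallest lag on ties.
   * *granger* — nested OLS: does adding $x_{t-1..t-p}$ to an AR($p$)
     model of $y$ reduce the residual sum of squares (block F-test)?
     The order $p$ is chosen by AIC over $1..L$; score $= 1 - p$-value.
   * *cca* — first canonical correlation between $y_t$ and the lag matrix
     $(x_t, \dots, x_{t-L})$, which for a univariate response is the
     multiple correlation coefficient, in $[0, 1]$.
   * *dtw* — dynamic time warping on z-normalized series, local cost
     $|x_i - y_j|$, steps $(1,0), (0,1), (1,1)$; distance $D$ mapped to
     $1/(1 + D/T) \in (0, 1]$.
   * *ccm* — convergent cross-mapping. If the gene drives the metabolite,
     the metabolite's delay embedding
     $(y_t, y_{t-\tau}, \dots, y_{t-(E-1)\tau})$ contains the gene's
     history, so the gene can be *reconstructed* from the metabolite's
     shadow manifold: each anchor's $E+1$ nearest library neighbors predict
     $x$ with exponential distance weights $w_i = e^{-d_i/d_1}$, and the
     skill $\rho(\Lambda)$ is the Pearson correlation between $x$ and its
     reconstruction. The score is $\rho$ at the largest library for the
     best lag; the convergence delta
     $\Delta\rho = \rho(\Lambda_{max}) - \rho(\Lambda_{min})$ should be
     positive for a genuine causal direction.

3. **Ranking.** The target's peak time point is its argmax (first index on
   ties); the decline point is the next sampled point. If the maximum sits
   at the final point — so no decline point exists — the peak shifts back
   to the latest interior local maximum, or to the penultimate point, with
   a warning. Each gene's $\log_2$ fold change between the two time points
   is computed on pseudocounted normalized means,
   $f_g = \log_2\frac{\bar c_{g,\mathrm{peak}} + pc}{\bar c_{g,\mathrm{decline}} + pc}$.
   Association scores (clamped at 0 from below) and $|f_g|$ are min–max
   normalized across genes and combined as
   $\mathrm{CAT}_g = \sqrt{s_{norm}^2 + f_{norm}^2} \in [0, \sqrt 2]$.
   A rule-based annotation bonus (first matching regex wins; default 0.2
   for enzyme-like descriptions, 0.1 for unknown-function ones) is added,
   and genes sort by the final score. The top 100 genes are emitted as a
   plain-text payload for any downstream reviewing hook; a filtered
   sub-list applies the raw thresholds (association ≥ 0.5 and
   $|f| \geq 1$, i.e. 2-fold, by default).

4. **Context.** A Pearson correlation network among the
   replicate-averaged metabolite series ($|r| \geq 0.8$ by default,
   restricted to the target's connected component) situates the target
   among co-accumulating compounds.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_lag` (L) | 1 | candidate lead of the gene, in sampling steps; lag-aware methods scan $0..L$ |
| `embedding_dim` (E) | 2 | CCM shadow-manifold dimension; 7–13 time points cannot support more |
| `embedding_delay` (tau) | 1 | embedding stride in sampling steps |
| `pseudocount` | 1 | guards zero counts in the fold change |
| `assoc_threshold` | 0.5 | raw-score filter for the thresholded sub-list |
| `fc_threshold` | 1 | raw $|\log_2$ FC$|$ filter (2-fold) |
| `top_n_agent` | 100 | size of the reviewing payload |

CCM's library schedule is the set of contiguous anchor prefixes from
$E + 2$ up to all anchors, in steps of 1; for long benchmark series the
step-1 schedule is thinned to at most 40 evenly spaced sizes (the minimum
and maximum are always kept, so the reported score and $\Delta\rho$ are
unaffected). The prediction set stays fixed while the library grows; this
is what makes $\Delta\rho$ a clean diagnostic — evaluating skill on the
library itself would drive $\rho(\Lambda_{min})$ toward $-1$ even for
unrelated series, because leave-one-out prediction from $k$ of only
$k+1$ anchors is forced to average nearly everything.

## Numerical choices and degenerate inputs

* z-normalization uses the population ($1/T$) standard deviation: the
  scale cancels in every downstream use and the $T-1$ form degenerates at
  tiny $T$. Constant series z-map to zeros and carry a flag.
* Constant gene or target series never error inside the scan: the gene is
  retained with score 0 and a `degenerate` flag.
* Ties break identically everywhere: smallest lag, then first index, and
  gene id as the final ranking tie-break, so reruns are byte-identical.
* A rank-deficient CCA lag matrix is ridge-regularized with
  $\lambda = 10^{-8}\,\mathrm{tr}(X^\top X)$ and a warning.
* Min–max of an all-equal vector returns zeros with a warning rather than
  dividing by zero; a singleton behaves the same way.
* The missing-data limit for metabolite series is one third (inclusive);
  interpolation needs a genuinely observed majority.
* The fold change enters the CAT vector as $|\log_2 \mathrm{FC}|$ — both
  induction and shut-off after the peak are signals — and the sign is
  reported in the output table. Negative associations are clamped to 0
  before normalization (anticorrelation is surfaced in diagnostics, not
  rewarded by a magnitude built for strength of association); setting
  `negative_mode = TRUE` uses $|s|$ instead for anticorrelation mining.

## What the synthetic generator emulates — and what it does not

`gen_synthetic_study()` is a first-class module, not a test fixture. It
emulates the data regime the pipeline targets:

* short designs: $T$ time points ($5..40$, default 13) with $R$ replicates
  (default 3);
* counts: negative-binomial with fixed dispersion 0.1 (typical RNA-seq
  overdispersion) around $\mathrm{depth}_j \cdot e^{\mathrm{latent}_g(t)}$,
  depth factors log-normal with $\sigma = 0.25$;
* drivers: a single logistic pulse (sharp induction, short plateau,
  shut-off — the canonical profile of a strongly induced biosynthetic
  gene), swinging $3 \times \mathrm{effect}$ natural-log units
  (a ~20-fold induction at the default effect 1);
* decoy genes: smooth low-order Fourier trajectories whose amplitude is
  exponentially distributed (median ≈ 0.3 natural-log units — most genes
  vary mildly, a few strongly) plus per-time biological noise;
* the target metabolite: a saturating Michaelis–Menten-style response
  ($K = 0.7$, below full saturation) to the lag-$\ell$ driver sum, with
  Gaussian noise at 5% of the dynamic range, floored at 0;
* decoy metabolites correlated with the target at strengths spanning
  0.95 to 0, for network tests.

It does **not** emulate LC–MS peak shapes, structured missingness, batch
effects, or correlated gene modules. That last omission matters for
interpreting green tests: real transcriptomes contain whole co-regulated
modules that track the metabolite as tightly as the true driver, so
planted-driver recovery here bounds what the ranking can do under
*independent* decoys, not under collinear ones.

A second, harder caveat is sample size. Cross-map skill is a correlation
computed over roughly $T - (E-1)\tau$ anchors. At $T = 13$ that is 12
numbers: under the null, chance alone puts a per-gene probability of
roughly 5% on $\rho \geq 0.5$, so among 100 independent null genes the
*maximum* score essentially always exceeds 0.5. A high CCM score for one
gene at desk-scale $T$ is a candidate, never a conclusion; the convergence
delta, the cross-method comparison, and the fold-change component exist
precisely to temper that. The package's own specificity stress test (no
drivers planted, demanding that *no* gene of 100 passes 0.5 in 90% of
runs) is deliberately kept failing as a statement of this limit rather
than being papered over with a laxer threshold.

## Design choices that were genuinely open

* **Sample labeling.** Nothing upstream fixes a sample-name format; the
  default header grammar is `<time>_r<replicate>`, with an explicit design
  table as the alternative. Time labels order by their embedded number
  ("T10" after "T9"), never lexically.
* **Replicate handling.** Replicates (or donors) are averaged per time
  point *before* association; per-replicate modeling is out of scope.
* **CCM orientation.** The gene→metabolite causality score embeds the
  *effect* (metabolite) and reconstructs the *cause* (gene) — the standard
  cross-mapping convention.
* **Granger order.** Chosen by AIC of the unrestricted fit over $1..L$,
  falling back to order 1 with a message when the series is too short.
* **Global lag.** One `max_lag` is passed to every lag-aware method and
  consumed per-method (scan for ccf/ccm, order bound for granger, lag-matrix
  width for cca); lag-blind methods ignore it.
* **Min–max scope.** Normalization is per metric across genes (score and
  |FC| separately), not joint.
* **Thresholds.** The fold-change filter applies to the *raw*
  $|\log_2 \mathrm{FC}| \geq 1$; a min–max-normalized value cannot
  meaningfully be thresholded at 1.
* **The reviewing hook.** The package builds the exact top-100 payload as
  plain text/JSON and accepts any downstream consumer; no network calls
  anywhere in core or tests.

## Worked example

```{r example, eval = FALSE}
library(omiclink)

exdir <- system.file("extdata", "example", package = "omiclink")
cfg <- pipeline_config(target_metabolite = "target_met", method = "ccm",
                       max_lag = 1, seed = 7)
res <- run_pipeline(file.path(exdir, "expression.csv"),
                    file.path(exdir, "metabolites.csv"), cfg,
                    annotation = file.path(exdir, "annotation.tsv"),
                    outdir = tempfile())
head(res$ranking)
```

The bundled study (30 genes, 9 time points, 2 replicates, seed 42) plants
one driver gene; the pipeline ranks it first with a CCM score of 0.93 and
a peak-to-decline $\log_2$ FC of 2.02 (see the README for the printed
table). Everything the run produced — ranked table, network edge list,
agent payload, manifest, plots — lands in `outdir`.

## Known limitations

* Estimator power at $T < 10$ is limited for every lag-aware method;
  Granger in particular needs $T \geq 3p + 3$ for order $p$.
* One gene versus one metabolite: multivariate causality (gene sets acting
  jointly) is a non-goal.
* The annotation bonus is a regex heuristic over free text; it knows
  nothing about EC hierarchy or orthology confidence.
* CCM significance via surrogate series is not implemented; the
  convergence delta is the only built-in specificity aid.
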