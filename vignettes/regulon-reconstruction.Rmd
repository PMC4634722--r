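---
title: "Reconstructing a transcription-factor regulon from ChIP binding and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a transcription-factor regulon from ChIP binding and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

## The inference problem

Global transcription factors of the FNR/FnrL family switch large parts of a
bacterium's transcriptome between aerobic and anaerobic programmes. Two
genome-wide measurements constrain their regulon: ChIP enrichment tells us
*where* the factor binds, and wild-type versus deletion-mutant RNA
profiling tells us *which* genes respond. Neither alone identifies direct
targets — binding without response happens (silent sites), and response
without binding is the signature of downstream regulatory cascades.
`regulonscan` fuses the two into an exhaustive, mutually exclusive
partition of the genes:

* **direct** — at least one called ChIP peak assigned to the gene *and* a
  significant expression change;
* **scan_candidate** — no peak, but a genome-scan motif hit assigned by
  the same geometric rule, plus a significant change. ChIP crosslinking is
  known to miss bound sites, so sequence evidence can rescue likely direct
  targets; they are kept as a category of their own (a compatibility
  switch folds them into `indirect` for file-level comparison with studies
  that do so);
* **indirect** — a significant change with no binding evidence;
* **none** — everything else, including genes under a peak that do not
  respond. Peaks whose assigned genes all fall in this class are flagged
  *silent* rather than discarded: they may act under untested conditions.

Every stage of the pipeline — simulation, peak calling, motif model,
genome scan, differential expression, integration, cross-species
comparison — is an exported function; `run_regulon_pipeline()` chains them
under one configuration and one seed.

## Geometry: assigning a genomic position to genes

All assignment logic keys on a single anchor point: the peak **summit**
(or a motif-site centre), never the peak edges. A summit inside a gene
body makes the peak *intragenic*; its host gene is the target, and if the
next same-strand gene starts within `operon_gap` (default 100 bp) of the
summit, that downstream gene is added — the operon read-through case where
a site inside one cistron controls the next. Any other summit is
*intergenic*; every gene whose start *faces* it within
`max_upstream_dist` (default 600 bp) is a target. Facing is strand-aware:
a `+` gene faces positions upstream (left) of its start, a `-` gene faces
positions beyond its right end. An intergenic summit between two
divergently transcribed genes therefore targets both — the classic shared
promoter of head-to-head pairs. Intergenic summits facing no start in
range stay in the intergenic tally as orphans. Distances wrap across the
origin on circular genomes; genes annotated across the origin itself are
rejected at parse, a deliberate simplification that the synthetic
generator honours.

"Promoter region" is operationalised as "summit in intergenic space": the
two notions are deliberately conflated in the enrichment test, whose
baseline is the genome's intergenic fraction. The test itself is a
one-degree-of-freedom goodness of fit,
$\chi^2 = \sum (O - E)^2 / E$ over the intergenic/genic split with
$E_\text{intergenic} = n f$, and it is cross-checked in the test suite
against `stats::chisq.test()`.

Internally all coordinates are 1-based inclusive — the native convention
of the R/Bioconductor interval stack this package sits on (IRanges,
GenomicRanges, rtracklayer). BED input and output convert to and from
0-based half-open form at the boundary, and the conversion helpers are
round-trip tested.

## The simplified peak caller

The caller consumes per-base IP and input coverage directly rather than
reads. Input is scaled to the IP total; the genome is tiled with
non-overlapping windows (default 50 bp) and each window's IP sum is tested
against a Poisson upper tail with rate
$\lambda = \max(\lambda_\text{genome}, \lambda_\text{local})$, the local
rate estimated from scaled input over `local_window` (default 5 kb)
centred on — and excluding — the tested window. Excluding the window
itself keeps a real binding signal from inflating its own background.
Benjamini–Hochberg runs over *all* tested windows (not merged peaks, so
the FDR statement applies at the tested unit); windows passing
`peak_fdr` merge when adjacent. The summit is the argmax of the smoothed
IP-minus-input difference within the merged interval, leftmost on ties.
The smoothing width (default 201 bp, about a sonicated-fragment length)
matters: coverage over a bound site is a plateau the width of the
fragment, and a moving average of comparable width turns that plateau
into a tent whose apex sits at the binding position. Enrichment is
reported as $(\text{IP}_s + 1)/(\text{input}_s + 1)$ at the summit.

Two caller properties are enforced by tests: on background-only coverage
the expected fraction of flagged windows stays at or below `peak_fdr`,
and raising the threshold never removes a peak.

## The motif model

`build_pwm()` counts letters per column over aligned sites; frequencies
are $(c + p)/(n + 4p)$ with pseudocount $p$ (default 0.5). The degenerate
consensus renders a column as one letter when its top *raw* frequency
reaches `invariant_thresh` (0.99), as the descending-frequency set of
letters at or above `include_thresh` (0.20) otherwise, and as N when the
set is uninformative; runs of N collapse in the formatted string, giving
the familiar `(T/C/A)TGA-N6-TCAA` style for FNR-family sites. Scanning
scores each window as $\sum_j \log_2 f_j(b)/q(b)$ on both strands, with
wraparound windows on circular genomes; windows containing N score
$-\infty$ and are never reported. The background $q$ defaults to the
genome's mononucleotide composition rather than uniform — on a 66 % GC
genome a uniform background systematically inflates AT-rich motif scores.
The scanner is verified base-for-base against brute-force enumeration.

Motif discovery is a one-occurrence-per-sequence Gibbs sampler of fixed
width: positions are resampled from the predictive distribution under the
model built from the other sequences, the best restart by total
information content is polished by deterministic argmax passes, and
whole-alignment phase shifts of up to three columns are attempted — the
standard cure for the sampler's habit of converging one base off frame.
Exact information-content ties canonicalise to the lowest offset. Peak
regions are extracted as ±2 motif widths around the summit: the caller
locates summits only to within a few tens of bp, and a ±1-width window
would frequently truncate the site, leaving the finder to align
background. Because planted (and real) sites sit on either strand, the
pipeline runs the finder with two-strand window scoring.

## The differential-expression stand-in

The count test is intentionally minimal and clearly labelled a stand-in:
the pipeline prefers an externally supplied DEG table with the same
schema whenever one is given. Counts are normalised by joint
median-of-ratios size factors; per-gene dispersion is the pooled
within-group method of moments floored at $10^{-8}$; the Wald statistic
divides the log ratio of group means (with a 0.5 pseudo-mean) by its
delta-method standard error $\sqrt{\sum_g (1/\mu_g + \alpha)/n_g}$.

The reference distribution was the one genuinely open choice. With three
replicates the dispersion estimate carries four residual degrees of
freedom, and simulation shows the normal reference inflates the null
rejection rate to about 0.10 at $\alpha = 0.05$, while a $t_4$ reference
over-corrects to 0.04 and costs about nine points of power at the planted
effect sizes. A $t$ reference with $2(n_1 + n_2 - 2)$ degrees of freedom
splits the difference — the mean-driven part of the variance is not
estimated from the residuals, so the effective information exceeds the
residual degrees of freedom — and lands at a null rate of about 0.07 with
most of the power retained. The suite checks this calibration directly.
Significance defaults to the *raw* p-value at `alpha_deg` = 0.05 (the
adjusted column is always emitted): regulon studies in this family filter
on raw p ≤ 0.05 to stay comparable across species, and the default
follows that practice. Note two documented approximations: scaling one
library is absorbed by the size factors only up to the global scale of
the normalised counts, so p-values are nearly but not bit-exactly
invariant; and swapping the group labels is exactly antisymmetric.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions the acceptance checks
run under: a 1 Mb circular chromosome at 66 % GC; 900 genes with
lognormal length variation around 1 kb packed to a 9.19 % intergenic
fraction (the gene density of a compact bacterial genome, with at least
one divergent pair by construction); 20 intergenic, 8 intragenic and 6
silent planted 14-bp sites sampled column-wise from an FNR-style model
(invariant TG/CA core, degenerate first position); 120 indirect genes;
ChIP coverage at background depth 20 with 10–30× plateau enrichment over
a 200 bp fragment; and three replicates per condition of
negative-binomial counts (dispersion 0.1, lognormal(4, 1) base means,
library factors in 0.7–1.3) with planted $|\log_2 FC| \in [1.5, 3.5]$,
activation on 60 % of planted genes. The 1 Mb scale keeps a full run in
seconds while preserving realistic gene/gap geometry; gene count and
genome length scale together so gap widths match real promoters.

Truth bookkeeping uses the same geometric rule as the classifier, so
recovery scores measure peak calling and expression testing, not a
definition mismatch. Silent sites are placed more than
`2 * max_upstream_dist` from every gene start and never inside a gene
targeted by a productive site — otherwise they would not be silent by
construction.

What the generator does *not* emulate, and what passing tests therefore
do not certify on real data: read-level noise (alignment, duplicates,
mappability), operonic covariance between counts, cascade structure
behind indirect regulation (indirect genes are planted directly),
sequence composition heterogeneity, and condition-dependent binding. The
planted-recovery property (median precision and recall ≥ 0.9 over 20
seeds, ≥ 90 % of silent sites non-productive) is a correctness floor for
the machinery, not a sensitivity claim for any real experiment.

## Cross-species comparison

Orthologue maps are consumed, never computed; many-to-many rows are
dropped (with a count) because per-gene congruence needs unambiguous
pairs. For each one-to-one pair with at least one significant side the
congruence class follows the sign table — convergently activated,
convergently repressed, divergent, or unique to one species — and the
summary satisfies `common = conv_act + conv_rep + divergent` by
construction. A gene absent from one species' table is simply
not-significant there; absence of evidence and evidence of absence
collapse deliberately. Common peak positions require both orthologues to
carry peak evidence in the same orientation class (upstream promoter
versus inside the coding region); a relaxed mode reports
orientation-mismatched pairs flagged, for sensitivity analysis, since
"same position relative to a common downstream gene" has no canonical
formalisation. The three-species report intersects two maps anchored on
one species and keeps triples that are direct with one regulation sign
everywhere.

## Numerical and degenerate-input choices

* Peak-caller trailing bases shorter than one window are untested;
  circular local background wraps, but peaks are not merged across the
  origin (rare and harmless at desk scale).
* All-zero count rows report p = 1; a significant gene with exactly zero
  fold change (practically impossible) gets regulation `none` and a log
  message.
* `scan_score_thresh` (default 8 bits) is an honest tuning knob: the
  number of genome-scan hits — and with it the scan-candidate count — is
  sensitive to it, and no principled value reproduces any particular
  published count, so it is configuration, not science.
* Stage seeds are salted with the stage name, so inserting a stage never
  perturbs the random stream of another; reruns with one seed are
  byte-identical.
* Headline counts (how many direct genes, how many silent peaks) depend
  on `max_upstream_dist` and `operon_gap`; the defaults are field-typical
  but any comparison across datasets must hold them fixed.

## A worked run

```{r run, eval = FALSE}
cfg <- analysis_config(seed = 7)
run <- run_regulon_pipeline(cfg)
run
evaluate_recovery(run)
```

On this seed the run calls 33 peaks (27 productive, 6 silent), finds 223
significant genes partitioned into 31 direct, 113 scan candidates and 79
indirect, rediscovers the planted motif's invariant core, and recovers
the planted direct set with precision 1.00 and recall 0.94; all six
planted silent sites are called as peaks and flagged non-productive. The
curated FnrL site table shipped with the package
(`fnrl_example_sites()`) exercises the motif stack on real sequences:

```{r sites, eval = FALSE}
sites <- fnrl_example_sites()
pwm <- build_pwm(sites$recognition_sequence, pseudocount = 0)
format(consensus_string(pwm, invariant_thresh = 0.99,
                        include_thresh = 0.20))
```

## Known limitations

The peak caller has no fragment-shift estimation, duplicate handling or
control-free mode; the DE stand-in has no dispersion shrinkage, GLM
covariates or independent filtering; motif discovery is fixed-width with
no ZOOPS/ANR model selection or E-value calibration; orthology and COG
assignments are inputs. Each of these is the point where a production
analysis would substitute the field's dedicated tool — the package's
contribution is the integration logic and the testable end-to-end
harness around it.
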