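---
title: "Models and methods behind seedcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedcoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seedcoex analyses temporal gene expression in developing seed across a
diversity panel: a panel of inbred lines sampled repeatedly through grain
fill (days after anthesis, DAA) with 3' tag RNA-seq, genotyped with
markers, and phenotyped for mature-seed metabolites. This vignette explains
the models each stage fits, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable construction existed.

## The study design and the synthetic generator

The default `study_design()` is 22 lines x 6 sampling times (8, 13, 18,
23, 28, 33 DAA) x 2 locations x 2 replicates — 528 potential samples — with
a default missing fraction of 109/528, emulating field losses. Sample drops
are uniform at random; real losses have field causes (plot failures,
insufficient seed) that are not modelled.

`simulate_counts()` draws tag counts from a negative binomial whose log2
mean is built from four parts:

* a per-transcript baseline, uniform on log2 counts 4–8;
* a **temporal pattern code**: a string over `{u, d, 0}` with one character
  per adjacent time interval; each `u`/`d` moves the log2 mean by
  `step_log2` (default 1.0) cumulatively, `0` leaves it flat;
* a **per-line offset** shared within a genetic module: the module's line
  values are multivariate normal with covariance the kinship `K`, scaled so
  the genetic fraction of the offset variance equals the module
  heritability (`line_sd` 0.5 log2 units total by default, `h2` drawn in
  0.6–0.9);
* one **latent batch factor** loading on a random 30% of transcripts with
  N(0, 1) loadings, standing in for the unexplained sample-cluster split
  that global QC must detect; its magnitude is configurable because
  nothing constrains it a priori.

Dispersions are log-uniform on [0.01, 1] — the paper-scale range for tag
counts — and per-sample depth factors are log-uniform in `depth_range`.
All randomness flows from one integer seed; regeneration is byte-identical.

`simulate_markers()` draws biallelic dosages; with `n_families > 1` and
`fst > 0` family allele frequencies drift by a Balding–Nichols model. This
matters: with one observation per line, the additive variance of a
line-level score is identifiable only through off-diagonal structure in
`K`. A GRM built from unrelated lines is nearly diagonal and leaves the
genetic and residual variances almost confounded; the package's
parameter-recovery exercises therefore use family-structured panels
(e.g. 100 lines in 20 families for the heritability recovery run, 22 lines
in 6 families elsewhere), and `estimate_h2()` resolves flat likelihoods
toward zero genetic variance rather than letting ties drift to one.

Metabolites are measured once per line x location x replicate; a linked
metabolite is `beta` times its module's per-line score plus a location
effect, a replicate-within-location block effect, a location-by-line
interaction and a plot residual, each with a stated variance.

What the generator does **not** emulate: read-level artefacts (mapping,
positional bias), transcript-length effects (3' tag counts are length-free
by design), correlated dispersion across co-expressed transcripts,
non-random missingness, and genotype-by-environment interaction in
expression. Passing tests demonstrate that the pipeline recovers structure
it is designed to detect under its own model; they do not certify
performance on real data whose violations of that model are unknown.

## Quality control

Samples are filtered first (column sum below `min_mapped`, default 5e5),
then transcripts. The published transcript filter — removing those "with
less than two mapped reads in at least ten samples" — is grammatically
ambiguous; the adopted reading **retains transcripts with >= 2 reads in
>= 10 samples**, the standard expression filter, with the literal
complementary reading behind `literal = TRUE`.

Size factors are plain median-of-ratios: the median over reference
transcripts (positive geometric mean across samples) of the count-to-
geometric-mean ratio. Variance stabilisation is the shifted log,
`log2(count/sf + 1)`: downstream stages use the matrix only through
variance ranking, linear models and PCA, for which the shifted log is an
accepted stabiliser; the dispersion-trend-based VST curve is not
reproduced. Note that median-of-ratios assumes a stable majority of
transcripts; compositionally extreme simulations (every transcript
strongly changing in one direction) bias it, which is a property of the
estimator, not an artefact of this implementation.

Sample PCA uses the `top_n` (default 500) highest-variance transcripts,
centred but not scaled. The outlier-cluster step codifies what was
originally a visual call: 2-means on PC1–PC2 with deterministic initial
centres (the two most distant samples). A split is accepted only when the
minor group holds at least `min_minor_fraction` (default 0.05) of samples
**and** the centres are separated by more than `min_separation` (default
3) pooled within-cluster standard deviations. The separation rule is
essential: 2-means cuts even a unimodal cloud roughly in half, so a
minimum-minor-size rule alone would discard half of perfectly homogeneous
data.

## Differential expression

Each transcript is modelled as NB with a log link, log size factors as
offsets, and a fixed per-transcript dispersion.

**Dispersion estimation.** The per-transcript estimate maximises the
Cox–Reid adjusted profile likelihood given the design's replicate cells;
the adjustment (`-0.5 * sum(log W_c)` over cell weight sums) compensates
the degrees of freedom spent on cell means. A gamma-GLM trend
`alpha(mu) = a0 + a1/mu` is fitted across transcripts, and estimates are
shrunk toward it on the log scale with an adaptive empirical-Bayes weight
— the ratio of the estimated population spread of true dispersions around
the trend to the total spread (population + sampling, the latter
approximated by `2/df`). Equal-weight shrinkage was tried first and
rejected: when true dispersions genuinely vary over decades, halving the
log-distance to the trend systematically understates large dispersions and
the interaction LRT's null rejection rate rose several-fold above nominal.
Raw estimates far above the trend (1.5 robust SDs on the log scale) are
dispersion outliers and are not shrunk. Everything is floored at 1e-8.
There is no independent filtering or count-outlier replacement.

**Interaction screen.** Per transcript, the LRT of
`~ genotype + time + genotype:time` against `~ genotype + time`, referred
to chi-squared with df equal to the realised rank difference of the two
design matrices (the nominal `(G-1)(T-1)` when every genotype x time cell
is observed). Transcripts significant at BH-FDR 0.1 are removed before
pattern analysis: the global pattern code assumes a temporal profile shared
across genotypes.

**Adjacent contrasts.** One fit of `~ genotype + time` per transcript;
each of the 5 adjacent intervals is a Wald test on the difference of
consecutive time coefficients, sign = later minus earlier, BH-adjusted
within interval (one family per contrast, one for the screen).

## Temporal pattern coding

A transcript's code has one character per interval: `u` if adjusted
p < 0.05 and log2FC > 0, `d` if significant and negative, else `0`;
all-`0` transcripts are not differentially expressed transcripts (DETs)
and leave the universe. For 5 intervals there are 3^5 = 243 possible
codes. Pattern tables rank codes by transcript count with lexicographic
tie-break (ties at the margin otherwise make the "top k" ambiguous).

The permutation null of inter-interval independence shuffles each
interval's character column across transcripts — per-interval marginals
are preserved exactly, inter-interval dependence is destroyed — and
recomputes the number of distinct patterns, the top-k mass, the monotone
fraction and the down-then-up fraction among direction reversers. One
caveat discovered during calibration and worth stating: because the DET
universe is conditioned on "not all-zero", the column-shuffle null is an
exact null for the observed codes only when the probability of the
all-zero code is negligible. When `P(00000)` is large the null slightly
over-disperses the fine-grained statistics (distinct-pattern count, top-k
mass); the direction statistics are essentially unaffected. In DET-rich
regimes — the regime in which the statistics are interesting — the null is
calibrated, and the package's calibration tests run there.

## Genetic co-expression (GCoE)

The normalised matrix is adjusted for one latent factor: residualise every
transcript on the known design (`~ line + location + location/replicate +
time`), take PC1 of the residual matrix across samples — the leading
surrogate variable under an SVA-type model — and subtract its rank-1
contribution. Because the factor lies in the design's residual space, the
design effects are untouched, and the factor is only identifiable up to
that projection.

Per-line lsmeans come from one multivariate least-squares fit of the same
design, predicting each line at equal weight over all levels of the other
factors; on balanced data this is the line's sample mean. Transcripts of a
TCoE set are subclustered by Ward (`ward.D2`) agglomeration on Euclidean
distances between per-transcript-standardised line profiles —
standardisation makes the partition reflect profile shape rather than
expression magnitude, and Ward gives compact, size-balanced clusters,
which the cluster-size test downstream implicitly assumes. Both choices
are package decisions where the original procedure was silent; `linkage`
is exposed.

Each subcluster's eigengene is PC1 over lines x member transcripts
(centred), sign-fixed to correlate positively with the mean member
profile. The subcluster count `k` is chosen in `k_range` (default 4–20)
to maximise `median(h2) - lambda * IQR(h2)` over the subclusters' PC1
heritabilities (`lambda` = 1): high and homogeneous heritabilities win,
ties go to the smaller `k`. A caution from the package's own
model-selection experiments: this score cannot separate two purely
genetic modules from their union (any linear combination of heritable
line-directions is itself heritable), so it recovers the module count
only when the set mixes heritable and non-heritable coherent subgroups —
which is exactly the situation it was designed for.

## Heritability

`estimate_h2()` fits `y = mu + u + e`, `u ~ N(0, K sigma_u2)`,
`e ~ N(0, I sigma_e2)` by REML — REML rather than ML so the nested models
share the same fixed part (`mu`) and the LRT is legitimate. The restricted
likelihood is profiled over the variance ratio on the eigenbasis of `K`
(121-point log grid on [1e-6, 1e6], then golden-section refinement), and
the LRT against the no-genetics model is referred to the boundary mixture
`0.5 chi2_0 + 0.5 chi2_1` (plain `chi2_1` behind a flag). Heritability is
`sigma_u2 / (sigma_u2 + sigma_e2)`. Singular `K` gets a 1e-6 ridge with a
warning; flat likelihoods (e.g. `K = I`) resolve to zero genetic variance.

The GCoE permutation null shuffles the line labels of the lsmean matrix
relative to `K` and re-runs the entire procedure — subcluster-count
choice, clustering, PC1, REML — per permutation (default 50 permuted data
sets). Expression covariance among transcripts is preserved; only the
genetic alignment is destroyed.

Metabolite heritability uses the all-random RCBD model
`~ (1|line) + (1|location) + (1|location:replicate) + (1|line:location)`
fitted by `lme4::lmer` (REML), and the line-mean formula
`sigma2_L / (sigma2_L + sigma2_LxLoc/n_loc + sigma2_e/(n_loc * n_rep))` —
denominators 2 and 4 for two locations and two replicates. Balanced-design
EMS closed forms serve as a cross-check in the tests, not as the
implementation.

## The cluster-size permutation test

For a TCoE set, "expression permuted relative to each other" is
operationalised as an independent shuffle of each transcript's line
profile across lines — marginals preserved exactly, transcript–transcript
co-association destroyed. Each permuted matrix is clustered into `k = 8`
groups with the same distance and linkage as the real subclustering, the
sizes sorted descending and the smallest dropped (implemented literally),
giving a 7-vector. The observed vector's squared Mahalanobis distance from
the permutation mean under the permutation covariance is referred to
chi-squared with 7 df; 1000 permutations by default (calibration tests use
200 with the corresponding Monte-Carlo tolerance). A singular permutation
covariance falls back to the pseudo-inverse with a warning. Bonferroni
corrects across the tested sets.

## Metabolite–module association

Metabolites passing the strict `h2 > 0.4` filter are regressed, one at a
time, on each GCoE set's PC1 scores: ordinary least squares at the line
level (response = per-line mean over locations and replicates, consistent
with the lsmean logic; `--aggregate` semantics are exposed through the
response aggregation helper), two-sided p from t with `n_lines - 2` df.
No multiple-testing correction is applied on the metabolite x GCoE grid —
power at 22 lines cannot carry that burden; inference rests on the
comparison with 100 permutations of the PC1 scores, summarised per GCoE by
quantiles and overall by a one-sided rank-sum test of whether observed
p-values are stochastically smaller. The rank-sum summary is an addition;
the original comparison was purely graphical.

## Numerical choices and degenerate inputs

* BH adjustment delegates to `p.adjust`; missing p-values stay missing.
* GLM convergence: IRLS, deviance tolerance 1e-8, 100 iterations;
  non-converged fits propagate missing p-values.
* `estimate_h2` tie-breaks flat restricted likelihoods toward the smaller
  variance ratio; constant responses return h2 = 0 with a warning.
* Zero-variance transcripts standardise to zero before clustering; a
  zero-variance PC1 predictor yields a missing regression p.
* Pattern-rank ties and k-selection ties break deterministically
  (lexicographic; smaller k).
* Every permutation routine takes an explicit integer seed; the pipeline
  derives per-stage seeds deterministically from one master seed, so
  changing one stage's permutation count cannot perturb another stage's
  draws.

## Problem sizes used by the tests and the acceptance script

The test-suite and `scripts/acceptance.R` run the full machinery on
deliberately modest synthetic studies: 8-line single-location courses
(96 samples) for DE calibration at 2000 null transcripts; 400 null sets at
200 permutations for the cluster-size test's type-I error; a 100-line,
20-family panel for heritability recovery (the 22-line panel's single-draw
estimates are too dispersed for a sharp recovery check, as the vignette's
identifiability discussion explains); 22-line panels everywhere else.
These sizes are the package's choices for fast, reproducible
demonstration; all thresholds are stated in the tests themselves.

## Known limitations

* The exact DESeq2 machinery (dispersion empirical Bayes with full priors,
  Cook's-distance outlier handling, the dispersion-trend VST curve) is
  intentionally simplified; calibration, not numerical identity with
  DESeq2, is the design target.
* h2 at 22 lines with one observation per line is weakly identified under
  a near-diagonal GRM; estimates are honest but noisy, and single-module
  values should be read as draws from a wide sampling distribution.
* The column-shuffle pattern null is slightly mis-specified when the
  all-zero code has non-negligible probability (see above).
* The latent-factor adjustment removes exactly one factor; multi-factor
  batch structure is out of scope.
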