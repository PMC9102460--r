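---
title: "Methods: lncRNA discovery and regulatory networks in thermogenic receptacles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermolnc` implements the downstream analysis of a transcript catalogue
from thermogenic floral tissue sampled over five developmental stages
with three biological replicates. This vignette is the package's own
account of the models and procedures, the parameters that matter, the
synthetic data the tests rely on, and the choices made where the design
was genuinely open.

## Consensus biotype classification

Coding potential is assessed on four channels: two discriminative
scores (CPC, CNCI; both thresholded at 0), an ORF-quality score
(txCdsPredict; thresholded at 500), and a Pfam protein-domain hit. A
channel votes *noncoding* when its score is **strictly below** its
threshold (absence of a Pfam hit is the noncoding vote for that
channel); a score exactly at a threshold therefore counts as coding,
the conservative reading of "below the threshold". A transcript is
confirmed lncRNA or mRNA only when at least `votes_required = 3` of the
four channels agree; 2–2 splits are classed `uncertain` and excluded
from both classes rather than forced into either one. Confirmed
lncRNAs must additionally be longer than `min_len = 200` nt (strictly:
a 200-nt transcript is excluded).

Missing channels are an error, never imputed — a transcript with
partial evidence cannot participate in a 3-of-4 vote honestly.

Two consequences of the vote worth keeping in mind:

* with independent per-channel error ε, the probability that at least
  three channels are simultaneously correct is (1−ε)⁴ + 4ε(1−ε)³ ≈
  0.986 at ε = 0.05, so some transcripts always land in `uncertain`;
* a *wrong confirmed call* needs at least three simultaneous channel
  errors (≈ 5 × 10⁻⁴ at ε = 0.05). Classification quality is therefore
  reported as agreement among confirmed calls, which is what the
  confirm-only-on-consensus design optimizes.

## Stage presence

A transcript is present in a stage when its mean FPKM over that stage's
replicates reaches the floor. No floor is inherent to the data, so it
is an explicit parameter (`floor`, default FPKM ≥ 0.5 on the stage
mean, recorded in the output's metadata). Categories follow from the
presence vector: `all-stages`, `stage-specific` (exactly one stage),
`partial`, and `absent` for transcripts below the floor everywhere —
kept as its own category so the all-stages complement is unambiguous.

## Differential expression

The test operates on raw counts. Replicates of each stage are pooled by
summation into per-transcript counts \(C_a, C_b\) with stage library
sizes \(N_a, N_b\) (total pooled counts), and the two-proportion
z-statistic under the pooled binomial null is used:

\[
\hat p = \frac{C_a + C_b}{N_a + N_b},\qquad
z = \frac{C_b/N_b - C_a/N_a}
         {\sqrt{\hat p(1-\hat p)(1/N_a + 1/N_b)}}
\]

with a two-sided normal p-value, Benjamini–Hochberg adjustment across
all transcripts of a comparison, and the filter |log2FC| ≥ log2(2) and
adjusted p ≤ 0.001. The fold change uses a pseudocount of 1 count in
both numerators so it stays finite at zero counts; the pseudocount
never enters the test statistic. When both proportions are zero the
statistic is defined as z = 0, p = 1.

Assumptions and calibration: the statistic models count sampling
(binomial/Poisson-like), not biological replicate dispersion. Under a
pure count-sampling null it is calibrated — on 10,000+ null transcripts
the fraction with p ≤ 0.05 sits within binomial noise of 0.05 — but
under overdispersed replicates it is anti-conservative, a known
property of pooled-count tests. The package therefore treats the
adjusted-p threshold (0.001) together with the fold-change gate as the
operative filter, and the synthetic calibration check is run at
dispersion 0 where the test's own null model holds. Replicate-aware
negative-binomial GLMs are deliberately out of scope.

The BH step is `stats::p.adjust(method = "BH")` behind a validated
wrapper; tests compare it against a literal step-up implementation on
all permutations of up to six p-values.

K-means profile clustering of the DELs uses the per-stage mean of
log2(FPKM + 1), z-scored across stages (constant profiles are kept
unscaled and flagged). Initialization is k-means++ under a caller seed
with 50 restarts, keeping the lowest within-cluster sum of squares;
labels are renumbered by descending cluster size so output is
deterministic. `k = 6` by default.

## Cis targets

For each protein-coding gene the cis window runs from 10 kb before the
gene's strand-aware start to 20 kb after its strand-aware end — for a
minus-strand gene "upstream" lies at higher coordinates. Any lncRNA
whose span intersects the window on the same chromosome is a
candidate; the lncRNA's own strand is not restricted (antisense overlap
is legitimate cis regulation and is flagged via `same_strand` and
`relation = "overlapping"`, distance 0). Distances are gaps between
closest span edges, with a gap of exactly 10,000/20,000 nt still
inside. Coordinates are 0-based half-open internally and 1-based
inclusive in GTF, which keeps the window arithmetic free of off-by-one
cases; the interval search runs on `IRanges::findOverlaps` and is
checked in the tests against an all-pairs oracle on hundreds of random
fixtures. Windows are anchored on gene boundaries (not TSS-only), the
plain reading of a "window around the gene".

Candidates then pass a dual gate computed across all 15 samples:
Spearman ≥ 0.6 (average-rank ties) **and** Pearson ≥ 0.6, both
one-sided positive. Gene-level expression is the sum of the gene's
isoform FPKMs. Zero-variance vectors make correlation undefined; such
pairs are dropped and recorded in the `dropped` attribute rather than
erroring. Applying the gate only to windowed candidates is equivalent
to correlating genome-wide first and intersecting, at a fraction of the
cost.

## Co-expression modules

The network is unsigned: \(a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta\) on
log2(FPKM + 1), zero diagonal. β is the smallest power in 1..20 whose
scale-free fit reaches `r2_min = 0.8` (R² of the regression of log10
p(k) on log10 k over 10 connectivity bins); if none qualifies the best
fit is used with a warning. Topological overlap is

\[
\omega_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_u a_{iu} a_{uj},
\]

with \(\omega_{ii} = 1\), verified against a triple-loop oracle.
Modules come from average-linkage clustering of \(1 - \omega\) with a
**static cut**; clusters below `min_size = 10` go to `grey`, and
surviving modules take the canonical color sequence (turquoise, blue,
brown, …) in descending size order. Transcripts are sorted
lexicographically before clustering so membership is input-order
invariant.

The static cut height default is 0.7. With only 15 samples the
sampling noise of pairwise correlations is large (sd ≈ 0.27 under
independence), and the shared-neighbor term of the TOM transitively
inflates similarity among unrelated transcripts; a cut near 1 therefore
chains noise into spurious modules and can even absorb real modules
into one blob. At 0.7 a cluster survives only where average
topological overlap within it exceeds 0.3 — planted structure of
within-module correlation ≈ 0.9 merges far below the cut, while
independent transcripts (pairwise ω near 0) merge far above it and are
left `grey`. The height remains a documented knob (`cut_height`), and
dynamic tree cutting is deliberately not reimplemented.

Each module's eigengene is the first principal component of its
standardized member expression, scaled to unit variance, with the sign
fixed so it correlates positively with the module's mean standardized
profile — this single convention makes the whole fit deterministic.
Module–trait analysis expands the per-stage receptacle temperature to
samples (each stage value repeated over its replicates), Pearson-
correlates it with each eigengene, and takes two-sided p-values from
the t-distribution with n − 2 df. Hubs are members with kME =
cor(member, eigengene) ≥ 0.9, capped at the top 10; a trans-target pair
is any lncRNA–mRNA pair in one module with both kMEs ≥ 0.9, independent
of genomic location. The kME threshold and cap are conventions — no
canonical hub criterion exists — and both are exposed.

## ceRNA / eTM network

lncRNA–mRNA pairs are tested only when they share at least 3 miRNAs.
With N the miRNA universe (all miRNAs of the loaded interaction table —
the prediction input set, recorded in the output), K the miRNAs
targeting the lncRNA and n those targeting the mRNA, the p-value is the
hypergeometric upper tail P(X ≥ k). It is authored in log-space
(`lchoose` + log-sum-exp) so it is stable for any N, and tested against
direct term summation over the full grid N ≤ 60 and against
`stats::phyper`. BH correction is applied across all tested pairs as
one family (per-lncRNA grouping would change the error unit without a
stated reason); pairs at FDR ≤ 0.05 are significant and expand into eTM
records, one per shared miRNA, so record counts conserve k per pair.

miRNA–target interactions are pluggable: the faithful path ingests an
external prediction table; the built-in `seed_match_targets()` scorer
records an interaction when the reverse complement of the miRNA seed
(positions 2–8 from the 5′ end) occurs in the transcript, scoring by
distinct site count. It is a transparent stand-in, not a
thermodynamic model: no position-weighted complementarity, no duplex
free energy, no G:U wobble.

## The synthetic receptacle study

`generate_receptacle_study()` emulates the study design so recovery is
checkable end to end: 5 stages × 3 replicates named `S{stage}R{rep}`, a
receptacle temperature trait of (18, 30, 35, 30, 20) °C peaking at
stage 3 — the thermogenic chamber range — and, at the default scale,
600 coding genes (occasionally multi-isoform, mostly multi-exon,
lengths mostly > 500 nt) plus 400 single-locus lncRNAs (80% of lengths
in 201–500 nt, 85% single-exon) on 8 chromosomes. Intergenic gaps are
≥ 50 kb so the only lncRNAs inside any cis window are the planted 15%,
placed 0.5–8 kb upstream or 0.5–17 kb downstream of their host with a
shared random stage profile.

Counts are negative binomial (`dispersion = 0.05` by default, a
realistic bulk-RNA-seq overdispersion; 0 gives Poisson) around
stage-dependent means with lognormal per-transcript baselines,
per-sample size factors, and expected library size 5 × 10⁵ — scaled
down from sequencing reality so the full pipeline runs in seconds; the
proportion-based test only sees relative depth. FPKM is
10⁹ · count / (length × library size) with the column total as library
size. Planted effects:

* **DE**: 10% of transcripts shifted by |log2FC| = 2 at one target
  stage relative to stage 1, direction random, recorded per comparison;
* **stage-specific**: 10% of lncRNAs expressed (at their baseline) in
  exactly one stage and at a background mean of 0.02 elsewhere — the
  presence floor is a knob precisely because no biological constant
  exists here;
* **modules**: three modules of sizes 40/60/80 (≈ 30% lncRNA members)
  whose stage profiles are mutually orthogonal unit-sd vectors that
  each project onto the standardized trait with correlation 1/√M,
  signed per module (alternating +/−). Orthogonality is what makes
  M modules separable from one another while all remaining
  trait-correlated; a single planted module uses the trait profile
  itself. At most `stages − 1` such modules exist, which the
  configuration enforces;
* **eTMs**: five lncRNA–mRNA pairs each sharing 3–5 miRNAs, on top of
  background interactions at density 0.005 per miRNA × transcript cell;
* **coding evidence**: each channel errs independently at 5% per
  channel by default.

All four generators are deterministic given the configured seed (the
sub-generators use fixed small offsets of it).

What the generator does **not** emulate: read-level artifacts
(alignment, assembly fragmentation, multi-mapping), genomic sequence
content, correlated channel errors in coding-potential tools, isoform
switching, and hub-structured miRNA targeting. Passing recovery tests
therefore demonstrates that the pipeline's logic is correct under its
stated models — not that those models capture every property of real
receptacle data.

## Recovery conditions and problem sizes

The recovery suite runs at the scales above (≈ 1,150 transcripts).
Biotype agreement, DE sensitivity, cis recovery and eTM recovery are
measured on the full default study. Module recovery (adjusted Rand
index against planted membership, grey for unassigned, plus
trait-correlation signs) is measured on a modules-only study —
planted DE and stage-specific transcripts are genuinely co-expressed
groups, so a run that plants them too is expected to detect them as
additional modules; that is correct behavior, but it makes planted-set
ARI the wrong yardstick for the clustering itself. Type-I calibration
uses a dedicated null study of ≈ 11,500 transcripts at dispersion 0
(the test's own sampling model, as discussed above). These sizes keep
the full suite within a couple of minutes on one CPU while leaving all
statistical margins wide.

## Known limitations

* The DE statistic ignores replicate dispersion (see above); it mirrors
  pooled-count testing practice, not modern GLM practice.
* The static tree cut is simpler than dynamic hybrid cutting and will
  fragment modules whose internal topological overlap varies strongly.
* The seed matcher is a complementarity filter, not an energy model;
  externally predicted tables are the faithful input.
* `uncertain` transcripts are reported as a third class; analyses that
  fold them into mRNA counts can do so downstream, both accountings are
  reproducible from the output.
* FPKM is taken as given (computed from counts and lengths); no
  between-sample normalization beyond library size is applied.
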