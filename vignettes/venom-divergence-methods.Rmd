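---
title: "Methods: compositional divergence, QC callers, turnover, and selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional divergence, QC callers, turnover, and selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmviper)
```

`palmviper` packages the statistical machinery of a two-species venom-gland
transcriptome comparison. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions that were
genuinely open — in enough detail that a reader can judge what a passing
test suite does and does not establish about real data.

## The compositional divergence screen

TPM values are relative abundances: each sample's column closes to $10^6$,
so an increase in one transcript forces every other value down. Comparing
raw TPM between individuals confounds biology with closure. The screen
therefore works in centered log-ratio coordinates,
$\mathrm{clr}(x_i) = \ln x_i - \frac{1}{D}\sum_j \ln x_j$, which are
invariant to per-sample rescaling. The geometric mean is taken over **all**
transcripts (toxins and nontoxins together) because the null distribution
is built from nontoxins on that same scale.

CLR needs strictly positive input. Zeros are replaced by multiplicative
simple replacement: each zero becomes `delta_fraction` (default 0.5) times
the sample's smallest nonzero value, and the nonzero values are rescaled to
preserve the column total. The rule is deterministic, and the method label
and parameter are recorded in the output attribute. A Bayesian-multiplicative
replacement would be an alternative; the simple rule was chosen because it
is exactly reproducible and its single parameter is easy to reason about.

With only two individuals per species no formal replicate-based test is
possible. Instead the ~1500 nontoxins act as an empirical null for
between-individual divergence: a total-least-squares line (orthogonal
regression with error-variance ratio 1, equivalently the principal axis of
the 2×2 covariance) is fitted through the nontoxin CLR cloud, and the null
band is the empirical $(\alpha/2, 1-\alpha/2)$ quantiles of the nontoxins'
signed perpendicular residuals, $\alpha = 1 - \texttt{level}$ with
`level = 0.99` by default. Toxins strictly outside the band are called
over-expression outliers; a point exactly on a boundary is inside
(conservative tie rule). The divergence coordinate is the *signed orthogonal
residual*, not the raw CLR difference: the band must be defined in the same
geometry as the fitted line, and the residual handles fitted slopes away
from 1 (unequal library behaviour) correctly. A raw-difference variant is
available via `coordinate = "clr_difference"`.

Two one-sided readings of "outside the 99th percentile" are possible; the
two-sided band at total mass 1% (0.5% per tail) is used because divergence
has no preferred direction and the direction column of the outlier calls
(which individual over-expresses) only makes sense with a two-sided band. A
one-sided variant is a `level` choice away.

With ~1500 background points the empirical 99% band is estimated from about
seven observations per tail, so the realised false-positive rate on null
toxins sits slightly above the nominal 1% (around 1.0–1.25% in the
calibration runs); `build_null_band()` warns below 100 background points.

## Coverage, chimera, k-mer, and clustering QC

Quantifiers can assign nonzero TPM to transcripts that are not in an
individual's transcriptome, through mis-mapping from similar regions. The
presence caller therefore works on coverage, not abundance: a transcript is
absent when more than `max_low_fraction` (default 0.10) of its bases are
covered below `min_depth` (default 5×). Real but lowly expressed
transcripts give thin, uniform coverage; phantom transcripts give patchy
coverage concentrated in shared motifs. The call is monotone in both
thresholds. All coordinates are 0-based half-open throughout the package;
conversion happens only at ingress/egress of 1-based formats.

The chimera screen encodes the signature of a mis-joined assembly: no read
spans the junction, so at sites near it the mean read bases to the left and
right, computed over covering reads, become asymmetric. A site is flagged
when $|\text{left}-\text{right}|$ exceeds `asym_fraction` (default 0.5)
times the mean read length. Sites within one mean read length of either end
are ineligible (overhang means are ill-defined there; this is also why the
simulator refuses junctions that close to an end — they are undetectable by
construction), and a site needs `min_reads_at_site` (default 3) covering
reads. Whether the overhang means should be taken over covering reads or
over a window is ambiguous; the covering-read interpretation is implemented.
The screen only flags — removal is left to review, and a depth-discontinuity
report can be derived from `depth_profile()`.

The k-mer cross-talk filter addresses index hopping between samples
sequenced together: canonical 21-mer counts are normalised per million
k-mers within each sample, and a k-mer whose pseudo-counted ratio
$(\text{high}+0.5)/(\text{low}+0.5)$ exceeds `fold` (default 500) between a
sample pair is flagged; reads of the *lower*-count sample containing it are
removed, the low side being the presumed bleed-through recipient. `k`,
the normalisation, the pseudo-count and the removal side are implementation
choices (the upstream tools leave them open); all are parameters and are
recorded. Identical spectra remove nothing, and a ratio of exactly `fold`
is retained (strict inequality).

Transcript clustering collapses alleles and very recent paralogs at 98%
identity. It is greedy centroid clustering, longest-first with ties broken
by sequence then name — which makes the result invariant to input order —
using global-alignment identity defined as matches over alignment columns
(match +1, mismatch −1, gap open −2, extend −0.5, via
`Biostrings::pairwiseAlignment`). Cluster counts are non-increasing in the
threshold.

## Orthology, turnover, and the ortholog/paralog factorial

For two species, orthogroup classification is purely combinatorial: 1:1
groups are one-to-one orthologs; a side with $m>1$ members records $m-1$
duplication events in that species; an empty side records a loss in that
species. With two taxa, "loss in A" and "gain in B" are equally
parsimonious; the loss wording is used and the polarity caveat is recorded
in the events-table metadata. Orphan transcripts become their own 1:0
groups with a warning. The classification exactly inverts the
`simulate_orthogroups()` generator, and two conservation identities hold by
construction: duplication events sum to $\sum(\max(m_A,m_B)-1)$ over
multi-member groups, and loss events count the groups with an empty side.

Merged cross-species expression has one row per orthogroup member.
One-to-one rows take their partner's values in the other species' samples;
every other member is zero-filled there, and those cells are flagged as
*structural* zeros — "the transcript does not exist in that species" — which
must never be touched by sampling-zero replacement. The ortholog-vs-paralog
factorial (`clr ~ type * species`) uses each member's CLR expression in its
own species' samples and type II sums of squares, because the design is
unbalanced (unequal member counts per class) and type II keeps main-effect
tests interpretable there.

Event-to-tree mapping places a duplication on the stem edge of the
duplicated tips when they are monophyletic in the family tree, otherwise on
the tips; a loss is attached at the surviving ortholog's tip, marking the
sister position where the lost copy would branch. One annotation is
produced per event, so annotation counts conserve event counts.

## The simplified negative-binomial Wald stage

The package's DE stage is deliberately transparent rather than maximally
powerful, and labels itself "deseq2-like (simplified)": median-of-ratios
size factors; per-transcript dispersion by pooled within-group method of
moments, $\hat\alpha = (\hat v - \hat\mu)/\hat\mu^2$ floored at $10^{-8}$
(no shrinkage across transcripts); $\log_2$ fold change with a half-minimum
pseudo-mean for zero group means; a delta-method standard error under the
NB variance $\mu + \alpha\mu^2$; a standard-normal reference for the Wald
statistic; and Benjamini–Hochberg adjustment (missing p-values propagate
and do not count toward $m$). Cook's-distance filtering and independent
filtering are intentionally absent. The stage is validated by its sampling
properties — type-I error within $0.05 \pm 0.02$ on Poisson nulls at
$n = 5$ per group and ≥90% power for planted 4-fold changes at dispersion
0.1 — not by numerical agreement with any particular production DE tool,
whose shrinkage estimators it does not attempt to match. On the real
published contrasts the package operates on the printed summary tables
(recomputing Wald statistics and significance counts) rather than
pretending to regenerate them from unavailable raw counts. With single
replicates the dispersion cannot be estimated and the stage degrades to the
floored (near-Poisson) variance; results at $n=1$ are for exploration only.

## Coexpression submodules

The module pipeline is a compact weighted-coexpression implementation:
`log2(x + 1)` variance-stabilising transform; a variance filter that ranks
transcripts by residual dispersion around a loess mean–variance trend
(constants always drop; `filter_quantile` defaults to 0.75, keeping the top
quarter); Pearson correlation raised to the soft threshold $\beta = 10$,
unsigned ($|r|^\beta$); topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$; and average-linkage clustering of $1-\mathrm{TOM}$ cut at the
height in $\{0.05, \dots, 0.95\}$ maximising mean silhouette width, with
clusters below `min_module_size` (default 1) sent to module 0. The unsigned
default reflects that anti-correlated transcripts under shared regulation
belong together; within the generator's factor model, modules with
proportional — even opposite — treatment profiles remain separable because
each module carries its own sample-level factor noise. Note that the
popular dynamic tree cut is *not* reproduced; the silhouette-chosen static
cut is simpler, deterministic, and validated by planted-module recovery
(adjusted Rand ≥ 0.95 at within-module correlation ≥ 0.9 with ≥4 samples
per treatment) rather than by matching any published module count, which
would require the unpublished nontoxin expression data. The stage refuses
to run below 4 samples and warns below 8 — with venom-type "treatments" of
1–2 individuals each, module assignments are hypotheses, not findings.

## Nei–Gojobori selection screens

Sequence divergence uses NG86 counting, chosen over ML codon models because
it is deterministic and desk-verifiable against hand enumeration; outputs
label the method, and values should be compared with ML estimates by rank
only. Sites: at each codon position the three single-base changes are
classified; mutations creating stops are excluded entirely, so a position's
synonymous site count is (synonymous changes)/3 and $N+S$ falls short of 3
per codon by the excluded stop fractions. Differences: per codon, all
orderings of the differing positions are enumerated; pathways through stop
codons are discarded (all pathways are used if none is stop-free) and
synonymous/nonsynonymous steps are averaged with equal weight. Proportions
$p_N = N_d/N$, $p_S = S_d/S$ get the Jukes–Cantor correction
$d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined at $p \ge 3/4$;
$\omega = d_N/d_S$ exists only when $d_S > 0$. Gapped codon columns drop
pairwise with a count reported; only the standard genetic code is
supported.

Pairs with $d_S < 0.001$ (unstable $\omega$) or $d_S > 0.10$ (likely
mis-paired orthologs) are excluded before group contrasts. The
toxin-vs-nontoxin contrast uses the *unpaired* Wilcoxon rank-sum test with
normal approximation and tie correction — the groups are independent and of
unequal size, so a signed-rank (paired) form is inapplicable, though it is
available behind `paired = TRUE` for matched designs. Percentile flags mark
toxins strictly above the nontoxin 95th percentile of $\omega$, $d_N$, or
$d_S$, computed on the dS-filtered set by default, with the $d_N$/$d_S$
overlap reported separately.

## What the generators emulate — and what they do not

Each `simulate_*` function plants recoverable truth under the study's
design: two individuals and a ~40-toxin / ~1500-nontoxin composition closed
to $10^6$ (`simulate_expression`, with outlier shift 5 and noise 0.5 CLR
units as the default effect scale — a calibration choice, since no
empirical effect size is available for "over-expression"); clipped uniform
read tilings with junctions no read spans and zero-depth windows
(`simulate_coverage`; planted absences are true zero coverage, not low
TPM, keeping "absent" distinct from "lowly expressed"); coding-sequence
pairs with exact synonymous/nonsynonymous difference counts
(`simulate_codon_pair`); orthogroup tables with exact planted turnover; and
factor-model coexpression blocks whose pairwise within-module correlation
equals `within_cor`.

They deliberately do not emulate: sequencing error or quality profiles (no
read-level FASTQ simulation), quantifier estimation noise (TPM is treated
as exact), real toxin-family abundance spectra, phylogenetic correlation
among nontoxins, or mean–variance coupling beyond the NB model. Passing
tests therefore demonstrate that each procedure is *correct and calibrated
under its own model*, not that the model captures every property of real
venom-gland data.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with classed conditions (`format`,
`validation`, `config`, `lookup`, `fit`). Ties at band or percentile
boundaries are always resolved conservatively (not flagged). Quantiles are
R's default type 7. The TLS fit refuses degenerate clouds and vertical
principal axes. The test and acceptance runs use deliberately modest sizes
chosen to make their Monte-Carlo tolerances meaningful: 10,000 null-toxin
draws (250 simulated pairs) for band calibration, 1000 random tilings and
100 planted junctions for the chimera screen, a 200-scenario orthology
sweep, 200 replicates of a 2000-transcript Poisson null at $n = 5$ per
group for the Wald stage, and 100 replicates of the two-block module
design. Reported values regenerate from these simulations at run time under
the session seed.

## Known limitations

* Two individuals per species cannot separate individual from population
  variation; the nontoxin null absorbs both.
* The DE stand-in's unshrunken dispersions are noisy at small $n$; its
  p-values are calibrated in aggregate but individually unstable near the
  floor.
* NG86 underestimates divergence where transition/transversion bias or
  codon bias is strong; $\omega$ ranks are more trustworthy than levels.
* With min module size 1, background transcripts can form singleton
  modules; module 0 plus the silhouette cut mitigate but do not remove
  this, and module calls at these sample sizes are exploratory.
* The k-mer filter's removal side assumes the lower-count sample is the
  recipient; simultaneous bidirectional contamination of the same k-mer is
  not modelled.
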