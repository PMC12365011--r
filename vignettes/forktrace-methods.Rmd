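---
title: "Methods: fork calling, stall scoring and treatment effects in forktrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fork calling, stall scoring and treatment effects in forktrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forktrace)
```

## The measurement

A sequential pulse-chase — 5 minutes of EdU, 10 minutes of BrdU, then a
thymidine chase — stamps every active replication fork with an ordered
two-colour label. On a nanopore read, a base-analogue caller reports the
probability of EdU and BrdU at each thymidine; `forktrace` starts from those
per-read probability tracks (the *detect* format, documented in
`?read_tracks`) and never touches raw signal. All coordinates in the package
are 0-based and half-open, in reference space; strand is recorded but plays
no role in fork direction, which is purely a reference-coordinate notion.

## Segmentation and fork calling

A per-position call is positive when its probability strictly exceeds
`call_threshold` (default 0.5). Candidate segments are maximal runs of
positions covered by a *positive window*: a genomic window of `window_size`
(default 1000 bp) holding at least `min_window_thymidines` (default 5)
thymidines, whose positive-call fraction for the analogue reaches
`window_fraction_floor` (default 0.3) and exceeds the other analogue's
fraction in the same window. Runs shorter than `min_track_length` (1000 bp)
are dropped. The window floor of 0.3 mirrors the ">30% of thymidine
positions called" operating point used when analogue-calling models are
trained; window arithmetic is genomic rather than thymidine-count because
the downstream stall windows are genomic, and the thymidine floor guards
AT-poor windows. Candidate detection ahead of trimming is a design choice of
this package: published descriptions specify the trimming rule but not the
initial detection, so both are explicit parameters here.

Each candidate segment is then trimmed to its incorporation plateau: the
positive-call fraction over the middle third of the segment sets the
reference level, and a `window_size` window advances inward from each end
until it first meets that level; the segment is cut at the outer edge of the
first qualifying window on each side. Trimming never grows a segment, and on
noise-free tracks it is idempotent. Under call noise it is only
approximately idempotent — about half of all windows sit below the
middle-third *mean* by construction, so a re-trim can move within the
plateau; the test suite asserts exact idempotency on clean tracks and the
shrinking property in general. Segments too short to hold a middle third
plus two windows are returned unchanged and flagged.

Trimmed EdU and BrdU segments are paired into forks. Because EdU comes
first, an EdU segment upstream of its BrdU partner makes a rightward fork
and downstream a leftward fork; the fork track runs from the far end of the
EdU segment to the far end of the BrdU segment. Pairing tolerates a gap of
up to `max_pair_gap` (default 5000 bp — analogue callers tend to leave a gap
between the two segments) and an overlap of up to one window (window-edge
noise can blur adjacent boundaries). When a segment could pair on both
sides, the smaller gap wins; every segment joins at most one fork. Two
adjacent forks diverging with EdU segments within the pairing gap are called
an origin (the interval between the inner EdU ends, zero-length if they
touch); two converging with adjacent BrdU segments are a termination. All
forks on such reads carry `on_read_with_origin` / `on_read_with_termination`
flags.

## Fork speed

Speed is the fork-track length divided by the total pulse duration
(`pulse_minutes`, default 15), in kb/min. Forks on a read with a called
origin or termination, or starting/ending within `read_end_margin` (default
3000 bp) of a read end, have artificially short tracks and are excluded with
a tagged reason rather than reported. The margin comparison is strict: a
fork ending exactly at the margin is kept.

## Stall score

At the fork's BrdU end (its leading edge at the end of the pulse: right end
of the BrdU segment for rightward forks, left end for leftward — the mirror
convention is implied by fork direction), two genomic windows of `window`
(2000 bp) are scored: B, the fraction of thymidines with positive BrdU calls
just inside the segment, and A, the same just outside. The raw score
R = (B − A)/B is scaled by the shifted softplus

stall = α·log(1 + e^{β(R−1)}) − α·log(1 + e^{−β}),

clamped below at zero. The transform is exactly 0 at R = 0, monotone, and
maps R = 1 to just below 1 under both shipped presets — `stall_params("v3")`
(α = 1.55, β = 3) and `stall_params("v4")` (α = 2.63, β = 1, calibrated for
cleaner call chemistry). Raw scores may be negative (A > B); the scaler is
defined there and the clamp preserves the [0, 1] contract. Scores are
declined, not fabricated, when the outside window would leave the read, the
fork is a termination member, an indel longer than `max_indel` (100 bp)
falls in either window, either window holds fewer than `min_thymidines`
(10; published descriptions give no floor, so a small one is imposed to
avoid degenerate fractions), or B = 0. Windows are anchored at the trimmed
BrdU end; whether the upstream caller anchors at the trimmed or pre-trim
end is unpublished, and the trimmed end is the coherent choice given that
trimming defines the reported track.

## Stress signatures

Eight features per fork: total track length, EdU and BrdU track lengths
(bp), the four cross-analogue positive-call fractions within the two
segments, and the stall score. Each feature is rescaled across forks to
(x − median)/IQR; a zero-IQR feature carries no information and is zeroed
with a warning. After subsampling `forks_per_run` (125) forks per sequencing
run, the matrix is embedded with UMAP using 25 nearest neighbours, minimum
embedded distance 0 and the Chebyshev metric. The installed UMAP backend
(`uwot`) has no native Chebyshev support, so exact k-nearest neighbours are
computed in-package from the full L∞ distance matrix and passed through
`uwot`'s precomputed-neighbour interface; at the few-thousand-fork scale
this is exact and fast. K-means (K = 5, 10 restarts) runs on the 2-d
embedding by default — centroids then live in the plotted space — with the
rescaled feature space as an option; which space the original analysis
clustered in is unpublished, so both are exposed. The embedding seed is a
first-class parameter, subsampled row indices are returned for manifests,
and a fixed seed reproduces the embedding bit-for-bit (single-threaded
layout). Density panels use a Gaussian KDE with the plotting default
bandwidth.

One structural consequence of IQR rescaling worth knowing: every
uninformative feature ends up with unit spread, so under the Chebyshev
metric a handful of strongly informative features can only dominate up to a
point. The test suite demonstrates this: conditions separated only in the
three length features embed well above chance purity but not perfectly, and
dropping those features collapses purity to chance.

## Replication timing

Trep is fitted per 50-kb bin from a multi-fraction timing profile: the
per-fraction signal is accumulated, normalised to [0, 1] (making the fit
invariant to uniform rescaling of the raw signal), and a logistic
S(t) = 1/(1 + e^{−k(t − Trep)}) is fitted by Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`; the `nls` wrapper rejects the near-singular
perfect-fit cases a step-like bin produces). Initialisation interpolates the
first 0.5-crossing; k is bounded in [10⁻³, 100] and Trep to the fraction
range ±5 h. Fits with root-mean-square residual above `max_resid` (0.15) or
degenerate signal are marked missing. The logistic-in-time parameterisation
is declared here; the upstream Repli-Seq processing (smoothing, scaling) is
assumed done.

Forks take the Trep of the bin containing their track midpoint — the least
biased single point for a 15-minute track; midpoints exactly on a boundary
go to the right (half-open) bin, and forks in missing bins are dropped with
a warning. Trends over S-phase group forks by `floor(Trep)` (matching
per-hour strip plots), require at least 3 hours with 5 forks each, take
per-hour medians, and regress median on hour by OLS. Reported are the
Pearson correlation of the medians, the slope, and a one-sided p-value —
alternative slope > 0 for speed, slope < 0 for stall score; swapping the
alternative maps p to 1 − p.

## Treatment effects

Both models share the partial-pooling structure: per-condition group means,
replicate-level means drawn from the group level, and a fork-level
likelihood.

Speed: y ~ Normal(θ_rep, σ_group); θ_rep ~ Normal(μ_group, τ_group);
μ_untreated ~ Normal(1.5, 0.5), μ_treated ~ Normal(0.7, 0.5) kb/min; all
SDs half-Normal(0.5). The model is sampled in the non-centred
parameterisation (θ = μ + τ·z) — with two replicates per condition the
centred form funnels as τ → 0 and produces heavy divergence counts.

Stall score: y ~ Beta(θ_rep·φ, (1 − θ_rep)·φ) with precision φ shared
across all replicates and both conditions (a per-group option exists);
θ_rep ~ Beta(μ_group·κ, (1 − μ_group)·κ); μ_group ~ Beta(2, 5);
φ ~ Gamma(2, 0.1). The replicate-level concentration κ is this package's
interpretation — the published model names only a group mean and shared
precision — and it carries the same Gamma(2, 0.1) prior as φ: κ is itself a
precision, and a short-tailed prior on κ caps how tightly replicate means
may cluster, leaving a persistent posterior tail through the ROPE even when
replicates agree exactly. Scores at exactly 0 or 1 are nudged inward by
10⁻⁴ to keep the likelihood finite.

Posteriors are sampled by the package's own No-U-Turn sampler (`nuts_sample`)
— dual-averaging step-size adaptation (target acceptance 0.8), a diagonal
mass matrix estimated from the middle of warmup, slice-sampling tree
building with maximum depth 10 and divergence threshold 1000 — with
analytic gradients on sufficient statistics, so each density evaluation is
O(replicates). Defaults are 2000 draws after 1000 tuning steps, 4 chains
(chain count and seed are configuration; published settings state only
draws and tuning). Split-R̂ ≥ 1.01 or a high divergence count produce
warnings, never silent failure, and the test suite cross-checks the speed
posterior against an independent Gibbs implementation (JAGS) of the same
model.

Reported quantities per fit: Δ1 = treated − untreated group mean, Δ2 and Δ3
(absolute differences of the untreated / treated replicate means; with more
than two replicates, the mean absolute pairwise difference), the adjusted
effect Δ1 − Δ2, and the fraction of Δ1 draws outside the ROPE (±0.1 kb/min
for speed, ±0.05 for stall). An effect is significant when that fraction is
at least 0.95 — the boundary is inclusive. Δ3 is reported but takes no part
in significance.

## The simulator

`simulate_experiment()` emulates the labelling protocol, not the sequencer:
reads are lognormal with a configurable length-weighted N50 (default
90 kb, an ultra-long run), thymidines are placed per-base at
`at_fraction/2` (default 0.3), and three event types are laid onto reads at
per-Mb rates — single forks (origins fired before the pulse), origins
firing during the EdU pulse (two diverging forks), and terminations (two
converging forks). Fork speeds are Normal (default mean 1.4 kb/min, SD 0.3,
matching unperturbed human cells); a stalled fork stops dead at a uniform
draw from `stall_time_range`. Called probabilities are independent
per-thymidine Beta draws — Beta(8, 2) at labelled, Beta(2, 8) at unlabelled
positions — because every consumer of these tracks operates on
probabilities, not signal; `noise_free = TRUE` gives exact 0/1 calls for
ground-truth recovery tests.

Two features of real data are modelled deliberately: BrdU incorporation
decays exponentially into the chase (time constant `chase_tau`, 3 min),
which is what gives unstalled forks their gradual BrdU tail and moderate raw
stall scores, and a detection gap (`event_gap`, 3000 bp) is left where
diverging or converging tracks meet, as analogue callers do. Not modelled:
sequence-context-dependent calling error, leading/lagging-strand asymmetry,
basecalling or alignment error, and pause-and-resume stalls (stops are
final). Passing tests on simulated data therefore demonstrate that the
analytics recover the protocol's geometry and statistics under calibrated
per-position noise — not that they are robust to every failure mode of real
sequencing runs. Under noise, called track boundaries erode inward by a few
hundred bp (the window floor) while the chase tail extends the called BrdU
end outward; the net speed bias is small but visible in noisy simulations,
and disappears in noise-free ones.

## Problem sizes and determinism

The shipped tests run at desk scale, chosen so the full suite exercises
every stage in minutes: tens of reads per simulation (hundreds of forks),
20 seeds × 2 chains × 2000 draws for sampler recovery and null calibration,
200 null replicates for the trend test's type-I calibration, and
1250-point embeddings. All randomness flows from explicit seeds; the
simulator and embedding restore the caller's RNG state, and identical seeds
give byte-identical simulator output and bit-identical embeddings.

## Known limitations

Stall scores cannot be validated against an orthogonal measurement here (or
in the field); what is tested is the contract — geometry in, score out.
Origin/termination recall degrades when event footprints approach read
length or events crowd within the pairing gap. The Beta treatment-effect
model assumes a unimodal per-replicate score distribution; strongly bimodal
stall distributions (a stalled subpopulation against a running one) are
summarised, not modelled. The trend test treats per-hour medians as
homoscedastic observations, as the original analysis does.
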