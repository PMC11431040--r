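---
title: "Mapping mRNA degradation at single-nucleotide resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mRNA degradation at single-nucleotide resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprtseq)
```

## The measurement model

mRNA degrades predominantly by in-line transesterification: a deprotonated
2′-hydroxyl attacks its own backbone phosphate and the chain breaks. A
reverse transcriptase extending a primer along a broken template falls off
at the break, so the length of each cDNA encodes a break position. With a
single primer this read-out covers only ~500 nt; tiling the molecule with
several 5′-labeled primers — each responsible for the section between its
own pairing site and the next primer 5′ of it — extends coverage to the
whole molecule.

The package's coordinate convention is fixed and shared between simulator
and reader: a break *at* position $p$ severs the bond 5′ of nucleotide $p$,
the downstream fragment begins at $p$, and an RT primer pairing at
$s..e$ inside that fragment yields a cDNA of length $s - p$. Reading a peak
table back therefore maps cDNA length $k$ to position $s - k$ exactly; the
round trip is the identity, which the tests exploit for every position of a
500-nt construct. Positions inside a primer's own pairing footprint, and
everything 3′ of the last pairing start (notably the poly(A) tail), are
reported as missing — they are unreadable, not zero.

## From peaks to a profile

Per-primer position maps are assembled under a *section map*: the 5′-most
primer owns positions $1..s_1-1$ and primer $i$ owns $s_{i-1}..s_i-1$.
Reads a primer produces outside its own section are discarded rather than
averaged — each section has one responsible primer, so section joins never
mix chemistries with different efficiencies.

Normalization uses the community-standard box-plot rule per section: the
top 2% of values are set aside as outliers and the mean of the next 8%
becomes the section's scaling factor, putting typical strong signals near
1. The factor table is recorded on the returned profile. Two behaviors are
worth knowing:

- Factors can be computed on one profile and *applied* to another
  (`normalization_factors()` + `normalize_profile(factors =)`). The
  pipeline computes factors on the pooled stress gradient of a regime and
  applies them to every treatment, so means remain comparable across doses
  — per-treatment factors would erase exactly the dose trend the method is
  meant to show.
- On sparse count data (few molecules, low dose) the trimmed top mean can
  be degenerate; with `robust = TRUE` an all-zero section gets factor 1 and
  a section whose positives all fall in the excluded 2% falls back to the
  mean of its positive values. The strict variant errors instead, naming
  the section.

Control subtraction is per-position; negative differences are clamped to
zero (degradation cannot be negative) and the clamp count is kept on the
result.

## The baseline and hotspot calls

High intensity is defined against a rescaled average line
$IA(N) = A (1+q)^N$, where $A$ is the regime's total average degradation
reactivity over its whole stress gradient, $q$ a small dimensionless
rescale factor, and $N$ the 1-based nucleotide position. The reference
parameters bundled with the package are $A = 3.5$, $q = 10^{-6}$ for
freeze–thaw cycling and $A = 8.8$, $q = 3.5\times10^{-4}$ for 37 °C
incubation. A position is high strictly above the line; ties are low. When
the pipeline classifies its own simulated profiles it keeps the configured
$q$ but derives $A$ from the data (the mean over the regime's
control-subtracted gradient), because the configured $A$ values live on the
instrument scale while classification happens on the pipeline's normalized
scale.

The published description of degradation-sensitive regions — a handful of
short runs of successive high nucleotides recurring in both stress regimes,
sometimes with low-reactivity bases inside — is descriptive rather than
algorithmic. The caller operationalizes it as: per condition, merge high
positions at most `max_gap` nt apart into runs (default 3, allowing the
observed interior dips); intersect-merge overlapping runs across
conditions; require at least `min_high` high positions per required
condition (default 2, so isolated single-position spikes never become
calls); clip each call to its outermost high positions. Both parameters are
exposed. With the reference fixture — planted high reactivity at the four
canonical loci in both regimes — these defaults return exactly four calls.

Fold changes divide a window's mean reactivity by an explicit reference
average. The reference is always an argument, never inferred: regimes have
both gradient-wide averages and window-specific ones, and silently guessing
which applies would be worse than asking.

## Structure context

Dot-bracket input is stack-parsed (pseudoknot bracket types are rejected
outright rather than mis-parsed). Every position gets exactly one element
label: paired positions are `stem_5prime`/`stem_3prime` by whether they
pair downstream or upstream; unpaired positions are labeled by the loop
that directly contains them — hairpin loop (no enclosed helix), bulge (one
enclosed helix, unpaired bases on one strand), internal loop (one helix,
both strands), multiloop (two or more helices), exterior. The
implementation is a single linear pass; the test suite checks it against an
independent brute-force loop decomposition on *every* balanced dot-bracket
string up to length 12 (24,870 structures), plus a mirror-symmetry
property.

Hotspot annotation walks the helix stack inward from the hotspot's
innermost base pair, crossing bulges and internal loops until a hairpin
loop or a multiloop ends the walk. It reports whether the hotspot sits
mostly on the 5′ strand, whether the stack terminates in an apical loop,
and whether a bulge/internal loop interrupts the stack between the hotspot
and that loop (or within the hotspot span), along with nucleotide distances
— the distance is reported rather than thresholded, because how far a bulge
may sit and still count as "mid-stem" is a judgment call best left to the
analyst.

## CE integrity

Migration time is calibrated to size by piecewise-linear interpolation in
log(size) through the marker table (mobility is roughly linear in log
length), with linear extrapolation beyond the markers. Integrity is the
percentage of trapezoidal trace area inside the main-peak window, 2100–3300
nt by default for the ~2.9-knt reference construct; the average fragment
size is the area-weighted mean. Signal below 100 nt is excluded from both
numerator and denominator so the alignment-marker peak (20 nt) cannot
deflate integrity; the floor is configurable. Baseline correction is a
rolling-minimum subtraction with the window recorded on the result — the
vendor algorithm is proprietary, so the package uses this openly specified
analogue and makes no claim of numerical equivalence to instrument
software.

## The simulator and what it does (not) show

The simulator generates the statistical structure the analysis assumes,
not the chemistry. Per molecule, the number of breaks is Poisson with mean
`per_event_rate × dose`; break sites are drawn proportional to a
per-nucleotide propensity that multiplies three factors: base identity
(default `A = 1.2, C = 4, G = 2, U = 1`, encoding the C > G > A ≈ U
sensitivity ordering), structural context (paired positions 0.35, loops 1 —
pairing shields the 2′-OH), and planted hotspot multipliers. Reverse
transcription is ideal: every cDNA reaches the fragment 5′ end, so the
read-out is exactly invertible and noise enters only through an explicit
Gaussian `noise_sd`. Electropherograms are the mass-weighted fragment
length histogram under a Gaussian sizing kernel (default 25 nt).

Default event rates were chosen once: 0.008 expected breaks per molecule
per freeze–thaw cycle and 0.005 per hour at 37 °C, so that the zero-to-top
dose ladders span roughly the single-digit-percent integrity decline that
bulk CE shows for constructs of this size, with the thermal regime the more
damaging at its top dose. The dose ladders themselves are 5/10/20 cycles
and 24/48 h, and validation runs use 10,000 molecules per sample with five
seed replicates where sampling error matters; these sizes keep every
property check well resolved while the whole suite stays quick.

What passing tests show: coordinate bookkeeping is exact; normalization is
scale-invariant and order-preserving; integrity is non-increasing and mean
reactivity non-decreasing in dose; planted ten-fold hotspots are recovered
with zero misses. What they do not show: anything about RT processivity
artifacts, signal decay along real traces, sequence-dependent primer
efficiency, RNase or radical chemistry at 37 °C, or instrument smear
algorithms — real data carry all of these, and the simulator deliberately
carries none. The background cleavage model also produces many
above-average positions, so on simulated data the caller reports planted
regions *among* other calls rather than uniquely; specificity on real data
depends on the baseline parameters and the stress contrast, not on the
caller alone.

## Reproducibility and degenerate inputs

All randomness flows through explicit integer seeds (`withr::with_seed`),
so a pipeline run with the same configuration and seed reproduces every
numeric table byte-for-byte; the report embeds the seed and a config hash.
Degenerate inputs fail loudly and specifically: all-zero propensity with a
positive rate, cDNA lengths at or past the pairing start, unbalanced
brackets (with position), non-monotone size markers, zero-area traces,
all-missing windows. The one deliberate silence: a fragment that does not
contain a primer's full pairing site simply contributes nothing to that
primer, which is what the chemistry does.
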