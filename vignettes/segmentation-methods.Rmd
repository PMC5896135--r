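---
title: "Significance-ranked segmentation of genomic signal profiles: methods and design"
author: "segscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance-ranked segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscan)
```

## The problem and the model

Many genomic assays reduce to a long one-dimensional profile: one numeric
value per fixed-width bin along a chromosome. Copy-number arrays produce
log-ratio profiles, and differential nuclease-sensitivity (DNS) sequencing
produces signed difference tracks (light-digest minus heavy-digest read
density) in which both positive "peaks" and negative "valleys" are
biologically meaningful. The segmentation task is to find the regions whose
mean differs from the background level, ranked by statistical significance.

`segscan` models the profile as $N$ independent measurements
$X_1, \dots, X_N$ with

$$X_k \sim \mathcal{N}(\mu_0, \sigma^2) \text{ for background bins}, \qquad
  X_k \sim \mathcal{N}(\mu_i, \sigma^2) \text{ inside segment } i,$$

with $\mu_i \neq \mu_0$ and a common, unknown $\sigma$. The independence
assumption is shared with most mean-shift segmentation methods; it is an
idealization of real tracks (see *Limitations*).

### Robust noise estimation and the z-test

The one-sample $t$ statistic $t = \bar{x}\sqrt{n}/s$ cannot score segments
of length 1, and a separate single-point statistic would not be consistent
with the multi-bin one. `segscan` therefore estimates $\sigma$ once,
globally, with the median absolute deviation,

$$\widehat{\sigma} = 1.4826 \times \mathrm{median}\,|x_i - \mathrm{median}(\boldsymbol{x})|,$$

and then treats it as known, so every segment — down to a single bin — is
scored with the same z statistic

$$z = \frac{(\bar{x} - \mu_0)\sqrt{n}}{\widehat{\sigma}}, \qquad
  p = 2\,\Phi(-|z|).$$

Two design points deserve comment:

* **The consistency constant.** The MAD definition alone estimates the
  scale of the absolute deviations; the factor 1.4826 makes
  $\widehat{\sigma}$ estimate the SD of the Gaussian background. Because
  the MAD is a median-based statistic it is unaffected by sparse signal
  regions, which is what makes a single global estimate workable. With
  dense signal (a large fraction of bins inside segments) the estimate
  inflates somewhat; the simulations below quantify the effect indirectly.
* **Sidedness.** The default test is two-sided, so enriched and depleted
  segments are found in one pass — essential for signed DNS-style tracks.
  One-sided modes (`alternative = "greater"`/`"less"`) are available when
  only one direction is of interest.

A profile with MAD 0 (more than half the bins identical) has no usable
robust scale; `estimate_noise()` refuses it and asks for an explicit
`sigma` rather than guessing.

### The multi-scale scan

All windows of all lengths is an $O(N W_{\max})$ family; `segscan` prunes
it two ways, following the standard multi-scale scan design:

* **Geometric window ladder.** Window lengths are the deduplicated
  ceilings of $W_{\min}\rho^i$ while the un-rounded length stays within
  $W_{\max}$ (defaults $W_{\min} = 1$, $W_{\max} = 300$, power factor
  $\rho = 1.1$). Ceiling-plus-dedup is the natural way to map the
  multiplicative ladder onto integer bin counts and matches the rounding
  convention used for window spacing.
* **Overlapping windows with spacing $\lceil W/5 \rceil$.** Each ladder
  rung slides in steps of a fifth of the window length, so every bin is
  covered by several phases of every length. Window starts are multiples
  of the step plus one extra window flushed against the right profile
  edge; without the flush, up to step−1 trailing bins would never be
  scanned at that length.

Running sums make each window mean an $O(1)$ lookup: with
$S_k = \sum_{i \le k} x_i$ precomputed, the mean of $[i, j)$ is
$(S_j - S_i)/(j - i)$. Sums of squares are kept alongside for
diagnostics, but the tests themselves always use the global
$\widehat{\sigma}$ — that choice is exactly what makes single-point and
long-segment scores comparable.

Windows with $p \le p_s$ enter the candidate pool. The default
$p_s = 0.001$ is the per-test Bonferroni level for 100 simultaneous
tests at family-wise level 0.1 (and a slightly conservative bound for
the Sidak level); it is a permissive pre-filter, not the final
significance criterion.

### Selecting non-overlapping segments

Candidates are ranked by p-value and accepted greedily: the most
significant candidate is kept, and any candidate overlapping a previously
accepted one is discarded. The classical implementation couples two
balanced binary trees (a p-value-ordered pool and a boundary store); the
contract that matters is the greedy result plus logarithmic-cost overlap
queries, which `segscan` meets with a binary-searched sorted boundary
vector (`accepted_index()`). A test asserts exact behavioral equivalence
with a quadratic reference implementation.

Two details are implementation choices:

* **Tie-breaking.** The p-value order is completed to a deterministic
  total order by larger $|z|$, then longer length, then smaller start.
  The $|z|$ key matters in practice: for $|z| \gtrsim 39$ the two-sided
  p-value underflows double precision (it is clamped to the smallest
  positive double), and $|z|$ still ranks such candidates correctly.
* **Discard, not re-score.** A candidate rejected for overlap is dropped;
  its p-value is not recomputed on the residual data. Re-scanning after
  each acceptance would change the complexity class for no demonstrated
  accuracy benefit.

### Refinement and merging

Scan windows land near, not on, the true boundaries. Each accepted
segment is refined — expand left, expand right, then shrink, looping to a
fixed point — with every single-bin move required to *strictly* decrease
the p-value (equivalently, increase $|z|$, which is how it is computed, so
underflowed p-values cannot stall the comparison). Strict improvement
gives termination for free: the score increases at every move, so no
state repeats, and expansion is bounded by the profile ends and the
current boundaries of neighboring segments, so disjointness is preserved.
Segments are processed most-significant-first, letting strong segments
claim contested territory before weak ones.

Merging then repairs over-fragmentation: for each adjacent pair whose gap
is at most `max_merge_gap` bins (default 0 — strictly consecutive, the
recommended setting for DNS difference tracks), the union span including
the gap bins is scored, and the pair is merged iff the union beats both
members. A new merged segment is immediately re-tested against its
neighbors, and passes repeat until a full pass makes no merge, so the
operation is idempotent. Under the two-sided test, opposite-sign
neighbors can never qualify (their sums partially cancel), so the
optional `merge_same_sign_only` flag is a belt-and-braces guard for
one-sided analyses rather than a behavioral change in the default
configuration.

### FDR control and the choice of denominator

The final segment list receives a Benjamini–Hochberg step-up filter at
`fdr_alpha` (default 0.01): sort p-values, find the largest $k$ with
$p_{(k)} \le k\alpha/m$, keep everything at or below $p_{(k)}$.

The denominator $m$ is the one genuinely open design decision, and
`segscan` resolves it in favor of the family of tests actually performed:
by default $m$ is the **number of windows scored during the scan**
(`bh_denominator = "scanned"`). The alternative — $m$ = the number of
final segments entering the filter — is exposed as an option but is
vacuous as a default: every final segment already has
$p \le p_s = 0.001 < \alpha$, so with $m$ equal to the segment count the
step-up condition is satisfied at $k = m$ and the filter never removes
anything. Multiple-comparison control that scales with the length of the
profile is the stated purpose of the FDR step, and only the test-count
denominator delivers it; the null-calibration simulation below is the
empirical check (pure-noise profiles essentially never emit calls under
the default, and essentially always would under the vacuous variant).
When a multi-chromosome file is segmented through the command-line
interface, one joint B–H correction is applied across all chromosomes of
the invocation, since FDR is a per-experiment guarantee.

### Biological-cutoff tiers

Statistical significance is not effect size: a 300-bin segment 0.3 SD
above background can be overwhelmingly significant yet biologically
uninteresting. The biological cutoff annotates each segment with the
tiers $bc \in \{1.0, 1.5, 2.0, 3.0\}$ (defaults) it passes, where passing
means $|\bar{x} - \mu_0| > bc \cdot \widehat{\sigma}$, strictly,
regardless of length. Tiers are nested by construction, and the BED
output writes one track per tier plus the unfiltered list.

## The synthetic-profile generator

`simulate_profile()` reproduces the simulation design the method is
benchmarked under: Gaussian background of mean 0 and SD 1, with planted
disjoint segments whose bins are $\mathcal{N}(\text{base mean} \times
\text{SNR}, 1)$. SNR is thus the planted mean in units of the noise SD —
the simplest reading of "normalized to an approximate signal-to-noise
ratio" — with 0.5, 1.0 and 2.0 representing poor, realistic and
best-case regimes.

The default short fixture is a length-5000 profile with six planted
segments of base means 0.72, 0.83, 0.76, 0.9, 0.7 and 0.6. Segment
locations and lengths are not part of the published design, so they are
implementation-chosen and fixed: lengths 100, 200, 150, 300, 50 and 1,
spread across the profile, with the two largest means assigned to the
two longest segments so that the poor-SNR regime retains detectable
signal, and one single-bin segment to exercise the length-1 code path
(at these SNRs a lone bin of height ≤ 1.8 is undetectable by any method
controlling false positives; it is there to exercise coordinates, not to
be found). The long fixture is a length-100,000 profile with seven
segments placed sparsely (~1.5% of bins carry signal), the sparse-signal
regime the multi-scale scan is designed for.

What the generator does **not** emulate — and therefore what passing
simulations do not demonstrate about real tracks: autocorrelated noise
(read-count smoothing, GC waves), heavy-tailed or skewed backgrounds,
within-segment variance changes, baseline drift, and mappability gaps.
The model-based z-test inherits the i.i.d. Gaussian assumption; on real
data the practical mitigations are the robust global scale estimate, the
biological-cutoff tiers, and the FDR layer, not the test itself.

## Numerical and degenerate-input choices

* p-values are clamped to the smallest positive double on underflow;
  every ordering or comparison that could hit the clamp is performed on
  $|z|$ (or signed $z$ for one-sided tests) instead.
* BED scores are $-10\log_{10} p$ computed on the log scale (so extreme
  segments do not saturate at the underflow boundary prematurely),
  clamped to [0, 1000].
* A constant-majority profile (MAD 0) is an error, not a silent fallback.
* Missing bins are an error by default; `na_action = "fill"` imputes
  $\mu_0$ explicitly, and bedGraph gaps are padded the same way only
  under that flag.
* Zero-length intervals, overlapping planted intervals, and overlapping
  segment sets handed to the writers all raise immediate contract errors.
* Window lengths are capped at the profile length; a profile shorter
  than $W_{\min}$ is still scanned by the flush window at each capped
  length.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on ten length-5000 profiles per
SNR regime, 200 pure-noise length-5000 profiles for null calibration,
one length-100,000 profile for the sparse long-profile setting, and an
11-profile synthetic copy-number panel for the consensus-gold-standard
workflow; oracle-equivalence checks use 1000 random segments, 1000
overlap queries, 100 random candidate pools and 1000 random p-vectors.
These sizes were chosen to exercise every regime of interest at
interactive runtimes; all of them scale linearly if larger checks are
wanted.

## Limitations

* The i.i.d. Gaussian background is the model; heavy autocorrelation
  will inflate the effective number of discoveries at a given FDR.
  Pre-binning (e.g. 20-bp windows) absorbs some but not all of it.
* The greedy independent set maximizes significance locally, not a
  global objective; a slightly weaker candidate that would tile the
  signal better can be displaced by a stronger overlapping one (the
  refinement step exists largely to repair this).
* Boundary refinement is a strict local search; a single unfavorable
  noise bin at a boundary stops it, so boundaries are typically within a
  few bins of truth rather than exact at moderate SNR.
* The scorer interface is Gaussian-only by design; count-based scorers
  (Poisson, negative binomial) would slot into `score_segment()`'s
  position but are deliberately out of scope.
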