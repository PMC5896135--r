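# segscan

Significance-ranked segmentation of long one-dimensional genomic signal
profiles: per-bin tracks such as aCGH/copy-number log-ratios, binned
read-count coverage, and signed differential nuclease-sensitivity (DNS)
difference tracks where both positive peaks and negative valleys matter.
`segscan` finds the non-overlapping regions whose mean differs from the
background, ranked by statistical significance, and annotates them with
FDR control and effect-size tiers. It is written for analysts who already
have a binned signal (bedGraph or one value per line) and want ranked,
browser-ready segment calls.

## Method at a glance

The profile is modeled as independent Gaussians with a common SD: bins in
the background follow N(mu0, sigma^2) and bins inside segment *i* follow
N(mu_i, sigma^2), mu_i != mu0. The noise SD is estimated once, robustly,
via the median absolute deviation,

    sigma_hat = 1.4826 * median(|x - median(x)|),

and then treated as known, so every candidate segment — down to a single
bin — is scored with the same z-test:

    z = (mean - mu0) * sqrt(n) / sigma_hat,    p = 2 * Phi(-|z|).

The pipeline is:

1. **Multi-scale scan.** Window lengths grow geometrically from `w_min`
   (1) to `w_max` (300) by power factor `rho` (1.1); each length slides
   in steps of `ceiling(W/5)` with prefix-sum (running-sum) means, so
   every window mean is an O(1) lookup. Windows with p <= `p_s` (0.001)
   become candidates.
2. **Greedy selection.** Candidates are ranked by p-value; each is
   accepted iff it overlaps no previously accepted segment, with
   overlap queries answered in logarithmic time by a sorted boundary
   index.
3. **Refinement and merging.** Boundaries expand and shrink one bin at
   a time while the p-value strictly decreases; adjacent segments (gap
   <= `max_merge_gap`, default 0) merge when their union is more
   significant than both members, iterated to a fixed point.
4. **FDR and effect-size tiers.** A Benjamini–Hochberg step-up filter at
   `fdr_alpha` (0.01) controls the false discovery rate over the family
   of tests performed in the scan, and each surviving segment is
   annotated with the biological-cutoff tiers (`bc` = 1.0/1.5/2.0/3.0)
   it passes: |mean − mu0| > bc × sigma_hat.

The methods vignette (`vignettes/segmentation-methods.Rmd`) documents the
model, every tunable, and the design decisions in detail.

## Worked example

```r
library(segscan)

sim <- simulate_profile(short_profile_spec(snr = 2, seed = 1))
res <- segment_profile(sim$profile, verbose = TRUE)
#> scan: 59050 windows scored, 5958 candidates at p_s = 0.001
#> selection: 8 non-overlapping segments
#> refine+merge: 6 segments
#> B-H filter: 5 segments at alpha = 0.01 (m = 59050, cutoff = 9.12e-21)
#>   bc 1.0: 5 segments
#>   bc 1.5: 1 segments
#>   bc 2.0: 0 segments
#>   bc 3.0: 0 segments

res
#> <segscan_result 'sim_n5000_snr2_seed1': 5 segments>
#>   sigma_hat = 1.147, mu0 = 0, 59050 windows scored, B-H cutoff 9.12e-21
#>   tier counts: bc1.0=5, bc1.5=1, bc2.0=0, bc3.0=0
#>   start  end   n     mean         z             p
#> 1   501  600  99 1.343599 11.659133  2.061313e-31
#> 2  1200 1425 225 1.540196 20.148660  2.764958e-90
#> 3  2001 2147 146 1.524271 16.062668  4.660678e-58
#> 4  2800 3103 303 1.772784 26.912631 1.562700e-159
#> 5  3700 3750  50 1.515496  9.345846  9.115761e-21

f1_score(res, sim$truth, 5000)[c("precision", "recall", "f1")]
#> $precision [1] 0.9659773
#> $recall    [1] 0.9925094
#> $f1        [1] 0.9790637
```

Reading the output: the simulated profile plants six segments (base
means 0.72–0.9, doubled at SNR 2) in unit-variance noise. The scan
scores ~59k windows, keeps 5958 sub-threshold candidates, and greedy
selection plus refinement/merging reduces them to five disjoint
segments — the five plantings longer than one bin, each recovered within
a few bins of its true boundaries (the planted single-bin segment of
height 1.2 is statistically undetectable by design). All five clear the
FDR filter and the 1-SD biological cutoff; one also clears 1.5 SD.
Bin-level F1 against the ground truth is 0.979.

`write_segments(res, sim$profile, "calls")` writes `calls.bed` plus one
BED per tier (`calls.bc1.0.bed`, ...), with strand `+`/`-` marking
enrichment/depletion and score `-10*log10(p)`.

The same pipeline is available from the shell via the installed script
(`system.file("cli", "segscan.R", package = "segscan")`), with
subcommands `segment`, `simulate`, `evaluate`, and `consensus`, and flag
names matching the scan parameters (`--minwl --maxwl --pf --ps --fdr
--bc --maxgap`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","segscan.R",package="segscan"))')
Rscript $CLI simulate --length 5000 --snr 2 --seed 1 --out sim
Rscript $CLI segment  --input sim.bedgraph --out calls
Rscript $CLI evaluate --calls calls.bed --truth sim.truth.bed --input sim.bedgraph
#> precision  0.965978
#> recall     0.992509
#> f1         0.979064
```

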