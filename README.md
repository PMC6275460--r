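# depthscan

Detection of under- and over-covered genomic regions of interest (ROIs) in
per-base coverage tracks, with robust per-base statistics, adaptive
thresholds, and copy-number estimates.

## Who this is for

Anyone with a mapped high-throughput sequencing sample who wants to know
*where* the genome coverage departs from its expected level and *how
confidently*: deleted genes, duplications and CNVs, collapsed repeats,
depleted regions. Input is the 3-column per-base dialect written by
`bedtools genomecov -d` (chromosome, 1-based position, coverage); circular
chromosomes (plasmids, most bacterial genomes) and multi-chromosome files
are handled. BAM files are converted externally
(`bedtools genomecov -d -ibam sample.bam > sample.bed`).

## The method

Let `C_b` be the coverage at base `b`. Naive fixed thresholds fail on real
tracks because coverage carries trends (e.g. the bow shape induced by the
origin of replication) and because an arbitrary cutoff carries no
significance. Instead:

1. **Detrend** with a running median over `W` bases (default 20,001;
   window wraps on circular chromosomes). The median ignores atypical
   stretches shorter than `W/2` — exactly the events being sought — where a
   moving average would be dragged by them. Normalized coverage:
   `C̃_b = C_b / RM_W(b)`, centred on 1.
2. **Fit** a `k = 2` Gaussian mixture to `C̃_b` by EM. The dominant
   component `N(μ̃₀, σ̃₀²)` is the central distribution; each base gets
   `z(b) = (C̃_b − μ̃₀)/σ̃₀`. Equivalently, in the original space the
   thresholds become the adaptive curves `(μ̃₀ ± n·σ̃₀)·RM_W(b)`.
3. **Cluster** with a double threshold: a cluster extends while
   `|z| ≥ m = α·n` (defaults `n = ±4`, `α = 1/2`) and is reported if its
   extremum reaches `n`. Each ROI carries mean/max z, mean coverage, mean
   RM, and the copy-number ratio `CN ≈ mean_cov / mean_RM` with its log2.

A simulator (Poisson or read-placement noise, optional bow trend, injected
deletions/duplications at chosen copy numbers) supports validation of every
stage; see the vignette `vignettes/coverage-roi-detection.Rmd` for the
model, parameter guidance and limitations.

## A worked example

Simulate a 20 kb circular plasmid sequenced at 1000X with two clean
deletions (700 and 800 bases), then analyze it with a 4,001-base window:

```r
library(depthscan)
spec <- simulation_spec(G = 20000, depth = 1000, noise = "poisson",
                        circular = TRUE,
                        events = data.frame(start = c(5001, 14001),
                                            end = c(5700, 14800), cn = 0))
tr <- simulate_coverage(spec, seed = 81)
res <- analyze_track(tr, W = 4001)
res$stats
#> Coverage summary over 20000 bases
#>   DOC 924.88X (median 996), sigma 265.08, CV 0.287, BOC 0.9250
#>   centralness 0.9250 (W = 4001)
res$fit
#> Gaussian mixture fit (k = 2, EM, 3 iterations)
#>   central: mu0 = 1.0035, sigma0 = 0.0318, pi0 = 1.0000
#>   outlier: mu1 = 0.8869, sigma1 = 0.0060, pi1 = 0.0000
res$rois[, c("start", "end", "size", "side", "mean_zscore", "cn_ratio")]
#>   start   end size side mean_zscore cn_ratio
#> 1  5001  5700  700  low    -31.5929        0
#> 2 14001 14800  800  low    -31.5929        0
```

Both deletions come back as low-side ROIs with exact breakpoints; the
depth of coverage (924.9X vs the nominal 1000X) and breadth of coverage
(0.925) reflect the 1,500 deleted bases. `write_roi_csv()` and
`write_summary_json()` export the per-chromosome outputs. The same
pipeline is scriptable from the shell:

```sh
Rscript inst/scripts/depthscan --input sample.bed -w 4001 -o --output-dir results/
```

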