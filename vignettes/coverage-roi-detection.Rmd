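---
title: "Detecting under- and over-covered genomic regions with depthscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting under- and over-covered genomic regions with depthscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthscan)
```

## The problem

Per-base genome coverage — the number of mapped reads over each reference
position $b$, written $C_b$ — carries biological signal beyond mapping
quality: deleted genes show up as holes, duplications and copy-number
variants (CNVs) as plateaus of excess depth, and repetitive or biased
regions as systematic dips. Two obstacles make naive fixed-threshold
screening unreliable. First, coverage is rarely flat: rapidly dividing
bacteria show a smooth "bow" trend from the origin of replication, so any
fixed pair of cutoffs misclassifies both ends and middle of the chromosome.
Second, fixed cutoffs carry no significance: an event 3 standard deviations
out and one barely past an arbitrary line look the same.

`depthscan` addresses both with a three-stage pipeline:

1. **Detrend** the coverage with a running median (RM) over a window of
   $W$ bases and normalize, $\tilde C_b = C_b / \mathrm{RM}_W(b)$.
2. **Model** the normalized coverage with a two-component Gaussian mixture
   fitted by EM; the dominant component
   $\mathcal N(\tilde\mu_0, \tilde\sigma_0^2)$ is the *central
   distribution*, and each base gets a z-score
   $z(b) = (\tilde C_b - \tilde\mu_0)/\tilde\sigma_0$.
3. **Cluster** threshold-crossing bases into regions of interest (ROIs)
   with a double-threshold (hysteresis) rule, and annotate each ROI with
   robust statistics (mean/max z, mean coverage, copy-number ratio).

## Detrending: why the running median

A moving average is dragged by the very events we want to detect: a long
deletion pulls the local mean down, which both masks the deletion's own
boundaries and produces false positives in its flanks. The median of a
window is unaffected by an atypical stretch occupying less than half the
window, so the RM tracks the slow trend while ignoring events shorter than
$W/2$. This dictates the window policy: $W$ should exceed twice the longest
event expected. The default is $W = 20\,001$ for chromosomes longer than
100 kb and one fifth of the chromosome length (forced odd) below that;
`default_window()` implements the policy. Fitted parameters are stable over
a wide range of $W$ (the test suite checks $\tilde\mu_0$ moves by < 0.5%
and $\tilde\sigma_0$ by < 10% between $W$ = 5,001 and 100,001 on a 1 Mb
Poisson track), so the choice mainly trades off the longest detectable
event against trend fidelity. Running two passes (one small, one large $W$)
is a sensible strategy when event lengths are unknown.

The RM is computed with an incremental two-multiset order-statistic window
(O($N \log W$) overall) whose output is exactly the naive sorted-window
median at every position — the test suite asserts bit-identical agreement
with a brute-force oracle over randomized series, linear and circular.
Circular chromosomes wrap their windows; on linear chromosomes the edge
windows are truncated to the available bases rather than left undefined, so
detection covers the full chromosome (users who prefer the conservative
behaviour can mask the first and last $(W-1)/2$ positions). Truncated
windows can hold an even number of points, in which case the two central
order statistics are averaged.

Where the RM itself is zero (long, fully deleted regions) the normalized
coverage is undefined; those bases are flagged, excluded from model
fitting, and force-classified as low-side candidates (sentinel
$z = -\infty$). Bases where $\tilde C_b = 0$ but the RM is positive are
*also* excluded from the fit — they are deleted bases, not draws from the
central distribution — but they keep their finite z-score
$-\tilde\mu_0/\tilde\sigma_0$, which is what makes deletions filterable by
mean z downstream.

## The mixture model

For depths well above ~10X the central part of $\tilde C_b$ is close to
Gaussian, but the track as a whole is a mixture: deletions, duplications
and other events contribute mass far from 1. Fitting a single Gaussian
would inflate $\tilde\sigma_0$; instead a $k = 2$ mixture is fitted by EM,
with the central component taken as the one whose mean is nearest 1 (ties
broken toward the larger weight). Only $\tilde\mu_0$, $\tilde\sigma_0$ and
the weight $\tilde\pi_0$ matter downstream; the outlier component exists to
absorb what should not contaminate the central fit, and the working
hypothesis is $\tilde\pi_0 \gg \tilde\pi_1$.

Numerical choices:

* **Initialization.** $\tilde\mu_0$ starts at the median and
  $\tilde\sigma_0$ at $1.4826\,\mathrm{MAD}$ — robust estimates that are
  already close to the answer when the central distribution dominates. The
  outlier component starts at the mean of the points beyond
  $\tilde\mu_0 \pm 3\tilde\sigma_0$ *provided that mean itself lies outside
  the central region*; otherwise at 0.5, the typical location of depleted
  events. The proviso matters: on an event-free track the "far" points are
  just the two symmetric tails of the central distribution and their mean
  sits on top of $\tilde\mu_0$, so without it the second component starts
  inside the bulk and EM converges to a degenerate solution that splits the
  central distribution in two (several percent of null data assigned to the
  "outlier" component and $\tilde\sigma_0$ deflated by ~5%, which more than
  doubles the false-positive rate at the default thresholds). Starting the
  component outside the bulk lets its weight fall toward zero when there is
  nothing for it to model.
* **Convergence.** Absolute log-likelihood change below $10^{-6}$, at most
  200 iterations. The per-iteration likelihood trace is kept and tested for
  monotonicity.
* **Stability.** A floor of $10^{-6}$ on both standard deviations prevents
  component collapse; responsibilities are computed in log space.
* **Speed.** The likelihood is evaluated on a $2^{15}$-bin histogram of the
  values (weighted EM). The bin width is ~$10^{-3}\tilde\sigma_0$ at
  typical depths, and the induced error on the fitted parameters
  (relative $\sim 10^{-7}$) is far below their statistical uncertainty.

Because the z-score is an affine function of $\tilde C_b$, the original
coverage is recoverable exactly:
$C_b = (\tilde\mu_0 + z(b)\,\tilde\sigma_0)\,\mathrm{RM}_W(b)$, and the
fixed z-thresholds map back to position-dependent coverage thresholds
$(\tilde\mu_0 \pm n\,\tilde\sigma_0)\,\mathrm{RM}_W(b)$ — adaptive in the
original space, constant in the normalized one.

Two analytic companions put the thresholds in context:
`tolerance_interval(n)` $= \mathrm{erf}(n/\sqrt 2)$ is the central normal
mass within $\pm n$ (99.73% at $n=3$), and `expected_chance_outliers(G, n)`
is the count of bases expected beyond $\pm n$ by chance alone — about 2,700
per Mbp at $n = 3$, which is why the default outer threshold is $n = 4$
(~63 chance bases per Mbp) rather than 3. The *centralness*
$\Theta_n = 1 - \#\{|z| \ge n\}/G$ summarises how dominant the central
distribution is; values below 0.5 void the model's premise and trigger a
warning.

## Double-threshold clustering

A single threshold fragments one biological event into many short
crossings. The hysteresis rule uses an inner threshold $m = \alpha n$
(default $\alpha = 1/2$, so $m = \pm 2$): scanning left to right, a cluster
opens when $z$ reaches $m$, extends while it stays beyond $m$, and is
reported only if its extremum reaches $n$. Ties at exactly $m$ belong to
the cluster — deterministic and errs toward inclusion. High- and low-side
scans run independently and cannot claim the same base since
$m^+ > 0 > m^-$.

On circular chromosomes the scan starts from a position quiet on the
scanned side, so an event spanning the origin is reported once; its `end`
coordinate may exceed the chromosome length and is understood modulo $G$.
If no quiet position exists the whole chromosome is a single candidate
cluster. This makes detection invariant under rotation of the origin
(tested).

Each ROI records the signed extremum of $z$ ("max z" is the most negative
value for low-side events), the mean z over bases with defined
normalization, mean/max coverage, mean RM, and the copy-number ratio
$\widehat{\mathrm{CN}} = \overline{C}/\overline{\mathrm{RM}}$ with its
$\log_2$. No length-adjusted significance is computed for long events —
consecutive bases are strongly dependent, so the mean and max z are
reported as-is.

For copy-number screening, the filter `filter_rois(min_mean_z = 5,
min_size = 100)` removes events explainable by counting noise alone; the
bounds come from the null experiment below. In plain ROI mode no filter is
applied.

## The simulator and what it does (not) emulate

`simulate_coverage()` generates study-condition tracks: a 3 Mb circular
chromosome at 100X is the canonical validation setting, mirroring a
bacterial sequencing run. Three noise models are available: `"poisson"`
(independent per-base counts — the Lander–Waterman idealization),
`"read_placement"` (uniform random placement of 100 b reads, by default as
fragment pairs with insert $350 \pm 30$ b, which reproduces the short-range
autocorrelation of real mapped coverage), and `"none"` (noise-free, for
exact tests). A `bow` trend emulates the origin-of-replication shape, and
`inject_events()` adds deletions ($\mathrm{cn}=0$), binomial thinning
($\mathrm{cn}<1$) or Poisson duplication ($\mathrm{cn}>1$). Injection sites
are drawn uniformly with overlap rejection and a guard gap of half the
running-median window, the resolvability condition of the detrending
stage: a window whose atypical content exceeds $W/2$ collapses the median
and fuses neighbouring events.

The simulator deliberately omits mapping artifacts: GC bias, repeats,
mappability holes, chimeric pairs. Passing the validation suite therefore
demonstrates the statistical machinery — detrending, fitting, clustering,
CN estimation — under clean counting noise, not robustness to
alignment pathology on real genomes. Two consequences are worth knowing.
First, real tracks usually carry *more* structure than the null model, so
observed false-positive counts on real data exceed the simulated ones.
Second, the chance-event regime is exquisitely sensitive to the fitted
$\tilde\sigma_0$: at $n = 4$, a few percent change in $\tilde\sigma_0$
moves the expected count of chance ROIs by a factor of ~2, and the
chance-cluster *lengths* scale with the noise autocorrelation length. Under
idealized uniform placement we observe on the order of 20–30 chance ROIs
per 3 Mb null replicate with maximum cluster lengths occasionally in the
100–350 b range; coverage derived from a full read simulator plus mapping
yields somewhat fewer and shorter chance clusters. The CNV filter bounds
(mean z ≥ 5, length ≥ 100) sit well above the mean-z regime of chance
events in either case, but length alone should not be relied on as the only
guard under idealized noise.

## Validation problem sizes

The shipped tests and the acceptance script use: 100 event-free 3 Mb
replicates at 100X for the null experiment; 30 injected deletions and 80
injected duplications (lengths 1,000–8,000 b) for sensitivity, breakpoint
accuracy (≤ 5 b) and CN recovery; 200 randomized series for the
running-median oracle sweep; 20 seeded mixtures of $10^5$ points for EM
parameter recovery; and a 20 kb, 1000X circular plasmid with two clean
deletions as the end-to-end fixture. These sizes were chosen to exercise
the method at realistic scale while keeping a full validation run in the
tens of minutes on one core.

## Known limitations

* Depths below ~10X break the Gaussian approximation of the central
  distribution; a negative-binomial mixture would be the appropriate
  extension and is not implemented.
* The CN estimate is a ratio of means; for events comparable in length to
  $W/2$ the RM itself begins to absorb the event and the estimate biases
  toward 1. Genome-wide duplication load also inflates the RM slightly (a
  12% duplicated genome shifts the window median by ~2%), which is visible
  as event-averaged CN estimates slightly below the injected value.
* Interval input (bedGraph), BAM parsing, GC-bias correction, per-gene
  aggregation and joint segmentation across samples are out of scope;
  coverage tracks are expected in the 3-column `bedtools genomecov -d`
  dialect.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(G = 20000, depth = 1000, noise = "poisson",
                        circular = TRUE,
                        events = data.frame(start = c(5001, 14001),
                                            end = c(5700, 14800), cn = 0))
tr <- simulate_coverage(spec, seed = 81)
res <- analyze_track(tr, W = 4001)
res$fit
res$rois[, c("start", "end", "size", "side", "mean_zscore", "cn_ratio")]
```

The two injected deletions come back as two low-side ROIs with breakpoint
errors of at most a few bases; `write_roi_csv()` and
`write_summary_json()` export the standard per-chromosome outputs, and the
`inst/scripts/depthscan` front end exposes the same pipeline on the shell.
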