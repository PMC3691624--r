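---
title: "Rank-based multi-sample detection of rare CNVs from aCGH cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based multi-sample detection of rare CNVs from aCGH cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical aCGH screening for constitutional disorders looks for *rare*
copy-number variants: a CNV present in at most about 1% of a patient cohort
is the primary candidate for pathogenicity, while common (polymorphic)
variation is almost always benign. Two artifacts make single-sample
segmentation unreliable at high resolution: the "wave" — a slowly varying,
genome-position-correlated oscillation of logratios whose pattern is shared
across samples — and per-probe experimenter/batch bias. Both push
segmenters into calling spurious breakpoints.

rareCGH analyses the whole cohort logratio matrix at once. The key
observation is that both artifacts act on a *probe column as a whole*:
every sample at a given probe is shifted by (approximately) the same
amount. Any statistic computed from the column-wise *ranks* of the matrix
is therefore exactly invariant to them, while a genuine rare CNV — one or
two samples departing from everyone else over a run of consecutive probes —
becomes more prominent, not less.

## The model

### Pseudo-ranks

For a cohort of $n$ samples, each logratio $L_{qs}$ (probe $q$, sample $s$)
is replaced by its pseudo-rank

$$R_{qs} = \frac{\operatorname{rank}(L_{qs} \text{ within column } q)}{n + 1} \in (0, 1).$$

Ties get midranks, which keeps every fully observed column summing to
$n/2$; missing cells are excluded and the denominator uses the observed
count, so the observed marginals stay uniform. Under the null each window
row is a point in the unit hypercube $(0,1)^k$ with uniform marginals — the
setting in which copulas describe the joint law; this package uses the
empirical-Beta route below rather than parametric copula fits, whose
mixture versions are high-dimensional and only locally identifiable.

### The windowed outlier statistic

For every window $Q$ of $k$ consecutive probes (default $k = 7$, sliding by
1, never crossing a chromosome) and every sample $s$, the statistic is the
mean $L_d$ distance to all samples' window vectors (default $d = 1$,
Manhattan; the zero self-term stays inside the mean):

$$\mu_d^s = \frac{1}{n} \sum_{j=1}^{n}
  \Big( \sum_{l \in Q} |R_{ls} - R_{lj}|^d \Big)^{1/d}.$$

A rare-CNV carrier has extreme ranks on all $k$ probes, so its vector sits
near a corner of the hypercube and its mean distance is large. For $k = 1$
and $d = 1$ the statistic has a transparent large-cohort limit: the mean
distance of pseudo-rank $z$ to a uniform crowd is
$\int_0^1 |t - z|\,dt = \tfrac{1}{2}\left(z^2 + (1-z)^2\right)$, i.e.
$2\mu^1(z) \to z^2 + (1-z)^2$ — exactly the sum of squared distances from
$z$ to the two extreme corners 0 and 1. `mu_closed_form_k1()` returns the
corner-distance form $z^2 + (1-z)^2$, and every limit check in the test
suite compares $2\mu$ against it; the factor two is purely a matter of
scale and cancels in everything downstream, because the null is fitted
after min–max rescaling. For $d = 1$ the statistic is a sum of independent
per-column contributions under the independence null, which is what
`simulate_independence_null()` samples; its $k$-window mean converges to
$k \cdot \tfrac{2}{3}$ on the corner-distance scale.

### The Beta null and markers

Within each window the cohort's own $\mu$ values define the null: they are
rescaled to $(0,1)$ over their observed range $[\min \mu, \max \mu]$ and a
$\mathrm{Beta}(\alpha, \beta)$ is fitted by the method of moments
(deterministic, no optimizer; the rescaled extremes land on 0/1 where the
Beta likelihood degenerates, so values are nudged inward by
$\varepsilon = 1/(2n)$ before moment matching). A `(sample, window)` pair
is a **marker** when its upper-tail p-value is strictly below 0.01 — the
1% tail mirrors the frequency that defines a rare CNV. Only the upper tail
is tested: outliers *maximize* mean distance, so a lower tail has no
interpretation here. No multiple-testing correction is applied across
windows — the raw 1% tail *is* the definition of the marker, not an
inference claim.

The Beta fit has a lighter tail than the exact independence null at small
$k$, so it is deliberately the less conservative choice; on an iid-normal
null cohort the realized marker rate sits near 2% rather than 1% (the
acceptance suite pins it inside a factor-two band of the nominal rate).
Degenerate windows — fewer than 8 observed values, zero range, or moments
incompatible with a Beta — yield no fit and therefore no markers. A sample
with a missing cell anywhere in a window is excluded from that window
entirely: it gets no statistic, contributes to no one's mean, and can
never be a marker there. This avoids imputation bias at the cost of a
slightly smaller effective cohort per window.

### Polymorphism filtering

Markers also fire in highly polymorphic regions, where the background
itself is far from the null. The cohort's segmentation is mapped back onto
probes (each probe inherits its segment's mean; probes in no segment carry
0 and never count), and probe $q$ is flagged polymorphic when strictly
more than $\max(1, \lfloor 0.01\,n \rfloor)$ samples have
$|\text{signal}| > 0.07$ there. Both comparisons are strict. The 0.07
log10 threshold is the conventional conservative aberration threshold of
0.24 on the log2 scale ($0.24 \log_{10} 2 \approx 0.07$);
`log2_to_log10_threshold()` performs the conversion. The floor is clamped
to 1 so that sub-100 cohorts still require at least two samples — a lone
outlier is by definition rare, not polymorphic. Runs of $k$ consecutive
flagged probes define polymorphic windows; by default markers are removed
when their window position is *in* that set (`"intersect"`), with an
`"overlap"` mode (any shared probe) available — the two exclusion
semantics are both defensible readings of the filtering rule, and the
stricter one is not assumed.

### Density score and candidates

Surviving markers are laid onto the segmentation (external SEG input, the
built-in plumbing segmenter, or segmentation-free marker clustering). For
each segment the **density score** is the percent of its probes covered by
the union of that sample's flagged windows; segments with no marker probe
are sieved out. Candidates must have density score strictly above 50% and
$|$segment mean$|$ strictly above 0.1, and are reported sorted by score. A
window straddling a segment boundary contributes exactly its in-segment
probes — coverage is counted per probe, the simplest reading of "percent
of the segment covered", and the one that needs no extra rule for
boundary windows.

### Annotation

Candidates are intersected with interval databases playing three roles:
pathogenic (ISCA-like), benign population variation (DGV-like) and disease
association (GAD-like). Any BED file can be registered under a role; the
package never fetches live databases. A segment with at least 3 benign-db
hits is labelled `common_dgv` regardless of other evidence; otherwise any
pathogenic/association hit yields `rare_candidate`, else `unsupported`.
The overlap rule defaults to any single base, with an optional reciprocal
fraction, since "significant intersection" has no canonical fraction.
`enrichment_curve()` evaluates how well the density-score ranking
concentrates known positives at the top of the list.

## The plumbing segmenter

`simple_segment()` exists so the pipeline runs without an external
segmentation; any SEG file takes precedence. It is a CBS-style recursive
scan: on each interval it finds the sub-segment maximizing the pooled
two-sample t statistic between segment and rest, Bonferroni-adjusts the
best p-value over all candidate segments, accepts when below `alpha`
(default 0.01) with at least `min_probes` (default 10) probes in both
segment and complement, and recurses into the parts. The segment-vs-rest
form matters: a plain left/right breakpoint statistic dilutes a short
interior CNV into the flank average and misses 30-probe events that the
circular form isolates with $t \approx 15$. Degenerate (piecewise
constant) intervals are handled with scale-aware tolerances so that
rounding noise in the prefix sums can never manufacture a split. The scan
is quadratic in chromosome probe count — adequate plumbing for cohorts of
a few thousand probes per chromosome, not a replacement for a production
segmenter.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the structure the method
assumes, plus ground truth for evaluation:

* Gaussian probe noise (`noise_sd`, default 0.1 log10 units — the order of
  magnitude of residual noise on clinical oligo arrays), inflated 3× on a
  `disrupted_probes` fraction (default 1%).
* A sinusoidal wave over probe order: amplitude 0.05 (half the noise sd;
  published wave amplitudes are a few hundredths on the log10 scale),
  period 120 probes, and per-sample phase jitter scaled by
  `1 - shared_fraction` (default 0.8) — `shared_fraction = 1` makes the
  wave identical in every sample, in which case rank invariance guarantees
  *no* marker call changes.
* Per-batch offsets on a random 1% of probes (experimenter bias).
* Planted CNVs: rare ones in at most 1% of samples (a single carrier is
  always admissible) and polymorphic ones above 1%. The default deletion
  amplitude is −0.3 log10 — a single-copy loss with the signal compression
  typical of hybridization.

What the generator does *not* model: probe GC content, dye-swap effects,
genuine hybridization chemistry, length/amplitude coupling of real CNVs,
or the heavy-tailed noise of failing arrays. Passing tests demonstrate the
method's statistical behavior under its own assumptions, not clinical
performance on real arrays.

## Reference problem sizes and numerical choices

The quantitative checks in the test suite and the acceptance script use
these problem sizes, chosen as the package's reference experiments:

* **Null marker rate**: 200 samples × 1400 probes (two chromosomes),
  iid-normal logratios, $k = 7$.
* **Closed-form limit**: $n = 5000$; after rank transformation any
  distinct column is exactly the grid $i/(n+1)$, so the check is
  deterministic.
* **Wave robustness**: the same 200 × 1400 null cohort; a shared per-probe
  offset must change zero calls (exact), and per-sample sinusoidal waves
  at twice the noise sd must flip fewer than 5% of all (sample, window)
  decisions.
* **Recovery experiment**: 100 samples × 600 probes, noise sd 0.1, one
  single-carrier 30-probe deletion at −0.3 plus one 5%-carrier polymorphic
  deletion of the same shape, 50 seeded replicates, pipeline run with the
  built-in segmenter. This is a controlled parameter-recovery design: the
  wave/batch artifacts are switched off so that the measured rates isolate
  the detection and filtering machinery; the artifacts' effects are tested
  separately (and exactly) by the invariance checks above.
* **Independence null**: 3000 replicates at cohort size 1000.

Numerical choices worth knowing: midranks for ties (deterministic,
sum-conserving); method-of-moments Beta fitting with $\varepsilon$-nudged
boundaries; strict inequalities wherever a threshold defines a class
(markers, polymorphism counts, candidate score and mean); windows never
span chromosomes; and all simulation entry points take explicit seeds,
with `simulate_independence_null()` restoring the caller's RNG state.

## Known limitations

* The Beta null is fitted per window on the same values it tests — with
  very few samples the extremes dominate the fitted range (the window
  maximum always has $p = 0$), which is why a cohort of well below ~50
  samples is not a sensible input.
* The polymorphic profile at small $n$ has little headroom: with
  $n = 100$ the count threshold is 1, so two co-located samples above
  0.07 already flag a region. This mirrors the scaling of the rule it
  implements rather than a tunable defect.
* Rank invariance neutralizes *shared* waves exactly, but strongly
  sample-specific waves (large phase jitter) act as genuine signal and
  will perturb a small fraction of calls.
* The built-in segmenter is quadratic per chromosome and has no
  permutation p-values or pruning; external segmentations are first-class
  inputs and should be preferred on real data.
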