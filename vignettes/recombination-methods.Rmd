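---
title: "Pedigree recombination maps and crossover interference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree recombination maps and crossover interference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canrec)
```

## Scope

`canrec` analyses crossovers called from parent--child duos in dog pedigrees:
it filters the calls, builds sex-specific genetic maps with an
effective-meioses correction, summarizes the recombination landscape, and
fits crossover-interference models. Phasing and HMM-based crossover calling
(the upstream steps that produce a crossover-call table from genotypes) are
out of scope; the package starts from the call table, and its simulator
emits such tables directly with known ground truth.

## The crossover process and its likelihood

Crossovers are modelled on the genetic scale (Morgans), where one unit is
one expected crossover per meiosis. The chiasma process along the
four-strand bundle is a stationary renewal process whose inter-arrival
distances follow a gamma distribution with shape $\nu$ and rate $2\nu$; each
chiasma involves a given chromatid with probability $1/2$ ("chromatid
thinning"), which converts the chiasma process into the observed crossover
process at rate one per Morgan for every $\nu$. $\nu = 1$ is the
no-interference (Poisson) case; $\nu > 1$ spreads crossovers apart
(positive interference). Under thinning the inter-crossover density is the
geometric mixture

$$f(x) = \sum_{j \ge 1} \left(\tfrac12\right)^j
  \,\mathrm{Gamma}(x;\, j\nu,\; 2\nu),$$

truncated when $(1/2)^j < 10^{-12}$ (at most 40 terms; terms whose gamma
component carries no mass below the longest chromosome are also dropped).

The gamma-escape (Housworth--Stahl) extension superposes a second,
non-interfering pathway: a homogeneous Poisson process with rate $p$ per
Morgan, while the interfering pathway slows to inter-chiasma rate
$2\nu(1-p)$, preserving the total rate of one crossover per Morgan. $p$ is
the proportion of events escaping interference.

Sequence likelihoods use the full stationary-renewal form with end effects,
not an i.i.d. gamma density on observed gaps: the first event on a
chromosome of genetic length $L$ contributes the equilibrium
forward-recurrence density $S(x_1)/\mu$, interior gaps contribute $f$, the
right end contributes the survival $S(L - x_k)$, and an event-free
chromosome contributes $P(N=0) = (\mu - L + \int_0^L F)/\mu$, with
$\int_0^L F$ evaluated in closed form from gamma CDFs. A naive gamma fit to
observed gaps ignores censoring at chromosome ends and chromatid thinning
and is biased; it is not offered as a default. For the escape model the
likelihood sums over all $2^k$ assignments of a sequence's $k$ events to the
two pathways; $k$ is capped at 20 (beyond the cap, exact enumeration is
infeasible and such sequences are excluded with a message -- at dog-like
designs per-chromosome counts rarely exceed 6).

Three exactness properties anchor the implementation and are enforced in the
test suite: at $\nu = 1$ the total log-likelihood is $-\sum L$ for any event
placement; the escape model at $p = 0$ equals the gamma model to $10^{-9}$;
and on short intervals the density plus $P(N = 0)$ integrates to one within
$10^{-4}$ (quadrature).

### Estimation choices

* Events are placed on the genetic scale at the map image of the physical
  midpoint of their bounding interval (the localization of an event within
  its interval is not identified by the data).
* Distances are measured on the genetic scale through the package's own
  sex-matched map; each chromosome is one sequence, and zero-event
  sequences are retained (they carry likelihood information).
* `n` in $\mathrm{BIC} = -2\log L + k\log n$ is the number of
  meiosis-by-chromosome sequences. The alternative (number of
  inter-crossover gaps) changes only the penalty scale; with thousands of
  sequences the model ranking is insensitive to the choice.
* The bootstrap resamples whole meioses (not chromosomes) with replacement,
  preserving within-meiosis dependence, and reports percentile 95%
  intervals. $\nu$ is optimized on the log scale within $[0.1, 200]$
  (`optimize`, tolerance $10^{-3}$); the escape model uses `L-BFGS-B` over
  $(\log\nu, p)$ from two starts (the gamma solution with $p = 0.05$, and
  four times that shape), taking the better optimum.
* Age-stratified fits cut a numeric covariate into equal-frequency bins
  (default 7) and fit each bin independently; strata below 10 meioses are
  skipped with a warning.

## Genetic map construction

For each parent--child duo, crossovers are observable only between the
parent's first and last heterozygous markers (the *informative span*). At
each marker interval the *effective number of meioses* `n_eff` is the count
of duos whose span fully contains the interval -- full containment rather
than partial overlap, since an interval only partially covered by a span
cannot flank events on both sides throughout. Each crossover distributes
one unit of mass over the marker intervals intersecting its bounding
interval, proportionally to physical overlap (a midpoint-assignment mode is
available as a configuration switch); per-interval recombination fractions
`mass / n_eff` (expected counts, so non-integer numerators are allowed) are
converted to genetic distances with Haldane's map function
$d = -\tfrac12\ln(1 - 2r)$. Because `n_eff` is never larger than the duo
count, the correction can only lengthen the map. Intervals covered by very
few duos can produce fractions at or above $1/2$, where the map distance
diverges; these are capped at $r = 0.49$ with a warning rather than
aborting, keeping degenerate regions visible without destroying the map.
Sex-averaged maps are the per-interval arithmetic mean of the female and
male genetic distances on a shared grid. Chromosomes stored in reverse
orientation in the assembly (dog chromosomes 27 and 32) are mirrored with
an involutive coordinate flip before landscape analyses.

## Landscape statistics

*Telomeric proportion*: the fraction of total map length within a window
(default 5 Mb) of each chromosome's distal end, pooled genome-wide rather
than averaged per chromosome -- pooling weights chromosomes by their map
length, matching how a genome-wide proportion is naturally quoted, and the
dog's acrocentric karyotype gives each autosome a single telomeric arm end.

*Concentration curve*: map intervals sorted by rate in descending order,
accumulating genetic against physical proportion (a Lorenz-type curve read
from the high-rate end). Intervals longer than 1 Mb are treated as large
physical gaps (e.g. around centromeres) and removed first; the threshold is
configurable. Confidence bands resample chromosomes with replacement (1000
draws by default) and take per-point 2.5/97.5 percentiles on a fixed grid
of physical proportions.

*Feature profiles*: physical-length-weighted mean rates in non-overlapping
10-kb bins at signed offsets from anchors (strand-aware transcription start
sites from GTF annotations -- protein-coding genes, longest isoform per
gene -- or CpG-island midpoints from BED). CpG islands can be thinned to at
most five per 500-kb window to control for CpG clustering.

*Marker-framework thinning*: to compare maps built at different marker
densities, the denser marker set is iteratively thinned until its
inter-marker gap distribution matches a reference set: the procedure
removes random markers from regions whose gap sizes are over-represented
relative to the reference (per-bin count excess over reference-quantile
bins), forbidding adjacent removals within one pass and halving the step
adaptively whenever a proposal would overshoot the median band. Convergence
requires the median gaps to agree within 5% *and* the maximal CDF
difference between gap distributions to be below 0.08. The distributional
tolerance reflects two facts: marker removal can only merge gaps, so the
right tail can never be reshaped exactly, and the two-sample CDF-distance
noise floor at typical framework sizes (hundreds of gaps) is already
0.03--0.07. Crossover intervals are then expanded outward to the nearest
retained framework markers, so intervals only widen.

## Quality-control filters

* Call probability: strictly greater than 0.5 retained.
* Blacklist regions: any record overlapping a configured region removed.
* Clustered double crossovers: successive crossovers of one meiosis whose
  inner boundaries lie within 1 Mb form a clustered pair; a pair is removed
  only when a second meiosis of the same parent carries a clustered pair
  sharing an identical boundary coordinate -- the signature of a genotyping
  error at a shared SNP, as opposed to genuine gene conversion. The
  conjunctive reading (both conditions required) is deliberate: removing
  all within-1-Mb pairs would also delete genuine tight double crossovers.
  The inner gap is used because it is the event spacing the caller actually
  resolves.
* Outlier meioses: per sex, meioses whose autosome-wide crossover count
  falls outside the median $\pm$ 4 robust standard deviations
  ($1.4826 \times \mathrm{MAD}$, with MAD the unscaled median absolute
  deviation) are removed entirely. If the MAD is zero the sample standard
  deviation is used; if that is also zero nothing is excluded -- a
  homogeneous dataset should never be emptied by its own outlier rule.
* Marker QC: missingness above 5% (strict), duo Mendelian conflicts
  (parent homozygous for one allele, child homozygous for the other), and
  per-marker error probabilities above 0.9. Multi-iteration pedigree-wide
  error detection as implemented in dedicated linkage software is not
  re-implemented; the error-probability filter is the configurable stand-in
  for its downstream effect.

## The synthetic data generator

The generator's defaults encode the dog pedigree study design, so the whole
pipeline can be exercised at realistic scale with known truth:

| Parameter | Default | Meaning |
|---|---|---|
| meioses per sex | 204 | informative meioses per parental sex |
| chromosomes | 38 canFam3.1 autosomes | physical lengths from the assembly |
| map totals | 2162 cM (F), 1816 cM (M) | split across chromosomes proportionally to physical length |
| $\nu$ | 30.64 (F), 14.05 (M) | escape-model interference shapes |
| $p$ | 0.035 (F), 0.055 (M) | escape proportions |
| telomere bias | 38.2% (M) / 9.7% (F) of map length in the distal 5 Mb | two-segment per-chromosome rate profile |
| marker spacing | 100 kb | median bounding-interval width of calls |
| censoring | 5% of chromosome ends | expected fraction lacking informative markers |
| artifacts | ~0.5% cluster groups per meiosis, 1.45% outlier meioses | labelled ground truth for filter checks |

Per-chromosome genetic lengths are proportional to physical length because
only the autosomal totals are established; the strong observed correlation
between map and physical length makes this a reasonable stand-in, and none
of the estimators are sensitive to the exact split. Interfering-pathway
events are simulated by a burn-in of 20 mean inter-arrivals before the
origin (simpler than, and equivalent to, sampling the equilibrium
first-arrival density -- and independent of the likelihood code, so the
simulator doubles as its oracle), thinned per chromatid; escape events are
drawn directly as a Poisson process at rate $p$ per Morgan. Genetic
positions map to base pairs through the inverse cumulative truth map
(piecewise linear; maps with zero-rate segments are rejected as
non-invertible). Informative spans are drawn uniformly per duo end with the
configured expected censored fraction; retained events are reported as the
grid-marker interval bounding the true position, with call probabilities
drawn from Beta(20, 1) for genuine events. Injected artifacts -- shared
boundary double-crossover pairs across two meioses of one parent, placed
away from genuine calls so the truth labels are unambiguous, and
count-inflated outlier meioses -- carry provenance flags, making filter
sensitivity and specificity measurable.

What the generator does *not* emulate: genotype-level data (alleles,
phasing errors, Mendelian-error sequences), gene conversion tracts, the X
chromosome, fine-scale hotspot structure beyond the two-segment telomere
profile, and spatial correlation of marker informativeness (real
heterozygosity deserts are clustered, not uniform). Passing recovery tests
on this generator therefore demonstrates the correctness of the estimators
under the stated model, not robustness to every artefact of real array
data.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; call/span/map TSVs are
  1-based inclusive on disk (linkage convention), BED stays 0-based as the
  format mandates. Conversion is confined to the I/O layer.
* Likelihood survival and density terms are floored at $10^{-300}$ before
  taking logs; mixture terms are truncated by weight and by mass.
* `sequence_fraction_at` interpolates the concentration curve linearly and
  takes the minimal physical proportion at ties (zero-rate intervals).
* Empty call tables run through the whole pipeline: maps come out with zero
  rates, the landscape stage is skipped for zero-length maps, and the
  interference stage reports an explicit zero-survivor skip.
* Maps correlated over fewer than three shared 5-Mb windows raise an error
  rather than returning a meaningless coefficient.

## Problem sizes in the test suite

The routine suite simulates small designs (tens of meioses, two to eight
chromosomes) for behavioural checks, and three larger designs chosen as the
smallest that make the statistical assertions sharp: 10,000 single-
chromosome meioses for the Poisson goodness-of-fit of the simulator, 400
meioses over three chromosomes for map-length recovery within 5%, and five
replicates of the full 204-meiosis, 38-autosome female design for shape
recovery within 10% (the acceptance script runs twenty).

## Known limitations

* The escape-model likelihood is exact but exponential in per-sequence
  event count; designs with long chromosomes on the genetic scale (more
  than ~20 events per chromosome) need the enumeration cap raised or such
  chromosomes split.
* The effective-meioses profile uses full-containment counting; partial
  overlap weighting would differ only for intervals comparable in size to
  span ends (100-kb intervals vs multi-Mb spans here).
* Bootstrap intervals are percentile-based; no bias correction is applied.
* The thinning procedure targets the gap distribution, not linkage
  information content; two frameworks with matched gaps can still differ
  in informativeness.
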