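---
title: "Quantifying replication origin activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication origin activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological question

In budding yeast, entry into S phase activates only a subset of the
licensed replication origins, because the initiation kinase DDK
(Cdc7–Dbf4) is present in limiting amounts.  Two targeting mechanisms
concentrate DDK at particular origins: the Forkhead transcription factors
Fkh1/Fkh2 recruit it to a large class of early-firing ("Fkh-activated")
origins, and the Ctf19 kinetochore complex recruits it to centromeres,
stimulating the nearest origin on each side of each centromere
("CEN-proximal" origins) out to roughly 25 kb.  Quantitative BrdU-IP-seq
(QBU) in hydroxyurea-arrested cells freezes an early-S snapshot in which
the per-origin BrdU signal reports how often, across the cell population,
each origin fired.  Comparing QBU between a wild-type strain and strains
lacking one of the targeting pathways shows which origin class each
pathway serves; Dbf4 occupancy ChIP-seq shows where the kinase itself
sits.

`repliquant` implements the computational side of such a study twice
over: a quantification pipeline that goes from coverage tracks and origin
annotations to per-origin statistics and strain contrasts, and a
mechanistic simulator that generates synthetic experiments with known
truth, so that every pipeline stage can be validated at desk scale.

## The quantification pipeline

Signal conditioning follows the field's standard recipe:

1. **Binning** (`read_bedgraph()`): coverage is placed on fixed 50 bp
   bins.  A record's value is spread over the bins it overlaps in
   proportion to base pairs of overlap, and the bin value is the per-bp
   mean over the bin (uncovered base pairs count as zero).  This
   conserves mass exactly and makes a bin covered entirely by one record
   carry that record's value bit-for-bit.  The final bin of each
   chromosome is kept at its true (shorter) width.
2. **Median smoothing** (`median_smooth()`, 1000 bp default): a running
   median per chromosome.  1000 bp at 50 bp bins is 20 bins — an even
   count — so the window is widened to the next odd count, 21 bins
   (1050 bp), to stay symmetric.  At chromosome ends the window is
   truncated rather than padded: no data are invented, at the cost of
   noisier estimates in the outermost 10 bins.
3. **Replicate handling** (`replicate_correlation()`,
   `average_replicates()`): genome-wide Pearson correlation between
   replicate tracks is computed on the smoothed tracks, zero bins
   included and untransformed, and recorded in the profile's provenance;
   no correlation threshold is enforced.  Replicates are then averaged
   bin-wise.  Each replicate is smoothed before averaging, and the
   provenance strings record that order.
4. **Scale normalization** (`scale_normalize()`): each strain's track is
   multiplied by a single scalar so that all strains share the same
   genome-wide total signal (by default the mean of the input totals).
   One scalar per strain preserves every within-strain ratio of bin
   values exactly, which is the property that makes cross-strain scatter
   plots meaningful.  Quantile normalization was considered and rejected
   because it distorts peak shape, which the peak-width analysis relies
   on.  The same normalized profile is used for plotting and for all
   statistics.

Quantification then works on windows centered on feature midpoints
(half-open coordinates throughout; the midpoint is
`floor((start + end) / 2)`):

* `window_signal()` takes the bp-overlap-weighted mean of bin values in a
  500 bp window.  A window overhanging a chromosome end is averaged over
  its clipped extent and flagged rather than dropped.
* `delta_signal()` forms per-origin differences `reference − test`;
  positive values mean activity lost in the test strain.
* `group_boxplot_stats()` gives five-number summaries per origin group,
  with quartiles by linear interpolation (R's type 7).  Tukey hinges were
  rejected so that the quartile rule is identical for every group size.
* `two_sided_ttest()` is Welch's unequal-variance t test.  The flavor is
  a choice: group variances differ visibly between origin classes, and
  Welch costs nothing when they do not.  When both samples have zero
  variance and equal means the test is defined as t = 0, p = 1.  Raw
  p-values are primary; Benjamini–Hochberg q-values appear only as a
  clearly labelled extra column.
* `peak_width_fwhm()` measures full width at half maximum around an
  origin: baseline = minimum in the 10 kb search span, half-height
  crossings located by linear interpolation between bin centers.  A
  constant span is an explicit "flat" result and a peak whose crossing is
  not reached inside the span is "censored", never silently numeric.
* `heatmap_matrix()` samples bin values at fixed offsets across a 10 kb
  span centered on each feature; out-of-genome cells are NA.
* `scatter_fit()` fits ordinary least squares per origin group and
  reports slope, intercept and Pearson r.

Default parameters, all overridable: bin width 50 bp, smoothing window
1000 bp, signal window 500 bp, heatmap span 10000 bp, CEN stimulation
range 25000 bp.

## The simulator

The generator embodies the limiting-pool competition model directly.

**Weights.** Each origin gets a recruitment weight

```
w = base_efficiency
    × fkh_boost       [if Fkh-activated and the Forkhead pathway serves it]
    × cen_boost(d)    [if within cen_range of a centromere and the CEN pathway is intact]
    × global_multiplier(dbf4 allele)
```

with `cen_boost(d)` decaying linearly from its maximum at the centromere
to 1 at `cen_range` (default 25 kb, configurable because stimulation
beyond 25 kb is plausible).  Fkh1-sensitive origins require Fkh1
specifically; other Fkh-activated origins are served by either Fkh1 or
Fkh2, which is what gives a lone *fkh1* deletion its partial phenotype.
The `Zn*` and `dC` alleles force the CEN pathway off — their defining
defect — and carry global multipliers 0.8 and 0.4.  Those two numbers are
free parameters chosen once to produce the ordering dC ≪ Zn* < WT in
overall activity; they are configuration, not biological estimates.

**Firing.** Per cell, `pool_size` origins (default 20 of 160) are drawn
without replacement with probability proportional to weight, by
successive draws.  This is where competition lives: raising one origin's
weight weakly lowers every other origin's firing frequency.  A
genotype-wide multiplier would cancel out of such a draw — proportional
sampling is scale-invariant — so a hypomorphic kinase must act elsewhere:
the effective pool shrinks to `max(1, round(pool_size × multiplier))`.
That is the mechanistically natural reading of "less active kinase":
fewer origins served per cell, which is exactly how the dC allele comes
to depress every origin class at once even after normalization.

**Forks.** Under arrest all firing is collapsed to t = 0 (the data are a
single early-S snapshot); an exponential-waiting-time option exists
behind `firing_times = "exponential"` but is off by default.  Each fired
origin replicates `[midpoint − L, midpoint + L)`.  If every fork always
ran the full `fork_speed × duration`, average peak width would not depend
on how many origins fire, contradicting the well-known inverse relation
between peak width and firing density.  The model therefore gives each
cell a synthesis capacity (the dNTP budget under hydroxyurea) equal to
`capacity_origins` (default 5) full-extent origins:
`L = min(vT, vT × capacity_origins / n_fired)`.  A lone fired origin
still replicates its full `2vT`; twenty share the budget and each fork
travels a quarter as far.

**Readout.** The per-bin replicated-cell fraction `f` is observed as
Poisson counts with mean `read_depth × f` (negative binomial when an
overdispersion knob is turned).  The Dbf4 occupancy track is a flat
Poisson background plus Gaussian peaks: strong at centromeres, weak at
CEN-proximal origins, minimal at other origins; the `Zn*` allele
suppresses the CEN peaks by 0.3 and the CEN-proximal origin peaks by 0.6,
leaving distal origin peaks untouched.

**What the generator does and does not emulate.**  It produces:
per-origin peaks of genotype-dependent height and pool-dependent width,
replicate-level sampling noise at realistic correlation (~0.98–0.99
between replicates at default depth), class-specific suppression under
each mutant genotype, and CEN-enriched occupancy tracks.  It does not
model fork stalling or restart, checkpoint signalling, whole-S-phase
timing, GC or mappability artifacts, or library-construction biases.
Passing tests on synthetic data therefore validate the *computations* —
binning, smoothing, normalization, classification, statistics — and the
qualitative genotype contrasts, not the pipeline's robustness to
real-library artifacts.

## Numerical and edge-case decisions

* Coordinates are 0-based half-open everywhere, including all BED and
  bedGraph I/O.
* Distances anchor at origin midpoints and centromere points (interval
  midpoints); equidistant flanking candidates are broken by
  lexicographically smaller name; an origin whose midpoint coincides with
  the centromere counts as left-flanking.  CEN-proximal classification
  runs on the rDNA-excluded confirmed set.
* Unknown chromosomes in any input are a hard error, never skipped:
  silent genome-version mixups are the failure mode this guards against.
* Run-length bedGraph output writes values with 17 significant digits,
  so a write/read round trip reproduces bin values bit-exactly, and
  all-zero runs are written explicitly.
* Peak FWHM in the pool-size analyses is measured on the median-smoothed
  track.  On raw Poisson counts the peak height estimate (a maximum
  statistic) is upward-biased at low coverage, which artificially narrows
  the measured width; the 21-bin median removes that bias while plateaus
  at all default pool sizes (15 bins and wider) pass through the filter.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic data.
The simulator's toy genome is 16 chromosomes of 300 kb with origins every
30 kb (160 origins, 37 Fkh-activated, 14 Fkh1-sensitive, 32 CEN-proximal,
2 rDNA) — the yeast layout at one-tenth scale, sized so a full
five-genotype, two-replicate, 2000-cell experiment simulates in about two
seconds.  Genotype-contrast checks use 2000 cells and 20 seeds;
peak-width checks use 400 cells over pool sizes {5, 10, 20, 40}; the
genome-scale annotation fixture carries the full published group sizes
(410/95/35/32, two rDNA origins).  These sizes were chosen as the
smallest at which the mechanistic contrasts are unambiguous on virtually
every seed.

## Known limitations

* The scale normalization assumes strains differ in shape, not in
  meaningful total signal; a genotype that genuinely replicates less DNA
  is renormalized to the common total, so only *relative* redistribution
  among origins is interpretable — which is also true of the assay.
* The without-replacement pool draw has no closed-form inclusion
  probabilities for K > 1; the package validates it against exhaustive
  enumeration on small cases rather than offering analytic expectations.
* `fkh2-dsm` is modelled as a clean off-switch for Fkh2's origin
  function; pleiotropic Forkhead effects are out of scope.
* Simulated fork extents are deterministic given the fired count;
  cell-to-cell variability in fork speed is not modelled.

## A minimal end-to-end run

```{r example}
library(repliquant)

cfg <- sim_config()
sim <- simulate_experiment(cfg, genotype_panel(), replicates = 2, seed = 1)

profiles <- lapply(split(sim$tracks, sim$tracks$strain), function(df) {
  reps <- lapply(split(df, df$replicate), function(r) {
    median_smooth(r[, c("chrom", "start", "end", "value")], 1000)
  })
  average_replicates(reps, df$strain[1])
})
normalized <- scale_normalize(profiles)

windows <- window_signal(normalized, sim$origins, 500)
comparison <- group_comparison(windows, sim$origins,
                               groups = c("cen_proximal", "fkh_activated"))
tidy(comparison)
autoplot(comparison)

deltas <- delta_signal(windows, "WT", "ctf19d")
head(deltas[order(-deltas$delta), ])
```
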