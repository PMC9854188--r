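---
title: "Composite selection signal scans: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection signal scans: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csscan)
```

## The problem

When one population has been bred or has adapted for a trait that a related
population lacks, recent positive selection leaves three footprints around
the causal locus: allele-frequency differentiation between the populations
(measured by $F_{ST}$), a directional frequency shift of the favoured allele
in the selected population ($\Delta$SAF), and an unusually long stretch of
haplotype homozygosity in the selected population (measured by XP-EHH).
Each statistic alone is noisy; `csscan` combines all three into a single
per-SNP composite selection signal (CSS) and scans the genome for clustered
outliers, the strategy used for selection mapping in livestock with
medium- and high-density SNP array data.

## The composite statistic

For each SNP $i$ and each component test $j$ with value $t_{ij}$ (oriented
so that larger means more evidence of selection in the target cohort):

1. **Fractional ranks.** Available values of component $j$ are ranked
   ascending; rank $k$ of $n$ becomes $r = k/(n+1)$, ties receiving the
   mean of their tied ranks. Ranks rather than raw values make the
   combination invariant to any monotone transform of a component and
   sidestep the components' wildly different scales and null
   distributions.
2. **Inverse-normal scores.** $z_{ij} = \Phi^{-1}(r_{ij})$.
3. **Mean score and p-value.** With $m_i$ components available at SNP $i$,
   $\bar z_i$ is their mean; under an independence null
   $\bar z_i \sim N(0, 1/m_i)$, so
   $p_i = 1 - \Phi(\bar z_i \sqrt{m_i})$ and the CSS is $-\log_{10} p_i$.

The combination step is isolated in `css_from_ranks()` so an alternative
combiner can be swapped in without touching ranking, smoothing or
thresholding.

**A caution on calibration.** The $1/m$ null treats components as
independent, but under neutrality $F_{ST}$ is approximately a monotone
function of $|\Delta\mathrm{SAF}|$ — a strong nonlinear dependence with
near-zero linear correlation. The resulting $p_i$ are therefore *not*
exactly uniform under the null (a Kolmogorov–Smirnov distance of roughly
0.06–0.08 at 10,000 SNPs in our neutral simulations, reproducible with a
mechanism-only re-derivation outside the package). This is why significance
is declared by genome-wide *empirical* quantiles of the smoothed score, not
by the nominal p-value scale; the CSS value is best read as a relative
score.

## Smoothing, thresholds, regions

Raw CSS is averaged over all SNPs on the same chromosome within half a
window of each SNP (window centred per SNP; windows never cross chromosome
ends). The window is a tuning constant tied to marker density: 100 kb for
~500K-array density, 1 Mb for ~50K-array density; `window_bp` in
`scan_config()`. Smoothing suppresses isolated single-SNP spikes, at the
cost of correlating neighbouring smoothed values — which is also why a
neutral genome still shows clustered top-quantile SNPs (see below).

Significance flags are empirical: exactly $\lceil 0.001\,n\rceil$ SNPs are
flagged top-0.1% and $\lceil 0.01\,n \rceil$ top-1% genome-wide — all
autosomes pooled rather than per-chromosome quantiles, the standard
practice for CSS scans. Ties at a quantile boundary are broken
deterministically by (chromosome, position).

Cluster regions require at least one top-0.1% SNP supported by at least
five top-1% SNPs in a run whose consecutive members are at most `gap_bp`
apart (default: the smoothing window). The protocol this follows does not
state whether the significant SNP counts toward the five, nor the maximal
intra-run gap; we default to counting it (top-0.1% ⊂ top-1%) and expose
the stricter reading (`support_includes_significant = FALSE`) and the gap
as configuration. Regions closer than 1 Mb (strict) merge transitively;
ranks are by peak smoothed CSS; ±0.5 Mb flanks are attached after merging
and do not trigger further merging. Region bounds are outermost member-SNP
positions, matching reported sub-megabase region spans; coordinates are
1-based closed internally and 0-based half-open in BED output.

## Component details and numerical choices

* **FST** — Weir & Cockerham's two-population $\theta$ in haploid form on
  haplotype allele counts. Negative estimates are kept: ranks order them
  correctly and clamping would create artificial ties. SNPs monomorphic in
  both cohorts are flagged unavailable; SNPs with fewer available
  components stay in the scan with null variance $1/m_i$, preserving the
  SNP count that the empirical quantiles rely on.
* **EHH/iHH** — EHH at distance $d$ is
  $\sum_h \binom{n_h}{2}/\binom{n}{2}$ over distinct haplotypes spanning
  core to $d$ (core allele included); EHH(0) is 1 by convention.
  Extension stops below an EHH floor of 0.05, past an inter-marker gap of
  200 kb, or at a chromosome end; both constants are exposed
  (`ehh_truncation`, `ehh_max_gap`). iHH integrates the decay
  trapezoidally over physical distance, *excluding* points below the
  floor (so a core isolated by a large gap has iHH 0). Distance is
  physical bp — no genetic maps exist for these panels, a known deviation
  from recombination-map-based XP-EHH.
* **XP-EHH** — $\ln(\mathrm{iHH}_{sel}) - \ln(\mathrm{iHH}_{ref})$
  (computed as a difference of logs so antisymmetry is exact in floating
  point), standardized genome-wide to mean 0, sd 1 over available SNPs.
  Zero iHH on either side makes the SNP unavailable for this component.
* **$\Delta$SAF** — $p_{sel} - p_{ref}$ on the alt allele. The protocol
  does not define "selected allele"; we rank the signed alt-allele change,
  so a sweep on the ref allele at a SNP scores low on this component and
  must be carried by FST and XP-EHH. One-sidedness throughout is encoded
  in the ranking direction, not in the p-value.

QC removes markers with missing rate strictly above 0.05 or MAF strictly
below 0.01 (boundary values survive, mirroring the source inequalities),
computed on all samples pooled before any contrast. Scanning requires
complete phased data; the package refuses to impute or phase (external
tools' territory) and raises instead of silently dropping haplotypes.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates two cohorts (default 19 vs 81 diploids, a
rare-breed-versus-pooled-reference contrast size)
of biallelic SNPs on 2 chromosomes × 2,500 markers with exponential
spacing (mean 20 kb → ~50 Mb chromosomes, a realistic equine autosome
length at a marker density between a 500K and a 50K array). The neutral
background is Balding–Nichols: ancestral $p \sim U(0.05, 0.95)$, cohort
frequencies Beta-distributed around $p$ with differentiation parameter
$F$ (default 0.05, typical of closely related breeds; the realized mean
Weir–Cockerham FST calibrates to $F$ within ±0.02 in the tests).

The sweep is a copy-with-escape model rather than a coalescent
simulation: a founder haplotype spans ±500 kb of the core; each haplotype
is a carrier with its cohort's probability (defaults 0.8 vs 0.1); carriers
copy the founder outward until a per-direction exponential escape distance
(rate 2·10⁻⁶/bp, i.e. 500 kb mean) truncates the copy, then 1% per-site
flips model mutation and genotyping noise. The core site is the beneficial
mutation itself: carriers get alt, non-carriers ref, so the expected core
$\Delta$SAF is exactly the carrier-fraction difference. This gives direct,
independent control of the three signal axes the three components measure
— frequency shift, differentiation, haplotype length — at trivial compute
cost.

Deliberately absent: background linkage disequilibrium outside the sweep
(sites are independent), demography (bottlenecks, migration), genetic
maps, and diploid selection dynamics. A green sweep-recovery test
therefore establishes that the pipeline detects a joint
frequency/haplotype signal against a differentiated-but-LD-free
background; it does not establish calibration on real genomes, where
background LD inflates the spatial correlation of all three components.
Note also that at non-core sweep markers the founder carries the alt or
ref allele at random, so $\Delta$SAF across the swept window is of mixed
sign — realistic, and the reason recovery leans on FST and XP-EHH away
from the core.

All generation is seed-deterministic; the three stages draw from separate
streams derived from one user seed, so frequency draws never share a
stream with allele draws.

## Degenerate inputs and tie-breaks

A constant smoothed track has no empirical quantiles and is an error, as
is a panel emptied by QC or a threshold request with fewer than
$1/\min(\text{fraction})$ SNPs. Unphased ("/") genotypes are an error
under `strict = TRUE` in `read_vcf()` and a skip-with-warning otherwise;
PLINK ingestion is always flagged unphased and is refused by haplotype
statistics. All tie-breaks (quantile boundaries, region ranks) are
deterministic by (chromosome, position), making every pipeline output
byte-reproducible.

## Known limitations

* The p-scale of the CSS is nominal, not calibrated (see above);
  empirical thresholds are the significance machinery.
* Because smoothing correlates neighbours, a fully neutral genome still
  yields clustered top-quantile SNPs, and with ≥ ~5 SNPs per window a
  neutral scan frequently calls at least one cluster region. Region
  counts should be compared between contrasts, not read as
  false-discovery-controlled calls.
* XP-EHH on physical distance is density-sensitive; sparse panels weaken
  the haplotype component of the composite.
* The five-SNP support rule and intra-run gap follow a verbal protocol
  description with two acknowledged ambiguities, both exposed as
  configuration rather than silently resolved.
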