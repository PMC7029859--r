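---
title: "Simulating and detecting segregation distortion in biparental populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting segregation distortion in biparental populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsim)
```

## The problem

Segregation distortion is the deviation of progeny genotype frequencies
from Mendelian expectation in the offspring of a cross — 1 AA : 2 AB : 1 BB
in an F2, and a 1:1 ratio of the two homozygotes in advanced selfing
generations. Distortion can be caused by genuine selection (e.g. gametes
carrying one parental allele being less viable) or by nothing more than
sampling error, and the two are confounded in any single empirical
population. With high-density SNP genotyping the problem is compounded by
multiple testing: hundreds of linked markers are tested per chromosome, so
the probability that *some* marker looks distorted by chance alone is far
above the nominal test size.

`sdsim` provides an in-silico laboratory for this problem: a simulator of
single-seed-descent (SSD/RIL) populations with locus-specific gametic
selection of known strength and position, the per-marker detection
statistics, and a Monte-Carlo harness that measures how often each
detection criterion fires with and without selection.

## The simulation model

**Meiosis.** Haplotypes are tracked over two parental alleles, A and B.
Per chromosome, a gamete receives a Poisson-distributed number of
crossovers with mean $L/100$ ($L$ = map span in cM between the first and
last marker), crossover positions uniform along the chromosome, starting
strand chosen with probability $\tfrac12$, and strand switching at every
crossover. This is the Haldane model: no chiasma interference and no
obligate chiasma. We validated it against the reference behaviour of this
design — about 2.59 observed genotype transitions per F2 plant on a
130.48 cM chromosome (expectation $2L/100 = 2.61$, slightly shrunk by
double crossovers between adjacent markers), estimated map lengths
averaging ~131 cM, and a lag-1 autocorrelation of the per-marker
segregation ratio around 0.95 for 96 individuals.

**Population structure.** The founders are fully homozygous, so the F1 is
heterozygous at every marker. `simulate_ssd_population()` selfs the F1
into $n$ F2 individuals and then advances each line by single seed
descent — exactly one selfed offspring per line per generation — to the
requested $F_k$. Lines are independent; heterozygosity halves each
generation, $E[\mathrm{het}(F_k)] = 0.5^{\,k-1}$.

**Gametic selection.** A `selection_target(chrom, index, allele, s)`
makes every gamete carrying the targeted allele at that locus survive
with probability $1-s$; factors multiply across targets. Selection acts
on *every* gamete (ovule and pollen alike) at *every* selfing
generation, which is what makes $s = 1$ fix the locus (genotype counts
$0:0:n$); single-pool selection would leave heterozygotes behind. A
non-viable gamete is redrawn (rejection sampling), so the population
size stays fixed. From a heterozygous parent the targeted-allele
frequency among accepted gametes is $(1-s)/(2-s)$ — e.g. $s = 1/20$
gives the 100:95 gamete ratio, i.e. frequency $0.95/1.95 \approx 0.487$.

**Reproducibility.** Every simulation accepts a seed; the experiment
harness derives an independent child seed per replicate from its master
seed, so parameter sweeps are bit-reproducible and replicates are
exchangeable.

## Detection statistics

`scan_distortion()` computes, per marker:

* genotype counts $a$ (AA), $h$ (AB), $b$ (BB), missing calls excluded;
* the magnitude of distortion $M = a/(a+b)$, with 0.5 = undistorted and
  `NA` when no homozygotes are present;
* an uncorrected chi-square goodness-of-fit statistic — against 1:2:1 on
  2 df for F2, or homozygotes-only against 1:1 on 1 df for later
  generations (the `auto` ratio rule). Residual heterozygotes in an
  advanced generation are discarded from the 1:1 test, the only reading
  that keeps the ratio well defined;
* raw, Benjamini–Hochberg (FDR) and Bonferroni adjusted p-values,
  adjusted jointly across all markers in the scan.

Segregation distortion regions (`detect_sdrs()`) are maximal runs of at
least two consecutive significant markers, annotated with their skew
direction; `sdr_overlap()` intersects SDR sets from replicate
populations. The peak of distortion is the marker maximising
$|M - 0.5|$ (ties to the lowest index).

```{r example}
map <- make_clustered_map()        # 224 markers, 130.48 cM, centromeric cluster
regime <- selection_regime(selection_target("1A", 200, "B", "1/4"))
pop <- simulate_ssd_population(map, 1000, "F2", regime, seed = 42)
scan <- scan_distortion(pop, alpha = 0.05, correction = "fdr")
summary(scan)
```

## The surrogate wheat chromosome map

Many published rates depend on the correlation structure of real marker
maps. `make_clustered_map()` provides a deterministic stand-in for a
wheat chromosome-1A linkage group: 224 markers spanning 130.48 cM with
60% of markers placed in the central 20% of the map (the recombination-
suppressed centromeric region) and the remainder evenly spaced along the
arms. Positions are evenly spaced *within* each segment — a fixed,
RNG-free choice. On this map the familywise null rate of the raw
$p<0.05$ criterion at $n = 1000$ comes out at ~56–57%, matching the
published 56.1% for the empirical map; an empirical map CSV can be
supplied instead via `read_map_csv()` wherever a map is accepted.

What the generator does *not* emulate: genotyping errors, missing data,
marker misordering, or segregation of more than two founder alleles.
A green simulation-based test therefore establishes correctness of the
statistics under the stated model, not robustness to assay artefacts —
empirical data are noisier (e.g. their segregation-ratio autocorrelation
is lower than simulated, 0.875 vs 0.95).

## Experiments

Each `run_*` function sweeps a parameter grid with (default) 1000
replicates per cell and returns a tidy data frame:

* `run_null_sweep()` — familywise false-positive rates and mean peak
  magnitude $\max|M-0.5|$ across population sizes and generations, no
  selection;
* `run_marker_spacing_experiment()` — type-I rates for a single marker
  (~5%), two tightly linked markers (1 cM apart, barely above one
  marker) and two loosely linked markers (40 cM apart, nearly two
  independent tests);
* `run_deviation_heatmap()` — mean deviation score $\sum(y-0.5)^2$ over
  a 20-marker / 100 cM map across (population size, selection strength)
  tiles, 20 replicates per tile;
* `run_threshold_comparison()` — fraction of replicates flagged per
  criterion (raw 0.05/0.01/0.001, FDR 0.05, Bonferroni 0.05) across
  selection strengths;
* `run_power_grid()` / `run_peak_localization()` — detection power and
  the fraction of replicates whose distortion peak falls within 10
  markers of the selected locus.

## Numerical and design choices

* **Indices are 1-based** throughout (R convention): `marker_index` in
  selection targets, SDR start/end, peak positions.
* **No continuity correction** in any chi-square statistic; the
  reference worked values (e.g. $\chi^2 = 664.07$ for counts 1:31:268
  against 1:2:1) match the uncorrected statistic exactly.
* **Correction scope**: p-value adjustment spans all markers of one scan
  (all chromosomes jointly).
* **Skeleton binning** (`bin_to_skeleton()`): greedy runs by cM
  proximity, keeping the first marker of each run — a deterministic,
  map-only rule; the window ε is user-set.
* **Distance proxy**: pairwise marker distances weight
  homozygote–heterozygote mismatches 0.5 and opposite homozygotes 1 (the
  co-dominant Hamming convention); adjacent-interval proxies are capped
  at 0.4999 before inverse-Haldane conversion
  $d = -50\ln(1-2r)$ in `estimate_map_length()`.
* **Deviation-heatmap defaults**: the generation (F2) and the selected
  locus (the central marker) are not pinned down by the reference
  design; both are package choices, fixed once.
* **Degenerate inputs**: a zero-length chromosome recombines nothing; a
  marker with no homozygous calls has undefined $M$ (NA, flagged, never
  an error); a parent homozygous for an allele targeted with $s = 1$
  raises a non-viability error; rejection sampling is capped to avoid
  non-termination.
* **Test scale**: the packaged test suite runs most Monte-Carlo checks
  at full scale (1000 replicates) but the F5 power grid at 600
  replicates per cell for runtime; Monte-Carlo standard errors stay
  several times smaller than the tolerances checked.

## Limitations

The documented gametic-selection model reproduces the reference
behaviour closely but not perfectly at every operating point: under weak
selection (s = 1/20) in an F5 population of 1000 lines, the fraction of
simulations containing a significant marker converges to ~79%, several
points below the ~85% reported for the original pipeline (the smaller
population sizes agree within Monte-Carlo noise). The original
pipeline's printed strong-selection genotype ratios contain fewer
heterozygotes than a purely gametic viability model yields, so its
effective selection per generation was somewhat stronger than the
documented 1 − s per gamete; `sdsim` implements the documented model.

Only biparental, strictly selfing SSD designs with two founder alleles
are modelled — no outcrossing, doubled haploids, zygotic or
frequency-dependent selection, genotyping error or missing-data
injection. Genetic-map *construction* (clustering/ordering) is out of
scope; `export_mstmap()` writes simulated populations in MSTMap's text
dialect so external mapping software can be applied to distorted data.
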