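---
title: "Detecting mutagenic side effects of gene-drive elements with hybrid mutation-accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutagenic side effects of gene-drive elements with hybrid mutation-accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohdrive)
```

## The scientific problem

A CRISPR-Cas9 gene drive (CCGD) spreads through a population by cutting
the wild-type allele at its target locus and copying itself in via
homology-directed repair (HDR). The same machinery — a Cas9 endonuclease,
with or without its guide RNA — can in principle cut or bind elsewhere in
the genome, raising two safety questions: does carrying a drive elevate
the genome-wide rate of loss-of-heterozygosity (LOH) events, and does it
elevate the rate of de novo point mutations and indels?

The experimental design `lohdrive` supports answers these questions with a
mutation-accumulation (MA) experiment in a hybrid diploid yeast. Two
diverged parental strains are crossed, producing a founder heterozygous at
roughly 40,000 marker sites spaced on average ~320 bp apart. MA lines
descended from founders that carry a full drive cassette, a Cas9-only
cassette, or an empty control cassette are propagated through repeated
single-colony bottlenecks for hundreds of generations, so that selection
is minimized and events accumulate nearly neutrally. An LOH event —
HDR using the homologous chromosome as template — converts a run of
adjacent markers from heterozygous to homozygous calls, which is how it is
detected. The analysis then compares event rates, event classes
(interstitial vs terminal), length distributions and genomic distributions
across the founder genotypes.

`lohdrive` implements the full desk half of this design: a ground-truth
cohort simulator, the LOH caller, the mutation caller, the rate and
resampling statistics, design power calculations, construct-mutation
expectation calculators, and PAM/gRNA off-target similarity scanning.

## The generative model

The simulator treats LOH accumulation in each MA line as a Poisson
process: the number of events per clone is Poisson with mean
$\mu = \lambda m T$, where $\lambda$ is the per-genome per-generation
event rate, $m$ a founder-specific rate multiplier, and $T$ the number of
generations. Each event is terminal with probability $q$ and interstitial
otherwise:

* **Terminal (tLOH)** events extend from a breakpoint drawn uniformly
  along a chromosome arm (arms chosen proportionally to length) to the
  telomere. With ~750-kb chromosomes and mid-chromosome centromeres this
  yields median tracts of roughly 200 kb, matching the scale reported for
  yeast hybrids.
* **Interstitial (iLOH)** events get a log-normal length (median 471 bp)
  and a uniform position.

Markers inside the event interval are set to one homolog chosen with
equal probability; later events overwrite earlier ones (the physics of
sequential repair). SNMs and indels accumulate as independent Poisson
processes at per-bp per-generation rates over `ploidy` copies of the
effective genome; they are recorded in the truth but never alter marker
calls, since a point mutation does not erase a flanking marker.

### Default parameters

| parameter | default | unit | why |
|---|---|---|---|
| `loh_rate` | 1.76e-2 | events / genome / generation | rate measured in comparable yeast hybrids |
| `generations` | 800 | generations | post-hoc estimate of the MA propagation length (750 for a priori power work) |
| `terminal_fraction` | 0.192 | — | observed tLOH share of classified events |
| iLOH length | lognormal, median 471 bp, `sdlog` 1.5 | bp | median from the control background; `sdlog` 1.5 gives the heavy right tail (quartiles ~0.2–1.3 kb) typical of reported gene-conversion tracts |
| `snm_rate` | 1.67e-10 | / bp / generation | yeast MA estimate |
| `indel_rate` | 7.5e-12 | / bp / generation | yeast MA estimate (a ~5.0e-12 figure also circulates; both are accepted as parameters) |
| marker spacing | exponential, mean 320 bp | bp | only the mean spacing is known; exponential gaps are the maximum-entropy choice and make markers a Poisson process, which the detection model exploits |

Only the *mean* spacing and the iLOH *median* are externally given; the
gap distribution and `sdlog` are the package's own modelling choices,
stated here once and used everywhere (simulator, correction model,
tests).

### What the simulator does and does not emulate

It reproduces the statistical structure the caller relies on: marker
density, Poisson event counts, the terminal/interstitial mixture with
distinct length scales, overwriting of overlapping events, and per-clone
seed-derived reproducibility. It does **not** emulate read-level noise,
genotyping error, repeat-masked regions (these enter only through
`effective_length`), aneuploidy, recombination hotspots, or selection.
Passing oracle tests therefore demonstrates that the caller inverts the
marker-conversion process faithfully — not that it is robust to
genotyping artifacts, which are upstream of this package's inputs.

## The LOH caller

1. **Tracts** (`call_tracts`): maximal runs of adjacent markers
   homozygous for the same homolog. A boundary is the midpoint between
   the outermost converted marker and the adjacent unconverted (or
   differently converted) marker; at chromosome ends the boundary is the
   end itself. `MISSING` calls are transparent by default — they neither
   break a run nor count as converted — with `missing = "break"`
   available.
2. **Events** (`merge_tracts`): tracts whose boundaries are separated by
   less than 10 kb merge transitively. The rule applies only to
   same-homolog neighbours: a homolog switch implies two distinct repair
   products, so a P2 tract sitting between two P1 tracts blocks their
   merger. The inequality is strict — a gap of exactly 10 kb stays two
   events.
3. **Classification** (`classify_events`): an event containing the
   telomere-proximal marker of an arm (the chromosome's first or last
   marker) is terminal; otherwise interstitial. A fully homozygous
   chromosome is terminal and flagged `possible_aneuploidy`, because
   chromosome loss leaves the same marker signature and coverage-based
   detection is out of scope here.
4. **Breakpoints** (`estimate_breakpoints`): interstitial events and
   terminal events under 20 kb get the midpoint of the boundary interval.
   Longer terminal events get a point 10 kb from the centromere-proximal
   boundary, reflecting that strand resection extends homozygosity far
   beyond the causal break. Whole-chromosome events have no
   centromere-proximal side and fall back to the midpoint.

All internal coordinates are 1-based closed; BED exports are 0-based
half-open. Because midpoint boundaries fall between markers, the BED-like
files keep half-integer positions rather than rounding, so round trips
are lossless.

## Correcting for undetected events

An interstitial event of length $\ell$ on a Poisson marker process with
mean spacing $s$ covers at least one marker with probability
$p(\ell) = 1 - e^{-\ell/s}$; terminal events reach a telomere-adjacent
marker and are effectively always detected. `correct_counts` applies a
single inverse-detection-probability (Horvitz–Thompson) correction over
the universe of events longer than 17 bp. This approximates — it does not
replicate — the multi-step corrections used with dual-reference
genotyping pipelines.

A subtlety decided by simulation during development: weighting each
detected event by $1/p(\hat\ell)$ with $\hat\ell$ its *called* boundary
length is biased (−15% under the default length model), because the
called length of a single-marker footprint overestimates the true length
of exactly the events most likely to be missed. The default
`method = "parametric"` therefore weights interstitial events by the
reciprocal of the *marginal* detection probability
$\bar p = E_\ell[p(\ell)]$ under the configured log-normal length model,
which is unbiased for the true count (−0.2% in the same experiment). The
literal per-event form is retained as `method = "per_event"` for
sensitivity analyses. The length model is an assumption supplied to
`correction_model()` — it must come from prior knowledge or the
simulation configuration, not from fitting the detected events, which are
length-biased.

On a full-scale simulated cohort (16 chromosomes, 12 Mb, 95 lines,
$\lambda T = 14.1$) the corrected genome-wide rate lands within a few
percent of the simulated $\lambda$; the residual shortfall comes from
physically overlapping events that merge into one call, which no
count-level correction can resolve.

## Mutation calling

De novo SNMs and indels are accepted only at sites that are neither
parental-difference markers nor ancestrally heterozygous, and only when
observed in a single end-point clone. The justification is quantitative:
with per-site rate $r$, $T$ generations and $n$ clones, the chance a site
is hit twice is $P_{2+} = 1 - e^{-\mu}(1+\mu) \approx \mu^2/2$ with $\mu
= rTn$, giving ~0.01 expected duplicate sites genome-wide for realistic
rates (`expected_duplicate_sites`) — so recurrent variants are artifacts,
not mutations. Mutations within 100 bp of each other in one clone are
merged into a single "complex" event by single-linkage
(`merge_complex`); chains are allowed, a deliberate reading since sets
observed in practice are pairwise close. Unsequenced founders are imputed
(`impute_founder`) when at least six descendants support a call and all
other founders agree unanimously; descendants may disagree (they can
have undergone LOH at the site) but founders may not.

## Resampling statistics

Strain comparisons deliberately avoid distributional assumptions:

* `permutation_test` reshuffles founder labels and compares means (or
  medians), two-sided by default on the absolute difference.
* `wasserstein_test` compares the genomic *placement* of events via
  $W = \int |E_1(x) - E_2(x)|\,dx$ between empirical CDFs, with a
  label-reshuffling Monte-Carlo null (5,000 reshuffles by default).
* `arm_chisq` tests whether two founders distribute events differently
  across chromosome arms (marginal rates cancel).
* `bh_adjust` applies Benjamini–Hochberg step-up control across windows.

**p-value convention.** All resampling p-values use an add-one mid-p
rule, $p = (1 + \#\{d > d_{obs}\} + \tfrac12\#\{d = d_{obs}\})/(1+B)$.
With integer event counts, permuted mean differences tie the observed one
in a substantial fraction of draws (~20% at the design size), and the two
textbook extremes are both miscalibrated: counting ties as extreme is
conservative enough to visibly distort the null p-value distribution and
cost several points of power, while ignoring them is anti-conservative.
Half-weighting centers the null distribution on uniform (verified by KS
checks in the test suite) and never returns exactly zero. If every
permuted statistic equals the observed one (constant data), the test
returns $p = 1$: a point-mass null carries no evidence.

Windows are 50 kb, 1-based closed, with the terminal short window kept
and length-normalized. Events are assigned to windows **by breakpoint**,
not by overlap — the breakpoint localizes the causal cut, and a 200-kb
terminal event would otherwise inflate every window it covers. A
breakpoint exactly on a boundary belongs to the earlier (closed) window.

## Statistical power

`theoretical_power` simulates the design exactly as specified: baseline
and alternate Poisson samples ($\mu$ and $\mu(1+f_e)$), a two-sided
permutation test on means, rejection at $p \le \alpha$. At the study
design ($\mu = 13.2$, 95 vs 95, $\alpha = 0.01$, 1,000 permutations) the
power to detect a 15% rate increase is ~84%, within the Monte-Carlo and
convention slack of the ~85.7% figure the design targets, and tracks the
normal-approximation closed form `power_normal_approx`
($\Phi(z - z_{\alpha/2}) + \Phi(-z - z_{\alpha/2})$ with
$z = \mu f_e / \sqrt{\mu(2+f_e)/n}$) to within ~1.4 points everywhere on
the 5–50% grid.

`observed_power` replaces the Poisson assumption with the pooled
empirical per-clone counts, which may be over-dispersed: the alternate
population adds `round(total * f_e)` events uniformly at random across
clones, and groups of the actual retained sizes (e.g. 79 vs 67) are
sampled without replacement. One published phrasing reads as adding
$n(1+f_e)$ events — which would more than double the mean and contradict
the definition of $f_e$; the package implements the $n f_e$ reading and
keeps the literal one behind `literal_augmentation = TRUE` rather than
guessing silently. Because baseline and alternate samples are drawn from
overlapping clone pools, the procedure is slightly conservative at
$f_e = 0$; this mirrors the design being emulated.

## Construct expectations

Closed forms, kept separate from any simulation: a clone carries on
average `copies × (snm_rate + indel_rate) × length × T` construct
mutations; multiplying by clone counts gives expected mutant clones; the
fraction of mutations that deactivate the drive is estimated
conservatively as the component-length share of the cassette
(`deactivating_fraction`), treating every hit inside the gRNA or Cas9
cassette (promoters and terminators included) as deactivating. Because
local mutation rates vary up to ~6-fold across a genome,
`uncertainty_band` brackets any expectation by [1/6, 6] by default. The
shipped `constructs.yaml` records the three cassette geometries (7,999 /
7,601 / 2,770 bp; components 388 + 4,890 bp) and retained clone counts.
Composing the printed intermediate values reproduces the published
per-clone and per-experiment expectations; the two published
"deactivating clones" figures (0.090/0.11) do not exactly equal the
product of their own printed intermediates, so the package composes the
intermediates and leaves that discrepancy documented rather than
targeted.

## PAM scanning and gRNA similarity

`index_pam_sites` scans both strands for NGG and NAG PAMs (via
Biostrings, ambiguity codes other than N rejected, N-containing or
truncated protospacers dropped) and extracts the 20-bp protospacer 5' of
each PAM on its strand. `mit_score` implements the MIT/Hsu single-site
scheme: the product of $(1 - W_p)$ over mismatched positions with the
20-entry empirical weight vector, a penalty for tightly clustered
mismatches via the mean adjacent-mismatch distance, and a $1/m^2$
mismatch-count penalty. Two properties worth knowing: positions 1, 2, 4,
5 and 8 (PAM-distal numbering) carry zero empirical weight, so a lone
mismatch there scores 1.0 — a feature of the published weights, not a
bug; and NAG sites are scored with the same weights as NGG, with the PAM
class recorded so users can down-weight them downstream. No gRNA sequence
is hard-coded; the guide is always a user input.
`rate_similarity_regression` then asks the safety question directly:
does the normalized per-window rate difference
$r = (R_s - R_W)/(R_s + R_W)$ increase with window similarity (or PAM
density)? Constant similarity degenerates the fit and is flagged rather
than fitted.

## Numerical choices and degenerate inputs

* Seeds: one root seed; per-clone and per-stage streams derived by a
  counter (`derive_seed`), all below $2^{31}$. The same configuration is
  byte-identical on disk.
* `correction_model` integrates the length model over quantile-bounded
  limits and adds the upper tail mass analytically, so concentrated
  length models cannot defeat the quadrature; a non-positive detection
  probability is an error, and `p_floor` bounds per-event weights.
* Chromosomes shorter than twice the marker spacing are rejected at map
  construction; maps with fewer than two realised markers per chromosome
  are errors, not warnings.
* Zero-rate processes, empty event lists, header-only BED files and
  all-HET clones are all exact no-ops through the pipeline.
* `normalized_rate(0, 0)` is NA (undefined), never 0.

## Problem sizes used by the test suite

The suite chooses sizes that make each statistical claim decidable while
keeping a full run around ten minutes: count calibration over 5,000
simulated clones; caller–simulator equivalence over 220 clones on a
dense 0.7-Mb two-chromosome map (overlap-rich, which stresses the
merge/overwrite logic); parameter recovery on one full-scale 12-Mb,
95-line cohort; 200 replicate cohorts for bootstrap coverage; 1,000
null draws for each KS uniformity check; 1,000–3,000 simulated
experiments per power point (3,000 on the power-curve comparison, where
the ~1.4-point true gap to the normal approximation needs sub-point
Monte-Carlo resolution).

## Known limitations

* The undetected-event correction is a single parametric approximation;
  it does not reconstruct events lost to physical overlap (two terminal
  events on one arm merge irrecoverably), which costs a few percent at
  realistic densities and more on toy genomes with short arms.
* Conversion fractions are marker-weighted, not bp-weighted; with
  exponential spacing the difference is negligible at genome scale.
* The caller assumes clean genotype calls; systematic genotyping error
  (e.g. allele-specific mapping bias) is upstream and unmodelled.
* Aneuploidy is only flagged (`possible_aneuploidy`), never resolved.
* The MIT score predicts binding-site similarity, not cutting frequency;
  CFD-style or learned scores are out of scope.
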