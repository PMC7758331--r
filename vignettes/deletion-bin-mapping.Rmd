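---
title: "Deletion-bin dosage karyotyping and physical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion-bin dosage karyotyping and physical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delbin)
```

## The problem

Hexaploid wheat tolerates whole-chromosome and chromosome-arm dosage
changes, and collections of such cytogenetic stocks — nullisomic-
tetrasomic lines, ditelosomics, and terminal-deletion lines with known
fraction-length (FL) breakpoints — are a classical instrument for
placing a locus on a physical map without any crossing. If a trait
fails in every stock that lacks a chromosomal segment and is intact in
every stock that retains it, the causal locus must lie in the
intersection of the missing segments. `delbin` implements this
*deletion-bin mapping* for a binary phenotype (here: whether a wheat
line can form viable hybrid seed when crossed with rye, a proxy for a
functional endosperm-development locus on chromosome arm 1DL), plus
the read-depth karyotyping needed to verify what each stock actually
carries.

The package has four computational layers:

1. **Coordinate model** — chromosomes, centromeres, fixed-width bins,
   and FL arithmetic (`genome_layout()`, `build_bins()`, `fl_of()`,
   `position_of()`). FL is the fraction of the arm length measured
   from the centromere: a deletion line with breakpoint FL 0.41
   retains the proximal 41% of the arm. Coordinates are 0-based
   half-open throughout; bins and calls are exchanged in BED
   convention.
2. **Dosage karyotyping** — from a line x bin matrix of GBS read
   counts to copy-number states and karyotype events
   (`two_step_normalize()`, `smooth_track()`, `call_states()`,
   `segment_states()`, `classify_events()`, wrapped by
   `karyotype_panel()`).
3. **Locus mapping** — interval logic combining per-line absence
   calls with the phenotype under a homoeologous dosage-compensation
   rule (`apply_compensation()`, `map_locus()`,
   `detect_conflicts()`), optionally intersected with a gene
   annotation (`genes_in_interval()`).
4. **Trait statistics** — seed set, potential spikelet productivity,
   and the multi-line comparison (one-way ANOVA with Fisher's
   protected LSD, `anova_lsd()` / `summarize_panel()`).

A fifth component, the simulator (`sim_config()`,
`simulate_panel()`), generates the whole 16-line panel with known
truth so that every stage is testable without touching the archived
sequencing data.

## Dosage karyotyping model

GBS coverage is deliberately sparse and extremely uneven along the
genome, but the unevenness is *reproducible across libraries*: it
reflects where restriction sites fall. Per-bin counts are therefore
modeled as

$$\mu_{ib} = s_i \cdot d \cdot w_b \cdot \frac{c_{ib}}{2},$$

where $s_i$ is a line's library-size factor, $d$ the panel's mean
depth per bin, $w_b$ a bin's capture weight shared by all lines, and
$c_{ib}$ the copy number. Two normalization steps cancel the nuisance
terms: dividing by each line's total count removes $s_i$, and taking
per-bin log2 ratios against a euploid reference removes $w_b$. What
remains is $\log_2(c_{ib}/2)$ plus noise: 0 for euploid bins, about
+1 for tetrasomic ones, and strongly negative values for homozygous
absence (exactly $-\infty$ only if the pseudocount is disabled; the
default pseudocount of 0.5 per bin keeps deleted bins finite but far
below any threshold).

Working choices, all configurable:

* **Pseudocount 0.5** before step 1. The counts in a deleted region
  are all zero; without a pseudocount the log ratio is undefined.
* **Per-line median recentering** (`recenter = TRUE`). Step 1
  normalizes by *total* genomic content, so an aneuploid line's whole
  track is shifted by the log2 ratio of its genome size to the
  reference's (a tetrasomic chromosome would sit at ~0.85 rather than
  1 in a nulli-tetra line). The genome-wide median ratio estimates
  this shift because most of the genome is always at copy number 2;
  subtracting it is a no-op for euploid lines. This estimator breaks
  down only if half the genome deviates from two copies, far beyond
  any stock in the panel.
* **Running-median smoothing, window 3 bins**, truncated at ends and
  never crossing a chromosome *or arm* boundary — in these stocks
  dosage changes exactly at the centromere, and smoothing across it
  blurs the one boundary that matters for telosomic and arm-addition
  calls.
* **State thresholds** at −2.0 / −0.5 / 0.5 / 0.8, near the log2
  midpoints between the expected ratios of copy numbers 0–4 relative
  to 2 (−∞, −1, 0, 0.585, 1). The original analysis read dosage off
  plotted tracks; these cut points are a numeric reconstruction and
  deliberately configurable.
* **Segmentation** into maximal constant-state runs; runs shorter
  than `min_run = 3` bins are absorbed into the neighbor with the
  closer mean smoothed ratio (ties to the lower-coordinate side).
* **Mean-gap merging** (`merge_gap = 0.3`): threshold calling splits
  a single true segment whenever the track hovers near a cut point,
  but genuine dosage steps in homozygous material separate segment
  means by at least log2(4/3) ≈ 0.415. Adjacent segments whose means
  differ by less than 0.3 are therefore re-joined and re-called from
  the combined mean. At zero noise nothing merges.
* **Despeckling**: a short run (≤ 2% of the chromosome, at least 3
  bins) whose state differs from two agreeing flanks — or that sits at
  a chromosome end one state level from its only neighbor, shorter
  than that neighbor — is threshold flicker and is relabeled. Runs of
  state 0 are never relabeled: a short homozygous absence is
  evidence, not noise.
* **Classification** matches per-arm patterns (arms assigned by bin
  midpoint): whole-chromosome 0 is nullisomy, whole-chromosome 4
  tetrasomy, a 2-arm facing a 0-arm a telosomic, a proximal-2 /
  distal-0 arm a terminal deletion (breakpoint at the first deleted
  bin, reported as FL and as a one-bin-wide interval, the tiling's
  intrinsic uncertainty), and a 4-arm over a euploid rest an arm
  addition. Up to a handful of bins of blur at the centromere is
  tolerated. Anything else is returned as an explicit `unclassified`
  record with its raw segments — never silently dropped.

With the default settings and the study's depth (50 reads/bin), all
16 lines of the bundled panel classify correctly in the large
majority of simulation replicates and the terminal-deletion
breakpoint lands within one bin of truth in far more than 95% of
simulated deletion lines; at zero noise classification is exact.
Residual misses at this depth are short noise runs that straddle both
the merge gap and the despeckle cap — with five biological states
packed into ~3 log2 units and per-bin standard deviations around
0.25 at this depth, no threshold rule is flicker-free.

## The mapping logic

Each line contributes a `line_call()`: its intervals of called copy
number 0 and its phenotype. The candidate region is

> (intersection of the absences of every constraining non-viable
> line) minus (union of the absences of every constraining viable
> line).

Two groups of lines do not constrain. Lines with unknown phenotype
are ignored with a notice. *Compensated* lines — whose compensating
homoeologous chromosome is entirely at the required dose (four, by
default) — are excluded because their phenotype is explained without
the target locus: in the published panel, the line combining 1D
nullisomy with 1B tetrasomy forms viable hybrid seed although it
lacks 1D entirely, so under a no-compensation reading it would be a
hard contradiction. `detect_conflicts()` deliberately evaluates that
reading and reports exactly such lines; `map_locus()` with the
compensation rule excludes them. Compensation is modeled as
deterministic for viability; the paper-scale "partial" compensation
appears in the quantitative traits, where compensated lines sit
between euploid and deleted means (fraction 0.5 by default — a free
parameter, as no penetrance is published).

The mapper works on exact bp intervals rather than bin memberships:
on bin-aligned calls from the karyotyper the two are identical (the
test suite proves this against an exhaustive per-bin oracle), while
on table-encoded calls with exact FL breakpoints the candidate bounds
reproduce the printed FL values exactly instead of bin-quantized
approximations. Encoding the published table (`table1_calls()`)
yields a single candidate on 1DL bounded proximally at FL 0.29 from
the initial panel, tightened to FL 0.41 by the later-tested deletion
line; because the physical positions of those FL breakpoints depend
on the 1D centromere coordinate — which no assembly release fixes —
centromere positions are mandatory user parameters, and the bundled
values are representative, not authoritative. Reproducing the
published bp interval (259–494 Mb) and its gene content requires the
archived GBS reads and the full reference annotation; the exact
external commands are returned by `refseq_reproduction_notes()`.

Soundness and monotonicity hold by construction and are tested as
properties: every candidate bin is absent in all constraining
non-viable lines and present in all constraining viable ones, and
adding a line can only shrink the candidate set. Multiple disjoint
candidates are all reported; an empty result comes back with
diagnostics naming the viable lines that erased the non-viable core,
not as an error.

## Trait statistics

Seed set is scored in florets 1 and 2 of developed spikelets:
$SS = 100 \cdot g / (2n)$ for $g$ grains over $n$ developed
spikelets, capped at 100 (reduced spikelets are excluded upstream).
Potential spikelet productivity is grains per spikelet at harvest
maturity as a percentage of floret primordia per spikelet at the
terminal-spikelet stage, per spike position.

Line-versus-control comparisons use one-way ANOVA with Fisher's
*protected* LSD: pairwise flags are only awarded when the omnibus F
test rejects at the same level, with
$LSD = t_{1-\alpha/2,\,df_e}\sqrt{MSE\,(1/n_i + 1/n_c)}$, `"*"` at
0.05 and `"**"` at 0.01. The protection rule is the conventional
reading of "ANOVA combined with LSD"; no further multiplicity
correction is applied by default (a Bonferroni option exists but is
off, matching the reporting style of the source material). For two
groups the omnibus F is the square of the pooled t statistic, so the
procedure *is* the pooled two-sample t test and its per-comparison
type-I error is exactly nominal — that two-group design is what the
type-I simulation in the test suite checks. With more than two null
groups the omnibus gate makes the procedure conservative
per-comparison; that is a property of protected LSD itself, not of
this implementation. Control-versus-line comparisons are primary
(what the published table reports); all-pairs output is available via
`all_pairs = TRUE`.

## What the simulator does and does not emulate

`simulate_panel()` draws shared log-normal capture weights (mean 1,
sigma 0.5 — GBS bin coverage is heavy-tailed; no distributional form
is published, so this is a modeling choice), per-line library-size
factors, and Poisson counts around $s_i d w_b c_{ib}/2$ (negative
binomial and a degenerate noise-free law are available). Karyotypes
are expanded deterministically from event lists; stocks are
homozygous, so copy numbers move in steps of two and breakpoint bin
membership is decided by bin midpoint. Viability is a pure function
of the truth copy numbers; traits are normal around line means with
the effect directions of the published table (locus-absent lines:
fewer grains, lower thousand-grain weight and seed set, longer
spikes).

It does **not** emulate: read-level artifacts (mapping ambiguity,
duplicates), GC- or fragment-length-dependent bias beyond the static
capture weights, mosaicism or heterozygous dosage, segregation in the
stocks, or any environmental structure in the traits (years, field
versus greenhouse). Passing tests on simulated data therefore
validate the *computational* pipeline under the stated statistical
model, not the upstream sequencing or phenotyping.

Problem sizes used in the shipped analyses and tests: the three
group-1 chromosomes (~1.8 Gb, 1781 one-Mb bins) for the panel
simulations, 200 deletion lines for breakpoint-recovery measurements,
500 random toy-genome panels for mapper soundness, and 1000
replicates for the type-I simulation — sizes at which every check
runs in seconds to a couple of minutes on one core.

## Known limitations

* Dosage states above 4 saturate (an arm at six doses still calls as
  state 4); `extra_copies` beyond 1 is reported as 1 from data.
* Sub-bin breakpoint refinement is out of scope; breakpoint
  uncertainty is one bin by construction.
* The thresholds, merge gap and despeckle caps are tuned for ~50
  reads/bin; at much lower depth widen the smoothing window before
  anything else.
* Median recentering assumes the majority of the genome is at two
  copies (safe for this panel; not for, say, a triploid).
* The compensation rule tests whole-chromosome dosage; a
  compensating *segment* would need the rule applied at a known
  homoeolocus instead.

## Repository shape

The package doubles as an analysis repository: `analysis/01...04`
are thin narrative drivers (simulate, karyotype, map, traits) that
write their tables under `results/`, and every computation they
perform lives in exported package functions, which is also what the
test suite and `scripts/acceptance.R` call. There is no separate
command-line wrapper: the scripts and functions are the interface.
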