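---
title: "Methods: predicting kinase fusions from exon coverage asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting kinase fusions from exon coverage asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covasym)
```

## The model

Oncogenic tyrosine-kinase fusions (EML4--ALK being the canonical example)
retain the 3' portion of the kinase gene — the exons encoding the tyrosine
kinase (TK) domain — under the control of the partner gene's promoter, while
the 5' exons upstream of the breakpoint are lost from the fusion transcript.
In tissues where the wild-type gene is essentially silent, this produces a
distinctive RNA-seq signature: near-zero coverage of the 5' exons and clear
coverage of the TK-domain exons. Detecting the fusion then reduces to
detecting a 5'/3' *coverage asymmetry* within one gene. Unlike
junction-based callers, this requires no reads spanning the fusion
breakpoint, so it works at modest depth and is agnostic to the fusion
partner.

For ALK the breakpoint almost always falls in intron 19, so the assay
compares two disjoint exon groups of the canonical 29-exon transcript:

* **control exons 2--6**: always upstream of the breakpoint, silent in a
  fusion, expressed in wild-type expressers;
* **TK exons 20--24**: always retained by the fusion.

Exon 1 is excluded from the control group (promoter-proximal coverage is
noisy) and exons 25--29 from the test group (the long 3' UTR exon dominates
length-weighted statistics). Both groups have five members, which fixes the
resolution of the exact test below.

## Coverage statistic

For each exon the engine counts **aligned reference bases** (not reads) from
records that pass all of:

* mapping quality strictly greater than 100 (`min_mapq = 101`), which with
  STAR output selects unique mappers at MAPQ 255;
* at least 10 bases aligned to the reference (CIGAR M/=/X/D operations; N
  gaps, soft clips and insertions do not count);
* not a duplicate, not secondary, not supplementary, not unmapped.

Bases are split by transcript orientation using the library protocol: for a
reverse-stranded library a read is *sense* when its alignment strand is
opposite the gene strand (read 2 of a pair is first flipped to the fragment
strand); for a forward-stranded library when it is equal; an unstranded
library cannot distinguish orientations and everything is counted as sense.
Only sense bases enter the test — antisense coverage from overlapping
opposite-strand transcription would otherwise masquerade as expression.

Counts are normalized per exon:

$$\text{norm}_e = \frac{\text{bases}_e / \text{length}_e}{\text{library
reads}} \times 10^6,$$

where the library size is the number of primary, mapped, non-duplicate
records genome-wide (no mapping-quality filter — it is a yield metric, not a
precision metric). Normalizing by exon length makes exons comparable within
a sample; normalizing by library size makes samples comparable within a
cohort. The statistic below is rank-based and therefore invariant to the
library-size factor, but the normalized values are what reports and plots
show, and the expression-floor verdicts depend on them.

## The exact one-sided test

With only five values per group, large-sample rank tests are inappropriate
and ties are the rule, not the exception (silent exons are exactly zero).
`exact_mwu_one_sided()` therefore computes the mid-rank Mann--Whitney U —
each (control, TK) pair scores 1 if the TK value is larger, 0.5 on a tie —
and derives the p-value by *complete enumeration*: all
$\binom{10}{5} = 252$ reassignments of the pooled values are scored, and the
p-value is the fraction with $U$ at least the observed value. Consequences:

* the p-value support is $k/252$; the smallest achievable p-value is
  $1/252 \approx 0.004$, attained exactly at complete separation;
* with every value zero in both groups the test is degenerate and returns
  $p = 1$ — the assay cannot (and should not) call a silent gene;
* the attained test size at $\alpha = 0.05$ is $12/252 \approx 0.0476$, so
  the test is slightly conservative.

```{r exact-test}
exact_mwu_one_sided(c(0, 0, 0, 0, 0), c(0.1, 0.15, 0.2, 0.25, 0.3))$p_value
exact_mwu_one_sided(rep(0, 5), rep(0, 5))$p_value
```

A comparison against the observed U uses a `1e-9` slack so that mid-rank
halves, which are exactly representable in binary floating point but arise
from sums of many terms, never drop a tied reassignment. Enumeration is
capped at 14 pooled values (3432 splits), far above the assay's 10.

## Verdicts and the reliability gate

`classify_asymmetry()` maps the test to a verdict: `FUSION_PREDICTED` when
$p < \alpha$; otherwise `WILD_TYPE_EXPRESSION` when mean control coverage is
at least the expression floor; `NOT_EXPRESSED` when both group means are
below the floor; `NO_ASYMMETRY` otherwise. The floor (default 0.01
normalized units) is a heuristic separating "expressed" from "noise"; it
only discriminates among non-significant verdicts and never creates or
suppresses a fusion call.

Independent of the verdict, the **TK depth** — total sense bases over TK
exons divided by their combined length, i.e. mean per-position depth — is
compared against a reliability gate (default 0.7). Below the gate the call
is annotated `LOW_COVERAGE_UNRELIABLE` but *not changed*: at such depths a
significant asymmetry is plausible yet fragile (see the subsampling
experiment), and masking it would hide true fusions in shallow libraries.
By default the depth counts sense bases only, consistent with the test
statistic; `depth_both_strands = TRUE` switches to total coverage for
libraries with appreciable antisense signal. A separate library-level QC
(default 2.5 million usable reads, boundary inclusive) marks whole samples
as `QC_FAIL` in batch screening.

## The simulator: realism and limits

`sim_profile()` + `simulate_alignments()` generate coordinate-sorted SAM
files with a known truth label. On-target reads are assigned to exons with
probability proportional to *weight × length* (`FUSION`: zero weight before
the breakpoint exon, `fold` above it; `WILD_TYPE`: uniform; `SILENT`:
nothing), start uniformly at positions where the read fits entirely inside
its exon, carry MAPQ 255, and get their alignment strand from the configured
library convention — with an optional `antisense_fraction` emulating
read-through from a neighboring opposite-strand gene. Background reads fall
uniformly on a decoy contig, so library size and on-target depth are
controlled independently.

Deliberate simplifications: no reads span exon--exon junctions (real RNA-seq
has spliced reads; the counting engine handles N gaps, the generator just
does not emit them), no sequencing errors, no fragment-length model, no
multimappers, single-end only. These omissions are conservative for testing
the *statistics* — every generated base lands in exactly one exon, so
expected counts are known in closed form — but mean the simulator is a test
harness, not a read-level benchmark generator. Output is byte-identical
given the same seed (`withr::with_seed`, no global RNG pollution).

## The depth subsampling experiment

The reliability gate is calibrated by `depth_reliability_experiment()`:
simulate one master fusion library, subsample it without replacement to a
grid of total read counts in triplicate, and record TK depth and p-value per
subsample. The published design used 1--20 million reads; this package
reproduces the experiment *in shape, not magnitude* — a grid in the tens of
thousands of reads with the on-target fraction chosen so the resulting TK
depths straddle the 0.7 gate. That keeps the experiment deterministic,
seconds-fast and CI-friendly while exercising the same phenomenon: above the
gate every replicate is significant; below it, missing coverage on single
exons makes the 5-vs-5 enumeration lose resolution (with zero controls,
significance needs at least four of the five TK exons covered) and calls
become unstable.

```{r subsample, eval = FALSE}
profile <- sim_profile("FUSION", alk_exon_model(), seed = 1L)
res <- depth_reliability_experiment(profile, config = assay_config(min_library_reads = 1000))
power_curve(res)
autoplot(res)
```

## Numerical and design choices

* **Coordinates**: 0-based half-open internally; GTF (1-based closed) and
  BED12 are converted on load. Exon numbering always follows transcription
  order, so on the minus strand exon 1 has the largest genomic start.
* **Bases, not reads**: counting aligned bases per exon with length
  normalization avoids double-counting boundary reads and weights partial
  overlaps naturally.
* **Exact, not asymptotic**: at $n = 5 + 5$ with heavy ties, the normal
  approximation to U is badly sized; enumeration is exact, deterministic and
  costs 252 evaluations.
* **Rounding is display-only**: p-values print at three decimals and
  percentages at one decimal, matching reporting conventions; JSON artifacts
  retain full precision, and tests assert on exact fractions like
  $1/252$.
* **Subsampling from alignments**, not re-sequencing: emulates lower depth
  from the same library, which is the question the gate answers; it cannot
  model depth-dependent duplication rates.
* **Desk-scale problem sizes** (hundreds-to-thousands of simulated reads per
  sample, tens of thousands in the subsampling experiment) are a package
  choice: every documented result recomputes from scratch in seconds on one
  CPU with no external data.

## Open questions carried as configuration

The exon groups, alpha, the depth gate, the expression floor, the read
filters and the library protocol are all fields of `assay_config()` and can
be re-targeted to another kinase gene by supplying a different gene model
(`read_exon_model()` accepts GTF, BED12 and a plain exon table) and exon
groups. The defaults encode the published ALK assay; none of them is claimed
optimal for other genes, tissues or library preparations.
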