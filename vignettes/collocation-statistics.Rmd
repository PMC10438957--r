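---
title: "Quantifying genomic collocation: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic collocation: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcoloc)
```

## The problem

Deciding whether two sets of genomic intervals — ChIP-seq peaks of two
transcription factors, ATAC-seq open-chromatin regions versus a binding-site
catalogue — "overlap more than expected" is usually done by picking an
overlap cutoff, labelling each query peak overlapped or not, and counting.
That binary reduction throws away the magnitude of each overlap and makes
the result depend on an arbitrary threshold and, worse, on how many peaks
each database entry happens to have. peakcoloc instead measures collocation
at base-pair resolution: every statistic is a function of the four base
counts

$$|A|,\quad |B|,\quad |A \cap B|,\quad G,$$

where $|A|$ is the number of distinct bases covered by set $A$ after
merging redundant coverage, $|A \cap B|$ the bases covered by both sets,
and $G$ the genome (background) size from a chrom.sizes file. Every input
interval contributes to these counts whether or not it overlaps the other
set.

## The six statistics

Four intersection-based coefficients normalize $|A \cap B|$ by different
summaries of the two set sizes, all bounded in $[0, 1]$:

| statistic | definition | denominator |
|---|---|---|
| collocation coefficient $C$ | $|A \cap B| / \sqrt{|A||B|}$ | geometric mean |
| Jaccard $J$ | $|A \cap B| / |A \cup B|$ | union |
| Sørensen–Dice $SD$ | $2|A \cap B| / (|A| + |B|)$ | arithmetic mean |
| Szymkiewicz–Simpson $SS$ | $|A \cap B| / \min(|A|, |B|)$ | smaller set |

Since $\min \le \sqrt{|A||B|} \le (|A|+|B|)/2 \le |A \cup B|$, the scores
always order $SS \ge C \ge SD \ge J$, and $J$ and $SD$ are deterministic
transforms of one another ($J = SD/(2-SD)$). $J$ and $SD$ are dragged down
by a large size imbalance, $SS$ saturates whenever one set is nested in the
other; $C$'s geometric mean is the compromise least sensitive to skew.
All four are defined as 0 when either set is empty.

Two information-theoretic measures compare the observed joint coverage
probability with the product of the marginals, $p(X) = |X|/G$:

$$\mathrm{PMI} = \ln \frac{p(A \cap B)}{p(A)\,p(B)}, \qquad
\mathrm{NPMI} = \frac{\mathrm{PMI}}{-\ln p(A \cap B)}
             = \frac{\ln p(A)p(B)}{\ln p(A \cap B)} - 1 .$$

PMI is 0 exactly when the sets share as many bases as independent placement
would predict, positive when they collocate, negative when they avoid each
other; its upper bound $\min(-\ln p(A), -\ln p(B))$ depends on the set
sizes, which is why NPMI — rescaled to $[-1, 1]$ with $-1$ = no shared
bases, $0$ = independence, $1$ = identical sets — is preferred for
cross-comparison. We use natural logarithms for PMI (NPMI is base-invariant).

Boundary conventions, chosen to agree with the printed bounds and tested
explicitly: empty intersection gives $\mathrm{PMI} = -\infty$ and
$\mathrm{NPMI} = -1$ (the limiting values); $p(A \cap B) = 1$ (both sets are
the whole genome) gives $\mathrm{NPMI} = 1$, the identical-set bound, where
the defining ratio is $0/0$; an *empty input set* yields NA for PMI/NPMI
rather than a number, because $\ln 0$ in a marginal is not a collocation
signal — the intersection-based scores return 0 there instead.

```{r boundaries}
g <- sim_genome(c(chr1 = 1000))
a <- tibble::tibble(chrom = "chr1", start = 0, end = 200)
b <- tibble::tibble(chrom = "chr1", start = c(190, 300), end = c(200, 340))
coloc_stats(a, b, g)
```

## Interval handling

Coordinates are BED convention (0-based, half-open); all cardinalities are
sums of `end − start` after merging. Merging fuses overlapping *and*
abutting intervals, so duplicated peaks never double-count bases.
Chromosome names are matched as exact strings (`"chr1"` ≠ `"1"`); an
interval on a chromosome absent from the genome is an error, as is an
interval running past the chromosome end — `clip = TRUE` opts into
truncation with a warning, because silent clipping hides genome-version
mismatches. Strand is ignored throughout: peak comparisons are
strand-agnostic. The heavy lifting (merge, intersection, complement) is
done by GenomicRanges; the test suite checks every base count against an
independent per-base boolean-array oracle on small genomes.

## Bootstrap confidence intervals

`coloc_bootstrap()` resamples 75% of each set's raw (pre-merge) intervals
— independently for A and B, without replacement, `max(1, floor(0.75 n))`
intervals — 20 times by default, recomputing the statistic each time.
Two 95% intervals are reported: the normal approximation (replicate mean
± 1.96 SD, clamped to the metric's range), the default because the
percentile interval is unstable at 20 replicates, and the raw percentile
interval alongside.

One property of this scheme matters for interpretation: subsampling both
sets at fraction $f$ retains a shared base only when both covering
intervals survive, so $|A' \cap B'| \approx f^2 |A \cap B|$ while
$|A'| \approx f|A|$. The intersection-based scores of a replicate are
therefore shrunk by roughly $f$ relative to the full-data score, and their
intervals describe variability around that shrunken recomputed value, not
around the point estimate. PMI is invariant under this scaling
($\ln(f^2 p_{ab} / (f p_a \, f p_b)) = \mathrm{PMI}$), and NPMI nearly so;
the replicate-coverage property test is accordingly run on PMI. Replicates
with an empty resampled intersection give $-\infty$ PMI and are excluded
from the interval with their count reported; if more than half the
replicates are $-\infty$, the interval is NA.

## The scan and the combined Z-score

`coloc_scan()` computes the six statistics between one query and every
database entry, converts each metric column to Z-scores
$Z_i = (x - \mu)/\sigma$ — $\mu, \sigma$ taken over the scan table itself,
the only population available, with the sample (n−1) SD — and combines

$$Z = \frac{\sum_i Z_i}{\sqrt{k}},$$

$k$ being the number of non-missing metrics (6 normally; fewer when a
target's PMI is $-\infty$, which cannot be standardized and is treated as
missing for that column). The $\sqrt{k}$ denominator follows the
Z-combination convention of gene-set variation analysis; `method = "mean"`
gives $\sum Z_i / k$ instead. Both are monotone transforms of the plain
sum, so ranks and outlier calls are identical — only the scale changes, and
the suite asserts that invariance. Targets are ranked by combined Z
descending (ties broken by name, stably), and a target is flagged an
outlier — a putative cofactor or master regulator — when its combined Z is
more than 3 sample SDs from the scan mean. A metric with zero variance
across targets is assigned Z = 0 with a warning rather than dividing by
zero; with as few as 3 targets the n−1 SD choice is material and is
documented here deliberately.

`baseline_scan()` implements the conventional threshold-and-count
comparison at the usual cutoff ladder (1 nt, then 10/30/50/80/100% of each
query peak's own length, a peak's overlap summed across target fragments,
query peaks counted as given rather than merged). Proportions are
non-increasing along that ladder by construction.

## What the generators emulate — and what they do not

The fixture generators stand in for real peak catalogues so that every
behaviour above is testable offline.

* `sim_genome()` defaults to one chromosome of 1 Mb: large enough for
  stable coverage fractions, small enough that the per-base oracle and the
  full test suite stay fast.
* `sim_intervals()` places peaks uniformly and non-overlapping (≥ 1 bp
  apart, so requested and realized interval counts agree), with lengths
  uniform in 100–300 bp by default — a typical ChIP-seq peak-width range.
* `sim_pair()` plants a target fraction of A's bases into B by copying
  whole A intervals (plus one trimmed prefix to land on the exact base
  budget) and places B's remaining intervals in the complement of A, so the
  realized shared fraction equals the plant up to one interval's rounding;
  the generator reports its own bookkeeping, which the tests then verify
  against the measurement code.
* `sim_independent_pair()` is a deterministic block construction with
  exactly $|A \cap B| = |A||B|/G$, hence PMI = NPMI = 0 to machine
  precision; it requires $|A||B|$ divisible by $G$ and otherwise suggests
  the nearest feasible cardinality.
* `sim_biased_database()` reproduces, in silico, the failure mode that
  motivates threshold-free scoring: one target made of a few of the query's
  own peaks (truly collocated), and independent targets whose peak counts
  span two orders of magnitude (50–5000 at 100 bp on the 1 Mb genome). At
  those defaults the largest independent target covers half the genome, so
  it overlaps roughly 60% of query peaks at the 1-nt cutoff by chance alone
  — more than the collocated target's 20% — while its Jaccard/NPMI stay at
  independence level. Threshold-and-count therefore ranks it first;
  the combined Z-score ranks the collocated target first and flags it as
  the sole outlier. These expectations follow from the placement
  arithmetic, not from fitting.

None of the generators mimic real peak-width distributions, GC- or
mappability-dependent placement, chromosome-territory effects, or the
correlation structure of real TF databases. Passing tests therefore
demonstrate correctness of the statistics and pipelines under controlled
overlap structure — not that any biological ranking will be recovered on
real data, where background models matter.

## Numerical choices

Base counts are held as doubles (cardinality products overflow 32-bit
integers at megabase scale) and all ratios are computed in double
precision from exact integer counts; the library never rounds. Oracle
agreement is asserted to 1e−12 absolute. Problem sizes in the routine test
run — genomes up to 100 kb for per-base validation, 1000 random fixtures,
10,000 random summaries for the algebraic identities — were chosen so the
whole suite exercises every path at desk scale.

## Known limitations

* PMI/NPMI treat the genome as a uniform background; no local background
  correction (GC, mappability, blacklists) is attempted.
* No significance testing is provided for pairwise scores — the package's
  viewpoint is that effect-size measures, not threshold-dependent test
  statistics, are the right currency for collocation.
* The bootstrap quantifies resampling variability only; see the shrinkage
  caveat above for the intersection-based metrics.
* BAM input, peak calling, and coordinate liftover are out of scope; inputs
  are BED3+ and chrom.sizes.
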