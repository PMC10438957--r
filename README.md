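# peakcoloc

Threshold-free collocation statistics for genomic interval sets.

## The problem

A constant task in regulatory genomics is asking how strongly two sets of
genomic intervals co-locate: do the ChIP-seq peaks of one transcription
factor sit on the binding sites of another? Do condition-specific
open-chromatin regions coincide with a factor's catalogued sites? The
common recipe — pick an overlap cutoff, call each query peak overlapped or
not, report the overlapped percentage — makes binary calls out of a
continuous quantity. The result depends on the arbitrary cutoff and is
systematically inflated for database entries that simply have many peaks,
so genuinely collocated partners can be outranked by large unspecific peak
sets.

peakcoloc measures collocation at base-pair resolution instead. With
`|A|`, `|B|` the merged (non-redundant) base counts of the two sets,
`|A∩B|` their shared bases, and `G` the genome size, it computes six
statistics:

* **Collocation coefficient** `C = |A∩B| / sqrt(|A||B|)` — intersection
  over the geometric mean, the least size-skew-sensitive of the family;
* **Jaccard** `J = |A∩B| / |A∪B|`;
* **Sørensen–Dice** `SD = 2|A∩B| / (|A|+|B|)` (with `J = SD/(2−SD)`);
* **Szymkiewicz–Simpson** `SS = |A∩B| / min(|A|,|B|)`;
* **PMI** `= ln( p(A∩B) / (p(A)p(B)) )` with `p(X) = |X|/G` — 0 under
  independence, positive for more overlap than expected;
* **NPMI** `= ln(p(A)p(B)) / ln(p(A∩B)) − 1` — PMI rescaled to [−1, 1].

On top of the pairwise scores it provides non-parametric bootstrap
confidence intervals (75% of raw intervals resampled without replacement,
20 replicates by default), a one-query-vs-many-database scan that converts
each metric to Z-scores, combines them as `Z = ΣZᵢ/√k`, ranks targets and
flags putative cofactors more than 3 SD from the scan mean, the
conventional threshold-and-count baseline for comparison, and generators
for synthetic BED fixtures with controlled overlap structure.

Inputs are plain BED3+ files (0-based half-open, gzip accepted) and a UCSC
chrom.sizes file; everything is a tibble in and a tibble out, so results
pipe straight into dplyr/ggplot2.

## Worked example

Simulate a 1 Mb genome, a query of 500 peaks of 100 bp, and a database
containing one truly collocated target (100 of the query's own peaks) plus
19 independent targets whose peak counts span 50–5000:

```r
library(peakcoloc)

g  <- sim_genome(c(chr1 = 1e6))
q  <- sim_intervals(g, 500, lengths = list(dist = "fixed", len = 100), seed = 10)
db <- sim_biased_database(g, q, seed = 20)

coloc_scan(q, db$database, g)
#> # A tibble: 4 × 8      (first rows; z columns omitted)
#>   target     card_b      j    ss     npmi combined_z  rank outlier
#> 1 collocated  10000 0.2    1      0.651        9.48      1 TRUE
#> 2 random_19  500000 0.0489 0.513  0.00714      1.13      2 FALSE
#> 3 random_18  387100 0.0436 0.365 -0.0144       0.528     3 FALSE
#> 4 random_16  232100 0.0453 0.244  0.0117       0.404     4 FALSE
```

The planted target ranks first with a combined Z-score of 9.5 and is the
only 3-SD outlier; the independent targets cluster near zero, NPMI ≈ 0
reflecting independence. The conventional baseline at the most relaxed
cutoff tells the opposite story — the 5000-peak random target covers half
the genome and touches 82% of query peaks by chance, outranking the real
signal:

```r
baseline_scan(q, db$database, thresholds = "1nt")
#>   threshold target    n_query_peaks n_overlapped proportion  rank
#> 1 1nt       random_19           500          410      0.82      1
#> 2 1nt       random_18           500          331      0.662     2
#> 3 1nt       random_17           500          259      0.518     3
```

Bootstrap intervals for a pair with a planted 50% shared fraction:

```r
ab <- sim_pair(g, n_a = 200, n_b = 200, shared_fraction = 0.5, seed = 1)
tidy(coloc_bootstrap(ab$a, ab$b, g, seed = 7))
#>   metric estimate ci_low ci_high ci_low_pct ci_high_pct n_dropped
#> 1 c         0.494  0.317   0.415      0.326       0.415         0
#> 2 j         0.328  0.187   0.261      0.195       0.262         0
#> ...
#> 5 pmi       2.54   2.40    2.65       2.43        2.65          0
#> 6 npmi      0.642  0.511   0.602      0.520       0.601         0
```

(Subsampling both sets shrinks the intersection-based replicate scores by
roughly the resample fraction — see the vignette for why the PMI interval,
which is invariant under that scaling, covers the point estimate while the
others sit below it.)

A thin command-line wrapper ships in `inst/cli/coloc.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","coloc.R",package="peakcoloc"))') \
  stat A.bed B.bed -g genome.chrom.sizes -o pair.tsv --bootstrap
```

with subcommands `stat`, `scan`, `baseline` and `simulate`.

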