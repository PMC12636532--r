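# hybridploid

Genome-architecture analysis for allodiploid hybrids — clonally propagating
diploids whose two chromosome sets descend from different parental species.
Such genomes (best characterized in yeasts, and increasingly in green algae
such as *Auxenochlorella*) accumulate a distinctive set of signatures during
asexual growth: high inter-haplotype heterozygosity from the original
hybridization, loss-of-heterozygosity (LOH) tracts where mitotic
recombination has homogenized the homologs, chromosome-scale mosaics of the
two parental subgenomes produced by mitotic crossovers, and transient
aneuploidy visible as integer steps in sequencing depth.  `hybridploid`
provides the complete analysis chain for dissecting these signatures from
standard genomics files, plus the curation rules needed to build a clean
long-read (IsoSeq) gene annotation on such a genome.

The package is aimed at genome-assembly and population-genomics
practitioners working with phased diploid assemblies of clonal eukaryotes.

## What it computes

* **Windowed heterozygosity and divergence.**  Chromosomes are tiled with
  10-kb windows; heterozygosity is the count of heterozygous SNVs relative
  to the number of alignable sites per window, and windows with < 2,000
  aligned sites are excluded.  Divergence of a diploid strain to a
  reference half-weights sites at which only one of the two haplotypes
  differs.  Coding positions are classified as 0-, 2-, 3- or 4-fold
  degenerate under the standard genetic code.
* **LOH segmentation.**  LOH events are maximal stretches free of
  heterozygous sites of ≥ 1 kb, bounded by the inner edges of the flanking
  het sites, clipped to the alignable blocks, and classed interstitial,
  terminal, or whole-chromosome.  Event sets from two strains can be
  matched by reciprocal overlap, and sites unaffected by LOH in every
  strain extracted for phylogenetics.
* **Parent-of-origin assignment.**  Each haplotype window is labeled P1 or
  P2 by contrasting its divergence to the two parental references
  (divergence to the true parent sits at the within-species heterozygosity
  level; to the other parent at the between-species level).  Label changes
  co-located on both haplotypes with opposite directions are reciprocal
  switches (mitotic crossovers); single-haplotype changes are
  nonreciprocal, LOH-consistent switches.
* **Aneuploidy.**  Read depth is averaged in 20-kb bins; each chromosome's
  median bin depth is compared to the genome-wide per-copy baseline, with
  `copy = round(ratio)` against a phased diploid reference and
  `copy = round(2·ratio)` against a collapsed haploid one.  Partial
  aneuploidy is segmented by recursive binary segmentation on
  log2(depth/baseline) with a 0.5 acceptance gap.  Sequence scans locate
  internally mapped telomere repeats (`(TTAGGG)n`) and AT-rich intergenic
  centromere candidates.
* **Methylation metaplots.**  Per-site 5mC/6mA fractions (sites with < 5
  valid reads removed) are aggregated as the median per nucleotide
  position relative to IsoSeq TSSs, and the nucleosome-scale period is
  estimated by autocorrelation.
* **IsoSeq gene-model curation.**  Gene decoupling by shared CDS, isoform
  filtering (< 5 reads or < 5% of the gene total), primary-isoform
  selection by the 50%/80% read-support/coding-length cascade, ORF
  extension under a Kozak position-frequency log-odds model (extend to the
  5'-most in-frame upstream ATG scoring above the training 25th percentile
  or above the annotated start), antisense-lncRNA association at ≥ 30%
  overlap of the coding gene span, and gene-ID assignment (increments of
  5, allelic B genes inherit their A partner's number, organelles from
  80000/90000).
* **A synthetic allodiploid genome simulator** (`simulate_hybrid()`) that
  plants all of the above as ground truth — two parental subgenomes at
  ≈ 2.7% divergence with within-parent diversity 0.6%/1.35%, 36 LOH tracts
  of all three classes, reciprocal and nonreciprocal switches,
  whole-chromosome and partial copy gains, cosine-periodic methylation,
  and multi-isoform genes — and emits every observable file (FASTA, VCF,
  BED, bedGraph, bedMethyl-like TSV, GFF3).

## Worked example

Simulate the default 2.2-Mb hybrid and run the main callers:

```r
library(hybridploid)

cfg   <- sim_config(seed = 1)
truth <- simulate_hybrid(cfg)
truth
#> <hybrid_truth> 12 chromosomes, 2.20 Mb; 34376 het sites; 36 LOH tracts;
#>   7 switches; 13 copy segments; 120 transcripts

blocks <- as.data.frame(truth$blocks)
loh <- call_loh(truth$variants_het, truth$chrom_lengths, blocks = blocks)
summarize_loh(loh, sum(truth$chrom_lengths))
#> <loh_summary> 36 events, 894895 bp (40.7% of genome)
#>              kind  n total_bp
#>      interstitial 28   194526
#>          terminal  5   170369
#>  whole_chromosome  3   530000
#> events > 5000 bp: 20; max length: 210000 bp

het_summary(truth$variants_het, blocks, truth$chrom_lengths,
            loh = loh)$rate_pct
#> [1] 2.714                  # planted between-parent divergence was 2.7%

bins <- bin_coverage(truth$coverage, truth$chrom_lengths)
subset(call_ploidy(bins, mode = "phased"), copy_number > 1 | flagged)
#>   chrom median_bin_depth baseline_depth    ratio copy_number flagged
#> 3 chr03            101.3        50.1375 2.020444           2   FALSE
#> 5 chr05             73.6        50.1375 1.467963           1    TRUE

estimate_periodicity(tss_metaplot(truth$methyl, truth$tss))
#> <periodicity> period 199 bp; peaks at 200, 400, 600, ...
```

The 40.7% homozygous fraction is the called LOH span over the genome; the
heterozygosity outside LOH recovers the planted 2.7% divergence.  chr03 at
depth ratio 2.0 is the planted whole-chromosome gain (trisomy when counting
both haplotypes); chr05 is flagged at ratio 1.47 because only half of it is
duplicated — `segment_partial_aneuploidy()` places its breakpoint at the
planted position, where `find_internal_telomeres()` also reports an
internally mapped telomere repeat.  The methylation metaplot recovers the
planted 200-bp nucleosome-scale period.

A thin command-line front end is installed as `exec/hybridploid`
(`Rscript $(Rscript -e 'cat(system.file("exec/hybridploid", package="hybridploid"))') simulate --out DIR --seed 1`).

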