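---
title: "Methods and design notes for hybridploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hybridploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical procedures implemented in
`hybridploid`, the assumptions behind them, and the reasoning behind the
design choices that were genuinely open.  It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

# The biological model

An allodiploid hybrid carries one chromosome set from each of two parental
species.  Three divergence scales structure everything the package
computes:

* **between-parent divergence** (default 2.7% per site) — the distance
  between the two subgenomes, and therefore the heterozygosity of the
  hybrid wherever the two haplotypes still descend from different
  parents;
* **within-parent diversity** of each species (defaults 0.6% for parent 1
  and 1.35% for parent 2) — the distance between a haplotype and an
  independent reference genome *of its own* species;
* **zero** — the distance between the two haplotypes wherever mitotic
  recombination has copied one homolog over the other (LOH).

Because these scales are separated by roughly 2–4x, window-level rates
simultaneously identify LOH (heterozygosity collapses to zero), assign a
parent of origin (divergence to the true parent sits at the within-species
level), and expose mitotic crossovers (the parent-of-origin labels switch
along a chromosome, reciprocally on both haplotypes for a crossover,
on one haplotype for an LOH-mediated switch).

# Windowed rates

Heterozygosity and divergence are computed in fixed windows (default
10 kb, anchored at coordinate 0) as `100 * variant_weight /
aligned_sites`.  The denominator is the number of alignable-block bases in
the window — never the window width — so unalignable sequence cannot
deflate rates.  Windows with fewer than 2,000 aligned sites are excluded
(rate `NA`); the final partial window of each chromosome is kept and
subjected to the same filter.  For divergence of a diploid strain against
a reference, a site carried by only one of the strain's two haplotypes
contributes weight 0.5, a site carried by both weight 1.0, making the
window statistic an average over haplotypes.  The same exclusion threshold
is applied to divergence windows as to heterozygosity windows; whether
that filter should differ between the two statistics is configurable
through `min_aligned`.

Degeneracy classification assigns each CDS position the number of
alternative bases preserving the amino acid (+1): classes 0, 2, 3 and 4.
The 3-fold class (isoleucine third positions) is kept as its own class
rather than merged into a neighbor — merging would discard information,
and downstream summaries can pool classes as they wish.

# LOH calling

An LOH event is a maximal stretch with no heterozygous site of at least
`min_len` (default 1,000 bp).  Between consecutive het sites at 1-based
positions `p1 < p2`, the het-free interval is `[p1, p2-1)` in 0-based
half-open coordinates — the *inner-edge* convention, from the base after
the left flanking het to the base before the right one.  This is the
tightest interval defensible from the data; the true recombination tract
may extend up to the flanking het sites, so reported lengths are
conservative.  Gaps are clipped to the alignable blocks before the length
filter, so unalignable sequence is never reported as homozygous (clipping
only shrinks a gap, which also makes the implementation safe to prefilter
by length).  A gap touching a chromosome end is `terminal`; a chromosome
with no het site at all yields a single `whole_chromosome` event spanning
the chromosome.  Between-strain comparison treats two events as shared
when their overlap reaches 50% of *each* event's length (reciprocal
overlap), greedily by decreasing overlap; the criterion is configurable
because no principled value is forced by the data.

# Parent-of-origin assignment

For each haplotype, every window carries two divergence rates, `d_p1` and
`d_p2`.  The confident rule is scale-free: label P1 when
`d_p2 / d_p1 >= 2`, P2 for the converse.  At the default simulation rates
the P1 contrast is ~2.7/0.6 = 4.5x and trivially confident, but the P2
contrast is 2.7/1.35 = 2.0x — *exactly at* the threshold — so roughly half
of genuinely P2 windows fail the ratio test from binomial noise alone.
Treating those windows as unknowable would shred true segments into
fragments.  The package therefore distinguishes confidence from direction:
windows failing the ratio test but with unequal rates receive the
maximum-likelihood *lean* (the parent with the smaller divergence, which at
10-kb windows errs with probability far below 1%), and the `confident`
column records which rule fired.  Smoothing then proceeds in two passes per
chromosome:

1. a non-ambiguous run shorter than `min_run_windows` (default 3) lying
   between runs that agree on a different label is an isolated island and
   is demoted to ambiguous; its neighbors merge and the check repeats.
   Terminal runs and runs between disagreeing neighbors are kept — at a
   marginal contrast, weak but unopposed evidence is still evidence;
2. each maximal ambiguous run is absorbed into agreeing (or single)
   flanks; between *disagreeing* flanks each window falls back to its
   lean, which pins the transition to within one window.

Windows with at least half their width inside a called LOH event are
labeled directly by the lean and exempted from suppression: inside LOH
both haplotypes carry the shared post-LOH parent, so the direct divergence
comparison is the correct statistic there and a single-window LOH label is
not noise.  Consequences: boundaries of window-scale LOH tracts surface as
additional (real, LOH-attributed) nonreciprocal switches, and windows
split exactly 50/50 by a tract boundary are genuinely tied — evaluations
in the test suite count either label as correct there.

Switch detection pairs breakpoints across haplotypes within ±1 window; an
opposite label exchange is `reciprocal` (mitotic crossover), anything else
`nonreciprocal` (LOH-consistent).  The simulator's ground-truth switches
are restricted to boundaries whose flanking segments both span at least
`switch_min_bp` (default 30 kb = 3 windows): a planted tract below the
window scale is not a parentage switch at window resolution.

# Aneuploidy

Depth is averaged in 20-kb bins (length-weighted re-binning from whatever
granularity the input track has; uncovered bases count as zero).  The
per-copy baseline is the median of per-chromosome median bin depths,
recomputed once after dropping chromosomes deviating more than 25% —
medians keep focal amplifications and the aneuploid chromosomes themselves
from dragging the baseline.  Two reference modes cover the two mapping
strategies in use: against a *phased* diploid assembly each haplotype
receives its own reads, so the baseline is one copy and
`copy = round(ratio)`; against a *collapsed* haploid assembly both
homologs pile together, the baseline is two copies and
`copy = round(2*ratio)`.  A ratio far from an integer (beyond `int_tol`,
default 0.2) is flagged rather than forced — that is exactly the signature
of partial aneuploidy, which recursive binary segmentation on
`log2(depth/baseline)` then resolves.  A split is accepted when segment
means differ by at least 0.5 in log2 — half the spacing of adjacent
integer copy states — with at least 5 bins per segment; both values are
parameters because the acceptance gap trades breakpoint sensitivity
against false segmentation under depth noise.

The telomere scan reports maximal tandem runs of the motif (default
`TTAGGG`, both strands) with at least 4 copies; a run at least 10 kb from
both chromosome ends is `internal`.  Both values are conventional rather
than forced by data: 4 copies (24 bp) is the shortest run unlikely by
chance in a ~60% GC genome, and 10 kb comfortably exceeds subtelomere
scale.  The centromere scan looks for AT-rich islands in the intergenic
complement of the gene spans: maximal runs whose 500-bp sliding GC stays
at or below 55%, kept between 2 and 10 kb.  The thresholds bracket the
regional-centromere summary statistics reported for streamlined algal
genomes (candidates near 48% GC, 2.1–7.6 kb, against a ~64% GC
background) without being tuned to any one genome.

# Methylation metaplots

Sites with fewer than 5 valid reads are removed first.  Offsets are
oriented by the gene (`pos - tss` on plus, `tss - pos` on minus strand)
and the per-offset statistic is the *median* across genes — robust to the
bimodal (all-or-none) per-site fractions typical of CpG methylation — with
the contributing site count reported so sparse offsets can be masked.  The
default window is 1 kb upstream to 2 kb downstream, covering the first few
nucleosomes where the periodic signal concentrates.  Period estimation
detrends the profile by its mean and takes the autocorrelation-maximizing
lag in 50–500 bp; autocorrelation is insensitive to baseline shifts and to
the phase of the first peak, which a direct peak-spacing estimate is not.
Peaks are local maxima above the 75th percentile separated by at least
half a period.  One TSS per gene is used (the primary isoform's); using
all isoform TSSs would double-count internally initiated transcripts.

# IsoSeq curation rules

Gene decoupling builds connected components over same-strand CDS overlap
(≥ 1 bp); UTR overlap deliberately creates no edge, since 3'-UTR overlap
of adjacent genes is routine in compact genomes.  Isoform filtering drops
isoforms with < 5 reads or < 5% of the gene's read total, with fractions
computed on the *pre-filter* total in a single pass — iterating the
fraction filter would make the retained set depend on removal order — and
a guard retains the single most abundant isoform if all fail.  Primary
selection: the longest-CDS isoform wins if it is also most abundant, or
carries ≥ 50% of the most abundant isoform's reads; otherwise the most
abundant isoform wins if its CDS is ≥ 80% of the longest; otherwise the
longest (truncated isoforms are over-represented in full-length cDNA
data).  Ties on CDS length fall to read count, then exon length, then id,
making the choice order-invariant.

The Kozak model scores the start-codon context at offsets −10..−1 and
+4..+6 (A of the ATG at +1) — the span over which initiation-context
information is empirically concentrated — as
`sum(log2(freq/background))`, with per-position frequencies
pseudocounted by 1 and the background taken from the composition of the
training windows themselves.  Training uses only transcripts with no
reachable in-frame upstream ATG (no extension possible, so the annotated
start is presumed real).  Extension fires when an in-frame upstream ATG
with no intervening in-frame stop scores above the training 25th
percentile *or* above the annotated start's own score; among qualifying
candidates the 5'-most wins (maximal extension — the most conservative
choice against truncation, and the one that makes the operation
idempotent: the qualification threshold `min(q25, annotated)` can only
rise after an extension, so a second pass never fires).

Antisense lncRNA association measures opposite-strand overlap against the
coding gene's *genomic span* (not summed exon length): the threshold
phrase "gene length" most naturally reads as the locus span, and the
choice is configurable.  The bidirectional subclass requires the lncRNA
TSS inside the gene body with a sense-strand isoform TSS within 500 bp.

Gene IDs: A-haplotype genes take 5, 10, 15, ... along the chromosomes;
paired B genes inherit their A partner's number (so allelic pairs share a
number regardless of B-side order); unpaired B genes continue past the
last A number; plastome and mitogenome genes start at 80000 and 90000.

# The simulator: what it emulates, and what it does not

`simulate_hybrid()` plants every structure the pipeline calls: Bernoulli
variant placement at the three divergence scales; LOH tracts (3
whole-chromosome, 5 terminal of 30–40 kb, 28 interstitial of 1.5–20 kb —
sizes spanning both sides of every length threshold in the pipeline); a
reciprocal crossover pair; copy gains in depth with negative-binomial
noise (per 1-kb step, variance `mu + phi*mu^2`, default `phi = 0.02`,
configurable to harsher regimes — the model is a pragmatic standard for
depth overdispersion, not a claim about any sequencer); cosine
methylation (period 200 bp, amplitude 0.45 over baseline 0.5) downstream
of each TSS; and 6 genes per chromosome, every third with 3 isoforms at
read counts 60/25/3.  The deterministic mode (`stochastic = FALSE`)
replaces Bernoulli placement by regular 1/p spacing and removes all
sampling noise, giving planted structures exact, reproducible boundaries
for exactness tests.  Component seeds derive from independent streams, so
changing the methylation stream leaves variant emissions untouched.

In a clonal hybrid, matched parentage between the haplotypes arises
through copy events, so LOH regions emit zero heterozygosity; a
label-only switch (crossover with `copy = FALSE`) instead emits
heterozygosity at the shared parent's within-species rate, covering the
scenario of two independent same-species lineages.

Deliberately *not* emulated: read-level data (FASTQ, alignment and
calling error), sequencing-error SNVs, indels and structural variants,
transposons and rearrangement breakpoints, GC-coupled coverage bias,
cell-population mosaicism, and isoform structures beyond nested-CDS
truncation.  Tests passing on this simulator therefore demonstrate the
*algorithms* recover what was planted under the stated noise; they do not
validate variant calling or alignment choices upstream, and real data
adds failure modes (mapping bias in duplicated regions, reference bias
near dense variation) that sit outside the package's scope.

Default problem sizes — a 2.2-Mb genome over 12 chromosomes (one tenth of
the 22-Mb haploid genome that motivated the architecture), ~34,000 het
sites, 2,200 coverage steps, ~22,000 methylation sites, 120 transcripts —
keep a full simulate-and-recover cycle in seconds while leaving every
per-window statistic enough sites for its noise regime.

# Numerical and degenerate-input choices

* Interval arithmetic is 0-based half-open throughout; VCF and bedMethyl
  positions stay 1-based at the file boundary.
* Rates over zero aligned sites are `NA`, never `NaN`/`Inf`; an
  all-masked genome reports `undefined` with a warning.
* `call_loh` asserts on every run that no emitted event contains a het
  site.
* Binary segmentation floors depth at `baseline/1000` before the log to
  keep zero-coverage bins finite.
* Ploidy with fewer than 3 chromosomes warns that the baseline is
  unreliable rather than refusing.
* Kozak context windows running off the transcript 5' end skip the
  missing positions rather than padding.
* Degenerate isoform sets (all isoforms failing filters, zero-read genes)
  are guarded explicitly: the former retains the most abundant isoform,
  the latter is an error.

# Known limitations

* LOH boundaries are resolution-limited by the local het-site density;
  in sparse regions the inner-edge interval may substantially exceed the
  true tract.
* Parentage assignment assumes exactly two candidate parents; admixture
  from a third lineage would surface as ambiguous labels, not as a third
  class.
* The switch classifier reports LOH-attributed label changes at
  window-scale tract boundaries as nonreciprocal switches; callers who
  want only crossover-scale events should intersect switches with the LOH
  track.
* Copy-number calls assume an integer-ploidy mixture-free sample;
  population mosaicism produces intermediate ratios that surface only
  through the integer-deviation flag.
* The Kozak model is a position-independence (PFM) model; dependencies
  between context positions are not captured.
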