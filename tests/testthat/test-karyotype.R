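test_that("re-binning averages depth by covered length", {
  cl <- c(chr1 = 40000L)
  # constant depth 50 -> all bins 50
  d <- coverage_bins(rep("chr1", 40), seq(0, 39000, 1000),
                     seq(1000, 40000, 1000), 50)
  b <- bin_coverage(d, cl, bin_bp = 20000L)
  expect_equal(b$mean_depth, c(50, 50))
  # 10 over the first half of a bin, 30 over the second -> mean 20
  d2 <- coverage_bins(c("chr1", "chr1"), c(0, 10000), c(10000, 20000),
                      c(10, 30))
  b2 <- bin_coverage(d2, c(chr1 = 20000L), bin_bp = 20000L)
  expect_equal(b2$mean_depth, 20)
  # uncovered gap counts as zero depth
  d3 <- coverage_bins("chr1", 0, 10000, 40)
  b3 <- bin_coverage(d3, c(chr1 = 20000L), bin_bp = 20000L)
  expect_equal(b3$mean_depth, 20)
  expect_error(bin_coverage(data.frame(chrom = "chr1", start = 0,
                                       end = 10, mean_depth = -1),
                            c(chr1 = 10L)), "negative depth")
  # last partial bin keeps its true width
  b4 <- bin_coverage(d, c(chr1 = 30000L), bin_bp = 20000L)
  expect_equal(b4$end - b4$start, c(20000L, 10000L))
})

test_that("copy calls are scale invariant and mode aware", {
  mk <- function(depths) {
    n <- length(depths)
    coverage_bins(sprintf("c%02d", seq_len(n)), 0L, 20000L, depths)
  }
  bins <- mk(c(272, 272, 272, 272, 272, 528, 272, 272))
  pc <- call_ploidy(bins, mode = "phased")
  expect_equal(pc$copy_number[pc$chrom == "c06"], 2L)
  expect_equal(round(pc$ratio[pc$chrom == "c06"], 2), 1.94)
  expect_true(all(pc$copy_number[pc$chrom != "c06"] == 1L))
  # multiplying every depth by a constant changes no call
  bins10 <- bins
  bins10$mean_depth <- bins10$mean_depth * 10
  pc10 <- call_ploidy(bins10, mode = "phased")
  expect_equal(pc10$copy_number, pc$copy_number)
  # collapsed-haploid reference: baseline depth means two copies
  bins2 <- mk(c(54, 54, 54, 54, 76, 54, 54, 54))
  pc2 <- call_ploidy(bins2, mode = "collapsed")
  expect_equal(pc2$copy_number[pc2$chrom == "c05"], 3L)
  expect_true(all(pc2$copy_number[pc2$chrom != "c05"] == 2L))
  expect_warning(call_ploidy(mk(c(50, 50)), mode = "phased"),
                 "fewer than 3")
})

test_that("binary segmentation finds exact noise-free breakpoints", {
  bins <- coverage_bins(rep("c1", 100), seq(0, 99) * 20000L,
                        seq(1, 100) * 20000L, c(rep(100, 50), rep(200, 50)))
  seg <- segment_partial_aneuploidy(bins, mode = "phased", baseline = 100)
  expect_equal(nrow(seg$segments), 2L)
  expect_equal(seg$breakpoints$pos, 50L * 20000L)
  expect_equal(seg$segments$copy_number, c(1L, 2L))
  # constant coverage: no breakpoints
  flat <- coverage_bins(rep("c1", 100), seq(0, 99) * 20000L,
                        seq(1, 100) * 20000L, 100)
  seg2 <- segment_partial_aneuploidy(flat, mode = "phased", baseline = 100)
  expect_equal(nrow(seg2$breakpoints), 0L)
})

test_that("copy-constant chromosomes rarely segment under realistic noise", {
  # depth noise at the simulator default (NB dispersion 0.02, 50x/copy)
  ok <- 0L
  for (r in 1:100) {
    set.seed(4000 + r)
    depth <- rnbinom(110, mu = 50, size = 50)
    bins <- coverage_bins(rep("c1", 110), seq(0, 109) * 20000L,
                          seq(1, 110) * 20000L, depth)
    seg <- segment_partial_aneuploidy(bins, mode = "phased", baseline = 50)
    if (nrow(seg$breakpoints) == 0L) ok <- ok + 1L
  }
  expect_gte(ok, 99L)
})

test_that("tandem telomere repeats are found with end-margin logic", {
  run <- strrep("TTAGGG", 5)
  bg <- strrep("C", 10000)
  seq1 <- paste0(bg, run, strrep("C", 50000 - 10000 - nchar(run)))
  g <- Biostrings::DNAStringSet(c(c1 = seq1))
  hits <- find_internal_telomeres(g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$repeat_count, 5L)
  expect_equal(hits$start, 10000L)
  expect_true(hits$internal)  # sits exactly at the 10 kb margin
  hits2 <- find_internal_telomeres(g, end_margin = 15000L)
  expect_false(hits2$internal)
  # run at position 0 is an end hit
  g3 <- Biostrings::DNAStringSet(c(c1 = paste0(run, strrep("A", 30000))))
  h3 <- find_internal_telomeres(g3)
  expect_false(h3$internal)
  # reverse-complement strand is scanned too
  rc <- strrep("CCCTAA", 6)
  g4 <- Biostrings::DNAStringSet(c(c1 = paste0(
    strrep("G", 15000), rc, strrep("G", 15000))))
  h4 <- find_internal_telomeres(g4)
  expect_equal(h4$strand, "-")
  expect_true(h4$internal)
  # motif-free sequence yields nothing
  expect_equal(nrow(find_internal_telomeres(
    Biostrings::DNAStringSet(c(c1 = strrep("A", 1000))))), 0L)
})

test_that("AT-rich candidate scan respects length and gene filters", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  mk <- function(n, gc) paste(sample(bases, n, TRUE,
                                     prob = c((1 - gc) / 2, gc / 2,
                                              gc / 2, (1 - gc) / 2)),
                              collapse = "")
  seq1 <- paste0(mk(20000, 0.64), mk(3000, 0.48), mk(20000, 0.64))
  g <- Biostrings::DNAStringSet(c(c1 = seq1))
  genes <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  cand <- find_at_rich_candidates(g, genes)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$gc_pct - 48), 3)
  expect_true(cand$start > 19000 && cand$end < 24000)
  # a 1,500 bp run is below min_len
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0(
    mk(20000, 0.64), mk(1500, 0.48), mk(20000, 0.64))))
  expect_equal(nrow(find_at_rich_candidates(g2, genes)), 0L)
  # the same run inside a gene is not intergenic
  genes3 <- data.frame(chrom = "c1", start = 19000L, end = 24000L)
  expect_equal(nrow(find_at_rich_candidates(g, genes3)), 0L)
})
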