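test_that("windowed heterozygosity computes rates over aligned sites", {
  cl <- c(chr1 = 10000L)
  # 68 het sites in a window with 2,500 aligned sites -> 2.72%
  blocks <- alignable_blocks("chr1", 0L, 2500L)
  sites <- variant_sites(rep("chr1", 68), seq(10L, by = 30L, length.out = 68))
  w <- het_windows(sites, blocks, cl)
  expect_equal(nrow(w), 1L)
  expect_false(w$excluded)
  expect_equal(w$rate_pct, 100 * 68 / 2500)
  expect_equal(w$rate_pct, 2.72)
})

test_that("windows under the aligned-site minimum are excluded", {
  cl <- c(chr1 = 10000L)
  w <- het_windows(variant_sites("chr1", 50L),
                   alignable_blocks("chr1", 0L, 1999L), cl)
  expect_true(w$excluded)
  expect_true(is.na(w$rate_pct))
  w2 <- het_windows(variant_sites("chr1", 50L),
                    alignable_blocks("chr1", 0L, 2000L), cl)
  expect_false(w2$excluded)
  # zero het sites, fully aligned -> exactly 0
  w3 <- het_windows(variant_sites(character(), integer()),
                    alignable_blocks("chr1", 0L, 10000L), cl)
  expect_equal(w3$rate_pct, 0)
})

test_that("divergence half-weights single-haplotype variants", {
  cl <- c(chr1 = 10000L)
  blocks <- alignable_blocks("chr1", 0L, 1000L)
  v <- variant_sites("chr1", c(seq(10, by = 5, length.out = 10),
                               seq(200, by = 5, length.out = 5)),
                     zygosity = c(rep("het", 10), rep("hom_alt", 5)),
                     haplotype_hits = c(rep(1L, 10), rep(2L, 5)))
  w <- divergence_windows(v, blocks, cl, min_aligned = 500L)
  expect_equal(w$rate_pct[1], (10 * 0.5 + 5) / 1000 * 100)
  expect_equal(w$rate_pct[1], 1.0)
  # all both-haplotype variants equal the plain density
  v2 <- variant_sites("chr1", seq(10, by = 5, length.out = 15),
                      zygosity = "hom_alt", haplotype_hits = 2L)
  w2 <- divergence_windows(v2, blocks, cl, min_aligned = 500L)
  expect_equal(w2$rate_pct[1], 1.5)
  v3 <- v2
  v3$haplotype_hits[1] <- 0L
  expect_error(divergence_windows(v3, blocks, cl), "haplotype_hits = 0")
})

test_that("aligned sites across windows account for every block base", {
  set.seed(5)
  cl <- c(a = 95000L, b = 40000L)
  s <- sort(sample.int(90000L, 20))
  e <- pmin(s + sample.int(3000L, 20), 95000L)
  keep <- s < e
  blocks <- suppressWarnings(alignable_blocks(rep("a", sum(keep)), s[keep],
                                              e[keep]))
  w <- het_windows(variant_sites(character(), integer()), blocks, cl)
  expect_equal(sum(w$aligned_sites), sum(blocks$end - blocks$start))
  # splitting a block at an arbitrary interior point changes nothing
  blocks2 <- blocks
  b1 <- blocks[1, ]
  mid <- b1$start + (b1$end - b1$start) %/% 2L
  blocks2 <- rbind(blocks[-1, ], data.frame(chrom = b1$chrom,
                                            start = c(b1$start, mid),
                                            end = c(mid, b1$end)))
  blocks2 <- suppressWarnings(alignable_blocks(blocks2$chrom,
                                               blocks2$start, blocks2$end))
  w2 <- het_windows(variant_sites(character(), integer()), blocks2, cl)
  expect_equal(w2$aligned_sites, w$aligned_sites)
})

test_that("degeneracy classification matches known codon anatomy", {
  # single-exon plus-strand gene: ATG GGG AAA TAA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "TTTT", "ATGGGGAAATAA", "TTTT")))
  tx <- transcript_models("t1", "g1", "chr1", "+",
                          exons = list(cbind(4L, 16L)),
                          cds = list(cbind(4L, 16L)), read_count = 10L)
  d <- classify_degeneracy(tx, genome)
  expect_equal(d$fold[d$cds_pos %in% 1:3], c(0L, 0L, 0L))  # ATG
  expect_equal(d$fold[d$cds_pos == 6], 4L)                 # GGG wobble
  expect_equal(d$fold[d$cds_pos == 9], 2L)                 # AAA wobble
  # minus strand: reverse complement of the same CDS
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGGGAAATAA")))
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0("TTTT", rc, "TTTT")))
  tx2 <- transcript_models("t1", "g1", "chr1", "-",
                           exons = list(cbind(4L, 16L)),
                           cds = list(cbind(4L, 16L)), read_count = 10L)
  d2 <- classify_degeneracy(tx2, genome2)
  expect_equal(d2$fold[order(d2$cds_pos)], d$fold[order(d$cds_pos)])
})

test_that("transcripts with internal stops or broken frames are skipped", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "TTTT", "ATGTAAAAATAA", "TTTT")))
  tx <- transcript_models("t1", "g1", "chr1", "+",
                          exons = list(cbind(4L, 16L)),
                          cds = list(cbind(4L, 16L)), read_count = 10L)
  expect_warning(d <- classify_degeneracy(tx, genome), "internal stop")
  expect_equal(nrow(d), 0L)
  tx2 <- transcript_models("t2", "g2", "chr1", "+",
                           exons = list(cbind(4L, 15L)),
                           cds = list(cbind(4L, 15L)), read_count = 10L)
  expect_warning(d2 <- classify_degeneracy(tx2, genome), "divisible by 3")
  expect_equal(nrow(d2), 0L)
})

test_that("overall heterozygosity masks LOH tracts and flags degeneracy", {
  cl <- c(chr1 = 20000L)
  blocks <- alignable_blocks("chr1", 0L, 20000L)
  sites <- variant_sites("chr1", c(100L, 5000L, 15000L))
  # no LOH: plain genome-wide rate
  s0 <- het_summary(sites, blocks, cl)
  expect_equal(s0$rate_pct, 100 * 3 / 20000)
  # mask [0, 10000): only the site at 15000 and 10000 aligned bp remain
  loh <- loh_events("chr1", 0L, 10000L, "terminal")
  s1 <- het_summary(sites, blocks, cl, loh = loh)
  expect_equal(s1$het_sites, 1L)
  expect_equal(s1$aligned_sites, 10000L)
  # everything masked: undefined, flagged
  loh2 <- loh_events("chr1", 0L, 20000L, "whole_chromosome")
  expect_warning(s2 <- het_summary(sites, blocks, cl, loh = loh2),
                 "undefined")
  expect_true(s2$undefined)
  expect_true(is.na(s2$rate_pct))
})
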