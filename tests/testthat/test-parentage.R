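# fabricate a window_stats track with given per-window rates
make_track <- function(rates, chrom = "c1", window_bp = 10000L,
                       excluded = FALSE) {
  n <- length(rates)
  structure(data.frame(
    chrom = chrom, start = seq(0L, by = window_bp, length.out = n),
    end = seq(window_bp, by = window_bp, length.out = n),
    aligned_sites = ifelse(rep_len(excluded, n), 0L, window_bp),
    variant_weight = rates / 100 * window_bp,
    rate_pct = ifelse(rep_len(excluded, n), NA_real_, rates),
    excluded = rep_len(excluded, n)),
    class = c("window_stats", "data.frame"))
}

test_that("divergence contrasts assign the parent of origin", {
  # haplotype-A style contrast: 0.57% to P1 vs 2.84% to P2
  p1 <- make_track(rep(0.57, 4))
  p2 <- make_track(rep(2.84, 4))
  calls <- assign_parentage(p1, p2)
  expect_true(all(calls$label == "P1"))
  expect_true(all(calls$confident))
  # equal divergence is ambiguous by symmetry
  eq <- assign_parentage(make_track(rep(1.5, 4)), make_track(rep(1.5, 4)))
  expect_true(all(eq$label == "ambiguous"))
  # excluded windows are always ambiguous
  ex <- assign_parentage(make_track(rep(0.5, 4), excluded = TRUE),
                         make_track(rep(2.5, 4), excluded = TRUE))
  expect_true(all(ex$label == "ambiguous"))
  expect_error(assign_parentage(p1, make_track(rep(1, 3))),
               "same windowing")
})

test_that("isolated label islands are smoothed into the flanking run", {
  # P1 P1 P2 P1 P1 with min_run_windows = 3: the island is absorbed
  d1 <- make_track(c(0.5, 0.5, 2.7, 0.5, 0.5))
  d2 <- make_track(c(2.7, 2.7, 0.5, 2.7, 2.7))
  calls <- assign_parentage(d1, d2, min_run_windows = 3L)
  expect_equal(calls$label, rep("P1", 5))
})

test_that("windows inside LOH events are pinned to the shared parent", {
  # middle two windows sit in an LOH tract resembling the lower-divergence
  # parent on both haplotypes; without the LOH track they would be smoothed
  d1 <- make_track(c(2.7, 2.7, 0.6, 0.6, 2.7, 2.7, 2.7))
  d2 <- make_track(c(1.35, 1.35, 2.7, 2.7, 1.35, 1.35, 1.35))
  loh <- loh_events("c1", 20000L, 40000L, "interstitial")
  calls <- assign_parentage(d1, d2, loh = loh)
  expect_equal(calls$label[3:4], c("P1", "P1"))
  calls2 <- assign_parentage(d1, d2)
  expect_equal(calls2$label[3:4], c("P2", "P2"))
})

test_that("opposite co-located label changes are one reciprocal switch", {
  a <- assign_parentage(make_track(c(0.5, 0.5, 0.5, 2.7, 2.7, 2.7)),
                        make_track(c(2.7, 2.7, 2.7, 0.5, 0.5, 0.5)),
                        haplotype = "A")
  b <- assign_parentage(make_track(c(2.7, 2.7, 2.7, 0.5, 0.5, 0.5)),
                        make_track(c(0.5, 0.5, 0.5, 2.7, 2.7, 2.7)),
                        haplotype = "B")
  res <- detect_switches(a, b)
  expect_equal(nrow(res$switches), 1L)
  expect_equal(res$switches$type, "reciprocal")
  expect_equal(res$switches$pos_start, 30000)
  expect_equal(res$switches$haplotypes, "A+B")
})

test_that("a single-haplotype change is a nonreciprocal switch", {
  a <- assign_parentage(make_track(c(2.7, 2.7, 2.7, 0.5, 0.5, 0.5)),
                        make_track(c(1.35, 1.35, 1.35, 2.7, 2.7, 2.7)),
                        haplotype = "A")
  b <- assign_parentage(make_track(rep(0.5, 6)),
                        make_track(rep(2.7, 6)), haplotype = "B")
  res <- detect_switches(a, b)
  expect_equal(nrow(res$switches), 1L)
  expect_equal(res$switches$type, "nonreciprocal")
  expect_equal(res$switches$haplotypes, "A")
  expect_equal(res$switches$from_A, "P2")
  expect_equal(res$switches$to_A, "P1")
  # downstream of the switch both haplotypes carry the same parent
  expect_equal(a$label[4:6], b$label[4:6])
})

test_that("constant identical labels yield no switches", {
  a <- assign_parentage(make_track(rep(0.5, 6)), make_track(rep(2.7, 6)),
                        haplotype = "A")
  res <- detect_switches(a, a)
  expect_equal(nrow(res$switches), 0L)
  expect_true(all(res$segments$label == "P1"))
  # segments tile the chromosome
  seg <- res$segments[res$segments$haplotype == "A", ]
  expect_equal(min(seg$start), 0L)
  expect_equal(max(seg$end), 60000L)
})

test_that("relabeling P1<->P2 flips labels and preserves switches", {
  set.seed(8)
  r1 <- round(runif(20, 0.3, 3), 2)
  r2 <- round(runif(20, 0.3, 3), 2)
  t1 <- make_track(r1); t2 <- make_track(r2)
  fwd <- assign_parentage(t1, t2, haplotype = "A")
  rev <- assign_parentage(t2, t1, haplotype = "A")
  flip <- c(P1 = "P2", P2 = "P1", ambiguous = "ambiguous")
  expect_equal(unname(flip[fwd$label]), rev$label)
  s_fwd <- detect_switches(fwd, fwd)
  s_rev <- detect_switches(rev, rev)
  expect_equal(s_rev$switches$pos_start, s_fwd$switches$pos_start)
  expect_equal(s_rev$switches$type, s_fwd$switches$type)
})
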