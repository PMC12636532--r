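# a small 3-chromosome configuration for fast, targeted checks
small_config <- function(seed = 1L, stochastic = TRUE, ...) {
  cl <- c(s1 = 200000L, s2 = 150000L, s3 = 100000L)
  sim_config(
    n_chroms = 3L, chrom_lengths = cl,
    loh_plan = data.frame(chrom = c("s1", "s2", "s3"),
                          start = c(50000L, 0L, 0L),
                          end = c(60000L, 40000L, 100000L),
                          source_haplotype = c("A", "B", "A")),
    crossover_plan = data.frame(chrom = "s1", pos = 120000L,
                                reciprocal = TRUE,
                                haplotype = NA_character_, copy = FALSE),
    ploidy_plan = data.frame(chrom = "s2", start = 0L, end = 150000L,
                             copies = 2L),
    masked_gaps = data.frame(chrom = "s1", start = 80000L, end = 85000L),
    genes_per_chrom = 3L, seed = seed, stochastic = stochastic, ...)
}

test_that("the same seed reproduces byte-identical truth and files", {
  t1 <- simulate_hybrid(small_config(seed = 9L))
  t2 <- simulate_hybrid(small_config(seed = 9L))
  expect_identical(as.data.frame(t1$variants_het),
                   as.data.frame(t2$variants_het))
  expect_identical(as.data.frame(t1$coverage), as.data.frame(t2$coverage))
  expect_identical(as.data.frame(t1$methyl), as.data.frame(t2$methyl))
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_observables(t1, d1)
  p2 <- emit_observables(t2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = nm)
})

test_that("seed streams are isolated between components", {
  cfg_a <- small_config(seed = 9L)
  cfg_b <- small_config(seed = 9L)
  cfg_b$stream_seeds$methyl <- cfg_b$stream_seeds$methyl + 1000L
  t_a <- simulate_hybrid(cfg_a)
  t_b <- simulate_hybrid(cfg_b)
  expect_identical(as.data.frame(t_a$variants_het),
                   as.data.frame(t_b$variants_het))
  expect_false(identical(as.data.frame(t_a$methyl),
                         as.data.frame(t_b$methyl)))
})

test_that("planted structures obey their construction invariants", {
  tr <- simulate_hybrid(small_config(seed = 4L))
  # truth LOH intervals contain zero planted het sites
  inside <- mapply(function(cn, p) any(
    tr$loh_truth$chrom == cn & tr$loh_truth$start <= p - 1 &
      p - 1 < tr$loh_truth$end),
    tr$variants_het$chrom, tr$variants_het$pos)
  expect_false(any(inside))
  # a whole-chromosome LOH spans its chromosome exactly
  wc <- tr$loh_truth[tr$loh_truth$kind == "whole_chromosome", ]
  expect_equal(wc$chrom, "s3")
  expect_equal(wc$length, 100000L)
  # parentage segments tile each haplotype chromosome exactly
  for (h in c("A", "B")) {
    seg <- tr$parentage[tr$parentage$haplotype == h, ]
    for (cn in names(tr$chrom_lengths)) {
      s <- seg[seg$chrom == cn, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 0L)
      expect_equal(s$end[nrow(s)], as.integer(tr$chrom_lengths[[cn]]))
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    }
  }
  # no variant is emitted inside a masked gap
  gap <- tr$config$masked_gaps
  in_gap <- tr$variants_het$chrom == gap$chrom &
    tr$variants_het$pos - 1L >= gap$start & tr$variants_het$pos <= gap$end
  expect_false(any(in_gap))
})

test_that("realized site counts follow the planted Bernoulli rates", {
  cl <- c(one = 1000000L)
  cfg <- sim_config(
    n_chroms = 1L, chrom_lengths = cl,
    loh_plan = data.frame(chrom = character(), start = integer(),
                          end = integer(),
                          source_haplotype = character()),
    crossover_plan = data.frame(chrom = character(), pos = integer(),
                                reciprocal = logical(),
                                haplotype = character(), copy = logical()),
    ploidy_plan = data.frame(chrom = character(), start = integer(),
                             end = integer(), copies = integer()),
    masked_gaps = data.frame(chrom = character(), start = integer(),
                             end = integer()),
    genes_per_chrom = 2L, seed = 77L)
  tr <- simulate_hybrid(cfg)
  n <- nrow(tr$variants_het)
  expected <- 1e6 * 0.027
  expect_lt(abs(n - expected), 3 * sqrt(1e6 * 0.027 * (1 - 0.027)))
})

test_that("noise-free copy plans yield exact window means", {
  tr <- simulate_hybrid(small_config(seed = 2L, stochastic = FALSE))
  cov <- tr$coverage
  expect_true(all(cov$mean_depth[cov$chrom == "s2"] == 100))
  expect_true(all(cov$mean_depth[cov$chrom != "s2"] == 50))
})

test_that("masked gaps leave an aligned-site deficit downstream", {
  tr <- simulate_hybrid(small_config(seed = 2L, stochastic = FALSE))
  w <- het_windows(tr$variants_het, as.data.frame(tr$blocks),
                   tr$chrom_lengths)
  gapw <- w[w$chrom == "s1" & w$start == 80000L, ]
  expect_equal(gapw$aligned_sites, 5000L)
  full <- w[w$chrom == "s1" & w$start == 0L, ]
  expect_equal(full$aligned_sites, 10000L)
})

test_that("methylation fractions peak at multiples of the planted period", {
  tr <- sim_noisefree()
  prof <- tss_metaplot(tr$methyl, tr$tss)
  pk <- prof$median_frac[prof$offset %in% c(200, 400, 600)]
  tr_off <- prof$median_frac[prof$offset %in% c(100, 300, 500)]
  expect_true(all(pk > 0.9))
  expect_true(all(tr_off < 0.1))
})
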