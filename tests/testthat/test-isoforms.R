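test_that("gene decoupling splits models that share no coding sequence", {
  # direct CDS overlap on the same strand: one gene
  tx <- transcript_models(
    id = c("a", "b"), gene_id = "merged", chrom = "c1", strand = "+",
    exons = list(cbind(50L, 260L), cbind(100L, 300L)),
    cds = list(cbind(100L, 200L), cbind(150L, 250L)),
    read_count = c(5L, 5L))
  g <- decouple_genes(tx)
  expect_equal(nrow(g), 1L)
  expect_setequal(g$members[[1]], c("a", "b"))
  # UTR-only overlap: two genes
  tx2 <- transcript_models(
    id = c("a", "b"), gene_id = "merged", chrom = "c1", strand = "+",
    exons = list(cbind(50L, 320L), cbind(250L, 450L)),
    cds = list(cbind(100L, 200L), cbind(300L, 400L)),
    read_count = c(5L, 5L))
  g2 <- decouple_genes(tx2)
  expect_equal(nrow(g2), 2L)
  # transitive chain I1-I2, I2-I3 with I1, I3 disjoint: one gene of three
  tx3 <- transcript_models(
    id = c("i1", "i2", "i3"), gene_id = "merged", chrom = "c1",
    strand = "+",
    exons = list(cbind(100L, 200L), cbind(150L, 320L), cbind(250L, 400L)),
    cds = list(cbind(100L, 200L), cbind(150L, 320L), cbind(250L, 400L)),
    read_count = c(5L, 5L, 5L))
  g3 <- decouple_genes(tx3)
  expect_equal(nrow(g3), 1L)
  expect_length(g3$members[[1]], 3L)
  # opposite strands never join
  tx4 <- transcript_models(
    id = c("a", "b"), gene_id = "merged", chrom = "c1",
    strand = c("+", "-"),
    exons = list(cbind(50L, 260L), cbind(100L, 300L)),
    cds = list(cbind(100L, 200L), cbind(150L, 250L)),
    read_count = c(5L, 5L))
  expect_equal(nrow(decouple_genes(tx4)), 2L)
})

test_that("read-support filtering applies both thresholds in one pass", {
  expect_setequal(filter_isoforms(c(i1 = 100L, i2 = 4L, i3 = 6L)),
                  c("i1", "i3"))  # 6/110 = 5.45% passes; 4 reads fail
  expect_equal(filter_isoforms(c(i1 = 100L, i2 = 5L)), "i1")  # 4.76% < 5%
  expect_equal(filter_isoforms(c(i1 = 3L)), "i1")  # last-isoform guard
  expect_error(filter_isoforms(c(i1 = 0L)), "zero total reads")
})

test_that("filtering is monotone in both thresholds", {
  set.seed(12)
  for (k in 1:300) {
    n <- sample(1:6, 1)
    counts <- setNames(sample(0:50, n, replace = TRUE), paste0("i", 1:n))
    counts[1] <- max(counts[1], 1L)
    r1 <- sample(1:10, 1); r2 <- r1 + sample(0:10, 1)
    f1 <- sample(c(0.01, 0.05, 0.1), 1); f2 <- f1 + sample(c(0, 0.1), 1)
    keep_loose <- filter_isoforms(counts, min_reads = r1, min_frac = f1)
    keep_tight <- filter_isoforms(counts, min_reads = r2, min_frac = f2)
    guard <- length(keep_tight) == 1 &&
      keep_tight == names(counts)[order(-counts, names(counts))][1]
    expect_true(all(keep_tight %in% keep_loose) || guard)
  }
})

test_that("primary-isoform selection follows the 50%/80% cascade", {
  # longest CDS not most abundant, support < 50%, 80% rule fails -> longest
  expect_equal(select_primary(c("L", "M"), c(900L, 600L), c(10L, 100L)),
               "L")
  # support >= 50% of the most abundant -> longest stays primary
  expect_equal(select_primary(c("L", "M"), c(900L, 600L), c(60L, 100L)),
               "L")
  # 80% coding-length rule selects the abundant isoform
  expect_equal(select_primary(c("L", "M"), c(900L, 800L), c(10L, 100L)),
               "M")
  # longest CDS also most abundant wins outright
  expect_equal(select_primary(c("x", "y"), c(500L, 900L), c(10L, 90L)),
               "y")
  # equal CDS lengths: most abundant wins the tie
  expect_equal(select_primary(c("x", "y"), c(900L, 900L), c(10L, 90L)),
               "y")
})

test_that("primary selection is invariant under input order", {
  set.seed(21)
  for (k in 1:200) {
    n <- sample(2:5, 1)
    ids <- paste0("i", 1:n)
    cds <- sample(seq(300L, 1500L, 30L), n, TRUE)
    reads <- sample(1:200, n, TRUE)
    pick <- select_primary(ids, cds, reads)
    o <- sample(n)
    expect_equal(select_primary(ids[o], cds[o], reads[o]), pick)
  }
})

test_that("the Kozak model matches hand-computed frequencies", {
  # two training windows with joint uniform base composition; position -6
  # carries C once: freq = (1+1)/(2+4) = 1/3 against background 1/4
  seqs <- c(paste0("AACCGGTT", "ATG", "GGGTAA"),
            paste0("TTGGCCAA", "ATG", "CCCTAA"))
  expect_warning(build_kozak_model(seqs, c(9L, 9L), offsets = -8:-1),
                 "training transcripts")
  model <- suppressWarnings(
    build_kozak_model(seqs, c(9L, 9L), offsets = -8:-1))
  expect_equal(unname(model$background), rep(0.25, 4))
  expect_equal(model$pfm["C", "-6"], 1 / 3)
  contrib <- log2((1 / 3) / 0.25)
  expect_equal(round(contrib, 3), 0.415)
  expect_equal(model$n_train, 2L)
  # a context identical to a training window scores at least as high as
  # any other candidate context over the same model
  s_train <- kozak_score(model, seqs[1], 9L)
  set.seed(3)
  rand <- replicate(50, paste0(
    paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), "ATG"))
  expect_true(all(vapply(rand, function(s)
    kozak_score(model, s, 9L), 0) <= max(model$training_scores) + 1e-9))
})

test_that("transcripts with reachable upstream ATGs are excluded from training", {
  # upstream in-frame ATG with no stop between: not trainable
  s_ext <- paste0("CCATGCCC", "ATG", "AAATAA")   # ATG at 3, in frame with 9
  s_ok <- paste0("CCTAACCC", "ATG", "AAATAA")    # in-frame stop barrier
  model <- suppressWarnings(build_kozak_model(c(s_ext, s_ok, s_ok),
                                              c(9L, 9L, 9L),
                                              offsets = -2:-1))
  expect_equal(model$n_train, 2L)
})

test_that("ORF extension fires the documented rules", {
  model <- structure(list(
    pfm = matrix(c(0.5, 0.25, 0.125, 0.125), ncol = 1,
                 dimnames = list(c("A", "C", "G", "T"), "-1")),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    offsets = -1L, n_train = 20L, training_scores = numeric(),
    q25 = 1.5), class = "kozak_model")
  # scores by the base preceding an ATG: A -> 1, C -> 0, G/T -> -1
  # upstream 1 > annotated 0, but 1 <= q25: above_annotated
  seq1 <- paste0("CCA", "ATG", "GCC", "ATG", "AAATAA")
  d1 <- extend_orf(seq1, 10L, model)
  expect_equal(d1$new_start, 4L)
  expect_equal(d1$rule_fired, "above_annotated")
  # upstream 0 < annotated 1 but 0 > q25 = -0.5: above_q25
  model$q25 <- -0.5
  seq2 <- paste0("CCC", "ATG", "GCA", "ATG", "AAATAA")
  d2 <- extend_orf(seq2, 10L, model)
  expect_equal(d2$new_start, 4L)
  expect_equal(d2$rule_fired, "above_q25")
  # upstream -1 below both: no extension
  seq3 <- paste0("CCG", "ATG", "GCA", "ATG", "AAATAA")
  d3 <- extend_orf(seq3, 10L, model)
  expect_equal(d3$new_start, 10L)
  expect_equal(d3$rule_fired, "none")
  # an intervening in-frame stop blocks the candidate
  seq4 <- paste0("CCA", "ATG", "TAA", "ATG", "AAATAA")
  d4 <- extend_orf(seq4, 10L, model)
  expect_equal(d4$rule_fired, "none")
  # among several qualifying candidates the 5'-most wins
  seq5 <- paste0("CCA", "ATG", "GCA", "ATG", "GCC", "ATG", "AAATAA")
  d5 <- extend_orf(seq5, 16L, model)
  expect_equal(d5$new_start, 4L)
  # missing ATG at the annotated start is flagged and skipped
  expect_warning(d6 <- extend_orf("CCCAAACCC", 4L, model), "no ATG")
  expect_true(d6$flagged)
})

test_that("antisense lncRNA association uses the 30% span threshold", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      start = 0L, end = 1000L)
  # 400 of 1,000 bp antisense overlap: associated
  lnc <- data.frame(id = "l1", chrom = "c1", strand = "-", start = 600L,
                    end = 1400L, tss = 1400L)
  res <- classify_antisense(genes, lnc)
  expect_equal(nrow(res), 1L)
  expect_equal(res$overlap_frac, 0.4)
  expect_equal(res$subclass, "unidirectional")
  # 250 of 1,000: below threshold
  lnc2 <- data.frame(id = "l1", chrom = "c1", strand = "-", start = 750L,
                     end = 1400L, tss = 1400L)
  expect_equal(nrow(classify_antisense(genes, lnc2)), 0L)
  # gene-internal lncRNA TSS with a sense truncated-isoform TSS 80 bp
  # away: bidirectional promoter
  lnc3 <- data.frame(id = "l1", chrom = "c1", strand = "-", start = 100L,
                     end = 700L, tss = 700L)
  sense <- data.frame(gene_id = "g1", tss = 780L)
  res3 <- classify_antisense(genes, lnc3, sense_tss = sense)
  expect_equal(res3$subclass, "bidirectional")
  # same-strand overlap never associates
  lnc4 <- data.frame(id = "l1", chrom = "c1", strand = "+", start = 0L,
                     end = 1000L, tss = 1L)
  expect_equal(nrow(classify_antisense(genes, lnc4)), 0L)
})

test_that("gene IDs follow the 5-increment, pairing and organelle rules", {
  ga <- data.frame(gene_id = c("a1", "a2", "a3"), chrom = "A01",
                   start = c(100L, 900L, 5000L))
  gb <- data.frame(gene_id = c("b1", "b2"), chrom = "B01",
                   start = c(50L, 800L))
  pairs <- data.frame(a = "a2", b = "b1")
  org <- data.frame(gene_id = c("p1", "m1"), chrom = c("xCp", "xMt"),
                    start = c(1L, 1L),
                    compartment = c("plastid", "mito"))
  ids <- assign_gene_ids(ga, gb, pairs, org)
  expect_equal(ids$number[match(c("a1", "a2", "a3"), ids$gene_id)],
               c(5L, 10L, 15L))
  expect_equal(ids$number[ids$gene_id == "b1"], 10L)  # inherits its pair
  expect_equal(ids$number[ids$gene_id == "b2"], 20L)  # continues past 15
  expect_equal(ids$new_id[ids$gene_id == "a1"], "A01.00005")
  expect_equal(ids$number[ids$gene_id == "p1"], 80000L)
  expect_equal(ids$number[ids$gene_id == "m1"], 90000L)
  expect_false(anyDuplicated(ids$new_id) > 0)
  expect_error(assign_gene_ids(ga, gb, data.frame(a = c("a1", "a1"),
                                                  b = c("b1", "b2"))),
               "duplicate")
})
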