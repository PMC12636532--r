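# Shared fixtures.  The full simulations are built once per test run and
# reused across test files; sizes are desk-scale (2.2 Mb genome).

sim_noisefree <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_hybrid(sim_config(seed = 101L, stochastic = FALSE))
    cache
  }
})

sim_stochastic <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_hybrid(sim_config(seed = 202L))
    cache
  }
})

# small deterministic transcript set: 2 coding genes (one on each strand)
# and one noncoding isoform
tiny_transcripts <- function() {
  transcript_models(
    id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g1", "g2"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "+", "-"),
    exons = list(cbind(100L, 1000L), cbind(100L, 1000L),
                 cbind(2000L, 2600L)),
    cds = list(cbind(200L, 800L), cbind(350L, 800L),
               cbind(2100L, 2400L)),
    read_count = c(50L, 10L, 20L))
}

# truth parentage label of each call window by majority overlap; exact
# 50/50 ties return both labels
truth_window_labels <- function(truth, calls, hap) {
  seg <- truth$parentage[truth$parentage$haplotype == hap, , drop = FALSE]
  lapply(seq_len(nrow(calls)), function(i) {
    s <- seg[seg$chrom == calls$chrom[i] & seg$start < calls$end[i] &
               seg$end > calls$start[i], , drop = FALSE]
    w <- pmin(s$end, calls$end[i]) - pmax(s$start, calls$start[i])
    s$label[w == max(w)]
  })
}

divergence_calls <- function(truth, hap, loh = NULL) {
  blocks <- as.data.frame(truth$blocks)
  w1 <- divergence_windows(truth$div_tracks[[sprintf("hap%s_p1", hap)]],
                           blocks, truth$chrom_lengths)
  w2 <- divergence_windows(truth$div_tracks[[sprintf("hap%s_p2", hap)]],
                           blocks, truth$chrom_lengths)
  assign_parentage(w1, w2, loh = loh, haplotype = hap)
}
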