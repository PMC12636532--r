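# Coverage-based ploidy calling, partial-aneuploidy segmentation, and
# sequence scans for internal telomeres and AT-rich centromere candidates.

#' Re-bin a depth track into fixed-width coverage bins
#'
#' Bins of arbitrary width (e.g. bedGraph runs or per-base depth) are
#' re-binned to fixed windows by length-weighted averaging of the mean
#' depth; the last partial bin of each chromosome keeps its true width.
#' Positions not covered by any input bin count as depth 0.
#'
#' @param depth [coverage_bins()] table (any bin widths, including width 1
#'   for per-base depth).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_bp output bin width, default 20000.
#' @return [coverage_bins()] table with fixed-width bins.
#' @export
bin_coverage <- function(depth, chrom_lengths, bin_bp = 20000L) {
  if (any(depth$mean_depth < 0)) stop("negative depth")
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- as.integer(chrom_lengths[[cn]])
    s <- seq.int(0L, L - 1L, by = bin_bp)
    e <- pmin(s + bin_bp, L)
    d <- depth[depth$chrom == cn, , drop = FALSE]
    acc <- numeric(length(s))
    if (nrow(d)) {
      iw <- IRanges::IRanges(s + 1L, e)
      id <- .as_iranges(d)
      hits <- IRanges::findOverlaps(iw, id)
      if (length(hits)) {
        w <- IRanges::width(IRanges::pintersect(
          iw[S4Vectors::queryHits(hits)], id[S4Vectors::subjectHits(hits)]))
        v <- w * d$mean_depth[S4Vectors::subjectHits(hits)]
        agg <- tapply(v, S4Vectors::queryHits(hits), sum)
        acc[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    data.frame(chrom = cn, start = s, end = e, mean_depth = acc / (e - s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  coverage_bins(res$chrom, res$start, res$end, res$mean_depth)
}

#' Call chromosome copy number from binned coverage
#'
#' The baseline depth is the median of the per-chromosome median bin
#' depths; chromosomes whose median deviates from the baseline by more than
#' 25\% are flagged as outliers and the baseline is recomputed without them
#' (one iteration).  In \code{phased} mode the reference is a phased
#' diploid assembly, so the baseline corresponds to one chromosome copy and
#' \code{copy_number = round(ratio)}; in \code{collapsed} mode reads from
#' both homologs pile on one haploid reference, the baseline corresponds to
#' two copies and \code{copy_number = round(2 * ratio)}.  Chromosomes whose
#' (mode-scaled) ratio deviates from the nearest integer by more than
#' \code{int_tol} are flagged.
#'
#' @param bins [coverage_bins()] table (fixed-width, from
#'   [bin_coverage()]).
#' @param mode \code{"phased"} or \code{"collapsed"}.
#' @param int_tol tolerance for the integer-deviation flag, default 0.2.
#' @param baseline optional externally supplied per-copy baseline depth;
#'   overrides the internal estimate.
#' @return data.frame of class \code{ploidy_calls}: chrom,
#'   median_bin_depth, baseline_depth, ratio, copy_number, flagged, mode.
#' @export
call_ploidy <- function(bins, mode = c("phased", "collapsed"),
                        int_tol = 0.2, baseline = NULL) {
  mode <- match.arg(mode)
  med <- tapply(bins$mean_depth, bins$chrom, median)
  if (length(med) < 3)
    warning("fewer than 3 chromosomes; baseline is unreliable")
  if (is.null(baseline)) {
    base0 <- median(med)
    keep <- med / base0 >= 0.75 & med / base0 <= 1.25
    baseline <- if (any(keep)) median(med[keep]) else base0
  }
  ratio <- as.numeric(med) / baseline
  scaled <- if (mode == "phased") ratio else 2 * ratio
  copy <- as.integer(round(scaled))
  res <- data.frame(chrom = names(med), median_bin_depth = as.numeric(med),
                    baseline_depth = baseline, ratio = ratio,
                    copy_number = copy,
                    flagged = abs(scaled - copy) > int_tol,
                    mode = mode, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("ploidy_calls", "data.frame")
  res
}

#' Segment chromosomes into copy-number states by binary segmentation
#'
#' Recursive binary segmentation on log2(bin depth / baseline): the split
#' maximizing the between-segment mean difference is accepted when the
#' means differ by at least \code{min_gap} in log2 (0.5 separates adjacent
#' integer copy states) and both sides hold at least
#' \code{min_segment_bins} bins.  Each accepted segment receives an integer
#' copy number as in [call_ploidy()].
#'
#' @param bins [coverage_bins()] table (fixed-width).
#' @param mode \code{"phased"} or \code{"collapsed"} (see [call_ploidy()]).
#' @param min_segment_bins minimum bins per segment, default 5.
#' @param min_gap minimum log2 mean difference to accept a split, default
#'   0.5.
#' @param baseline optional per-copy baseline depth; by default estimated
#'   as in [call_ploidy()].
#' @return list with \code{segments} (chrom, start, end, n_bins,
#'   median_depth, ratio, copy_number) and \code{breakpoints} (chrom, pos).
#' @export
segment_partial_aneuploidy <- function(bins, mode = c("phased", "collapsed"),
                                       min_segment_bins = 5L, min_gap = 0.5,
                                       baseline = NULL) {
  mode <- match.arg(mode)
  if (is.null(baseline)) {
    med <- tapply(bins$mean_depth, bins$chrom, median)
    base0 <- median(med)
    keep <- med / base0 >= 0.75 & med / base0 <= 1.25
    baseline <- if (any(keep)) median(med[keep]) else base0
  }
  eps <- baseline * 1e-3
  segments <- list(); breakpoints <- list()
  for (cn in unique(bins$chrom)) {
    d <- bins[bins$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    x <- log2(pmax(d$mean_depth, eps) / baseline)
    cuts <- .binseg(x, min_segment_bins, min_gap)
    bounds <- c(0L, cuts, length(x))
    for (k in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      mdep <- median(d$mean_depth[idx])
      ratio <- mdep / baseline
      scaled <- if (mode == "phased") ratio else 2 * ratio
      segments[[length(segments) + 1L]] <- data.frame(
        chrom = cn, start = d$start[idx[1]], end = d$end[idx[length(idx)]],
        n_bins = length(idx), median_depth = mdep, ratio = ratio,
        copy_number = as.integer(round(scaled)), stringsAsFactors = FALSE)
    }
    if (length(cuts))
      breakpoints[[length(breakpoints) + 1L]] <-
        data.frame(chrom = cn, pos = d$start[cuts + 1L],
                   stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, segments)
  breakpoints <- if (length(breakpoints)) do.call(rbind, breakpoints) else
    data.frame(chrom = character(), pos = integer())
  rownames(segments) <- rownames(breakpoints) <- NULL
  list(segments = segments, breakpoints = breakpoints, baseline = baseline,
       mode = mode)
}

# recursive binary segmentation; returns sorted cut indices (cut after
# position i means segments [1..i], [i+1..n])
.binseg <- function(x, min_bins, min_gap) {
  n <- length(x)
  if (n < 2L * min_bins) return(integer())
  csum <- cumsum(x)
  i <- min_bins:(n - min_bins)
  mean_l <- csum[i] / i
  mean_r <- (csum[n] - csum[i]) / (n - i)
  gap <- abs(mean_l - mean_r)
  best <- which.max(gap)
  if (gap[best] < min_gap) return(integer())
  cut <- i[best]
  sort(c(.binseg(x[seq_len(cut)], min_bins, min_gap), cut,
         cut + .binseg(x[(cut + 1L):n], min_bins, min_gap)))
}

#' Scan an assembly for tandem telomeric repeats
#'
#' Finds maximal tandem runs of the telomere motif on either strand (the
#' motif and its reverse complement) with at least \code{min_repeats}
#' units.  A hit further than \code{end_margin} from both chromosome ends
#' is flagged \code{internal} — internally mapped telomeric repeats mark
#' fission/fusion scars and partial-duplication breakpoints.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param motif telomere repeat unit, default \code{"TTAGGG"}.
#' @param min_repeats minimum tandem copies, default 4.
#' @param end_margin distance from a chromosome end (bp) under which a hit
#'   is considered end-associated, default 10000.
#' @return data.frame of class \code{telomere_hits}: chrom, start, end
#'   (0-based half-open), strand, motif, repeat_count, internal.
#' @export
find_internal_telomeres <- function(genome, motif = "TTAGGG",
                                    min_repeats = 4L, end_margin = 10000L) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  out <- list()
  for (cn in names(genome)) {
    seq <- as.character(genome[[cn]])
    L <- nchar(seq)
    for (m in unique(c(motif, rc))) {
      strand <- if (m == motif) "+" else "-"
      pat <- sprintf("(?:%s){%d,}", m, min_repeats)
      hits <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (hits[1] == -1) next
      len <- attr(hits, "match.length")
      start0 <- as.integer(hits) - 1L
      end0 <- start0 + len
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = start0, end = end0, strand = strand,
        motif = m, repeat_count = len %/% nchar(m),
        internal = start0 >= end_margin & (L - end0) >= end_margin,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), motif = character(),
               repeat_count = integer(), internal = logical(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("telomere_hits", "data.frame")
  res
}

#' Scan intergenic sequence for AT-rich centromere candidates
#'
#' In streamlined genomes lacking repeat-rich centromeres, short regional
#' centromeres appear as AT-rich intergenic islands against a GC-rich
#' background.  Within the intergenic complement of the gene spans, the
#' scan reports maximal runs whose sliding-window GC content stays at or
#' below \code{gc_max}, keeping runs between \code{min_len} and
#' \code{max_len} bp, each with its exact GC percentage.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param genes data.frame of gene spans (chrom, start, end; 0-based
#'   half-open), e.g. from [transcript_models()] via gene span aggregation.
#' @param gc_max maximum sliding-window GC percent, default 55.
#' @param min_len,max_len candidate length bounds in bp, defaults 2000 and
#'   10000.
#' @param gc_window sliding window width for the GC profile, default 500.
#' @return data.frame of class \code{centromere_candidates}: chrom, start,
#'   end, length, gc_pct.
#' @export
find_at_rich_candidates <- function(genome, genes, gc_max = 55,
                                    min_len = 2000L, max_len = 10000L,
                                    gc_window = 500L) {
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  whole <- data.frame(chrom = names(chrom_lengths), start = 0L,
                      end = as.integer(chrom_lengths),
                      stringsAsFactors = FALSE)
  intergenic <- if (nrow(genes))
    subtract_intervals(whole, genes[, c("chrom", "start", "end")]) else whole
  out <- list()
  for (cn in names(genome)) {
    seq <- genome[[cn]]
    gc <- as.integer(Biostrings::letterFrequencyInSlidingView(
      seq, gc_window, c("GC"))) / gc_window
    # gc[i] covers [i-1, i-1+gc_window); positions with no full window at
    # the chromosome tail reuse the last window value
    ig <- intergenic[intergenic$chrom == cn, , drop = FALSE]
    for (r in seq_len(nrow(ig))) {
      s <- ig$start[r]; e <- ig$end[r]
      wi_max <- length(gc)
      wis <- pmin(pmax(seq.int(s, e - 1L) - gc_window %/% 2L, 0L) + 1L,
                  wi_max)
      ok <- gc[wis] <= gc_max / 100
      rr <- rle(ok)
      pos_end <- cumsum(rr$lengths)
      pos_start <- pos_end - rr$lengths + 1L
      for (k in which(rr$values)) {
        rs <- s + pos_start[k] - 1L
        re <- s + pos_end[k]
        len <- re - rs
        if (len < min_len || len > max_len) next
        sub <- Biostrings::subseq(seq, rs + 1L, re)
        gc_pct <- 100 * sum(Biostrings::letterFrequency(sub, c("G", "C"))) /
          len
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = rs, end = re, length = len, gc_pct = gc_pct,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), gc_pct = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("centromere_candidates", "data.frame")
  res
}
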