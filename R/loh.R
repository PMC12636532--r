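# Loss-of-heterozygosity: calling, classification, summary, comparison.

#' Construct/validate a table of LOH events
#'
#' @param chrom,start,end event coordinates (0-based half-open).
#' @param kind \code{"interstitial"}, \code{"terminal"} or
#'   \code{"whole_chromosome"}.
#' @return data.frame of class \code{loh_events} with a derived
#'   \code{length} column, sorted per chromosome.
#' @export
loh_events <- function(chrom, start, end, kind) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), kind = as.character(kind),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  if (nrow(df)) {
    if (any(df$length <= 0L)) stop("LOH events require start < end")
    if (!all(df$kind %in% c("interstitial", "terminal", "whole_chromosome")))
      stop("unknown LOH event kind")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    ovl <- unlist(lapply(split(df, df$chrom), function(d)
      nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])))
    if (any(ovl)) stop("LOH events overlap within a chromosome")
    rownames(df) <- NULL
  }
  df <- df[, c("chrom", "start", "end", "length", "kind")]
  class(df) <- c("loh_events", "data.frame")
  df
}

#' Call loss-of-heterozygosity events from heterozygous sites
#'
#' An LOH event is a maximal stretch free of heterozygous sites of at least
#' \code{min_len} bp.  Between two consecutive het sites at 1-based
#' positions p1 < p2 the het-free interval is [p1, p2-1) (inner-edge
#' convention: from the base after the left het site to the base before the
#' right one); chromosome ends close the outermost gaps.  Gaps are clipped
#' to the alignable blocks so unalignable sequence is not reported as LOH;
#' each clipped piece is emitted when it still reaches \code{min_len}.  A
#' gap touching a chromosome end is classed \code{terminal}; a chromosome
#' with no het site at all yields a single \code{whole_chromosome} event
#' spanning it; all other events are \code{interstitial}.
#'
#' @param sites [variant_sites()] table (only het rows are used).
#' @param chrom_lengths named vector of chromosome lengths; every chromosome
#'   named here is scanned (a site on a chromosome absent from it is an
#'   error).
#' @param blocks optional [alignable_blocks()] table; \code{NULL} means the
#'   whole genome is alignable.
#' @param min_len minimum event length in bp, default 1000.
#' @return \code{loh_events} table.
#' @export
call_loh <- function(sites, chrom_lengths, blocks = NULL, min_len = 1000L) {
  het <- sites[sites$zygosity == "het", , drop = FALSE]
  bad <- setdiff(unique(het$chrom), names(chrom_lengths))
  if (length(bad))
    stop(sprintf("chromosome(s) missing from chrom_lengths: %s",
                 paste(bad, collapse = ", ")))
  out <- list()
  for (cn in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[cn]])
    p <- sort(het$pos[het$chrom == cn])
    if (length(p) == 0) {
      out[[cn]] <- data.frame(chrom = cn, start = 0L, end = L,
                              kind = "whole_chromosome",
                              stringsAsFactors = FALSE)
      next
    }
    # gaps: [0, p1-1), [p_i, p_{i+1}-1) ..., [p_n, L)
    gs <- c(0L, p)
    ge <- c(p - 1L, L)
    kind <- rep("interstitial", length(gs))
    kind[1] <- "terminal"
    kind[length(kind)] <- "terminal"
    # clipping to blocks only shrinks a gap, so sub-min_len gaps can be
    # dropped before the (expensive) clipping step
    keep <- ge - gs >= min_len
    gaps <- data.frame(chrom = rep(cn, sum(keep)), start = gs[keep],
                       end = ge[keep], kind = kind[keep],
                       stringsAsFactors = FALSE)
    if (!is.null(blocks) && nrow(gaps)) {
      blk <- blocks[blocks$chrom == cn, , drop = FALSE]
      pieces <- lapply(seq_len(nrow(gaps)), function(i) {
        clip <- intersect_intervals(gaps[i, c("chrom", "start", "end")],
                                    blk[, c("chrom", "start", "end")])
        clip$kind <- rep(gaps$kind[i], nrow(clip))
        clip
      })
      gaps <- do.call(rbind, pieces)
    }
    out[[cn]] <- gaps[gaps$end - gaps$start >= min_len, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character())
  ev <- loh_events(res$chrom, res$start, res$end, res$kind)
  # defensive invariant: no emitted event may contain a het site
  inside <- positions_in_intervals(het$chrom, het$pos,
                                   ev[, c("chrom", "start", "end")])
  stopifnot(!any(inside))
  ev
}

#' Summarize LOH events
#'
#' @param events \code{loh_events} table.
#' @param genome_length total genome length in bp.
#' @param size_threshold events strictly exceeding this length are counted
#'   in \code{n_above_threshold}; default 5000.
#' @return list of class \code{loh_summary}: per-kind counts and bp,
#'   totals, genome fraction, count above the threshold, and the maximum
#'   event length.
#' @export
summarize_loh <- function(events, genome_length, size_threshold = 5000L) {
  kinds <- c("interstitial", "terminal", "whole_chromosome")
  by_kind <- do.call(rbind, lapply(kinds, function(k) {
    e <- events[events$kind == k, , drop = FALSE]
    data.frame(kind = k, n = nrow(e), total_bp = sum(e$length))
  }))
  total_bp <- sum(events$length)
  res <- list(by_kind = by_kind, n_events = nrow(events),
              total_bp = total_bp,
              genome_fraction = total_bp / genome_length,
              n_above_threshold = sum(events$length > size_threshold),
              max_length = if (nrow(events)) max(events$length) else 0L,
              size_threshold = size_threshold)
  class(res) <- "loh_summary"
  res
}

#' @export
print.loh_summary <- function(x, ...) {
  cat(sprintf("<loh_summary> %d events, %d bp (%.1f%% of genome)\n",
              x$n_events, x$total_bp, 100 * x$genome_fraction))
  print(x$by_kind, row.names = FALSE)
  cat(sprintf("events > %d bp: %d; max length: %d bp\n",
              x$size_threshold, x$n_above_threshold, x$max_length))
  invisible(x)
}

#' Compare LOH event sets between two strains
#'
#' A pair of events is shared when their overlap is at least
#' \code{reciprocal_overlap_frac} of the length of \emph{each} event.  Each
#' event is matched at most once; candidate pairs are taken greedily by
#' decreasing overlap, ties broken by leftmost coordinate.
#'
#' @param events_a,events_b \code{loh_events} tables.
#' @param reciprocal_overlap_frac minimum reciprocal overlap fraction,
#'   default 0.5.
#' @return list with \code{shared} (data.frame of index pairs and overlap
#'   bp), \code{a_specific} and \code{b_specific} (row indices into the
#'   inputs).
#' @export
compare_loh <- function(events_a, events_b, reciprocal_overlap_frac = 0.5) {
  if (nrow(events_a) == 0 || nrow(events_b) == 0)
    return(list(shared = data.frame(a = integer(), b = integer(),
                                    overlap = integer()),
                a_specific = seq_len(nrow(events_a)),
                b_specific = seq_len(nrow(events_b))))
  pairs <- list()
  for (i in seq_len(nrow(events_a))) {
    same <- which(events_b$chrom == events_a$chrom[i])
    if (!length(same)) next
    ov <- pmin(events_a$end[i], events_b$end[same]) -
      pmax(events_a$start[i], events_b$start[same])
    ok <- ov >= reciprocal_overlap_frac * events_a$length[i] &
      ov >= reciprocal_overlap_frac * events_b$length[same]
    if (any(ok))
      pairs[[length(pairs) + 1L]] <-
        data.frame(a = i, b = same[ok], overlap = ov[ok])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = integer(), b = integer(), overlap = integer())
  ord <- order(-pairs$overlap, events_a$start[pairs$a],
               events_b$start[pairs$b])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(nrow(events_a)); used_b <- logical(nrow(events_b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!used_a[pairs$a[k]] && !used_b[pairs$b[k]]) {
      keep[k] <- TRUE
      used_a[pairs$a[k]] <- TRUE
      used_b[pairs$b[k]] <- TRUE
    }
  }
  shared <- pairs[keep, , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared,
       a_specific = which(!used_a),
       b_specific = which(!used_b))
}

#' Retain sites unaffected by LOH in every strain
#'
#' Filters candidate sites for phylogenetic use: a site is retained when its
#' chromosome is not excluded (e.g. chromosomes with reciprocal crossovers)
#' and its position lies outside every strain's LOH intervals.
#'
#' @param candidate_sites [variant_sites()] table (or any data.frame with
#'   chrom and 1-based pos).
#' @param loh_sets list of \code{loh_events} tables, one per strain.
#' @param excluded_chroms character vector of chromosomes to drop entirely.
#' @return the retained subset of \code{candidate_sites}.
#' @export
mask_invariant_sites <- function(candidate_sites, loh_sets,
                                 excluded_chroms = character()) {
  keep <- !(candidate_sites$chrom %in% excluded_chroms)
  for (loh in loh_sets) {
    if (is.null(loh) || nrow(loh) == 0) next
    inside <- positions_in_intervals(candidate_sites$chrom,
                                     candidate_sites$pos,
                                     loh[, c("chrom", "start", "end")])
    keep <- keep & !inside
  }
  candidate_sites[keep, , drop = FALSE]
}
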