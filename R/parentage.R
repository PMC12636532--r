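# Parent-of-origin assignment from divergence tracks and detection of
# reciprocal / nonreciprocal parentage switches.

#' Assign a parent of origin to each haplotype window
#'
#' Each window of a haplotype is compared to the two candidate parental
#' references through its divergence rates: divergence to the true parent
#' sits at the within-species heterozygosity level, divergence to the other
#' parent at the between-species level, so the scale-free ratio of the two
#' rates separates them.  A window is labeled P1 when
#' \code{d_p2/d_p1 >= ratio_threshold}, P2 for the reciprocal condition,
#' otherwise ambiguous; excluded windows are always ambiguous.  Two
#' smoothing passes follow, per chromosome: (1) runs of identical
#' non-ambiguous labels shorter than \code{min_run_windows} are relabeled
#' ambiguous; (2) each maximal ambiguous run is absorbed into its flanks —
#' when the flanking labels agree (or only one flank exists) the run takes
#' that label; when they disagree, each window in the run is assigned to
#' the parent with the smaller divergence rate, which pins the transition
#' to within one window even when the ratio test is marginal.
#'
#' @param div_p1,div_p2 \code{window_stats} from [divergence_windows()]
#'   for the same haplotype against parental references P1 and P2; they
#'   must share the windowing exactly.
#' @param ratio_threshold minimum divergence ratio for a confident call,
#'   default 2.
#' @param min_run_windows minimum run length of a label, default 3.
#' @param loh optional \code{loh_events} table from [call_loh()]; windows
#'   with at least half their width inside an LOH event are labeled by
#'   the shared post-LOH parent (direct divergence comparison) and are
#'   exempt from run suppression.
#' @param haplotype optional haplotype tag ("A"/"B") stored in the output.
#' @return data.frame of class \code{parentage_calls}: chrom, start, end,
#'   haplotype, d_p1, d_p2, label in \{P1, P2, ambiguous\}, confident.
#' @export
assign_parentage <- function(div_p1, div_p2, ratio_threshold = 2,
                             min_run_windows = 3L, loh = NULL,
                             haplotype = NA_character_) {
  if (nrow(div_p1) != nrow(div_p2) ||
      !all(div_p1$chrom == div_p2$chrom & div_p1$start == div_p2$start &
             div_p1$end == div_p2$end))
    stop("divergence tracks do not share the same windowing")
  d1 <- div_p1$rate_pct
  d2 <- div_p2$rate_pct
  n <- nrow(div_p1)
  ok <- !div_p1$excluded & !div_p2$excluded
  label <- rep("ambiguous", n)
  conf <- ok & (d1 + d2 > 0) &
    (d2 >= ratio_threshold * d1 | d1 >= ratio_threshold * d2)
  label[ok & d2 >= ratio_threshold * d1 & d1 + d2 > 0] <- "P1"
  label[ok & d1 >= ratio_threshold * d2 & d1 + d2 > 0] <- "P2"
  # maximum-likelihood lean for informative windows that fail the ratio
  # test: the parent with the smaller divergence
  lean <- ifelse(!ok | is.na(d1) | is.na(d2) | d1 == d2, "ambiguous",
                 ifelse(d1 < d2, "P1", "P2"))
  label[label == "ambiguous"] <- lean[label == "ambiguous"]
  fixed <- rep(FALSE, n)
  if (!is.null(loh) && nrow(loh)) {
    win <- data.frame(chrom = div_p1$chrom, start = div_p1$start,
                      end = div_p1$end)
    ovl <- numeric(n)
    for (cn in unique(win$chrom)) {
      i <- win$chrom == cn
      ovl[i] <- window_overlap_bp(win[i, , drop = FALSE],
                                  loh[loh$chrom == cn, , drop = FALSE])
    }
    fixed <- ovl >= 0.5 * (win$end - win$start) & lean != "ambiguous"
    label[fixed] <- lean[fixed]
  }
  calls <- data.frame(chrom = div_p1$chrom, start = div_p1$start,
                      end = div_p1$end, haplotype = haplotype,
                      d_p1 = d1, d_p2 = d2, label = label,
                      confident = conf, fixed = fixed, lean = lean,
                      stringsAsFactors = FALSE)
  out <- lapply(split(calls, calls$chrom), .smooth_labels,
                min_run_windows = min_run_windows)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- res[, c("chrom", "start", "end", "haplotype", "d_p1", "d_p2",
                 "label", "confident")]
  rownames(res) <- NULL
  class(res) <- c("parentage_calls", "data.frame")
  res
}

.smooth_labels <- function(d, min_run_windows) {
  lab <- d$label
  # pass 1: a non-ambiguous run shorter than min_run_windows that sits
  # between runs agreeing on a different label (an isolated island) is
  # demoted to ambiguous; its neighbors then merge and the check repeats.
  # Runs pinned by LOH, terminal runs and runs between disagreeing
  # neighbors are kept regardless of length.
  repeat {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    non_amb <- which(r$values != "ambiguous")
    changed <- FALSE
    for (j in seq_along(non_amb)) {
      k <- non_amb[j]
      if (r$lengths[k] >= min_run_windows) next
      idx <- starts[k]:ends[k]
      if (any(d$fixed[idx])) next
      left <- if (j > 1) r$values[non_amb[j - 1]] else NA_character_
      right <- if (j < length(non_amb)) r$values[non_amb[j + 1]] else
        NA_character_
      if (!is.na(left) && !is.na(right) && left == right &&
            left != r$values[k]) {
        lab[idx] <- "ambiguous"
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  # pass 2: absorb each maximal ambiguous run into its flanks: agreeing
  # (or single) flanks donate their label; disagreeing flanks fall back
  # to the per-window maximum-likelihood lean
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != "ambiguous") next
    left <- if (k > 1) r$values[k - 1] else NA_character_
    right <- if (k < length(r$values)) r$values[k + 1] else NA_character_
    idx <- starts[k]:ends[k]
    informative <- d$lean[idx] != "ambiguous"
    if (!is.na(left) && !is.na(right) && left != right) {
      lab[idx[informative]] <- d$lean[idx][informative]
    } else {
      fill <- if (!is.na(left)) left else right
      if (!is.na(fill)) {
        lab[idx[informative]] <- fill
      }
    }
  }
  d$label <- lab
  d
}

#' Detect parentage switches between adjacent windows on the two haplotypes
#'
#' A breakpoint exists on a haplotype wherever two consecutive
#' non-ambiguous parentage segments carry different labels.  Breakpoints
#' co-located on both haplotypes (within \code{tolerance_windows} windows)
#' with opposite label changes are classed \code{reciprocal} — the
#' signature of a mitotic crossover, which exchanges the distal parts of
#' the two homologs.  A change on a single haplotype that leaves the two
#' haplotypes locally carrying the same label on one side is classed
#' \code{nonreciprocal} (LOH-consistent).  Segments are reported merged
#' maximally per haplotype.
#'
#' @param calls_hapA,calls_hapB \code{parentage_calls} from
#'   [assign_parentage()] over identical windows.
#' @param tolerance_windows co-location tolerance for the reciprocal test,
#'   in windows; default 1.
#' @return list with \code{switches} (chrom, pos_start, pos_end of the
#'   breakpoint interval, type, haplotypes, labels either side per
#'   haplotype) and \code{segments} (chrom, haplotype, start, end, label).
#' @export
detect_switches <- function(calls_hapA, calls_hapB, tolerance_windows = 1L) {
  if (nrow(calls_hapA) != nrow(calls_hapB) ||
      !all(calls_hapA$chrom == calls_hapB$chrom &
             calls_hapA$start == calls_hapB$start))
    stop("haplotype calls do not share the same windowing")
  window_bp <- max(calls_hapA$end - calls_hapA$start)
  seg_a <- .label_segments(calls_hapA, "A")
  seg_b <- .label_segments(calls_hapB, "B")
  bp_a <- .segment_breaks(seg_a)
  bp_b <- .segment_breaks(seg_b)
  tol <- tolerance_windows * window_bp
  used_b <- logical(nrow(bp_b))
  switches <- list()
  mid <- function(b) (b$pos_start + b$pos_end) / 2
  for (i in seq_len(nrow(bp_a))) {
    cand <- which(!used_b & bp_b$chrom == bp_a$chrom[i] &
                    abs(mid(bp_b) - mid(bp_a[i, ])) <= tol &
                    bp_b$from == bp_a$to[i] & bp_b$to == bp_a$from[i])
    if (length(cand)) {
      j <- cand[which.min(abs(mid(bp_b[cand, ]) - mid(bp_a[i, ])))]
      used_b[j] <- TRUE
      switches[[length(switches) + 1L]] <- data.frame(
        chrom = bp_a$chrom[i],
        pos_start = min(bp_a$pos_start[i], bp_b$pos_start[j]),
        pos_end = max(bp_a$pos_end[i], bp_b$pos_end[j]),
        type = "reciprocal", haplotypes = "A+B",
        from_A = bp_a$from[i], to_A = bp_a$to[i],
        from_B = bp_b$from[j], to_B = bp_b$to[j],
        stringsAsFactors = FALSE)
    } else {
      switches[[length(switches) + 1L]] <- data.frame(
        chrom = bp_a$chrom[i], pos_start = bp_a$pos_start[i],
        pos_end = bp_a$pos_end[i], type = "nonreciprocal",
        haplotypes = "A", from_A = bp_a$from[i], to_A = bp_a$to[i],
        from_B = NA_character_, to_B = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  for (j in which(!used_b)) {
    switches[[length(switches) + 1L]] <- data.frame(
      chrom = bp_b$chrom[j], pos_start = bp_b$pos_start[j],
      pos_end = bp_b$pos_end[j], type = "nonreciprocal",
      haplotypes = "B", from_A = NA_character_, to_A = NA_character_,
      from_B = bp_b$from[j], to_B = bp_b$to[j],
      stringsAsFactors = FALSE)
  }
  switches <- if (length(switches)) do.call(rbind, switches) else
    data.frame(chrom = character(), pos_start = numeric(),
               pos_end = numeric(), type = character(),
               haplotypes = character(), from_A = character(),
               to_A = character(), from_B = character(),
               to_B = character(), stringsAsFactors = FALSE)
  switches <- switches[order(switches$chrom, switches$pos_start), ,
                       drop = FALSE]
  rownames(switches) <- NULL
  segments <- rbind(seg_a, seg_b)
  rownames(segments) <- NULL
  list(switches = switches, segments = segments)
}

# maximal runs of identical labels per chromosome -> genomic segments
.label_segments <- function(calls, haplotype) {
  out <- lapply(split(calls, calls$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    r <- rle(d$label)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = d$chrom[1], haplotype = haplotype,
               start = d$start[starts], end = d$end[ends],
               label = r$values, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# breakpoints between consecutive non-ambiguous segments with different
# labels; the breakpoint interval spans any ambiguous run in between
.segment_breaks <- function(seg) {
  out <- lapply(split(seg, seg$chrom), function(d) {
    d <- d[d$label != "ambiguous", , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    i <- which(d$label[-1] != d$label[-nrow(d)])
    if (!length(i)) return(NULL)
    data.frame(chrom = d$chrom[1], pos_start = d$end[i],
               pos_end = d$start[i + 1], from = d$label[i],
               to = d$label[i + 1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos_start = integer(),
                      pos_end = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
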