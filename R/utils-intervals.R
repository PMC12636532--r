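# Interval helpers.  All take/return 0-based half-open [start, end) integer
# coordinates in plain data.frames with columns chrom, start, end; IRanges
# does the heavy lifting (shifted +1 to its 1-based closed convention).

.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.from_iranges <- function(ir, chrom) {
  data.frame(chrom = rep_len(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

# Union (merge overlapping/adjacent-touching) per chromosome.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(.as_iranges(d))
    .from_iranges(ir, d$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Intersection of two interval sets (per chromosome).
intersect_intervals <- function(a, b) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(cn) {
    ia <- .as_iranges(a[a$chrom == cn, , drop = FALSE])
    ib <- .as_iranges(b[b$chrom == cn, , drop = FALSE])
    .from_iranges(IRanges::intersect(ia, ib), cn)
  })
  res <- rbind(empty, do.call(rbind, out))
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Subtraction a \ b per chromosome.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(a[, c("chrom", "start", "end")])
  out <- lapply(split(a, a$chrom), function(d) {
    cn <- d$chrom[1]
    bb <- b[b$chrom == cn, , drop = FALSE]
    if (nrow(bb) == 0) return(d[, c("chrom", "start", "end")])
    ia <- .as_iranges(d)
    ib <- IRanges::reduce(.as_iranges(bb))
    .from_iranges(IRanges::setdiff(ia, ib), cn)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Total bp per chromosome (named vector) of an interval set.
interval_bp <- function(df) {
  if (nrow(df) == 0) return(setNames(integer(), character()))
  tapply(df$end - df$start, df$chrom, sum)
}

# For 1-based positions, TRUE when the base [pos-1, pos) lies inside any
# interval of `df` on the same chromosome.
positions_in_intervals <- function(chrom, pos, df) {
  out <- logical(length(pos))
  if (length(pos) == 0 || nrow(df) == 0) return(out)
  for (cn in unique(chrom)) {
    i <- chrom == cn
    d <- df[df$chrom == cn, , drop = FALSE]
    if (nrow(d) == 0) next
    ir <- .as_iranges(d)
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos[i], width = 1L), ir)
    sel <- rep(FALSE, sum(i))
    sel[unique(S4Vectors::queryHits(hits))] <- TRUE
    out[i] <- sel
  }
  out
}

# Overlap width between each query window and an interval set, aggregated per
# window.  win and blk are data.frames for a single chromosome.
window_overlap_bp <- function(win, blk) {
  if (nrow(win) == 0) return(integer())
  if (nrow(blk) == 0) return(integer(nrow(win)))
  iw <- .as_iranges(win)
  ib <- IRanges::reduce(.as_iranges(blk))
  hits <- IRanges::findOverlaps(iw, ib)
  if (length(hits) == 0) return(integer(nrow(win)))
  w <- IRanges::width(IRanges::pintersect(iw[S4Vectors::queryHits(hits)],
                                          ib[S4Vectors::subjectHits(hits)]))
  out <- integer(nrow(win))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}
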