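# TSS-anchored methylation metaplots and periodicity estimation.

#' TSS-anchored metaplot of per-site modification fractions
#'
#' Aggregates per-site modification fractions (e.g. 5mC at CpG or 6mA at
#' ApT sites) around transcription start sites.  Sites with fewer than
#' \code{min_cov} valid reads are removed first.  For each gene, a site's
#' offset is \code{pos - tss} on the plus strand and \code{tss - pos} on
#' the minus strand, so positive offsets always point into the gene body.
#' The profile value at each offset is the \emph{median} modified fraction
#' across genes, with the contributing site count recorded so sparse
#' offsets can be masked downstream.
#'
#' @param methyl [methyl_sites()] table.
#' @param tss data.frame with columns chrom, pos (1-based TSS) and strand
#'   ("+"/"-"), one row per gene (typically the primary isoform's TSS).
#' @param upstream,downstream profile extent in bp, defaults 1000 and 2000.
#' @param min_cov minimum valid read coverage per site, default 5.
#' @param label modification label stored on the result (e.g. "5mC").
#' @return data.frame of class \code{tss_profile}: offset (in
#'   [-upstream, downstream]), median_frac, n_sites.
#' @export
tss_metaplot <- function(methyl, tss, upstream = 1000L, downstream = 2000L,
                         min_cov = 5L, label = "mod") {
  m <- methyl[methyl$valid_cov >= min_cov, , drop = FALSE]
  offsets <- seq.int(-upstream, downstream)
  known <- unique(m$chrom)
  bychrom <- split(m, m$chrom)
  off_all <- vector("list", nrow(tss))
  frac_all <- vector("list", nrow(tss))
  for (g in seq_len(nrow(tss))) {
    cn <- tss$chrom[g]
    if (!cn %in% known) {
      warning(sprintf("TSS on unknown chromosome %s skipped", cn))
      next
    }
    d <- bychrom[[cn]]
    flip <- tss$strand[g] == "-"
    lo <- if (flip) tss$pos[g] - downstream else tss$pos[g] - upstream
    hi <- if (flip) tss$pos[g] + upstream else tss$pos[g] + downstream
    sel <- d$pos >= lo & d$pos <= hi
    if (!any(sel)) next
    off_all[[g]] <- if (flip) tss$pos[g] - d$pos[sel] else
      d$pos[sel] - tss$pos[g]
    frac_all[[g]] <- d$frac_mod[sel]
  }
  off <- unlist(off_all)
  frac <- unlist(frac_all)
  med <- rep(NA_real_, length(offsets))
  counts <- integer(length(offsets))
  if (length(off)) {
    idx <- off + upstream + 1L
    agg_med <- tapply(frac, idx, median)
    agg_n <- tapply(frac, idx, length)
    med[as.integer(names(agg_med))] <- as.numeric(agg_med)
    counts[as.integer(names(agg_n))] <- as.integer(agg_n)
  }
  res <- data.frame(offset = offsets, median_frac = med, n_sites = counts)
  attr(res, "label") <- label
  class(res) <- c("tss_profile", "data.frame")
  res
}

#' Estimate the period of a TSS-anchored modification profile
#'
#' Detects the nucleosome-scale periodicity of a metaplot: the profile is
#' restricted to \code{offset_range}, missing offsets are filled by linear
#' interpolation, the mean is removed, and the period is taken as the lag
#' maximizing the autocorrelation over \code{lag_range}.  Peak offsets are
#' the local maxima above the profile's 75th percentile, greedily thinned
#' so that retained peaks are at least period/2 apart.
#'
#' @param profile \code{tss_profile} from [tss_metaplot()].
#' @param offset_range offsets to analyse, default c(0, max offset)
#'   (periodic signal sits downstream of the TSS).
#' @param lag_range candidate period range in bp, default c(50, 500).
#' @return list of class \code{periodicity}: \code{period_bp} (NA when the
#'   profile is flat), \code{peak_offsets}, \code{acf_max}, and
#'   \code{defined}.
#' @export
estimate_periodicity <- function(profile, offset_range = NULL,
                                 lag_range = c(50L, 500L)) {
  if (is.null(offset_range))
    offset_range <- c(0L, max(profile$offset))
  d <- profile[profile$offset >= offset_range[1] &
                 profile$offset <= offset_range[2], , drop = FALSE]
  grid <- seq.int(offset_range[1], offset_range[2])
  y <- rep(NA_real_, length(grid))
  y[match(d$offset, grid)] <- d$median_frac
  ok <- !is.na(y)
  if (sum(ok) < 2 || stats::sd(y[ok]) == 0) {
    return(structure(list(period_bp = NA_real_, peak_offsets = integer(),
                          acf_max = NA_real_, defined = FALSE),
                     class = "periodicity"))
  }
  if (any(!ok))
    y <- approx(grid[ok], y[ok], xout = grid, rule = 2)$y
  yc <- y - mean(y)
  lag_max <- min(lag_range[2], length(yc) - 1L)
  ac <- acf(yc, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  cand <- lags >= lag_range[1] & lags <= lag_max
  if (!any(cand) || all(!is.finite(ac[cand]))) {
    return(structure(list(period_bp = NA_real_, peak_offsets = integer(),
                          acf_max = NA_real_, defined = FALSE),
                     class = "periodicity"))
  }
  period <- lags[cand][which.max(ac[cand])]
  # local maxima above the 75th percentile, >= period/2 apart
  thr <- quantile(y, 0.75, names = FALSE)
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] > thr]
  loc <- loc[order(-y[loc])]
  peaks <- integer()
  for (p in loc) {
    if (all(abs(p - peaks) >= period / 2)) peaks <- c(peaks, p)
  }
  structure(list(period_bp = as.numeric(period),
                 peak_offsets = sort(grid[peaks]),
                 acf_max = max(ac[cand]), defined = TRUE),
            class = "periodicity")
}

#' @export
print.periodicity <- function(x, ...) {
  if (!x$defined) cat("<periodicity> undefined (flat profile)\n")
  else cat(sprintf("<periodicity> period %.0f bp; peaks at %s\n",
                   x$period_bp, paste(x$peak_offsets, collapse = ", ")))
  invisible(x)
}

#' Plot a TSS metaplot profile
#'
#' @param x \code{tss_profile} from [tss_metaplot()].
#' @param min_sites mask offsets supported by fewer sites than this,
#'   default 1.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tss_profile <- function(x, min_sites = 1L, ...) {
  y <- ifelse(x$n_sites >= min_sites, x$median_frac, NA_real_)
  plot(x$offset, y, type = "l", xlab = "offset from TSS (bp)",
       ylab = "median modified fraction",
       main = attr(x, "label"), ...)
  abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
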