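# Windowed heterozygosity / divergence and site-degeneracy classification.

# Tile chromosomes with fixed windows anchored at 0; the final partial
# window is kept and subjected to the same min-aligned filter.
.tile_windows <- function(chrom_lengths, window_bp) {
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- as.integer(chrom_lengths[[cn]])
    s <- seq.int(0L, L - 1L, by = window_bp)
    data.frame(chrom = cn, start = s, end = pmin(s + window_bp, L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.window_stats <- function(chrom, pos, weight, blocks, chrom_lengths,
                          window_bp, min_aligned) {
  win <- .tile_windows(chrom_lengths, window_bp)
  win$aligned_sites <- 0L
  win$variant_weight <- 0
  inblock <- positions_in_intervals(chrom, pos, blocks)
  n_outside <- sum(!inblock)
  chrom <- chrom[inblock]; pos <- pos[inblock]; weight <- weight[inblock]
  for (cn in names(chrom_lengths)) {
    wi <- which(win$chrom == cn)
    win$aligned_sites[wi] <-
      window_overlap_bp(win[wi, ], blocks[blocks$chrom == cn, , drop = FALSE])
    sel <- chrom == cn
    if (any(sel)) {
      idx <- findInterval(pos[sel] - 1L, win$start[wi])
      agg <- tapply(weight[sel], idx, sum)
      win$variant_weight[wi[as.integer(names(agg))]] <- as.numeric(agg)
    }
  }
  win$rate_pct <- ifelse(win$aligned_sites > 0,
                         100 * win$variant_weight / win$aligned_sites, NA_real_)
  win$excluded <- win$aligned_sites < min_aligned
  win$rate_pct[win$excluded] <- NA_real_
  attr(win, "sites_outside_blocks") <- n_outside
  class(win) <- c("window_stats", "data.frame")
  win
}

#' Windowed heterozygosity
#'
#' Tiles each chromosome with fixed windows and reports, per window, the
#' number of alignable sites, the count of heterozygous SNVs whose position
#' falls inside an alignable block, and the heterozygosity rate (percent of
#' aligned sites).  Windows with fewer aligned sites than \code{min_aligned}
#' are flagged \code{excluded} and their rate set to \code{NA}.  Sites
#' outside every block are tallied in the \code{sites_outside_blocks}
#' attribute and excluded from the numerator.
#'
#' @param sites [variant_sites()] table; only \code{zygosity == "het"} rows
#'   are counted.
#' @param blocks [alignable_blocks()] table.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_bp window width, default 10000.
#' @param min_aligned minimum aligned sites for a window to be reported,
#'   default 2000.
#' @return data.frame of class \code{window_stats} with columns chrom,
#'   start, end, aligned_sites, variant_weight, rate_pct, excluded.
#' @export
het_windows <- function(sites, blocks, chrom_lengths, window_bp = 10000L,
                        min_aligned = 2000L) {
  bad <- setdiff(unique(sites$chrom), names(chrom_lengths))
  if (length(bad))
    stop(sprintf("chromosome(s) missing from chrom_lengths: %s",
                 paste(bad, collapse = ", ")))
  het <- sites[sites$zygosity == "het", , drop = FALSE]
  .window_stats(het$chrom, het$pos, rep(1, nrow(het)), blocks, chrom_lengths,
                window_bp, min_aligned)
}

#' Windowed divergence with half-weighting of single-haplotype variants
#'
#' Divergence of a diploid strain to a reference, averaged over its two
#' haplotypes: a site at which only one haplotype differs from the reference
#' contributes weight 0.5, a site at which both differ contributes 1.0.
#'
#' @param strain_variants [variant_sites()] table with populated
#'   \code{haplotype_hits} (1 or 2); a record with 0 hits is rejected.
#' @inheritParams het_windows
#' @return data.frame of class \code{window_stats} (see [het_windows()]).
#' @export
divergence_windows <- function(strain_variants, blocks, chrom_lengths,
                               window_bp = 10000L, min_aligned = 2000L) {
  if (any(strain_variants$haplotype_hits == 0L))
    stop("divergence input contains records with haplotype_hits = 0")
  w <- ifelse(strain_variants$haplotype_hits == 1L, 0.5, 1.0)
  .window_stats(strain_variants$chrom, strain_variants$pos, w, blocks,
                chrom_lengths, window_bp, min_aligned)
}

# Degeneracy fold of every codon position under the standard genetic code:
# fold = (number of alternative bases preserving the amino acid) + 1, i.e.
# 0-fold is reported when no substitution is synonymous (count 0 maps to
# class 0; counts 1/2/3 map to classes 2/3/4).
.codon_fold_table <- function() {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  folds <- matrix(0L, nrow = length(codons), ncol = 3,
                  dimnames = list(codons, NULL))
  for (cd in codons) {
    for (p in 1:3) {
      syn <- 0L
      for (b in setdiff(bases, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (code[[alt]] == code[[cd]]) syn <- syn + 1L
      }
      folds[cd, p] <- c(0L, 2L, 3L, 4L)[syn + 1L]
    }
  }
  folds
}

#' Classify coding positions by degeneracy under the standard genetic code
#'
#' For each CDS position of each coding transcript, reports the degeneracy
#' fold: 0 (no synonymous substitution), 2, 3 or 4.  The 3-fold class (Ile
#' third positions) is kept as its own class.  Positions are mapped back to
#' genomic coordinates through the transcript's CDS intervals and strand.
#' Transcripts whose CDS length is not a multiple of 3 or that contain an
#' internal stop codon are skipped with a warning.
#'
#' @param tx [transcript_models()] table (coding transcripts).
#' @param genome named [Biostrings::DNAStringSet] (plus-strand assembly).
#' @return data.frame of class \code{degeneracy_sites} with columns chrom,
#'   pos (1-based genomic position), fold, transcript_id, cds_pos.
#' @export
classify_degeneracy <- function(tx, genome) {
  folds <- .codon_fold_table()
  out <- list()
  for (i in seq_len(nrow(tx))) {
    if (!tx$is_coding[i]) next
    cd <- tx$cds[[i]]
    gpos <- unlist(lapply(seq_len(nrow(cd)),
                          function(j) seq.int(cd[j, 1] + 1L, cd[j, 2])))
    if (tx$strand[i] == "-") gpos <- rev(gpos)
    n <- length(gpos)
    if (n %% 3 != 0) {
      warning(sprintf("transcript %s: CDS length not divisible by 3; skipped",
                      tx$id[i]))
      next
    }
    seq <- as.character(Biostrings::subseq(
      genome[[tx$chrom[i]]], start = 1L))
    base <- substring(seq, gpos, gpos)
    if (tx$strand[i] == "-")
      base <- chartr("ACGT", "TGCA", base)
    codons <- paste0(base[seq(1, n, 3)], base[seq(2, n, 3)], base[seq(3, n, 3)])
    aa_stop <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(aa_stop) && any(aa_stop < length(codons))) {
      warning(sprintf("transcript %s: internal stop codon; skipped", tx$id[i]))
      next
    }
    fold <- as.integer(t(folds[codons, , drop = FALSE]))
    out[[tx$id[i]]] <- data.frame(chrom = tx$chrom[i], pos = gpos,
                                  fold = fold, transcript_id = tx$id[i],
                                  cds_pos = seq_len(n),
                                  stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), fold = integer(),
               transcript_id = character(), cds_pos = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("degeneracy_sites", "data.frame")
  res
}

#' Overall heterozygosity after masking LOH tracts, optionally per
#' degeneracy class
#'
#' Overall heterozygosity is reported after removing homozygous tracts:
#' the rate is het sites outside every LOH event divided by aligned sites
#' outside LOH.  With a degeneracy classification, per-fold-class rates are
#' additionally computed over the classified coding positions (inside
#' blocks, outside LOH).
#'
#' @param sites [variant_sites()] table.
#' @param blocks [alignable_blocks()] table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param loh \code{loh_events} table from [call_loh()]; may be empty.
#' @param degeneracy optional \code{degeneracy_sites} from
#'   [classify_degeneracy()].
#' @return list with \code{rate_pct} (overall, NA with a flag when all
#'   aligned sequence is masked), \code{het_sites}, \code{aligned_sites},
#'   \code{undefined}, and (when degeneracy is given) \code{by_fold}, a
#'   data.frame with per-class site counts and rates.
#' @export
het_summary <- function(sites, blocks, chrom_lengths, loh = NULL,
                        degeneracy = NULL) {
  if (is.null(loh) || nrow(loh) == 0) {
    masked_blocks <- blocks[, c("chrom", "start", "end")]
  } else {
    masked_blocks <- subtract_intervals(blocks[, c("chrom", "start", "end")],
                                        loh[, c("chrom", "start", "end")])
  }
  aligned <- sum(interval_bp(masked_blocks))
  het <- sites[sites$zygosity == "het", , drop = FALSE]
  keep <- positions_in_intervals(het$chrom, het$pos, masked_blocks)
  n_het <- sum(keep)
  undefined <- aligned == 0
  if (undefined)
    warning("no aligned sites remain after LOH masking; rate undefined")
  res <- list(rate_pct = if (undefined) NA_real_ else 100 * n_het / aligned,
              het_sites = n_het, aligned_sites = as.integer(aligned),
              undefined = undefined)
  if (!is.null(degeneracy) && nrow(degeneracy)) {
    dkeep <- positions_in_intervals(degeneracy$chrom, degeneracy$pos,
                                    masked_blocks)
    d <- degeneracy[dkeep, , drop = FALSE]
    hetkey <- paste(het$chrom[keep], het$pos[keep])
    by_fold <- do.call(rbind, lapply(sort(unique(d$fold)), function(f) {
      dd <- d[d$fold == f, , drop = FALSE]
      nh <- sum(paste(dd$chrom, dd$pos) %in% hetkey)
      data.frame(fold = f, n_sites = nrow(dd), het_sites = nh,
                 rate_pct = if (nrow(dd)) 100 * nh / nrow(dd) else NA_real_)
    }))
    res$by_fold <- by_fold
  }
  res
}
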