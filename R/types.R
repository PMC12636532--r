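#' Construct and validate a table of genotyped variant sites
#'
#' A variant site is one genotyped single-nucleotide position of the sample
#' against a reference: 1-based position, ref/alt base, zygosity and the
#' number of the sample's two haplotypes carrying the alt allele.  Sites are
#' the atoms of heterozygosity, divergence and LOH analysis.
#'
#' @param chrom character chromosome names.
#' @param pos 1-based integer positions.
#' @param ref,alt single reference/alternate bases; \code{ref != alt}.
#' @param zygosity \code{"het"} or \code{"hom_alt"}.
#' @param haplotype_hits integer in 0..2; must be 1 exactly when
#'   \code{zygosity == "het"}.
#' @return data.frame of class \code{variant_sites}, sorted by chrom then pos.
#' @export
variant_sites <- function(chrom, pos, ref = "A", alt = "T",
                          zygosity = "het", haplotype_hits = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   zygosity = rep_len(as.character(zygosity), n),
                   stringsAsFactors = FALSE)
  if (is.null(haplotype_hits))
    haplotype_hits <- ifelse(df$zygosity == "het", 1L, 2L)
  df$haplotype_hits <- rep_len(as.integer(haplotype_hits), n)
  if (n) {
    if (any(df$pos < 1L)) stop("variant positions must be >= 1")
    if (any(df$ref == df$alt)) stop("ref and alt bases must differ")
    if (!all(df$zygosity %in% c("het", "hom_alt")))
      stop("zygosity must be 'het' or 'hom_alt'")
    if (any((df$zygosity == "het") != (df$haplotype_hits == 1L)))
      stop("zygosity 'het' must coincide with haplotype_hits == 1")
    if (any(df$haplotype_hits < 0L | df$haplotype_hits > 2L))
      stop("haplotype_hits must be in 0..2")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("variant_sites", "data.frame")
  df
}

#' Construct a normalized table of alignable (callable) blocks
#'
#' Alignable blocks are the half-open intervals of confidently aligned or
#' callable sequence; their total length is the denominator of every
#' heterozygosity and divergence rate.  Unsorted input is sorted and
#' overlapping blocks are merged, each with a warning.
#'
#' @param chrom,start,end block coordinates, 0-based half-open.
#' @return data.frame of class \code{alignable_blocks}, sorted and
#'   non-overlapping per chromosome.
#' @export
alignable_blocks <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("blocks require 0 <= start < end")
    o <- order(df$chrom, df$start)
    if (is.unsorted(o)) {
      warning("alignable blocks were unsorted; normalizing")
      df <- df[o, , drop = FALSE]
    }
    overlaps <- unlist(lapply(split(df, df$chrom), function(d)
      nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])))
    if (any(overlaps)) {
      warning("overlapping alignable blocks merged during normalization")
      df <- merge_intervals(df)
    }
    rownames(df) <- NULL
  }
  class(df) <- c("alignable_blocks", "data.frame")
  df
}

#' Construct a table of coverage bins
#'
#' @param chrom,start,end bin coordinates, 0-based half-open.
#' @param mean_depth mean reads per base over the bin, >= 0.
#' @return data.frame of class \code{coverage_bins}.
#' @export
coverage_bins <- function(chrom, start, end, mean_depth) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), mean_depth = as.numeric(mean_depth),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("bins require 0 <= start < end")
    if (any(df$mean_depth < 0)) stop("mean_depth must be >= 0")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("coverage_bins", "data.frame")
  df
}

#' Construct a table of per-site DNA-modification calls
#'
#' One row per genomic site carrying a base-modification summary (e.g. 5mC at
#' a CpG or 6mA at an ApT): 1-based position, strand, number of reads with a
#' valid call, and the fraction of those reads carrying the modification.
#'
#' @param chrom,pos site coordinates (pos is 1-based).
#' @param strand \code{"+"}, \code{"-"} or \code{"both"} (strand-aggregated
#'   pileups).
#' @param valid_cov integer read count, >= 0.
#' @param frac_mod modified fraction in [0, 1].
#' @return data.frame of class \code{methyl_sites}.
#' @export
methyl_sites <- function(chrom, pos, strand = "both", valid_cov, frac_mod) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = rep_len(as.character(strand), n),
                   valid_cov = as.integer(valid_cov),
                   frac_mod = as.numeric(frac_mod), stringsAsFactors = FALSE)
  if (n) {
    if (!all(df$strand %in% c("+", "-", "both")))
      stop("strand must be '+', '-' or 'both'")
    if (any(df$valid_cov < 0L)) stop("valid_cov must be >= 0")
    if (any(df$frac_mod < 0 | df$frac_mod > 1))
      stop("frac_mod must lie in [0, 1]")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("methyl_sites", "data.frame")
  df
}

#' Construct a set of transcript models
#'
#' Transcript models carry exon and CDS structure plus long-read support;
#' they are the substrate of the isoform-curation rules and the antisense
#' lncRNA scan.  Exon and CDS intervals are 0-based half-open two-column
#' matrices (start, end), stored as list columns.
#'
#' @param id,gene_id,chrom,strand character vectors, one entry per transcript.
#' @param exons,cds lists of integer matrices with columns start, end; CDS
#'   intervals must be contained in the exons; \code{cds} entries may have
#'   zero rows for noncoding transcripts.
#' @param read_count integer full-length read support, >= 0.
#' @return data.frame of class \code{transcript_models} with list columns
#'   \code{exons} and \code{cds} and a derived logical \code{is_coding}.
#' @export
transcript_models <- function(id, gene_id, chrom, strand, exons, cds,
                              read_count) {
  n <- length(id)
  norm <- function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1]), , drop = FALSE]
  }
  exons <- lapply(exons, norm)
  cds <- lapply(cds, norm)
  df <- data.frame(id = as.character(id), gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   read_count = as.integer(read_count),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  df$cds <- cds
  df$is_coding <- vapply(cds, nrow, 0L) > 0L
  if (n) {
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(df$read_count < 0L)) stop("read_count must be >= 0")
    for (i in seq_len(n)) {
      ex <- df$exons[[i]]
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
        stop(sprintf("transcript %s has overlapping exons", df$id[i]))
      cd <- df$cds[[i]]
      if (nrow(cd)) {
        exdf <- data.frame(chrom = "x", start = ex[, 1], end = ex[, 2])
        cddf <- data.frame(chrom = "x", start = cd[, 1], end = cd[, 2])
        left <- subtract_intervals(cddf, exdf)
        if (nrow(left))
          stop(sprintf("transcript %s has CDS outside its exons", df$id[i]))
      }
    }
  }
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts, %d genes, %d coding\n",
              nrow(x), length(unique(x$gene_id)), sum(x$is_coding)))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("id", "gene_id", "chrom",
                                             "strand", "read_count",
                                             "is_coding")], 10)
    print(show)
    if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

# genomic span (0-based half-open) of each transcript
.tx_span <- function(tx) {
  data.frame(id = tx$id, gene_id = tx$gene_id, chrom = tx$chrom,
             strand = tx$strand,
             start = vapply(tx$exons, function(m) min(m[, 1]), 0L),
             end = vapply(tx$exons, function(m) max(m[, 2]), 0L),
             stringsAsFactors = FALSE)
}

# total CDS length of each transcript
.tx_cds_len <- function(tx) {
  vapply(tx$cds, function(m) sum(m[, 2] - m[, 1]), 0L)
}

# transcription start site, 1-based (first transcribed base)
.tx_tss <- function(tx) {
  ifelse(tx$strand == "+",
         vapply(tx$exons, function(m) min(m[, 1]), 0L) + 1L,
         vapply(tx$exons, function(m) max(m[, 2]), 0L))
}
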