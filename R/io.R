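# Readers/writers for the standard formats consumed by the pipeline.
# Internal convention: 0-based half-open intervals; VCF and bedMethyl
# positions stay 1-based at the file boundary, as those formats define.

#' Read single-nucleotide variants from a VCF file
#'
#' Parses a VCF 4.x with a single sample and a GT genotype field (via
#' \pkg{vcfR}).  Only biallelic single-nucleotide records are kept; indels
#' and multi-base alleles are skipped with one counted warning, since all
#' downstream rates are SNV-based.  Genotypes 0/1 (or 0|1, 1|0) become
#' heterozygous sites, 1/1 homozygous-alt; 0/0 and missing genotypes are
#' dropped.
#'
#' @param path VCF file (plain or gzipped).
#' @return [variant_sites()] table.
#' @export
read_variants_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(variant_sites(character(), integer()))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  if (any(!snv))
    warning(sprintf("%d non-SNV record(s) skipped in %s", sum(!snv), path))
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  zyg <- rep(NA_character_, length(gt))
  zyg[gt %in% c("0/1", "1/0")] <- "het"
  zyg[gt == "1/1"] <- "hom_alt"
  keep <- snv & !is.na(zyg)
  variant_sites(chrom = fix[keep, "CHROM"],
                pos = as.integer(fix[keep, "POS"]),
                ref = ref[keep], alt = alt[keep], zygosity = zyg[keep],
                haplotype_hits = ifelse(zyg[keep] == "het", 1L, 2L))
}

#' Write variant sites as a minimal single-sample VCF
#'
#' Emits a VCF 4.2 with GT-only genotypes (0/1 for het, 1/1 for hom_alt)
#' that round-trips through [read_variants_vcf()] field for field.
#'
#' @param sites [variant_sites()] table.
#' @param path output file.
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   write \code{##contig} headers; if given, sites on chromosomes absent
#'   from it are an error.
#' @param sample_name sample column name.
#' @return \code{path}, invisibly.
#' @export
write_variants_vcf <- function(sites, path, chrom_lengths = NULL,
                               sample_name = "sample") {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(chrom_lengths)) {
    bad <- setdiff(unique(sites$chrom), names(chrom_lengths))
    if (length(bad))
      stop(sprintf("chromosome(s) not in genome index: %s",
                   paste(bad, collapse = ", ")))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths),
                                as.integer(chrom_lengths)))
  }
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample_name,
                            sep = "\t"))
  gt <- ifelse(sites$zygosity == "het", "0/1", "1/1")
  body <- if (nrow(sites)) {
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
          ".", "GT", gt, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignable blocks from a BED3 file
#'
#' @param path BED file (0-based half-open, as BED defines).
#' @return [alignable_blocks()] table (normalized, with a warning if the
#'   input was unsorted or overlapping).
#' @export
read_blocks_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  alignable_blocks(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr))
}

#' Write alignable blocks as BED3
#' @param blocks [alignable_blocks()] table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  .write_bedlike(data.frame(blocks$chrom, blocks$start, blocks$end), path)
}

#' Read LOH events from a BED4 file (event class in column 4)
#' @param path BED file.
#' @return data.frame of class \code{loh_events} (chrom, start, end, length,
#'   kind).
#' @export
read_loh_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  kind <- if (length(gr) && !is.null(gr$name)) as.character(gr$name)
          else character(length(gr))
  loh_events(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), kind = kind)
}

#' Write LOH events as BED4 with the event class in column 4
#' @param events \code{loh_events} table from [call_loh()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_loh_bed <- function(events, path) {
  .write_bedlike(data.frame(events$chrom, events$start, events$end,
                            events$kind), path)
}

#' Read a coverage track from a bedGraph file
#' @param path bedGraph file.
#' @return [coverage_bins()] table (bins of whatever width the file holds;
#'   re-bin with [bin_coverage()]).
#' @export
read_coverage_bedgraph <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_bins(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = BiocGenerics::start(gr) - 1L,
                end = BiocGenerics::end(gr),
                mean_depth = gr$score)
}

#' Write a coverage track as bedGraph
#' @param bins [coverage_bins()] table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_coverage_bedgraph <- function(bins, path) {
  .write_bedlike(data.frame(bins$chrom, bins$start, bins$end,
                            format(bins$mean_depth, trim = TRUE,
                                   scientific = FALSE)), path)
}

.write_bedlike <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read per-site modification calls from a bedMethyl-like TSV
#'
#' Expected tab-separated columns with a header: \code{chrom}, \code{pos}
#' (1-based), \code{strand}, \code{valid_cov}, \code{percent_modified}
#' (0-100; stored internally as a fraction).
#'
#' @param path TSV file.
#' @return [methyl_sites()] table.
#' @export
read_methyl_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  .stopifnot_cols(df, c("chrom", "pos", "strand", "valid_cov",
                        "percent_modified"), sprintf("bedMethyl %s", path))
  for (col in c("pos", "valid_cov", "percent_modified"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(df$pos) | !is.finite(df$valid_cov) |
                 !is.finite(df$percent_modified))
  if (length(bad))
    stop(sprintf("malformed record in %s at data line %d", path, bad[1]))
  methyl_sites(chrom = df$chrom, pos = df$pos, strand = df$strand,
               valid_cov = df$valid_cov, frac_mod = df$percent_modified / 100)
}

#' Write per-site modification calls as a bedMethyl-like TSV
#' @param sites [methyl_sites()] table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_methyl_tsv <- function(sites, path) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    strand = sites$strand, valid_cov = sites$valid_cov,
                    percent_modified = sites$frac_mod * 100)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GFF3 file
#'
#' Reads gene/mRNA(or transcript)/exon/CDS features (via \pkg{rtracklayer})
#' into a [transcript_models()] table.  Full-length read support is taken
#' from a \code{read_count} attribute on the transcript feature (0 when
#' absent).
#'
#' @param path GFF3 file.
#' @return [transcript_models()] table.
#' @export
read_transcripts_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")
  txs <- gr[is_tx]
  if (length(txs) == 0)
    return(transcript_models(character(), character(), character(),
                             character(), list(), list(), integer()))
  tx_id <- as.character(txs$ID)
  parent1 <- function(x) vapply(x, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  gene_id <- parent1(txs$Parent)
  gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  rc <- if ("read_count" %in% names(S4Vectors::mcols(txs)))
    suppressWarnings(as.integer(txs$read_count)) else rep(NA_integer_,
                                                          length(txs))
  rc[is.na(rc)] <- 0L
  sub <- gr[type %in% c("exon", "CDS")]
  sub_par <- parent1(sub$Parent)
  collect <- function(id, want) {
    sel <- sub_par == id & as.character(sub$type) == want
    if (!any(sel)) return(matrix(integer(), ncol = 2))
    cbind(start = BiocGenerics::start(sub[sel]) - 1L,
          end = BiocGenerics::end(sub[sel]))
  }
  transcript_models(
    id = tx_id, gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(txs)),
    strand = as.character(BiocGenerics::strand(txs)),
    exons = lapply(tx_id, collect, want = "exon"),
    cds = lapply(tx_id, collect, want = "CDS"),
    read_count = rc)
}

#' Write transcript models as GFF3
#'
#' Emits one gene feature per gene_id, one mRNA (coding) or transcript
#' (noncoding) feature per isoform carrying a \code{read_count} attribute,
#' plus exon and CDS features; round-trips through
#' [read_transcripts_gff3()].
#'
#' @param tx [transcript_models()] table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_transcripts_gff3 <- function(tx, path) {
  lines <- "##gff-version 3"
  span <- .tx_span(tx)
  for (g in unique(tx$gene_id)) {
    sel <- which(tx$gene_id == g)
    gs <- min(span$start[sel]); ge <- max(span$end[sel])
    chrom <- tx$chrom[sel[1]]; strand <- tx$strand[sel[1]]
    lines <- c(lines, sprintf("%s\thybridploid\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              chrom, gs + 1L, ge, strand, g))
    for (i in sel) {
      ftype <- if (tx$is_coding[i]) "mRNA" else "transcript"
      lines <- c(lines, sprintf(
        "%s\thybridploid\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;read_count=%d",
        chrom, ftype, span$start[i] + 1L, span$end[i], strand, tx$id[i], g,
        tx$read_count[i]))
      ex <- tx$exons[[i]]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, sprintf(
          "%s\thybridploid\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          chrom, ex[j, 1] + 1L, ex[j, 2], strand, tx$id[i]))
      cd <- tx$cds[[i]]
      for (j in seq_len(nrow(cd)))
        lines <- c(lines, sprintf(
          "%s\thybridploid\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
          chrom, cd[j, 1] + 1L, cd[j, 2], strand, tx$id[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read several tracks in one call
#'
#' @param paths named list of file paths; recognized names are \code{vcf},
#'   \code{blocks}, \code{loh}, \code{coverage}, \code{methyl}, \code{gff3}
#'   and \code{fasta}.
#' @return named list of parsed collections (same names).
#' @export
read_tracks <- function(paths) {
  readers <- list(vcf = read_variants_vcf, blocks = read_blocks_bed,
                  loh = read_loh_bed, coverage = read_coverage_bedgraph,
                  methyl = read_methyl_tsv, gff3 = read_transcripts_gff3,
                  fasta = read_genome_fasta)
  unknown <- setdiff(names(paths), names(readers))
  if (length(unknown))
    stop(sprintf("unknown track type(s): %s", paste(unknown, collapse = ", ")))
  lapply(setNames(names(paths), names(paths)),
         function(n) readers[[n]](paths[[n]]))
}

#' Write several tracks in one call
#'
#' @param tracks named list of collections, names as in [read_tracks()].
#' @param paths named list of destination paths (same names).
#' @return \code{paths}, invisibly.
#' @export
write_tracks <- function(tracks, paths) {
  writers <- list(vcf = write_variants_vcf, blocks = write_blocks_bed,
                  loh = write_loh_bed, coverage = write_coverage_bedgraph,
                  methyl = write_methyl_tsv, gff3 = write_transcripts_gff3,
                  fasta = write_genome_fasta)
  stopifnot(setequal(names(tracks), names(paths)))
  for (n in names(tracks)) writers[[n]](tracks[[n]], paths[[n]])
  invisible(paths)
}
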