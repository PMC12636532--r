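# IsoSeq gene-model curation: gene decoupling, isoform filtering,
# primary-isoform selection, Kozak-model ORF extension, antisense lncRNA
# classification, and gene-ID assignment.

#' Decouple incorrectly merged gene models by shared coding sequence
#'
#' Long-read pipelines group neighbouring genes under one model whenever
#' any isoforms overlap on the same strand; in compact genomes this merges
#' unrelated genes whose UTRs touch.  Isoforms are regrouped as the
#' connected components of the graph with an edge between two same-strand
#' isoforms whose CDS intervals overlap by at least 1 bp; UTR-only overlap
#' creates no edge, and noncoding isoforms (empty CDS) each form their own
#' group.
#'
#' @param tx [transcript_models()] table.
#' @return data.frame of gene groups: \code{gene_id} (new, \code{g1},
#'   \code{g2}, ... in positional order), \code{members} (list column of
#'   transcript ids) and \code{total_reads} (pre-filter read sum).
#' @export
decouple_genes <- function(tx) {
  n <- nrow(tx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  cds_bounds <- lapply(tx$cds, function(m)
    if (nrow(m)) m else matrix(integer(), ncol = 2))
  for (i in seq_len(n)) {
    ci <- cds_bounds[[i]]
    if (!nrow(ci)) next
    for (j in seq_len(n)) {
      if (j <= i) next
      if (tx$chrom[j] != tx$chrom[i] || tx$strand[j] != tx$strand[i]) next
      cj <- cds_bounds[[j]]
      if (!nrow(cj)) next
      hit <- FALSE
      for (a in seq_len(nrow(ci))) {
        ov <- pmin(ci[a, 2], cj[, 2]) - pmax(ci[a, 1], cj[, 1])
        if (any(ov > 0)) { hit <- TRUE; break }
      }
      if (hit) unite(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(seq_len(n), roots)
  ord <- order(vapply(comp, function(ii)
    min(vapply(tx$exons[ii], function(m) min(m[, 1]), 0L)), 0L))
  comp <- comp[ord]
  res <- data.frame(gene_id = sprintf("g%d", seq_along(comp)),
                    stringsAsFactors = FALSE)
  res$members <- lapply(comp, function(ii) tx$id[ii])
  res$total_reads <- vapply(comp, function(ii) sum(tx$read_count[ii]), 0L)
  res
}

#' Filter isoforms on read support
#'
#' Within one gene, an isoform is retained when it is supported by at
#' least \code{min_reads} reads \emph{and} by at least \code{min_frac} of
#' the gene's total reads; fractions are computed on the pre-filter total
#' in a single pass.  This suppresses spurious isoforms derived from
#' 5'-truncated reads.  If every isoform fails, the single most abundant
#' one is retained (ties by id) so a gene is never emptied.
#'
#' @param read_counts named integer vector of per-isoform read counts
#'   (names are isoform ids).
#' @param min_reads minimum absolute support, default 5.
#' @param min_frac minimum fraction of the gene total, default 0.05.
#' @return names of the retained isoforms.
#' @export
filter_isoforms <- function(read_counts, min_reads = 5L, min_frac = 0.05) {
  total <- sum(read_counts)
  if (total == 0) stop("gene has zero total reads")
  keep <- read_counts >= min_reads & read_counts / total >= min_frac
  if (!any(keep)) {
    best <- names(read_counts)[order(-read_counts, names(read_counts))][1]
    return(best)
  }
  names(read_counts)[keep]
}

#' Select the primary isoform of a gene
#'
#' The longest-CDS isoform is primary when it is also the most abundant.
#' Otherwise, it stays primary if its read support is at least 50\% of the
#' most abundant isoform's; failing that, the most abundant isoform is
#' selected if its coding length is at least 80\% of the longest coding
#' length; in all other cases the longest-CDS isoform wins (short isoforms
#' are over-represented in 5'-truncated long-read data).  Ties on CDS
#' length are broken by read count, then total exon (UTR-inclusive)
#' length, then lexicographic id, making the choice order-invariant.
#'
#' @param ids isoform ids.
#' @param cds_len integer coding lengths (bp).
#' @param read_counts integer read support.
#' @param exon_len optional total exonic lengths (tie-break); defaults to
#'   \code{cds_len}.
#' @return the primary isoform id.
#' @export
select_primary <- function(ids, cds_len, read_counts, exon_len = cds_len) {
  stopifnot(length(ids) >= 1)
  ord <- order(-cds_len, -read_counts, -exon_len, ids)
  longest <- ord[1]
  most <- order(-read_counts, -cds_len, -exon_len, ids)[1]
  if (longest == most) return(ids[longest])
  if (read_counts[longest] >= 0.5 * read_counts[most]) return(ids[longest])
  if (cds_len[most] >= 0.8 * cds_len[longest]) return(ids[most])
  ids[longest]
}

#' Build a Kozak position-frequency model of start-codon context
#'
#' A log-odds model of the sequence context around translation initiation
#' sites, trained on transcripts whose annotated ORF cannot be extended
#' (no in-frame upstream ATG reachable without an intervening in-frame
#' stop), on the assumption that those annotations mark true starts.  The
#' context window covers offsets -10..-1 and +4..+6 relative to the A of
#' the ATG at +1.  Per-position frequencies use a pseudocount of 1
#' (\code{(count+1)/(N+4)}); the background is the overall nucleotide
#' composition of all training windows; a context scores
#' \code{sum(log2(freq/background))} over its in-bounds positions.  The
#' 25th percentile of the training scores is stored as the extension
#' threshold.
#'
#' @param tx_seq character vector of spliced transcript sequences (5'->3').
#' @param cds_start 1-based position of the A of the annotated ATG within
#'   each transcript.
#' @param offsets context offsets relative to the start codon, default
#'   \code{c(-10:-1, 4:6)}.
#' @return object of class \code{kozak_model}: \code{pfm} (4 x positions),
#'   \code{background}, \code{offsets}, \code{training_scores}, \code{q25},
#'   \code{n_train}.
#' @export
build_kozak_model <- function(tx_seq, cds_start,
                              offsets = c(-10:-1, 4:6)) {
  stopifnot(length(tx_seq) == length(cds_start))
  trainable <- vapply(seq_along(tx_seq), function(i)
    length(.upstream_atgs(tx_seq[i], cds_start[i])) == 0, TRUE)
  has_atg <- substring(tx_seq, cds_start, cds_start + 2L) == "ATG"
  train <- which(trainable & has_atg)
  if (length(train) < 20)
    warning(sprintf("only %d training transcripts (>= 20 recommended)",
                    length(train)))
  if (length(train) == 0) stop("no trainable transcripts")
  bases <- c("A", "C", "G", "T")
  ctx <- t(vapply(train, function(i)
    .context_chars(tx_seq[i], cds_start[i], offsets),
    character(length(offsets))))
  counts <- apply(ctx, 2, function(col)
    vapply(bases, function(b) sum(col == b, na.rm = TRUE), 0L))
  n_at <- colSums(counts)
  pfm <- sweep(counts + 1, 2, n_at + 4, "/")
  dimnames(pfm) <- list(bases, as.character(offsets))
  all_chars <- ctx[!is.na(ctx)]
  background <- vapply(bases, function(b) sum(all_chars == b), 0)
  background <- (background + 1) / (sum(background) + 4)
  model <- structure(list(pfm = pfm, background = background,
                          offsets = offsets, n_train = length(train)),
                     class = "kozak_model")
  model$training_scores <- vapply(train, function(i)
    kozak_score(model, tx_seq[i], cds_start[i]), 0)
  model$q25 <- quantile(model$training_scores, 0.25, names = FALSE)
  model
}

#' @export
print.kozak_model <- function(x, ...) {
  cat(sprintf(
    "<kozak_model> %d training starts; offsets %s; q25 score %.3f\n",
    x$n_train, paste(range(x$offsets), collapse = ".."), x$q25))
  invisible(x)
}

# context characters at the model offsets; NA where the window runs off
# the transcript 5' end (those positions are skipped in the score)
.context_chars <- function(seq, atg_pos, offsets) {
  # the A of the ATG sits at offset +1, so transcript position is
  # atg_pos + offset - 1 for positive offsets and atg_pos + offset for
  # negative ones (offset -1 = base immediately 5' of the ATG)
  pos <- ifelse(offsets > 0, atg_pos + offsets - 1L, atg_pos + offsets)
  ch <- substring(seq, pos, pos)
  ch[pos < 1L | ch == ""] <- NA_character_
  ch
}

#' Score a start-codon context under a Kozak model
#'
#' @param model \code{kozak_model}.
#' @param seq spliced transcript sequence.
#' @param atg_pos 1-based position of the candidate ATG's A.
#' @return log2 odds score (positions outside the transcript are skipped).
#' @export
kozak_score <- function(model, seq, atg_pos) {
  ch <- .context_chars(seq, atg_pos, model$offsets)
  ok <- !is.na(ch) & ch %in% rownames(model$pfm)
  if (!any(ok)) return(0)
  sum(log2(model$pfm[cbind(ch[ok], as.character(model$offsets)[ok])] /
             model$background[ch[ok]]))
}

# in-frame upstream ATG positions reachable without an intervening
# in-frame stop codon, 5'-most first
.upstream_atgs <- function(seq, cds_start) {
  if (cds_start < 4L) return(integer())
  cand <- rev(seq.int(cds_start - 3L, 1L, by = -3L))
  codons <- substring(seq, cand, cand + 2L)
  stops <- cand[codons %in% c("TAA", "TAG", "TGA")]
  barrier <- if (length(stops)) max(stops) else -Inf
  cand[codons == "ATG" & cand > barrier]
}

#' Extend an annotated ORF to an upstream start codon
#'
#' Considers in-frame upstream ATGs with no intervening in-frame stop.  A
#' candidate qualifies when its Kozak score exceeds the model's training
#' 25th percentile (\code{above_q25}) or simply exceeds the annotated
#' start's score (\code{above_annotated}).  Among qualifying candidates
#' the 5'-most is chosen (maximal extension).  The operation is
#' idempotent: rerunning it on the extended transcript changes nothing.
#'
#' @param seq spliced transcript sequence.
#' @param cds_start 1-based position of the annotated ATG.
#' @param model \code{kozak_model} from [build_kozak_model()].
#' @return list of class \code{extension_decision}: \code{old_start},
#'   \code{new_start} (equal when no rule fires), \code{rule_fired} in
#'   \{above_q25, above_annotated, none\}, and the scores involved.
#' @export
extend_orf <- function(seq, cds_start, model) {
  if (substring(seq, cds_start, cds_start + 2L) != "ATG") {
    warning("no ATG at annotated start; transcript skipped")
    return(structure(list(old_start = cds_start, new_start = cds_start,
                          rule_fired = "none", annotated_score = NA_real_,
                          new_score = NA_real_, flagged = TRUE),
                     class = "extension_decision"))
  }
  ann_score <- kozak_score(model, seq, cds_start)
  cand <- .upstream_atgs(seq, cds_start)
  scores <- vapply(cand, function(p) kozak_score(model, seq, p), 0)
  qual <- scores > model$q25 | scores > ann_score
  if (!any(qual))
    return(structure(list(old_start = cds_start, new_start = cds_start,
                          rule_fired = "none", annotated_score = ann_score,
                          new_score = NA_real_, flagged = FALSE),
                     class = "extension_decision"))
  pick <- which(qual)[1]  # candidates are 5'-most first
  rule <- if (scores[pick] > model$q25) "above_q25" else "above_annotated"
  structure(list(old_start = cds_start, new_start = cand[pick],
                 rule_fired = rule, annotated_score = ann_score,
                 new_score = scores[pick], flagged = FALSE),
            class = "extension_decision")
}

#' Associate antisense lncRNAs with protein-coding genes
#'
#' A lncRNA is associated with a coding gene when their genomic spans
#' overlap on opposite strands by at least \code{min_overlap_frac} of the
#' coding gene's span.  An association is subclassed \code{bidirectional}
#' when the lncRNA TSS lies inside the coding gene body and a sense-strand
#' isoform TSS (typically of a truncated isoform fired from the same
#' internal promoter) lies within \code{bidir_window} bp of it; otherwise
#' \code{unidirectional}.
#'
#' @param coding_genes data.frame: gene_id, chrom, strand, start, end
#'   (0-based half-open genomic spans).
#' @param lnc data.frame: id, chrom, strand, start, end, tss (1-based).
#' @param sense_tss optional data.frame (gene_id, tss) of sense-strand
#'   isoform TSSs used for the bidirectional test.
#' @param min_overlap_frac minimum overlap fraction of the coding gene
#'   span, default 0.30.
#' @param bidir_window TSS co-location window in bp, default 500.
#' @return data.frame: gene_id, lnc_id, overlap_bp, overlap_frac, subclass.
#' @export
classify_antisense <- function(coding_genes, lnc, sense_tss = NULL,
                               min_overlap_frac = 0.30, bidir_window = 500L) {
  out <- list()
  for (i in seq_len(nrow(coding_genes))) {
    g <- coding_genes[i, ]
    opp <- lnc[lnc$chrom == g$chrom & lnc$strand != g$strand, , drop = FALSE]
    if (!nrow(opp)) next
    ov <- pmin(g$end, opp$end) - pmax(g$start, opp$start)
    frac <- ov / (g$end - g$start)
    sel <- which(frac >= min_overlap_frac)
    for (j in sel) {
      tss_inside <- opp$tss[j] > g$start & opp$tss[j] <= g$end
      bidir <- FALSE
      if (tss_inside && !is.null(sense_tss)) {
        st <- sense_tss$tss[sense_tss$gene_id == g$gene_id]
        bidir <- length(st) > 0 && any(abs(st - opp$tss[j]) <= bidir_window)
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, lnc_id = opp$id[j], overlap_bp = ov[j],
        overlap_frac = frac[j],
        subclass = if (bidir) "bidirectional" else "unidirectional",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), lnc_id = character(),
               overlap_bp = integer(), overlap_frac = numeric(),
               subclass = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign stable gene identifiers across haplotypes and organelles
#'
#' Haplotype-A genes are numbered along the chromosomes starting at 00005
#' in increments of 5.  Haplotype-B genes that form an allelic pair with
#' an A gene inherit its number regardless of their own order; unpaired B
#' genes continue from the last A number in increments of 5.  Plastome
#' genes are numbered from 80000 and mitogenome genes from 90000.  The
#' printed id is \code{<chrom>.<number>} with zero-padded 5-digit numbers;
#' isoforms are distinguished downstream by a suffix (\code{.1} for the
#' primary isoform).
#'
#' @param genes_a,genes_b data.frames (gene_id, chrom, start) of nuclear
#'   genes on haplotypes A and B; each is ordered by chrom then start
#'   internally.
#' @param allelic_pairs data.frame (a, b) of allelic gene_id pairs; a
#'   partial one-to-one mapping (duplicates are an error).
#' @param organelle optional data.frame (gene_id, chrom, start,
#'   compartment in \{"plastid", "mito"\}).
#' @return data.frame: gene_id, chrom, number, new_id; injective over all
#'   input genes.
#' @export
assign_gene_ids <- function(genes_a, genes_b,
                            allelic_pairs = data.frame(a = character(),
                                                       b = character()),
                            organelle = NULL) {
  if (anyDuplicated(allelic_pairs$a) || anyDuplicated(allelic_pairs$b))
    stop("duplicate gene in allelic pairing")
  a <- genes_a[order(genes_a$chrom, genes_a$start), , drop = FALSE]
  num_a <- seq_len(nrow(a)) * 5L
  res <- data.frame(gene_id = a$gene_id, chrom = a$chrom, number = num_a,
                    stringsAsFactors = FALSE)
  b <- genes_b[order(genes_b$chrom, genes_b$start), , drop = FALSE]
  pair_num <- res$number[match(allelic_pairs$a, res$gene_id)]
  names(pair_num) <- allelic_pairs$b
  num_b <- integer(nrow(b))
  paired <- b$gene_id %in% names(pair_num)
  num_b[paired] <- pair_num[b$gene_id[paired]]
  next_num <- if (nrow(a)) max(num_a) else 0L
  for (i in which(!paired)) {
    next_num <- next_num + 5L
    num_b[i] <- next_num
  }
  res <- rbind(res, data.frame(gene_id = b$gene_id, chrom = b$chrom,
                               number = num_b, stringsAsFactors = FALSE))
  if (!is.null(organelle) && nrow(organelle)) {
    org <- organelle[order(organelle$compartment, organelle$start), ,
                     drop = FALSE]
    for (comp in unique(org$compartment)) {
      oo <- org[org$compartment == comp, , drop = FALSE]
      base <- if (comp == "plastid") 80000L else 90000L
      res <- rbind(res, data.frame(
        gene_id = oo$gene_id, chrom = oo$chrom,
        number = base + (seq_len(nrow(oo)) - 1L) * 5L,
        stringsAsFactors = FALSE))
    }
  }
  res$new_id <- sprintf("%s.%05d", res$chrom, res$number)
  if (anyDuplicated(res$gene_id))
    stop("a gene_id appears in more than one input set")
  rownames(res) <- NULL
  res
}
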