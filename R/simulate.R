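# Synthetic allodiploid hybrid genome with fully planted ground truth.
#
# The simulator emulates a clonally propagating two-parent hybrid diploid:
# one haplotype set from each parental species, between-parent divergence
# around 2.7% and within-parent diversity around 0.6% (parent 1) and 1.35%
# (parent 2), with planted LOH tracts of all three classes, reciprocal and
# nonreciprocal parentage switches, whole- and partial-chromosome copy
# gains in read depth, periodic methylation downstream of TSSs, and
# multi-isoform genes with read counts.  Variants are emitted against
# haplotype A as the reference.

.default_chrom_lengths <- function() {
  setNames(as.integer(1000 * c(250, 230, 220, 210, 200, 200, 190, 180,
                               170, 150, 120, 80)),
           sprintf("chr%02d", 1:12))
}

.default_loh_plan <- function(chrom_lengths) {
  L <- chrom_lengths
  whole <- data.frame(chrom = c("chr04", "chr09", "chr10"),
                      start = 0L,
                      end = as.integer(L[c("chr04", "chr09", "chr10")]),
                      source_haplotype = c("A", "A", "B"),
                      stringsAsFactors = FALSE)
  terminal <- data.frame(
    chrom = c("chr01", "chr02", "chr07", "chr08", "chr11"),
    start = c(210000L, 0L, 150000L, 0L, 90000L),
    end = c(250000L, 30000L, 190000L, 30000L, 120000L),
    source_haplotype = c("B", "A", "A", "B", "A"),
    stringsAsFactors = FALSE)
  ichroms <- list(chr01 = 4L, chr02 = 5L, chr03 = 5L, chr05 = 4L,
                  chr07 = 4L, chr08 = 4L, chr12 = 2L)
  istart <- list(chr01 = 50000L, chr02 = 60000L, chr03 = 50000L,
                 chr05 = 40000L, chr07 = 40000L, chr08 = 50000L,
                 chr12 = 20000L)
  lens <- c(1500L, 2500L, 4000L, 6000L, 12000L, 20000L)
  k <- 0L
  inter <- do.call(rbind, lapply(names(ichroms), function(cn) {
    n <- ichroms[[cn]]
    s <- istart[[cn]] + (seq_len(n) - 1L) * 25000L
    ln <- lens[(k + seq_len(n) - 1L) %% length(lens) + 1L]
    k <<- k + n
    ln <- pmin(ln, if (cn == "chr12") 2500L else ln)
    data.frame(chrom = cn, start = s, end = s + ln,
               source_haplotype = rep(c("A", "B"), length.out = n),
               stringsAsFactors = FALSE)
  }))
  rbind(whole, terminal, inter)
}

.default_crossover_plan <- function() {
  data.frame(chrom = c("chr06", "chr06"), pos = c(80000L, 140000L),
             reciprocal = TRUE, haplotype = NA_character_, copy = FALSE,
             stringsAsFactors = FALSE)
}

.default_masked_gaps <- function(chrom_lengths) {
  pos <- c(chr01 = 170000L, chr02 = 190000L, chr03 = 185000L,
           chr04 = 100000L, chr05 = 20000L, chr06 = 30000L,
           chr07 = 20000L, chr08 = 160000L, chr09 = 80000L,
           chr10 = 70000L, chr11 = 40000L, chr12 = 60000L)
  data.frame(chrom = names(pos), start = as.integer(pos),
             end = as.integer(pos) + 4000L, stringsAsFactors = FALSE)
}

.default_ploidy_plan <- function(chrom_lengths) {
  data.frame(chrom = c("chr03", "chr05"),
             start = c(0L, 100000L),
             end = c(as.integer(chrom_lengths[["chr03"]]), 200000L),
             copies = c(2L, 2L), stringsAsFactors = FALSE)
}

#' Configure the synthetic allodiploid hybrid genome
#'
#' Defaults describe a desk-scale hybrid: 12 chromosomes totalling 2.2 Mb
#' (one tenth of a 22-Mb haploid genome), within-parent heterozygosity
#' 0.6\% (P1) and 1.35\% (P2), between-parent divergence 2.7\%, 36 planted
#' LOH tracts (3 whole-chromosome, 5 terminal, 28 interstitial), one
#' reciprocal crossover pair, one whole-chromosome and one terminal
#' partial copy gain, cosine methylation of period 200 bp downstream of
#' every TSS, and 6 genes per chromosome (every third gene with 3
#' isoforms).  Each randomised component draws from its own seed stream so
#' e.g. changing the methylation seed leaves variant emissions untouched.
#'
#' @param n_chroms,chrom_lengths chromosome count and named lengths (bp).
#' @param het_within_p1,het_within_p2 per-site heterozygosity of the two
#'   parental species.
#' @param div_between per-site between-parent divergence.
#' @param loh_plan data.frame (chrom, start, end, source_haplotype): LOH
#'   copy tracts; the named source haplotype's sequence replaces its
#'   homolog over the tract, so the tract contains no heterozygous site.
#' @param crossover_plan data.frame (chrom, pos, reciprocal, haplotype,
#'   copy): parentage switches downstream of pos; reciprocal switches swap
#'   both haplotypes' labels, nonreciprocal ones only \code{haplotype}'s,
#'   with \code{copy = TRUE} additionally copying the homolog (terminal
#'   LOH).
#' @param ploidy_plan data.frame (chrom, start, end, copies) of copy-gain
#'   segments (per-reference-copy semantics, i.e. phased mode).
#' @param masked_gaps data.frame (chrom, start, end) of unalignable gaps
#'   excluded from the alignable blocks (and from variant emission).
#' @param depth_per_copy mean sequencing depth per chromosome copy.
#' @param depth_dispersion negative-binomial overdispersion of per-bin
#'   depth (variance = mu + dispersion * mu^2); 0 gives noise-free depth.
#' @param coverage_step emitted coverage bin width (bp).
#' @param methyl_period,methyl_amp,methyl_baseline cosine methylation
#'   profile downstream of each TSS: baseline + amp * cos(2*pi*x/period).
#' @param methyl_spacing spacing of emitted methylation sites (bp).
#' @param mean_methyl_cov mean valid coverage of methylation sites.
#' @param genes_per_chrom genes placed per chromosome.
#' @param cds_codons CDS length of simulated genes, in codons (incl. stop).
#' @param isoform_plan list: \code{multi_every} (every k-th gene gets
#'   multiple isoforms), \code{read_counts}, \code{cds_fracs}.
#' @param gc_background,gc_centromere genome and planted-centromere GC.
#' @param switch_min_bp minimum segment span for a planted label change to
#'   count as a ground-truth parentage switch (window-scale resolution).
#' @param stochastic logical; FALSE places variants at regular 1/p spacing
#'   and removes all sampling noise (noise-free emissions).
#' @param seed integer master seed; component streams derive from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 12L,
                       chrom_lengths = .default_chrom_lengths(),
                       het_within_p1 = 0.006, het_within_p2 = 0.0135,
                       div_between = 0.027,
                       loh_plan = .default_loh_plan(chrom_lengths),
                       crossover_plan = .default_crossover_plan(),
                       ploidy_plan = .default_ploidy_plan(chrom_lengths),
                       masked_gaps = .default_masked_gaps(chrom_lengths),
                       depth_per_copy = 50, depth_dispersion = 0.02,
                       coverage_step = 1000L,
                       methyl_period = 200L, methyl_amp = 0.45,
                       methyl_baseline = 0.5, methyl_spacing = 10L,
                       mean_methyl_cov = 30,
                       genes_per_chrom = 6L, cds_codons = 400L,
                       isoform_plan = list(multi_every = 3L,
                                           read_counts = c(60L, 25L, 3L),
                                           cds_fracs = c(1, 0.6, 0.4)),
                       gc_background = 0.64, gc_centromere = 0.48,
                       switch_min_bp = 30000L,
                       stochastic = TRUE, seed = 1L) {
  probs <- c(het_within_p1, het_within_p2, div_between)
  if (any(probs <= 0 | probs >= 1))
    stop("rate parameters must lie in (0, 1)")
  if (length(chrom_lengths) != n_chroms)
    stop("chrom_lengths must have n_chroms entries")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  for (plan in list(loh_plan, ploidy_plan, masked_gaps)) {
    if (nrow(plan)) {
      bad <- !(plan$chrom %in% names(chrom_lengths)) |
        plan$start < 0 | plan$end > chrom_lengths[plan$chrom] |
        plan$start >= plan$end
      if (any(bad)) stop("planned interval outside its chromosome")
    }
  }
  if (nrow(loh_plan) &&
      !all(loh_plan$source_haplotype %in% c("A", "B")))
    stop("loh_plan source_haplotype must be 'A' or 'B'")
  if (any(ploidy_plan$copies < 1)) stop("copy numbers must be >= 1")
  if (nrow(crossover_plan)) {
    if (any(!crossover_plan$reciprocal & is.na(crossover_plan$haplotype)))
      stop("nonreciprocal crossovers need a haplotype")
    # a crossover breakpoint falling inside an LOH tract contradicts the
    # copy semantics of the tract
    for (i in seq_len(nrow(crossover_plan))) {
      x <- crossover_plan[i, ]
      inside <- loh_plan$chrom == x$chrom & loh_plan$start < x$pos &
        x$pos < loh_plan$end
      if (any(inside))
        stop(sprintf("crossover at %s:%d lies inside a planned LOH tract",
                     x$chrom, x$pos))
    }
  }
  cfg <- list(n_chroms = n_chroms, chrom_lengths = chrom_lengths,
              het_within = c(P1 = het_within_p1, P2 = het_within_p2),
              div_between = div_between, loh_plan = loh_plan,
              crossover_plan = crossover_plan, ploidy_plan = ploidy_plan,
              masked_gaps = masked_gaps, depth_per_copy = depth_per_copy,
              depth_dispersion = depth_dispersion,
              coverage_step = coverage_step,
              methyl_period = methyl_period, methyl_amp = methyl_amp,
              methyl_baseline = methyl_baseline,
              methyl_spacing = methyl_spacing,
              mean_methyl_cov = mean_methyl_cov,
              genes_per_chrom = genes_per_chrom, cds_codons = cds_codons,
              isoform_plan = isoform_plan,
              gc_background = gc_background,
              gc_centromere = gc_centromere,
              switch_min_bp = switch_min_bp,
              stochastic = stochastic, seed = as.integer(seed))
  cfg$stream_seeds <- list(genome = cfg$seed + 11L,
                           variants = cfg$seed + 22L,
                           coverage = cfg$seed + 33L,
                           methyl = cfg$seed + 44L,
                           isoforms = cfg$seed + 55L)
  class(cfg) <- "sim_config"
  cfg
}

# ---- internal: parentage/LOH region arithmetic -------------------------

# effective LOH tracts: planned tracts plus terminal copies implied by
# nonreciprocal crossovers with copy = TRUE
.effective_loh <- function(config) {
  loh <- config$loh_plan
  xo <- config$crossover_plan
  extra <- xo[!xo$reciprocal & xo$copy, , drop = FALSE]
  if (nrow(extra)) {
    loh <- rbind(loh, data.frame(
      chrom = extra$chrom, pos = NULL, start = extra$pos,
      end = as.integer(config$chrom_lengths[extra$chrom]),
      source_haplotype = ifelse(extra$haplotype == "A", "B", "A"),
      stringsAsFactors = FALSE)[, c("chrom", "start", "end",
                                    "source_haplotype")])
  }
  loh
}

# elementary regions of one chromosome with per-haplotype parent labels
# and the copy (LOH) indicator
.chrom_regions <- function(config, cn) {
  L <- as.integer(config$chrom_lengths[[cn]])
  loh <- .effective_loh(config)
  loh <- loh[loh$chrom == cn, , drop = FALSE]
  xo <- config$crossover_plan
  xo <- xo[xo$chrom == cn, , drop = FALSE]
  bounds <- sort(unique(c(0L, L, loh$start, loh$end, as.integer(xo$pos))))
  bounds <- bounds[bounds >= 0L & bounds <= L]
  n <- length(bounds) - 1L
  base <- c(A = "P1", B = "P2")
  flip <- function(p) ifelse(p == "P1", "P2", "P1")
  out <- data.frame(chrom = cn, start = bounds[-length(bounds)],
                    end = bounds[-1], label_A = NA_character_,
                    label_B = NA_character_, is_copy = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- out$start[i]
    par_cnt <- function(h) sum(xo$pos <= s &
                                 (xo$reciprocal |
                                    (!is.na(xo$haplotype) &
                                       xo$haplotype == h)))
    lab <- vapply(c("A", "B"), function(h) {
      p <- base[[h]]
      if (par_cnt(h) %% 2 == 1) p <- flip(p)
      p
    }, "")
    hit <- which(loh$start <= s & out$end[i] <= loh$end)
    if (length(hit)) {
      src <- loh$source_haplotype[hit[1]]
      lab[c("A", "B")] <- lab[[src]]
      out$is_copy[i] <- TRUE
    }
    out$label_A[i] <- lab[["A"]]
    out$label_B[i] <- lab[["B"]]
  }
  out
}

# place variant positions (1-based) in [start, end) at per-site rate p
.place_sites <- function(start, end, p, stochastic, phase = 0L) {
  len <- end - start
  if (p <= 0 || len <= 0) return(integer())
  if (stochastic) {
    n <- rbinom(1L, len, p)
    if (n == 0) return(integer())
    sort(sample.int(len, n)) + start
  } else {
    spacing <- max(1L, as.integer(round(1 / p)))
    first <- start + (phase %% spacing) + spacing
    if (first > end) return(integer())
    seq.int(first, end, by = spacing)
  }
}

# ---- main simulation ---------------------------------------------------

#' Simulate an allodiploid hybrid genome with planted truth
#'
#' Generates the full in-memory truth for a two-parent hybrid under a
#' [sim_config()]: the haplotype-A reference sequence (with telomeres, one
#' internal telomere at the planted partial-duplication breakpoint,
#' AT-rich centromere candidates and gene models written into it),
#' heterozygous sites of the hybrid against that reference, four
#' divergence tracks (each haplotype against each parental reference),
#' alignable blocks, parentage segments and ground-truth switches,
#' ground-truth LOH intervals (inner-edge convention: extended to the
#' planted heterozygous sites flanking each tract), copy-number segments
#' with binned coverage, methylation sites, and transcript models with
#' read counts.  Deterministic for a fixed seed.
#'
#' @param config [sim_config()].
#' @return list of class \code{hybrid_truth}.
#' @export
simulate_hybrid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$chrom_lengths
  genome_parts <- .sim_genome(config)
  genome <- genome_parts$genome
  tx <- genome_parts$tx
  whole <- data.frame(chrom = names(cl), start = 0L, end = as.integer(cl),
                      stringsAsFactors = FALSE)
  blk <- if (nrow(config$masked_gaps))
    subtract_intervals(whole, config$masked_gaps) else whole
  blocks <- alignable_blocks(blk$chrom, blk$start, blk$end)
  regions <- do.call(rbind, lapply(names(cl), .chrom_regions,
                                   config = config))

  set.seed(config$stream_seeds$variants)
  hw <- config$het_within
  div <- config$div_between
  het_pos <- list(); div_pos <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    rate_het <- if (r$is_copy) 0 else if (r$label_A != r$label_B) div else
      hw[[r$label_A]]
    p <- .place_sites(r$start, r$end, rate_het, config$stochastic)
    if (length(p))
      het_pos[[length(het_pos) + 1L]] <-
        data.frame(chrom = r$chrom, pos = p, stringsAsFactors = FALSE)
    for (h in c("A", "B")) {
      labh <- r[[paste0("label_", h)]]
      for (par in c("P1", "P2")) {
        rate <- if (labh == par) hw[[par]] else div
        ph <- (match(h, c("A", "B")) - 1L) * 2L + match(par, c("P1", "P2"))
        pp <- .place_sites(r$start, r$end, rate, config$stochastic,
                           phase = ph * 7L)
        if (length(pp))
          div_pos[[length(div_pos) + 1L]] <-
            data.frame(chrom = r$chrom, pos = pp, hap = h, parent = par,
                       stringsAsFactors = FALSE)
      }
    }
  }
  het <- if (length(het_pos)) do.call(rbind, het_pos) else
    data.frame(chrom = character(), pos = integer())
  divs <- if (length(div_pos)) do.call(rbind, div_pos) else
    data.frame(chrom = character(), pos = integer(), hap = character(),
               parent = character())
  # keep only callable positions
  het <- het[positions_in_intervals(het$chrom, het$pos,
                                    as.data.frame(blocks)), , drop = FALSE]
  divs <- divs[positions_in_intervals(divs$chrom, divs$pos,
                                      as.data.frame(blocks)), ,
               drop = FALSE]
  mkvars <- function(d) {
    if (!nrow(d)) return(variant_sites(character(), integer()))
    ref <- .genome_base(genome, d$chrom, d$pos)
    alt <- c(A = "C", C = "G", G = "T", T = "A")[ref]
    variant_sites(d$chrom, d$pos, ref = ref, alt = alt, zygosity = "het",
                  haplotype_hits = 1L)
  }
  variants_het <- mkvars(het)
  div_tracks <- list()
  for (h in c("A", "B")) for (par in c("P1", "P2")) {
    d <- divs[divs$hap == h & divs$parent == par, , drop = FALSE]
    v <- if (nrow(d)) {
      ref <- .genome_base(genome, d$chrom, d$pos)
      alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
      variant_sites(d$chrom, d$pos, ref = ref, alt = alt,
                    zygosity = "hom_alt", haplotype_hits = 2L)
    } else variant_sites(character(), integer())
    div_tracks[[sprintf("hap%s_%s", h, tolower(par))]] <- v
  }

  loh_truth <- .truth_loh(config, variants_het)
  parentage <- .truth_parentage(regions)
  switches <- .truth_switches(parentage, config$switch_min_bp)
  copy_segments <- .truth_copies(config)
  coverage <- .sim_coverage(config, copy_segments)
  tss <- .tx_primary_tss(tx)
  methyl <- .sim_methyl(config, tss, cl)

  structure(list(config = config, genome = genome,
                 chrom_lengths = cl, blocks = blocks,
                 variants_het = variants_het, div_tracks = div_tracks,
                 regions = regions, parentage = parentage,
                 switches = switches, loh_truth = loh_truth,
                 copy_segments = copy_segments, coverage = coverage,
                 methyl = methyl, transcripts = tx, tss = tss,
                 centromeres = genome_parts$centromeres,
                 internal_telomeres = genome_parts$internal_telomeres),
            class = "hybrid_truth")
}

#' @export
print.hybrid_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<hybrid_truth> %d chromosomes, %.2f Mb; %d het sites; %d LOH tracts;",
    " %d switches; %d copy segments; %d transcripts\n"),
    length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
    nrow(x$variants_het), nrow(x$loh_truth), nrow(x$switches),
    nrow(x$copy_segments), nrow(x$transcripts)))
  invisible(x)
}

.genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    s <- as.character(genome[[cn]])
    out[i] <- substring(s, pos[i], pos[i])
  }
  out
}

# ground-truth LOH intervals, inner-edge convention: each effective tract
# extended to the planted het sites flanking it (or the chromosome ends),
# then overlapping intervals merged
.truth_loh <- function(config, variants_het) {
  loh <- .effective_loh(config)
  cl <- config$chrom_lengths
  # whole-chromosome events for chromosomes with no het site at all
  out <- list()
  for (cn in names(cl)) {
    L <- as.integer(cl[[cn]])
    p <- sort(variants_het$pos[variants_het$chrom == cn])
    tr <- loh[loh$chrom == cn, , drop = FALSE]
    if (length(p) == 0) {
      if (nrow(tr))
        out[[cn]] <- data.frame(chrom = cn, start = 0L, end = L,
                                kind = "whole_chromosome")
      next
    }
    if (!nrow(tr)) next
    ext <- lapply(seq_len(nrow(tr)), function(i) {
      s <- tr$start[i]; e <- tr$end[i]
      left <- p[p <= s]
      left <- if (length(left)) max(left) else 0L
      right <- p[p >= e + 1L]
      right <- if (length(right)) min(right) - 1L else L
      c(left, right)
    })
    ext <- do.call(rbind, ext)
    merged <- merge_intervals(data.frame(chrom = cn, start = ext[, 1],
                                         end = ext[, 2]))
    kind <- ifelse(merged$start == 0L & merged$end == L, "whole_chromosome",
                   ifelse(merged$start == 0L | merged$end == L,
                          "terminal", "interstitial"))
    out[[cn]] <- data.frame(chrom = cn, start = merged$start,
                            end = merged$end, kind = kind)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(loh_events(character(), integer(), integer(), character()))
  loh_events(res$chrom, res$start, res$end, res$kind)
}

# per-haplotype parentage segments (merged maximal runs of one label)
.truth_parentage <- function(regions) {
  out <- list()
  for (h in c("A", "B")) {
    col <- paste0("label_", h)
    for (cn in unique(regions$chrom)) {
      d <- regions[regions$chrom == cn, , drop = FALSE]
      r <- rle(d[[col]])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, haplotype = h, start = d$start[starts],
        end = d$end[ends], label = r$values, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ground-truth switches at window-scale resolution: label boundaries whose
# flanking segments both span >= switch_min_bp; boundaries shared by both
# haplotypes with opposite changes are reciprocal
.truth_switches <- function(parentage, switch_min_bp) {
  brk <- list()
  for (h in c("A", "B")) {
    seg <- parentage[parentage$haplotype == h, , drop = FALSE]
    for (cn in unique(seg$chrom)) {
      d <- seg[seg$chrom == cn, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      big <- d$end - d$start >= switch_min_bp
      i <- which(d$label[-1] != d$label[-nrow(d)] & big[-1] & big[-nrow(d)])
      if (length(i))
        brk[[length(brk) + 1L]] <- data.frame(
          chrom = cn, pos = d$end[i], haplotype = h, from = d$label[i],
          to = d$label[i + 1], stringsAsFactors = FALSE)
    }
  }
  brk <- if (length(brk)) do.call(rbind, brk) else
    data.frame(chrom = character(), pos = integer(), haplotype = character(),
               from = character(), to = character())
  if (!nrow(brk)) {
    brk$type <- character()
    return(brk)
  }
  key <- paste(brk$chrom, brk$pos)
  recip <- vapply(seq_len(nrow(brk)), function(i) {
    j <- which(key == key[i] & brk$haplotype != brk$haplotype[i])
    length(j) > 0 && any(brk$from[j] == brk$to[i] &
                           brk$to[j] == brk$from[i])
  }, TRUE)
  brk$type <- ifelse(recip, "reciprocal", "nonreciprocal")
  # collapse the two haplotype rows of a reciprocal switch into one
  dup <- duplicated(paste(key, brk$type)) & brk$type == "reciprocal"
  res <- brk[!dup, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-chromosome copy-number segments (1 copy unless planned otherwise)
.truth_copies <- function(config) {
  cl <- config$chrom_lengths
  whole <- data.frame(chrom = names(cl), start = 0L,
                      end = as.integer(cl), stringsAsFactors = FALSE)
  plan <- config$ploidy_plan
  base <- subtract_intervals(whole, plan)
  base$copies <- 1L
  plan <- plan[, c("chrom", "start", "end", "copies")]
  res <- rbind(base, plan)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.sim_coverage <- function(config, copy_segments) {
  set.seed(config$stream_seeds$coverage)
  step <- config$coverage_step
  out <- lapply(names(config$chrom_lengths), function(cn) {
    L <- as.integer(config$chrom_lengths[[cn]])
    s <- seq.int(0L, L - 1L, by = step)
    e <- pmin(s + step, L)
    seg <- copy_segments[copy_segments$chrom == cn, , drop = FALSE]
    copies <- seg$copies[findInterval((s + e - 1) / 2, seg$start)]
    mu <- config$depth_per_copy * copies
    depth <- if (config$stochastic && config$depth_dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$depth_dispersion)
    else mu
    data.frame(chrom = cn, start = s, end = e, mean_depth = depth,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  coverage_bins(res$chrom, res$start, res$end, res$mean_depth)
}

.sim_methyl <- function(config, tss, chrom_lengths) {
  set.seed(config$stream_seeds$methyl)
  sp <- config$methyl_spacing
  offs <- seq.int(-1000L, 2000L, by = sp)
  out <- lapply(seq_len(nrow(tss)), function(g) {
    L <- as.integer(chrom_lengths[[tss$chrom[g]]])
    sign <- if (tss$strand[g] == "+") 1L else -1L
    pos <- tss$pos[g] + sign * offs
    keep <- pos >= 1L & pos <= L
    off <- offs[keep]; pos <- pos[keep]
    frac <- ifelse(off >= 0,
                   config$methyl_baseline +
                     config$methyl_amp * cos(2 * pi * off /
                                               config$methyl_period),
                   0.02)
    frac <- pmin(pmax(frac, 0), 1)
    cov <- if (config$stochastic) rpois(length(pos),
                                        config$mean_methyl_cov)
    else rep(as.integer(config$mean_methyl_cov), length(pos))
    data.frame(chrom = tss$chrom[g], pos = pos, strand = tss$strand[g],
               valid_cov = cov, frac_mod = frac, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("chrom", "pos", "strand")]), ,
             drop = FALSE]
  methyl_sites(res$chrom, res$pos, res$strand, res$valid_cov, res$frac_mod)
}

# one TSS per gene: the span start of its first (primary-plan) isoform
.tx_primary_tss <- function(tx) {
  span <- .tx_span(tx)
  first <- !duplicated(span$gene_id)
  data.frame(gene_id = span$gene_id[first], chrom = span$chrom[first],
             pos = .tx_tss(tx)[first], strand = span$strand[first],
             stringsAsFactors = FALSE)
}

# ---- genome sequence, genes, isoforms ----------------------------------

.sim_genome <- function(config) {
  set.seed(config$stream_seeds$genome)
  cl <- config$chrom_lengths
  gc <- config$gc_background
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  telo <- strsplit(strrep("TTAGGG", 8L), "")[[1]]
  telo_rc <- strsplit(strrep("CCCTAA", 8L), "")[[1]]
  genome <- list()
  centromeres <- list()
  internal_telomeres <- list()
  tx_acc <- list()
  iso_counter <- 0L
  for (ci in seq_along(cl)) {
    cn <- names(cl)[ci]
    L <- as.integer(cl[[ci]])
    set.seed(config$stream_seeds$genome + ci)
    chars <- sample(bases, L, replace = TRUE, prob = pb)
    chars[seq_along(telo_rc)] <- telo_rc
    chars[(L - length(telo) + 1L):L] <- telo
    # internal telomere at the partial-duplication breakpoint
    pp <- config$ploidy_plan
    part <- pp[pp$chrom == cn & (pp$start > 0 | pp$end < L), , drop = FALSE]
    if (nrow(part)) {
      bpos <- if (part$start[1] > 0) part$start[1] else part$end[1]
      unit <- strsplit(strrep("TTAGGG", 6L), "")[[1]]
      chars[(bpos + 1L):(bpos + length(unit))] <- unit
      internal_telomeres[[length(internal_telomeres) + 1L]] <-
        data.frame(chrom = cn, pos = bpos, stringsAsFactors = FALSE)
    }
    # AT-rich centromere candidate
    cen_s <- as.integer(round(L * 0.55))
    cen_len <- 3000L
    gcc <- config$gc_centromere
    pbc <- c((1 - gcc) / 2, gcc / 2, gcc / 2, (1 - gcc) / 2)
    chars[(cen_s + 1L):(cen_s + cen_len)] <-
      sample(bases, cen_len, replace = TRUE, prob = pbc)
    centromeres[[length(centromeres) + 1L]] <-
      data.frame(chrom = cn, start = cen_s, end = cen_s + cen_len,
                 stringsAsFactors = FALSE)
    # genes
    ng <- config$genes_per_chrom
    rel <- c(0.05, 0.15, 0.25, 0.35, 0.70, 0.80)[seq_len(ng)]
    utr5 <- 200L; utr3 <- 400L
    n_cod <- config$cds_codons
    cds_len <- 3L * n_cod
    glen <- utr5 + cds_len + utr3
    for (gi in seq_len(ng)) {
      gs <- as.integer(round(L * rel[gi]))
      strand <- if (gi %% 2 == 1) "+" else "-"
      sense <- c("ATG", .sample_sense_codons(n_cod - 2L), "TAA")
      tx_seq <- paste0(
        paste(sample(bases, utr5, replace = TRUE, prob = pb),
              collapse = ""),
        paste(sense, collapse = ""),
        paste(sample(bases, utr3, replace = TRUE, prob = pb),
              collapse = ""))
      gseq <- if (strand == "+") tx_seq else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(tx_seq)))
      chars[(gs + 1L):(gs + glen)] <- strsplit(gseq, "")[[1]]
      # CDS interval in genomic coordinates (includes the stop codon)
      if (strand == "+") {
        cds_iv <- c(gs + utr5, gs + utr5 + cds_len)
      } else {
        cds_iv <- c(gs + utr3, gs + utr3 + cds_len)
      }
      gene_id <- sprintf("%s_g%d", cn, gi)
      plan <- config$isoform_plan
      multi <- gi %% plan$multi_every == 0L
      n_iso <- if (multi) length(plan$read_counts) else 1L
      for (k in seq_len(n_iso)) {
        iso_counter <- iso_counter + 1L
        frac <- if (multi) plan$cds_fracs[k] else 1
        drop_cod <- as.integer(round((1 - frac) * n_cod))
        trim <- 3L * drop_cod
        civ <- if (strand == "+") c(cds_iv[1] + trim, cds_iv[2]) else
          c(cds_iv[1], cds_iv[2] - trim)
        rc <- if (multi) plan$read_counts[k] else 30L
        tx_acc[[iso_counter]] <- list(
          id = sprintf("%s.t%d", gene_id, k), gene_id = gene_id,
          chrom = cn, strand = strand,
          exons = matrix(c(gs, gs + glen), ncol = 2),
          cds = matrix(civ, ncol = 2), read_count = rc)
      }
    }
    genome[[cn]] <- paste(chars, collapse = "")
  }
  tx <- transcript_models(
    id = vapply(tx_acc, `[[`, "", "id"),
    gene_id = vapply(tx_acc, `[[`, "", "gene_id"),
    chrom = vapply(tx_acc, `[[`, "", "chrom"),
    strand = vapply(tx_acc, `[[`, "", "strand"),
    exons = lapply(tx_acc, `[[`, "exons"),
    cds = lapply(tx_acc, `[[`, "cds"),
    read_count = vapply(tx_acc, `[[`, 0L, "read_count"))
  list(genome = Biostrings::DNAStringSet(unlist(genome)),
       tx = tx,
       centromeres = do.call(rbind, centromeres),
       internal_telomeres = if (length(internal_telomeres))
         do.call(rbind, internal_telomeres) else
           data.frame(chrom = character(), pos = integer()))
}

# sense (non-stop) codons, uniform
.sample_sense_codons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

#' Plant heterozygous sites on coding sequence at degeneracy-specific rates
#'
#' Draws heterozygous sites over the classified coding positions of a
#' transcript set, with an independent per-site rate for each degeneracy
#' fold class — the pattern expected under stronger constraint at 0-fold
#' sites and near-neutrality at 4-fold sites.
#'
#' @param tx [transcript_models()] table.
#' @param genome named [Biostrings::DNAStringSet].
#' @param rate_by_fold named numeric vector of per-site rates, names among
#'   \code{"0","2","3","4"}.
#' @param seed integer seed.
#' @param stochastic FALSE plants sites deterministically every 1/p
#'   classified positions of the class.
#' @return list: \code{sites} ([variant_sites()]), \code{degeneracy}
#'   (the classification used), \code{rate_by_fold}.
#' @export
simulate_coding_het <- function(tx, genome,
                                rate_by_fold = c(`0` = 0.005, `2` = 0.02,
                                                 `3` = 0.03, `4` = 0.034),
                                seed = 1L, stochastic = TRUE) {
  set.seed(seed)
  deg <- classify_degeneracy(tx, genome)
  deg <- deg[!duplicated(paste(deg$chrom, deg$pos)), , drop = FALSE]
  picks <- list()
  for (f in names(rate_by_fold)) {
    d <- deg[deg$fold == as.integer(f), , drop = FALSE]
    if (!nrow(d)) next
    p <- rate_by_fold[[f]]
    sel <- if (stochastic) runif(nrow(d)) < p else
      (seq_len(nrow(d)) %% max(1L, as.integer(round(1 / p)))) == 0L
    picks[[f]] <- d[sel, , drop = FALSE]
  }
  hit <- do.call(rbind, picks)
  sites <- if (!is.null(hit) && nrow(hit)) {
    ref <- .genome_base(genome, hit$chrom, hit$pos)
    alt <- c(A = "C", C = "G", G = "T", T = "A")[ref]
    variant_sites(hit$chrom, hit$pos, ref = ref, alt = alt,
                  zygosity = "het", haplotype_hits = 1L)
  } else variant_sites(character(), integer())
  list(sites = sites, degeneracy = deg, rate_by_fold = rate_by_fold)
}

#' Write the observable files of a simulated hybrid genome
#'
#' Emits every file a real analysis would start from — reference FASTA,
#' het VCF, four divergence VCFs, alignable-block BED, coverage bedGraph,
#' bedMethyl-like TSV, GFF3 gene models — plus the ground truth as BED/TSV
#' (truth files carry a \code{truth_} prefix).
#'
#' @param truth \code{hybrid_truth} from [simulate_hybrid()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
emit_observables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(fasta = p("genome.fa"), vcf = p("sample.vcf"),
             blocks = p("blocks.bed"), coverage = p("coverage.bedgraph"),
             methyl = p("methyl.tsv"), gff3 = p("genes.gff3"))
  write_genome_fasta(truth$genome, paths["fasta"])
  write_variants_vcf(truth$variants_het, paths["vcf"],
                     chrom_lengths = truth$chrom_lengths)
  write_blocks_bed(truth$blocks, paths["blocks"])
  write_coverage_bedgraph(truth$coverage, paths["coverage"])
  write_methyl_tsv(truth$methyl, paths["methyl"])
  write_transcripts_gff3(truth$transcripts, paths["gff3"])
  for (nm in names(truth$div_tracks)) {
    f <- p(sprintf("div_%s.vcf", nm))
    write_variants_vcf(truth$div_tracks[[nm]], f,
                       chrom_lengths = truth$chrom_lengths)
    paths[paste0("div_", nm)] <- f
  }
  write_loh_bed(truth$loh_truth, p("truth_loh.bed"))
  write.table(truth$parentage, p("truth_parentage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$copy_segments, p("truth_ploidy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$switches, p("truth_switches.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(paths, truth_loh = p("truth_loh.bed"),
             truth_parentage = p("truth_parentage.tsv"),
             truth_ploidy = p("truth_ploidy.tsv"),
             truth_switches = p("truth_switches.tsv"))
  invisible(paths)
}
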