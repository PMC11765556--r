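# Genomic context statistics: TSS-proximity motif density, promoter
# target-gene assignment, and DAP-seq peak statistics (overlap + Fisher,
# top-peak motif containment, peak-intensity contrasts).

# motif matches on every chromosome of a genome: data.frame with 0-based
# half-open intervals (chrom, start, end, strand, score)
.genome_matches <- function(model, genome, threshold) {
  seqs <- if (inherits(genome, "GenomeAnnotation")) genome$sequences
          else genome
  w <- ncol(model$matrix)
  out <- list()
  for (ch in names(seqs)) {
    mm <- match_motif(model, as.character(seqs[[ch]]), threshold)
    if (nrow(mm))
      out[[ch]] <- data.frame(chrom = ch, start = mm$start - 1L,
                              end = mm$start - 1L + w,
                              strand = mm$strand, score = mm$score)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

#' Genome-wide motif matches
#'
#' Scans every chromosome on both strands at the given p-value and returns
#' BED-style matches (0-based half-open).
#'
#' @param model a [pwm_model].
#' @param genome a [GenomeAnnotation] or `DNAStringSet`.
#' @param p motif-match p-value (default 1e-5).
#' @param background base frequencies for the threshold.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `score`.
#' @export
genome_motif_matches <- function(model, genome, p = 1e-5,
                                 background = rep(0.25, 4)) {
  thr <- score_threshold_for_pvalue(model, background, p)
  .genome_matches(model, genome, thr)
}

#' Write motif matches as BED6
#'
#' @param matches data.frame from [genome_motif_matches()].
#' @param path output BED file.
#' @param name feature name (default `"motif"`).
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path, name = "motif") {
  df <- data.frame(matches$chrom, matches$start, matches$end, name,
                   round(matches$score, 3), matches$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Motif-match density around transcription start sites
#'
#' For each model with mean IC above `min_mean_ic`, matches on both strands
#' within `W` bp of each TSS are mapped to strand-oriented offsets (TSS = 0,
#' upstream negative; the offset of a match is the position of its 5'-most
#' base in the gene's orientation) and tallied as matches per gene per bp.
#' Genes truncated by contig ends contribute only their covered offsets:
#' the per-offset gene count is adjusted accordingly.
#'
#' @param genome a [GenomeAnnotation].
#' @param models a [pwm_model] or list of them.
#' @param W window half-width around the TSS (default 1000 bp).
#' @param min_mean_ic mean-IC filter applied before profiling (default 0.3).
#' @param p motif-match p-value (default 1e-5).
#' @param background base frequencies for the threshold.
#' @return named list (one per retained model) of `DensityProfile`
#'   data.frames with columns `offset` (-W..W), `matches`, `genes`,
#'   `density`; empty list (with a warning) when no model passes the
#'   filter.
#' @export
tss_density <- function(genome, models, W = 1000L, min_mean_ic = 0.3,
                        p = 1e-5, background = rep(0.25, 4)) {
  if (inherits(models, "PWMModel")) models <- list(models)
  keep <- vapply(models, function(m) m$mean_ic > min_mean_ic, logical(1))
  if (!any(keep)) {
    warning("no model passes the mean-IC filter")
    return(list())
  }
  models <- models[keep]
  lens <- setNames(Biostrings::width(genome$sequences),
                   names(genome$sequences))
  tss <- genome$tss
  offsets <- -W:W
  out <- list()
  for (m in models) {
    w <- ncol(m$matrix)
    matches <- genome_motif_matches(m, genome, p, background)
    counts <- integer(2L * W + 1L)
    genes <- integer(2L * W + 1L)
    for (g in seq_len(nrow(tss))) {
      ch <- tss$chrom[g]; t0 <- tss$pos[g]; len <- lens[[ch]]
      mm <- matches[matches$chrom == ch, , drop = FALSE]
      if (tss$strand[g] == "+") {
        off <- mm$start - t0
        lo <- max(-W, -t0); hi <- min(W, len - w - t0)
      } else {
        off <- t0 - (mm$end - 1L)
        lo <- max(-W, t0 - len + 1L); hi <- min(W, t0 - w + 1L)
      }
      off <- off[off >= -W & off <= W]
      if (length(off))
        counts <- counts + tabulate(off + W + 1L, nbins = 2L * W + 1L)
      if (lo <= hi)
        genes[(lo + W + 1L):(hi + W + 1L)] <-
          genes[(lo + W + 1L):(hi + W + 1L)] + 1L
    }
    density <- ifelse(genes > 0, counts / genes, NA_real_)
    prof <- data.frame(offset = offsets, matches = counts,
                       genes = genes, density = density)
    class(prof) <- c("DensityProfile", "data.frame")
    attr(prof, "motif") <- m$name
    out[[if (nzchar(m$name)) m$name else m$seed]] <- prof
  }
  out
}

#' Assign motif matches to target genes by promoter windows
#'
#' A match is assigned to every gene whose strand-oriented promoter window
#' `[TSS - upstream, TSS + downstream]` contains the match midpoint; these
#' gene lists are the input for external GO tooling.
#'
#' @param matches data.frame of genomic matches (0-based half-open
#'   `chrom`/`start`/`end`), e.g. from [genome_motif_matches()].
#' @param annotation a [GenomeAnnotation].
#' @param upstream,downstream promoter window extents (bp; defaults
#'   1000/200).
#' @return named integer vector: match count per gene (0 when none).
#' @export
assign_targets <- function(matches, annotation, upstream = 1000L,
                           downstream = 200L) {
  tss <- annotation$tss
  mid <- floor((matches$start + matches$end - 1) / 2)
  counts <- integer(nrow(tss))
  for (g in seq_len(nrow(tss))) {
    t0 <- tss$pos[g]
    win <- if (tss$strand[g] == "+") c(t0 - upstream, t0 + downstream)
           else c(t0 - downstream, t0 + upstream)
    counts[g] <- sum(matches$chrom == tss$chrom[g] &
                     mid >= win[1] & mid <= win[2])
  }
  setNames(counts, tss$gene_id)
}

#' Overlap statistics for a pair of peak sets
#'
#' Peaks overlap when they share at least one base (configurable through
#' `min_frac`, the required overlap as a fraction of the smaller peak).
#' Venn counts are at the peak level: peaks unique to each set, and shared
#' merged intervals covered by both. The Fisher 2x2 table is built by
#' tiling the genome into non-overlapping bins of the pooled median peak
#' width and cross-tabulating bin coverage by the two sets (two-sided
#' test); the construction is recorded in the returned object.
#'
#' @param a,b peak `GRanges` (e.g. from [read_narrowpeak()]) on the same
#'   genome.
#' @param min_frac minimum overlap fraction of the smaller peak
#'   (default 1e-9, i.e. any positive overlap).
#' @return list of class `peak_overlap`: `n_a`, `n_b`, `unique_a`,
#'   `unique_b`, `shared`, `table`, `p_value`, `odds_ratio`, `bin_width`.
#' @export
peak_overlap <- function(a, b, min_frac = 1e-9) {
  sa <- unique(as.character(GenomicRanges::seqnames(a)))
  sb <- unique(as.character(GenomicRanges::seqnames(b)))
  if (length(intersect(sa, sb)) == 0L)
    stop("peak sets share no chromosome: unknown chromosome in one set")
  ga <- GenomicRanges::granges(a); gb <- GenomicRanges::granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  if (min_frac > 0 && length(hits)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]))
    small <- pmin(GenomicRanges::width(ga)[S4Vectors::queryHits(hits)],
                  GenomicRanges::width(gb)[S4Vectors::subjectHits(hits)])
    hits <- hits[ov / small >= min_frac]
  }
  ov_a <- unique(S4Vectors::queryHits(hits))
  ov_b <- unique(S4Vectors::subjectHits(hits))
  merged <- GenomicRanges::reduce(c(ga, gb))
  in_a <- IRanges::overlapsAny(merged, ga)
  in_b <- IRanges::overlapsAny(merged, gb)
  shared <- sum(in_a & in_b)
  bw <- max(1L, floor(median(GenomicRanges::width(c(ga, gb)))))
  chroms <- union(sa, sb)
  tiles <- list()
  for (ch in chroms) {
    len <- max(GenomicRanges::end(ga[GenomicRanges::seqnames(ga) == ch]),
               GenomicRanges::end(gb[GenomicRanges::seqnames(gb) == ch]))
    st <- seq(1L, len, by = bw)
    tiles[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(st, pmin(st + bw - 1L, len)))
  }
  tiles <- do.call(c, unname(tiles))
  cov_a <- IRanges::overlapsAny(tiles, ga)
  cov_b <- IRanges::overlapsAny(tiles, gb)
  tab <- table(a = factor(cov_a, c(TRUE, FALSE)),
               b = factor(cov_b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  structure(list(n_a = length(ga), n_b = length(gb),
                 unique_a = length(ga) - length(ov_a),
                 unique_b = length(gb) - length(ov_b),
                 shared = shared, table = tab,
                 p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 bin_width = bw,
                 method = "Fisher's exact test on genome bins of the pooled median peak width"),
            class = "peak_overlap")
}

#' @export
print.peak_overlap <- function(x, ...) {
  cat(sprintf("peak_overlap: %d vs %d peaks | unique %d / %d, shared %d | Fisher p = %.3g\n",
              x$n_a, x$n_b, x$unique_a, x$unique_b, x$shared, x$p_value))
  invisible(x)
}

# peak sequences as a character vector
.peak_seqs <- function(peaks, genome) {
  seqs <- if (inherits(genome, "GenomeAnnotation")) genome$sequences
          else genome
  chars <- vapply(names(seqs), function(ch) as.character(seqs[[ch]]),
                  character(1))
  substring(chars[as.character(GenomicRanges::seqnames(peaks))],
            GenomicRanges::start(peaks), GenomicRanges::end(peaks))
}

#' Motif containment of the strongest peaks
#'
#' Takes the `top_n` peaks by rank (descending signalValue, ties by
#' chromosome then start) and reports the proportion containing at least
#' one motif match at the given threshold (both strands), together with
#' per-bin proportions over rank-contiguous bins — the replicate structure
#' used to compare containment between libraries with a t-test.
#'
#' @param peaks peak `GRanges` with `signalValue`.
#' @param genome a [GenomeAnnotation] or `DNAStringSet`.
#' @param model a [pwm_model].
#' @param top_n number of top peaks (default 3000; all peaks, with a
#'   warning, when fewer).
#' @param bins number of rank-contiguous bins (default 10).
#' @param p motif-match p-value (default 1e-5).
#' @param threshold optional explicit threshold overriding `p`.
#' @return list with `proportion`, `bin_proportions`, `n_used`, `contains`.
#' @export
top_peaks_motif_proportion <- function(peaks, genome, model, top_n = 3000L,
                                       bins = 10L, p = 1e-5,
                                       threshold = NULL) {
  ord <- peak_rank_order(peaks)
  if (length(ord) < top_n) {
    warning("fewer than top_n peaks; using all ", length(ord))
    top_n <- length(ord)
  }
  top <- peaks[ord[seq_len(top_n)]]
  if (is.null(threshold))
    threshold <- score_threshold_for_pvalue(model, rep(0.25, 4), p)
  contains <- count_motif_hits(model, .peak_seqs(top, genome), threshold) > 0L
  bin_id <- ceiling(seq_len(top_n) / (top_n / bins))
  list(proportion = mean(contains),
       bin_proportions = as.numeric(tapply(contains, bin_id, mean)),
       n_used = top_n, contains = contains)
}

#' Compare intensities of peaks containing one of two motifs
#'
#' Partitions peaks into those containing only motif A and only motif B
#' (peaks containing both or neither are excluded) and compares the group
#' intensities with a two-sided Welch t-test; the significance marker is
#' `"*"` at p <= 0.05, `"ns"` otherwise, and `"undefined"` when the test
#' cannot be computed (an empty group, or degenerate singleton groups).
#'
#' @param peaks peak `GRanges` with `signalValue`.
#' @param genome a [GenomeAnnotation] or `DNAStringSet`.
#' @param model_a,model_b [pwm_model]s of the two motifs.
#' @param p motif-match p-value (default 1e-5).
#' @return list with `intensity_a`, `intensity_b`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `statistic`, `p_value`, `significance`.
#' @export
peak_intensity_by_motif <- function(peaks, genome, model_a, model_b,
                                    p = 1e-5) {
  seqs <- .peak_seqs(peaks, genome)
  thr_a <- score_threshold_for_pvalue(model_a, rep(0.25, 4), p)
  thr_b <- score_threshold_for_pvalue(model_b, rep(0.25, 4), p)
  has_a <- count_motif_hits(model_a, seqs, thr_a) > 0L
  has_b <- count_motif_hits(model_b, seqs, thr_b) > 0L
  ia <- peaks$signalValue[has_a & !has_b]
  ib <- peaks$signalValue[has_b & !has_a]
  tt <- tryCatch(t.test(ia, ib), error = function(e) NULL)
  list(intensity_a = ia, intensity_b = ib,
       mean_a = if (length(ia)) mean(ia) else NA_real_,
       mean_b = if (length(ib)) mean(ib) else NA_real_,
       n_a = length(ia), n_b = length(ib),
       statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       significance = if (is.null(tt)) "undefined"
                      else if (tt$p.value <= 0.05) "*" else "ns")
}
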