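# Seed-based PWM construction (multinomial counting), information content,
# exact DP p-value thresholds on a discretised score lattice, motif matching
# on both strands, shuffled backgrounds, enrichment, and the methyl-vs-normal
# positional comparison.

#' Position weight matrix model
#'
#' @param matrix 4 x w base-probability matrix, rows A, C, G, T; every
#'   column must sum to 1 (within 1e-9).
#' @param seed IUPAC seed that generated the model (may be empty).
#' @param name motif name (e.g. `"M1"` or a dimer name such as `"ER0"`).
#' @param methylated flag of the library of origin.
#' @param nsites number of contributing windows (for MEME output).
#' @param enrichment optional enrichment ratio (see [motif_enrichment()]).
#' @return an object of class `PWMModel` with per-column information
#'   content `ic` (bits) and `mean_ic`.
#' @export
pwm_model <- function(matrix, seed = "", name = "", methylated = FALSE,
                      nsites = NA_real_, enrichment = NA_real_) {
  if (nrow(matrix) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(matrix < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("every PWM column must sum to 1")
  rownames(matrix) <- .BASES
  ic <- information_content(matrix)
  structure(list(matrix = matrix, seed = seed, name = name,
                 ic = ic$ic, mean_ic = ic$mean_ic,
                 methylated = isTRUE(methylated),
                 nsites = nsites, enrichment = enrichment),
            class = "PWMModel")
}

#' @export
print.PWMModel <- function(x, ...) {
  cat(sprintf("PWMModel '%s' (seed %s): width %d, mean IC %.3f bits%s%s\n",
              x$name, if (nzchar(x$seed)) x$seed else "-", ncol(x$matrix),
              x$mean_ic,
              if (is.finite(x$enrichment))
                sprintf(", enrichment %.2f", x$enrichment) else "",
              if (x$methylated) " [methylated library]" else ""))
  invisible(x)
}

#' Information content of a PWM
#'
#' Per-column IC against a uniform background:
#' `IC[c] = 2 + sum_b p log2 p` (bits), 0 for a uniform column, 2 for a
#' deterministic one.
#'
#' @param model a [pwm_model] or a 4 x w probability matrix.
#' @return list with `ic` (per column) and `mean_ic`.
#' @export
information_content <- function(model) {
  M <- if (inherits(model, "PWMModel")) model$matrix else model
  plogp <- ifelse(M > 0, M * log2(M), 0)
  ic <- 2 + colSums(plogp)
  list(ic = unname(ic), mean_ic = mean(ic))
}

# both-strand multinomial seed counts of a read set
.seed_counts <- function(codes, seed, level = 2L) {
  w <- nchar(seed)
  fw <- cpp_seed_counts(codes, iupac_allowed(seed), level)
  rv <- cpp_seed_counts(codes, iupac_allowed(revcomp(seed)), level)
  counts <- fw$counts + rv$counts[4:1, w:1, drop = FALSE]
  list(counts = counts, n = fw$n + rv$n, n_exact = fw$n_exact + rv$n_exact)
}

#' Build a PWM from an IUPAC seed by multinomial counting
#'
#' For each column c, base frequencies are counted over all windows (both
#' strands; reverse-strand windows contribute complemented bases at mirrored
#' columns) that match the seed at every position except c with at most
#' `multinomial_level - 1` further mismatches — the multinomial counting
#' hierarchy of seed-driven HT-SELEX motif building. At level 1 only exact
#' seed matches fill all columns; the default level 2 also lets 1-mismatch
#' windows fill every column, which is what makes gapped 12-17 nt dimer
#' seeds workable in libraries of ~1e4 reads, where exact occurrences of a
#' 12 bp footprint are Poisson-rare. A pseudocount is added per cell; when
#' a background (cycle-0) library is given, its counts, scaled to equal
#' contributing-window totals, are subtracted and the result floored at the
#' pseudocount before normalisation.
#'
#' @param library a [LigandLibrary] (or character vector of reads).
#' @param seed IUPAC seed, `N` allowed (e.g. gapped dimer seeds).
#' @param background optional cycle-0 [LigandLibrary] for correction.
#' @param name motif name (defaults to the seed).
#' @param pseudocount added per cell (default 1).
#' @param multinomial_level mismatch tolerance of the counting rule
#'   (default 2).
#' @return a [pwm_model].
#' @export
build_pwm_from_seed <- function(library, seed, background = NULL,
                                name = seed, pseudocount = 1,
                                multinomial_level = 2L) {
  reads <- if (inherits(library, "LigandLibrary")) library$reads else library
  methylated <- if (inherits(library, "LigandLibrary")) library$methylated else FALSE
  if (nchar(seed) > nchar(reads[1]))
    stop("seed wider than the reads")
  bcodes <- if (is.null(background)) NULL else
    encode_seqs(if (inherits(background, "LigandLibrary")) background$reads
                else background)
  .build_pwm_codes(encode_seqs(reads), bcodes, seed, name = name,
                   pseudocount = pseudocount, level = multinomial_level,
                   methylated = methylated)
}

# core of build_pwm_from_seed operating on pre-encoded read matrices
.build_pwm_codes <- function(codes, bcodes, seed, name = seed,
                             pseudocount = 1, level = 2L,
                             methylated = FALSE) {
  sig <- .seed_counts(codes, seed, level)
  if (sig$n == 0) stop("no windows match seed '", seed, "'")
  C <- sig$counts + pseudocount
  if (!is.null(bcodes)) {
    bg <- .seed_counts(bcodes, seed, level)
    if (bg$n > 0)
      C <- pmax(C - bg$counts * (sig$n / bg$n), pseudocount)
  }
  M <- sweep(C, 2, colSums(C), "/")
  pwm_model(M, seed = seed, name = name, methylated = methylated,
            nsites = sig$n)
}

#' Exact score threshold for a motif-match p-value
#'
#' Log-odds scores (base-2 against the background, PWM probabilities floored
#' at `prob_floor` to keep scores finite) are discretised onto a lattice of
#' `n_levels` distinct levels spanning the score range; the exact
#' distribution of the lattice score of a random background w-mer is
#' computed by column-wise convolution, and the smallest threshold t with
#' `P(score >= t) <= p` is returned together with the attained tail
#' probability. When `p` is below the smallest attainable tail, the maximum
#' score is returned with its tail probability.
#'
#' @param model a [pwm_model].
#' @param background base frequencies (A, C, G, T); uniform by default —
#'   SELEX randomised regions are near-uniform.
#' @param p target p-value in (0, 1).
#' @param n_levels lattice resolution (default 20000).
#' @param prob_floor PWM probability floor for log-odds (default 1e-6).
#' @param rule `"at_most"` (default): smallest threshold with
#'   `P(score >= t) <= p`; `"closest"`: the threshold whose tail
#'   probability is nearest to `p` on the log scale. The second rule makes
#'   background match rates commensurate across models of different widths
#'   and sharpness (a very sharp model's score distribution is so
#'   concentrated that the at-most rule can overshoot `p` by orders of
#'   magnitude), which is what enrichment comparisons between models need.
#' @return object of class `pwm_threshold`: list with `score` (threshold on
#'   the log-odds scale), `p_actual`, the integer score matrix `q`, lattice
#'   step `delta`, `offset` (score of lattice level 0), `level` (integer
#'   threshold), full lattice `dist` and `tail`, and the background used.
#' @export
score_threshold_for_pvalue <- function(model, background = rep(0.25, 4),
                                       p, n_levels = 20000L,
                                       prob_floor = 1e-6,
                                       rule = c("at_most", "closest")) {
  rule <- match.arg(rule)
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  P <- model$matrix
  Preg <- sweep(P + prob_floor, 2, colSums(P + prob_floor), "/")
  S <- log2(Preg / background)           # 4 x w, background recycled by row
  w <- ncol(S)
  colmin <- apply(S, 2, min); colmax <- apply(S, 2, max)
  rng <- sum(colmax) - sum(colmin)
  if (rng == 0) {
    return(structure(list(score = sum(colmax), p_actual = 1, p = p,
                          q = matrix(0L, 4, w), delta = 0,
                          offset = sum(colmin), level = 0L,
                          dist = 1, tail = 1, background = background,
                          prob_floor = prob_floor),
                     class = "pwm_threshold"))
  }
  delta <- rng / n_levels
  q <- round(sweep(S, 2, colmin, "-") / delta)
  storage.mode(q) <- "integer"
  dist <- 1
  for (cc in seq_len(w)) {
    mx <- max(q[, cc])
    nd <- numeric(length(dist) + mx)
    for (b in 1:4) {
      rngi <- seq_along(dist) + q[b, cc]
      nd[rngi] <- nd[rngi] + dist * background[b]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  level <- if (rule == "closest") {
    pos <- pmax(tail, .Machine$double.xmin)
    which.min(abs(log(pos) - log(p))) - 1L
  } else {
    idx <- which(tail <= p)
    if (length(idx)) idx[1] - 1L else length(tail) - 1L
  }
  structure(list(score = sum(colmin) + delta * level,
                 p_actual = tail[level + 1L], p = p,
                 q = q, delta = delta, offset = sum(colmin),
                 level = level, dist = dist, tail = tail,
                 background = background, prob_floor = prob_floor),
            class = "pwm_threshold")
}

#' @export
print.pwm_threshold <- function(x, ...) {
  cat(sprintf("pwm_threshold: score >= %.4f (p_actual %.3g, target %.3g)\n",
              x$score, x$p_actual, x$p))
  invisible(x)
}

# normalise the sequences argument of matching functions to a character
# vector of sequences
.as_seqs <- function(sequences) {
  if (inherits(sequences, "LigandLibrary")) return(sequences$reads)
  if (methods::is(sequences, "XStringSet")) return(as.character(sequences))
  as.character(sequences)
}

# integer lattice score matrix (w x 4) and cutoff for a given threshold
.threshold_lattice <- function(model, threshold) {
  if (inherits(threshold, "pwm_threshold"))
    return(list(score = t(threshold$q) + 0.0, cut = threshold$level + 0.0,
                delta = threshold$delta, offset = threshold$offset))
  # bare numeric threshold: score continuously with default regularisation
  P <- model$matrix
  Preg <- sweep(P + 1e-6, 2, colSums(P + 1e-6), "/")
  S <- log2(Preg / 0.25)
  list(score = t(S), cut = as.numeric(threshold), delta = 1, offset = 0)
}

#' Find motif matches in sequences
#'
#' Scans both strands of every sequence; a window counts once per
#' (position, strand) and overlapping matches are allowed.
#'
#' @param model a [pwm_model].
#' @param sequences character vector, [LigandLibrary] or `DNAStringSet`
#'   (sequences may differ in length).
#' @param threshold a `pwm_threshold` from [score_threshold_for_pvalue()]
#'   (exact lattice semantics) or a bare numeric log-odds cutoff.
#' @return data.frame with `seq` (sequence index), `start` (1-based, on the
#'   forward coordinates), `strand` and `score` (log-odds scale).
#' @export
match_motif <- function(model, sequences, threshold) {
  seqs <- .as_seqs(sequences)
  lat <- .threshold_lattice(model, threshold)
  w <- nrow(lat$score)
  res <- list()
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    if (len < w) next
    codes <- encode_seqs(seqs[idx])
    Sf <- cpp_window_scores(codes, lat$score)
    Sr <- cpp_window_scores(codes, lat$score[w:1, 4:1, drop = FALSE])
    for (strand in c("+", "-")) {
      S <- if (strand == "+") Sf else Sr
      hit <- which(S >= lat$cut, arr.ind = TRUE)
      if (nrow(hit))
        res[[paste(len, strand)]] <-
          data.frame(seq = idx[hit[, 1]], start = hit[, 2],
                     strand = strand,
                     score = lat$offset + lat$delta * S[hit])
    }
  }
  if (!length(res))
    return(data.frame(seq = integer(0), start = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$seq, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Count motif hits per sequence
#'
#' Fast both-strand hit counting (same matching semantics as
#' [match_motif()]).
#'
#' @inheritParams match_motif
#' @return integer vector: hits per sequence.
#' @export
count_motif_hits <- function(model, sequences, threshold) {
  seqs <- .as_seqs(sequences)
  lat <- .threshold_lattice(model, threshold)
  w <- nrow(lat$score)
  out <- integer(length(seqs))
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    if (len < w) next
    out[idx] <- .count_hits_codes(encode_seqs(seqs[idx]), lat)
  }
  out
}

# both-strand hit counts on a pre-encoded read matrix
.count_hits_codes <- function(codes, lat) {
  w <- nrow(lat$score)
  if (ncol(codes) < w) return(integer(nrow(codes)))
  cpp_count_hits(codes, lat$score, lat$cut) +
    cpp_count_hits(codes, lat$score[w:1, 4:1, drop = FALSE], lat$cut)
}

#' Mononucleotide shuffle of a library's randomised regions
#'
#' Each read's randomised region is independently permuted (flanks
#' untouched), exactly preserving per-read base composition — the standard
#' null for motif enrichment in SELEX libraries.
#'
#' @param library a [LigandLibrary].
#' @param seed optional RNG seed for reproducibility.
#' @return the shuffled [LigandLibrary].
#' @export
shuffle_library <- function(library, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- library$random_region[["start"]]
  len <- library$random_region[["length"]]
  pre <- substr(library$reads, 1L, s - 1L)
  post <- substr(library$reads, s + len, nchar(library$reads))
  shuf <- vapply(strsplit(region_reads(library), "", fixed = TRUE),
                 function(x) paste(sample(x), collapse = ""), character(1))
  LigandLibrary(paste0(pre, shuf, post), cycle = library$cycle,
                methylated = library$methylated,
                random_region = library$random_region,
                label = paste0(library$label,
                               if (nzchar(library$label)) " " else "",
                               "(shuffled)"))
}

#' Motif enrichment against a shuffled background
#'
#' The number of motif hits in the library divided by the number of hits in
#' its shuffled version (pseudocounted by +1), at a match threshold derived
#' from the requested p-value — the signal-strength measure attached to
#' each binding model.
#'
#' @param model a [pwm_model].
#' @param library selected [LigandLibrary].
#' @param shuffled its [shuffle_library()] counterpart (equal read count
#'   and length).
#' @param p motif-match p-value (default 1e-5).
#' @param background base frequencies for the threshold.
#' @return list with `enrichment`, `hits`, `hits_shuffled` and the
#'   `threshold` object.
#' @export
motif_enrichment <- function(model, library, shuffled, p = 1e-5,
                             background = rep(0.25, 4)) {
  if (length(library$reads) != length(shuffled$reads) ||
      nchar(library$reads[1]) != nchar(shuffled$reads[1]))
    stop("mismatched library sizes")
  thr <- score_threshold_for_pvalue(model, background, p)
  hits <- sum(count_motif_hits(model, library, thr))
  hits_sh <- sum(count_motif_hits(model, shuffled, thr))
  list(enrichment = hits / (hits_sh + 1),
       hits = hits, hits_shuffled = hits_sh, threshold = thr)
}

#' Positional comparison of a methylated and an unmethylated PWM
#'
#' Per position (from column 1, over the shared width): the preferred base
#' of each model and the change in combined C+G probability
#' (`delta_CG = (pC + pG)_methyl - (pC + pG)_normal`), called `"+"` when
#' methylation increases cytosine affinity beyond `tau`, `"-"` when it
#' decreases it, and `"."` otherwise. C and G are pooled because full
#' methylation places 5mC on both strands of every C/G pair.
#'
#' @param normal,methyl [pwm_model]s from the unmethylated and methylated
#'   libraries (same configuration; unequal widths are compared over the
#'   shared leading columns).
#' @param tau call threshold on `|delta_CG|` (default 0.05).
#' @return data.frame of class `MethylComparison` with columns `position`,
#'   `preferred_normal`, `preferred_methyl`, `delta_CG`, `call`.
#' @export
compare_methyl_pwms <- function(normal, methyl, tau = 0.05) {
  w <- min(ncol(normal$matrix), ncol(methyl$matrix))
  pn <- normal$matrix[, seq_len(w), drop = FALSE]
  pm <- methyl$matrix[, seq_len(w), drop = FALSE]
  delta <- (pm[2, ] + pm[3, ]) - (pn[2, ] + pn[3, ])
  df <- data.frame(position = seq_len(w),
                   preferred_normal = .BASES[apply(pn, 2, which.max)],
                   preferred_methyl = .BASES[apply(pm, 2, which.max)],
                   delta_CG = unname(delta),
                   call = ifelse(delta > tau, "+",
                                 ifelse(delta < -tau, "-", ".")))
  class(df) <- c("MethylComparison", "data.frame")
  df
}
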