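# k-mer counting, per-cycle enrichment trajectories, cross-library k-mer
# comparison, and enrichment-based mutual information (E-MI).

# integer k-mer codes (base-4) for every window start of the region matrix
.kmer_codes <- function(codes, k) {
  L <- ncol(codes)
  K <- L - k + 1L
  out <- vector("list", K)
  for (o in seq_len(K)) {
    v <- numeric(nrow(codes))
    for (j in seq_len(k)) v <- v * 4 + (codes[, o + j - 1L] - 1)
    out[[o]] <- v
  }
  out
}

.decode_kmer <- function(code, k) {
  m <- matrix(0L, length(code), k)
  for (j in k:1) {
    m[, j] <- code %% 4
    code <- code %/% 4
  }
  apply(m, 1, function(r) paste(.BASES[r + 1L], collapse = ""))
}

#' Count k-mers in the randomised region of a library
#'
#' Counts every length-k window of the randomised region of every read, on
#' the read's forward strand only (the merged SELEX read orientation is
#' arbitrary but consistent; reverse-complement signal is handled at the
#' motif level, and double-counting would distort totals).
#'
#' @param library a [LigandLibrary].
#' @param k k-mer length (1 <= k <= region length).
#' @return an object of class `KmerTable`: list with `k`, named integer
#'   vector `counts`, `total` (= n_reads * (L - k + 1)), `cycle`,
#'   `methylated`.
#' @export
count_kmers <- function(library, k) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  len <- library$random_region[["length"]]
  if (k > len) stop("k exceeds the randomised-region length")
  codes <- encode_seqs(region_reads(library))
  v <- unlist(.kmer_codes(codes, k), use.names = FALSE)
  sv <- sort(v, method = "radix")
  r <- rle(sv)
  counts <- setNames(as.integer(r$lengths), .decode_kmer(r$values, k))
  structure(list(k = k, counts = counts, total = length(v),
                 cycle = library$cycle, methylated = library$methylated),
            class = "KmerTable")
}

#' @export
print.KmerTable <- function(x, ...) {
  cat(sprintf("KmerTable: k=%d, %d distinct k-mers, total %d windows, cycle %d%s\n",
              x$k, length(x$counts), x$total, x$cycle,
              if (x$methylated) " (methylated)" else ""))
  invisible(x)
}

.kmer_freq <- function(table, kmer, pseudo = 0) {
  c0 <- table$counts[kmer]
  (ifelse(is.na(c0), 0, c0) + pseudo) / table$total
}

#' Per-cycle frequency trajectory of a k-mer
#'
#' @param tables list of [count_kmers()] tables, one per cycle, cycles
#'   contiguous from 0.
#' @param kmer the k-mer to follow.
#' @return numeric vector of frequencies (count/total), one per cycle;
#'   0 where the k-mer is absent.
#' @export
enrichment_trajectory <- function(tables, kmer) {
  ks <- vapply(tables, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("tables have mismatched k")
  if (nchar(kmer) != ks[1]) stop("k-mer length does not match tables")
  cyc <- unname(vapply(tables, `[[`, integer(1), "cycle"))
  tables <- tables[order(cyc)]
  cyc <- sort(cyc)
  if (!identical(cyc, seq(0L, length(tables) - 1L)))
    stop("cycles must be contiguous from 0")
  vapply(tables, .kmer_freq, numeric(1), kmer = kmer)
}

#' Log-linear fit of an enrichment trajectory
#'
#' Ordinary least squares of `log2(freq + pseudo)` on the cycle index.
#' Exponential per-cycle enrichment appears as a straight line on this
#' scale.
#'
#' @param trajectory frequencies from [enrichment_trajectory()].
#' @param pseudo small constant added before taking logs (default 0).
#' @return list with `slope` (log2 units per cycle), `intercept` and
#'   `r_squared` (`NA` when undefined, e.g. an all-zero or constant
#'   trajectory).
#' @export
fit_log_linear <- function(trajectory, pseudo = 0) {
  if (length(trajectory) < 3L) stop("need at least 3 cycles to fit")
  if (all(trajectory == 0))
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  y <- log2(trajectory + pseudo)
  if (any(!is.finite(y)))
    stop("trajectory contains zeros; use a positive pseudo count")
  cycle <- seq_along(y) - 1
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = NA_real_))
  fit <- lm(y ~ cycle)
  # exact doublings give a perfect fit; the summary warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Compare k-mer enrichments between two libraries
#'
#' For the union of the `top_n` most abundant k-mers (by final-cycle count)
#' in each library, computes the enrichment of every k-mer in both
#' libraries relative to its own cycle-0 background
#' (`freq_final / freq_background`, both frequencies pseudocounted by
#' `0.5/total`), supporting the cross-library scatter; a sign test on
#' `enrich_a - enrich_b` summarises which library wins among the selected
#' k-mers.
#'
#' @param table_a,table_b final-cycle [count_kmers()] tables.
#' @param background_a,background_b matching cycle-0 tables.
#' @param top_n how many top k-mers to take from each library.
#' @return list with `table` (data.frame: kmer, count_a, count_b, enrich_a,
#'   enrich_b), `p_value` (two-sided sign test) and `winner` (`"a"`, `"b"`
#'   or `"tie"`).
#' @export
compare_libraries <- function(table_a, table_b, background_a, background_b,
                              top_n = 100) {
  tabs <- list(table_a, table_b, background_a, background_b)
  ks <- vapply(tabs, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("tables have mismatched k")
  if (any(vapply(tabs, `[[`, integer(1), "total") == 0))
    stop("zero-total k-mer table")
  top <- function(tb) names(sort(tb$counts, decreasing = TRUE))[
    seq_len(min(top_n, length(tb$counts)))]
  kmers <- union(top(table_a), top(table_b))
  enr <- function(tb, bg, km)
    .kmer_freq(tb, km, 0.5) / .kmer_freq(bg, km, 0.5)
  df <- data.frame(kmer = kmers,
                   count_a = as.integer(.kmer_freq(table_a, kmers) * table_a$total),
                   count_b = as.integer(.kmer_freq(table_b, kmers) * table_b$total),
                   enrich_a = vapply(kmers, function(km) enr(table_a, background_a, km), numeric(1)),
                   enrich_b = vapply(kmers, function(km) enr(table_b, background_b, km), numeric(1)),
                   row.names = NULL)
  d <- df$enrich_a - df$enrich_b
  n_pos <- sum(d > 0); n_neg <- sum(d < 0)
  p <- if (n_pos + n_neg == 0) 1 else
    binom.test(n_pos, n_pos + n_neg)$p.value
  winner <- if (p > 0.05 || n_pos == n_neg) "tie" else
    if (n_pos > n_neg) "a" else "b"
  list(table = df, p_value = p, winner = winner)
}

#' Enrichment-based mutual information between 3-mer positions
#'
#' For every non-overlapping pair of 3-mer start positions (i, j), j >= i+3,
#' within the randomised region, tabulates the 64 x 64 joint distribution of
#' (3-mer at i, 3-mer at j) over reads with a pseudocount of 1 per cell and
#' sums the pointwise mutual information `f(a,b) log2(f(a,b)/(f(a) f(b)))`
#' of the `top_pairs` most frequent 3-mer pairs (marginals from the same
#' pseudocounted table). Sequence-specific selection concentrates E-MI at
#' position pairs spanning the selected site; an i.i.d. library gives
#' values near zero everywhere.
#'
#' @param library a [LigandLibrary] (randomised region >= 6 nt).
#' @param top_pairs number of most frequent 3-mer pairs summed (default 10).
#' @return object of class `EmiMatrix`: list with `values` (symmetric
#'   matrix over start positions, `NA` for overlapping pairs), `positions`
#'   (1-based starts) and `top_pairs` (per position pair, the contributing
#'   3-mer pairs with counts and pointwise MI).
#' @export
emi <- function(library, top_pairs = 10) {
  len <- library$random_region[["length"]]
  if (len < 6L) stop("randomised region shorter than 6 nt")
  n <- length(library$reads)
  if (n < 100L) warning("fewer than 100 reads: E-MI estimates are unstable")
  codes <- encode_seqs(region_reads(library))
  c3 <- .kmer_codes(codes, 3L)      # integer 3-mer codes per start
  P <- length(c3)
  vals <- matrix(NA_real_, P, P)
  tops <- list()
  km3 <- .decode_kmer(0:63, 3L)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (j < i + 3L) next
      joint <- tabulate(c3[[i]] * 64 + c3[[j]] + 1, nbins = 4096) + 1
      tot <- n + 4096
      f <- joint / tot
      fi <- rowSums(matrix(joint, 64, 64, byrow = TRUE)) / tot  # 3-mer at i
      fj <- colSums(matrix(joint, 64, 64, byrow = TRUE)) / tot  # 3-mer at j
      sel <- order(joint, decreasing = TRUE)[seq_len(top_pairs)]
      ai <- (sel - 1) %/% 64 + 1   # index of 3-mer at i
      bj <- (sel - 1) %% 64 + 1
      pmi <- log2(f[sel] / (fi[ai] * fj[bj]))
      e <- sum(f[sel] * pmi)
      vals[i, j] <- e; vals[j, i] <- e
      tops[[paste(i, j, sep = "_")]] <-
        data.frame(kmer_i = km3[ai], kmer_j = km3[bj],
                   count = joint[sel] - 1, pmi = pmi)
    }
  }
  structure(list(values = vals, positions = seq_len(P), top_pairs = tops,
                 definition = paste("sum of pointwise MI over the", top_pairs,
                                    "most frequent 3-mer pairs;",
                                    "joint table pseudocount 1 per cell")),
            class = "EmiMatrix")
}

#' @export
print.EmiMatrix <- function(x, ...) {
  v <- x$values
  i <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("EmiMatrix: %d positions, max E-MI %.4f bits at (%d, %d)\n",
              nrow(v), max(v, na.rm = TRUE), i[1], i[2]))
  invisible(x)
}

#' Write an E-MI matrix as long-format TSV
#'
#' @param x an [emi()] result.
#' @param path output TSV with columns i, j, emi.
#' @return `path`, invisibly.
#' @export
write_emi_tsv <- function(x, path) {
  idx <- which(!is.na(x$values) & row(x$values) < col(x$values), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], emi = x$values[idx])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
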