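# Shared fixtures, all generated in code.

# printed EMSA probe sequences (monomeric control plus the two everted-repeat
# dimeric probes)
PROBE_M1  <- "ATGCTAGCTCCATCTGTATTGATTGTTTATGGCGGTGACGTACT"
PROBE_ER0 <- "ATGCTAGCTCCATCTGTGATTGCAATCAATGGCGGTGACGTACT"
PROBE_ER1 <- "ATGCTAGCTCCATCTGTGATTGACAATCAATGGCGGTGACGTACT"

# uniform random ACGT reads
random_reads <- function(n, len, seed = 1) {
  set.seed(seed)
  apply(matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n),
        1, paste, collapse = "")
}

random_library <- function(n, len, seed = 1, ...) {
  LigandLibrary(random_reads(n, len, seed), ...)
}

# a deterministic PWM concentrated on a consensus sequence
consensus_pwm <- function(consensus, purity = 1, name = consensus) {
  bases <- strsplit(consensus, "")[[1]]
  w <- length(bases)
  M <- matrix((1 - purity) / 3, 4, w, dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(w)) M[bases[j], j] <- purity
  pwm_model(M, seed = consensus, name = name)
}

# temporary file helper
tmpfile <- function(ext) tempfile(fileext = ext)

# brute-force oracle: exact lattice-score tail over all 4^w sequences
brute_force_tail <- function(q, background) {
  w <- ncol(q)
  scores <- 0L; probs <- 1
  for (cc in seq_len(w)) {
    scores <- as.vector(outer(scores, q[, cc], "+"))
    probs <- as.vector(outer(probs, background))
  }
  dist <- numeric(max(scores) + 1L)
  for (i in seq_along(scores))
    dist[scores[i] + 1L] <- dist[scores[i] + 1L] + probs[i]
  rev(cumsum(rev(dist)))
}

random_pwm <- function(w, seed) {
  set.seed(seed)
  M <- matrix(stats::rgamma(4 * w, 1), 4, w)
  pwm_model(sweep(M, 2, colSums(M), "/"))
}
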