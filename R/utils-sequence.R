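# Low-level sequence utilities shared by all modules.

.BASES <- c("A", "C", "G", "T")

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# byte -> base code lookup (A=1, C=2, G=3, T=4, anything else 0)
.CODE_LOOKUP <- local({
  x <- integer(256)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
})

# Encode equal-length sequences as an n x L integer matrix (N and any
# non-ACGT byte become 0, which the kernels treat as "never matches,
# scores zero").
encode_seqs <- function(x) {
  x <- toupper(as.character(x))
  L <- nchar(x[1])
  if (any(nchar(x) != L)) stop("sequences must have equal length to encode")
  v <- .CODE_LOOKUP[utf8ToInt(paste(x, collapse = ""))]
  matrix(v, nrow = length(x), ncol = L, byrow = TRUE)
}

decode_codes <- function(m) {
  chars <- c("N", .BASES)[as.vector(t(m)) + 1L]
  apply(matrix(chars, ncol = ncol(m), byrow = TRUE), 1, paste, collapse = "")
}

#' Reverse complement of DNA strings (IUPAC-aware)
#'
#' @param x character vector of sequences (ACGT plus IUPAC ambiguity codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# 4 x w logical matrix: allowed[b, p] is TRUE when base b is accepted at
# position p of the IUPAC pattern.
iupac_allowed <- function(pattern) {
  syms <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(syms, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC symbol(s) in pattern: ", paste(unique(bad), collapse = ", "))
  vapply(syms, function(s) .BASES %in% .IUPAC[[s]], logical(4))
}

#' Consensus instantiation of an IUPAC pattern
#'
#' Resolves each ambiguity code to a single base with a fixed, documented
#' preference: `N` becomes `A`; otherwise `G` if allowed, else `C`, else `A`,
#' else `T`. With this rule the everted-repeat seed built from the `YAATYA`
#' half-site instantiates to the `TGATTG...CAATCA` cores seen in dimeric
#' probe sequences, and no instantiated half-site is accidentally palindromic.
#'
#' @param pattern IUPAC string.
#' @return character consensus sequence of the same width.
#' @export
iupac_consensus <- function(pattern) {
  syms <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  pick <- vapply(syms, function(s) {
    set <- .IUPAC[[s]]
    if (is.null(set)) stop("invalid IUPAC symbol: ", s)
    if (s == "N") return("A")
    for (b in c("G", "C", "A", "T")) if (b %in% set) return(b)
    set[1]
  }, character(1))
  paste(pick, collapse = "")
}

# Per-offset IUPAC mismatch counts of one sequence against a pattern
# (forward orientation only); codes 0 count as mismatches.
.iupac_mismatches <- function(codes, allowed) {
  w <- ncol(allowed)
  K <- length(codes) - w + 1L
  if (K < 1L) return(integer(0))
  ok <- rbind(allowed, rep(FALSE, w))   # row 5 for code 0
  codes[codes == 0L] <- 5L
  idx <- outer(seq_len(K), 0:(w - 1L), "+")
  m <- matrix(ok[cbind(as.vector(codes[idx]), rep(seq_len(w), each = K))], K, w)
  as.integer(rowSums(!m))
}
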