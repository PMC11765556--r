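# Half-site grammar: scan for half-sites on both strands, classify pairs
# into direct/inverted/everted repeats (DR/IR/ER) with spacing, name motifs
# (e.g. "ER0"), and enumerate dimeric seeds for PWM construction.
#
# Conventions (standard nuclear-receptor-style nomenclature):
#   DR = half-sites in the same orientation, strand pair (+,+) or (-,-)
#   IR = head-to-head, strand pair (+,-)
#   ER = tail-to-tail, strand pair (-,+)
#   spacing = gap in bases between the two half-site spans (>= 0)

# tie-break preference among equal-mismatch, equal-spacing pairs; everted
# first: a half-site instance whose degenerate positions make it palindromic
# satisfies all three orientations at once, and the everted reading is this
# factor family's dominant dimeric mode
.ORIENT_ORDER <- c(ER = 1L, IR = 2L, DR = 3L)

#' Scan a sequence for half-site matches on both strands
#'
#' Forward matches are windows matching the IUPAC half-site with at most
#' `max_mismatch` mismatches; reverse matches are windows matching its
#' reverse complement, reported with strand `-`. Offsets are 0-based
#' (BED-style), so results align with genomic interval conventions.
#'
#' @param sequence a single sequence (character).
#' @param half_site IUPAC half-site (default `"YAATYA"`).
#' @param max_mismatch maximum mismatches allowed (default 0).
#' @return data.frame with `start` (0-based), `strand`, `mismatches`,
#'   sorted by start.
#' @export
scan_half_sites <- function(sequence, half_site = "YAATYA",
                            max_mismatch = 0L) {
  sequence <- toupper(as.character(sequence)[1])
  h <- nchar(half_site)
  if (nchar(sequence) < h) stop("sequence shorter than the half-site")
  codes <- as.vector(encode_seqs(sequence))
  mmF <- .iupac_mismatches(codes, iupac_allowed(half_site))
  mmR <- .iupac_mismatches(codes, iupac_allowed(revcomp(half_site)))
  hitF <- which(mmF <= max_mismatch); hitR <- which(mmR <= max_mismatch)
  df <- rbind(
    data.frame(start = hitF - 1L, strand = rep("+", length(hitF)),
               mismatches = mmF[hitF]),
    data.frame(start = hitR - 1L, strand = rep("-", length(hitR)),
               mismatches = mmR[hitR]))
  df <- df[order(df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

.dimer_assignment <- function(orientation, spacing = NA_integer_,
                              name = orientation) {
  structure(list(orientation = orientation, spacing = spacing, name = name),
            class = "DimerAssignment")
}

#' @export
print.DimerAssignment <- function(x, ...) {
  cat("DimerAssignment:", x$name, "\n")
  invisible(x)
}

#' Classify an ordered pair of half-site matches
#'
#' `spacing = start2 - (start1 + half_len)`; a negative gap (overlapping
#' half-sites) is classified `"overlap"` and excluded from dimer naming.
#' Strand pairs map (+,+)/(-,-) to DR, (+,-) to IR and (-,+) to ER; dimer
#' names combine orientation and spacing (`"ER0"`, `"DR3"`, ...).
#'
#' @param m1,m2 half-site matches (rows of [scan_half_sites()] output, or
#'   lists with `start` and `strand`), with `m1$start <= m2$start`.
#' @param half_len half-site length.
#' @return a `DimerAssignment` (list with `orientation`, `spacing`, `name`).
#' @export
classify_pair <- function(m1, m2, half_len) {
  if (m1$start > m2$start) stop("m1 must not start after m2")
  spacing <- m2$start - (m1$start + half_len)
  if (spacing < 0) return(.dimer_assignment("overlap"))
  orientation <-
    if (m1$strand == m2$strand) "DR"
    else if (m1$strand == "+") "IR"
    else "ER"
  .dimer_assignment(orientation, as.integer(spacing),
                    paste0(orientation, spacing))
}

#' Classify a probe sequence by its half-site content
#'
#' Scans both strands; zero matches give `"none"`, one gives `"monomer"`,
#' and with two or more the best non-overlapping pair within `max_spacing`
#' is classified — fewest total mismatches first, then smallest spacing,
#' then a fixed orientation order (ER, IR, DR), then leftmost. The
#' orientation-order tie-break keeps classification invariant under
#' reverse complementation (and resolves palindromic half-site instances,
#' which satisfy every orientation at once, toward the everted reading).
#' If no pair qualifies the probe is reported as `"monomer"`.
#'
#' @param sequence probe sequence.
#' @param half_site IUPAC half-site (default `"YAATYA"`).
#' @param max_mismatch maximum mismatches per half-site (default 0).
#' @param max_spacing largest half-site gap considered (default 20).
#' @return a `DimerAssignment`; the half-site matches are attached as
#'   attribute `"matches"`.
#' @export
classify_probe <- function(sequence, half_site = "YAATYA",
                           max_mismatch = 0L, max_spacing = 20L) {
  m <- scan_half_sites(sequence, half_site, max_mismatch)
  h <- nchar(half_site)
  out <- NULL
  if (nrow(m) == 0L) {
    out <- .dimer_assignment("none", name = "none")
  } else if (nrow(m) == 1L) {
    out <- .dimer_assignment("monomer", name = "monomer")
  } else {
    lex_less <- function(a, b) {
      d <- which(a != b)
      length(d) > 0L && a[d[1]] < b[d[1]]
    }
    best <- NULL; best_key <- NULL
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in (i + 1L):nrow(m)) {
        a <- classify_pair(m[i, ], m[j, ], h)
        if (a$orientation == "overlap" || a$spacing > max_spacing) next
        key <- c(m$mismatches[i] + m$mismatches[j], a$spacing,
                 .ORIENT_ORDER[[a$orientation]], m$start[i], m$start[j])
        if (is.null(best_key) || lex_less(key, best_key)) {
          best <- a; best_key <- key
        }
      }
    }
    out <- if (is.null(best)) .dimer_assignment("monomer", name = "monomer")
           else best
  }
  attr(out, "matches") <- m
  out
}

#' Parse a dimer name into orientation and spacing
#'
#' @param name dimer name such as `"ER0"` or `"DR12"`.
#' @return list with `orientation` and integer `spacing`.
#' @export
parse_dimer_name <- function(name) {
  m <- regmatches(name, regexec("^(DR|IR|ER)([0-9]+)$", name))[[1]]
  if (length(m) != 3L) stop("not a dimer name: ", name)
  list(orientation = m[2], spacing = as.integer(m[3]))
}

#' Enumerate dimeric seeds for all orientations and spacings
#'
#' Builds the gapped IUPAC seed of every configuration from the half-site
#' HS, its reverse complement and an N-gap of the given spacing:
#' DRs = HS Ns HS, IRs = HS Ns revcomp(HS), ERs = revcomp(HS) Ns HS.
#' These seeds feed [build_pwm_from_seed()]; classifying the consensus
#' instantiation of any seed returns its own name.
#'
#' @param half_site IUPAC half-site (default `"YAATYA"`).
#' @param orientations subset of `c("DR", "IR", "ER")`.
#' @param max_spacing largest spacing enumerated.
#' @return data.frame with `name`, `orientation`, `spacing`, `seed`.
#' @export
enumerate_dimer_seeds <- function(half_site = "YAATYA",
                                  orientations = c("DR", "IR", "ER"),
                                  max_spacing = 10L) {
  if (max_spacing < 0L) stop("max_spacing must be >= 0")
  orientations <- match.arg(orientations, c("DR", "IR", "ER"),
                            several.ok = TRUE)
  hs <- toupper(half_site)
  rc <- revcomp(hs)
  rows <- list()
  for (or in orientations) {
    for (s in 0:max_spacing) {
      gap <- strrep("N", s)
      seed <- switch(or,
                     DR = paste0(hs, gap, hs),
                     IR = paste0(hs, gap, rc),
                     ER = paste0(rc, gap, hs))
      rows[[paste0(or, s)]] <- data.frame(name = paste0(or, s),
                                          orientation = or,
                                          spacing = s, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank dimeric configurations of a selected library by motif enrichment
#'
#' For every enumerated configuration: builds the seed PWM from the library
#' (background-corrected against cycle 0), derives the match threshold at
#' the given p-value, and computes the enrichment of the model against the
#' mononucleotide-shuffled library. Configurations whose seed matches no
#' window are reported with `NA` enrichment.
#'
#' Survey thresholds use the `"closest"` rule of
#' [score_threshold_for_pvalue()] so that every model's background match
#' rate sits as close as possible to `p`: with the one-sided rule, sharp
#' single-lineage models overshoot the target by orders of magnitude and
#' the enrichment ratios of different configurations stop being
#' comparable (their denominators collapse to Poisson noise around zero).
#'
#' Two guards keep the ranking meaningful on deeply selected (hence nearly
#' clonal) libraries, where several configuration models can converge onto
#' the same amplified reads:
#'
#' * Self-consistency: the consensus of the fitted PWM, classified by
#'   [classify_probe()] (one mismatch allowed), must return the
#'   configuration's own name; otherwise the model is a shifted or
#'   strand-symmetrised copy of another motif, assembled from chance
#'   near-matches.
#' * Read-level support: every read is classified once by
#'   [classify_probe()] (one mismatch per half-site), and a configuration
#'   must be the best assignment of at least `min_support` reads. A read
#'   containing a genuine everted site plus a chance half-site nearby can
#'   feed a second configuration's PWM, but the grammar's
#'   mismatch-minimising classification names the true arrangement, so the
#'   shadow configuration ends up unsupported.
#'
#' Models failing either guard keep their enrichment in the output
#' (`consistent` / `support` columns) but are demoted below all supported,
#' consistent models in the ranking.
#'
#' @param library selected (final-cycle) [LigandLibrary].
#' @param background cycle-0 [LigandLibrary].
#' @param shuffled optional pre-shuffled library (defaults to
#'   [shuffle_library()] of `library`, using the current RNG state).
#' @param half_site IUPAC half-site.
#' @param max_spacing largest spacing surveyed (default 10).
#' @param p motif-match p-value (default 1e-5).
#' @param min_support minimum number of reads whose best classification is
#'   the configuration (default `max(10, 0.1%)` of the library).
#' @return data.frame (name, orientation, spacing, seed, mean_ic, hits,
#'   hits_shuffled, enrichment) sorted by decreasing enrichment; the fitted
#'   [pwm_model]s are attached as attribute `"models"`.
#' @export
rank_dimer_configs <- function(library, background, shuffled = NULL,
                               half_site = "YAATYA", max_spacing = 10L,
                               p = 1e-5,
                               min_support = max(10, 0.001 * length(library$reads))) {
  if (is.null(shuffled)) shuffled <- shuffle_library(library)
  if (length(library$reads) != length(shuffled$reads) ||
      nchar(library$reads[1]) != nchar(shuffled$reads[1]))
    stop("mismatched library sizes")
  seeds <- enumerate_dimer_seeds(half_site, max_spacing = max_spacing)
  n <- nrow(seeds)
  # read-level configuration census over unique reads
  ur <- table(library$reads)
  cls <- vapply(names(ur), function(s)
    classify_probe(s, half_site, max_mismatch = 1L,
                   max_spacing = max_spacing)$name, character(1))
  census <- tapply(as.integer(ur), cls, sum)
  support <- as.integer(census[seeds$name])
  support[is.na(support)] <- 0L
  codes_lib <- encode_seqs(library$reads)
  codes_bg <- encode_seqs(background$reads)
  codes_sh <- encode_seqs(shuffled$reads)
  models <- vector("list", n); names(models) <- seeds$name
  mean_ic <- hits <- hits_sh <- enr <- rep(NA_real_, n)
  consistent <- rep(NA, n)
  for (i in seq_len(n)) {
    pwm <- tryCatch(
      .build_pwm_codes(codes_lib, codes_bg, seeds$seed[i],
                       name = seeds$name[i],
                       methylated = library$methylated),
      error = function(e) NULL)
    if (is.null(pwm)) next
    cons <- paste(.BASES[apply(pwm$matrix, 2, which.max)], collapse = "")
    consistent[i] <- identical(
      classify_probe(cons, half_site, max_mismatch = 1,
                     max_spacing = max_spacing)$name,
      seeds$name[i])
    thr <- score_threshold_for_pvalue(pwm, p = p, rule = "closest")
    lat <- .threshold_lattice(pwm, thr)
    h <- sum(.count_hits_codes(codes_lib, lat))
    h_sh <- sum(.count_hits_codes(codes_sh, lat))
    pwm$enrichment <- h / (h_sh + 1)
    models[[i]] <- pwm
    mean_ic[i] <- pwm$mean_ic
    hits[i] <- h; hits_sh[i] <- h_sh
    enr[i] <- pwm$enrichment
  }
  out <- cbind(seeds, mean_ic = mean_ic, hits = hits,
               hits_shuffled = hits_sh, enrichment = enr,
               consistent = consistent, support = support)
  key <- ifelse(is.na(out$enrichment) | !isTRUE_vec(out$consistent) |
                  out$support < min_support,
                -Inf, out$enrichment)
  out <- out[order(-key, -ifelse(is.na(out$enrichment), -Inf, out$enrichment),
                   out$name), ]
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
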