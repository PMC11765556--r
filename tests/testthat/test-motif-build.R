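# PWM construction, information content, DP p-value thresholds (against a
# brute-force oracle), matching, shuffling, enrichment, methyl comparison.

test_that("information content matches closed forms", {
  even <- pwm_model(matrix(0.25, 4, 1))
  expect_equal(information_content(even)$ic, 0)
  det <- pwm_model(matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(information_content(det)$ic, 2)
  half <- pwm_model(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(information_content(half)$ic, 1)
  expect_error(pwm_model(matrix(c(0.5, 0.2, 0.2, 0.2), 4, 1)), "sum to 1")
})

test_that("DP threshold tail equals brute-force enumeration for w in {4, 6, 8}", {
  for (w in c(4L, 6L, 8L)) {
    model <- random_pwm(w, seed = w)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    thr <- score_threshold_for_pvalue(model, bg, p = 1e-3)
    oracle <- brute_force_tail(thr$q, bg)
    expect_lt(max(abs(thr$tail - oracle)), 1e-12)
  }
})

test_that("threshold edge cases behave as documented", {
  model <- random_pwm(5, seed = 9)
  # p = 1 admits everything: threshold at the minimum score
  thr1 <- score_threshold_for_pvalue(model, p = 1)
  expect_equal(thr1$level, 0L)
  expect_equal(thr1$p_actual, 1)

  # deterministic consensus PWM at p = 4^-w admits exactly the consensus
  cons <- consensus_pwm("CAATCA")
  thr <- score_threshold_for_pvalue(cons, p = 4^-6)
  hits <- count_motif_hits(cons, c("CAATCA", "CAATCC", "AAATCA"), thr)
  expect_equal(hits, c(1L, 0L, 0L))
  expect_equal(thr$p_actual, 4^-6, tolerance = 1e-9)

  # p below the attainable tail returns the max score with its p_actual
  thr2 <- score_threshold_for_pvalue(cons, p = 1e-12)
  expect_equal(thr2$level, length(thr2$tail) - 1L)
  expect_gt(thr2$p_actual, 1e-12)

  expect_error(score_threshold_for_pvalue(model, p = 0), "p must")
})

test_that("match_motif scans both strands, allows overlaps, and is rc-invariant", {
  cons <- consensus_pwm("CAATCA")
  thr <- score_threshold_for_pvalue(cons, p = 4^-6)
  seqs <- c("GGCAATCAGG", "GGTGATTGGG", "CCCCCCCCCC")
  m <- match_motif(cons, seqs, thr)
  expect_equal(nrow(m), 2L)
  expect_equal(m$strand[m$seq == 1], "+")
  expect_equal(m$strand[m$seq == 2], "-")
  expect_equal(m$start[m$seq == 1], 3L)

  # reverse-complementing every sequence preserves counts, flips strands
  m2 <- match_motif(cons, revcomp(seqs), thr)
  expect_equal(nrow(m2), nrow(m))
  expect_setequal(paste(m2$seq, m2$strand),
                  paste(m$seq, chartr("+-", "-+", m$strand)))

  # threshold above the max score: no matches
  expect_equal(nrow(match_motif(cons, seqs, 1e6)), 0L)

  # overlapping matches are all reported
  mm <- match_motif(cons, "CAATCAATCA", thr)
  expect_equal(nrow(mm), 2L)
})

test_that("build_pwm_from_seed recovers degenerate and planted structure", {
  # degenerate: every read is exactly the seed's consensus
  lib <- LigandLibrary(rep("GGTGATTGCAATCAGG", 500))
  pwm <- build_pwm_from_seed(lib, "CAATCA", pseudocount = 1)
  expect_gt(pwm$mean_ic, 1.8)
  expect_equal(unname(pwm$matrix["C", 1]), 1, tolerance = 0.02)

  # uniform random reads: near-uniform columns, tiny IC
  null_lib <- random_library(10000, 30, seed = 21)
  pwm0 <- build_pwm_from_seed(null_lib, "CAATCA")
  expect_lt(pwm0$mean_ic, 0.05)
  expect_true(all(abs(pwm0$matrix - 0.25) < 0.05))

  # planted 70/30 mixture at one position is recovered within 0.05
  set.seed(8)
  n <- 10000
  variant <- ifelse(stats::runif(n) < 0.3, "T", "C")
  reads <- paste0(random_reads(n, 10, seed = 88), "CAAT", variant, "A",
                  random_reads(n, 10, seed = 99))
  mix <- LigandLibrary(reads)
  # classical multinomial level 1: the variant column is counted only from
  # windows matching the seed everywhere else
  pwmv <- build_pwm_from_seed(mix, "CAATCA", multinomial_level = 1)
  expect_equal(unname(pwmv$matrix["C", 5]), 0.7, tolerance = 0.05)
  expect_equal(unname(pwmv$matrix["T", 5]), 0.3, tolerance = 0.05)

  expect_error(build_pwm_from_seed(LigandLibrary("GGGGGGGGGG"), "CAATCA"),
               "no windows match")
})

test_that("mononucleotide shuffle preserves per-read composition and flanks", {
  lib <- random_library(50, 20, seed = 4, random_region = c(6, 10))
  sh <- shuffle_library(lib, seed = 1)
  expect_identical(substr(sh$reads, 1, 5), substr(lib$reads, 1, 5))
  expect_identical(substr(sh$reads, 16, 20), substr(lib$reads, 16, 20))
  sorted <- function(x, a, b) vapply(strsplit(substr(x, a, b), ""),
                                     function(s) paste(sort(s), collapse = ""),
                                     character(1))
  expect_identical(sorted(sh$reads, 6, 15), sorted(lib$reads, 6, 15))

  # all-A region is invariant under permutation
  mono <- LigandLibrary("AAAA")
  expect_identical(shuffle_library(mono, seed = 2)$reads, "AAAA")

  # reproducible by seed
  expect_identical(shuffle_library(lib, seed = 7)$reads,
                   shuffle_library(lib, seed = 7)$reads)
})

test_that("motif_enrichment is ~1 on a self-comparison and detects planted signal", {
  lib <- random_library(4000, 40, seed = 31)
  cons <- consensus_pwm("TGATTGCAATCA", purity = 0.9)
  # identical "shuffled" copy: ratio ~ 1
  e0 <- motif_enrichment(cons, lib, lib, p = 1e-3)
  expect_equal(e0$enrichment, e0$hits / (e0$hits + 1), tolerance = 1e-12)

  # planted motif in half the reads: strong enrichment vs real shuffle
  reads <- lib$reads
  substr(reads[1:2000], 11, 22) <- "TGATTGCAATCA"
  planted <- LigandLibrary(reads)
  e1 <- motif_enrichment(cons, planted, shuffle_library(planted, seed = 5))
  expect_gt(e1$enrichment, 2)

  # random PWM at stringent threshold on a null library: no real signal
  e2 <- motif_enrichment(random_pwm(8, seed = 55), lib,
                         shuffle_library(lib, seed = 6), p = 1e-4)
  expect_lt(e2$enrichment, 1.5)

  short <- random_library(100, 40, seed = 1)
  expect_error(motif_enrichment(cons, lib, short), "mismatched")
})

test_that("compare_methyl_pwms calls +, -, and . as specified", {
  norm <- consensus_pwm("TGATTGCAATCA", purity = 0.8)
  expect_true(all(compare_methyl_pwms(norm, norm)$call == "."))

  # raise C probability at position 5 in the methyl model -> "+"
  meth <- norm
  meth$matrix[, 5] <- c(0.1, 0.8, 0.05, 0.05)
  norm2 <- norm
  norm2$matrix[, 5] <- c(0.6, 0.3, 0.05, 0.05)
  cmp <- compare_methyl_pwms(norm2, meth)
  expect_equal(cmp$call[5], "+")
  expect_equal(cmp$preferred_normal[5], "A")
  expect_equal(cmp$preferred_methyl[5], "C")

  # lower C+G -> "-"
  cmp2 <- compare_methyl_pwms(meth, norm2)
  expect_equal(cmp2$call[5], "-")
})
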