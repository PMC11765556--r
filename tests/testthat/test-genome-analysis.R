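# Genomic context statistics: TSS density, target assignment, peak overlap
# with Fisher tests, top-peak motif containment, intensity contrasts.

test_that("tss_density spikes exactly at a planted offset and respects the IC filter", {
  # non-palindromic motif: an everted-repeat consensus is its own reverse
  # complement and would legitimately match both strands at each site
  motif <- "TGATTGCCGTCA"
  g <- simulate_genome(n_genes = 10, intergenic = 1000,
                       plant_motif = motif, plant_offset = -50, seed = 11)
  model <- consensus_pwm(motif)
  thr_p <- 4^-nchar(motif)   # admits exactly the consensus
  prof <- tss_density(g, model, W = 200, p = thr_p)[[1]]
  expect_equal(prof$density[prof$offset == -50], 1)
  expect_true(all(prof$density[prof$offset != -50] == 0))
  # integrates to assigned matches per gene over the window
  expect_equal(sum(prof$matches), 10)

  # a low-IC model is excluded
  flat <- pwm_model(matrix(0.25, 4, 8))
  expect_warning(out <- tss_density(g, flat, W = 100), "IC filter")
  expect_length(out, 0L)
})

test_that("minus-strand genes map matches to strand-oriented offsets", {
  motif <- "TGATTGCCGTCA"
  g <- simulate_genome(n_genes = 4, intergenic = 800,
                       plant_motif = motif, plant_offset = -50, seed = 2)
  model <- consensus_pwm(motif)
  prof <- tss_density(g, model, W = 100, p = 4^-12)[[1]]
  # both + and - genes contribute at -50 (4 genes, alternating strands)
  expect_equal(prof$matches[prof$offset == -50], 4)
})

test_that("assign_targets uses strand-oriented promoter windows on midpoints", {
  ann <- GenomeAnnotation(
    setNames(Biostrings::DNAStringSet(strrep("A", 10000)), "chr1"),
    data.frame(chrom = "chr1", pos = c(3000, 6000), strand = c("+", "-"),
               gene_id = c("g1", "g2")))
  matches <- data.frame(chrom = "chr1",
                        start = c(2990, 3100, 6100, 9000),
                        end = c(3002, 3112, 6112, 9012))
  tgt <- assign_targets(matches, ann, upstream = 1000, downstream = 200)
  expect_equal(unname(tgt["g1"]), 2L)   # -10 and +106 for the + gene
  expect_equal(unname(tgt["g2"]), 1L)   # -106 (upstream) for the - gene
  # match 3 kb away from every promoter stays unassigned
  expect_equal(sum(tgt), 3L)

  # divergent promoters both capture a shared upstream match
  ann2 <- GenomeAnnotation(
    setNames(Biostrings::DNAStringSet(strrep("A", 5000)), "chr1"),
    data.frame(chrom = "chr1", pos = c(2000, 2400), strand = c("-", "+"),
               gene_id = c("gl", "gr")))
  tgt2 <- assign_targets(data.frame(chrom = "chr1", start = 2195, end = 2207),
                         ann2)
  expect_equal(unname(tgt2), c(1L, 1L))
})

test_that("peak_overlap counts, symmetry, and the identity/disjoint cases", {
  gr <- function(starts, ends, chr = "chr1")
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                           signalValue = seq_along(starts))
  a <- gr(c(100, 500, 900), c(200, 600, 1000))
  b <- gr(c(150, 2000), c(260, 2100))

  ov <- peak_overlap(a, b)
  expect_equal(ov$unique_a, 2L)
  expect_equal(ov$unique_b, 1L)
  expect_equal(ov$shared, 1L)

  # swapping a and b swaps uniques, preserves shared and p
  ov2 <- peak_overlap(b, a)
  expect_equal(ov2$unique_a, ov$unique_b)
  expect_equal(ov2$unique_b, ov$unique_a)
  expect_equal(ov2$shared, ov$shared)
  expect_equal(ov2$p_value, ov$p_value)

  # identity: everything shared
  ovs <- peak_overlap(a, a)
  expect_equal(ovs$shared, 3L)
  expect_equal(ovs$unique_a + ovs$unique_b, 0L)

  # disjoint: nothing shared
  ovd <- peak_overlap(a, gr(c(3000, 4000), c(3100, 4100)))
  expect_equal(ovd$shared, 0L)

  expect_error(peak_overlap(a, gr(100, 200, chr = "chrX")), "chromosome")
})

test_that("Fisher p-value on the printed 2x2 table matches the hypergeometric closed form", {
  tab <- matrix(c(8, 2, 2, 8), 2)
  got <- fisher.test(tab)$p.value
  # independent oracle: two-sided hypergeometric enumeration at fixed margins
  k <- 0:10
  probs <- stats::dhyper(k, 10, 10, 10)
  oracle <- sum(probs[probs <= stats::dhyper(8, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, 0.023, tolerance = 0.002)
})

test_that("top-peak motif containment is exact on a constructed fixture", {
  motif <- "TGATTGCAATCA"
  model <- consensus_pwm(motif)
  thr <- score_threshold_for_pvalue(model, p = 4^-nchar(motif))
  ps <- simulate_peakset(n = 200, width = 100, motif = motif,
                         motif_fraction = 0.6, model = model,
                         threshold = thr, seed = 9)
  expect_warning(
    res <- top_peaks_motif_proportion(ps$peaks, ps$genome, model,
                                      top_n = 300, bins = 10,
                                      threshold = thr),
    "fewer than top_n")
  expect_equal(res$proportion, 0.6)
  expect_equal(res$n_used, 200L)
  expect_length(res$bin_proportions, 10L)
  expect_equal(mean(res$bin_proportions), 0.6, tolerance = 1e-9)
  # containment matches the generator's ground truth peak by peak
  ord <- peak_rank_order(ps$peaks)
  expect_identical(res$contains, ps$has_motif[ord])
})

test_that("peak intensity contrast: power, degenerate groups, markers", {
  motif_a <- "TGATTGCAATCA"; motif_b <- "CCGGAACCGGTT"
  model_a <- consensus_pwm(motif_a); model_b <- consensus_pwm(motif_b)
  mk <- function(int_a, int_b, seed) {
    n <- length(int_a) + length(int_b)
    ps <- simulate_peakset(n = n, width = 60, motif = motif_a,
                           motif_fraction = 0.5, seed = seed,
                           intensities = rep(1, n))
    # plant motif_b into the peaks lacking motif_a
    chrom <- as.character(ps$genome[[1]])
    st <- GenomicRanges::start(ps$peaks)
    for (i in which(!ps$has_motif))
      substr(chrom, st[i] + 20, st[i] + 19 + nchar(motif_b)) <- motif_b
    ps$genome <- setNames(Biostrings::DNAStringSet(chrom), "chrS")
    ps$peaks$signalValue <- NA_real_
    ps$peaks$signalValue[ps$has_motif] <- int_a
    ps$peaks$signalValue[!ps$has_motif] <- int_b
    ps
  }
  # clear separation: p << 0.001, marker "*"
  set.seed(1)
  ps <- mk(stats::rnorm(50, 20, 1), stats::rnorm(50, 10, 1), seed = 2)
  res <- peak_intensity_by_motif(ps$peaks, ps$genome, model_a, model_b,
                                 p = 4^-12)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$significance, "*")
  expect_gt(res$mean_a, res$mean_b)

  # identical singleton groups: undefined marker, no crash
  ps1 <- mk(1, 1, seed = 3)
  res1 <- peak_intensity_by_motif(ps1$peaks, ps1$genome, model_a, model_b,
                                  p = 4^-12)
  expect_equal(res1$significance, "undefined")
  expect_true(is.na(res1$p_value))
})

test_that("Welch test on null groups keeps its type-I error near nominal", {
  motif_a <- "TGATTGCAATCA"; motif_b <- "CCGGAACCGGTT"
  model_a <- consensus_pwm(motif_a); model_b <- consensus_pwm(motif_b)
  thr <- 4^-12
  ps0 <- simulate_peakset(n = 60, width = 60, motif = motif_a,
                          motif_fraction = 0.5, seed = 4,
                          intensities = rep(1, 60))
  chrom <- as.character(ps0$genome[[1]])
  st <- GenomicRanges::start(ps0$peaks)
  for (i in which(!ps0$has_motif))
    substr(chrom, st[i] + 20, st[i] + 19 + nchar(motif_b)) <- motif_b
  genome <- setNames(Biostrings::DNAStringSet(chrom), "chrS")
  set.seed(2024)
  rejections <- vapply(seq_len(200), function(r) {
    pk <- ps0$peaks
    pk$signalValue <- stats::rnorm(60, 10, 2)  # both groups null
    peak_intensity_by_motif(pk, genome, model_a, model_b,
                            p = thr)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.10)
})
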