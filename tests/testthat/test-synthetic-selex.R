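# Generative SELEX model: affinities, selection cycles, whole-series
# simulation, and the model's structural invariants.

test_that("binding_model validates its parameters", {
  expect_s3_class(binding_model(), "BindingModel")
  expect_error(binding_model(monomer_energy = matrix(0, 3, 4)), "6 x 4")
  bad <- gamma_map(5); bad["ER", 1] <- -1
  expect_error(binding_model(gamma = bad, methyl_gamma = gamma_map(5)), ">= 0")
  expect_error(binding_model(methyl_delta = c("9" = -1)), "0..7")
})

test_that("ligand_affinity is maximal at consensus and monotone in energy", {
  pad <- function(core) paste0("GGGGG", core, strrep("G", 30 - nchar(core)))
  mod <- binding_model(gamma = gamma_map(3, baseline = 0),
                       methyl_gamma = gamma_map(3, baseline = 0))
  w_cons <- ligand_affinity(mod, pad("CAATCA"))
  # single perfect site, gamma == 0: weight ~ monomer_weight * 1 (partly
  # overlapping windows contribute a little residual weight)
  expect_equal(w_cons, 1, tolerance = 0.05)
  # any single substitution scores strictly less
  for (p in 1:6) for (b in c("A", "C", "G", "T")) {
    core <- "CAATCA"
    if (substr(core, p, p) == b) next
    substr(core, p, p) <- b
    expect_lt(ligand_affinity(mod, pad(core)), w_cons)
  }

  # everted pair with gap 1 outweighs the same half-sites at gap 3 when
  # gamma peaks at (ER, 1)
  g <- gamma_map(5, baseline = 0, peaks = c(ER1 = 50))
  mod2 <- binding_model(gamma = g, methyl_gamma = g)
  expect_gt(ligand_affinity(mod2, pad("TGATTGACAATCA")),
            ligand_affinity(mod2, pad("TGATTGAAACAATCA")))

  # a negative methyl delta at a consensus C makes the methylated weight
  # strictly smaller for the same read
  mod3 <- binding_model(methyl_delta = c("1" = -1))
  expect_lt(ligand_affinity(mod3, pad("CAATCA"), methylated = TRUE),
            ligand_affinity(mod3, pad("CAATCA"), methylated = FALSE))

  expect_error(ligand_affinity(mod, "ACG"), "shorter")
})

test_that("selection preserves read geometry and is seed-reproducible", {
  mod <- binding_model()
  cfg <- sim_config(library_size = 500, cycles = 2, seed = 42)
  libs <- simulate_selex(cfg, mod)
  expect_length(libs, 3L)
  expect_equal(names(libs), c("cycle0", "cycle1", "cycle2"))
  expect_equal(vapply(libs, `[[`, integer(1), "cycle"), c(cycle0 = 0L, cycle1 = 1L, cycle2 = 2L))
  # length and alphabet unchanged by selection
  expect_true(all(nchar(libs$cycle2$reads) == nchar(libs$cycle0$reads[1])))
  expect_true(all(grepl("^[ACGT]+$", libs$cycle2$reads)))
  # all selected reads existed in the input pool
  expect_true(all(libs$cycle1$reads %in% libs$cycle0$reads))

  libs2 <- simulate_selex(cfg, mod)
  expect_identical(libs2$cycle2$reads, libs$cycle2$reads)

  # the methylated series shares cycle 0 with the unmethylated one
  cfgm <- sim_config(library_size = 500, cycles = 2, seed = 42,
                     methylated = TRUE)
  libsm <- simulate_selex(cfgm, mod)
  expect_identical(libsm$cycle0$reads, libs$cycle0$reads)
  expect_true(libsm$cycle0$methylated)
})

test_that("neutral selection is a uniform resample", {
  # flat energies, no cooperativity: planted k-mer frequency drifts but its
  # change is centred on zero across seeded runs
  flat <- binding_model(monomer_energy = matrix(0, 6, 4,
                          dimnames = list(1:6, c("A", "C", "G", "T"))),
                        gamma = gamma_map(2, baseline = 0),
                        methyl_gamma = gamma_map(2, baseline = 0))
  deltas <- vapply(1:20, function(sd) {
    cfg <- sim_config(library_size = 1000, cycles = 1, seed = sd,
                      plant_sequence = "CAGTCAGGTT", plant_fraction = 0.05)
    libs <- simulate_selex(cfg, flat)
    f <- vapply(libs, function(l) {
      tb <- count_kmers(l, 10)
      cnt <- tb$counts["CAGTCAGGTT"]
      (if (is.na(cnt)) 0 else cnt) / tb$total
    }, numeric(1))
    f[2] - f[1]
  }, numeric(1))
  # mean change within 3 standard errors of zero
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
})

test_that("planted consensus enriches under strong monomer selection", {
  # one-sided sign test over 20 seeds: frequency strictly increases
  mod <- binding_model(half_site = "CAGTCAGGTT",
                       monomer_energy = halfsite_energy_matrix("CAGTCAGGTT"),
                       gamma = gamma_map(2, baseline = 0),
                       methyl_gamma = gamma_map(2, baseline = 0),
                       monomer_weight = 5)
  ups <- vapply(1:20, function(sd) {
    cfg <- sim_config(library_size = 1000, cycles = 1, seed = sd,
                      plant_sequence = "CAGTCAGGTT", plant_fraction = 0.01)
    libs <- simulate_selex(cfg, mod)
    f <- vapply(libs, function(l) {
      cnt <- count_kmers(l, 10)$counts["CAGTCAGGTT"]
      ifelse(is.na(cnt), 0, cnt) / count_kmers(l, 10)$total
    }, numeric(1))
    f[2] > f[1]
  }, logical(1))
  bt <- binom.test(sum(ups), length(ups), alternative = "greater")
  expect_lt(bt$p.value, 0.05)

  # all weights at the floor: no binders
  gmod <- binding_model(half_site = "CCCCCC",
                        monomer_energy = halfsite_energy_matrix("CCCCCC",
                          mismatch = -100, degenerate = -100),
                        gamma = gamma_map(1, baseline = 0),
                        methyl_gamma = gamma_map(1, baseline = 0))
  lib <- LigandLibrary(rep(strrep("A", 30), 50))
  expect_error(run_selex_cycle(lib, gmod, sim_config(library_size = 50)),
               "no binders")
})

test_that("two-class selection matches the closed-form expected proportion", {
  # classes with weights (w1, w2) and counts (n1, n2) have expected
  # post-selection share n1 w1 / (n1 w1 + n2 w2); check by averaging
  # repeated cycles from the same input library
  mod <- binding_model(half_site = "CAGTCAGGTT",
                       monomer_energy = halfsite_energy_matrix("CAGTCAGGTT",
                         mismatch = -1, degenerate = -1),
                       gamma = gamma_map(1, baseline = 0),
                       methyl_gamma = gamma_map(1, baseline = 0),
                       monomer_weight = 1)
  flank <- strrep("G", 10)
  r1 <- paste0(flank, "CAGTCAGGTT", flank)       # perfect site
  r2 <- paste0(flank, "CAGTCAGGAA", flank)       # two mismatches
  reads <- c(rep(r1, 300), rep(r2, 700))
  w <- ligand_affinity(mod, reads)
  w1 <- w[1]; w2 <- w[301]
  expect_gt(w1, w2)
  expected <- (300 * w1) / (300 * w1 + 700 * w2)
  lib <- LigandLibrary(reads)
  cfg <- sim_config(library_size = 1000, selection_fraction = 0.5)
  set.seed(101)
  shares <- replicate(40, {
    out <- run_selex_cycle(lib, mod, cfg)
    mean(out$reads == r1)
  })
  expect_equal(mean(shares), expected, tolerance = 0.03)
})

test_that("with selection_fraction near 1 and flat energies the k-mer spectrum is stable", {
  flat <- binding_model(monomer_energy = matrix(0, 6, 4,
                          dimnames = list(1:6, c("A", "C", "G", "T"))),
                        gamma = gamma_map(2, baseline = 0),
                        methyl_gamma = gamma_map(2, baseline = 0))
  cfg <- sim_config(library_size = 4000, cycles = 5, seed = 17,
                    selection_fraction = 0.99)
  libs <- simulate_selex(cfg, flat)
  t0 <- count_kmers(libs$cycle0, 2)
  t5 <- count_kmers(libs$cycle5, 2)
  f0 <- t0$counts[sort(names(t0$counts))] / t0$total
  f5 <- t5$counts[sort(names(t0$counts))] / t5$total
  # all 16 dinucleotide frequencies equal within multinomial noise
  se <- sqrt(f0 * (1 - f0) / t5$total)
  expect_true(all(abs(f5 - f0) < 6 * se))
})

test_that("toy genome and peak simulators deliver their documented structure", {
  g <- simulate_genome(n_genes = 6, intergenic = 500,
                       plant_motif = "TGATTGCAATCA", plant_offset = -50,
                       seed = 3)
  expect_s3_class(g, "GenomeAnnotation")
  expect_equal(nrow(g$tss), 6L)
  chrom <- as.character(g$sequences[[1]])
  # plus-strand gene: motif planted at TSS - 50
  i <- which(g$tss$strand == "+")[1]
  expect_equal(substr(chrom, g$tss$pos[i] - 50 + 1, g$tss$pos[i] - 50 + 12),
               "TGATTGCAATCA")
  # minus-strand gene: reverse complement, 5'-most base at TSS + 50
  j <- which(g$tss$strand == "-")[1]
  expect_equal(substr(chrom, g$tss$pos[j] + 50 - 12 + 2, g$tss$pos[j] + 50 + 1),
               revcomp("TGATTGCAATCA"))

  ps <- simulate_peakset(n = 50, width = 80, motif = "TGATTGCAATCA",
                         motif_fraction = 0.4, seed = 5)
  expect_equal(sum(ps$has_motif), 20L)
  expect_length(ps$peaks, 50L)
  sv <- ps$peaks$signalValue
  expect_true(all(is.finite(sv) & sv >= 0))
})
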