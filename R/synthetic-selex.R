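# Generative model of SELEX / Methyl-SELEX with known ground truth.
#
# Occupancy is linear in Boltzmann weights: a read's selection weight is the
# sum of monomeric window weights plus cooperativity-weighted products of
# half-site window pairs, so exponential per-cycle enrichment of high-affinity
# classes falls out of the model rather than being imposed.

#' Half-site energy matrix from an IUPAC consensus
#'
#' Builds the monomer energy matrix of a [binding_model()]: the consensus
#' base of each position (via [iupac_consensus()], e.g. C at Y positions)
#' scores `match` (0 by convention), other bases allowed by the IUPAC
#' symbol score `degenerate`, and disallowed bases score `mismatch`
#' (negative log-affinity units). The preference for the C/G-containing
#' variant at degenerate positions matters: it is the cytosine-bearing
#' sites that methylation can act on, and it keeps instantiated half-sites
#' from being self-palindromic (an all-A/T half-site would match both
#' strands at once and let tandem AT repeats swamp the dimer signal).
#'
#' @param half_site IUPAC half-site string.
#' @param mismatch energy of a disallowed base (default -2).
#' @param degenerate energy of an allowed, non-consensus base (default -1).
#' @param match energy of the consensus base (default 0).
#' @return numeric matrix, one row per half-site position, columns A,C,G,T.
#' @export
halfsite_energy_matrix <- function(half_site, mismatch = -2,
                                   degenerate = -0.5, match = 0) {
  A <- iupac_allowed(half_site)
  E <- t(ifelse(A, degenerate, mismatch))
  colnames(E) <- .BASES
  rownames(E) <- seq_len(nrow(E))
  cons <- strsplit(iupac_consensus(half_site), "")[[1]]
  for (i in seq_len(nrow(E))) E[i, cons[i]] <- match
  E
}

#' Dimer cooperativity map
#'
#' A 3 x (max_spacing + 1) matrix (rows DR, IR, ER; columns spacings
#' 0..max_spacing) of cooperativity multipliers. `peaks` is a named numeric
#' vector keyed by configuration name (e.g. `c(ER1 = 60, ER0 = 30)`)
#' overriding the baseline.
#'
#' @param max_spacing largest half-site gap modelled.
#' @param baseline cooperativity of unnamed configurations.
#' @param peaks named numeric vector of configuration overrides.
#' @return numeric matrix of cooperativities.
#' @export
gamma_map <- function(max_spacing = 10, baseline = 2, peaks = numeric(0)) {
  G <- matrix(baseline, nrow = 3, ncol = max_spacing + 1,
              dimnames = list(c("DR", "IR", "ER"), 0:max_spacing))
  for (nm in names(peaks)) {
    cfg <- parse_dimer_name(nm)
    if (cfg$spacing > max_spacing) stop("spacing beyond max_spacing: ", nm)
    G[cfg$orientation, as.character(cfg$spacing)] <- peaks[[nm]]
  }
  G
}

.default_gamma <- function() {
  gamma_map(10, baseline = 0.25,
            peaks = c(ER1 = 80, ER0 = 10,
                      DR3 = 3, DR4 = 3, DR5 = 3,
                      IR6 = 1.5, IR7 = 1.5, IR8 = 1.5))
}

.default_methyl_gamma <- function() {
  gamma_map(10, baseline = 0.5,
            peaks = c(ER0 = 300, ER1 = 20,
                      DR3 = 6, DR4 = 6, DR5 = 6,
                      IR6 = 3, IR7 = 3, IR8 = 3))
}

#' Ground-truth binding model for the SELEX simulator
#'
#' Encodes, as explicit parameters, a factor that binds a short half-site as
#' a weak monomer and much more strongly as a DNA-scaffolded homodimer whose
#' cooperativity depends on the relative orientation (DR/IR/ER) and spacing
#' of the half-sites, and whose binding responds to full cytosine
#' methylation of the library in two ways:
#'
#' * `methyl_delta` shifts the energy of C (and of G, carrying the 5mC of
#'   the complementary strand) at given half-site window positions, position
#'   0 and `h + 1` being the immediate 5'/3' flanks. The default penalises C
#'   at half-site position 1, inhibiting the monomeric C-variants.
#' * `methyl_gamma` replaces `gamma` when the library is methylated:
#'   methylation of the half-site junction alters the DNA scaffold and hence
#'   the spacing preference of dimerisation. The defaults enhance dimer
#'   cooperativity overall and move its peak from ER1 to ER0. A purely
#'   additive per-window energy delta cannot represent such a spacing switch
#'   (any delta the zero-gap junction can realise, a free one-base spacer
#'   realises equally), which is why the cooperativity map itself is allowed
#'   to depend on the methylation state.
#'
#' The unmethylated defaults rank configurations ER1 > ER0 > DR3-5 > IR6-8,
#' the methylated ones ER0 > ER1.
#'
#' @param half_site IUPAC half-site (default `"YAATYA"`).
#' @param monomer_energy matrix from [halfsite_energy_matrix()].
#' @param gamma cooperativity map (rows DR/IR/ER x spacings), see
#'   [gamma_map()].
#' @param methyl_gamma cooperativity map used when the library is methylated.
#' @param methyl_delta named numeric vector: names are window positions
#'   (0 = 5' flank, 1..h half-site, h+1 = 3' flank), values are energies
#'   added to C and G there under methylation.
#' @param monomer_weight scalar multiplier of the monomeric occupancy term.
#' @param energy_floor windows scoring below this contribute nothing.
#' @return an object of class `BindingModel`.
#' @export
binding_model <- function(half_site = "YAATYA",
                          monomer_energy = halfsite_energy_matrix(half_site),
                          gamma = .default_gamma(),
                          methyl_gamma = .default_methyl_gamma(),
                          methyl_delta = c("1" = -1),
                          monomer_weight = 1,
                          energy_floor = -10) {
  h <- nchar(half_site)
  if (nrow(monomer_energy) != h || ncol(monomer_energy) != 4L)
    stop("monomer_energy must be ", h, " x 4")
  for (G in list(gamma, methyl_gamma)) {
    if (!all(rownames(G) == c("DR", "IR", "ER")))
      stop("gamma rows must be DR, IR, ER")
    if (any(!is.finite(G)) || any(G < 0))
      stop("gamma values must be finite and >= 0")
  }
  if (length(methyl_delta)) {
    pos <- suppressWarnings(as.integer(names(methyl_delta)))
    if (any(is.na(pos)) || any(pos < 0L) || any(pos > h + 1L))
      stop("methyl_delta positions must lie in 0..", h + 1L,
           " (0 and ", h + 1L, " are the flanks)")
  }
  structure(list(half_site = toupper(half_site),
                 monomer_energy = monomer_energy,
                 gamma = gamma, methyl_gamma = methyl_gamma,
                 methyl_delta = methyl_delta,
                 monomer_weight = monomer_weight,
                 energy_floor = energy_floor),
            class = "BindingModel")
}

#' @export
print.BindingModel <- function(x, ...) {
  top <- function(G) {
    i <- which(G == max(G), arr.ind = TRUE)[1, ]
    paste0(rownames(G)[i[1]], colnames(G)[i[2]])
  }
  cat(sprintf("BindingModel: half-site %s | top gamma %s (unmeth) / %s (meth)\n",
              x$half_site, top(x$gamma), top(x$methyl_gamma)))
  invisible(x)
}

#' Simulation settings for a SELEX series
#'
#' @param random_len length of the randomised region (nt).
#' @param library_size reads per cycle after amplification.
#' @param cycles number of selection cycles.
#' @param selection_fraction fraction of the library drawn (by affinity) at
#'   each selection step, before re-amplification; in (0, 1).
#' @param seed RNG seed for the series.
#' @param flank5,flank3 fixed flanking sequences (defaults are the PCR primer
#'   sequences of a typical SELEX library design).
#' @param methylated simulate a fully 5mC-methylated series.
#' @param plant_sequence optional sequence planted into a fraction of
#'   cycle-0 reads (at a random offset within the randomised region).
#' @param plant_fraction fraction of cycle-0 reads carrying the plant.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(random_len = 40L, library_size = 10000L, cycles = 5L,
                       selection_fraction = 0.3, seed = 1L,
                       flank5 = "CCCTACACGACGCTCTTCC",
                       flank3 = "CGGAAGAGCACACGTCTG",
                       methylated = FALSE,
                       plant_sequence = NULL, plant_fraction = 0) {
  if (selection_fraction <= 0 || selection_fraction >= 1)
    stop("selection_fraction must be in (0, 1)")
  if (cycles < 1L) stop("cycles must be >= 1")
  if (random_len < 1L) stop("random_len must be >= 1")
  if (!is.null(plant_sequence) && nchar(plant_sequence) > random_len)
    stop("plant_sequence longer than the randomised region")
  structure(list(random_len = as.integer(random_len),
                 library_size = as.integer(library_size),
                 cycles = as.integer(cycles),
                 selection_fraction = selection_fraction,
                 seed = as.integer(seed),
                 flank5 = toupper(flank5), flank3 = toupper(flank3),
                 methylated = isTRUE(methylated),
                 plant_sequence = if (is.null(plant_sequence)) NULL
                                  else toupper(plant_sequence),
                 plant_fraction = plant_fraction),
            class = "SimConfig")
}

# Extended-window weights (exp energies, floored to 0) for every window
# start, forward and reverse-complement orientation. The energy window is
# the half-site plus one flank base on each side; reads are padded with a
# neutral code so edge windows keep their core contributions.
.halfsite_weights <- function(model, codes, methylated) {
  h <- nrow(model$monomer_energy)
  we <- h + 2L
  E <- matrix(0, we, 4L)
  E[2:(h + 1L), ] <- model$monomer_energy
  if (methylated && length(model$methyl_delta)) {
    pos <- as.integer(names(model$methyl_delta))
    for (q in seq_along(pos)) {
      r <- pos[q] + 1L
      E[r, 2L] <- E[r, 2L] + model$methyl_delta[[q]]  # C
      E[r, 3L] <- E[r, 3L] + model$methyl_delta[[q]]  # G (5mC on minus strand)
    }
  }
  Erc <- E[we:1, 4:1]
  padded <- cbind(0L, codes, 0L)
  Sf <- cpp_window_scores(padded, E)
  Sr <- cpp_window_scores(padded, Erc)
  Wf <- exp(Sf); Wf[Sf < model$energy_floor] <- 0
  Wr <- exp(Sr); Wr[Sr < model$energy_floor] <- 0
  list(fwd = Wf, rev = Wr, h = h)
}

#' Selection weight of reads under a binding model
#'
#' The weight of a read is
#' `monomer_weight * sum(exp(E_window))` over both strands, plus
#' `sum(gamma(orientation, spacing) * exp(E_1 + E_2))` over ordered window
#' pairs, where strand pair (+,+)/(-,-) is a direct repeat, (+,-) an
#' inverted repeat (head-to-head) and (-,+) an everted repeat
#' (tail-to-tail). Windows scoring below the model's energy floor
#' contribute nothing; every read receives an additive pseudo-weight of
#' 1e-9 so weights stay positive.
#'
#' @param model a [binding_model()].
#' @param reads character vector of reads, or a [LigandLibrary].
#' @param methylated logical; defaults to the library's flag when `reads`
#'   is a [LigandLibrary], else FALSE.
#' @return numeric vector of positive weights, one per read.
#' @export
ligand_affinity <- function(model, reads, methylated = NULL) {
  if (inherits(reads, "LigandLibrary")) {
    if (is.null(methylated)) methylated <- reads$methylated
    reads <- reads$reads
  }
  if (is.null(methylated)) methylated <- FALSE
  h <- nrow(model$monomer_energy)
  if (any(nchar(reads) < h))
    stop("read shorter than the half-site (", h, " nt)")
  codes <- encode_seqs(reads)
  W <- .halfsite_weights(model, codes, methylated)
  weight <- model$monomer_weight * (rowSums(W$fwd) + rowSums(W$rev))
  G <- if (methylated) model$methyl_gamma else model$gamma
  K <- ncol(W$fwd)
  for (s in as.integer(colnames(G))) {
    d <- h + s
    if (d + 1L > K) next
    i1 <- seq_len(K - d); i2 <- i1 + d
    gDR <- G["DR", as.character(s)]
    gIR <- G["IR", as.character(s)]
    gER <- G["ER", as.character(s)]
    if (gDR > 0)
      weight <- weight + gDR *
        (rowSums(W$fwd[, i1, drop = FALSE] * W$fwd[, i2, drop = FALSE]) +
         rowSums(W$rev[, i1, drop = FALSE] * W$rev[, i2, drop = FALSE]))
    if (gIR > 0)
      weight <- weight + gIR *
        rowSums(W$fwd[, i1, drop = FALSE] * W$rev[, i2, drop = FALSE])
    if (gER > 0)
      weight <- weight + gER *
        rowSums(W$rev[, i1, drop = FALSE] * W$fwd[, i2, drop = FALSE])
  }
  weight + 1e-9
}

#' One SELEX cycle: selection then amplification
#'
#' Draws `round(selection_fraction * N)` reads multinomially with
#' probability proportional to [ligand_affinity()], then resamples with
#' replacement back to `library_size` (PCR without an error model). Uses
#' the current RNG state; [simulate_selex()] seeds it.
#'
#' @param library input [LigandLibrary].
#' @param model a [binding_model()].
#' @param cfg a [sim_config()].
#' @return the selected, re-amplified [LigandLibrary] (cycle + 1).
#' @export
run_selex_cycle <- function(library, model, cfg) {
  w <- ligand_affinity(model, library)
  if (max(w) <= 1e-9 * (1 + 1e-6)) stop("no binders: all weights at the floor")
  n <- length(library$reads)
  n_sel <- max(1L, round(cfg$selection_fraction * n))
  sel <- sample.int(n, n_sel, replace = TRUE, prob = w)
  amp <- sel[sample.int(n_sel, cfg$library_size, replace = TRUE)]
  LigandLibrary(library$reads[amp], cycle = library$cycle + 1L,
                methylated = library$methylated,
                random_region = library$random_region,
                label = library$label)
}

#' Simulate a full SELEX or Methyl-SELEX series
#'
#' Cycle 0 is i.i.d. uniform over ACGT in the randomised region (optionally
#' with a planted sequence in a fraction of reads); later cycles come from
#' [run_selex_cycle()]. Running the function twice with the same `cfg`
#' (including seed) reproduces the series exactly; the unmethylated and
#' methylated series generated from the same seed share their cycle-0
#' library.
#'
#' @param cfg a [sim_config()].
#' @param model a [binding_model()].
#' @return named list of [LigandLibrary] objects, `cycle0` .. `cycleC`.
#' @export
simulate_selex <- function(cfg, model) {
  set.seed(cfg$seed)
  n <- cfg$library_size
  len <- cfg$random_len
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  regions <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  if (!is.null(cfg$plant_sequence) && cfg$plant_fraction > 0) {
    k <- round(cfg$plant_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      wp <- nchar(cfg$plant_sequence)
      off <- sample.int(len - wp + 1L, k, replace = TRUE)
      substring(regions[idx], off, off + wp - 1L) <- cfg$plant_sequence
    }
  }
  reads <- paste0(cfg$flank5, regions, cfg$flank3)
  lib <- LigandLibrary(reads, cycle = 0L, methylated = cfg$methylated,
                       random_region = c(nchar(cfg$flank5) + 1L, len),
                       label = if (cfg$methylated) "methyl-selex" else "selex")
  out <- vector("list", cfg$cycles + 1L)
  out[[1]] <- lib
  for (i in seq_len(cfg$cycles)) out[[i + 1L]] <- run_selex_cycle(out[[i]], model, cfg)
  names(out) <- paste0("cycle", 0:cfg$cycles)
  out
}

#' Write a binding model as a JSON sidecar
#'
#' Serialises the ground truth next to simulated libraries so downstream
#' assertions can compare recovered parameters with the generator.
#'
#' @param model a [binding_model()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_binding_model_json <- function(model, path) {
  x <- list(half_site = model$half_site,
            monomer_energy = model$monomer_energy,
            gamma = model$gamma,
            methyl_gamma = model$methyl_gamma,
            methyl_delta = as.list(model$methyl_delta),
            monomer_weight = model$monomer_weight,
            energy_floor = model$energy_floor)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a toy annotated genome
#'
#' A single random chromosome with `n_genes` regularly spaced genes of
#' alternating strand. When `plant_motif` is given, its consensus is placed
#' at the same strand-oriented offset relative to every TSS (upstream
#' negative), which gives [tss_density()] a known spike to recover.
#'
#' @param n_genes number of genes.
#' @param intergenic spacing between consecutive TSSs (bp).
#' @param plant_motif optional sequence planted near every TSS.
#' @param plant_offset strand-oriented offset of the planted motif's 5' base
#'   relative to the TSS (default -50).
#' @param seed RNG seed.
#' @return a [GenomeAnnotation].
#' @export
simulate_genome <- function(n_genes = 20, intergenic = 2000,
                            plant_motif = NULL, plant_offset = -50,
                            seed = 1) {
  set.seed(seed)
  len <- (n_genes + 1L) * intergenic
  chrom <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
  tss <- data.frame(chrom = "chr1",
                    pos = intergenic * seq_len(n_genes),
                    strand = rep(c("+", "-"), length.out = n_genes),
                    gene_id = sprintf("gene%02d", seq_len(n_genes)))
  if (!is.null(plant_motif)) {
    w <- nchar(plant_motif)
    for (i in seq_len(n_genes)) {
      if (tss$strand[i] == "+") {
        s0 <- tss$pos[i] + plant_offset            # 0-based plant start
        ins <- plant_motif
      } else {
        s0 <- tss$pos[i] - plant_offset - w + 1L
        ins <- revcomp(plant_motif)
      }
      substr(chrom, s0 + 1L, s0 + w) <- ins
    }
  }
  GenomeAnnotation(setNames(Biostrings::DNAStringSet(chrom), "chr1"), tss)
}

#' Simulate a toy peak set with known motif content
#'
#' Generates `n` peak sequences on one synthetic chromosome; a fixed
#' fraction carries the given motif consensus (planted at a random internal
#' offset, random strand) and the remaining peaks are redrawn until they
#' contain no match, so the motif-bearing fraction is exact by
#' construction. Intensities are drawn from `intensity_fun` unless supplied.
#'
#' @param n number of peaks.
#' @param width peak width (bp).
#' @param motif consensus sequence planted into motif-bearing peaks.
#' @param motif_fraction exact fraction of peaks carrying the motif.
#' @param model,threshold optional [pwm_model] plus threshold (from
#'   [score_threshold_for_pvalue()]) used to screen motif-free peaks;
#'   when absent, screening is by exact string match of `motif` and its
#'   reverse complement.
#' @param gap gap between consecutive peaks on the chromosome (bp).
#' @param intensities optional numeric vector of peak intensities.
#' @param seed RNG seed.
#' @return list with `genome` (a `DNAStringSet`), `peaks` (a `GRanges` with
#'   `signalValue`) and `has_motif` (logical ground truth).
#' @export
simulate_peakset <- function(n = 100, width = 100, motif,
                             motif_fraction = 0.6,
                             model = NULL, threshold = NULL, gap = 20,
                             intensities = NULL, seed = 1) {
  set.seed(seed)
  n_with <- round(motif_fraction * n)
  has <- rep(FALSE, n); has[sample.int(n, n_with)] <- TRUE
  wm <- nchar(motif)
  clean <- function(s) {
    if (!is.null(model) && !is.null(threshold))
      return(sum(count_motif_hits(model, s, threshold)) == 0)
    !grepl(motif, s, fixed = TRUE) && !grepl(revcomp(motif), s, fixed = TRUE)
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(.BASES, width, replace = TRUE), collapse = "")
      if (has[i]) {
        off <- sample.int(width - wm + 1L, 1L)
        ins <- if (sample.int(2L, 1L) == 1L) motif else revcomp(motif)
        substr(s, off, off + wm - 1L) <- ins
        break
      }
      if (clean(s)) break
    }
    seqs[i] <- s
  }
  pad <- strrep("A", gap)
  chrom <- paste(vapply(seqs, function(s) paste0(s, pad), character(1)),
                 collapse = "")
  starts <- (seq_len(n) - 1L) * (width + gap) + 1L
  if (is.null(intensities)) intensities <- round(stats::rexp(n, 1 / 5) + 1, 3)
  peaks <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(starts, starts + width - 1L),
                                  signalValue = intensities)
  list(genome = setNames(Biostrings::DNAStringSet(chrom), "chrS"),
       peaks = peaks, has_motif = has)
}
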