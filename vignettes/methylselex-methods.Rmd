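---
title: "Models and methods behind methylselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylselex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A homeodomain transcription factor that recognises a short half-site
(`YAATYA`, six nucleotides, Y = C/T) can bind DNA as a weak monomer or as a
DNA-scaffolded homodimer, with the two half-sites arranged as direct (DR),
inverted (IR) or everted (ER) repeats separated by a gap of 0 or more base
pairs; a dimeric element is named by orientation plus gap, e.g. `ER0` or
`DR3`. Because the protein-level dimer interface is weak, the DNA scaffold —
including its cytosine-methylation state — co-determines which arrangement
binds best. Full 5mC methylation of a SELEX library (every C on both strands)
both shifts the base preferences within the half-site and changes the
preferred dimer spacing.

`methylselex` implements the downstream analysis used to establish these
observations from HT-SELEX / Methyl-SELEX read sets and DAP-seq peak lists:
k-mer enrichment trajectories, E-MI, seed-based PWM construction with exact
p-value thresholds, the dimer-configuration grammar, methyl-vs-normal
positional comparison, TSS-proximity profiles, and peak statistics. It also
ships a generative SELEX simulator with explicit ground truth so that every
stage can be validated at desk scale.

# The generative SELEX model

A `binding_model()` assigns each read a positive selection weight:

* **Monomer term.** Every window (half-site plus one flanking base on each
  side, both strands) gets an additive energy: 0 for the consensus base,
  -0.5 for a degenerate-but-allowed base (the T of a Y position), -2 for a
  disallowed base, in dimensionless log-affinity units. The monomeric
  occupancy is `monomer_weight` times the sum of Boltzmann factors
  `exp(E)` over windows; windows below the energy floor (-10) contribute
  nothing, which only removes terms smaller than `exp(-10)`.
* **Dimer term.** Every ordered pair of windows at gap `s` contributes
  `gamma(orientation, s) * exp(E1 + E2)`, with strand pairs (+,+)/(-,-)
  read as DR, (+,-) as IR and (-,+) as ER. Occupancy is linear in the
  Boltzmann weights (no saturation): this is the simplest model that makes
  the per-cycle enrichment of a read class proportional to its relative
  affinity, hence exponential across cycles.
* **Methylation.** Two parameter sets move when the library-level 5mC flag
  is on. `methyl_delta` adds position-specific energies to C (and to G,
  which carries the 5mC of the complementary strand); the default, -1 at
  half-site position 1, inhibits the monomeric C-variants, so methylation
  weakens monomer binding overall while leaving the T-variant intact.
  `methyl_gamma` replaces the cooperativity map: methylation enhances
  dimerisation overall and moves its peak from `ER1` to `ER0`. The spacing
  switch must live in the cooperativity map: for any additive per-window
  delta, every energy bonus the zero-gap junction can realise through its
  constrained consensus bases is realised equally well by a one-gap
  element through its free spacer base, so the maxima of all spacings
  shift together and their ranking cannot flip. Physically the map change
  reads as 5mC at the junction altering the DNA shape that scaffolds the
  dimer.

One selection cycle (`run_selex_cycle()`) draws
`round(selection_fraction * N)` reads multinomially with probability
proportional to weight, then resamples with replacement back to
`library_size` (PCR without an error model — substitutions would blur the
ground truth without serving any tested claim). Cycle 0 is i.i.d. uniform
over ACGT in the randomised region, with fixed primer-derived flanks, and
optionally a planted sequence in a chosen fraction of reads.

## Default parameters and why

The defaults are the conditions under which the package's own validation
runs: libraries of 10,000 reads with a 40 nt randomised region, five
selection cycles, both series generated from one ground truth.

* **Half-site energies 0 / -0.5 / -2.** The preference for the
  C/G-containing consensus at the degenerate Y positions matters twice:
  only cytosine-bearing sites can respond to methylation, and an all-A/T
  half-site instance (`TAATTA`) is its own reverse complement, so without
  the preference, AT-rich tandem arrays satisfy every orientation at once
  and swamp the dimer channel.
* **Cooperativities** (unmethylated: `ER1` 80, `ER0` 10, `DR3-5` 3,
  `IR6-8` 1.5, baseline 0.25; methylated: peak on `ER0`, `ER1` 20, the
  rest doubled). The qualitative ordering — everted peak, then narrow DRs
  and mid-range IRs, monomer weakest — encodes the biology; the magnitudes
  are set by desk-scale statistics. In a 10,000-read library the exact
  occurrences of a 12 bp dimer footprint are Poisson with mean about 0.5
  per configuration, so recovery of the preferred configuration must not
  hinge on which configuration won the founder lottery: the peak-to-
  runner-up cooperativity gap is set wider than the per-mismatch Boltzmann
  factor `exp(2)`, which is what makes the ranking reproducible across
  seeds rather than driven by one lucky exact founder.
* **`selection_fraction` 0.3.** Expected per-cycle enrichment ratios do
  not depend on the retained fraction, but their variance does: at 5%
  retention the multinomial selection step loses a substantial share of
  the rare 1-mismatch founders outright. 30% keeps them with high
  probability while still selecting strongly.

## What the simulator does and does not emulate

It emulates: exponential enrichment of high-affinity classes; the
dependence of dimeric signal on orientation and spacing; the monomer
channel; methylation acting on both strands; planted spikes for calibration
experiments. It does not emulate sequencing error, PCR substitution bias,
bead-capture kinetics or protein-concentration titration, and a 10,000-read
library is about three orders of magnitude shallower than a sequenced SELEX
pool — final simulated libraries are therefore far more clonal than real
ones. Passing tests show the algorithms recover a known ground truth under
these conditions; they do not certify performance on any particular real
dataset.

## The exponential-enrichment demonstration

The log-linearity of k-mer trajectories is demonstrated with a dedicated
configuration rather than the headline model: a 10-nt site bound only as a
monomer with soft mismatch energies (-0.7 per mismatch), planted into 0.5%
of cycle-0 reads. Those parameters keep the planted class's per-cycle
enrichment factor near 2, so it stays a minority through all five cycles
and its log2-frequency trajectory is a clean straight line; under the
headline cooperativities a planted consensus would saturate the library
within two cycles and the trajectory would bend. Both regimes are the same
model — only the ratio of the planted class's weight to the library mean
differs.

# Motif construction and matching

`build_pwm_from_seed()` uses multinomial seed counting: column `c` is
filled from windows (both strands) that match the IUPAC seed at every other
position with at most `multinomial_level - 1` extra mismatches. The package
defaults to level 2 rather than the classical level 1: with exact
occurrences of a gapped 12-17 nt seed essentially absent at desk scale,
level 1 degenerates (1-mismatch windows feed only their mismatched column
and every other column stays at the pseudocount), whereas level 2 lets the
dominant 1-mismatch instances fill the whole matrix. Counts get a
pseudocount of 1 per cell; cycle-0 background counts, scaled to equal
contributing-window totals, are subtracted with a floor at the pseudocount.

`score_threshold_for_pvalue()` computes exact match thresholds: log-odds
scores (PWM probabilities floored at 1e-6 against the background) are
rounded onto a lattice of 20,000 levels spanning the score range, the exact
null distribution of a background w-mer's lattice score is obtained by
column-wise convolution, and the threshold is the smallest score whose tail
probability is at most the requested p (1e-5 for motif matching, following
standard SELEX practice). Matching uses the same lattice, so threshold and
scan semantics agree exactly; the brute-force enumeration over all `4^w`
sequences reproduces the DP tail to numerical precision in the test suite.

Motif enrichment divides the hit count in a library by the hit count in its
mononucleotide-shuffled counterpart (randomised region permuted per read,
flanks intact, composition exactly preserved), pseudocounted by +1.

## The dimer-configuration survey

`rank_dimer_configs()` enumerates all DR/IR/ER seeds up to a maximal
spacing (default 10), fits each seed's PWM against cycle 0, and ranks
configurations by shuffled-library enrichment. Deeply selected desk-scale
libraries are nearly clonal, so several configuration models can converge
onto the same amplified reads; three guards keep the ranking meaningful:

* **Matched threshold stringency.** Survey thresholds use the `"closest"`
  rule of `score_threshold_for_pvalue()`: the lattice level whose tail
  probability is nearest the target p on the log scale. With the one-sided
  at-most rule, a very sharp single-lineage model overshoots the target by
  orders of magnitude, its shuffled-library hit count collapses to Poisson
  noise around zero, and enrichment ratios across models stop being
  comparable.
* **Self-consistency.** A fitted model is kept only if its consensus still
  classifies (one mismatch allowed) to the configuration's own name.
  Without this, a configuration with no genuine support converges onto a
  shifted or strand-symmetrised copy of the dominant motif, assembled from
  chance near-matches on highly amplified reads.
* **Read-level support.** Every read is classified once by
  `classify_probe()`, and a configuration must be the best assignment of a
  minimal number of reads (10, or 0.1% of the library). A read carrying a
  genuine everted site plus a chance half-site nearby feeds a second
  configuration's PWM with near-matches, but the grammar's
  mismatch-minimising classification names the true arrangement, so the
  shadow configuration ends up unsupported and is demoted below supported
  models.
* **Tie-breaks.** `classify_probe()` resolves competing half-site pairs by
  fewest mismatches, then smallest spacing, then orientation (ER, IR, DR),
  then position. The orientation step keeps classification invariant under
  reverse complementation and resolves palindromic half-site instances —
  which satisfy all three orientations simultaneously — toward the everted
  reading, this factor family's dominant dimeric mode.

# E-MI

For every non-overlapping pair of 3-mer start positions within the
randomised region, the 64 x 64 joint table over reads (pseudocount 1 per
cell) yields the sum of pointwise mutual information over the ten most
frequent 3-mer pairs. Under independence this plug-in estimator retains a
small positive bias from selecting the largest cells — at 10,000 reads the
per-pair null level is below 0.01 bits on average, with maxima slightly
above — while genuine positional dependence (a fixed 6-mer planted at two
overlapping 3-mer frames) scores more than an order of magnitude higher and
peaks exactly at the planted position pair. The definition is recorded in
the `emi()` output so results are self-describing.

# Genomic statistics

TSS-proximity profiles count matches per gene per bp at strand-oriented
offsets (upstream negative, the offset of a match being its 5'-most base in
the gene's orientation), with per-offset gene counts adjusted for contig
truncation; models are pre-filtered at mean IC > 0.3, the display threshold
used for motif surveys. The promoter window for target-gene assignment is
-1000/+200 around the TSS (configurable; the midpoint of a match decides
membership). Peak-set overlaps are tested with Fisher's exact test on a
2x2 table built by tiling the genome into bins of the pooled median peak
width and cross-tabulating bin coverage — the table construction is
recorded in the result object since overlap tables can be built in several
ways. "Top 3000 peaks" are taken by descending narrowPeak `signalValue`
with ties broken by chromosome and start; per-bin containment proportions
over ten rank-contiguous bins provide the replicate structure for t-tests
between libraries, and peak-intensity contrasts between motif-exclusive
peak groups use Welch's t-test, two-sided, with significance marked at
p <= 0.05.

# Problem sizes

The packaged validation works at desk scale: simulated libraries of 10,000
reads and 5 cycles, twenty seeded replicates for the configuration-switch
experiment, toy genomes of tens of kilobases, and peak fixtures of up to
3,000 intervals. These sizes were chosen so a full validation run completes
on a laptop while keeping every statistical check adequately powered.

# Known limitations

* Final simulated libraries are clonal compared to real SELEX pools; an
  occasional incidental half-site arrangement inside a winning lineage can
  rival the true configuration's enrichment ratio in a single run, which
  is why the configuration-switch validation is assessed across seeds.
* The enrichment ratio inherits Poisson noise from small shuffled-library
  hit counts; ratios among strongly enriched models should be read
  qualitatively at this depth.
* The simulator's energies and cooperativities are simulator parameters,
  not estimates of any protein's biochemistry.
* Methylation is a library-level state (fully methylated or not), matching
  the 5mC-PCR protocols; sparse genomic methylation patterns are out of
  scope.
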