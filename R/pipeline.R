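# End-to-end orchestration: simulate (or load) the SELEX and Methyl-SELEX
# series, run the k-mer, E-MI, motif and dimer-configuration analyses, and
# write a machine-readable summary naming the top-enriched dimeric
# configuration of each library.

.pipeline_defaults <- list(
  cycles = 5L, library_size = 10000L, random_len = 40L,
  selection_fraction = 0.05, half_site = "YAATYA", max_spacing = 10L,
  kmer_k = 10L, compare_k = c(8L, 12L), top_n_kmers = 100L,
  motif_p = 1e-5, trajectory_top = 10L)

#' Run the full SELEX/Methyl-SELEX analysis pipeline
#'
#' Given a configuration (a list, or the path of a YAML file with the same
#' keys), simulates an unmethylated and a fully methylated SELEX series
#' from one ground-truth binding model, writes per-cycle FASTA files, and
#' runs the downstream analyses: per-cycle k-mer tables and enrichment
#' trajectories with log-linear fits, cross-library 8-mer/12-mer
#' comparison, E-MI of the final libraries, the dimer-configuration survey
#' (seed PWMs in MEME format, enrichment ranking), and the
#' methyl-vs-normal positional comparison of the shared top configurations.
#' All results land in `outdir`; `summary.json` names the top-enriched
#' dimeric configuration per library. The run is fully deterministic given
#' the configuration (including its seed): identical runs produce
#' byte-identical summaries.
#'
#' Mandatory keys: `outdir`, `seed`. Optional keys (with defaults):
#' `cycles` (5), `library_size` (10000), `random_len` (40),
#' `selection_fraction` (0.05), `half_site` ("YAATYA"), `max_spacing` (10),
#' `kmer_k` (10), `compare_k` (8, 12), `top_n_kmers` (100), `motif_p`
#' (1e-5), plus an optional `model` list passed to [binding_model()].
#' Alternatively `normal_fasta`/`methyl_fasta` (character vectors of
#' per-cycle read files, cycle 0 first) with `random_region`, to analyse
#' real libraries instead of simulating.
#'
#' @param config list or YAML file path.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("outdir", "seed"))
    if (is.null(config[[key]])) stop("missing mandatory config key: ", key)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  if (cfg$cycles < 2L) stop("need >=2 cycles for enrichment")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  model <- if (is.null(cfg$model)) binding_model(half_site = cfg$half_site)
           else do.call(binding_model, cfg$model)

  series <- list()
  if (!is.null(cfg$normal_fasta)) {
    load_series <- function(paths, methylated) {
      lapply(seq_along(paths), function(i)
        read_sequences(paths[i], random_region = cfg$random_region,
                       methylated = methylated, cycle = i - 1L))
    }
    series$normal <- load_series(cfg$normal_fasta, FALSE)
    if (!is.null(cfg$methyl_fasta))
      series$methylated <- load_series(cfg$methyl_fasta, TRUE)
  } else {
    mk <- function(methylated) sim_config(
      random_len = cfg$random_len, library_size = cfg$library_size,
      cycles = cfg$cycles, selection_fraction = cfg$selection_fraction,
      seed = cfg$seed, methylated = methylated)
    series$normal <- simulate_selex(mk(FALSE), model)
    series$methylated <- simulate_selex(mk(TRUE), model)
    write_binding_model_json(model, file.path(cfg$outdir, "ground_truth.json"))
    for (nm in names(series))
      for (cyc in names(series[[nm]]))
        write_sequences(series[[nm]][[cyc]],
                        file.path(cfg$outdir, sprintf("%s_%s.fasta", nm, cyc)))
  }

  summary <- list(config = cfg[setdiff(names(cfg), "outdir")])
  tables_k <- list()
  for (nm in names(series)) {
    libs <- series[[nm]]
    final <- libs[[length(libs)]]

    # per-cycle k-mer tables and trajectories of the top final-cycle k-mers
    tabs <- lapply(libs, count_kmers, k = cfg$kmer_k)
    topk <- names(sort(tabs[[length(tabs)]]$counts, decreasing = TRUE))[
      seq_len(cfg$trajectory_top)]
    traj <- t(vapply(topk, function(km) enrichment_trajectory(tabs, km),
                     numeric(length(tabs))))
    fits <- lapply(topk, function(km) {
      tr <- enrichment_trajectory(tabs, km)
      fit_log_linear(tr, pseudo = 0.5 / tabs[[1]]$total)
    })
    traj_df <- data.frame(kmer = topk, traj,
                          slope = vapply(fits, `[[`, numeric(1), "slope"),
                          r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
    names(traj_df)[2:(length(tabs) + 1L)] <- paste0("cycle", seq_along(tabs) - 1L)
    write.table(traj_df, file.path(cfg$outdir, sprintf("%s_trajectories.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)

    # E-MI of the final library
    write_emi_tsv(emi(final), file.path(cfg$outdir, sprintf("%s_emi.tsv", nm)))

    # dimer-configuration survey
    shuffled <- shuffle_library(final)
    ranks <- rank_dimer_configs(final, libs[[1]], shuffled,
                                half_site = cfg$half_site,
                                max_spacing = cfg$max_spacing,
                                p = cfg$motif_p)
    write.table(ranks, file.path(cfg$outdir, sprintf("%s_dimer_ranks.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    models <- Filter(Negate(is.null), attr(ranks, "models"))
    monomer <- tryCatch(
      build_pwm_from_seed(final, cfg$half_site, libs[[1]], name = "M1"),
      error = function(e) NULL)
    if (!is.null(monomer)) {
      e <- motif_enrichment(monomer, final, shuffled, p = cfg$motif_p)
      monomer$enrichment <- e$enrichment
      models <- c(list(M1 = monomer), models)
    }
    write_motif_meme(models, file.path(cfg$outdir, sprintf("%s_motifs.meme", nm)))

    summary[[nm]] <- list(
      top_dimer = ranks$name[1],
      top_dimer_enrichment = ranks$enrichment[1],
      top_kmer = topk[1],
      top_kmer_slope = fits[[1]]$slope,
      top_kmer_r_squared = fits[[1]]$r_squared)
    tables_k[[nm]] <- list(libs = libs, models = attr(ranks, "models"))
  }

  # cross-library k-mer comparison (8-mers vs 12-mers)
  if (length(series) == 2L) {
    for (k in cfg$compare_k) {
      cmpk <- compare_libraries(
        count_kmers(series$normal[[length(series$normal)]], k),
        count_kmers(series$methylated[[length(series$methylated)]], k),
        count_kmers(series$normal[[1]], k),
        count_kmers(series$methylated[[1]], k),
        top_n = cfg$top_n_kmers)
      write.table(cmpk$table,
                  file.path(cfg$outdir, sprintf("compare_%dmers.tsv", k)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary[[sprintf("kmer%d_winner", k)]] <-
        c(a = "normal", b = "methylated", tie = "tie")[[cmpk$winner]]
    }

    # positional methyl-vs-normal comparison of the shared ER0/ER1 models
    for (cfg_name in c("ER0", "ER1")) {
      mn <- tables_k$normal$models[[cfg_name]]
      mm <- tables_k$methylated$models[[cfg_name]]
      if (!is.null(mn) && !is.null(mm)) {
        cmp <- compare_methyl_pwms(mn, mm)
        write.table(cmp, file.path(cfg$outdir,
                                   sprintf("methyl_comparison_%s.tsv", cfg_name)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summary[[sprintf("methyl_calls_%s", cfg_name)]] <-
          paste(cmp$call, collapse = "")
      }
    }
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
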