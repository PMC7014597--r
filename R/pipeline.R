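#' Default pipeline configuration
#'
#' Thresholds default to the values used throughout the Bothriechis analysis:
#' 99% nontoxin null band, 5x depth floor over at most 10% of length, 50%
#' read-overhang asymmetry, 500-fold k-mer cross-talk, 98% clustering
#' identity, soft threshold beta 10 with minimum module size 1, dS window
#' \[0.001, 0.10\], and alpha 0.05.
#'
#' @param stages Stages to run, a subset of `simulate`, `outliers`,
#'   `presence`, `chimera`, `orthology`, `de`, `modules`, `dnds`.
#' @param seed Integer seed used for every stochastic stage.
#' @param paths Named list of input files for non-simulated runs.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(stages = c("simulate", "outliers", "presence",
                                          "chimera", "orthology", "de",
                                          "modules", "dnds"),
                               seed = 1, paths = list()) {
  structure(list(
    stages = stages,
    seed = seed,
    paths = paths,
    thresholds = list(
      null_level = 0.99,
      delta_fraction = 0.5,
      min_depth = 5,
      max_low_fraction = 0.10,
      asym_fraction = 0.50,
      min_reads_at_site = 3,
      kmer_k = 21,
      kmer_fold = 500,
      identity = 0.98,
      beta = 10,
      min_module_size = 1,
      filter_quantile = 0.75,
      min_ds = 0.001,
      max_ds = 0.10,
      alpha = 0.05
    )
  ), class = "run_config")
}

known_stages <- c("simulate", "outliers", "presence", "chimera", "orthology",
                  "de", "modules", "dnds")

#' Validate a pipeline configuration
#'
#' Unknown keys (including unknown threshold names) are errors, so a
#' misspelled threshold cannot silently fall back to a default.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  ref <- default_run_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra) > 0) {
    stop_config(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  extra_thr <- setdiff(names(config$thresholds), names(ref$thresholds))
  if (length(extra_thr) > 0) {
    stop_config(sprintf("unknown threshold(s): %s", paste(extra_thr, collapse = ", ")))
  }
  bad_stage <- setdiff(config$stages, known_stages)
  if (length(bad_stage) > 0) {
    stop_config(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  }
  thr <- utils::modifyList(ref$thresholds, config$thresholds %||% list())
  if (thr$null_level <= 0.5 || thr$null_level >= 1) stop_config("null_level must be in (0.5, 1)")
  for (key in c("delta_fraction", "max_low_fraction", "asym_fraction",
                "identity", "filter_quantile", "alpha")) {
    if (thr[[key]] < 0 || thr[[key]] > 1) stop_config(sprintf("%s must be in [0, 1]", key))
  }
  for (key in c("min_depth", "min_reads_at_site", "kmer_k", "kmer_fold",
                "beta", "min_module_size")) {
    if (thr[[key]] <= 0) stop_config(sprintf("%s must be positive", key))
  }
  if (thr$min_ds < 0 || thr$max_ds <= thr$min_ds) stop_config("require 0 <= min_ds < max_ds")
  if (!is.numeric(config$seed) || length(config$seed) != 1) stop_config("seed must be a single integer")
  config$thresholds <- thr
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' Flat YAML document mirroring [default_run_config()]; unknown keys are
#' errors.
#'
#' @param path YAML file.
#' @return Validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_format(sprintf("cannot parse config: %s", conditionMessage(e))))
  cfg <- utils::modifyList(unclass(default_run_config()), raw)
  cfg <- structure(cfg, class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing one TSV per stage plus a
#' `run_log.yaml` recording the seed and thresholds. With `simulate` among
#' the stages, all inputs are generated with planted truth (and the truth
#' tables written alongside); otherwise the required inputs must be supplied
#' via `config$paths`. Identical config and seed give byte-identical stage
#' outputs.
#'
#' @param config A validated configuration (see [default_run_config()]).
#' @param outdir Output directory (created if needed).
#' @return Named list of per-stage result objects, invisibly; files are the
#'   primary output.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = tempfile("palmviper_run_")) {
  config <- validate_run_config(config)
  thr <- config$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  simulate <- "simulate" %in% config$stages
  need <- function(stage, key, what) {
    if (!simulate && is.null(config$paths[[key]])) {
      stop_config(sprintf("stage '%s' needs input '%s' (%s) or a 'simulate' stage", stage, key, what))
    }
  }
  # resolve inputs up front so a misconfigured run fails before writing
  for (stage in setdiff(config$stages, "simulate")) {
    switch(stage,
      outliers = need(stage, "expression", "expression TSV"),
      presence = need(stage, "alignments", "alignment TSV"),
      chimera = need(stage, "alignments", "alignment TSV"),
      orthology = need(stage, "orthogroups", "orthogroups TSV"),
      de = need(stage, "counts", "counts TSV"),
      modules = need(stage, "expression", "expression TSV"),
      dnds = need(stage, "fasta", "codon-aligned FASTA")
    )
  }
  write_stage <- function(name, tbl) {
    readr::write_tsv(tbl, file.path(outdir, paste0(name, ".tsv")), progress = FALSE)
  }
  if (simulate) {
    sim <- simulate_expression(seed = config$seed)
    results$simulate <- sim
    write_stage("simulated_expression", sim$expression)
    write_stage("simulated_annotation", sim$annotation)
    write_stage("simulated_truth_outliers", sim$truth)
  }
  if ("outliers" %in% config$stages) {
    if (simulate) {
      expr <- results$simulate$expression
      ann <- results$simulate$annotation
    } else {
      expr <- read_expression_table(config$paths$expression)
      ann <- read_annotation(config$paths$annotation)
    }
    calls <- divergence_outliers(expr, ann, pair = expr_samples(expr)[1:2],
                                 level = thr$null_level,
                                 delta_fraction = thr$delta_fraction)
    results$outliers <- calls
    write_stage("outliers", as_tibble(calls))
    band <- attr(calls, "band")
    write_stage("null_band", tibble(lower = band$lower, upper = band$upper,
                                    level = band$level, n_background = band$n_background))
    comp <- family_composition(expr, ann)
    write_stage("family_composition", comp)
  }
  if (any(c("presence", "chimera") %in% config$stages)) {
    if (simulate) {
      aln <- simulate_coverage(3000, 150, depth = 20,
                               low_region = c(1000, 1400), seed = config$seed)
      tx_len <- c(T1 = 3000)
    } else {
      aln <- readr::read_tsv(config$paths$alignments, show_col_types = FALSE, progress = FALSE)
      tx_len <- unlist(config$paths$transcript_length)
    }
    if ("presence" %in% config$stages) {
      prof <- depth_profile(aln, tx_len)
      pres <- call_presence(prof, thr$min_depth, thr$max_low_fraction)
      results$presence <- pres
      write_stage("presence", pres)
    }
    if ("chimera" %in% config$stages) {
      chim <- screen_chimeras(aln, tx_len, thr$asym_fraction, thr$min_reads_at_site)
      results$chimera <- chim
      write_stage("chimera", as_tibble(chim))
    }
  }
  if ("orthology" %in% config$stages) {
    og <- if (simulate) {
      simulate_orthogroups(n_one_to_one = 20, n_dup_a = 3, n_dup_b = 2,
                           n_loss_a = 2, n_loss_b = 3, seed = config$seed)
    } else {
      read_orthogroups(config$paths$orthogroups)
    }
    cls <- classify_orthogroups(og)
    results$orthology <- cls
    write_stage("orthology_classes", cls$classes)
    write_stage("orthology_events", as_tibble(cls$events))
  }
  if ("de" %in% config$stages) {
    if (simulate) {
      withr::with_seed(config$seed, {
        n <- 500
        counts <- tibble(
          transcript_id = sprintf("T%04d", seq_len(n)),
          !!!setNames(lapply(1:6, function(i) stats::rpois(n, 100)),
                      paste0("s", 1:6))
        )
      })
      groups <- setNames(rep(c("g1", "g2"), each = 3), paste0("s", 1:6))
    } else {
      counts <- read_expression_table(config$paths$counts)
      grp_tbl <- readr::read_tsv(config$paths$groups, show_col_types = FALSE, progress = FALSE)
      groups <- setNames(grp_tbl$group, grp_tbl$sample)
    }
    de <- nb_wald_test(counts, groups)
    results$de <- de
    write_stage("differential_expression", de)
  }
  if ("modules" %in% config$stages) {
    if (simulate) {
      simc <- simulate_coexpression(n_modules = 2, transcripts_per_module = 10,
                                    n_background = 20, within_cor = 0.95,
                                    n_samples_per_treatment = 4, seed = config$seed)
      expr <- simc$expression
      meta <- simc$sample_meta
      write_stage("simulated_truth_modules", simc$truth)
      fq <- 0
    } else {
      expr <- read_expression_table(config$paths$expression)
      meta <- readr::read_tsv(config$paths$sample_meta, show_col_types = FALSE, progress = FALSE)
      fq <- thr$filter_quantile
    }
    mods <- suppressWarnings(find_coexpression_modules(
      expr, meta, beta = thr$beta, min_module_size = thr$min_module_size,
      filter_quantile = fq
    ))
    results$modules <- mods
    write_stage("module_assignment", mods$assignment)
    write_stage("module_profiles", mods$profiles)
  }
  if ("dnds" %in% config$stages) {
    stats <- if (simulate) {
      purrr::map(1:20, function(i) {
        pair <- simulate_codon_pair(200, target_syn_diffs = i %% 4,
                                    target_nonsyn_diffs = (i + 1) %% 3,
                                    seed = config$seed + i)
        pairwise_dnds(pair$seq1, pair$seq2, pair_id = sprintf("pair%02d", i))
      }) |> list_rbind()
    } else {
      seqs <- Biostrings::readDNAStringSet(config$paths$fasta)
      if (length(seqs) %% 2 != 0) stop_validation("dnds FASTA must hold sequence pairs")
      purrr::map(seq_len(length(seqs) / 2), function(i) {
        pairwise_dnds(as.character(seqs[[2 * i - 1]]), as.character(seqs[[2 * i]]),
                      pair_id = names(seqs)[2 * i - 1])
      }) |> list_rbind()
    }
    stats <- apply_ds_filters(stats, thr$min_ds, thr$max_ds)
    results$dnds <- stats
    write_stage("dnds", stats)
  }
  log <- list(seed = config$seed, stages = config$stages, thresholds = thr)
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(results)
}

#' Recompute the headline Bothriechis summary counts
#'
#' Reruns the package's own callers and counters over the bundled toxin and
#' differential-expression tables and returns the quantities a reader would
#' check first: table sizes, ortholog counts, over-expression and absence
#' calls, significant-DE counts, the PLA2 share of the Type A individual's
#' toxin expression, and the Wald statistic recomputed for the headline
#' SVSP-1 row.
#'
#' @return A named list of numbers.
#' @export
bothriechis_summary <- function() {
  t2 <- bothriechis_toxins("nigroviridis")
  t3 <- bothriechis_toxins("nubestris")
  t4 <- bothriechis_de("typeA")
  t5 <- bothriechis_de("typeAB")
  ann2 <- tibble(transcript_id = t2$toxin_id, class = "toxin", family = t2$family,
                 orthology_label = t2$orthology_label)
  expr2 <- bothriechis_expression("nigroviridis")
  comp2 <- family_composition(expr2, ann2, "per_sample")
  ann3 <- tibble(transcript_id = t3$toxin_id, class = "toxin", family = t3$family,
                 orthology_label = t3$orthology_label)
  expr3 <- bothriechis_expression("nubestris")
  comp3 <- family_composition(expr3, ann3, "species_average")
  list(
    nigroviridis_toxins = nrow(t2),
    nubestris_toxins = nrow(t3),
    nigroviridis_orthologs = sum(t2$orthology_label == "Ortholog"),
    nubestris_orthologs = sum(t3$orthology_label == "Ortholog"),
    nigroviridis_overexpressed = sum(t2$over_expression != "-"),
    nubestris_overexpressed = sum(t3$over_expression != "-"),
    nigroviridis_absent_total = sum(t2$presence_CLP1856 == "-") + sum(t2$presence_CLP1864 == "-"),
    nigroviridis_absent_southern = sum(t2$presence_CLP1856 == "-"),
    nigroviridis_absent_northern = sum(t2$presence_CLP1864 == "-"),
    nubestris_absent_total = sum(t3$presence_CLP1859 == "-") + sum(t3$presence_CLP1865 == "-"),
    de_significant_typeA = count_significant(t4),
    de_significant_typeAB = count_significant(t5),
    pla2_share_CLP1864 = comp2$percent[comp2$family == "PLA2" & comp2$sample == "CLP1864"],
    ctl_share_nubestris = comp3$percent[comp3$family == "CTL"],
    svmp_share_nubestris = comp3$percent[comp3$family == "SVMP"],
    svsp1_wald_stat = wald_stat_from_table(
      t4$log2_fold_change[t4$toxin == "SVSP-1"], t4$lfc_se[t4$toxin == "SVSP-1"]
    )
  )
}
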