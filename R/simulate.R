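#' Simulate a compositional expression table with planted outliers
#'
#' Emulates the intraspecific study design: two venom-gland samples from one
#' species, a large nontoxin background whose log-abundances scatter about a
#' shared line, and a toxin set of which `n_outliers` are shifted by
#' `outlier_shift` (CLR units) in one randomly chosen sample. Abundances are
#' drawn on the natural-log scale and closed to the TPM constant (columns sum
#' to 1e6), mirroring the compositional closure that motivates the CLR
#' analysis.
#'
#' @param n_toxins,n_nontoxins Transcript counts (defaults 40 and 1500, the
#'   scale of a curated venom-gland transcriptome).
#' @param n_outliers Number of planted over-expressed toxins (<= n_toxins).
#' @param outlier_shift Log-scale shift of planted outliers (default 5).
#' @param noise_sd Per-sample log-abundance noise (default 0.5).
#' @param n_families Number of toxin families to cycle ids through
#'   (default 14).
#' @param seed Integer seed.
#' @param samples Names of the two samples.
#' @return List of class `sim_expression` with `expression` (TPM tibble),
#'   `annotation`, and `truth` (tibble `transcript_id`, `direction`).
#' @export
simulate_expression <- function(n_toxins = 40, n_nontoxins = 1500, n_outliers = 5,
                                outlier_shift = 5, noise_sd = 0.5, n_families = 14,
                                seed = 1, samples = c("S1", "S2")) {
  if (n_toxins <= 0 || n_nontoxins <= 0) stop_validation("transcript counts must be positive")
  if (n_outliers > n_toxins) stop_validation("n_outliers cannot exceed n_toxins")
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  withr::local_seed(seed)
  n <- n_toxins + n_nontoxins
  ids <- c(sprintf("TOX%03d", seq_len(n_toxins)), sprintf("NT%04d", seq_len(n_nontoxins)))
  mu <- rnorm(n, mean = 2, sd = 2)
  log1 <- mu + rnorm(n, 0, noise_sd)
  log2 <- mu + rnorm(n, 0, noise_sd)
  truth <- tibble(transcript_id = character(0), direction = character(0))
  if (n_outliers > 0) {
    picked <- sample(seq_len(n_toxins), n_outliers)
    side <- sample(c(1, 2), n_outliers, replace = TRUE)
    log1[picked[side == 1]] <- log1[picked[side == 1]] + outlier_shift
    log2[picked[side == 2]] <- log2[picked[side == 2]] + outlier_shift
    truth <- tibble(transcript_id = ids[picked], direction = samples[side]) |>
      arrange(.data$transcript_id)
  }
  close_tpm <- function(x) 1e6 * exp(x) / sum(exp(x))
  expr <- tibble(transcript_id = ids,
                 !!samples[1] := close_tpm(log1),
                 !!samples[2] := close_tpm(log2))
  fams <- paste0("FAM", seq_len(n_families))
  annotation <- tibble(
    transcript_id = ids,
    class = rep(c("toxin", "nontoxin"), c(n_toxins, n_nontoxins)),
    family = c(rep_len(fams, n_toxins), rep("", n_nontoxins)),
    orthology_label = "unassigned"
  )
  structure(list(expression = expr, annotation = annotation, truth = truth),
            class = "sim_expression")
}

#' Simulate a read-alignment table with optional planted defects
#'
#' Produces a uniformly tiled alignment table (0-based, half-open intervals,
#' reads clipped at transcript ends so interior depth is uniform). A planted
#' chimeric junction splits the tiling so that no read spans the junction; a
#' planted low-coverage region removes every read overlapping it, driving its
#' depth to zero.
#'
#' @param transcript_length,read_length Bases; `read_length` must be smaller.
#' @param depth Target fold coverage.
#' @param junction_at Optional junction position; must lie at least
#'   `read_length` from both ends (nearer junctions are undetectable by
#'   construction and rejected).
#' @param low_region Optional length-2 vector `c(start, end)` (half-open) to
#'   deplete.
#' @param seed Integer seed (randomises the tiling phase).
#' @param transcript_id Id used in the table.
#' @return Alignment tibble `read_id`, `transcript_id`, `start`, `end`.
#' @export
simulate_coverage <- function(transcript_length, read_length, depth = 20,
                              junction_at = NULL, low_region = NULL, seed = 1,
                              transcript_id = "T1") {
  if (read_length >= transcript_length) {
    stop_validation("read_length must be smaller than transcript_length")
  }
  if (!is.null(junction_at)) {
    if (junction_at < read_length || junction_at > transcript_length - read_length) {
      stop_validation("junction within read_length of a transcript end is undetectable")
    }
  }
  withr::local_seed(seed)
  step <- max(1L, as.integer(round(read_length / depth)))
  phase <- sample.int(step, 1) - 1L
  tile <- function(a, b) {
    # clipped tiling of [a, b): reads may start before a / end after b and
    # are truncated, keeping interior depth at read_length / step
    starts <- seq(a - read_length + step + phase, b - 1, by = step)
    s <- pmax(starts, a)
    e <- pmin(starts + read_length, b)
    keep <- e - s >= 1
    tibble(start = as.integer(s[keep]), end = as.integer(e[keep]))
  }
  reads <- if (is.null(junction_at)) {
    tile(0, transcript_length)
  } else {
    bind_rows(tile(0, junction_at), tile(junction_at, transcript_length))
  }
  if (!is.null(low_region)) {
    keep <- reads$end <= low_region[1] | reads$start >= low_region[2]
    reads <- reads[keep, ]
  }
  reads |>
    mutate(read_id = sprintf("r%05d", row_number()),
           transcript_id = transcript_id) |>
    select("read_id", "transcript_id", "start", "end")
}

#' Simulate a coding-sequence pair with exact substitution targets
#'
#' Generates a random stop-free coding sequence and introduces exactly
#' `target_syn_diffs` synonymous and `target_nonsyn_diffs` nonsynonymous
#' single-base changes, each in a distinct codon, never creating a stop.
#'
#' @param n_codons Number of codons.
#' @param target_syn_diffs,target_nonsyn_diffs Difference counts; their sum
#'   must not exceed `n_codons`.
#' @param seed Integer seed.
#' @return List with `seq1`, `seq2`, and `truth`
#'   (`syn_diffs`, `nonsyn_diffs`).
#' @export
simulate_codon_pair <- function(n_codons, target_syn_diffs = 0,
                                target_nonsyn_diffs = 0, seed = 1) {
  if (n_codons < 1) stop_validation("n_codons must be positive")
  if (target_syn_diffs < 0 || target_nonsyn_diffs < 0 ||
      target_syn_diffs + target_nonsyn_diffs > n_codons) {
    stop_validation("infeasible substitution targets for n_codons")
  }
  withr::local_seed(seed)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  has_change <- function(codon, synonymous) {
    for (pos in 1:3) {
      neigh <- codon_neighbors(codon, pos)
      aa <- code[neigh]
      ok <- aa != "*" & if (synonymous) aa == code[[codon]] else aa != code[[codon]]
      if (any(ok)) return(TRUE)
    }
    FALSE
  }
  syn_capable <- sense[vapply(sense, has_change, logical(1), synonymous = TRUE)]
  nonsyn_capable <- sense[vapply(sense, has_change, logical(1), synonymous = FALSE)]
  codons <- character(n_codons)
  slots <- sample.int(n_codons)
  syn_slots <- slots[seq_len(target_syn_diffs)]
  nonsyn_slots <- slots[target_syn_diffs + seq_len(target_nonsyn_diffs)]
  codons[syn_slots] <- sample(syn_capable, target_syn_diffs, replace = TRUE)
  codons[nonsyn_slots] <- sample(nonsyn_capable, target_nonsyn_diffs, replace = TRUE)
  rest <- setdiff(seq_len(n_codons), c(syn_slots, nonsyn_slots))
  codons[rest] <- sample(sense, length(rest), replace = TRUE)
  mutate_codon <- function(codon, synonymous) {
    options <- list()
    for (pos in 1:3) {
      neigh <- codon_neighbors(codon, pos)
      aa <- code[neigh]
      ok <- aa != "*" & if (synonymous) aa == code[[codon]] else aa != code[[codon]]
      for (alt in neigh[ok]) options <- c(options, list(alt))
    }
    unlist(sample(options, 1))
  }
  codons2 <- codons
  for (i in syn_slots) codons2[i] <- mutate_codon(codons[i], TRUE)
  for (i in nonsyn_slots) codons2[i] <- mutate_codon(codons[i], FALSE)
  list(seq1 = paste(codons, collapse = ""), seq2 = paste(codons2, collapse = ""),
       truth = list(syn_diffs = target_syn_diffs, nonsyn_diffs = target_nonsyn_diffs))
}

#' Simulate a two-species orthogroup table with planted turnover
#'
#' @param n_one_to_one Number of 1:1 orthogroups.
#' @param n_dup_a,n_dup_b Orthogroups with a duplication (2 members) in
#'   species A / B and one member in the other.
#' @param n_loss_a,n_loss_b Orthogroups lost in species A / B (members only
#'   in the other species).
#' @param seed Integer seed (shuffles orthogroup order).
#' @param species Length-2 species names.
#' @return Long orthology tibble `orthogroup`, `species`, `transcript_id`
#'   with a `"species"` attribute.
#' @export
simulate_orthogroups <- function(n_one_to_one = 10, n_dup_a = 0, n_dup_b = 0,
                                 n_loss_a = 0, n_loss_b = 0, seed = 1,
                                 species = c("A", "B")) {
  counts <- c(n_one_to_one, n_dup_a, n_dup_b, n_loss_a, n_loss_b)
  if (any(counts < 0)) stop_validation("orthogroup counts must be non-negative")
  withr::local_seed(seed)
  kinds <- rep(c("one_to_one", "dup_a", "dup_b", "loss_a", "loss_b"), counts)
  if (length(kinds) == 0) {
    return(structure(tibble(orthogroup = character(0), species = character(0),
                            transcript_id = character(0)), species = species))
  }
  kinds <- sample(kinds)
  rows <- imap(kinds, function(kind, i) {
    og <- sprintf("OG%04d", i)
    a_n <- switch(kind, one_to_one = 1, dup_a = 2, dup_b = 1, loss_a = 0, loss_b = 1)
    b_n <- switch(kind, one_to_one = 1, dup_a = 1, dup_b = 2, loss_a = 1, loss_b = 0)
    bind_rows(
      if (a_n > 0) tibble(orthogroup = og, species = species[1],
                          transcript_id = sprintf("%s_a%d_%d", og, seq_len(a_n), i)),
      if (b_n > 0) tibble(orthogroup = og, species = species[2],
                          transcript_id = sprintf("%s_b%d_%d", og, seq_len(b_n), i))
    )
  }) |> list_rbind()
  structure(rows, species = species)
}

#' Simulate treatment-structured coexpression blocks
#'
#' Builds an expression table in which each planted module shares a latent
#' profile: transcript i of module m is
#' `sqrt(r) * f_m + sqrt(1 - r) * noise`, where the module factor
#' `f_m = (z_m + eta_m) / sqrt(2)` mixes a standardised treatment-level
#' pattern `z_m` with module-level per-sample noise `eta_m`. Pairwise
#' within-module correlation is therefore `r = within_cor`, and modules with
#' proportional (even opposite) treatment patterns remain statistically
#' separable. Background transcripts are pure noise. Values are mapped to a
#' TPM-like scale as `2^(8 + 2x) - 1`, so the network pipeline's
#' `log2(x + 1)` transform recovers the latent values exactly.
#'
#' @param n_modules Number of planted modules.
#' @param transcripts_per_module Module size.
#' @param n_background Number of unstructured background transcripts.
#' @param within_cor Target pairwise within-module correlation in \[0, 1).
#' @param n_samples_per_treatment Replicates per treatment (>= 2 treatments
#'   required).
#' @param treatments Treatment labels (default the three venom types).
#' @param profiles Optional treatment-by-module matrix of patterns; defaults
#'   to cycled orthogonal polynomial contrasts with sign flips.
#' @param seed Integer seed.
#' @return List of class `sim_coexpression` with `expression`, `sample_meta`
#'   (`sample_id`, `venom_type`), and `truth` (tibble `transcript_id`,
#'   `module`; 0 = background).
#' @export
simulate_coexpression <- function(n_modules = 2, transcripts_per_module = 10,
                                  n_background = 20, within_cor = 0.9,
                                  n_samples_per_treatment = 4,
                                  treatments = c("A", "A+B", "B"),
                                  profiles = NULL, seed = 1) {
  if (within_cor < 0 || within_cor >= 1) stop_validation("within_cor must be in [0, 1)")
  if (length(treatments) < 2) stop_validation("need at least 2 treatments")
  withr::local_seed(seed)
  n_t <- length(treatments)
  n_samples <- n_t * n_samples_per_treatment
  treatment_of <- rep(treatments, each = n_samples_per_treatment)
  sample_ids <- sprintf("%s_%d", gsub("[^A-Za-z]", "", treatment_of),
                        sequence(rep(n_samples_per_treatment, n_t)))
  if (is.null(profiles) && n_modules > 0) {
    contrasts <- stats::poly(seq_len(n_t), degree = n_t - 1)
    profiles <- vapply(seq_len(n_modules), function(m) {
      base <- contrasts[, ((m - 1) %% (n_t - 1)) + 1]
      base * (-1)^((m - 1) %/% (n_t - 1))
    }, numeric(n_t))
  }
  r <- within_cor
  vals <- matrix(0, nrow = 0, ncol = n_samples)
  ids <- character(0)
  modules <- integer(0)
  for (m in seq_len(n_modules)) {
    z <- profiles[match(treatment_of, treatments), m]
    z <- (z - mean(z)) / sd(z)
    eta <- rnorm(n_samples)
    f <- (z + eta) / sqrt(2)
    block <- t(vapply(seq_len(transcripts_per_module), function(i) {
      sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples)
    }, numeric(n_samples)))
    vals <- rbind(vals, block)
    ids <- c(ids, sprintf("M%d_T%02d", m, seq_len(transcripts_per_module)))
    modules <- c(modules, rep(m, transcripts_per_module))
  }
  if (n_background > 0) {
    vals <- rbind(vals, matrix(rnorm(n_background * n_samples), nrow = n_background))
    ids <- c(ids, sprintf("BG_T%03d", seq_len(n_background)))
    modules <- c(modules, rep(0L, n_background))
  }
  tpm <- 2^(8 + 2 * vals) - 1
  colnames(tpm) <- sample_ids
  expr <- bind_cols(tibble(transcript_id = ids), as_tibble(tpm))
  structure(
    list(expression = expr,
         sample_meta = tibble(sample_id = sample_ids, venom_type = treatment_of),
         truth = tibble(transcript_id = ids, module = modules)),
    class = "sim_coexpression"
  )
}
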