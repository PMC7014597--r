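# Standard genetic code tables, built once at load from Biostrings.
codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$code)) {
    codon_env$code <- Biostrings::GENETIC_CODE
    codon_env$stops <- names(codon_env$code)[codon_env$code == "*"]
  }
  codon_env$code
}

stop_codons <- function() {
  genetic_code()
  codon_env$stops
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) stop_validation("sequence length must be divisible by 3")
  if (nchar(seq) < 3) stop_validation("sequence must contain at least one codon")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

check_codons <- function(codons, allow_gaps = FALSE) {
  ok <- grepl("^[ACGT]{3}$", codons)
  if (allow_gaps) ok <- ok | grepl("-", codons)
  if (!all(ok)) stop_validation(sprintf("invalid codon(s): %s", paste(head(codons[!ok], 3), collapse = ", ")))
  internal <- codons[grepl("^[ACGT]{3}$", codons)]
  if (any(internal %in% stop_codons())) stop_validation("stop codon in coding sequence")
  invisible(codons)
}

bases <- c("A", "C", "G", "T")

codon_neighbors <- function(codon, pos) {
  ref <- substr(codon, pos, pos)
  alts <- setdiff(bases, ref)
  vapply(alts, function(b) { x <- codon; substr(x, pos, pos) <- b; x }, character(1))
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' For each codon position the three single-base changes are classified with
#' the standard genetic code; changes creating a stop codon are excluded from
#' the counting entirely, so such positions contribute less than one site in
#' total. The synonymous site count of a position is (synonymous changes)/3
#' and the nonsynonymous count (non-stop, nonsynonymous changes)/3; `N + S`
#' therefore equals 3 per codon minus the excluded stop fractions.
#'
#' @param seq Coding nucleotide sequence (length divisible by 3, no stops).
#' @return Named numeric vector `c(N = ..., S = ...)`.
#' @export
count_sites <- function(seq) {
  codons <- split_codons(seq)
  check_codons(codons)
  code <- genetic_code()
  S <- 0; N <- 0
  for (codon in codons) {
    for (pos in 1:3) {
      neigh <- codon_neighbors(codon, pos)
      aa <- code[neigh]
      nonstop <- aa != "*"
      syn <- sum(nonstop & aa == code[[codon]])
      S <- S + syn / 3
      N <- N + (sum(nonstop) - syn) / 3
    }
  }
  c(N = N, S = S)
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal mutational pathways, weighting valid (stop-free) pathways
# equally. If every pathway passes through a stop codon, all pathways are
# used (standard fallback).
codon_pair_diffs <- function(c1, c2) {
  code <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(Nd = 0, Sd = 0))
  perms <- permutations(pos)
  path_counts <- lapply(perms, function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") valid <- FALSE
      if (code[[nxt]] == code[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, valid = valid)
  })
  valid <- map_lgl(path_counts, "valid")
  use <- if (any(valid)) path_counts[valid] else path_counts
  c(Nd = mean(map_dbl(use, "nonsyn")), Sd = mean(map_dbl(use, "syn")))
}

permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Computes expected synonymous/nonsynonymous site counts (averaged over the
#' two sequences), observed difference counts averaged with equal weight over
#' all minimal stop-free mutational pathways per codon, the proportions
#' `pN = Nd/N`, `pS = Sd/S`, Jukes-Cantor corrected distances
#' `d = -3/4 log(1 - 4p/3)`, and `omega = dN/dS` (defined only when
#' `dS > 0`). Codon columns containing an alignment gap in either sequence
#' are dropped pairwise and reported in `n_dropped`.
#'
#' @param seq1,seq2 Codon-aligned coding sequences of equal length (gaps
#'   `-` allowed).
#' @param pair_id Optional identifier carried into the output.
#' @return One-row tibble with `pair_id`, `n_codons`, `n_dropped`, `N`, `S`,
#'   `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, `filter_status`
#'   (`"kept"` placeholder, or `"undefined"` when a distance does not exist).
#' @export
pairwise_dnds <- function(seq1, seq2, pair_id = NA_character_) {
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop_validation("sequences must have equal codon length")
  gap <- grepl("-", c1) | grepl("-", c2)
  c1 <- c1[!gap]; c2 <- c2[!gap]
  if (length(c1) == 0) stop_validation("no gap-free codon columns to compare")
  check_codons(c1); check_codons(c2)
  sites1 <- count_sites(paste(c1, collapse = ""))
  sites2 <- count_sites(paste(c2, collapse = ""))
  N <- (sites1[["N"]] + sites2[["N"]]) / 2
  S <- (sites1[["S"]] + sites2[["S"]]) / 2
  diffs <- purrr::map2(c1, c2, codon_pair_diffs)
  Nd <- sum(map_dbl(diffs, "Nd"))
  Sd <- sum(map_dbl(diffs, "Sd"))
  pN <- Nd / N
  pS <- Sd / S
  jc <- function(p) {
    if (!is.finite(p) || p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dN <- jc(pN)
  dS <- jc(pS)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  status <- if (is.na(dN) || is.na(dS)) "undefined" else "kept"
  tibble(pair_id = pair_id, n_codons = length(c1), n_dropped = sum(gap),
         N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         dN = dN, dS = dS, omega = omega, filter_status = status)
}

#' Apply the dS exclusion windows
#'
#' Pairs with `dS` below `min_ds` risk wildly inflated omega (division by a
#' near-zero synonymous distance); pairs with `dS` above `max_ds` risk being
#' misidentified orthologs. Both are excluded from downstream contrasts. The
#' filter is idempotent.
#'
#' @param stats Tibble of [pairwise_dnds()] rows.
#' @param min_ds,max_ds Inclusive dS window (defaults 0.001 and 0.10).
#' @return The same tibble with `filter_status` set to one of `kept`,
#'   `excluded_low_dS`, `excluded_high_dS`, `undefined`.
#' @export
apply_ds_filters <- function(stats, min_ds = 0.001, max_ds = 0.10) {
  stats |>
    mutate(filter_status = case_when(
      is.na(.data$dS) | is.na(.data$dN) ~ "undefined",
      .data$dS < min_ds ~ "excluded_low_dS",
      .data$dS > max_ds ~ "excluded_high_dS",
      TRUE ~ "kept"
    ))
}

#' Toxin versus nontoxin divergence contrast
#'
#' Two-sample Wilcoxon rank-sum test (normal approximation with tie
#' correction) of a divergence quantity between toxin and nontoxin ortholog
#' pairs. The groups are unpaired and of unequal size, so the rank-sum form
#' is the applicable test; a paired signed-rank variant is available for
#' matched designs.
#'
#' @param stats Filtered stats tibble with a `class` column
#'   (`"toxin"`/`"nontoxin"`).
#' @param quantity One of `"omega"`, `"dN"`, `"dS"`.
#' @param paired Use the signed-rank (paired) form; requires equal group
#'   sizes in matching order (default FALSE).
#' @return One-row tibble `quantity`, `statistic`, `p_value`, `n_toxin`,
#'   `n_nontoxin`.
#' @export
compare_groups <- function(stats, quantity = c("omega", "dN", "dS"), paired = FALSE) {
  quantity <- match.arg(quantity)
  if (!"class" %in% names(stats)) stop_validation("stats must carry a class column")
  x <- stats[[quantity]][stats$class == "toxin"]
  y <- stats[[quantity]][stats$class == "nontoxin"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop_validation("need at least one value per group")
  if (length(unique(c(x, y))) == 1) {
    return(tibble(quantity = quantity, statistic = NA_real_, p_value = 1,
                  n_toxin = length(x), n_nontoxin = length(y)))
  }
  wt <- wilcox.test(x, y, paired = paired, exact = FALSE, correct = TRUE)
  tibble(quantity = quantity, statistic = unname(wt$statistic),
         p_value = wt$p.value, n_toxin = length(x), n_nontoxin = length(y))
}

#' Flag toxins above the nontoxin 95th percentile
#'
#' @param stats Filtered stats tibble with `class` and `pair_id` columns.
#' @param quantity One of `"omega"`, `"dN"`, `"dS"`.
#' @param level Percentile level (default 0.95); the comparison is strict, a
#'   toxin exactly at the percentile is not flagged.
#' @return Tibble `pair_id`, `value`, `flagged` for toxins, with the
#'   threshold in attribute `"threshold"`.
#' @export
percentile_flags <- function(stats, quantity = c("omega", "dN", "dS"), level = 0.95) {
  quantity <- match.arg(quantity)
  bg <- stats[[quantity]][stats$class == "nontoxin"]
  bg <- bg[!is.na(bg)]
  if (length(bg) < 20) warn("fewer than 20 nontoxin values: percentile threshold is unstable")
  thr <- quantile(bg, level, names = FALSE)
  tox <- stats |> filter(.data$class == "toxin")
  out <- tibble(pair_id = tox$pair_id, value = tox[[quantity]],
                flagged = !is.na(tox[[quantity]]) & tox[[quantity]] > thr)
  attr(out, "threshold") <- thr
  out
}

#' Percentile flags for all three quantities with their overlap
#'
#' @inheritParams percentile_flags
#' @return List with per-quantity flag tibbles (`omega`, `dN`, `dS`) and
#'   `overlap`, the toxin ids flagged for both dN and dS.
#' @export
selection_flag_overlap <- function(stats, level = 0.95) {
  flags <- lapply(c(omega = "omega", dN = "dN", dS = "dS"), function(q) {
    percentile_flags(stats, q, level)
  })
  flagged_ids <- lapply(flags, function(f) f$pair_id[f$flagged])
  c(flags, list(overlap = intersect(flagged_ids$dN, flagged_ids$dS)))
}
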