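#' Per-base depth profile from a read-alignment table
#'
#' Coordinates are 0-based, half-open: a read `[start, end)` covers bases
#' `start .. end-1`.
#'
#' @param alignments Tibble with columns `read_id`, `transcript_id`, `start`,
#'   `end`.
#' @param transcript_length Named integer vector of transcript lengths, or a
#'   single length when the table holds one transcript.
#' @return A tibble of class `coverage_profile`: `transcript_id`, `pos`
#'   (0-based), `depth`.
#' @export
depth_profile <- function(alignments, transcript_length) {
  check_alignments(alignments)
  lens <- resolve_lengths(alignments, transcript_length)
  out <- imap(lens, function(L, tx) {
    al <- alignments[alignments$transcript_id == tx, ]
    if (any(al$start < 0 | al$end > L)) {
      stop_validation(sprintf("alignment interval out of bounds for %s", tx))
    }
    d <- diff_array_sum(al$start, al$end, rep(1, nrow(al)), L)
    tibble(transcript_id = tx, pos = 0:(L - 1), depth = d)
  }) |> list_rbind()
  structure(out, class = c("coverage_profile", class(out)))
}

check_alignments <- function(alignments) {
  need <- c("read_id", "transcript_id", "start", "end")
  if (!is.data.frame(alignments) || !all(need %in% names(alignments))) {
    stop_validation("alignments must have columns read_id, transcript_id, start, end")
  }
  if (any(alignments$start >= alignments$end)) {
    stop_validation("alignment intervals must satisfy start < end (0-based half-open)")
  }
  invisible(alignments)
}

resolve_lengths <- function(alignments, transcript_length) {
  txs <- unique(alignments$transcript_id)
  if (is.null(names(transcript_length))) {
    if (length(transcript_length) != 1 || length(txs) != 1) {
      stop_validation("transcript_length must be named when multiple transcripts are present")
    }
    transcript_length <- setNames(transcript_length, txs)
  }
  missing <- setdiff(txs, names(transcript_length))
  if (length(missing) > 0) {
    stop_validation(sprintf("no length given for transcript(s): %s", paste(missing, collapse = ", ")))
  }
  as.list(transcript_length[txs])
}

# Sum `w` over intervals [start, end) as a per-base vector of length L,
# via a difference array (O(reads + L)).
diff_array_sum <- function(start, end, w, L) {
  d <- numeric(L + 1)
  for (i in seq_along(start)) {
    d[start[i] + 1] <- d[start[i] + 1] + w[i]
    d[end[i] + 1] <- d[end[i] + 1] - w[i]
  }
  cumsum(d)[seq_len(L)]
}

#' Coverage-based presence/absence call
#'
#' A transcript is called absent from an individual when the fraction of its
#' bases covered below `min_depth` exceeds `max_low_fraction` — low expression
#' leaves thin but uniform coverage, whereas a transcript that is not actually
#' present picks up only patchy mis-mapped reads.
#'
#' @param profile A [depth_profile()] result (any number of transcripts).
#' @param min_depth Depth floor in reads (default 5).
#' @param max_low_fraction Maximum tolerated fraction of low-coverage bases
#'   (default 0.10).
#' @return Tibble `transcript_id`, `low_fraction`, `verdict`
#'   (`"present"`/`"absent"`).
#' @export
call_presence <- function(profile, min_depth = 5, max_low_fraction = 0.10) {
  if (!all(c("transcript_id", "depth") %in% names(profile))) {
    stop_validation("profile must be a coverage_profile tibble")
  }
  if (nrow(profile) == 0) stop_validation("zero-length transcript")
  profile |>
    group_by(.data$transcript_id) |>
    summarise(low_fraction = mean(.data$depth < min_depth), .groups = "drop") |>
    mutate(verdict = ifelse(.data$low_fraction > max_low_fraction, "absent", "present"))
}

#' Screen transcripts for chimeric junctions
#'
#' At a chimeric junction no single read spans the joint, so the mean number
#' of read bases to the left and to the right of the site becomes strongly
#' asymmetric. For every eligible site i (at least one mean read length from
#' both ends and covered by at least `min_reads_at_site` reads) the screen
#' computes, over the covering reads, `left = mean(i - start)` and
#' `right = mean(end - i - 1)` and flags the site when
#' `|left - right| > asym_fraction * mean read length`.
#'
#' @inheritParams depth_profile
#' @param asym_fraction Asymmetry threshold as a fraction of the mean read
#'   length (default 0.50).
#' @param min_reads_at_site Minimum covering reads for a site to be eligible
#'   (default 3).
#' @return Tibble `transcript_id`, `site`, `left_mean`, `right_mean`,
#'   `asymmetry` with one row per flagged site; the per-transcript mean read
#'   lengths are in the `"mean_read_length"` attribute.
#' @export
screen_chimeras <- function(alignments, transcript_length,
                            asym_fraction = 0.50, min_reads_at_site = 3) {
  check_alignments(alignments)
  if (nrow(alignments) == 0) stop_validation("no reads to screen")
  lens <- resolve_lengths(alignments, transcript_length)
  mrls <- c()
  out <- imap(lens, function(L, tx) {
    al <- alignments[alignments$transcript_id == tx, ]
    if (any(al$start < 0 | al$end > L)) {
      stop_validation(sprintf("alignment interval out of bounds for %s", tx))
    }
    mrl <- mean(al$end - al$start)
    mrls[[tx]] <<- mrl
    depth <- diff_array_sum(al$start, al$end, rep(1, nrow(al)), L)
    sum_start <- diff_array_sum(al$start, al$end, al$start, L)
    sum_end <- diff_array_sum(al$start, al$end, al$end, L)
    pos <- 0:(L - 1)
    eligible <- pos >= mrl & (L - 1 - pos) >= mrl & depth >= min_reads_at_site
    if (!any(eligible)) return(tibble())
    i <- pos[eligible]
    d <- depth[eligible]
    left <- i - sum_start[eligible] / d
    right <- sum_end[eligible] / d - i - 1
    asym <- abs(left - right)
    flag <- asym > asym_fraction * mrl
    if (!any(flag)) return(tibble())
    tibble(transcript_id = tx, site = i[flag], left_mean = left[flag],
           right_mean = right[flag], asymmetry = asym[flag])
  }) |> list_rbind()
  attr(out, "mean_read_length") <- unlist(mrls)
  out
}

#' Cross-sample k-mer bleed-through filter
#'
#' Reads mis-assigned during demultiplexing carry k-mers that are abundant in
#' their sample of origin but vanishingly rare in the recipient. Canonical
#' k-mer counts are normalised per million k-mers within each sample; for a
#' sample pair, a k-mer whose pseudo-counted ratio
#' `(higher + 0.5) / (lower + 0.5)` exceeds `fold` is flagged, and reads of
#' the lower-count sample containing it are removed (the low side is the
#' presumed bleed-through recipient). The comparison is strict, so a ratio of
#' exactly `fold` is retained.
#'
#' @param reads_by_sample Named list of character vectors of read sequences.
#' @param k K-mer length (default 21).
#' @param fold Normalised-count fold threshold (default 500).
#' @return List with `reads` (the filtered named list) and `removed`
#'   (tibble `sample`, `read_index`, `read`).
#' @export
kmer_crosstalk_filter <- function(reads_by_sample, k = 21, fold = 500) {
  if (!is.list(reads_by_sample) || length(reads_by_sample) < 2 ||
      is.null(names(reads_by_sample))) {
    stop_validation("reads_by_sample must be a named list of at least 2 samples")
  }
  if (any(unlist(lapply(reads_by_sample, nchar)) < k)) {
    stop_validation("k exceeds the length of at least one read")
  }
  kmer_sets <- lapply(reads_by_sample, function(reads) lapply(reads, read_kmers, k = k))
  counts <- lapply(kmer_sets, function(sets) {
    tab <- table(unlist(sets))
    1e6 * tab / sum(tab)  # per-million normalisation
  })
  samples <- names(reads_by_sample)
  drop <- lapply(samples, function(s) logical(length(reads_by_sample[[s]])))
  names(drop) <- samples
  removed_kmers <- lapply(samples, function(s) character(0))
  names(removed_kmers) <- samples
  for (i in seq_along(samples)[-length(samples)]) {
    for (j in (i + 1):length(samples)) {
      a <- counts[[i]]; b <- counts[[j]]
      all_k <- union(names(a), names(b))
      ca <- ifelse(all_k %in% names(a), as.numeric(a[all_k]), 0)
      cb <- ifelse(all_k %in% names(b), as.numeric(b[all_k]), 0)
      hi <- pmax(ca, cb); lo <- pmin(ca, cb)
      flagged <- (hi + 0.5) / (lo + 0.5) > fold
      if (!any(flagged)) next
      low_side <- ifelse(ca < cb, samples[i], samples[j])
      for (s in unique(low_side[flagged])) {
        removed_kmers[[s]] <- union(removed_kmers[[s]], all_k[flagged & low_side == s])
      }
    }
  }
  for (s in samples) {
    if (length(removed_kmers[[s]]) == 0) next
    drop[[s]] <- map_lgl(kmer_sets[[s]], function(km) any(km %in% removed_kmers[[s]]))
  }
  removed <- imap(drop, function(dr, s) {
    tibble(sample = s, read_index = which(dr), read = reads_by_sample[[s]][dr])
  }) |> list_rbind()
  reads <- imap(reads_by_sample, function(r, s) r[!drop[[s]]])
  list(reads = reads, removed = removed)
}

read_kmers <- function(read, k) {
  n <- nchar(read)
  kmers <- substring(read, 1:(n - k + 1), k:n)
  unique(canonical_kmer(kmers))
}

canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Greedy identity clustering of transcripts
#'
#' Collapses alleles and near-identical recent paralogs: sequences are
#' processed longest-first (ties broken by sequence, then name, so the result
#' is invariant to input order) and each sequence joins the first established
#' centroid whose global-alignment identity (matches / alignment columns)
#' reaches the threshold, otherwise founds a new cluster. The representative
#' is the longest member. Alignment scoring: match +1, mismatch -1, gap open
#' -2, gap extend -0.5.
#'
#' @param sequences Named character vector of nucleotide sequences (or a
#'   `DNAStringSet`).
#' @param identity Identity threshold in (0, 1]; default 0.98.
#' @return Tibble `transcript_id`, `cluster`, `representative`.
#' @export
cluster_transcripts <- function(sequences, identity = 0.98) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0) stop_validation("empty sequence set")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  if (any(nchar(sequences) == 0)) stop_validation("empty sequence")
  ord <- order(-nchar(sequences), sequences, names(sequences))
  sequences <- sequences[ord]
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  centroids <- integer(0)
  assignment <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      aln <- Biostrings::pairwiseAlignment(
        sequences[i], sequences[centroids[ci]], type = "global",
        substitutionMatrix = mat, gapOpening = 2, gapExtension = 0.5
      )
      ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (Biostrings::nmatch(aln) / ncol_aln >= identity) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assignment[i] <- length(centroids)
    }
  }
  reps <- map_dbl(seq_along(centroids), function(ci) {
    members <- which(assignment == ci)
    members[which.max(nchar(sequences[members]))]
  })
  tibble(
    transcript_id = names(sequences),
    cluster = assignment,
    representative = names(sequences)[reps[assignment]]
  )
}
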