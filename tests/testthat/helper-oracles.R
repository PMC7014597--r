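# Independent brute-force oracles used to pin expected values.

# Benjamini-Hochberg step-up, straight from the definition: adjusted p of the
# i-th smallest p is min_{j >= i} min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Topological overlap by the definitional triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Per-base depth by direct counting.
oracle_depth <- function(starts, ends, L) {
  vapply(0:(L - 1), function(i) sum(starts <= i & i < ends), numeric(1))
}

# Average synonymous/nonsynonymous step counts between two codons over all
# orderings of the differing positions, by depth-first recursion over
# intermediate codons (structurally independent of the package's
# permutation-based implementation).
oracle_codon_path <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  recurse <- function(cur, remaining, syn, nonsyn) {
    if (length(remaining) == 0) {
      return(list(list(syn = syn, nonsyn = nonsyn, valid = TRUE)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      step_syn <- syn + as.integer(code[[nxt]] != "*" && code[[nxt]] == code[[cur]])
      step_nonsyn <- nonsyn + as.integer(code[[nxt]] == "*" || code[[nxt]] != code[[cur]])
      sub <- recurse(nxt, setdiff(remaining, p), step_syn, step_nonsyn)
      if (code[[nxt]] == "*") sub <- lapply(sub, function(s) { s$valid <- FALSE; s })
      out <- c(out, sub)
    }
    out
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(Nd = 0, Sd = 0))
  paths <- recurse(c1, pos, 0, 0)
  valid <- vapply(paths, function(s) s$valid, logical(1))
  use <- if (any(valid)) paths[valid] else paths
  c(Nd = mean(vapply(use, function(s) s$nonsyn, numeric(1))),
    Sd = mean(vapply(use, function(s) s$syn, numeric(1))))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}
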