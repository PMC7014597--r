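#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over transcripts
#' with all-positive counts, of the ratio of the sample's count to the
#' transcript's geometric mean across samples.
#'
#' @param counts Count tibble (`transcript_id` + numeric sample columns,
#'   RSEM-style expected counts allowed).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  check_expr(counts)
  m <- expr_matrix(counts)
  if (any(m < 0)) stop_validation("counts must be non-negative")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) stop_validation("no transcript with all-positive counts; size factors undefined")
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  apply(m[ref, , drop = FALSE], 2, function(col) median(col / geo))
}

#' Simplified negative-binomial Wald test
#'
#' A deliberately transparent two-group differential-expression stage
#' (labelled "deseq2-like (simplified)" in its output attribute): counts are
#' normalised by median-of-ratios size factors; the per-transcript dispersion
#' is estimated by pooled within-group method of moments with a floor of
#' 1e-8; the log2 fold change uses a half-minimum pseudo-mean for groups with
#' zero mean; its standard error comes from the delta method under the
#' NB variance `mu + alpha * mu^2`; and the Wald statistic LFC/SE is referred
#' to a standard normal. No dispersion shrinkage, Cook's filtering, or
#' independent filtering is applied.
#'
#' @param counts Count tibble.
#' @param groups Named character/factor vector mapping every sample column to
#'   one of two levels; the fold change is level2 over level1 (factor order).
#' @return Tibble `transcript_id`, `base_mean`, `log2_fold_change`, `lfc_se`,
#'   `stat`, `p_value`, `p_adj` with attribute `method`.
#' @export
nb_wald_test <- function(counts, groups) {
  check_expr(counts)
  samples <- expr_samples(counts)
  if (!all(samples %in% names(groups))) {
    stop_validation("groups must name every sample column")
  }
  g <- factor(groups[samples])
  if (nlevels(g) != 2) stop_validation("groups must have exactly two levels")
  m <- expr_matrix(counts)
  sf <- size_factors(counts)
  norm <- sweep(m, 2, sf, "/")
  idx1 <- which(g == levels(g)[1])
  idx2 <- which(g == levels(g)[2])
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(norm[, idx1, drop = FALSE])
  m2 <- rowMeans(norm[, idx2, drop = FALSE])
  if (all(m1 == 0) || all(m2 == 0)) {
    stop_validation("one group has zero counts for every transcript")
  }
  # pooled within-group method-of-moments dispersion, floored
  v1 <- if (n1 > 1) apply(norm[, idx1, drop = FALSE], 1, var) else rep(NA_real_, nrow(norm))
  v2 <- if (n2 > 1) apply(norm[, idx2, drop = FALSE], 1, var) else rep(NA_real_, nrow(norm))
  pool_var <- rowMeans(cbind(v1, v2), na.rm = TRUE)
  pool_mean <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- (pool_var - pool_mean) / pool_mean^2
  alpha[!is.finite(alpha)] <- 0
  alpha <- pmax(alpha, 1e-8)
  pos <- c(m1[m1 > 0], m2[m2 > 0])
  pseudo <- if (length(pos) > 0) 0.5 * min(pos) else 0.5
  m1p <- ifelse(m1 > 0, m1, pseudo)
  m2p <- ifelse(m2 > 0, m2, pseudo)
  lfc <- log2(m2p / m1p)
  se <- sqrt(((1 / m1p + alpha) / n1 + (1 / m2p + alpha) / n2)) / log(2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  out <- tibble(
    transcript_id = counts$transcript_id,
    base_mean = unname(rowMeans(norm)),
    log2_fold_change = unname(lfc),
    lfc_se = unname(se),
    stat = unname(stat),
    p_value = unname(p),
    p_adj = unname(bh_adjust(p))
  )
  attr(out, "method") <- "deseq2-like (simplified)"
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' Missing p-values propagate as missing and do not count toward the number
#' of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_validation("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Wald statistic from reported fold change and standard error
#'
#' @param log2fc Log2 fold change(s).
#' @param lfcse Matching standard error(s), strictly positive.
#' @return `log2fc / lfcse`.
#' @export
wald_stat_from_table <- function(log2fc, lfcse) {
  if (any(lfcse <= 0, na.rm = TRUE)) stop_validation("lfcSE must be positive")
  log2fc / lfcse
}

#' Parse reported p-value strings
#'
#' Published tables print truncated significance values; `"<0.001"` parses to
#' 0.0005 (any value below the usual alpha levels yields identical counts)
#' and `"NA"` to missing.
#'
#' @param x Character (or numeric) vector.
#' @return Numeric vector.
#' @export
parse_reported_p <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  is_na <- is.na(x) | x == "NA"
  lt <- !is_na & grepl("^<", x)
  out[lt] <- suppressWarnings(as.numeric(sub("^<", "", x[lt]))) / 2
  plain <- !is_na & !lt
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  bad <- plain & is.na(out)
  bad <- bad | (lt & is.na(out))
  if (any(bad)) {
    stop_format(sprintf("unparseable p-value cell(s): %s",
                        paste(unique(head(x[bad], 3)), collapse = ", ")))
  }
  out
}

#' Count significant transcripts in a differential-expression table
#'
#' @param table DE tibble with a `p_adj` column (numeric or printed strings,
#'   see [parse_reported_p()]).
#' @param alpha Significance level (default 0.05); the comparison is strict
#'   (`p_adj < alpha`) and missing values are never counted.
#' @return Integer count.
#' @export
count_significant <- function(table, alpha = 0.05) {
  if (!"p_adj" %in% names(table)) stop_format("table must have a p_adj column")
  p <- parse_reported_p(table$p_adj)
  sum(p < alpha, na.rm = TRUE)
}
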