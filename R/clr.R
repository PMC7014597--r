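#' Multiplicative zero replacement
#'
#' TPM tables contain sampling zeros that the log-ratio transform cannot
#' handle. Each zero is replaced by `delta_fraction` times the smallest
#' nonzero value of its sample, and the nonzero values of that sample are
#' multiplicatively rescaled so the sample total is preserved (multiplicative
#' simple replacement). The replacement rule and parameter are recorded in the
#' `"zero_replacement"` attribute.
#'
#' @param expr Expression tibble (`transcript_id` + numeric sample columns),
#'   non-negative.
#' @param delta_fraction Fraction of the per-sample minimum nonzero value used
#'   for replaced zeros (default 0.5).
#' @return Strictly positive expression tibble with unchanged column totals.
#' @export
replace_zeros <- function(expr, delta_fraction = 0.5) {
  check_expr(expr)
  if (delta_fraction <= 0 || delta_fraction > 1) {
    stop_validation("delta_fraction must be in (0, 1]")
  }
  m <- expr_matrix(expr)
  if (any(m < 0)) stop_validation("expression values must be non-negative")
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    z <- x == 0
    if (all(z)) stop_validation(sprintf("sample %s is all zero", colnames(m)[j]))
    if (!any(z)) next
    total <- sum(x)
    delta <- delta_fraction * min(x[!z])
    x[z] <- delta
    x[!z] <- x[!z] * (total - sum(z) * delta) / total
    m[, j] <- x
  }
  out <- matrix_expr(m)
  attr(out, "zero_replacement") <- list(method = "multiplicative_simple",
                                        delta_fraction = delta_fraction)
  out
}

#' Centered log-ratio transform
#'
#' Maps each sample's composition to an unconstrained zero-sum coordinate
#' system: `clr(x) = log(x) - mean(log(x))`, the mean being taken over all
#' transcripts of the sample. The transform is invariant to per-sample
#' rescaling, which is what makes closed TPM data comparable across samples.
#'
#' @param expr Strictly positive expression tibble (run [replace_zeros()]
#'   first if the table contains zeros).
#' @return Tibble of CLR values (natural-log units); each sample column sums
#'   to zero.
#' @export
clr_transform <- function(expr) {
  check_expr(expr)
  m <- expr_matrix(expr)
  if (any(m <= 0)) {
    stop_validation("clr_transform needs strictly positive values; call replace_zeros() first")
  }
  lg <- log(m)
  clr <- sweep(lg, 2, colMeans(lg))
  out <- matrix_expr(clr)
  attr(out, "units") <- "clr"
  out
}

#' Total least squares line through a sample pair
#'
#' Fits the line minimising the sum of squared perpendicular (orthogonal)
#' distances, i.e. a Deming fit with error-variance ratio 1. The slope is the
#' direction of the principal axis of the 2x2 covariance matrix. Signed
#' residuals are perpendicular distances, positive above the line:
#' `(y - slope*x - intercept) / sqrt(1 + slope^2)`.
#'
#' @param x,y Numeric vectors (CLR values of the two samples being compared).
#' @return An object of class `tls_fit` with elements `slope`, `intercept`,
#'   `residuals`, `n`. `tidy()` and `glance()` methods are provided.
#' @export
fit_orthogonal_line <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_fit("need at least 3 points for an orthogonal fit")
  if (sd(x) == 0 && sd(y) == 0) stop_fit("degenerate input: all points identical")
  if (sd(x) == 0) stop_fit("x values are all equal; orthogonal slope is vertical")
  v <- cov(cbind(x, y))
  e <- eigen(v, symmetric = TRUE)
  dir <- e$vectors[, 1]
  if (abs(dir[1]) < .Machine$double.eps) stop_fit("principal axis is vertical")
  slope <- dir[2] / dir[1]
  intercept <- mean(y) - slope * mean(x)
  res <- (y - slope * x - intercept) / sqrt(1 + slope^2)
  structure(
    list(slope = slope, intercept = intercept, residuals = res, n = length(x)),
    class = "tls_fit"
  )
}

#' @export
print.tls_fit <- function(x, ...) {
  cat(sprintf("Orthogonal (total least squares) fit: y = %.4f x + %.4f  (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' @rdname fit_orthogonal_line
#' @param x A `tls_fit` object.
#' @param ... Unused.
#' @export
tidy.tls_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"), estimate = c(x$slope, x$intercept))
}

#' @rdname fit_orthogonal_line
#' @export
glance.tls_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n = x$n,
         rss = sum(x$residuals^2))
}

tls_residuals <- function(fit, x, y) {
  (y - fit$slope * x - fit$intercept) / sqrt(1 + fit$slope^2)
}

#' Nontoxin null band for expression divergence
#'
#' The divergence null is built from the signed orthogonal residuals of the
#' background (nontoxin) transcripts around their own total-least-squares
#' fit. At `level = 0.99` the band spans the empirical 0.5% and 99.5%
#' residual quantiles, i.e. a two-sided band carrying 1% total mass.
#'
#' @param fit A [fit_orthogonal_line()] result computed on the background
#'   points only.
#' @param level Total coverage of the band, in (0.5, 1); default 0.99.
#' @return An object of class `null_band` with `lower`, `upper`, `level`,
#'   `n_background`.
#' @export
build_null_band <- function(fit, level = 0.99) {
  if (!inherits(fit, "tls_fit")) stop_validation("fit must be a tls_fit")
  if (level <= 0.5 || level >= 1) stop_validation("level must be in (0.5, 1)")
  res <- fit$residuals
  if (length(res) < 100 && level >= 0.99) {
    warn("fewer than 100 background points: the 99% band quantiles are unstable")
  }
  a <- (1 - level) / 2
  q <- quantile(res, c(a, 1 - a), names = FALSE)
  structure(
    list(lower = q[1], upper = q[2], level = level, n_background = length(res)),
    class = "null_band"
  )
}

#' @export
print.null_band <- function(x, ...) {
  cat(sprintf("Nontoxin null band (%.1f%%): [%.4f, %.4f]  (n = %d background)\n",
              100 * x$level, x$lower, x$upper, x$n_background))
  invisible(x)
}

#' Call divergence outliers against the nontoxin band
#'
#' A toxin is called an outlier when its signed orthogonal residual falls
#' strictly outside the null band; points exactly on a band boundary are
#' inside (conservative tie rule). For flagged toxins `direction` is the
#' sample on whose side of the fitted line the point lies, i.e. the sample
#' with the relatively higher CLR expression.
#'
#' @param clr CLR tibble (from [clr_transform()]).
#' @param toxin_ids Character vector of toxin transcript ids to test.
#' @param fit Background [fit_orthogonal_line()] fit for the pair.
#' @param band Matching [build_null_band()] result.
#' @param pair Length-2 character vector of sample column names `(x, y)`.
#' @return A tibble of class `divergence_calls`: `transcript_id`, `residual`,
#'   `outlier`, `direction` (NA unless flagged).
#' @export
call_outliers <- function(clr, toxin_ids, fit, band, pair) {
  check_expr(clr)
  if (length(pair) != 2 || !all(pair %in% expr_samples(clr))) {
    stop_lookup("pair must name two sample columns of the CLR table")
  }
  missing <- setdiff(toxin_ids, clr$transcript_id)
  if (length(missing) > 0) {
    stop_lookup(sprintf("toxin id(s) missing from CLR matrix: %s",
                        paste(head(missing, 3), collapse = ", ")))
  }
  rows <- match(toxin_ids, clr$transcript_id)
  x <- clr[[pair[1]]][rows]
  y <- clr[[pair[2]]][rows]
  res <- tls_residuals(fit, x, y)
  out <- res < band$lower | res > band$upper
  direction <- ifelse(out, ifelse(res > 0, pair[2], pair[1]), NA_character_)
  calls <- tibble(transcript_id = toxin_ids, residual = res,
                  outlier = out, direction = direction)
  structure(calls, class = c("divergence_calls", class(calls)),
            pair = pair, band = band, fit = fit)
}

#' Intraspecific expression-divergence screen
#'
#' End-to-end wrapper for a two-sample comparison: multiplicative zero
#' replacement, CLR transform, total-least-squares fit through the nontoxin
#' cloud, nontoxin null band, and outlier calls for the toxins.
#'
#' @param expr Expression tibble (TPM scale) containing both samples.
#' @param annotation Annotation tibble with `transcript_id` and `class`.
#' @param pair Two sample column names; the second is the y axis.
#' @param level Band coverage (default 0.99).
#' @param delta_fraction Zero-replacement parameter, see [replace_zeros()].
#' @param coordinate `"tls_residual"` (default) scores divergence as the
#'   signed orthogonal residual from the nontoxin fit; `"clr_difference"`
#'   uses the raw CLR difference `y - x` with band quantiles taken on the
#'   same coordinate.
#' @return A `divergence_calls` tibble (see [call_outliers()]) with the CLR
#'   coordinates of every toxin attached as columns `clr_x`, `clr_y`.
#' @export
divergence_outliers <- function(expr, annotation, pair, level = 0.99,
                                delta_fraction = 0.5,
                                coordinate = c("tls_residual", "clr_difference")) {
  coordinate <- match.arg(coordinate)
  check_expr(expr)
  check_annotation(annotation)
  sub <- expr[c("transcript_id", pair)]
  clr <- clr_transform(replace_zeros(sub, delta_fraction))
  nontoxin <- annotation$transcript_id[annotation$class == "nontoxin"]
  toxin <- annotation$transcript_id[annotation$class == "toxin"]
  bg <- clr |> filter(.data$transcript_id %in% nontoxin)
  if (coordinate == "tls_residual") {
    fit <- fit_orthogonal_line(bg[[pair[1]]], bg[[pair[2]]])
  } else {
    # raw CLR difference: slope 1, intercept 0, residual (y - x)/sqrt(2)
    res <- (bg[[pair[2]]] - bg[[pair[1]]]) / sqrt(2)
    fit <- structure(list(slope = 1, intercept = 0, residuals = res,
                          n = length(res)), class = "tls_fit")
  }
  band <- build_null_band(fit, level)
  calls <- call_outliers(clr, intersect(toxin, clr$transcript_id), fit, band, pair)
  rows <- match(calls$transcript_id, clr$transcript_id)
  calls$clr_x <- clr[[pair[1]]][rows]
  calls$clr_y <- clr[[pair[2]]][rows]
  calls
}

#' Toxin family composition
#'
#' Per-family percentages of total toxin expression, the standard summary of
#' a venom-gland transcriptome ("family X accounts for p% of toxin TPM").
#'
#' @param expr Expression tibble (TPM scale).
#' @param annotation Annotation tibble (`transcript_id`, `class`, `family`).
#' @param scope `"per_sample"` (default) or `"species_average"`, the latter
#'   being the arithmetic mean of the per-sample percentages.
#' @return A tibble `family`, `sample`, `percent` (per sample) or `family`,
#'   `percent` (species average). Percentages sum to 100 within each sample.
#' @export
family_composition <- function(expr, annotation,
                               scope = c("per_sample", "species_average")) {
  scope <- match.arg(scope)
  check_expr(expr)
  check_annotation(annotation)
  tox <- annotation |> filter(.data$class == "toxin") |> select("transcript_id", "family")
  joined <- expr |> inner_join(tox, by = "transcript_id")
  long <- joined |>
    pivot_longer(all_of(expr_samples(expr)), names_to = "sample", values_to = "tpm")
  totals <- long |> group_by(.data$sample) |> summarise(total = sum(.data$tpm))
  if (any(totals$total == 0)) stop_validation("zero total toxin TPM in a sample")
  per_sample <- long |>
    group_by(.data$family, .data$sample) |>
    summarise(tpm = sum(.data$tpm), .groups = "drop") |>
    left_join(totals, by = "sample") |>
    mutate(percent = 100 * .data$tpm / .data$total) |>
    select("family", "sample", "percent")
  if (scope == "per_sample") return(per_sample)
  per_sample |>
    group_by(.data$family) |>
    summarise(percent = mean(.data$percent), .groups = "drop")
}
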