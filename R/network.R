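#' Transform and variance-filter an expression table for network analysis
#'
#' Applies a variance-stabilising `log2(x + 1)` transform to TPM-scale
#' expression and retains the transcripts whose variance exceeds the
#' mean-variance trend the most: a loess trend of per-transcript variance on
#' mean is fitted on the transformed data and transcripts are ranked by the
#' residual (trend-decoupled) dispersion. Constant transcripts are always
#' dropped.
#'
#' @param expr Expression tibble with at least 4 sample columns.
#' @param filter_quantile Proportion of (non-constant) transcripts to drop
#'   from the bottom of the residual-dispersion ranking; 0 retains all
#'   (default 0.75, i.e. keep the top quarter).
#' @return Transformed expression tibble restricted to retained transcripts,
#'   with the ranking in attribute `"dispersion"`.
#' @export
transform_and_filter <- function(expr, filter_quantile = 0.75) {
  check_expr(expr)
  samples <- expr_samples(expr)
  if (length(samples) < 4) stop_validation("network analysis needs at least 4 samples")
  if (filter_quantile < 0 || filter_quantile >= 1) {
    stop_validation("filter_quantile must be in [0, 1)")
  }
  m <- log2(expr_matrix(expr) + 1)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep_var <- v > 0
  disp <- rep(NA_real_, nrow(m))
  if (sum(keep_var) >= 2) {
    mu_k <- mu[keep_var]; v_k <- v[keep_var]
    trend <- if (sum(keep_var) >= 10) {
      fitted(loess(v_k ~ mu_k, degree = 1, span = 0.75))
    } else {
      fitted(lm(v_k ~ mu_k))
    }
    disp[keep_var] <- v_k - trend
  } else {
    disp[keep_var] <- v[keep_var]
  }
  ranking <- tibble(transcript_id = expr$transcript_id, mean = mu,
                    variance = v, dispersion = disp)
  retained <- keep_var
  if (filter_quantile > 0 && any(keep_var)) {
    cut <- quantile(disp[keep_var], filter_quantile, names = FALSE)
    retained <- keep_var & !is.na(disp) & disp > cut
    if (!any(retained)) retained <- keep_var & disp == max(disp[keep_var])
  }
  out <- matrix_expr(m[retained, , drop = FALSE])
  attr(out, "dispersion") <- ranking
  out
}

#' Soft-threshold coexpression adjacency
#'
#' Raises the Pearson correlation between transcript profiles to the power
#' `beta`, the soft threshold that suppresses weak correlations while keeping
#' the network weighted. The unsigned variant (default) uses `|cor|^beta`, so
#' strongly anti-correlated transcripts are adjacent; the signed variant uses
#' `((1 + cor)/2)^beta`.
#'
#' @param texpr Transformed expression tibble (see [transform_and_filter()]),
#'   at least 3 samples.
#' @param beta Soft-threshold exponent, >= 1 (default 10).
#' @param signed Use the signed adjacency (default FALSE).
#' @return Symmetric adjacency matrix in \[0, 1\] with zero diagonal,
#'   transcript ids as dimnames.
#' @export
adjacency <- function(texpr, beta = 10, signed = FALSE) {
  check_expr(texpr)
  if (beta < 1) stop_validation("beta must be >= 1")
  m <- expr_matrix(texpr)
  if (ncol(m) < 3) stop_validation("need at least 3 samples for correlations")
  if (any(apply(m, 1, var) == 0)) {
    stop_validation("zero-variance transcript present; run transform_and_filter() first")
  }
  r <- cor(t(m))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' Network similarity that augments direct adjacency with shared-neighbour
#' weight: `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k` the row sums of the adjacency; `TOM_ii = 1`.
#'
#' @param adj Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop_validation("adjacency must be square")
  if (max(abs(adj - t(adj))) > 1e-8) stop_validation("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1)) stop_validation("adjacency values must lie in [0, 1]")
  if (any(diag(adj) != 0)) stop_validation("adjacency diagonal must be zero")
  k <- rowSums(adj)
  shared <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (shared + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at the height (over the grid 0.05, 0.10, ..., 0.95) that maximises the
#' mean silhouette width. Clusters smaller than `min_module_size` are
#' reassigned to module 0 (background); surviving modules are renumbered by
#' decreasing size.
#'
#' @param tom TOM similarity matrix from [topological_overlap()].
#' @param min_module_size Smallest cluster kept as a module (default 1).
#' @return Tibble of class `module_assignment`: `transcript_id`, `module`
#'   (0 = background), with the chosen cut height in attribute
#'   `"cut_height"`.
#' @export
detect_modules <- function(tom, min_module_size = 1) {
  if (!is.matrix(tom)) stop_validation("tom must be a matrix")
  n <- nrow(tom)
  ids <- rownames(tom) %||% paste0("t", seq_len(n))
  if (n == 1) {
    labels <- 1L
    height <- NA_real_
  } else {
    d <- as.dist(1 - tom)
    hc <- hclust(d, method = "average")
    heights <- seq(0.05, 0.95, by = 0.05)
    best <- NULL
    for (h in heights) {
      lab <- cutree(hc, h = h)
      k <- length(unique(lab))
      if (k < 2 || k >= n) next
      sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])
      if (is.null(best) || sil > best$sil) best <- list(sil = sil, lab = lab, h = h)
    }
    if (is.null(best)) {
      labels <- rep(1L, n)
      height <- NA_real_
    } else {
      labels <- best$lab
      height <- best$h
    }
  }
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_module_size]
  labels[labels %in% as.integer(small)] <- 0L
  kept <- sort(table(labels[labels != 0]), decreasing = TRUE)
  relabel <- setNames(seq_along(names(kept)), names(kept))
  module <- ifelse(labels == 0, 0L, relabel[as.character(labels)])
  out <- tibble(transcript_id = ids, module = as.integer(module))
  structure(out, class = c("module_assignment", class(out)), cut_height = height)
}

#' Per-treatment module expression profiles
#'
#' @param assignment Module assignment tibble ([detect_modules()]).
#' @param texpr Transformed expression tibble used for detection.
#' @param sample_meta Tibble `sample_id`, `venom_type` covering every sample.
#' @return Tibble `module`, `venom_type`, `mean_expression`, `background`
#'   (TRUE for module 0) with per-transcript z-scored profile lines in
#'   attribute `"lines"`.
#' @export
module_profiles <- function(assignment, texpr, sample_meta) {
  check_expr(texpr)
  samples <- expr_samples(texpr)
  if (!all(samples %in% sample_meta$sample_id)) {
    stop_validation("every sample needs a treatment in sample_meta")
  }
  long <- texpr |>
    pivot_longer(all_of(samples), names_to = "sample_id", values_to = "value") |>
    left_join(sample_meta, by = "sample_id") |>
    left_join(assignment, by = "transcript_id")
  profiles <- long |>
    group_by(.data$module, .data$venom_type) |>
    summarise(mean_expression = mean(.data$value), .groups = "drop") |>
    mutate(background = .data$module == 0)
  lines <- long |>
    group_by(.data$transcript_id) |>
    mutate(z = if (sd(.data$value) > 0) (.data$value - mean(.data$value)) / sd(.data$value) else 0) |>
    ungroup() |>
    group_by(.data$module, .data$transcript_id, .data$venom_type) |>
    summarise(z = mean(.data$z), .groups = "drop")
  attr(profiles, "lines") <- lines
  profiles
}

#' Full coexpression submodule analysis
#'
#' Chains [transform_and_filter()], [adjacency()], [topological_overlap()],
#' [detect_modules()] and [module_profiles()]. A warning is issued for fewer
#' than 8 samples, where correlations are necessarily noisy (the analysis
#' refuses to run below 4).
#'
#' @inheritParams transform_and_filter
#' @inheritParams adjacency
#' @inheritParams detect_modules
#' @param sample_meta Tibble `sample_id`, `venom_type`.
#' @return Object of class `coexpression_modules`: list with `assignment`,
#'   `profiles`, `tom`, and the configuration used.
#' @export
find_coexpression_modules <- function(expr, sample_meta, beta = 10, signed = FALSE,
                                      min_module_size = 1, filter_quantile = 0.75) {
  if (length(expr_samples(expr)) < 8) {
    warn("fewer than 8 samples: module assignment will be noisy")
  }
  texpr <- transform_and_filter(expr, filter_quantile)
  adj <- adjacency(texpr, beta = beta, signed = signed)
  tom <- topological_overlap(adj)
  assignment <- detect_modules(tom, min_module_size)
  profiles <- module_profiles(assignment, texpr, sample_meta)
  structure(
    list(assignment = assignment, profiles = profiles, tom = tom,
         config = list(beta = beta, signed = signed,
                       min_module_size = min_module_size,
                       filter_quantile = filter_quantile)),
    class = "coexpression_modules"
  )
}

#' @export
print.coexpression_modules <- function(x, ...) {
  k <- sum(unique(x$assignment$module) != 0)
  cat(sprintf("Coexpression analysis: %d transcripts in %d modules (beta = %g, %s)\n",
              nrow(x$assignment), k, x$config$beta,
              if (x$config$signed) "signed" else "unsigned"))
  invisible(x)
}

#' @rdname find_coexpression_modules
#' @param x A `coexpression_modules` object.
#' @param ... Unused.
#' @export
tidy.coexpression_modules <- function(x, ...) x$assignment
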