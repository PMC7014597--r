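#' Read a transcript expression table
#'
#' Reads relative-abundance (TPM-scale) expression into the wide tibble used
#' throughout the package: one `transcript_id` column plus one numeric column
#' per sample.
#'
#' Two dialects are supported. `"wide_tsv"` is the package's own format
#' (written by [write_expression_table()]). `"rsem_results"` is the per-sample
#' results file of the RSEM quantifier; the reader is header-driven and
#' accepts any column superset as long as `transcript_id`, `expected_count`
#' and `TPM` are present, so it tolerates column drift across RSEM versions.
#' For the RSEM dialect `path` may be a vector of per-sample files; names are
#' used as sample ids (falling back to file basenames).
#'
#' @param path Path to a TSV file, or for `dialect = "rsem_results"` a
#'   (optionally named) vector of per-sample files.
#' @param dialect `"wide_tsv"` or `"rsem_results"`.
#' @param value For the RSEM dialect, which column to tabulate
#'   (`"TPM"` or `"expected_count"`).
#' @return A tibble with `transcript_id` and one numeric column per sample.
#'   The per-sample totals are recorded in the `"sample_totals"` attribute.
#' @export
read_expression_table <- function(path, dialect = c("wide_tsv", "rsem_results"),
                                  value = c("TPM", "expected_count")) {
  dialect <- match.arg(dialect)
  value <- match.arg(value)
  if (dialect == "wide_tsv") {
    if (length(path) != 1) stop_format("wide_tsv dialect expects a single file")
    if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
    tbl <- tryCatch(
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) stop_format(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
    )
    if (nrow(tbl) == 0 && ncol(tbl) == 0) stop_format(sprintf("empty expression file: %s", path))
    if (!"transcript_id" %in% names(tbl)) {
      stop_format("malformed header: expected a transcript_id column")
    }
    tbl <- as_tibble(tbl)
  } else {
    if (is.null(names(path)) || any(names(path) == "")) {
      names(path) <- sub("\\.[^.]*$", "", basename(path))
    }
    cols <- imap(path, function(p, sample) {
      if (!file.exists(p)) stop_format(sprintf("file not found: %s", p))
      rs <- tryCatch(
        readr::read_tsv(p, show_col_types = FALSE, progress = FALSE),
        error = function(e) stop_format(sprintf("cannot parse %s: %s", p, conditionMessage(e)))
      )
      need <- c("transcript_id", "expected_count", "TPM")
      if (!all(need %in% names(rs))) {
        stop_format(sprintf(
          "malformed RSEM header in %s: need columns %s", p, paste(need, collapse = ", ")
        ))
      }
      tibble(transcript_id = as.character(rs$transcript_id), !!sample := rs[[value]])
    })
    tbl <- purrr::reduce(cols, function(a, b) {
      out <- full_join(a, b, by = "transcript_id")
      if (anyNA(out)) {
        stop_validation("transcript sets differ across RSEM files; zero-fill explicitly if intended")
      }
      out
    })
  }
  check_expr(tbl)
  m <- expr_matrix(tbl)
  if (any(m < 0)) stop_validation("expression values must be non-negative")
  attr(tbl, "sample_totals") <- colSums(m)
  tbl
}

#' Write a wide expression table
#'
#' @param expr Expression tibble (`transcript_id` + sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  check_expr(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read transcript annotation
#'
#' Annotation assigns each transcript a class (`toxin`/`nontoxin`), a toxin
#' family (empty for nontoxins) and an orthology label.
#'
#' @param path TSV with columns `transcript_id`, `class`, `family`,
#'   `orthology_label`.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("transcript_id", "class", "family", "orthology_label")
  if (!all(need %in% names(tbl))) {
    stop_format(sprintf("malformed annotation header: need %s", paste(need, collapse = ", ")))
  }
  tbl$family[is.na(tbl$family)] <- ""
  check_annotation(tbl)
  tbl
}

check_annotation <- function(ann) {
  if (anyDuplicated(ann$transcript_id)) stop_validation("annotation transcript ids must be unique")
  if (!all(ann$class %in% c("toxin", "nontoxin"))) {
    stop_validation("annotation class must be 'toxin' or 'nontoxin'")
  }
  bad <- (ann$class == "toxin") != (ann$family != "")
  if (any(bad)) {
    stop_validation(sprintf(
      "family must be non-empty exactly for toxins (offending: %s)",
      paste(head(ann$transcript_id[bad], 3), collapse = ", ")
    ))
  }
  invisible(ann)
}

#' Read an orthogroups table
#'
#' Expects the OrthoFinder-style layout: an `Orthogroup` id column followed by
#' one column per species holding comma-separated member transcript ids.
#'
#' @param path TSV path.
#' @return A long tibble with columns `orthogroup`, `species`,
#'   `transcript_id`; the species column names are kept in the `"species"`
#'   attribute.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(tbl) < 3 || !tolower(names(tbl)[1]) %in% c("orthogroup", "og")) {
    stop_format("malformed orthogroups header: expected Orthogroup + one column per species")
  }
  species <- names(tbl)[-1]
  long <- tbl |>
    rename(orthogroup = 1) |>
    pivot_longer(-"orthogroup", names_to = "species", values_to = "members") |>
    filter(!is.na(.data$members), .data$members != "") |>
    mutate(transcript_id = strsplit(.data$members, ",\\s*")) |>
    select(-"members") |>
    tidyr::unnest("transcript_id")
  dup <- long$transcript_id[duplicated(long$transcript_id)]
  if (length(dup) > 0) {
    stop_validation(sprintf(
      "transcript(s) assigned to more than one orthogroup: %s",
      paste(unique(head(dup, 3)), collapse = ", ")
    ))
  }
  structure(long, species = species)
}

#' Read / write gene-family trees
#'
#' Thin wrappers around \pkg{ape}'s newick parser that signal classed format
#' errors and optionally check tip labels against an orthology table.
#'
#' @param path Newick file.
#' @param orthology Optional long orthology tibble (see [read_orthogroups()]);
#'   tips absent from it trigger a warning, not an error.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_tree <- function(path, orthology = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) NULL)
  if (is.null(tree)) stop_format(sprintf("unparseable newick: %s", path))
  if (!is.null(orthology)) {
    missing <- setdiff(tree$tip.label, orthology$transcript_id)
    if (length(missing) > 0) {
      warn(sprintf("tree tips not in orthology table: %s", paste(missing, collapse = ", ")))
    }
  }
  tree
}

#' @rdname read_tree
#' @param tree A `phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bundled Bothriechis toxin tables
#'
#' Curated per-toxin summaries for the *Bothriechis nigroviridis* /
#' *B. nubestris* venom-gland transcriptome comparison: orthology label, toxin
#' family, TPM in each of two individuals, the over-expression call from the
#' intraspecific divergence screen (the id of the over-expressing individual,
#' or `"-"`), and the coverage-based presence call (`"+"`/`"-"`) per
#' individual.
#'
#' @param species `"nigroviridis"` or `"nubestris"`.
#' @return A tibble with one row per toxin transcript.
#' @export
bothriechis_toxins <- function(species = c("nigroviridis", "nubestris")) {
  species <- match.arg(species)
  path <- system.file("extdata", sprintf("bothriechis_%s_toxins.tsv", species),
                      package = "palmviper", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  mutate(tbl, across(starts_with("tpm_"), as.numeric))
}

#' Bundled Bothriechis differential-expression tables
#'
#' Per-toxin DESeq2 summaries for the two interspecific contrasts of the
#' Bothriechis comparison: the Type A *B. nigroviridis* individual versus
#' *B. nubestris*, and the Type A+B individual versus *B. nubestris*.
#' Significance columns are kept as printed (`"<0.001"`, `"NA"`); use
#' [parse_reported_p()] or [count_significant()] to work with them.
#'
#' @param comparison `"typeA"` or `"typeAB"`.
#' @return A tibble with columns `toxin`, `base_mean`, `log2_fold_change`,
#'   `lfc_se`, `stat`, `p_value`, `p_adj`.
#' @export
bothriechis_de <- function(comparison = c("typeA", "typeAB")) {
  comparison <- match.arg(comparison)
  path <- system.file("extdata", sprintf("bothriechis_de_%s_vs_nubestris.tsv", comparison),
                      package = "palmviper", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    toxin = "c", base_mean = "d", log2_fold_change = "d",
                    lfc_se = "d", stat = "d", p_value = "c", p_adj = "c"
                  ))
}

#' Expression tibble for a bundled toxin table
#'
#' Convenience accessor reshaping [bothriechis_toxins()] into the package's
#' wide expression layout (toxins only).
#'
#' @inheritParams bothriechis_toxins
#' @return Expression tibble with two sample columns.
#' @export
bothriechis_expression <- function(species = c("nigroviridis", "nubestris")) {
  tbl <- bothriechis_toxins(species)
  out <- tbl |> select("toxin_id", starts_with("tpm_")) |> rename(transcript_id = "toxin_id")
  names(out) <- sub("^tpm_", "", names(out))
  out
}
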