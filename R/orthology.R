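#' Classify orthogroups into one-to-one orthologs, duplications and losses
#'
#' For a two-species orthogroup with `mA` and `mB` members: 1:1 groups are
#' one-to-one orthologs; groups with more than one member on a side record
#' `max(mA, mB) - 1` duplication events in the multi-member species; groups
#' with an empty side record a loss in the empty species. With only two
#' species, "loss in A" and "gain in B" are equally parsimonious; the loss
#' wording is used and recorded in the `"polarity"` attribute of the events
#' table.
#'
#' @param orthology Long tibble `orthogroup`, `species`, `transcript_id`
#'   (see [read_orthogroups()] / [simulate_orthogroups()]).
#' @param species Optional length-2 character giving the two species; by
#'   default taken from the table (which must then contain exactly two).
#' @return List with `classes` (tibble `transcript_id`, `species`,
#'   `orthogroup`, `class` in `one_to_one` / `duplication_member` /
#'   `lost_in_other`) and `events` (tibble `orthogroup`, `event`, `species`,
#'   `count`).
#' @export
classify_orthogroups <- function(orthology, species = NULL) {
  if (!all(c("orthogroup", "species", "transcript_id") %in% names(orthology))) {
    stop_validation("orthology must have columns orthogroup, species, transcript_id")
  }
  if (is.null(species)) species <- attr(orthology, "species") %||% sort(unique(orthology$species))
  if (length(species) != 2) stop_validation("classification requires exactly two species")
  extra <- setdiff(unique(orthology$species), species)
  if (length(extra) > 0) {
    stop_validation(sprintf("unexpected species in table: %s", paste(extra, collapse = ", ")))
  }
  sizes <- orthology |>
    count(.data$orthogroup, .data$species) |>
    pivot_wider(names_from = "species", values_from = "n", values_fill = 0)
  for (s in species) if (!s %in% names(sizes)) sizes[[s]] <- 0L
  mA <- sizes[[species[1]]]
  mB <- sizes[[species[2]]]
  grp_class <- case_when(
    mA == 1 & mB == 1 ~ "one_to_one",
    mA == 0 | mB == 0 ~ "lost_in_other",
    TRUE ~ "duplication_member"
  )
  # multi-member groups with an empty side are still losses, but their extra
  # members also count as duplications (max(m) - 1 events)
  dup_events <- tibble(
    orthogroup = sizes$orthogroup,
    event = "duplication",
    species = ifelse(mA >= mB, species[1], species[2]),
    count = pmax(mA, mB) - 1L
  ) |> filter(.data$count >= 1)
  loss_events <- tibble(
    orthogroup = sizes$orthogroup,
    event = "loss",
    species = case_when(mA == 0 ~ species[1], mB == 0 ~ species[2], TRUE ~ NA_character_),
    count = 1L
  ) |> filter(!is.na(.data$species))
  classes <- orthology |>
    select("transcript_id", "species", "orthogroup") |>
    left_join(tibble(orthogroup = sizes$orthogroup, class = grp_class), by = "orthogroup") |>
    as_tibble()
  events <- bind_rows(dup_events, loss_events) |> arrange(.data$orthogroup, .data$event)
  attr(events, "polarity") <- "losses polarised to the species lacking members; gain-in-other-species is equally parsimonious for two taxa"
  list(classes = classes, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge cross-species expression with zero-filled paralogs
#'
#' Builds the combined interspecific expression table: one row per orthogroup
#' member. One-to-one orthologs get their partner's values in the other
#' species' samples; every other member (paralogs, species-specific
#' transcripts) is zero-filled there, and those cells are flagged as
#' structural zeros — they mean "transcript does not exist in that species",
#' not "expression sampled as zero" — so downstream zero replacement must not
#' touch them (see [structural_zeros()]).
#'
#' @param classes `classes` tibble from [classify_orthogroups()].
#' @param orthology The long orthology tibble used for classification.
#' @param expr_a,expr_b Expression tibbles for the two species (sample
#'   columns must not overlap).
#' @param species Length-2 character naming the species of `expr_a` and
#'   `expr_b`, in that order.
#' @return Tibble `transcript_id`, `species`, `orthogroup`, `class` plus all
#'   sample columns of both species; structural-zero flags in the
#'   `"structural"` attribute.
#' @export
merge_cross_species_expression <- function(classes, orthology, expr_a, expr_b, species) {
  check_expr(expr_a); check_expr(expr_b)
  if (length(intersect(expr_samples(expr_a), expr_samples(expr_b))) > 0) {
    stop_validation("sample columns of the two species overlap")
  }
  lookup <- list(expr_a, expr_b)
  names(lookup) <- species
  missing <- classes |>
    mutate(found = map2_lgl_(classes$transcript_id, classes$species, function(id, sp) {
      id %in% lookup[[sp]]$transcript_id
    })) |>
    filter(!.data$found)
  if (nrow(missing) > 0) {
    stop_lookup(sprintf("no expression for classified transcript(s): %s",
                        paste(head(missing$transcript_id, 3), collapse = ", ")))
  }
  partner_of <- function(id, sp, og, cls) {
    if (cls != "one_to_one") return(NA_character_)
    other <- setdiff(species, sp)
    orthology$transcript_id[orthology$orthogroup == og & orthology$species == other]
  }
  samples_a <- expr_samples(expr_a)
  samples_b <- expr_samples(expr_b)
  rows <- pmap(classes, function(transcript_id, species_, orthogroup, class, ...) {
    sp <- species_
    own <- if (sp == species[1]) expr_a else expr_b
    own_vals <- own[match(transcript_id, own$transcript_id), expr_samples(own), drop = FALSE]
    other_samples <- if (sp == species[1]) samples_b else samples_a
    if (class == "one_to_one") {
      partner <- partner_of(transcript_id, sp, orthogroup, class)
      other_tbl <- if (sp == species[1]) expr_b else expr_a
      other_vals <- other_tbl[match(partner, other_tbl$transcript_id), other_samples, drop = FALSE]
      structural <- setNames(rep(FALSE, length(other_samples)), other_samples)
    } else {
      other_vals <- as_tibble(setNames(as.list(rep(0, length(other_samples))), other_samples))
      structural <- setNames(rep(TRUE, length(other_samples)), other_samples)
    }
    list(
      row = bind_cols(tibble(transcript_id = transcript_id, species = sp,
                             orthogroup = orthogroup, class = class),
                      own_vals, other_vals),
      structural = tibble(transcript_id = transcript_id,
                          sample = names(structural), structural = unname(structural))
    )
  })
  out <- list_rbind(map(rows, "row"))
  out <- out[c("transcript_id", "species", "orthogroup", "class", samples_a, samples_b)]
  attr(out, "structural") <- list_rbind(map(rows, "structural"))
  out
}

# pmap over a tibble passes columns by name; `species` clashes with the
# argument, so rename defensively.
pmap <- function(tbl, f) {
  purrr::pmap(list(tbl$transcript_id, tbl$species, tbl$orthogroup, tbl$class),
              function(a, b, c, d) f(a, b, c, d))
}

map2_lgl_ <- function(x, y, f) purrr::map2_lgl(x, y, f)

#' Structural-zero flags of a merged expression table
#'
#' @param merged Result of [merge_cross_species_expression()].
#' @return Long tibble `transcript_id`, `sample`, `structural` covering the
#'   other-species samples of each member.
#' @export
structural_zeros <- function(merged) {
  attr(merged, "structural") %||% stop_validation("not a merged expression table")
}

#' Map duplication and loss events onto a gene-family tree
#'
#' Duplications are attached to the stem edge (MRCA node) of the duplicated
#' tips when they are monophyletic in the family tree, otherwise to the tips
#' themselves; losses are attached to the surviving ortholog's tip — its
#' sister position marks where the lost copy would branch. One annotation row
#' is produced per event row.
#'
#' @param tree `phylo` gene-family tree with transcript-id tip labels.
#' @param events Events tibble from [classify_orthogroups()].
#' @param orthology Long orthology tibble mapping transcripts to orthogroups.
#' @return Object of class `turnover_map`: list with `tree` and `annotations`
#'   (tibble `orthogroup`, `event`, `species`, `count`, `node`, `placement`).
#' @export
map_events_on_tree <- function(tree, events, orthology) {
  if (!inherits(tree, "phylo")) stop_validation("tree must be an ape phylo object")
  ann <- purrr::pmap(events, function(orthogroup, event, species, count) {
    members <- orthology[orthology$orthogroup == orthogroup, ]
    if (event == "duplication") {
      tips <- intersect(members$transcript_id[members$species == species], tree$tip.label)
      if (length(tips) == 0) {
        warn(sprintf("orthogroup %s: no tips in tree; event left unannotated", orthogroup))
        return(NULL)
      }
      if (length(tips) > 1 && ape::is.monophyletic(tree, tips)) {
        node <- ape::getMRCA(tree, tips)
        placement <- "stem_edge"
      } else {
        node <- match(tips[1], tree$tip.label)
        placement <- "tips"
      }
    } else {
      survivors <- intersect(members$transcript_id, tree$tip.label)
      if (length(survivors) == 0) {
        warn(sprintf("orthogroup %s: no surviving tip in tree; loss left unannotated", orthogroup))
        return(NULL)
      }
      node <- match(survivors[1], tree$tip.label)
      placement <- "sister_of_tip"
    }
    tibble(orthogroup = orthogroup, event = event, species = species,
           count = count, node = node, placement = placement)
  }) |> list_rbind()
  structure(list(tree = tree, annotations = ann), class = "turnover_map")
}

#' @export
print.turnover_map <- function(x, ...) {
  cat(sprintf("Gene-family turnover map: %d tips, %d annotated events\n",
              length(x$tree$tip.label), nrow(x$annotations)))
  invisible(x)
}

#' Write an annotated gene-family tree
#'
#' Event annotations are appended to tip / node labels as
#' `"[duplication:A]"`-style comments so the newick remains parseable.
#'
#' @param map A [map_events_on_tree()] result.
#' @param path Output newick path.
#' @export
write_annotated_tree <- function(map, path) {
  tree <- map$tree
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  if (nrow(map$annotations) > 0) {
    for (r in seq_len(nrow(map$annotations))) {
      a <- map$annotations[r, ]
      tag <- sprintf("[%s:%s]", a$event, a$species)
      if (a$node <= n_tip) {
        tree$tip.label[a$node] <- paste0(tree$tip.label[a$node], tag)
      } else {
        k <- a$node - n_tip
        tree$node.label[k] <- paste0(tree$node.label[k], tag)
      }
    }
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Two-way factorial test of ortholog versus paralog expression
#'
#' Fits `clr_expression ~ toxin_type * species` where `toxin_type` contrasts
#' one-to-one orthologs against duplicated/species-specific toxins, using
#' each transcript's CLR expression in its own species' samples as the
#' observations. Type II sums of squares are used because the design is
#' unbalanced (unequal member counts per class).
#'
#' @param merged_clr Merged expression table in CLR units (same layout as
#'   [merge_cross_species_expression()] output).
#' @param sample_species Named character vector mapping sample columns to
#'   species.
#' @return Tidy tibble `term`, `sumsq`, `df`, `statistic`, `p_value`.
#' @export
ortholog_paralog_factorial <- function(merged_clr, sample_species) {
  samples <- intersect(names(sample_species), names(merged_clr))
  if (length(samples) == 0) stop_validation("no sample columns matched sample_species")
  obs <- merged_clr |>
    pivot_longer(all_of(samples), names_to = "sample", values_to = "value") |>
    mutate(sample_sp = sample_species[.data$sample]) |>
    filter(.data$sample_sp == .data$species) |>
    mutate(toxin_type = ifelse(.data$class == "one_to_one", "ortholog", "paralog"))
  cells <- obs |> count(.data$toxin_type, .data$species)
  if (nrow(cells) < 4 || any(cells$n < 2)) {
    empty <- tidyr::expand_grid(toxin_type = c("ortholog", "paralog"),
                                species = unique(obs$species)) |>
      anti_join(cells |> filter(.data$n >= 2), by = c("toxin_type", "species"))
    stop_validation(sprintf(
      "need >=2 observations per cell; deficient cell(s): %s",
      paste(paste(empty$toxin_type, empty$species, sep = ":"), collapse = ", ")
    ))
  }
  mod <- lm(value ~ toxin_type * species, data = obs)
  a2 <- car::Anova(mod, type = 2)
  tibble(
    term = rownames(a2),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p_value = a2$`Pr(>F)`
  ) |> filter(.data$term != "Residuals")
}
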