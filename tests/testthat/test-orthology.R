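test_that("orthogroup classification follows the definitional cases", {
  og <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG2", "OG2", "OG2", "OG3"),
    species = c("A", "B", "A", "A", "B", "B"),
    transcript_id = c("a1", "b1", "a2", "a3", "b2", "b3")
  )
  cls <- classify_orthogroups(og, species = c("A", "B"))
  got <- setNames(cls$classes$class, cls$classes$transcript_id)
  expect_equal(unname(got[c("a1", "b1")]), rep("one_to_one", 2))
  expect_equal(unname(got[c("a2", "a3", "b2")]), rep("duplication_member", 3))
  expect_equal(unname(got["b3"]), "lost_in_other")
  dup <- cls$events[cls$events$event == "duplication", ]
  expect_equal(dup$species, "A")
  expect_equal(dup$count, 1L)
  loss <- cls$events[cls$events$event == "loss", ]
  expect_equal(loss$species, "A")
})

test_that("classification inverts the generator over a parameter sweep", {
  withr::local_seed(12)
  for (i in 1:50) {
    n <- c(sample(0:8, 1), sample(0:4, 1), sample(0:4, 1), sample(0:4, 1), sample(0:4, 1))
    if (sum(n) == 0) n[1] <- 1
    og <- simulate_orthogroups(n[1], n[2], n[3], n[4], n[5], seed = i)
    cls <- classify_orthogroups(og)
    ev <- cls$events
    count_of <- function(event, sp) sum(ev$count[ev$event == event & ev$species == sp])
    expect_equal(count_of("duplication", "A"), n[2])
    expect_equal(count_of("duplication", "B"), n[3])
    expect_equal(count_of("loss", "A"), n[4])
    expect_equal(count_of("loss", "B"), n[5])
    expect_equal(sum(cls$classes$class == "one_to_one") / 2, n[1])
  }
})

test_that("event conservation identities hold on random tables", {
  withr::local_seed(13)
  for (i in 1:20) {
    og <- simulate_orthogroups(sample(1:6, 1), sample(0:3, 1), sample(0:3, 1),
                               sample(0:3, 1), sample(0:3, 1), seed = 100 + i)
    sizes <- og |>
      dplyr::count(.data$orthogroup, .data$species) |>
      tidyr::pivot_wider(names_from = "species", values_from = "n", values_fill = 0)
    if (!"A" %in% names(sizes)) sizes$A <- 0L
    if (!"B" %in% names(sizes)) sizes$B <- 0L
    ev <- classify_orthogroups(og)$events
    expect_equal(sum(ev$count[ev$event == "duplication"]),
                 sum(pmax(sizes$A, sizes$B) - 1))
    expect_equal(sum(ev$count[ev$event == "loss"]),
                 sum(sizes$A == 0 | sizes$B == 0))
  }
})

test_that("both bundled toxin tables label 32 orthologs", {
  expect_equal(sum(bothriechis_toxins("nigroviridis")$orthology_label == "Ortholog"), 32)
  expect_equal(sum(bothriechis_toxins("nubestris")$orthology_label == "Ortholog"), 32)
})

test_that("merged expression zero-fills paralogs and conserves rows", {
  og <- simulate_orthogroups(4, 1, 1, 1, 1, seed = 14)
  cls <- classify_orthogroups(og)
  ids_a <- cls$classes$transcript_id[cls$classes$species == "A"]
  ids_b <- cls$classes$transcript_id[cls$classes$species == "B"]
  withr::local_seed(14)
  ea <- tibble::tibble(transcript_id = ids_a, A1 = rexp(length(ids_a)), A2 = rexp(length(ids_a)))
  eb <- tibble::tibble(transcript_id = ids_b, B1 = rexp(length(ids_b)), B2 = rexp(length(ids_b)))
  merged <- merge_cross_species_expression(cls$classes, og, ea, eb, c("A", "B"))
  expect_equal(nrow(merged), nrow(og))

  sz <- structural_zeros(merged)
  one2one <- merged$transcript_id[merged$class == "one_to_one"]
  expect_false(any(sz$structural[sz$transcript_id %in% one2one]))
  b_only <- merged$transcript_id[merged$class == "lost_in_other" & merged$species == "B"]
  expect_true(length(b_only) > 0)
  for (id in b_only) {
    expect_equal(unlist(merged[merged$transcript_id == id, c("A1", "A2")]),
                 c(A1 = 0, A2 = 0))
    expect_true(all(sz$structural[sz$transcript_id == id & sz$sample %in% c("A1", "A2")]))
  }

  expect_error(
    merge_cross_species_expression(cls$classes, og, ea[-1, ], eb, c("A", "B")),
    class = "palmviper_lookup_error"
  )
})

test_that("turnover events map onto trees with one annotation per event", {
  og <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG1"),
    species = c("A", "A", "B"),
    transcript_id = c("a1", "a2", "b1")
  )
  cls <- classify_orthogroups(og, species = c("A", "B"))
  tree <- ape::read.tree(text = "((a1,a2),b1);")
  map <- map_events_on_tree(tree, cls$events, og)
  expect_equal(nrow(map$annotations), nrow(cls$events))
  ann <- map$annotations
  expect_equal(ann$placement[ann$event == "duplication"], "stem_edge")
  expect_equal(ann$node[ann$event == "duplication"], ape::getMRCA(tree, c("a1", "a2")))

  flat <- ape::read.tree(text = "(a1,b1);")
  none <- classify_orthogroups(
    tibble::tibble(orthogroup = "OG1", species = c("A", "B"),
                   transcript_id = c("a1", "b1")),
    species = c("A", "B")
  )
  map0 <- map_events_on_tree(flat, none$events, og)
  expect_equal(nrow(map0$annotations), 0)

  out <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_tree(map, out)
  expect_match(paste(readLines(out), collapse = ""), "duplication")
})

test_that("annotation counts equal event counts on random planted scenarios", {
  withr::local_seed(15)
  for (i in 1:10) {
    og <- simulate_orthogroups(sample(2:5, 1), sample(0:2, 1), sample(0:2, 1),
                               sample(0:2, 1), sample(0:2, 1), seed = 200 + i)
    cls <- classify_orthogroups(og)
    tips <- og$transcript_id
    tree <- ape::rtree(length(tips), tip.label = sample(tips))
    map <- suppressWarnings(map_events_on_tree(tree, cls$events, og))
    expect_equal(nrow(map$annotations), nrow(cls$events))
  }
})

test_that("the factorial test is calibrated under the null and detects interactions", {
  withr::local_seed(16)
  make_merged <- function(interaction = 0) {
    n_per <- 20
    cls <- tibble::tibble(
      transcript_id = sprintf("t%03d", 1:(4 * n_per)),
      species = rep(c("A", "B"), each = 2 * n_per),
      orthogroup = sprintf("OG%03d", 1:(4 * n_per)),
      class = rep(rep(c("one_to_one", "duplication_member"), each = n_per), 2)
    )
    value <- rnorm(4 * n_per)
    bump <- cls$species == "B" & cls$class == "one_to_one"
    value[bump] <- value[bump] + interaction
    tibble::tibble(
      transcript_id = cls$transcript_id, species = cls$species,
      orthogroup = cls$orthogroup, class = cls$class,
      A1 = ifelse(cls$species == "A", value, 0),
      B1 = ifelse(cls$species == "B", value, 0)
    )
  }
  labels <- c(A1 = "A", B1 = "B")
  null_p <- replicate(400, {
    res <- ortholog_paralog_factorial(make_merged(0), labels)
    res$p_value[res$term == "toxin_type:species"]
  })
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif"))$p.value, 0.01)

  power_hits <- replicate(40, {
    res <- ortholog_paralog_factorial(make_merged(2), labels)
    res$p_value[res$term == "toxin_type:species"] < 0.01
  })
  expect_gte(mean(power_hits), 0.95)
})

test_that("factorial errors name deficient cells", {
  merged <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), species = c("A", "A", "B"),
    orthogroup = c("OG1", "OG2", "OG3"),
    class = c("one_to_one", "one_to_one", "duplication_member"),
    A1 = c(1, 2, 0), B1 = c(0, 0, 3)
  )
  expect_error(ortholog_paralog_factorial(merged, c(A1 = "A", B1 = "B")),
               "deficient cell", class = "palmviper_validation_error")
})
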