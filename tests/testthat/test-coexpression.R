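sim_texpr <- function(n, samples = 6, seed = 1) {
  withr::local_seed(seed)
  m <- matrix(rnorm(n * samples), nrow = n)
  dplyr::bind_cols(
    tibble::tibble(transcript_id = sprintf("t%02d", seq_len(n))),
    tibble::as_tibble(as.data.frame(m), .name_repair = ~sprintf("s%d", seq_len(samples)))
  )
}

test_that("transform-and-filter drops constants and keeps planted dispersion", {
  withr::local_seed(19)
  base <- 2^rnorm(30, 8, 0.1)
  flat <- matrix(rep(base, 6), ncol = 6)           # constant transcripts
  noisy <- flat * 2^matrix(rnorm(30 * 6, 0, 2), ncol = 6)  # high dispersion, same mean
  m <- rbind(flat, noisy)
  expr <- dplyr::bind_cols(
    tibble::tibble(transcript_id = sprintf("t%02d", 1:60)),
    tibble::as_tibble(as.data.frame(m), .name_repair = ~sprintf("s%d", 1:6))
  )
  kept <- transform_and_filter(expr, filter_quantile = 0.5)
  expect_true(all(grepl("t[3-6]", kept$transcript_id)))  # only noisy block survives
  expect_false(any(expr$transcript_id[1:30] %in% kept$transcript_id))

  # monotone transform preserves per-transcript sample ranks
  texpr <- transform_and_filter(expr, filter_quantile = 0)
  raw_row <- unlist(expr[expr$transcript_id == "t45", -1])
  t_row <- unlist(texpr[texpr$transcript_id == "t45", -1])
  expect_equal(rank(raw_row), rank(t_row))

  expect_error(transform_and_filter(expr[, 1:4]), class = "palmviper_validation_error")
})

test_that("adjacency follows the soft-threshold arithmetic", {
  withr::local_seed(20)
  texpr <- sim_texpr(6, samples = 8)
  adj <- adjacency(texpr, beta = 10)
  r <- cor(t(as.matrix(texpr[-1])))
  expect_equal(adj[1, 2], abs(r[1, 2])^10)
  expect_equal(adj, t(adj))
  expect_true(all(adj >= 0 & adj <= 1))
  expect_equal(unname(diag(adj)), rep(0, 6))

  # a correlation of 0.9 at beta 10 gives 0.3487; anticorrelation is adjacent
  x <- c(1, 2, 3, 4, 5)
  expect_equal(abs(0.9)^10, 0.3486784401)
  anti <- tibble::tibble(transcript_id = c("u", "v"),
                         s1 = c(1, -1), s2 = c(2, -2), s3 = c(3.5, -3.5), s4 = c(7, -7))
  expect_equal(adjacency(anti, beta = 10)["u", "v"], 1)

  # increasing beta never increases adjacency for |cor| < 1
  a5 <- adjacency(texpr, beta = 5)
  a12 <- adjacency(texpr, beta = 12)
  expect_true(all(a12 <= a5 + 1e-12))

  const <- tibble::tibble(transcript_id = c("a", "b"), s1 = c(1, 1), s2 = c(1, 2), s3 = c(1, 3))
  expect_error(adjacency(const), class = "palmviper_validation_error")
})

test_that("topological overlap matches hand arithmetic and the brute-force loop", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(unname(diag(tom)), rep(1, 3))

  zero <- matrix(0, 4, 4)
  expect_equal(unique(as.vector(topological_overlap(zero) - diag(4))), 0)

  withr::local_seed(21)
  for (i in 1:10) {
    r <- matrix(runif(100), 10, 10)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    tom <- topological_overlap(adj)
    expect_equal(tom, oracle_tom(adj), tolerance = 1e-12)
    expect_true(all(tom <= 1 + 1e-12))
  }

  asym <- matrix(runif(9), 3, 3); diag(asym) <- 0
  expect_error(topological_overlap(asym), class = "palmviper_validation_error")
})

test_that("two planted blocks are recovered exactly, including opposite profiles", {
  sim <- simulate_coexpression(n_modules = 2, transcripts_per_module = 10,
                               n_background = 0, within_cor = 0.99,
                               n_samples_per_treatment = 4, seed = 22)
  mods <- suppressWarnings(find_coexpression_modules(sim$expression, sim$sample_meta,
                                                     filter_quantile = 0))
  truth <- sim$truth$module[match(mods$assignment$transcript_id, sim$truth$transcript_id)]
  expect_equal(length(setdiff(unique(mods$assignment$module), 0)), 2)
  expect_equal(adjusted_rand(mods$assignment$module, truth), 1)

  z <- c(-1, 0, 1)
  opp <- simulate_coexpression(n_modules = 2, transcripts_per_module = 10,
                               n_background = 0, within_cor = 0.99,
                               n_samples_per_treatment = 4,
                               profiles = cbind(z, -z), seed = 23)
  mods_o <- suppressWarnings(find_coexpression_modules(opp$expression, opp$sample_meta,
                                                       filter_quantile = 0))
  truth_o <- opp$truth$module[match(mods_o$assignment$transcript_id, opp$truth$transcript_id)]
  expect_equal(adjusted_rand(mods_o$assignment$module, truth_o), 1)
})

test_that("background-only data never mimics planted structure", {
  withr::local_seed(24)
  aris <- replicate(10, {
    sim <- simulate_coexpression(n_modules = 0, transcripts_per_module = 0,
                                 n_background = 30, within_cor = 0,
                                 n_samples_per_treatment = 4,
                                 seed = sample.int(1e6, 1))
    mods <- suppressWarnings(find_coexpression_modules(sim$expression, sim$sample_meta,
                                                       filter_quantile = 0))
    fake_truth <- rep(1:2, each = 15)
    adjusted_rand(mods$assignment$module, fake_truth)
  })
  expect_lt(mean(abs(aris)), 0.05)
})

test_that("min_module_size larger than n sends everything to background", {
  texpr <- sim_texpr(5, samples = 6, seed = 25)
  tom <- topological_overlap(adjacency(texpr, beta = 6))
  assignment <- detect_modules(tom, min_module_size = 10)
  expect_equal(assignment$module, rep(0L, 5))

  single <- detect_modules(matrix(1, 1, 1, dimnames = list("t1", "t1")))
  expect_equal(single$module, 1L)
})

test_that("module profiles summarise treatments and flag background", {
  sim <- simulate_coexpression(n_modules = 1, transcripts_per_module = 5,
                               n_background = 5, within_cor = 0.95,
                               n_samples_per_treatment = 3, seed = 26)
  texpr <- transform_and_filter(sim$expression, filter_quantile = 0)
  assignment <- detect_modules(topological_overlap(adjacency(texpr)), 2)
  prof <- module_profiles(assignment, texpr, sim$sample_meta)
  expect_setequal(unique(prof$venom_type), c("A", "A+B", "B"))
  expect_true(all(prof$background == (prof$module == 0)))
  expect_equal(nrow(prof), length(unique(assignment$module)) * 3)

  # a module of identical transcripts has the profile of any member
  ident <- tibble::tibble(transcript_id = c("x", "y"),
                          s1 = c(4, 4), s2 = c(8, 8), s3 = c(6, 6), s4 = c(2, 2))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         venom_type = c("A", "A", "B", "B"))
  asg <- tibble::tibble(transcript_id = c("x", "y"), module = 1L)
  p <- module_profiles(asg, ident, meta)
  expect_equal(p$mean_expression[p$venom_type == "A"], 6)
  expect_equal(p$mean_expression[p$venom_type == "B"], 4)

  expect_error(module_profiles(asg, ident, meta[1:2, ]),
               class = "palmviper_validation_error")
})
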