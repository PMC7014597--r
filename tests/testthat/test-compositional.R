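test_that("multiplicative zero replacement matches the hand-computed example", {
  expr <- tibble::tibble(transcript_id = c("a", "b", "c"), s = c(0, 10, 90))
  out <- replace_zeros(expr, delta_fraction = 0.5)
  expect_equal(out$s, c(5, 9.5, 85.5))  # delta 5, others scaled by 95/100
  expect_equal(sum(out$s), sum(expr$s))

  pos <- tibble::tibble(transcript_id = c("a", "b"), s = c(2, 7))
  expect_identical(replace_zeros(pos)$s, pos$s)

  allzero <- tibble::tibble(transcript_id = c("a", "b"), s = c(0, 0))
  expect_error(replace_zeros(allzero), class = "palmviper_validation_error")
})

test_that("zero replacement preserves column totals on random compositions", {
  withr::local_seed(1)
  for (i in 1:10) {
    x <- stats::rexp(50)
    x[sample(50, 10)] <- 0
    expr <- tibble::tibble(transcript_id = sprintf("t%d", 1:50), s = x)
    out <- replace_zeros(expr, delta_fraction = 0.65)
    expect_true(all(out$s > 0))
    expect_equal(sum(out$s), sum(x), tolerance = 1e-9)
  }
})

test_that("CLR transform has the closed form, zero sum, and scale invariance", {
  expr <- tibble::tibble(transcript_id = c("a", "b", "c"), s = c(1, 2, 4))
  clr <- clr_transform(expr)
  expect_equal(clr$s, c(-log(2), 0, log(2)), tolerance = 1e-12)

  uni <- tibble::tibble(transcript_id = letters[1:4], s = rep(3, 4))
  expect_equal(clr_transform(uni)$s, rep(0, 4))

  withr::local_seed(2)
  x <- stats::rexp(30)
  a <- clr_transform(tibble::tibble(transcript_id = paste0("t", 1:30), s = x))
  b <- clr_transform(tibble::tibble(transcript_id = paste0("t", 1:30), s = 137.5 * x))
  expect_equal(a$s, b$s, tolerance = 1e-12)
  expect_equal(sum(a$s), 0, tolerance = 1e-9 * 30)

  withzero <- tibble::tibble(transcript_id = c("a", "b"), s = c(0, 1))
  expect_error(clr_transform(withzero), class = "palmviper_validation_error")
})

tls_residual_of <- function(fit, x, y) {
  (y - fit$slope * x - fit$intercept) / sqrt(1 + fit$slope^2)
}

test_that("orthogonal fit recovers exact lines and point-to-line geometry", {
  f <- fit_orthogonal_line(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$residuals, rep(0, 3))

  # signed distance of (0, 1) from y = x is 1/sqrt(2), above the line
  expect_equal(tls_residual_of(f, 0, 1), 1 / sqrt(2))

  expect_error(fit_orthogonal_line(c(1, 1, 1), c(2, 2, 2)), class = "palmviper_fit_error")
  expect_error(fit_orthogonal_line(c(1, 2), c(1, 2)), class = "palmviper_fit_error")
})

test_that("orthogonal slope equals the principal-axis eigenvector ratio", {
  withr::local_seed(3)
  for (i in 1:20) {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60, sd = 0.7)
    f <- fit_orthogonal_line(x, y)
    ev <- eigen(cov(cbind(x, y)))$vectors[, 1]
    expect_equal(f$slope, ev[2] / ev[1], tolerance = 1e-10)
    # residuals of a TLS fit sum to ~0 over the fitted points
    expect_equal(sum(f$residuals), 0, tolerance = 1e-8)
  }
})

test_that("orthogonal fit is symmetric under swapping the axes", {
  withr::local_seed(4)
  for (i in 1:10) {
    x <- rnorm(40)
    y <- 1.7 * x + rnorm(40, sd = 0.5)
    m <- fit_orthogonal_line(x, y)$slope
    m_swapped <- fit_orthogonal_line(y, x)$slope
    expect_equal(m_swapped, 1 / m, tolerance = 1e-8)
  }
})

test_that("null band matches normal quantiles and holds its coverage", {
  withr::local_seed(5)
  res <- rnorm(10000, sd = 2)
  fit <- structure(list(slope = 1, intercept = 0, residuals = res, n = 10000),
                   class = "tls_fit")
  band <- build_null_band(fit, 0.99)
  expect_equal(band$lower, -2.576 * 2, tolerance = 0.15)
  expect_equal(band$upper, 2.576 * 2, tolerance = 0.15)
  outside <- mean(res < band$lower | res > band$upper)
  expect_lte(outside, 0.01 + 1 / 10000)

  small_fit <- structure(list(slope = 1, intercept = 0, residuals = rnorm(50), n = 50),
                         class = "tls_fit")
  expect_warning(build_null_band(small_fit, 0.99), "unstable")
  expect_error(build_null_band(fit, 0.4), class = "palmviper_validation_error")
})

test_that("degenerate all-zero background band flags every nonzero toxin", {
  fit <- structure(list(slope = 1, intercept = 0, residuals = rep(0, 200), n = 200),
                   class = "tls_fit")
  band <- build_null_band(fit, 0.99)
  expect_equal(c(band$lower, band$upper), c(0, 0))
  clr <- tibble::tibble(transcript_id = c("t1", "t2"), s1 = c(0, 1), s2 = c(0.5, 1))
  calls <- call_outliers(clr, c("t1", "t2"), fit, band, c("s1", "s2"))
  expect_equal(calls$outlier, c(TRUE, FALSE))  # t2 sits exactly on the line
})

test_that("boundary residuals are inside the band (strict tie rule)", {
  fit <- structure(list(slope = 0, intercept = 0, residuals = seq(-1, 1, length.out = 200),
                        n = 200), class = "tls_fit")
  band <- build_null_band(fit, 0.9)
  at_edge <- tibble::tibble(transcript_id = "t", s1 = 0, s2 = band$upper)
  calls <- call_outliers(at_edge, "t", fit, band, c("s1", "s2"))
  expect_false(calls$outlier)
  expect_true(is.na(calls$direction))
})

test_that("planted outliers are recovered exactly, with direction", {
  for (seed in c(2, 23, 101)) {
    sim <- simulate_expression(n_outliers = 5, outlier_shift = 5, noise_sd = 0.5,
                               seed = seed)
    calls <- divergence_outliers(sim$expression, sim$annotation, pair = c("S1", "S2"))
    flagged <- dplyr::filter(calls, .data$outlier)
    # every planted outlier is recovered; null toxins may add ~1% false flags
    expect_true(all(sim$truth$transcript_id %in% flagged$transcript_id))
    expect_lte(nrow(flagged) - nrow(sim$truth), 3)
    joined <- dplyr::inner_join(flagged, sim$truth, by = "transcript_id",
                                suffix = c("", "_true"))
    expect_equal(joined$direction, joined$direction_true)
  }
})

test_that("missing toxin ids are a lookup error", {
  sim <- simulate_expression(seed = 1)
  clr <- clr_transform(replace_zeros(sim$expression))
  fit <- fit_orthogonal_line(clr$S1, clr$S2)
  band <- build_null_band(fit)
  expect_error(call_outliers(clr, "NOT_A_TOXIN", fit, band, c("S1", "S2")),
               class = "palmviper_lookup_error")
})

test_that("family composition reproduces shares, closure, and the PLA2 headline", {
  tox <- bothriechis_toxins("nigroviridis")
  ann <- tibble::tibble(transcript_id = tox$toxin_id, class = "toxin",
                        family = tox$family, orthology_label = tox$orthology_label)
  expr <- bothriechis_expression("nigroviridis")
  comp <- family_composition(expr, ann, "per_sample")
  sums <- dplyr::count(comp, .data$sample, wt = .data$percent)
  expect_equal(sums$n, rep(100, 2), tolerance = 1e-9)
  pla2 <- comp$percent[comp$family == "PLA2" & comp$sample == "CLP1864"]
  expect_equal(pla2, 60.3, tolerance = 0.3)

  single <- family_composition(
    tibble::tibble(transcript_id = c("x", "y"), s = c(1, 2)),
    tibble::tibble(transcript_id = c("x", "y"), class = "toxin",
                   family = "PLA2", orthology_label = "Ortholog")
  )
  expect_equal(single$percent, 100)

  zero <- tibble::tibble(transcript_id = "x", s = 0)
  zann <- tibble::tibble(transcript_id = "x", class = "toxin", family = "F",
                         orthology_label = "Ortholog")
  expect_error(family_composition(zero, zann), class = "palmviper_validation_error")
})

test_that("species-average composition reproduces the nubestris family shares", {
  tox <- bothriechis_toxins("nubestris")
  ann <- tibble::tibble(transcript_id = tox$toxin_id, class = "toxin",
                        family = tox$family, orthology_label = tox$orthology_label)
  comp <- family_composition(bothriechis_expression("nubestris"), ann, "species_average")
  expect_equal(comp$percent[comp$family == "CTL"], 40.4, tolerance = 0.1)
  expect_equal(comp$percent[comp$family == "SVMP"], 34.9, tolerance = 0.1)
})
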