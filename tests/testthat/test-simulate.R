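test_that("zero growth yields identical populations at both censuses", {
  g <- build_lattice(6, "grid")
  pop <- simulate_populations(g, census_years = c(2000, 2010),
                              base_size = 10000, growth_range = c(0, 0),
                              seed = 4)
  wide <- tidyr::pivot_wider(pop, names_from = "year",
                             values_from = "population")
  expect_equal(wide$`2000`, wide$`2010`)
})

test_that("the same seed reproduces the population grid bitwise", {
  g <- build_lattice(6, "grid")
  p1 <- simulate_populations(g, seed = 9)
  p2 <- simulate_populations(g, seed = 9)
  expect_identical(p1, p2)
  p3 <- simulate_populations(g, seed = 10)
  expect_false(identical(p1, p3))
})

test_that("2%/yr growth over 10 years compounds region totals to base * 1.02^10", {
  g <- build_lattice(5, "ring")
  pop <- simulate_populations(g, census_years = c(2000, 2010),
                              base_size = 10000,
                              growth_range = c(0.02, 0.02), seed = 2)
  totals <- pop |>
    dplyr::filter(year == 2010) |>
    dplyr::group_by(region) |>
    dplyr::summarise(total = sum(population))
  expect_equal(totals$total, rep(10000 * 1.02^10, 5), tolerance = 1e-10)
})

test_that("fewer than two census years is an input error", {
  g <- build_lattice(4, "grid")
  expect_error(simulate_populations(g, census_years = 2006), "two census")
})

test_that("completeness endpoints are honoured exactly at the first and last period", {
  g <- build_lattice(8, "grid")
  cov <- simulate_covariates(g, completeness_endpoints = c(0.22, 0.75),
                             seed = 5)
  first <- dplyr::filter(cov, period == "2000-2003")
  last <- dplyr::filter(cov, period == "2008-2010")
  expect_equal(unique(first$completeness), 0.22)
  expect_equal(unique(last$completeness), 0.75)

  full <- simulate_covariates(g, completeness_endpoints = c(1, 1), seed = 5)
  expect_equal(unique(full$completeness), 1)
  expect_error(simulate_covariates(g, completeness_endpoints = c(0, 0.5)),
               "\\(0, 1\\]")
})

test_that("wealth smoothing with weight 1 on a ring equals the neighbour mean", {
  g <- build_lattice(4, "ring")
  raw <- simulate_covariates(g, wealth_smoothing = 0, seed = 13)
  sm <- simulate_covariates(g, wealth_smoothing = 1, seed = 13)
  z <- raw |>
    dplyr::distinct(region, wealth_index) |>
    dplyr::pull(wealth_index, name = region)
  w <- sm |>
    dplyr::distinct(region, wealth_index) |>
    dplyr::pull(wealth_index, name = region)
  for (r in g$region_ids) {
    expect_equal(unname(w[r]), mean(z[g$neighbours[[r]]]), tolerance = 1e-12)
  }
})

test_that("null effects give pooled O/E concentrated at 1", {
  g <- build_lattice(1000, "ring")
  expected <- tibble::tibble(region = g$region_ids, period = "p1",
                             expected = 100)
  cov <- tibble::tibble(region = g$region_ids, period = "p1",
                        completeness = 1, urbanisation = 0.5, yos = 6,
                        wealth_index = 0)
  truth <- list(alpha = 0, beta = numeric(0),
                u = stats::setNames(numeric(1000), g$region_ids),
                v = stats::setNames(numeric(1000), g$region_ids),
                tau_u = 1, tau_v = 1)
  counts <- simulate_counts(expected, cov, truth, g, seed = 8)
  expect_gte(mean(counts$count / 100), 0.95)
  expect_lte(mean(counts$count / 100), 1.05)
})

test_that("zero expected count forces zero simulated count", {
  g <- build_lattice(3, "ring")
  expected <- tibble::tibble(region = g$region_ids, period = "p1",
                             expected = c(0, 5, 0))
  cov <- tibble::tibble(region = g$region_ids, period = "p1",
                        completeness = 1)
  truth <- list(alpha = 1, beta = numeric(0),
                u = stats::setNames(numeric(3), g$region_ids),
                v = stats::setNames(numeric(3), g$region_ids))
  counts <- simulate_counts(expected, cov, truth, g, seed = 1)
  expect_equal(counts$count[expected$expected == 0], c(0, 0))
  expected$expected[1] <- -1
  expect_error(simulate_counts(expected, cov, truth, g), ">= 0")
})

test_that("Poisson counts have the analytic mean (alpha = log 2, E = 10)", {
  n <- 10000
  g <- build_lattice(n, "ring")
  expected <- tibble::tibble(region = g$region_ids, period = "p1",
                             expected = 10)
  cov <- tibble::tibble(region = g$region_ids, period = "p1",
                        completeness = 1)
  truth <- list(alpha = log(2), beta = numeric(0),
                u = stats::setNames(numeric(n), g$region_ids),
                v = stats::setNames(numeric(n), g$region_ids))
  counts <- simulate_counts(expected, cov, truth, g, seed = 3)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(counts$count) - 20), 3 * se)
})

test_that("thinning leaves counts unchanged at full completeness and kills them as c -> 0", {
  g <- build_lattice(5, "ring")
  panel <- tibble::tibble(region = g$region_ids, period = "p1",
                          count = c(10L, 0L, 7L, 100L, 3L))
  cov1 <- tibble::tibble(region = g$region_ids, period = "p1",
                         completeness = 1)
  expect_equal(thin_counts(panel, cov1, seed = 2)$count, panel$count)

  cov0 <- dplyr::mutate(cov1, completeness = 1e-9)
  panel$count <- 100L
  expect_equal(thin_counts(panel, cov0, seed = 2)$count, rep(0L, 5))

  covbad <- dplyr::mutate(cov1, completeness = 1.5)
  expect_error(thin_counts(panel, covbad), "\\(0, 1\\]")
})

test_that("thinning at c = 0.22 of O = 1000 averages 220 and never exceeds the input", {
  n <- 10000
  g <- build_lattice(n, "ring")
  panel <- tibble::tibble(region = g$region_ids, period = "p1",
                          count = 1000L)
  cov <- tibble::tibble(region = g$region_ids, period = "p1",
                        completeness = 0.22)
  thinned <- thin_counts(panel, cov, seed = 6)
  expect_true(all(thinned$count <= panel$count))
  se <- sqrt(1000 * 0.22 * 0.78 / n)
  expect_lt(abs(mean(thinned$count) - 220), 3 * se)
})

test_that("raising completeness never lowers the mean thinned count", {
  n <- 400
  g <- build_lattice(n, "ring")
  panel <- tibble::tibble(region = g$region_ids, period = "p1",
                          count = 50L)
  means <- vapply(c(0.2, 0.5, 0.9), function(cc) {
    cov <- tibble::tibble(region = g$region_ids, period = "p1",
                          completeness = cc)
    mean(thin_counts(panel, cov, seed = 14)$count)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the full generative pipeline is reproducible under a fixed seed", {
  p1 <- simulate_panel(n_regions = 9, seed = 5)
  p2 <- simulate_panel(n_regions = 9, seed = 5)
  expect_identical(p1$counts_observed, p2$counts_observed)
  expect_identical(p1$covariates, p2$covariates)
  expect_identical(p1$truth$u, p2$truth$u)
})

test_that("simulated truth recentres u to zero mean and rejects bad precisions", {
  g <- build_lattice(12, "grid")
  tr <- simulate_truth(g, tau_u = 5, tau_v = 5, seed = 7)
  expect_lt(abs(mean(tr$u)), 1e-10)
  expect_error(simulate_truth(g, tau_u = -1), "positive")
})

test_that("panel tables and truth serialise to plain-text files", {
  p <- simulate_panel(n_regions = 6, seed = 2)
  dir <- withr::local_tempdir()
  write_panel(p, dir)
  expect_true(all(file.exists(file.path(dir,
    c("populations.csv", "covariates.csv", "counts_observed.csv",
      "adjacency.csv", "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$alpha, p$truth$alpha)
})
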