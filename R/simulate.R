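#' Default 5-year age bands for women aged 30 and above
#'
#' Eleven contiguous bands, `30-34` through `75-79` plus the open band
#' `80+`. The lower limit reflects the study population (women aged 30+);
#' the 5-year width is the registry-reporting convention.
#'
#' @return Character vector of band labels, ordered by age.
#' @export
default_age_bands <- function() {
  c(paste(seq(30, 75, 5), seq(34, 79, 5), sep = "-"), "80+")
}

#' Default study periods
#'
#' Three calendar intervals, 2000-2003, 2004-2007 and 2008-2010 (4, 4 and
#' 3 years respectively).
#' @return Character vector of period labels.
#' @export
default_periods <- function() c("2000-2003", "2004-2007", "2008-2010")

#' Years covered by each period label
#'
#' Parses labels of the form `"2000-2003"` into the integer years they
#' span, the mapping used when expected counts are accumulated over the
#' person-years of an interval.
#'
#' @param periods Character vector of `"start-end"` period labels.
#' @return Named list mapping each label to an integer vector of years.
#' @export
period_years <- function(periods = default_periods()) {
  out <- lapply(periods, function(p) {
    ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(ab) != 2 || anyNA(ab) || ab[2] < ab[1]) {
      abort_input("period labels must look like 'YYYY-YYYY'")
    }
    seq.int(ab[1], ab[2])
  })
  names(out) <- periods
  out
}

#' A breast-cancer-like reference schedule of age-specific rates
#'
#' Age-specific incidence rises steeply with age; the default schedule
#' climbs from about 20 per 100,000 person-years in the 30-34 band to
#' about 200 per 100,000 in the 80+ band, the order of magnitude national
#' female breast-cancer registries report.
#'
#' @param age_bands Band labels (see [default_age_bands()]).
#' @param scale Multiplier applied to the whole schedule.
#' @return Tibble with columns `age_band` and `rate` (events per
#'   person-year).
#' @export
default_rate_schedule <- function(age_bands = default_age_bands(), scale = 1) {
  k <- seq_along(age_bands) - 1
  rate <- 1e-4 * (1 + k)^0.95 * scale
  tibble::tibble(age_band = age_bands, rate = rate)
}

#' Simulate census populations on a region lattice
#'
#' Emulates census extracts of the female population by region and 5-year
#' age band at a small set of census years. Every region starts from the
#' same first-census total (`base_size`) split across bands by a noisy
#' declining age pyramid; each region then grows geometrically at its own
#' annual rate drawn uniformly from `growth_range`.
#'
#' @param graph A [bym_graph()].
#' @param census_years Integer vector of at least two census years.
#' @param base_size Total female population (30+) per region at the first
#'   census.
#' @param growth_range Length-2 interval of annual growth rates; a
#'   degenerate interval gives every region the same rate.
#' @param age_bands Band labels.
#' @param seed Integer seed.
#' @return Tibble (`region`, `age_band`, `year`, `population`) with one
#'   row per region x band x census year; the population grid.
#' @export
simulate_populations <- function(graph, census_years = c(1996, 2006, 2011),
                                 base_size = 2e5,
                                 growth_range = c(0.005, 0.03),
                                 age_bands = default_age_bands(),
                                 seed = 1L) {
  if (length(census_years) < 2) {
    abort_input("at least two census years are required")
  }
  census_years <- sort(as.integer(census_years))
  ids <- graph$region_ids
  n <- length(ids)
  nb_bands <- length(age_bands)

  with_seed(substream_seed(seed, "populations"), {
    # declining pyramid with per-region multiplicative noise, renormalised
    base_shape <- exp(-0.18 * (seq_len(nb_bands) - 1))
    shares <- vapply(seq_len(n), function(i) {
      w <- base_shape * exp(stats::rnorm(nb_bands, 0, 0.1))
      w / sum(w)
    }, numeric(nb_bands))
    growth <- stats::runif(n, growth_range[1], growth_range[2])
  })

  grid <- tidyr::expand_grid(
    region = ids, age_band = factor(age_bands, levels = age_bands),
    year = census_years
  )
  i <- match(grid$region, ids)
  a <- as.integer(grid$age_band)
  grid$population <- base_size * shares[cbind(a, i)] *
    (1 + growth[i])^(grid$year - census_years[1])
  grid$age_band <- as.character(grid$age_band)
  grid
}

#' Simulate region-level covariates
#'
#' Produces the covariate panel the model consumes: registry completeness
#' (shared by all regions, linear in time between the stated endpoints,
#' emulating a single national insurance-derived rate), female
#' urbanisation (a logit-normal region effect with a mild upward drift),
#' mean years of schooling (positive, rising over periods), and a wealth
#' index simulated as a spatially autocorrelated Gaussian field by
#' one-step neighbour averaging so that wealth quintiles form contiguous
#' blocks.
#'
#' @param graph A [bym_graph()].
#' @param periods Period labels.
#' @param completeness_endpoints Completeness in the first and last
#'   period, each in (0, 1]. Defaults to the 0.22 -> 0.75 rise of the
#'   emulated registry.
#' @param wealth_smoothing Weight in `[0, 1]` on the neighbour mean when
#'   smoothing the wealth field; `1` replaces each draw by its neighbour
#'   mean exactly.
#' @param seed Integer seed.
#' @return Tibble (`region`, `period`, `completeness`, `urbanisation`,
#'   `yos`, `wealth_index`), one row per region x period; the wealth
#'   index is constant over periods.
#' @export
simulate_covariates <- function(graph, periods = default_periods(),
                                completeness_endpoints = c(0.22, 0.75),
                                wealth_smoothing = 0.7,
                                seed = 1L) {
  if (length(completeness_endpoints) != 2 ||
      any(completeness_endpoints <= 0) || any(completeness_endpoints > 1)) {
    abort_input("completeness endpoints must lie in (0, 1]")
  }
  ids <- graph$region_ids
  n <- length(ids)
  np <- length(periods)
  compl <- if (np == 1) completeness_endpoints[1] else {
    completeness_endpoints[1] +
      (completeness_endpoints[2] - completeness_endpoints[1]) *
        (seq_len(np) - 1) / (np - 1)
  }

  with_seed(substream_seed(seed, "covariates"), {
    urb0 <- stats::plogis(stats::rnorm(n, 0.3, 0.6))
    urb_drift <- 0.02 * (seq_len(np) - 1)
    yos0 <- pmax(stats::rnorm(n, 6, 1.5), 0.5)
    yos_drift <- 0.5 * (seq_len(np) - 1)
    z <- stats::rnorm(n)
  })

  nb <- graph_nb_index(graph)
  nb_mean <- vapply(seq_len(n), function(i) {
    if (length(nb[[i]]) == 0) z[i] else mean(z[nb[[i]]])
  }, numeric(1))
  wealth <- (1 - wealth_smoothing) * z + wealth_smoothing * nb_mean

  tidyr::expand_grid(region = ids, period = periods) |>
    dplyr::mutate(
      .p = match(.data$period, periods),
      .i = match(.data$region, ids),
      completeness = compl[.data$.p],
      urbanisation = pmin(pmax(urb0[.data$.i] + urb_drift[.data$.p], 0), 1),
      yos = yos0[.data$.i] + yos_drift[.data$.p],
      wealth_index = wealth[.data$.i]
    ) |>
    dplyr::select(-".p", -".i")
}

#' Draw a set of true model parameters
#'
#' Samples the generative truth for the log relative risk decomposition:
#' an intercept, covariate coefficients on the standardised scale,
#' spatially structured effects `u` drawn from the intrinsic CAR
#' distribution restricted to its proper subspace (zero-mean within each
#' graph component, via the Laplacian pseudo-inverse), and exchangeable
#' effects `v` drawn iid Gaussian.
#'
#' @param graph A [bym_graph()].
#' @param alpha Intercept (log relative risk at covariate means).
#' @param beta Named numeric vector of coefficients per standardised
#'   covariate; names select covariate columns.
#' @param tau_u,tau_v Precisions of the spatial and exchangeable effects.
#' @param seed Integer seed.
#' @return A `bym_truth` list: `alpha`, `beta`, `u`, `v` (named by
#'   region), `tau_u`, `tau_v`.
#' @export
simulate_truth <- function(graph, alpha = 0,
                           beta = c(urbanisation = 0.5, yos = -0.3),
                           tau_u = 10, tau_v = 25, seed = 1L) {
  if (tau_u <= 0 || tau_v <= 0) abort_input("precisions must be positive")
  ids <- graph$region_ids
  n <- length(ids)
  u <- stats::setNames(numeric(n), ids)
  with_seed(substream_seed(seed, "truth"), {
    if (n > 1) {
      Q <- icar_structure_matrix(graph)
      eg <- eigen(Q, symmetric = TRUE)
      pos <- eg$values > 1e-9 * max(eg$values)
      if (any(pos)) {
        z <- stats::rnorm(sum(pos))
        u[] <- as.vector(eg$vectors[, pos, drop = FALSE] %*%
                           (z / sqrt(tau_u * eg$values[pos])))
      }
    }
    v <- stats::setNames(stats::rnorm(n, 0, 1 / sqrt(tau_v)), ids)
  })
  # recentre within components (pseudo-inverse sampling already lies in
  # the zero-mean subspace; this guards against numerical drift)
  for (k in unique(graph$component)) {
    idx <- graph$component == k
    u[idx] <- u[idx] - mean(u[idx])
  }
  structure(
    list(alpha = alpha, beta = beta, u = u, v = v,
         tau_u = tau_u, tau_v = tau_v),
    class = "bym_truth"
  )
}

#' @export
print.bym_truth <- function(x, ...) {
  cat("<bym_truth> alpha =", format(x$alpha),
      " beta = [", paste(format(x$beta), collapse = ", "), "]",
      " tau_u =", x$tau_u, " tau_v =", x$tau_v, "\n")
  invisible(x)
}

#' Simulate event counts from the generative BYM model
#'
#' Draws observed counts `O ~ Poisson(E * theta)` with
#' `theta = exp(alpha + x' beta + u + v)`, where the covariates named in
#' `beta` are standardised (mean 0, sd 1) across the region x period
#' cells, matching the standardisation the fitting routine applies.
#'
#' @param expected Tibble (`region`, `period`, `expected`) of expected
#'   counts from indirect standardisation.
#' @param covariates Covariate panel (see [simulate_covariates()]).
#' @param truth A `bym_truth` object.
#' @param graph A [bym_graph()].
#' @param seed Integer seed.
#' @return Event panel tibble (`region`, `period`, `count`).
#' @export
simulate_counts <- function(expected, covariates, truth, graph, seed = 1L) {
  if (any(expected$expected < 0)) abort_input("expected counts must be >= 0")
  cells <- dplyr::inner_join(expected, covariates,
                             by = c("region", "period"))
  if (nrow(cells) != nrow(expected)) {
    abort_input("covariates do not cover all expected-count cells")
  }
  eta <- truth$alpha
  if (length(truth$beta) > 0) {
    X <- standardise_columns(cells, names(truth$beta))$X
    eta <- eta + as.vector(X %*% truth$beta)
  }
  i <- match(cells$region, graph$region_ids)
  if (anyNA(i)) abort_input("expected counts refer to regions not in graph")
  mu <- cells$expected * exp(eta + truth$u[i] + truth$v[i])
  with_seed(substream_seed(seed, "counts"), {
    cells$count <- stats::rpois(nrow(cells), mu)
  })
  dplyr::select(cells, "region", "period", "count")
}

#' Thin counts by registry completeness
#'
#' Applies the under-registration mechanism: each true count is replaced
#' by a Binomial(`count`, completeness) draw, emulating a registry that
#' captures each case independently with probability equal to the
#' period's completeness.
#'
#' @param panel Event panel (`region`, `period`, `count`).
#' @param covariates Covariate panel supplying `completeness` per
#'   region x period.
#' @param seed Integer seed.
#' @return Event panel with thinned counts; cell-wise never exceeding the
#'   input.
#' @export
thin_counts <- function(panel, covariates, seed = 1L) {
  cells <- dplyr::inner_join(
    panel, dplyr::select(covariates, "region", "period", "completeness"),
    by = c("region", "period")
  )
  if (nrow(cells) != nrow(panel)) {
    abort_input("covariates do not cover all panel cells")
  }
  check_completeness(cells$completeness)
  with_seed(substream_seed(seed, "thin"), {
    cells$count <- stats::rbinom(nrow(cells), cells$count, cells$completeness)
  })
  dplyr::select(cells, "region", "period", "count")
}

#' Simulate national reference-year counts by age band
#'
#' Draws region x age-band counts for the reference year under the true
#' age-specific rate schedule, the raw material for
#' [build_reference_rates()].
#'
#' @param populations Population grid containing the reference year.
#' @param schedule Tibble (`age_band`, `rate`) of true age-specific rates.
#' @param reference_year Year to simulate (must be present in
#'   `populations`, interpolate first if needed).
#' @param seed Integer seed.
#' @return Tibble (`region`, `age_band`, `year`, `count`).
#' @export
simulate_reference_counts <- function(populations,
                                      schedule = default_rate_schedule(),
                                      reference_year, seed = 1L) {
  ref <- dplyr::filter(populations, .data$year == reference_year)
  if (nrow(ref) == 0) abort_input("reference year not present in populations")
  ref <- dplyr::inner_join(ref, schedule, by = "age_band")
  with_seed(substream_seed(seed, "reference"), {
    ref$count <- stats::rpois(nrow(ref), ref$population * ref$rate)
  })
  dplyr::select(ref, "region", "age_band", "year", "count")
}

#' Generate a complete synthetic study panel
#'
#' One call producing every input of the downstream pipeline at the
#' emulated study scale: a 31-region lattice, census populations at
#' 1996/2006/2011, covariates over three periods with completeness rising
#' 0.22 to 0.75, true BYM parameters, expected counts by indirect
#' standardisation against a simulated reference year, true Poisson
#' counts, and completeness-thinned observed counts.
#'
#' @param n_regions Number of regions.
#' @param topology Lattice topology (see [build_lattice()]).
#' @param periods Period labels.
#' @param census_years Census years.
#' @param reference_year Reference year for the rate schedule (defaults
#'   to the final study year, 2010).
#' @param truth Optional `bym_truth`; drawn via [simulate_truth()] when
#'   `NULL`.
#' @param base_size,growth_range Population settings (see
#'   [simulate_populations()]).
#' @param completeness_endpoints First/last-period completeness.
#' @param schedule Reference rate schedule.
#' @param seed Integer seed fanned out to per-stage substreams.
#' @return A list of class `bym_panel` with elements `graph`,
#'   `populations`, `covariates`, `truth`, `reference_counts`,
#'   `reference_rates`, `expected`, `counts_true`, `counts_observed`.
#' @export
simulate_panel <- function(n_regions = 31, topology = "grid",
                           periods = default_periods(),
                           census_years = c(1996, 2006, 2011),
                           reference_year = 2010,
                           truth = NULL,
                           base_size = 2e5, growth_range = c(0.005, 0.03),
                           completeness_endpoints = c(0.22, 0.75),
                           schedule = default_rate_schedule(),
                           seed = 1L) {
  graph <- build_lattice(n_regions, topology, seed = seed)
  populations <- simulate_populations(
    graph, census_years, base_size, growth_range, seed = seed
  )
  covariates <- simulate_covariates(
    graph, periods, completeness_endpoints, seed = seed
  )
  if (is.null(truth)) truth <- simulate_truth(graph, seed = seed)

  years_needed <- sort(unique(c(unlist(period_years(periods)), reference_year)))
  pop_yearly <- interpolate_population(populations, years_needed)

  reference_counts <- simulate_reference_counts(
    pop_yearly, schedule, reference_year, seed = seed
  )
  reference_rates <- build_reference_rates(
    reference_counts, pop_yearly, reference_year
  )
  expected <- compute_expected(pop_yearly, reference_rates,
                               period_years(periods))
  counts_true <- simulate_counts(expected, covariates, truth, graph,
                                 seed = seed)
  counts_observed <- thin_counts(counts_true, covariates, seed = seed)

  structure(
    list(graph = graph, populations = populations, covariates = covariates,
         truth = truth, reference_counts = reference_counts,
         reference_rates = reference_rates, expected = expected,
         counts_true = counts_true, counts_observed = counts_observed),
    class = "bym_panel"
  )
}

#' @export
print.bym_panel <- function(x, ...) {
  cat("<bym_panel> ", length(x$graph$region_ids), " regions, ",
      length(unique(x$expected$period)), " periods, reference ASR ",
      format(reference_asr(x$reference_rates), digits = 4),
      " per 100,000\n", sep = "")
  invisible(x)
}

#' Write the tables of a synthetic panel as tidy CSV / JSON
#'
#' Populations, covariates, counts and expected counts are written as
#' one-row-per-cell CSVs, the adjacency graph as an edge-list CSV and the
#' truth record as JSON.
#'
#' @param panel A `bym_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(panel$populations, file.path(dir, "populations.csv"))
  readr::write_csv(panel$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(panel$counts_true, file.path(dir, "counts_true.csv"))
  readr::write_csv(panel$counts_observed, file.path(dir, "counts_observed.csv"))
  readr::write_csv(panel$expected, file.path(dir, "expected.csv"))
  readr::write_csv(panel$reference_counts, file.path(dir, "reference_counts.csv"))
  write_graph_csv(panel$graph, file.path(dir, "adjacency.csv"))
  jsonlite::write_json(
    list(alpha = panel$truth$alpha, beta = as.list(panel$truth$beta),
         u = as.list(panel$truth$u), v = as.list(panel$truth$v),
         tau_u = panel$truth$tau_u, tau_v = panel$truth$tau_v),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
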