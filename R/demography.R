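#' Intercensal population interpolation
#'
#' Estimates the population of every region x age-band cell at the target
#' year(s) by the exponential (geometric) growth formula between the two
#' bracketing censuses: `P_t = P_a * (P_b / P_a)^((t - a) / (b - a))`.
#' Census years reproduce the census values exactly. Years up to
#' `max_extrapolate` beyond the last census are extrapolated from the last
#' two censuses; anything earlier than the first census or further beyond
#' is an error.
#'
#' @param grid Population grid tibble (`region`, `age_band`, `year`,
#'   `population`) holding at least two census years.
#' @param target_year Integer year(s) to interpolate to.
#' @param max_extrapolate Years allowed beyond the last census (default 5).
#' @return Population grid at the target year(s) only.
#' @export
interpolate_population <- function(grid, target_year, max_extrapolate = 5) {
  census_years <- sort(unique(grid$year))
  if (length(census_years) < 2) {
    abort_input("population grid must contain at least two census years")
  }
  lo <- census_years[1]
  hi <- census_years[length(census_years)]
  target_year <- as.integer(target_year)
  if (any(target_year < lo) || any(target_year > hi + max_extrapolate)) {
    abort_input(
      "target year outside [", lo, ", ", hi + max_extrapolate, "]"
    )
  }

  wide <- grid |>
    dplyr::arrange(.data$region, .data$age_band, .data$year) |>
    tidyr::pivot_wider(names_from = "year", values_from = "population")

  one_year <- function(t) {
    if (t %in% census_years) {
      a <- b <- t
    } else if (t > hi) {
      a <- census_years[length(census_years) - 1]
      b <- hi
    } else {
      a <- max(census_years[census_years < t])
      b <- min(census_years[census_years > t])
    }
    pa <- wide[[as.character(a)]]
    pb <- wide[[as.character(b)]]
    if (a == b) {
      p <- pa
    } else {
      if (any(pa == 0 & pb > 0)) {
        abort_input("degenerate growth: zero population at earlier census ",
                    "with positive population later")
      }
      f <- (t - a) / (b - a)
      p <- ifelse(pa == 0, 0, pa * (pb / pa)^f)
    }
    tibble::tibble(region = wide$region, age_band = wide$age_band,
                   year = t, population = p)
  }

  dplyr::bind_rows(lapply(target_year, one_year))
}

#' National reference rates by age band
#'
#' Constructs the indirect-standardisation reference: the national
#' age-specific event rate in the reference year,
#' `rate_a = events_a / population_a`, with the national population of
#' that year as the default standard weights. The implied reference ASR,
#' `1e5 * sum(rate_a * w_a) / sum(w_a)` per 100,000, anchors the scale on
#' which relative risks are reported.
#'
#' @param national_counts Tibble (`age_band`, `count`, optionally
#'   `region`/`year`) of events in the reference year; summed over any
#'   region column.
#' @param national_pop Population grid containing the reference year.
#' @param reference_year Year defining both rates and standard weights.
#' @return A `reference_rates` tibble (`age_band`, `rate`, `weight`) with
#'   attribute `reference_asr` (per 100,000), accessible via
#'   [reference_asr()].
#' @export
build_reference_rates <- function(national_counts, national_pop,
                                  reference_year) {
  if ("year" %in% names(national_counts)) {
    national_counts <- dplyr::filter(national_counts,
                                     .data$year == reference_year)
  }
  counts <- national_counts |>
    dplyr::group_by(.data$age_band) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  pop <- national_pop |>
    dplyr::filter(.data$year == reference_year) |>
    dplyr::group_by(.data$age_band) |>
    dplyr::summarise(weight = sum(.data$population), .groups = "drop")
  if (nrow(pop) == 0) abort_input("reference year not present in populations")

  ref <- dplyr::inner_join(counts, pop, by = "age_band")
  if (nrow(ref) != nrow(counts)) {
    abort_input("counts and populations do not share all age bands")
  }
  if (any(ref$weight <= 0)) {
    abort_input("zero population in an age band: rate undefined")
  }
  ref <- ref |>
    dplyr::mutate(rate = .data$count / .data$weight) |>
    dplyr::select("age_band", "rate", "weight")
  attr(ref, "reference_asr") <-
    1e5 * sum(ref$rate * ref$weight) / sum(ref$weight)
  class(ref) <- c("reference_rates", class(ref))
  ref
}

#' Reference age-standardised rate implied by a `reference_rates` object
#'
#' @param ref A `reference_rates` object.
#' @return The reference ASR per 100,000.
#' @export
reference_asr <- function(ref) {
  asr <- attr(ref, "reference_asr")
  if (is.null(asr)) {
    asr <- 1e5 * sum(ref$rate * ref$weight) / sum(ref$weight)
  }
  asr
}

#' Expected counts by indirect standardisation
#'
#' Applies the reference age-specific rates to each region's person-years:
#' `E_{i,p} = sum_{t in p} sum_a rate_a * P_{i,a,t}`, summing over the
#' calendar years of each period. The ratio `O/E` is then the
#' standardised incidence (or mortality) ratio the model smooths.
#'
#' @param pop Population grid covering every year of every period (see
#'   [interpolate_population()]).
#' @param ref A `reference_rates` object.
#' @param period_years Named list mapping period label to the years it
#'   spans (see [period_years()]).
#' @return Tibble (`region`, `period`, `expected`).
#' @export
compute_expected <- function(pop, ref, period_years) {
  if (length(period_years) == 0) abort_input("period_years must be non-empty")
  missing_bands <- setdiff(unique(pop$age_band), ref$age_band)
  if (length(missing_bands) > 0) {
    abort_input("reference rates missing age bands: ",
                paste(missing_bands, collapse = ", "))
  }
  year_map <- tibble::tibble(
    period = rep(names(period_years), lengths(period_years)),
    year = unlist(period_years, use.names = FALSE)
  )
  missing_years <- setdiff(year_map$year, unique(pop$year))
  if (length(missing_years) > 0) {
    abort_input("population grid missing years: ",
                paste(missing_years, collapse = ", "))
  }
  pop |>
    dplyr::inner_join(year_map, by = "year",
                      relationship = "many-to-many") |>
    dplyr::inner_join(tibble::as_tibble(ref)[, c("age_band", "rate")],
                      by = "age_band") |>
    dplyr::group_by(.data$region, .data$period) |>
    dplyr::summarise(expected = sum(.data$population * .data$rate),
                     .groups = "drop")
}

#' Adjust expected counts for registry completeness
#'
#' In `offset` mode (default) the expected counts are multiplied by the
#' completeness fraction, `E' = E * c`, so that modelled means refer to
#' *observed* (under-registered) counts and the Poisson likelihood keeps
#' integer data. `inflate` mode returns `E` unchanged and instead divides
#' the observed counts by `c` upstream; it is provided for comparison
#' only, since non-integer inflated counts are rejected by the count
#' likelihood.
#'
#' @param expected Tibble (`region`, `period`, `expected`).
#' @param covariates Covariate panel supplying `completeness`.
#' @param mode `"offset"` or `"inflate"`.
#' @return Adjusted expected counts tibble (same shape).
#' @export
adjust_for_completeness <- function(expected, covariates,
                                    mode = c("offset", "inflate")) {
  mode <- match.arg(mode)
  cells <- dplyr::inner_join(
    expected, dplyr::select(covariates, "region", "period", "completeness"),
    by = c("region", "period")
  )
  if (nrow(cells) != nrow(expected)) {
    abort_input("covariates do not cover all expected-count cells")
  }
  check_completeness(cells$completeness)
  if (mode == "offset") {
    cells$expected <- cells$expected * cells$completeness
  }
  dplyr::select(cells, "region", "period", "expected")
}

#' Inflate observed counts by completeness (companion to `inflate` mode)
#'
#' Divides counts by completeness; the result is generally non-integer and
#' is intended for descriptive comparison, not for the Poisson
#' likelihood.
#'
#' @inheritParams thin_counts
#' @return Event panel with `count` replaced by `count / completeness`.
#' @export
inflate_counts <- function(panel, covariates) {
  cells <- dplyr::inner_join(
    panel, dplyr::select(covariates, "region", "period", "completeness"),
    by = c("region", "period")
  )
  check_completeness(cells$completeness)
  cells$count <- cells$count / cells$completeness
  dplyr::select(cells, "region", "period", "count")
}

#' Age-standardised rates from relative-risk draws
#'
#' Converts posterior relative-risk draws to the rate scale by linear
#' scaling against the reference ASR: `ASR = theta * reference_asr`, per
#' 100,000. A relative risk of 1 therefore maps to the national reference
#' rate.
#'
#' @param theta_draws Numeric vector/matrix of non-negative relative-risk
#'   draws (draws x cells when a matrix).
#' @param ref A `reference_rates` object (or a single reference ASR).
#' @return Draws on the per-100,000 rate scale, same shape as input.
#' @export
asr_from_relative_risk <- function(theta_draws, ref) {
  if (any(theta_draws < 0, na.rm = TRUE)) {
    abort_input("relative risks must be non-negative")
  }
  asr <- if (is.numeric(ref) && length(ref) == 1) ref else reference_asr(ref)
  theta_draws * asr
}
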