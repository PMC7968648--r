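#' Summarise posterior draws as mean and 95% credible interval
#'
#' Mean plus the 2.5th and 97.5th posterior percentiles; percentiles use
#' linear interpolation between order statistics (R's default quantile
#' rule, type 7).
#'
#' @param draws Numeric vector of draws, or a draws-by-cells matrix as
#'   returned by [monitor_theta()] (whose `cells` attribute supplies
#'   `region`/`period` columns).
#' @param level Credible level (default 0.95).
#' @return Tibble with columns `mean`, `lo`, `hi` (one row per cell;
#'   preceded by `region`/`period` when available).
#' @export
summarize_draws <- function(draws, level = 0.95) {
  if (is.null(draws) || length(draws) == 0) abort_input("no draws supplied")
  a <- (1 - level) / 2
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 2) abort_input("need at least two draws")
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE, type = 7)
  out <- tibble::tibble(mean = colMeans(draws), lo = qs[1, ], hi = qs[2, ])
  cells <- attr(draws, "cells")
  if (!is.null(cells)) out <- dplyr::bind_cols(tibble::as_tibble(cells), out)
  else if (!is.null(colnames(draws))) {
    out <- dplyr::bind_cols(tibble::tibble(cell = colnames(draws)), out)
  }
  out
}

#' Percentage change between two periods
#'
#' `100 * (r2 - r1) / r1`. In `per-draw` mode (default) the change is
#' computed draw-wise and then summarised with mean and 95% credible
#' interval, which is how asymmetric change intervals arise; in `point`
#' mode the formula is applied directly to point estimates (the
#' arithmetic used to check printed tables).
#'
#' @param draws_t1,draws_t2 Rates in the earlier and later period:
#'   draw vectors/matrices (per-draw mode, equal draw counts and
#'   matching cells) or point values (point mode).
#' @param mode `"per-draw"` or `"point"`.
#' @return Point mode: numeric vector of changes (%). Per-draw mode: a
#'   summary tibble from [summarize_draws()] of the draw-wise changes.
#' @export
percent_change <- function(draws_t1, draws_t2, mode = c("per-draw", "point")) {
  mode <- match.arg(mode)
  if (any(draws_t1 <= 0)) {
    abort_input("percentage change undefined: non-positive baseline rate")
  }
  if (mode == "point") {
    return(100 * (draws_t2 - draws_t1) / draws_t1)
  }
  if (length(draws_t1) != length(draws_t2)) {
    abort_input("per-draw mode needs equal draw counts")
  }
  ch <- 100 * (draws_t2 - draws_t1) / draws_t1
  if (!is.matrix(ch)) ch <- matrix(ch, ncol = 1)
  summarize_draws(ch)
}

#' Assign regions to wealth quintiles
#'
#' Regions are sorted by ascending wealth index (ties broken by region
#' identifier, so assignment is deterministic) and split into five
#' ordered groups, Q1 the poorest to Q5 the wealthiest. When the region
#' count is not a multiple of five the remainder goes to the poorest
#' quintiles first, so 31 regions split (7, 6, 6, 6, 6).
#'
#' @param wealth_index Named numeric vector (names = regions), or a
#'   tibble with `region` and `wealth_index` columns (extra columns and
#'   duplicated region rows, as in a multi-period covariate panel, are
#'   tolerated: the first value per region is used).
#' @return Tibble (`region`, `wealth_index`, `quintile`) with `quintile`
#'   an ordered factor Q1 < ... < Q5.
#' @export
assign_quintiles <- function(wealth_index) {
  if (inherits(wealth_index, "data.frame")) {
    wi <- wealth_index |>
      dplyr::distinct(.data$region, .keep_all = TRUE)
    wealth_index <- stats::setNames(wi$wealth_index, wi$region)
  }
  n <- length(wealth_index)
  if (n < 5) abort_input("need at least 5 regions to form quintiles")
  if (any(!is.finite(wealth_index))) abort_input("wealth index must be finite")
  ord <- order(wealth_index, names(wealth_index))
  sizes <- rep(n %/% 5, 5)
  r <- n %% 5
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  labels <- paste0("Q", 1:5)
  tibble::tibble(
    region = names(wealth_index)[ord],
    wealth_index = unname(wealth_index[ord]),
    quintile = factor(rep(labels, sizes), levels = labels, ordered = TRUE)
  )
}

#' Per-quintile rate summaries
#'
#' For each retained draw the quintile rate is the (optionally
#' population-weighted) mean of its member regions' rates; the draw-wise
#' quintile rates are then summarised with mean and 95% credible
#' interval.
#'
#' @param draws Draws-by-regions matrix of rates (columns named by
#'   region, e.g. from [monitor_theta()] scaled by
#'   [asr_from_relative_risk()] for one period).
#' @param quintiles Assignment from [assign_quintiles()].
#' @param weighting `"unweighted"` (default, the stratified-table
#'   convention) or `"population"`.
#' @param weights Named population weights per region (required for
#'   population weighting).
#' @return Tibble (`quintile`, `mean`, `lo`, `hi`).
#' @export
quintile_summary <- function(draws, quintiles,
                             weighting = c("unweighted", "population"),
                             weights = NULL) {
  weighting <- match.arg(weighting)
  regions <- sub("\\..*$", "", colnames(draws))
  q_of <- stats::setNames(as.character(quintiles$quintile), quintiles$region)
  if (!all(regions %in% names(q_of))) {
    abort_input("every region in draws must have a quintile")
  }
  if (weighting == "population" && is.null(weights)) {
    abort_input("population weighting requires weights")
  }
  labels <- levels(quintiles$quintile)
  out <- lapply(labels, function(q) {
    members <- which(q_of[regions] == q)
    if (length(members) == 0) abort_input("empty quintile: ", q)
    w <- if (weighting == "population") {
      wt <- weights[regions[members]]
      wt / sum(wt)
    } else rep(1 / length(members), length(members))
    qd <- as.vector(draws[, members, drop = FALSE] %*% w)
    dplyr::bind_cols(tibble::tibble(quintile = q), summarize_draws(qd))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(quintile = factor(.data$quintile, levels = labels,
                                    ordered = TRUE))
}

#' Rank regions by rate and track rank changes between periods
#'
#' Dense ranks by descending mean rate within each period (rank 1 =
#' highest rate; tied means share a rank). `display_rank` breaks ties by
#' region identifier and is therefore a permutation of `1..n` within
#' each period. When two or more periods are present, `delta` is the
#' first-period rank minus the last-period rank (positive = the region
#' moved up the table).
#'
#' @param summaries Tibble with `region`, `period`, `mean` (one row per
#'   region per period), e.g. from [summarize_draws()].
#' @param periods Periods to rank; default all, ordered as first
#'   encountered. Deltas compare the first against the last.
#' @return Tibble (`region`, `period`, `mean`, `rank`, `display_rank`,
#'   `delta`).
#' @export
rank_regions <- function(summaries, periods = NULL) {
  if (is.null(periods)) periods <- unique(summaries$period)
  if (!all(periods %in% summaries$period)) {
    abort_input("period(s) missing from summaries")
  }
  tab <- summaries |>
    dplyr::filter(.data$period %in% periods) |>
    dplyr::group_by(.data$period) |>
    dplyr::mutate(
      rank = dplyr::dense_rank(dplyr::desc(.data$mean)),
      display_rank = rank(-.data$mean, ties.method = "first")
    ) |>
    dplyr::ungroup()
  dup <- tab |>
    dplyr::count(.data$region, .data$period) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort_input("more than one summary per region x period")

  if (length(periods) >= 2) {
    p1 <- periods[1]
    p2 <- periods[length(periods)]
    delta_tab <- tab |>
      dplyr::filter(.data$period %in% c(p1, p2)) |>
      dplyr::select("region", "period", "rank") |>
      tidyr::pivot_wider(names_from = "period", values_from = "rank") |>
      dplyr::mutate(delta = .data[[p1]] - .data[[p2]]) |>
      dplyr::select("region", "delta")
    tab <- dplyr::left_join(tab, delta_tab, by = "region")
  } else {
    tab$delta <- NA_integer_
  }
  dplyr::arrange(tab, .data$period, .data$display_rank) |>
    dplyr::select("region", "period", "mean", "rank", "display_rank", "delta")
}

#' Posterior rate summaries for every region x period of a fit
#'
#' Convenience wrapper: relative-risk draws from [monitor_theta()],
#' scaled to the per-100,000 rate scale against the reference ASR, then
#' summarised per cell.
#'
#' @param fit A `bym_fit` (or a named list of per-period fits).
#' @param ref A `reference_rates` object or a single reference ASR.
#' @return Tibble (`region`, `period`, `mean`, `lo`, `hi`) on the
#'   per-100,000 scale.
#' @export
rate_summaries <- function(fit, ref) {
  fits <- if (inherits(fit, "bym_fit")) list(fit) else fit
  dplyr::bind_rows(lapply(fits, function(f) {
    summarize_draws(asr_from_relative_risk(monitor_theta(f), ref))
  }))
}
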