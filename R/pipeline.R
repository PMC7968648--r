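#' Fit the full disease-mapping pipeline
#'
#' Chains the standard analysis: completeness adjustment of the expected
#' counts, one independent BYM fit per period (each interval is reported
#' on its own, so fits do not share parameters across periods), posterior
#' rate summaries on the per-100,000 scale, percentage change between the
#' first and last period, residual Moran's I per period, DIC per period
#' and convergence summaries.
#'
#' @param counts Observed event panel (`region`, `period`, `count`).
#' @param expected Unadjusted expected counts from [compute_expected()].
#' @param covariates Covariate panel.
#' @param graph A [bym_graph()].
#' @param ref A `reference_rates` object (or single reference ASR).
#' @param config An [mcmc_config()]; each period's fit derives its own
#'   seed sub-stream from `config$seed`.
#' @param completeness How registry completeness enters: `"offset"`
#'   (default, multiplies `E`), `"covariate"` (log-completeness as a
#'   standardised regression column), `"both"`, or `"none"`.
#' @param covariate_names Regression columns besides any completeness
#'   term.
#' @param n_perm Permutations for the residual Moran's I test.
#' @return A `bym_analysis` list: `fits` (per period), `rates`,
#'   `changes`, `moran`, `dic`, `convergence`, `quintiles`, plus the
#'   inputs needed by the reporting helpers.
#' @export
bym_analysis <- function(counts, expected, covariates, graph, ref,
                         config = mcmc_config(),
                         completeness = c("offset", "covariate", "both",
                                          "none"),
                         covariate_names = c("urbanisation", "yos"),
                         n_perm = 999) {
  completeness <- match.arg(completeness)
  covariates <- dplyr::mutate(covariates,
                              log_completeness = log(.data$completeness))
  if (completeness %in% c("offset", "both")) {
    expected <- adjust_for_completeness(expected, covariates, "offset")
  }
  if (completeness %in% c("covariate", "both")) {
    covariate_names <- union(covariate_names, "log_completeness")
  }

  periods <- unique(counts$period)
  fits <- lapply(periods, function(p) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("period.", p))
    run_mcmc(dplyr::filter(counts, .data$period == p),
             dplyr::filter(expected, .data$period == p),
             covariates, graph, cfg, covariate_names = covariate_names)
  })
  names(fits) <- periods

  rates <- rate_summaries(fits, ref)

  changes <- if (length(periods) >= 2) {
    p1 <- periods[1]
    p2 <- periods[length(periods)]
    asr1 <- asr_from_relative_risk(monitor_theta(fits[[p1]]), ref)
    asr2 <- asr_from_relative_risk(monitor_theta(fits[[p2]]), ref)
    # align columns by region
    reg <- intersect(attr(asr1, "cells")$region, attr(asr2, "cells")$region)
    i1 <- match(reg, attr(asr1, "cells")$region)
    i2 <- match(reg, attr(asr2, "cells")$region)
    ch <- percent_change(asr1[, i1, drop = FALSE], asr2[, i2, drop = FALSE])
    dplyr::bind_cols(tibble::tibble(region = reg),
                     ch[, c("mean", "lo", "hi")])
  } else NULL

  moran <- lapply(fits, function(f) {
    morans_i(pearson_residuals(f), graph, n_perm = n_perm,
             seed = substream_seed(config$seed, "moran"))
  })
  dic <- lapply(fits, compute_dic)
  convergence <- lapply(fits, convergence_summary)
  quintiles <- assign_quintiles(covariates)

  structure(
    list(fits = fits, rates = rates, changes = changes, moran = moran,
         dic = dic, convergence = convergence, quintiles = quintiles,
         ref = ref, graph = graph, periods = periods),
    class = "bym_analysis"
  )
}

#' @export
print.bym_analysis <- function(x, ...) {
  cat("<bym_analysis> ", length(x$periods), " period(s): ",
      paste(x$periods, collapse = ", "), "\n", sep = "")
  cat("DIC:", paste(sprintf("%s = %.1f", names(x$dic),
                            vapply(x$dic, `[[`, numeric(1), "dic")),
                    collapse = ", "), "\n")
  cat("Residual Moran's I p-values:",
      paste(sprintf("%s = %.3f", names(x$moran),
                    vapply(x$moran, `[[`, numeric(1), "p_value")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-quintile rate summaries of an analysis
#'
#' @param analysis A `bym_analysis`.
#' @param period Period label.
#' @inheritParams quintile_summary
#' @return Tibble (`quintile`, `mean`, `lo`, `hi`) on the per-100,000
#'   scale.
#' @export
analysis_quintile_rates <- function(analysis, period,
                                    weighting = c("unweighted", "population"),
                                    weights = NULL) {
  if (!period %in% names(analysis$fits)) abort_input("unknown period")
  asr <- asr_from_relative_risk(monitor_theta(analysis$fits[[period]]),
                                analysis$ref)
  colnames(asr) <- attr(asr, "cells")$region
  quintile_summary(asr, analysis$quintiles, weighting, weights)
}
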