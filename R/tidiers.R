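#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a BYM fit
#'
#' One row per monitored scalar with posterior mean, sd and 95% credible
#' bounds; region effects can be dropped to keep the table short.
#'
#' @param x A `bym_fit`.
#' @param pars `"fixed"` (default: intercept, coefficients, precisions)
#'   or `"all"` (adds the per-region `u` and `v` effects).
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`).
#' @export
tidy.bym_fit <- function(x, pars = c("fixed", "all"), ...) {
  pars <- match.arg(pars)
  cols <- setdiff(names(x$draws), c("chain", "iteration"))
  if (pars == "fixed") cols <- grep("^(u_|v_)", cols, value = TRUE,
                                    invert = TRUE)
  d <- as.matrix(x$draws[, cols, drop = FALSE])
  qs <- apply(d, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = cols,
    estimate = colMeans(d),
    std.error = apply(d, 2, stats::sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

#' Glance at a BYM fit
#'
#' @param x A `bym_fit`.
#' @param ... Unused.
#' @return One-row tibble: chain/draw counts, DIC and effective number of
#'   parameters, worst split-Rhat over fixed effects and precisions, and
#'   mean Metropolis acceptance rates.
#' @export
glance.bym_fit <- function(x, ...) {
  dic_res <- compute_dic(x)
  conv <- convergence_summary(x)
  fixed <- !grepl("^(u_|v_)", conv$parameter)
  acc <- colMeans(x$acceptance)
  tibble::tibble(
    n_chains = max(x$draws$chain),
    n_draws = nrow(x$draws),
    dic = dic_res$dic,
    p_d = dic_res$p_d,
    max_rhat = max(conv$rhat[fixed]),
    accept_alpha = unname(acc["alpha"]),
    accept_u = unname(acc["u"]),
    accept_v = unname(acc["v"])
  )
}
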