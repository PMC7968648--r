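#' Per-region residuals from a fitted model
#'
#' Pearson residuals `(O - mu_hat) / sqrt(mu_hat)` on the posterior-mean
#' fitted values `mu_hat = E * mean(theta draws)`, averaged over periods
#' to one value per region (the vector Moran's I is applied to).
#' Deviance residuals are available behind `type = "deviance"`.
#'
#' @param fit A `bym_fit`.
#' @param type `"pearson"` (default) or `"deviance"`.
#' @return Tibble (`region`, `residual`), one row per region.
#' @export
pearson_residuals <- function(fit, type = c("pearson", "deviance")) {
  type <- match.arg(type)
  theta <- monitor_theta(fit)
  mu_hat <- fit$cells$expected * colMeans(theta)
  O <- fit$cells$count
  if (any(mu_hat == 0 & O > 0)) {
    abort_input("zero fitted mean with positive observed count")
  }
  r <- if (type == "pearson") {
    (O - mu_hat) / sqrt(mu_hat)
  } else {
    term <- ifelse(O > 0, O * log(O / mu_hat), 0) - (O - mu_hat)
    sign(O - mu_hat) * sqrt(2 * pmax(term, 0))
  }
  tibble::tibble(region = fit$cells$region, residual = r) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(residual = mean(.data$residual), .groups = "drop")
}

#' Moran's I with a permutation test
#'
#' Computes `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` over the graph's neighbour weights and assesses
#' significance by random relabelling of the regions. The permutation
#' p-value is two-sided around the null expectation `-1/(n-1)` and
#' includes the observed configuration in the null set, so it is never
#' smaller than `1/(n_perm + 1)`.
#'
#' @param x Numeric vector, one value per region (named by region or in
#'   graph order). Typically residuals from [pearson_residuals()].
#' @param graph A [bym_graph()].
#' @param weighting `"binary"` (default) symmetric 0/1 weights, or
#'   `"row-standardised"` weights summing to 1 within each region's
#'   neighbour set (the slope-of-neighbour-mean reading of the statistic).
#' @param n_perm Number of random relabellings.
#' @param seed Integer seed for the permutations.
#' @return A `moran_result` list: `I`, `expected_I`, `p_value`, `n_perm`,
#'   `weighting`.
#' @export
morans_i <- function(x, graph, weighting = c("binary", "row-standardised"),
                     n_perm = 999, seed = 1L) {
  weighting <- match.arg(weighting)
  if (inherits(x, "data.frame")) x <- stats::setNames(x$residual, x$region)
  n <- length(graph$region_ids)
  if (length(x) != n) abort_input("x must have one value per region")
  if (n < 3) abort_input("Moran's I needs at least 3 regions")
  if (!is.null(names(x))) x <- x[graph$region_ids]
  if (stats::sd(x) == 0) abort_input("x has zero variance: Moran's I undefined")

  W <- matrix(0, n, n)
  ei <- graph_edge_index(graph)
  if (nrow(ei) > 0) {
    W[ei] <- 1
    W[ei[, c(2, 1), drop = FALSE]] <- 1
  }
  if (weighting == "row-standardised") {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  S0 <- sum(W)
  if (S0 == 0) abort_input("graph has no edges: Moran's I undefined")

  stat <- function(z) {
    zc <- z - mean(z)
    (n / S0) * as.numeric(crossprod(zc, W %*% zc)) / sum(zc^2)
  }
  I_obs <- stat(x)
  e_i <- -1 / (n - 1)

  with_seed(substream_seed(seed, "moran"), {
    I_perm <- vapply(seq_len(n_perm), function(b) stat(sample(x)), numeric(1))
  })
  p <- (1 + sum(abs(I_perm - e_i) >= abs(I_obs - e_i) - 1e-12)) / (n_perm + 1)

  structure(list(I = I_obs, expected_I = e_i, p_value = min(p, 1),
                 n_perm = n_perm, weighting = weighting),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Moran's I = ", format(x$I, digits = 4),
      " (null expectation ", format(x$expected_I, digits = 4),
      "), permutation p = ", format(x$p_value, digits = 4),
      " [", x$n_perm, " permutations, ", x$weighting, " weights]\n",
      sep = "")
  invisible(x)
}

#' Deviance Information Criterion
#'
#' `DIC = dbar + p_D` with `dbar` the posterior mean deviance,
#' `d_hat` the deviance at the posterior means of `alpha`, `beta`, `u`
#' and `v` (plug-in at the relative-risk level, the BUGS default focus),
#' and `p_D = dbar - d_hat` the effective number of parameters. Deviance
#' is `-2` times the Poisson log-likelihood with the same `log(O!)`
#' omission as [poisson_loglik()], so only differences are meaningful.
#'
#' @param fit A `bym_fit` with at least two retained draws.
#' @return A `dic_result` list: `dbar`, `d_hat`, `p_d`, `dic` (satisfying
#'   `dic = 2 * dbar - d_hat` exactly).
#' @export
compute_dic <- function(fit) {
  d <- fit$draws
  if (nrow(d) < 2) abort_input("DIC needs at least two retained draws")
  theta <- monitor_theta(fit)
  O <- fit$cells$count
  E <- fit$cells$expected
  const <- sum(O * log(E))
  ll <- const + as.vector(log(theta) %*% O) - as.vector(theta %*% E)
  dev <- -2 * ll
  if (any(!is.finite(dev))) {
    abort_input("non-finite deviance in draw(s) ",
                paste(utils::head(which(!is.finite(dev)), 5), collapse = ", "))
  }
  dbar <- mean(dev)

  # plug-in deviance at posterior means of the latent parameters
  pm <- colMeans(d[, setdiff(names(d), c("chain", "iteration"))])
  ids <- fit$graph$region_ids
  r <- fit$cells$region
  eta_hat <- pm[["alpha"]] +
    (if (ncol(fit$X) > 0) {
      as.vector(fit$X %*% pm[paste0("beta_", colnames(fit$X))])
    } else 0) +
    pm[paste0("u_", r)] + pm[paste0("v_", r)]
  mu_hat <- E * exp(eta_hat)
  d_hat <- -2 * sum(O * log(mu_hat) - mu_hat)

  structure(list(dbar = dbar, d_hat = d_hat, p_d = dbar - d_hat,
                 dic = 2 * dbar - d_hat),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat("DIC = ", format(x$dic, digits = 6), "  (Dbar = ",
      format(x$dbar, digits = 6), ", pD = ", format(x$p_d, digits = 4),
      ")\n", sep = "")
  invisible(x)
}

#' Effective sample size of one chain (Geyer initial monotone sequence)
#' @noRd
ess_chain <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- as.vector(stats::acf(x, lag.max = min(n - 1, 2000),
                              plot = FALSE)$acf)[-1]
  # pair sums; truncate at the first negative, enforce monotonicity
  n_pairs <- floor(length(rho) / 2)
  if (n_pairs == 0) return(n)
  g <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  pos <- which(g <= 0)
  if (length(pos) > 0) g <- g[seq_len(pos[1] - 1)]
  if (length(g) > 1) g <- cummin(g)
  denom <- max(1 + 2 * sum(g), 1e-8)
  min(n / denom, n)
}

#' MCMC convergence summaries
#'
#' Split-`Rhat` (each chain halved, the potential scale reduction factor
#' computed across the half-chains, floored at 1) and effective sample
#' size (Geyer initial-monotone-sequence estimate summed over chains) for
#' every monitored scalar. Parameters with `Rhat` above the threshold are
#' flagged.
#'
#' @param fit A `bym_fit`, or a draws tibble with `chain` and `iteration`
#'   columns.
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return Tibble (`parameter`, `rhat`, `ess`, `flagged`).
#' @export
convergence_summary <- function(fit, rhat_threshold = 1.05) {
  d <- if (inherits(fit, "bym_fit")) fit$draws else tibble::as_tibble(fit)
  pars <- setdiff(names(d), c("chain", "iteration"))
  n_chain <- length(unique(d$chain))
  n_iter <- nrow(d) / n_chain
  if (n_chain < 2 && n_iter < 100) {
    abort_input("need at least 2 chains or 100 draws")
  }

  out <- lapply(pars, function(p) {
    chains <- split(d[[p]], d$chain)
    # split each chain in half
    halves <- unlist(lapply(chains, function(x) {
      h <- floor(length(x) / 2)
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(halves)
    n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    rhat <- if (W == 0) {
      if (B == 0) 1 else Inf
    } else {
      max(1, sqrt(((n - 1) / n * W + B / n) / W))
    }
    ess <- sum(vapply(chains, ess_chain, numeric(1)))
    tibble::tibble(parameter = p, rhat = rhat, ess = ess)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(flagged = .data$rhat > rhat_threshold)
}
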