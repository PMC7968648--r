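#' Bundle BYM model parameters
#'
#' A `bym_state` holds one point in parameter space of the
#' Besag-York-Mollie model: intercept `alpha`, covariate coefficients
#' `beta` (named), spatial effects `u` and exchangeable effects `v`
#' (named by region), and the two precisions.
#'
#' @param alpha Intercept (log relative risk).
#' @param beta Named numeric vector of covariate coefficients (may be
#'   empty).
#' @param u,v Named numeric vectors of region effects.
#' @param tau_u,tau_v Positive precisions.
#' @return A `bym_state` list.
#' @export
bym_state <- function(alpha = 0, beta = numeric(0), u = numeric(0),
                      v = numeric(0), tau_u = 1, tau_v = 1) {
  if (tau_u <= 0 || tau_v <= 0) abort_input("precisions must be positive")
  structure(list(alpha = alpha, beta = beta, u = u, v = v,
                 tau_u = tau_u, tau_v = tau_v),
            class = "bym_state")
}

#' Standardise covariate columns
#'
#' Centre/scale the named columns of a cell table to mean 0, sd 1
#' (constant columns are centred only). Returns the design matrix and the
#' mapping so that fits can report coefficients on either scale.
#' @noRd
standardise_columns <- function(cells, cols) {
  if (length(cols) == 0) {
    return(list(X = matrix(0, nrow(cells), 0), center = numeric(0),
                scale = numeric(0)))
  }
  missing_cols <- setdiff(cols, names(cells))
  if (length(missing_cols) > 0) {
    abort_input("missing covariate columns: ",
                paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(cells[, cols, drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(X, 2, center), 2, scale, "/")
  list(X = X, center = center, scale = scale)
}

#' Poisson log-likelihood of the BYM model
#'
#' Evaluates `sum_{cells} O * log(mu) - mu` with
#' `mu = E * exp(alpha + x' beta + u_i + v_i)`; the data-only constant
#' `log(O!)` is omitted throughout the package (likelihood, deviance and
#' DIC all share the convention, so comparisons are unaffected). Cells
#' with `E = 0` contribute 0 when `O = 0` and drive the likelihood to
#' `-Inf` (with a warning, not an error) when `O > 0`.
#'
#' @param state A [bym_state()]; `u`/`v` entries are matched to cells by
#'   region name (missing regions contribute 0).
#' @param counts Event panel (`region`, `period`, `count`).
#' @param expected Adjusted expected counts (`region`, `period`,
#'   `expected`).
#' @param covariates Optional covariate panel; the columns named in
#'   `state$beta` are used as-is (standardise beforehand if the
#'   coefficients are on the standardised scale).
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
poisson_loglik <- function(state, counts, expected, covariates = NULL) {
  cells <- dplyr::inner_join(counts, expected, by = c("region", "period"))
  if (nrow(cells) != nrow(counts)) {
    abort_input("counts and expected counts do not share all cells")
  }
  if (any(cells$expected < 0)) abort_input("expected counts must be >= 0")
  eta <- rep(state$alpha, nrow(cells))
  if (length(state$beta) > 0) {
    if (is.null(covariates)) abort_input("state has beta but no covariates given")
    cells2 <- dplyr::inner_join(cells, covariates, by = c("region", "period"))
    X <- as.matrix(cells2[, names(state$beta), drop = FALSE])
    eta <- eta + as.vector(X %*% state$beta)
  }
  if (length(state$u) > 0) eta <- eta + state$u[cells$region]
  if (length(state$v) > 0) eta <- eta + state$v[cells$region]
  mu <- cells$expected * exp(eta)

  zero <- mu == 0
  if (any(zero & cells$count > 0)) {
    warning("observed events with zero expected count: log-likelihood is -Inf")
    return(-Inf)
  }
  sum(ifelse(zero, 0, cells$count * log(mu) - mu))
}

#' ICAR structure matrix (graph Laplacian)
#' @noRd
icar_structure_matrix <- function(graph) {
  n <- length(graph$region_ids)
  W <- matrix(0, n, n, dimnames = list(graph$region_ids, graph$region_ids))
  ei <- graph_edge_index(graph)
  if (nrow(ei) > 0) {
    W[ei] <- 1
    W[ei[, c(2, 1), drop = FALSE]] <- 1
  }
  diag(rowSums(W)) - W
}

#' Intrinsic CAR log-prior density
#'
#' The improper pairwise-difference prior on the spatial effects:
#' `((n - k)/2) * log(tau_u) - (tau_u/2) * sum_{i~j} (u_i - u_j)^2`, the
#' sum running over unordered neighbour pairs, with `k` the number of
#' connected components (the prior's rank deficiency, one per component).
#' The density is invariant to adding a constant within a component; the
#' sampler removes that null direction by recentring.
#'
#' @param u Numeric vector of spatial effects, one per graph region (in
#'   graph order, or named by region).
#' @param tau_u Positive precision.
#' @param graph A [bym_graph()].
#' @return Unnormalised log-density.
#' @export
icar_logprior <- function(u, tau_u, graph) {
  n <- length(graph$region_ids)
  if (length(u) != n) abort_input("u must have one entry per region")
  if (tau_u <= 0) abort_input("tau_u must be positive")
  if (!is.null(names(u))) u <- u[graph$region_ids]
  ei <- graph_edge_index(graph)
  ss <- if (nrow(ei) > 0) sum((u[ei[, 1]] - u[ei[, 2]])^2) else 0
  k <- graph$n_components
  (n - k) / 2 * log(tau_u) - tau_u / 2 * ss
}

#' MCMC configuration
#'
#' Sampler settings with disease-mapping defaults: vague
#' `Gamma(0.5, 0.0005)` hyperpriors on both precisions (the BUGS
#' convention for BYM models), `Normal(0, 10)` priors on the intercept
#' and the standardised-scale coefficients, 3 chains of 20,000 sweeps
#' with 10,000 burn-in and thinning 5, and random-walk proposal scales
#' adapted during burn-in towards 20-50% acceptance.
#'
#' @param n_iter Total sweeps per chain.
#' @param n_burnin Burn-in sweeps discarded (must be `< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param n_chains Number of chains.
#' @param proposal_sd Named list of initial random-walk sds for blocks
#'   `alpha`, `beta`, `u`, `v`.
#' @param tau_prior Length-2 (shape, rate) Gamma hyperprior shared by
#'   `tau_u` and `tau_v`.
#' @param prior_sd_fixed Gaussian prior sd for `alpha` and each `beta`.
#' @param adapt Tune proposal sds during burn-in?
#' @param seed Integer seed; the single source of randomness for the fit.
#' @return A `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 20000, n_burnin = 10000, thin = 5,
                        n_chains = 3,
                        proposal_sd = list(alpha = 0.05, beta = 0.05,
                                           u = 0.3, v = 0.3),
                        tau_prior = c(shape = 0.5, rate = 0.0005),
                        prior_sd_fixed = 10,
                        adapt = TRUE, seed = 1L) {
  if (n_iter <= n_burnin) abort_input("n_iter must exceed n_burnin")
  if (thin < 1) abort_input("thin must be >= 1")
  if (any(unlist(proposal_sd) <= 0) || prior_sd_fixed <= 0) {
    abort_input("all proposal and prior sds must be positive")
  }
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 proposal_sd = proposal_sd, tau_prior = tau_prior,
                 prior_sd_fixed = prior_sd_fixed,
                 adapt = isTRUE(adapt), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the BYM model by Metropolis-within-Gibbs
#'
#' Samples the posterior of the Besag-York-Mollie Poisson model
#' `O_cell ~ Poisson(E_cell * exp(alpha + x_cell' beta + u_i + v_i))`
#' with an intrinsic CAR prior on `u`, iid Gaussian prior on `v`, and
#' Gamma hyperpriors on both precisions. Precisions are updated by their
#' conjugate Gamma full conditionals; `alpha`, each `beta`, and the
#' region effects move by random-walk Metropolis. Region effects are
#' updated in graph-colour blocks (regions of one colour share no edge,
#' so their single-site full conditionals do not interact and the block
#' is accepted element-wise). After every sweep `u` is recentred to mean
#' zero within each graph component, the removed mean being folded into
#' `alpha` (an exact reparametrisation on connected graphs).
#'
#' Covariates named in `covariate_names` are standardised internally to
#' mean 0, sd 1 across the modelled cells; the mapping is stored in the
#' fit. Cells with zero adjusted expected count are excluded from the
#' likelihood with a warning.
#'
#' @param counts Event panel (`region`, `period`, `count`).
#' @param expected Completeness-adjusted expected counts (`region`,
#'   `period`, `expected`); see [adjust_for_completeness()].
#' @param covariates Covariate panel; `NULL` for an intercept-only model.
#' @param graph A [bym_graph()] covering the panel's regions.
#' @param config An [mcmc_config()].
#' @param covariate_names Columns of `covariates` to use as regression
#'   terms (default urbanisation and schooling; completeness enters as
#'   the offset on `expected`). Use `character(0)` for intercept-only.
#' @param include_u,include_v Set `FALSE` to pin the spatial or the
#'   exchangeable effects at zero (used e.g. to reduce the model to a
#'   single-region intercept-only form).
#' @return A `bym_fit` with elements `draws` (tibble: `chain`,
#'   `iteration`, then one column per monitored scalar), `config`,
#'   `graph`, `cells`, `scaling` (covariate centring map), `acceptance`
#'   (per-block rates), and flags. Identical `config` (including seed)
#'   reproduces the draws bitwise.
#' @export
run_mcmc <- function(counts, expected, covariates = NULL, graph,
                     config = mcmc_config(),
                     covariate_names = if (is.null(covariates)) character(0)
                                       else intersect(c("urbanisation", "yos"),
                                                      names(covariates)),
                     include_u = TRUE, include_v = TRUE) {
  cells <- dplyr::inner_join(counts, expected, by = c("region", "period"))
  if (nrow(cells) != nrow(counts)) {
    abort_input("counts and expected counts do not share all cells")
  }
  if (!is.null(covariates) && length(covariate_names) > 0) {
    cells <- dplyr::inner_join(cells, covariates, by = c("region", "period"))
  }
  if (any(cells$expected < 0)) abort_input("expected counts must be >= 0")
  drop <- cells$expected == 0
  if (any(drop)) {
    if (any(cells$count[drop] > 0)) {
      warning("cells with O > 0 but E = 0 excluded from the likelihood")
    } else {
      warning(sum(drop), " cell(s) with E = 0 excluded from the likelihood")
    }
    cells <- cells[!drop, , drop = FALSE]
  }
  if (nrow(cells) == 0) abort_input("no cells with positive expected count")

  ids <- graph$region_ids
  n <- length(ids)
  r_cell <- match(cells$region, ids)
  if (anyNA(r_cell)) abort_input("panel regions missing from graph")

  sc <- standardise_columns(cells, covariate_names)
  X <- sc$X
  p <- ncol(X)

  O <- cells$count
  E <- cells$expected
  # rowsum drops empty groups; build full-length per-region aggregates
  agg <- function(x) {
    out <- numeric(n)
    s <- rowsum(x, r_cell)
    out[as.integer(rownames(s))] <- s
    out
  }
  O_r <- agg(O)
  O_tot <- sum(O)

  # graph structures
  ei <- graph_edge_index(graph)
  W <- matrix(0, n, n)
  if (nrow(ei) > 0) {
    W[ei] <- 1
    W[ei[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(W)
  comp <- graph$component
  k_comp <- graph$n_components
  colour <- if (n > 1) {
    ig <- igraph::graph_from_edgelist(
      if (nrow(ei) > 0) ei else matrix(integer(0), 0, 2), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    as.integer(igraph::greedy_vertex_coloring(ig))
  } else rep(1L, n)
  colour_sets <- split(seq_len(n), colour)

  a_tau <- config$tau_prior[["shape"]]
  b_tau <- config$tau_prior[["rate"]]
  s0 <- config$prior_sd_fixed
  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin

  par_names <- c("alpha",
                 if (p > 0) paste0("beta_", colnames(X)),
                 paste0("u_", ids), paste0("v_", ids),
                 "tau_u", "tau_v")

  run_chain <- function(chain_id) {
    with_seed(substream_seed(config$seed, paste0("chain", chain_id)), {
      # over-dispersed but deterministic-in-seed initial values
      alpha <- log(max(O_tot, 0.5) / sum(E)) + stats::rnorm(1, 0, 0.2)
      beta <- if (p > 0) stats::rnorm(p, 0, 0.2) else numeric(0)
      u <- numeric(n)
      v <- if (include_v) stats::rnorm(n, 0, 0.05) else numeric(n)
      tau_u <- stats::rgamma(1, 10, 1)   # diffuse start near 10
      tau_v <- stats::rgamma(1, 10, 1)

      sd_a <- config$proposal_sd$alpha
      sd_b <- rep(config$proposal_sd$beta, p)
      sd_u <- config$proposal_sd$u
      sd_v <- config$proposal_sd$v

      eta_x <- if (p > 0) as.vector(X %*% beta) else numeric(nrow(cells))
      mu <- E * exp(alpha + eta_x + u[r_cell] + v[r_cell])
      if (!all(is.finite(mu))) {
        stop("non-finite fitted means at the initial state; check inputs",
             call. = FALSE)
      }
      mu_r <- agg(mu)
      mu_tot <- sum(mu)

      acc <- c(alpha = 0, beta = 0, u = 0, v = 0)
      prop <- c(alpha = 0, beta = 0, u = 0, v = 0)
      draws <- matrix(NA_real_, n_keep, length(par_names),
                      dimnames = list(NULL, par_names))
      keep_i <- 0L

      for (iter in seq_len(config$n_iter)) {
        ## -- Gibbs: precisions ------------------------------------------
        if (include_u && n > 1) {
          ss_u <- if (nrow(ei) > 0) sum((u[ei[, 1]] - u[ei[, 2]])^2) else 0
          tau_u <- stats::rgamma(1, a_tau + (n - k_comp) / 2,
                                 rate = b_tau + ss_u / 2)
        }
        if (include_v) {
          tau_v <- stats::rgamma(1, a_tau + n / 2,
                                 rate = b_tau + sum(v^2) / 2)
        }

        ## -- alpha (random walk; likelihood change has closed form) -----
        d <- stats::rnorm(1, 0, sd_a)
        log_r <- O_tot * d - (exp(d) - 1) * mu_tot +
          (stats::dnorm(alpha + d, 0, s0, log = TRUE) -
             stats::dnorm(alpha, 0, s0, log = TRUE))
        prop["alpha"] <- prop["alpha"] + 1
        if (log(stats::runif(1)) < log_r) {
          alpha <- alpha + d
          f <- exp(d)
          mu <- mu * f; mu_r <- mu_r * f; mu_tot <- mu_tot * f
          acc["alpha"] <- acc["alpha"] + 1
        }

        ## -- beta, element-wise random walk -----------------------------
        if (p > 0) {
          for (j in seq_len(p)) {
            d <- stats::rnorm(1, 0, sd_b[j])
            fac <- exp(d * X[, j])
            log_r <- sum(O * d * X[, j]) - sum(mu * (fac - 1)) +
              (stats::dnorm(beta[j] + d, 0, s0, log = TRUE) -
                 stats::dnorm(beta[j], 0, s0, log = TRUE))
            prop["beta"] <- prop["beta"] + 1
            if (log(stats::runif(1)) < log_r) {
              beta[j] <- beta[j] + d
              mu <- mu * fac
              acc["beta"] <- acc["beta"] + 1
            }
          }
          mu_r <- agg(mu); mu_tot <- sum(mu)
        }

        ## -- u: colour-block single-site Metropolis ---------------------
        if (include_u && n > 1) {
          for (set in colour_sets) {
            d <- stats::rnorm(length(set), 0, sd_u)
            s_nb <- as.vector(W[set, , drop = FALSE] %*% u)
            dll <- O_r[set] * d - (exp(d) - 1) * mu_r[set]
            dpr <- -tau_u / 2 * (d^2 * deg[set] +
                                   2 * d * (deg[set] * u[set] - s_nb))
            ok <- log(stats::runif(length(set))) < dll + dpr
            prop["u"] <- prop["u"] + length(set)
            acc["u"] <- acc["u"] + sum(ok)
            if (any(ok)) {
              idx <- set[ok]
              u[idx] <- u[idx] + d[ok]
              f_r <- rep(1, n); f_r[idx] <- exp(d[ok])
              mu_r <- mu_r * f_r
              mu <- mu * f_r[r_cell]
            }
          }
          mu_tot <- sum(mu)

          # recentre within components, folding the mean into alpha
          m_c <- tapply(u, comp, mean)
          u <- u - m_c[comp]
          shift <- sum(m_c * tabulate(comp, k_comp)) / n
          alpha <- alpha + shift
          if (k_comp > 1) {
            # component means differ from the global shift: refresh mu
            eta_x <- if (p > 0) as.vector(X %*% beta) else 0
            mu <- E * exp(alpha + eta_x + u[r_cell] + v[r_cell])
            mu_r <- agg(mu); mu_tot <- sum(mu)
          }
        }

        ## -- v: simultaneous single-site Metropolis (no cross-terms) ----
        if (include_v) {
          d <- stats::rnorm(n, 0, sd_v)
          dll <- O_r * d - (exp(d) - 1) * mu_r
          dpr <- -tau_v / 2 * (2 * v * d + d^2)
          ok <- log(stats::runif(n)) < dll + dpr
          prop["v"] <- prop["v"] + n
          acc["v"] <- acc["v"] + sum(ok)
          if (any(ok)) {
            v[ok] <- v[ok] + d[ok]
            f_r <- rep(1, n); f_r[ok] <- exp(d[ok])
            mu_r <- mu_r * f_r
            mu <- mu * f_r[r_cell]
            mu_tot <- sum(mu)
          }
        }

        ## -- burn-in adaptation -----------------------------------------
        if (config$adapt && iter <= config$n_burnin && iter %% 50 == 0) {
          rates <- ifelse(prop > 0, acc / prop, 0.35)
          tune <- function(sd, rate) {
            if (rate < 0.2) sd * 0.8 else if (rate > 0.5) sd * 1.25 else sd
          }
          sd_a <- tune(sd_a, rates["alpha"])
          if (p > 0) sd_b <- vapply(sd_b, tune, numeric(1),
                                    rate = rates["beta"])
          sd_u <- tune(sd_u, rates["u"])
          sd_v <- tune(sd_v, rates["v"])
          acc[] <- 0; prop[] <- 0
        }

        ## -- store -------------------------------------------------------
        if (iter > config$n_burnin &&
            (iter - config$n_burnin) %% config$thin == 0) {
          keep_i <- keep_i + 1L
          draws[keep_i, ] <- c(alpha, beta, u, v, tau_u, tau_v)
        }
      }

      list(draws = draws,
           acceptance = ifelse(prop > 0, acc / prop, NA_real_))
    })
  }

  chains <- lapply(seq_len(config$n_chains), run_chain)
  draws <- dplyr::bind_rows(lapply(seq_len(config$n_chains), function(ch) {
    d <- tibble::as_tibble(chains[[ch]]$draws)
    dplyr::bind_cols(tibble::tibble(chain = ch, iteration = seq_len(nrow(d))),
                     d)
  }))
  acceptance <- do.call(rbind, lapply(chains, `[[`, "acceptance"))

  structure(
    list(draws = draws, config = config, graph = graph,
         cells = cells[, c("region", "period", "count", "expected")],
         X = X,
         scaling = list(names = colnames(X), center = sc$center,
                        scale = sc$scale),
         acceptance = acceptance,
         include_u = include_u, include_v = include_v),
    class = "bym_fit"
  )
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("<bym_fit> ", length(x$graph$region_ids), " regions, ",
      nrow(x$cells), " cells, ", max(x$draws$chain), " chain(s) x ",
      max(x$draws$iteration), " retained draws\n", sep = "")
  if (length(x$scaling$names) > 0) {
    cat("covariates:", paste(x$scaling$names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative-risk draws for region x period cells
#'
#' Reconstructs `theta = exp(alpha + x' beta + u_i + v_i)` for each
#' retained draw and each requested cell, using the standardised
#' covariate values stored in the fit.
#'
#' @param fit A `bym_fit`.
#' @param regions,periods Optional filters; defaults to every modelled
#'   cell.
#' @return Numeric matrix, retained draws in rows and cells in columns
#'   (named `region.period`), with a `cells` attribute tibble giving the
#'   column key. All entries are strictly positive.
#' @export
monitor_theta <- function(fit, regions = NULL, periods = NULL) {
  cells <- fit$cells
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(regions)) {
    if (!all(regions %in% cells$region)) abort_input("unknown region requested")
    keep <- keep & cells$region %in% regions
  }
  if (!is.null(periods)) {
    if (!all(periods %in% cells$period)) abort_input("unknown period requested")
    keep <- keep & cells$period %in% periods
  }
  if (!any(keep)) abort_input("no cells match the request")

  d <- fit$draws
  alpha <- d$alpha
  n_draws <- nrow(d)
  idx <- which(keep)
  X <- fit$X
  p <- ncol(X)
  B <- if (p > 0) {
    as.matrix(d[, paste0("beta_", colnames(X)), drop = FALSE])
  } else matrix(0, n_draws, 0)

  out <- matrix(NA_real_, n_draws, length(idx))
  for (j in seq_along(idx)) {
    cell <- idx[j]
    r <- cells$region[cell]
    eta <- alpha +
      (if (p > 0) as.vector(B %*% X[cell, ]) else 0) +
      d[[paste0("u_", r)]] + d[[paste0("v_", r)]]
    out[, j] <- exp(eta)
  }
  colnames(out) <- paste(cells$region[idx], cells$period[idx], sep = ".")
  attr(out, "cells") <- cells[idx, c("region", "period")]
  out
}
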