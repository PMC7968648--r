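# Shared fixtures, built in code at test time.

# A hand-assembled bym_fit whose draws are written down explicitly, for
# exercising the diagnostics/reporting arithmetic without running MCMC.
fake_fit <- function(cells, alphas, graph = NULL,
                     u = NULL, v = NULL) {
  regions <- unique(cells$region)
  if (is.null(graph)) {
    n <- length(regions)
    edges <- if (n >= 2) {
      tibble::tibble(from = regions[seq_len(n - 1)], to = regions[-1])
    } else {
      tibble::tibble(from = character(), to = character())
    }
    graph <- bym_graph(regions, edges)
  }
  n_draws <- length(alphas)
  d <- tibble::tibble(chain = 1L, iteration = seq_len(n_draws),
                      alpha = alphas)
  for (r in graph$region_ids) {
    d[[paste0("u_", r)]] <- if (is.null(u)) 0 else rep(u[[r]], n_draws)
    d[[paste0("v_", r)]] <- if (is.null(v)) 0 else rep(v[[r]], n_draws)
  }
  d$tau_u <- 1
  d$tau_v <- 1
  structure(
    list(draws = d, config = NULL, graph = graph,
         cells = cells[, c("region", "period", "count", "expected")],
         X = matrix(0, nrow(cells), 0),
         scaling = list(names = character(0), center = numeric(0),
                        scale = numeric(0)),
         acceptance = matrix(0.3, 1, 4,
                             dimnames = list(NULL,
                                             c("alpha", "beta", "u", "v"))),
         include_u = TRUE, include_v = TRUE),
    class = "bym_fit"
  )
}

# Small synthetic panel reused by slower tests (built once per run).
.fixture_env <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- simulate_panel(n_regions = 16, seed = 11)
  }
  .fixture_env$panel
}

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    p <- small_panel()
    e_adj <- adjust_for_completeness(p$expected, p$covariates)
    cfg <- mcmc_config(n_iter = 3000, n_burnin = 1000, thin = 2,
                       n_chains = 2, seed = 21)
    .fixture_env$fit <- run_mcmc(p$counts_observed, e_adj, p$covariates,
                                 p$graph, cfg)
  }
  .fixture_env$fit
}
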