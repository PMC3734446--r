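# Shared fixtures, built in code at test time.

make_lattice <- function(n_rows, n_cols, river = FALSE) {
  geo <- generate_geography(n_rows, n_cols, river = river)
  list(geo = geo, adj = contiguity_adjacency(geo))
}

# Suburb table with a spatially smooth standardized covariate and counts
# drawn from the convolution model.
make_counts <- function(n_rows, n_cols, births = 400, beta0 = qlogis(0.05),
                        beta1 = 0, sigma_u = 0, sigma_v = 0, seed = 1,
                        smoothness = 0.8) {
  l <- make_lattice(n_rows, n_cols)
  ses <- as.numeric(generate_ses(l$geo, smoothness, seed = seed + 1000))
  sub <- data.frame(suburb_id = l$adj$ids, ses_raw = ses,
                    ses_std = standardize_ses(ses), births = as.integer(births),
                    stringsAsFactors = FALSE)
  p <- simulation_params(beta0 = beta0, beta1 = beta1, sigma_u = sigma_u,
                         sigma_v = sigma_v, seed = seed)
  list(tab = simulate_counts(sub, l$adj, p), adj = l$adj, geo = l$geo, params = p)
}

# One small cached full-model fit shared across summary tests.
demo_full_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_counts(8, 8, births = 300, beta1 = -0.3, sigma_u = 0.2,
                       sigma_v = 0.15, seed = 11)
      cache <<- suppressWarnings(
        fit_bym(bym_model("full"), d$tab, d$adj,
                mcmc_config(iterations = 8000, burnin = 3000, thin = 5, seed = 4)))
    }
    cache
  }
})

# Minimal hand-built fit object for summary-function algebra tests.
fake_fit <- function(u, v, beta1 = NULL, ses_std = NULL,
                     sigma_u = NULL, sigma_v = NULL) {
  n <- ncol(u)
  ids <- sprintf("S%03d", seq_len(n))
  colnames(u) <- ids
  if (!is.null(v)) colnames(v) <- ids
  structure(list(
    spec = bym_model(if (is.null(beta1)) "random" else "full"),
    ids = ids,
    table = data.frame(suburb_id = ids, births = 100L, cases = 5L,
                       ses_std = if (is.null(ses_std)) rep(0, n) else ses_std),
    draws = list(beta0 = rep(qlogis(0.05), nrow(u)), beta1 = beta1,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 u = u, v = v, deviance = rep(0, nrow(u)))),
    class = "bym_fit")
}
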