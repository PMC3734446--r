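#' Specify one of the four nested binomial-logit models
#'
#' The four models are: `"null"` (intercept only), `"random"` (intercept +
#' ICAR spatial effect + exchangeable effect, the convolution model of
#' Besag, York and Mollie), `"fixed"` (intercept + SES fixed effect) and
#' `"full"` (fixed effect plus both random effects). Priors follow the
#' study convention: Normal(0, 100^2) on the regression coefficients and
#' half-Normal with scale 100 on both random-effect SDs.
#'
#' @param model one of `"null"`, `"random"`, `"fixed"`, `"full"`.
#' @param prior_sd_beta,prior_sd_sigma prior scales (default 100).
#' @return a `bym_model_spec`.
#' @export
bym_model <- function(model = c("null", "random", "fixed", "full"),
                      prior_sd_beta = 100, prior_sd_sigma = 100) {
  model <- match.arg(model)
  structure(list(model = model,
                 include_fixed = model %in% c("fixed", "full"),
                 include_car = model %in% c("random", "full"),
                 include_iid = model %in% c("random", "full"),
                 prior_sd_beta = prior_sd_beta,
                 prior_sd_sigma = prior_sd_sigma),
            class = "bym_model_spec")
}

#' MCMC configuration
#'
#' Desk-scale defaults (60,000 iterations, 20,000 burn-in, thinning 10,
#' i.e. 4,000 retained draws) keep a full-model fit to a few seconds while
#' giving stable DIC and credible intervals; the heavier settings used in
#' large registry analyses (10^6 iterations, 10^6 burn-in, thin 100) are
#' available through the same fields.
#'
#' @param iterations total MCMC sweeps.
#' @param burnin sweeps discarded (must be < `iterations`).
#' @param thin retain one sweep in `thin` (>= 1).
#' @param seed integer RNG seed.
#' @param adapt_window sweeps between proposal-scale adaptations during
#'   burn-in.
#' @return an `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 60000, burnin = 20000, thin = 10,
                        seed = 1L, adapt_window = 50) {
  if (burnin >= iterations) stop("burn-in must be smaller than iterations")
  if (thin < 1) stop("thinning interval must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window)),
            class = "mcmc_config")
}

#' Binomial log-likelihood at a given linear predictor
#'
#' `sum_i [R_i eta_i - N_i log(1 + exp(eta_i))]`, i.e. the binomial
#' log-likelihood without the data-only binomial-coefficient constant
#' (which cancels from all model comparisons used here).
#'
#' @param table suburb table with `births` (`N`) and `cases` (`R`).
#' @param eta per-suburb linear predictor (log-odds).
#' @return scalar log-likelihood.
#' @export
bym_log_likelihood <- function(table, eta) {
  stopifnot(length(eta) == nrow(table))
  r <- table$cases; n <- table$births
  sum(r * eta - n * log1p(exp(pmin(eta, 35))) - n * pmax(eta - 35, 0))
}

#' Intrinsic CAR log-prior (up to a constant)
#'
#' `-(1 / (2 sigma_u^2)) * sum_(i~j) (u_i - u_j)^2` over undirected edges.
#' The implied full conditional is
#' `u_i | u_(-i) ~ Normal(mean of neighbours, sigma_u^2 / n_i)`. Island
#' units (no neighbours) must carry `u = 0` and are excluded from the sum.
#'
#' @param u named (or adjacency-ordered) numeric vector of spatial effects.
#' @param adj a `suburb_adjacency`.
#' @param sigma_u conditional SD (> 0).
#' @return scalar log-density up to an additive constant.
#' @export
car_log_prior <- function(u, adj, sigma_u) {
  stopifnot(length(u) == length(adj$ids), sigma_u > 0)
  uu <- if (!is.null(names(u))) u[adj$ids] else stats::setNames(u, adj$ids)
  island <- lengths(adj$nbr) == 0
  if (any(island & abs(uu) > 1e-12)) {
    stop("island unit(s) must have u fixed at 0: ",
         paste(adj$ids[island & abs(uu) > 1e-12], collapse = ", "))
  }
  ss <- 0
  for (i in adj$ids) {
    for (j in adj$nbr[[i]]) if (i < j) ss <- ss + (uu[[i]] - uu[[j]])^2
  }
  -ss / (2 * sigma_u^2)
}

#' Fit a BYM-type model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler (single-site random-walk
#' updates, adaptive proposals during burn-in only, log-scale random walk
#' for the SDs, per-sweep sum-to-zero recentering of the ICAR effect with
#' the mean absorbed into the intercept). Geweke z-scores are computed for
#' every monitored scalar (intercept, slope, SDs, deviance); any |z| > 3
#' raises a warning with the diagnostics attached, never a silent success.
#'
#' @param spec a [bym_model()] specification.
#' @param table suburb table with `suburb_id`, `births`, `cases` and, for
#'   models with a fixed effect, `ses_std`.
#' @param adj a `suburb_adjacency` over the same units (required for models
#'   with a spatial effect; optional otherwise).
#' @param config an [mcmc_config()].
#' @return a `bym_fit`: retained draws (`beta0`, `beta1`, `sigma_u`,
#'   `sigma_v`, matrices `u`, `v`, `deviance`), the inputs, acceptance
#'   rates and Geweke z-scores.
#' @export
fit_bym <- function(spec, table, adj = NULL, config = mcmc_config()) {
  stopifnot(inherits(spec, "bym_model_spec"), inherits(config, "mcmc_config"))
  ids <- as.character(table$suburb_id)
  if (spec$include_fixed && is.null(table$ses_std)) {
    stop("models with a fixed SES effect need a ses_std column")
  }
  if (spec$include_car) {
    if (is.null(adj)) stop("models with a spatial effect need an adjacency")
    if (!setequal(ids, adj$ids)) stop("table and adjacency unit ids differ")
    table <- table[match(adj$ids, ids), , drop = FALSE]
    ids <- adj$ids
    nbr_idx <- lapply(adj$nbr, function(v) match(v, ids) - 1L)
    comp <- as.integer(connected_components(adj)[ids]) - 1L
  } else {
    nbr_idx <- replicate(nrow(table), integer(0), simplify = FALSE)
    comp <- seq_len(nrow(table)) - 1L
  }
  X <- if (spec$include_fixed) as.numeric(table$ses_std) else numeric(nrow(table))
  set.seed(config$seed)
  raw <- bym_mcmc_cpp(as.integer(table$births), as.integer(table$cases), X,
                      nbr_idx, comp,
                      spec$include_fixed, spec$include_car, spec$include_iid,
                      spec$prior_sd_beta, spec$prior_sd_sigma,
                      config$iterations, config$burnin, config$thin,
                      config$adapt_window)
  draws <- list(beta0 = raw$beta0,
                beta1 = if (spec$include_fixed) raw$beta1 else NULL,
                sigma_u = if (spec$include_car) raw$sigma_u else NULL,
                sigma_v = if (spec$include_iid) raw$sigma_v else NULL,
                u = if (spec$include_car) raw$u else NULL,
                v = if (spec$include_iid) raw$v else NULL,
                deviance = raw$deviance)
  if (!is.null(draws$u)) colnames(draws$u) <- ids
  if (!is.null(draws$v)) colnames(draws$v) <- ids
  mon <- list(beta0 = draws$beta0, deviance = draws$deviance)
  if (!is.null(draws$beta1)) mon$beta1 <- draws$beta1
  if (!is.null(draws$sigma_u)) mon$sigma_u <- draws$sigma_u
  if (!is.null(draws$sigma_v)) mon$sigma_v <- draws$sigma_v
  gz <- vapply(mon, function(ch) tryCatch(geweke_z(ch), error = function(e) NA_real_),
               numeric(1))
  fit <- structure(list(spec = spec, config = config, table = table,
                        ids = ids, draws = draws,
                        acceptance = raw$acceptance, geweke = gz),
                   class = "bym_fit")
  if (any(abs(gz) > 3, na.rm = TRUE)) {
    bad <- names(gz)[!is.na(gz) & abs(gz) > 3]
    warning("possible non-convergence (|Geweke z| > 3) for: ",
            paste(sprintf("%s (z = %.2f)", bad, gz[bad]), collapse = ", "))
  }
  fit
}

#' @export
print.bym_fit <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("BYM fit: %s model, %d suburbs, %d retained draws\n",
              x$spec$model, nrow(x$table), length(x$draws$beta0)))
  cat(sprintf("  DIC = %.1f, pD = %.1f\n", s$dic, s$pd))
  cat(sprintf("  p (inverse-logit of beta0): %.3f (%.3f, %.3f)\n",
              s$p_mean, s$p_ci[1], s$p_ci[2]))
  if (!is.null(x$draws$beta1)) {
    cat(sprintf("  beta1: %.2f (%.2f, %.2f)\n",
                s$beta1_mean, s$beta1_ci[1], s$beta1_ci[2]))
  }
  invisible(x)
}

#' @export
summary.bym_fit <- function(object, ...) {
  d <- dic(object)
  p <- stats::plogis(object$draws$beta0)
  out <- list(model = object$spec$model, dic = d$dic, pd = d$pd,
              p_mean = mean(p),
              p_ci = unname(stats::quantile(p, c(0.025, 0.975))),
              geweke = object$geweke)
  if (!is.null(object$draws$beta1)) {
    out$beta1_mean <- mean(object$draws$beta1)
    out$beta1_ci <- unname(stats::quantile(object$draws$beta1, c(0.025, 0.975)))
  }
  if (!is.null(object$draws$sigma_u)) {
    out$sigma_u_mean <- mean(object$draws$sigma_u)
    out$sigma_u_ci <- unname(stats::quantile(object$draws$sigma_u, c(0.025, 0.975)))
  }
  if (!is.null(object$draws$sigma_v)) {
    out$sigma_v_mean <- mean(object$draws$sigma_v)
    out$sigma_v_ci <- unname(stats::quantile(object$draws$sigma_v, c(0.025, 0.975)))
  }
  out
}

#' Posterior mean linear predictor per suburb
#'
#' Because the linear predictor is linear in its components, its posterior
#' mean is the sum of the component posterior means.
#'
#' @param fit a `bym_fit`.
#' @return numeric vector over suburbs.
#' @export
posterior_mean_eta <- function(fit) {
  eta <- rep(mean(fit$draws$beta0), nrow(fit$table))
  if (!is.null(fit$draws$beta1)) eta <- eta + mean(fit$draws$beta1) * fit$table$ses_std
  if (!is.null(fit$draws$u)) eta <- eta + colMeans(fit$draws$u)
  if (!is.null(fit$draws$v)) eta <- eta + colMeans(fit$draws$v)
  eta
}

#' Deviance Information Criterion
#'
#' `Dbar` is the mean posterior deviance; the plug-in deviance is evaluated
#' at the posterior means of each suburb's linear predictor (the
#' "stochastic parents" convention); `pD = Dbar - D(plug-in)` and
#' `DIC = Dbar + pD`. Deviance excludes the data-only binomial-coefficient
#' constant, which cancels from pD and from all DIC differences.
#'
#' @param fit a `bym_fit` with at least 100 retained draws.
#' @return list `dic`, `pd`, `dbar`, `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(fit$draws$deviance) < 100) {
    stop("fewer than 100 retained draws: DIC estimate would be unstable")
  }
  dbar <- mean(fit$draws$deviance)
  dhat <- -2 * bym_log_likelihood(fit$table, posterior_mean_eta(fit))
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late chain segment:
#' `z = (mean_first - mean_last) / sqrt(s0_first / n_first + s0_last /
#' n_last)` with `s0` the spectral density at frequency zero, estimated
#' from an AR fit (`stats::ar`, AIC order selection) as
#' `var.pred / (1 - sum(ar))^2`.
#'
#' @param chain numeric vector of MCMC draws.
#' @param first_frac,last_frac fractions of the chain used for the early
#'   and late segments (defaults 0.1 and 0.5).
#' @return the z-score.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 20) stop("chain too short for the Geweke diagnostic")
  x1 <- chain[seq_len(floor(first_frac * n))]
  x2 <- chain[seq.int(n - floor(last_frac * n) + 1, n)]
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    if (mean(x1) == mean(x2)) return(0)
    stop("zero-variance chain segment")
  }
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# Spectral density at frequency zero from an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  n <- length(x)
  fit <- stats::ar(x, aic = TRUE, order.max = min(floor(10 * log10(n)), n - 2))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}
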