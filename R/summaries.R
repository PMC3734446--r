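#' Interquartile odds ratio of per-suburb effects
#'
#' `exp(q75 - q25)` of per-suburb effect sizes on the log-odds scale: the
#' ratio of the odds at the 75th versus the 25th centile among suburbs.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), fixed because the IQOR is sensitive to the
#' quantile rule at a few hundred suburbs. By construction IQOR >= 1 and is
#' invariant to adding a constant to all effects.
#'
#' @param effects numeric vector of per-suburb posterior-mean effects on
#'   the log-odds scale (>= 4 suburbs).
#' @return the interquartile odds ratio.
#' @export
iqor <- function(effects) {
  if (length(effects) < 4) stop("IQOR needs at least 4 suburbs")
  q <- stats::quantile(effects, c(0.25, 0.75), names = FALSE, type = 7)
  exp(q[2] - q[1])
}

#' Per-suburb posterior-mean effect components
#'
#' Extracts, per suburb, the posterior means of the spatially-uncorrelated
#' effect `v`, the spatially-correlated effect `u`, their sum `u + v`, and
#' the socioeconomic fixed-effect contribution `mean(beta1) * X_i` (the
#' fixed effect expressed per suburb so it can be summarised on the same
#' footing as the random effects).
#'
#' @param fit a `bym_fit`.
#' @param components character subset of `c("u", "v", "u_plus_v", "ses")`;
#'   requesting a component absent from the fitted model is an error.
#' @return named list of numeric vectors (suburb order of the fit).
#' @export
component_effects <- function(fit, components = c("u", "v", "u_plus_v", "ses")) {
  stopifnot(inherits(fit, "bym_fit"))
  out <- list()
  for (comp in components) {
    out[[comp]] <- switch(
      comp,
      u = {
        if (is.null(fit$draws$u)) stop("model has no spatially-correlated effect")
        colMeans(fit$draws$u)
      },
      v = {
        if (is.null(fit$draws$v)) stop("model has no spatially-uncorrelated effect")
        colMeans(fit$draws$v)
      },
      u_plus_v = {
        if (is.null(fit$draws$u) || is.null(fit$draws$v)) {
          stop("model lacks one of the random-effect components")
        }
        colMeans(fit$draws$u) + colMeans(fit$draws$v)
      },
      ses = {
        if (is.null(fit$draws$beta1)) stop("model has no fixed SES effect")
        mean(fit$draws$beta1) * fit$table$ses_std
      },
      stop("unknown component: ", comp)
    )
  }
  out
}

#' Share of random-effect variance that is spatially structured
#'
#' For each retained sample, the empirical variance across suburbs of the
#' sampled `u` vector and of the sampled `v` vector; the reported fraction
#' is the mean across samples of `var(u) / (var(u) + var(v))`. The
#' empirical reading is the default because the ICAR hyperparameter
#' `sigma_u^2` is a conditional, not marginal, variance; the hyperparameter
#' ratio `sigma_u^2 / (sigma_u^2 + sigma_v^2)` is available via
#' `method = "hyper"`.
#'
#' @param fit a `bym_fit` containing both random effects.
#' @param method `"empirical"` (default) or `"hyper"`.
#' @return the mean fraction in `[0, 1]`.
#' @export
variance_partition <- function(fit, method = c("empirical", "hyper")) {
  method <- match.arg(method)
  if (is.null(fit$draws$u) || is.null(fit$draws$v)) {
    stop("variance partition needs both random effects in the model")
  }
  if (method == "hyper") {
    num <- fit$draws$sigma_u^2
    den <- fit$draws$sigma_u^2 + fit$draws$sigma_v^2
  } else {
    num <- apply(fit$draws$u, 1, stats::var)
    den <- num + apply(fit$draws$v, 1, stats::var)
  }
  if (all(den == 0)) {
    warning("both effect variances identically zero; returning 0")
    return(0)
  }
  zero <- den == 0
  if (any(zero)) den[zero] <- NA
  mean(num / den, na.rm = TRUE)
}

#' Posterior exceedance probabilities for the combined random effect
#'
#' Per suburb, the fraction of retained samples with `u_i + v_i > 0`: the
#' posterior probability that the suburb's odds of poor fetal growth exceed
#' the (model-adjusted) mean. In a model with a fixed SES effect the
#' comparison is automatically SES-adjusted, since `beta1 * X` is not part
#' of the component. Suburbs with probability above `threshold` are
#' flagged.
#'
#' @param fit a `bym_fit` with both random effects.
#' @param threshold flagging threshold (default 0.90).
#' @return data frame `suburb_id`, `prob`, `flagged`.
#' @export
exceedance <- function(fit, threshold = 0.90) {
  if (is.null(fit$draws$u) || is.null(fit$draws$v)) {
    stop("exceedance needs the combined random effect u + v")
  }
  s <- fit$draws$u + fit$draws$v
  prob <- colMeans(s > 0)
  data.frame(suburb_id = fit$ids, prob = as.numeric(prob),
             flagged = as.numeric(prob) > threshold,
             stringsAsFactors = FALSE)
}

#' Between-period stability of effects
#'
#' Suburb-by-suburb Pearson correlations between two periods for each
#' effect supplied (typically the spatially-correlated effect `u`, the
#' uncorrelated effect `v`, and the raw SES index).
#'
#' @param effects_a,effects_b named lists of per-suburb numeric vectors,
#'   each named by suburb id (or aligned by position); the two periods must
#'   cover the same suburbs and the same components.
#' @return named numeric vector of correlations, one per component.
#' @export
period_stability <- function(effects_a, effects_b) {
  comps <- names(effects_a)
  if (!setequal(comps, names(effects_b))) stop("component sets differ between periods")
  vapply(comps, function(cn) {
    a <- effects_a[[cn]]; b <- effects_b[[cn]]
    if (!is.null(names(a)) && !is.null(names(b))) {
      if (!setequal(names(a), names(b))) stop("suburb ids differ for component ", cn)
      b <- b[names(a)]
    } else if (length(a) != length(b)) {
      stop("length mismatch for component ", cn)
    }
    pearson_r(as.numeric(a), as.numeric(b))
  }, numeric(1))
}

#' Effect-size table across fitted models (IQOR layout)
#'
#' Builds the component-by-IQOR summary for the random-effects and full
#' models of one period: spatially-uncorrelated, spatially-correlated and
#' combined random effects, plus the SES fixed effect for the full model.
#'
#' @param fits named list of `bym_fit` objects, with at least `random`
#'   and/or `full`.
#' @return data frame `model`, `effect`, `iqor`.
#' @export
iqor_table <- function(fits) {
  rows <- list()
  add <- function(model, effect, value) {
    rows[[length(rows) + 1]] <<- data.frame(model = model, effect = effect,
                                            iqor = value, stringsAsFactors = FALSE)
  }
  for (m in intersect(c("random", "full"), names(fits))) {
    f <- fits[[m]]
    ce <- component_effects(f, c("u", "v", "u_plus_v"))
    add(m, "spatially_uncorrelated", iqor(ce$v))
    add(m, "spatially_correlated", iqor(ce$u))
    add(m, "combined_random_effects", iqor(ce$u_plus_v))
    if (m == "full") add(m, "ses", iqor(component_effects(f, "ses")$ses))
  }
  do.call(rbind, rows)
}

#' Model-diagnostics table (DIC / pD / p / beta1 layout)
#'
#' @param fits named list of `bym_fit` objects (any subset of the four
#'   models).
#' @return data frame `model`, `dic`, `pd`, `p_mean`, `p_lo`, `p_hi`,
#'   `beta1_mean`, `beta1_lo`, `beta1_hi`.
#' @export
model_table <- function(fits) {
  rows <- lapply(names(fits), function(m) {
    s <- summary(fits[[m]])
    data.frame(model = m, dic = s$dic, pd = s$pd,
               p_mean = s$p_mean, p_lo = s$p_ci[1], p_hi = s$p_ci[2],
               beta1_mean = if (is.null(s$beta1_mean)) NA_real_ else s$beta1_mean,
               beta1_lo = if (is.null(s$beta1_ci)) NA_real_ else s$beta1_ci[1],
               beta1_hi = if (is.null(s$beta1_ci)) NA_real_ else s$beta1_ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
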