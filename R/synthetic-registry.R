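#' Parameters of the synthetic suburb registry
#'
#' Collects the generating values for the binomial-logit convolution model
#' `logit(p_i) = beta0 + beta1 * X_i + u_i + v_i` and for the birth-record
#' generator. Defaults emulate the study conditions the analysis assumes: a
#' mean incidence of poor fetal growth near 5% (`beta0 = qlogis(0.05)`), a
#' socioeconomic log-odds slope of -0.22 per SD of the index, weak residual
#' spatial structure (`sigma_u = sigma_v = 0.1`), about 172 eligible births
#' per suburb per period, and 1.5% missing POBW.
#'
#' @param beta0 log-odds intercept.
#' @param beta1 log-odds slope per SD of the standardized SES index.
#' @param sigma_u conditional SD of the spatially-correlated (ICAR) effect;
#'   must be >= 0.
#' @param sigma_v SD of the spatially-uncorrelated effect; must be >= 0.
#' @param mean_births expected eligible births per suburb (> 0).
#' @param pobw_missing_rate fraction of birth records with null POBW, in
#'   `[0, 1)`.
#' @param missingness_bias strength of the bias making null POBW more likely
#'   for smaller births (0 = missing completely at random).
#' @param seed integer RNG seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(beta0 = stats::qlogis(0.05), beta1 = -0.22,
                              sigma_u = 0.1, sigma_v = 0.1,
                              mean_births = 172, pobw_missing_rate = 0.015,
                              missingness_bias = 0, seed = 1L) {
  if (sigma_u < 0 || sigma_v < 0) stop("sigma_u and sigma_v must be non-negative")
  if (pobw_missing_rate < 0 || pobw_missing_rate >= 1) {
    stop("pobw_missing_rate must be in [0, 1)")
  }
  if (mean_births <= 0) stop("mean_births must be positive")
  structure(list(beta0 = beta0, beta1 = beta1, sigma_u = sigma_u,
                 sigma_v = sigma_v, mean_births = mean_births,
                 pobw_missing_rate = pobw_missing_rate,
                 missingness_bias = missingness_bias, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Spatially autocorrelated SES surface on a lattice
#'
#' Draws a Gaussian field whose precision interpolates between the identity
#' (independent standard normals) and the graph Laplacian of the queen
#' lattice: `Q = (1 - s) I + s (D - W)` at smoothness `s`. Higher `s` gives
#' higher Moran's I in expectation; `s = 0` returns an iid field. The field
#' is rescaled to an index-like raw scale (location 1000, spread ~80) and is
#' standardized downstream by [standardize_ses()].
#'
#' @param geography a `suburb_geography`.
#' @param spatial_smoothness real in `[0, 1)`.
#' @param seed integer seed.
#' @return numeric vector of raw SES values, named by unit id.
#' @export
generate_ses <- function(geography, spatial_smoothness, seed = 1L) {
  stopifnot(inherits(geography, "suburb_geography"))
  if (!is.numeric(spatial_smoothness) || length(spatial_smoothness) != 1 ||
      is.na(spatial_smoothness) || spatial_smoothness < 0 || spatial_smoothness >= 1) {
    stop("spatial_smoothness must lie in [0, 1)")
  }
  adj <- contiguity_adjacency(geography)
  n <- length(adj$ids)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  s <- spatial_smoothness
  if (s > 0) {
    W <- adjacency_matrix(adj)
    Q <- (1 - s) * diag(n) + s * (diag(rowSums(W)) - W)
    L <- chol(Q)                       # Q = L'L, so x = L^{-1} z has precision Q
    x <- backsolve(L, z)
  } else {
    x <- z
  }
  x <- as.numeric(x)
  raw <- 1000 + 80 * (x - mean(x)) / stats::sd(x)
  stats::setNames(raw, adj$ids)
}

#' Dense 0/1 weight matrix of an adjacency
#' @param adj a `suburb_adjacency`.
#' @return symmetric binary matrix with unit ids as dimnames.
#' @export
adjacency_matrix <- function(adj) {
  n <- length(adj$ids)
  W <- matrix(0, n, n, dimnames = list(adj$ids, adj$ids))
  for (i in adj$ids) W[i, adj$nbr[[i]]] <- 1
  W
}

#' Draw from the intrinsic CAR (ICAR) distribution
#'
#' Samples `u` with density proportional to
#' `exp(-sum_(i~j) (u_i - u_j)^2 / (2 sigma_u^2))` subject to a sum-to-zero
#' constraint per connected component, via the spectral decomposition of the
#' graph Laplacian (zero-eigenvalue directions excluded). Island units (no
#' neighbours) get `u = 0`.
#'
#' @param adj a `suburb_adjacency`.
#' @param sigma_u conditional SD scaling the field.
#' @return numeric vector named by unit id, summing to zero within each
#'   connected component.
#' @export
simulate_icar <- function(adj, sigma_u) {
  n <- length(adj$ids)
  u <- stats::setNames(rep(0, n), adj$ids)
  if (sigma_u == 0) return(u)
  comp <- connected_components(adj)
  for (cl in unique(comp)) {
    members <- names(comp)[comp == cl]
    m <- length(members)
    if (m < 2) next
    W <- adjacency_matrix(restrict_adjacency(adj, members))
    Q <- diag(rowSums(W)) - W
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > 1e-9 * max(eg$values)
    z <- stats::rnorm(sum(pos))
    u_c <- eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos]))
    u[members] <- sigma_u * as.numeric(u_c)
    u[members] <- u[members] - mean(u[members])   # numeric guard; already ~0
  }
  u
}

#' Simulate suburb-level case counts from the convolution model
#'
#' Draws the spatially-correlated effect `u` from the ICAR distribution, the
#' uncorrelated effect `v` iid `N(0, sigma_v^2)`, then case counts
#' `R_i ~ Binomial(N_i, plogis(beta0 + beta1 X_i + u_i + v_i))`. Birth
#' totals are taken from a `births` column when present, otherwise drawn
#' `Poisson(mean_births)` (floored at 1). The generating `u`, `v` are
#' returned alongside for recovery experiments.
#'
#' @param suburbs data frame with `suburb_id`, standardized SES `ses_std`
#'   and optionally `births` and `ses_raw`.
#' @param adj a `suburb_adjacency` covering exactly the same units.
#' @param params a [simulation_params()] object (its `seed` seeds the draw).
#' @return data frame `suburb_id`, `births`, `cases`, `ses_raw`, `ses_std`,
#'   `true_u`, `true_v`.
#' @export
simulate_counts <- function(suburbs, adj, params) {
  stopifnot(inherits(params, "simulation_params"))
  ids <- as.character(suburbs$suburb_id)
  if (!setequal(ids, adj$ids)) {
    stop("suburb ids do not align with the adjacency structure")
  }
  if (is.null(suburbs$ses_std)) stop("standardized SES column ses_std is required")
  suburbs <- suburbs[match(adj$ids, ids), , drop = FALSE]
  set.seed(params$seed)
  n <- nrow(suburbs)
  births <- if (!is.null(suburbs$births)) as.integer(suburbs$births) else {
    pmax(1L, stats::rpois(n, params$mean_births))
  }
  u <- simulate_icar(adj, params$sigma_u)
  v <- stats::rnorm(n, 0, params$sigma_v)
  eta <- params$beta0 + params$beta1 * suburbs$ses_std + u + v
  p <- stats::plogis(eta)
  cases <- stats::rbinom(n, births, p)
  data.frame(suburb_id = adj$ids, births = births, cases = cases,
             ses_raw = if (!is.null(suburbs$ses_raw)) suburbs$ses_raw else NA_real_,
             ses_std = suburbs$ses_std,
             true_u = as.numeric(u), true_v = v,
             stringsAsFactors = FALSE)
}

#' Expected birthweight used for synthetic POBW
#'
#' A deliberately simple, documented stand-in for a published
#' optimal-birthweight regression: an exponential gestation curve with
#' multiplicative adjustments for fetal sex, primiparity and maternal
#' height. It exists only so the classification mechanics (POBW =
#' birthweight / expected weight) can be exercised on synthetic records.
#'
#' @param gestation completed weeks.
#' @param sex `"M"` or `"F"`.
#' @param primiparous logical.
#' @param maternal_height cm; `NA` falls back to the population centre
#'   (165 cm).
#' @return expected birthweight in grams.
#' @export
expected_birthweight <- function(gestation, sex, primiparous, maternal_height) {
  h <- ifelse(is.na(maternal_height), 165, maternal_height)
  3450 * exp(0.058 * (gestation - 40)) *
    ifelse(sex == "M", 1.035, 0.965) *
    ifelse(primiparous, 0.955, 1) *
    (1 + 0.0025 * (h - 165))
}

#' Load the packaged synthetic SGA reference table
#'
#' A synthetic sex-by-gestation table of 10th-centile birthweights (weeks
#' 33-43) used by [classify_sga()]. It is not a published national
#' reference; only the classification mechanics matter here.
#'
#' @return data frame `sex`, `gestation`, `p10_weight_g`.
#' @export
sga_reference <- function() {
  path <- system.file("extdata", "sga_centiles_synthetic.csv", package = "bymgrowth")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate birth-level records for a suburb table
#'
#' For every suburb, generates its eligible records (liveborn singletons of
#' 33+ weeks) so their POBW falls below 80% with the suburb's generating
#' probability, plus a small admixture of ineligible records (preterm,
#' multiple births, stillbirths) so eligibility filtering has work to do.
#' POBW is set to null with probability `pobw_missing_rate`; with
#' `missingness_bias > 0` nulls are more likely for smaller births (the
#' mechanism is a missing maternal height, which also nulls that field).
#' An SGA flag is derived from the packaged reference table, and each record
#' inherits its suburb's SES quintile.
#'
#' @param suburbs a suburb table from [simulate_counts()] (columns
#'   `suburb_id`, `births`, `ses_std`, `true_u`, `true_v` are used; the
#'   suburb probability is rebuilt from the generating linear predictor).
#' @param params a [simulation_params()] object.
#' @return data frame of birth records: `suburb_id`, `birthweight_g`,
#'   `gestation`, `sex`, `singleton`, `liveborn`, `primiparous`,
#'   `maternal_height_cm`, `pobw`, `sga`, `ses_quintile`, `eligible`.
#' @export
simulate_birth_records <- function(suburbs, params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed + 1L)
  ref <- sga_reference()
  quint <- ses_quintiles(suburbs$ses_std)
  p_suburb <- if (!is.null(suburbs$true_u)) {
    stats::plogis(params$beta0 + params$beta1 * suburbs$ses_std +
                    suburbs$true_u + suburbs$true_v)
  } else {
    (suburbs$cases + 0.5) / (suburbs$births + 1)
  }
  pobw_sd <- 0.125
  out <- vector("list", nrow(suburbs))
  for (k in seq_len(nrow(suburbs))) {
    n_elig <- suburbs$births[k]
    n_pre <- stats::rpois(1, 0.020 * n_elig)   # <33 weeks
    n_multi <- stats::rpois(1, 0.015 * n_elig) # plurality > 1
    n_still <- stats::rpois(1, 0.007 * n_elig)
    n <- n_elig + n_pre + n_multi + n_still
    gest <- c(sample(33:42, n_elig, replace = TRUE,
                     prob = c(1, 1.5, 2.5, 5, 12, 24, 28, 18, 6, 2)),
              sample(26:32, n_pre, replace = TRUE),
              sample(33:41, n_multi + n_still, replace = TRUE))
    singleton <- c(rep(TRUE, n_elig + n_pre), rep(FALSE, n_multi), rep(TRUE, n_still))
    liveborn <- c(rep(TRUE, n_elig + n_pre + n_multi), rep(FALSE, n_still))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    primi <- stats::runif(n) < 0.4
    height <- stats::rnorm(n, 165, 6.5)
    mu <- 0.8 + stats::qnorm(1 - p_suburb[k]) * pobw_sd
    pobw <- stats::rnorm(n, mu, pobw_sd)
    pobw <- pmax(pobw, 0.35)
    bw <- round(pobw * expected_birthweight(gest, sex, primi, height))
    gest_cap <- pmin(pmax(gest, min(ref$gestation)), max(ref$gestation))
    sga <- bw < ref$p10_weight_g[match(paste(sex, gest_cap), paste(ref$sex, ref$gestation))]
    if (params$pobw_missing_rate > 0) {
      sc <- stats::qlogis(params$pobw_missing_rate) +
        params$missingness_bias * (0.9 - pobw)
      miss <- stats::runif(n) < stats::plogis(sc)
    } else miss <- rep(FALSE, n)
    height[miss] <- NA_real_
    pobw[miss] <- NA_real_
    out[[k]] <- data.frame(
      suburb_id = suburbs$suburb_id[k], birthweight_g = bw, gestation = gest,
      sex = sex, singleton = singleton, liveborn = liveborn,
      primiparous = primi, maternal_height_cm = height,
      pobw = pobw, sga = sga, ses_quintile = quint[k],
      eligible = c(rep(TRUE, n_elig), rep(FALSE, n - n_elig)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Suburb-level SES quintiles
#' @param ses numeric SES values (raw or standardized).
#' @return integer 1-5 quintile per value (1 = most disadvantaged end).
#' @export
ses_quintiles <- function(ses) {
  br <- stats::quantile(ses, probs = seq(0, 1, 0.2), names = FALSE, type = 7)
  br[1] <- -Inf; br[length(br)] <- Inf
  as.integer(cut(ses, breaks = br, labels = FALSE, include.lowest = TRUE))
}

#' Write a suburb table to CSV
#' @param suburbs suburb table data frame.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_suburb_table <- function(suburbs, path) {
  utils::write.csv(suburbs, path, row.names = FALSE)
  invisible(path)
}

#' Read a suburb table from CSV
#' @param path input file.
#' @return data frame.
#' @export
read_suburb_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
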