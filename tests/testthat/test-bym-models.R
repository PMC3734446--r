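test_that("binomial log-likelihood matches closed forms and brute force", {
  tab1 <- data.frame(suburb_id = "A", births = 2L, cases = 1L)
  expect_equal(bym_log_likelihood(tab1, 0), log(0.25))

  set.seed(3)
  tab <- data.frame(suburb_id = letters[1:5],
                    births = sample(50:200, 5), cases = sample(0:30, 5))
  eta <- rnorm(5)
  direct <- sum(dbinom(tab$cases, tab$births, plogis(eta), log = TRUE)) -
    sum(lchoose(tab$births, tab$cases))
  expect_equal(bym_log_likelihood(tab, eta), direct)

  # with R = N/2 the likelihood in beta0 is maximal at 0
  tab2 <- data.frame(suburb_id = "A", births = 100L, cases = 50L)
  lls <- vapply(c(-0.5, -0.1, 0, 0.1, 0.5),
                function(b) bym_log_likelihood(tab2, b), numeric(1))
  expect_identical(which.max(lls), 3L)
})

test_that("ICAR log-prior has the pairwise-difference form", {
  adj <- new_adjacency(c("a", "b"), list(a = "b", b = "a"))
  expect_equal(car_log_prior(c(a = 0, b = 0), adj, 0.5), 0)
  a <- 0.7; s <- 0.4
  expect_equal(car_log_prior(c(a = a, b = -a), adj, s), -2 * a^2 / s^2)

  # full conditional mean of u_i is the mean of its neighbours
  l <- make_lattice(3, 3)
  set.seed(1)
  u <- rnorm(9); names(u) <- l$adj$ids
  i <- "S005"  # centre cell
  opt <- optimize(function(ui) {
    uu <- u; uu[i] <- ui
    -car_log_prior(uu, l$adj, 0.3)
  }, c(-5, 5))
  expect_equal(opt$minimum, mean(u[l$adj$nbr[[i]]]), tolerance = 1e-4)

  # islands must be pinned at zero
  iso <- new_adjacency(c("a", "b", "c"), list(a = "b", b = "a", c = character(0)))
  expect_equal(car_log_prior(c(a = 1, b = -1, c = 0), iso, 1), -2)
  expect_error(car_log_prior(c(a = 1, b = -1, c = 0.5), iso, 1), "island")
})

test_that("null-model posterior tracks the pooled incidence", {
  d <- make_counts(8, 8, births = 300, seed = 17)
  f <- suppressWarnings(fit_bym(bym_model("null"), d$tab, d$adj,
                                mcmc_config(10000, 3000, 5, seed = 2)))
  p <- plogis(f$draws$beta0)
  pooled <- sum(d$tab$cases) / sum(d$tab$births)
  expect_lt(abs(mean(p) - pooled), 2 * sd(p))
})

test_that("MCMC runs are reproducible under a fixed seed", {
  d <- make_counts(5, 5, births = 200, beta1 = -0.2, sigma_u = 0.2,
                   sigma_v = 0.2, seed = 23)
  cfg <- mcmc_config(4000, 1500, 5, seed = 9)
  f1 <- suppressWarnings(fit_bym(bym_model("full"), d$tab, d$adj, cfg))
  f2 <- suppressWarnings(fit_bym(bym_model("full"), d$tab, d$adj, cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("retained ICAR draws respect the sum-to-zero constraint", {
  f <- demo_full_fit()
  expect_lt(max(abs(rowSums(f$draws$u))), 1e-6)
  expect_true(all(f$draws$sigma_u >= 0))
  expect_true(all(f$draws$sigma_v >= 0))
})

test_that("DIC requires enough draws and decomposes as Dbar + pD", {
  f <- demo_full_fit()
  d <- dic(f)
  expect_equal(d$dic, d$dbar + d$pd)
  expect_equal(d$pd, d$dbar - d$dhat)
  short <- f
  short$draws$deviance <- short$draws$deviance[1:50]
  expect_error(dic(short), "100 retained")
})

test_that("posterior SDs concentrate near zero on no-random-effect data", {
  d <- make_counts(12, 12, births = 400, beta0 = qlogis(0.05), seed = 29)
  f <- suppressWarnings(fit_bym(bym_model("full"), d$tab, d$adj,
                                mcmc_config(seed = 3)))
  expect_lt(median(f$draws$sigma_u), 0.15)
  expect_lt(median(f$draws$sigma_v), 0.15)
})

test_that("model specification encodes the four nested models", {
  expect_false(bym_model("null")$include_fixed)
  expect_false(bym_model("null")$include_car)
  m2 <- bym_model("random")
  expect_false(m2$include_fixed); expect_true(m2$include_car); expect_true(m2$include_iid)
  m3 <- bym_model("fixed")
  expect_true(m3$include_fixed); expect_false(m3$include_car)
  m4 <- bym_model("full")
  expect_true(all(c(m4$include_fixed, m4$include_car, m4$include_iid)))
  expect_identical(m4$prior_sd_beta, 100)
  expect_identical(m4$prior_sd_sigma, 100)
  expect_error(mcmc_config(1000, 2000), "burn-in")
  expect_error(mcmc_config(1000, 100, 0), "thinning")
})

test_that("Geweke diagnostic: identical segments, trends, degenerate input", {
  chain <- rep(c(1, 2, 3, 4, 5), 60)
  expect_equal(geweke_z(chain), 0)

  set.seed(4)
  trended <- rnorm(4000, sd = 0.5) + seq(0, 3, length.out = 4000)
  expect_gt(abs(geweke_z(trended)), 3)

  expect_error(geweke_z(c(rep(0, 100), rnorm(900) + 5)), "zero-variance")

  # null calibration at reduced scale (fuller version in the acceptance suite)
  set.seed(6)
  zs <- replicate(50, geweke_z(rnorm(5000)))
  expect_gte(mean(abs(zs) < 3), 0.98)
})

test_that("fits are stable under unit relabeling up to MC error", {
  d <- make_counts(6, 6, births = 400, beta1 = -0.3, sigma_u = 0.2,
                   sigma_v = 0.15, seed = 41)
  set.seed(2)
  perm <- sample(seq_len(nrow(d$tab)))
  tab_p <- d$tab[perm, ]
  adj_p <- new_adjacency(d$adj$ids[perm], d$adj$nbr)  # same graph, new unit order
  cfg <- mcmc_config(20000, 8000, 5, seed = 12)
  f1 <- suppressWarnings(fit_bym(bym_model("full"), d$tab, d$adj, cfg))
  f2 <- suppressWarnings(fit_bym(bym_model("full"), tab_p, adj_p, cfg))
  expect_lt(abs(mean(f1$draws$beta1) - mean(f2$draws$beta1)), 0.06)
  expect_lt(abs(mean(f1$draws$sigma_u) - mean(f2$draws$sigma_u)), 0.06)
  # per-suburb effects align by id, not position
  expect_lt(max(abs(colMeans(f1$draws$u)[f1$ids] - colMeans(f2$draws$u)[f1$ids])), 0.15)
})
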