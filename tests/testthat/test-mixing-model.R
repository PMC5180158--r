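test_that("DTDF correction shifts means and convolves variances", {
  cs <- corrected_source(study$sources$mesopelagic,
                         study$dtdfs$large_shark)
  expect_equal(unname(cs$mean["d15N"]), 8.49)
  expect_equal(unname(cs$mean["d13C"]), -16.7)
  expect_equal(unname(cs$var["d13C"]), 0.7489)
  cs0 <- corrected_source(study$sources$mesopelagic, no_dtdf)
  expect_equal(cs0$mean, study$sources$mesopelagic$mean)
  expect_equal(cs0$var, study$sources$mesopelagic$sd^2)
})

test_that("log likelihood matches a termwise normal-density oracle", {
  set.seed(2)
  cons <- data.frame(d13C = rnorm(7, -17, 1), d15N = rnorm(7, 10, 1.2))
  cfg <- two_source_config(cons)
  p <- c(0.3, 0.7)
  eps <- c(0.6, 1.1)
  # independent oracle: explicit per-consumer, per-isotope normal density
  s1 <- corrected_source(cfg$sources[[1]], cfg$dtdf)
  s2 <- corrected_source(cfg$sources[[2]], cfg$dtdf)
  oracle <- 0
  for (i in seq_len(nrow(cons))) {
    for (j in c("d13C", "d15N")) {
      mu <- p[1] * s1$mean[[j]] + p[2] * s2$mean[[j]]
      v <- p[1]^2 * s1$var[[j]] + p[2]^2 * s2$var[[j]] +
        eps[if (j == "d13C") 1 else 2]^2
      oracle <- oracle + dnorm(cons[[j]][i], mu, sqrt(v), log = TRUE)
    }
  }
  expect_equal(mixing_loglik(p, eps, cfg), oracle)
  expect_error(mixing_loglik(c(0.4, 0.4), eps, cfg), "simplex")
  expect_error(mixing_loglik(c(-0.2, 1.2), eps, cfg), "simplex")
})

test_that("identical corrected sources make the likelihood symmetric in p", {
  cons <- data.frame(d13C = c(-17, -16.5), d15N = c(10, 11))
  twin <- list(source_spec("a", -18, 1, 8, 1), source_spec("b", -18, 1, 8, 1))
  cfg <- mixing_config(twin, no_dtdf, cons, mcmc = quick_mcmc())
  for (q in seq(0, 0.5, by = 0.1)) {
    expect_equal(mixing_loglik(c(q, 1 - q), c(0.5, 0.5), cfg),
                 mixing_loglik(c(1 - q, q), c(0.5, 0.5), cfg))
  }
  # with zero source spread the mixture variance no longer depends on p
  # and the likelihood is exactly flat
  flat <- list(source_spec("a", -18, 0, 8, 0), source_spec("b", -18, 0, 8, 0))
  cfg_flat <- mixing_config(flat, no_dtdf, cons, mcmc = quick_mcmc())
  lls <- vapply(seq(0, 1, by = 0.1),
                function(q) mixing_loglik(c(q, 1 - q), c(0.5, 0.5), cfg_flat),
                0)
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-10)
})

test_that("likelihood peaks at p = (1, 0) for a consumer on source 1", {
  s1 <- corrected_source(sep_sources[[1]], no_dtdf)
  cons <- data.frame(d13C = s1$mean[["d13C"]], d15N = s1$mean[["d15N"]])
  tiny <- list(source_spec("inshore", -20, 1e-3, 6, 1e-3),
               source_spec("offshore", -14, 1e-3, 12, 1e-3))
  cfg <- mixing_config(tiny, no_dtdf, cons, mcmc = quick_mcmc())
  grid <- seq(0, 1, by = 0.01)
  lls <- vapply(grid,
                function(q) mixing_loglik(c(q, 1 - q), c(1e-3, 1e-3), cfg), 0)
  expect_equal(grid[which.max(lls)], 1)
})

test_that("prior-only sampling recovers Dirichlet(1) moments", {
  cons <- data.frame(d13C = -17, d15N = 10)
  for (K in 2:3) {
    src <- c(sep_sources, list(source_spec("mid", -17, 0.5, 9, 0.5)))[1:K]
    cfg <- mixing_config(src, no_dtdf, cons,
                         mcmc = mcmc_control(chains = 2, iter = 8000,
                                             burn = 1000, seed = 5))
    fit <- sample_posterior(cfg, prior_only = TRUE)
    expect_equal(fit$stats$mean, rep(1 / K, K), tolerance = 0.05)
    expect_equal(fit$stats$sd^2, rep((K - 1) / (K^2 * (K + 1)), K),
                 tolerance = 0.15)
  }
})

test_that("posterior draws stay on the simplex with monotone quantiles", {
  cons <- simulate_consumers(consumer_sim_spec(
    c(0.4, 0.6), sep_sources, no_dtdf, n = 30, seed = 8))
  fit <- sample_posterior(two_source_config(cons, seed = 8,
                                            sources = sep_sources,
                                            dtdf = no_dtdf))
  p <- fit$draws$p
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)))
  qs <- as.matrix(fit$stats[, c("q2.5", "q25", "q50", "q75", "q97.5")])
  expect_true(all(apply(qs, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(fit$stats$mean >= 0 & fit$stats$mean <= 1))
})

test_that("symmetric sources around the consumer give p near (1/2, 1/2)", {
  sym <- list(source_spec("below", -18, 0.5, 9, 0.5),
              source_spec("above", -16, 0.5, 11, 0.5))
  cons <- data.frame(d13C = rep(-17, 40) + rep(c(-0.1, 0.1), 20),
                     d15N = rep(10, 40) + rep(c(0.1, -0.1), 20))
  fit <- sample_posterior(mixing_config(sym, no_dtdf, cons,
                                        mcmc = quick_mcmc(3)))
  expect_equal(fit$stats$mean, c(0.5, 0.5), tolerance = 0.05)
})

test_that("near-zero variances concentrate on the exact mass balance", {
  tiny <- list(source_spec("inshore", -20, 1e-4, 6, 1e-4),
               source_spec("offshore", -14, 1e-4, 12, 1e-4))
  p_true <- c(0.35, 0.65)
  mu <- c(p_true[1] * -20 + p_true[2] * -14, p_true[1] * 6 + p_true[2] * 12)
  cons <- data.frame(d13C = mu[1], d15N = mu[2])
  cfg <- mixing_config(tiny, no_dtdf, cons,
                       mcmc = mcmc_control(chains = 2, iter = 6000,
                                           burn = 2000, seed = 11),
                       residual_sd_prior_upper = 0.05)
  exact <- mass_balance_solution(mu, cfg)
  expect_equal(unname(exact), p_true, tolerance = 1e-9)
  fit <- sample_posterior(cfg)
  expect_lt(max(abs(fit$stats$mean - exact)), 0.01)
})

test_that("posterior of p is invariant under a common isotope shift", {
  cons <- simulate_consumers(consumer_sim_spec(
    c(0.3, 0.7), sep_sources, no_dtdf, n = 40, seed = 13))
  fit0 <- sample_posterior(two_source_config(cons, seed = 13,
                                             sources = sep_sources,
                                             dtdf = no_dtdf))
  shift <- 5
  src_s <- lapply(sep_sources, function(s) {
    source_spec(s$name, s$mean[["d13C"]] + shift, s$sd[["d13C"]],
                s$mean[["d15N"]] + shift, s$sd[["d15N"]])
  })
  cons_s <- cons
  cons_s$d13C <- cons_s$d13C + shift
  cons_s$d15N <- cons_s$d15N + shift
  fit_s <- sample_posterior(two_source_config(cons_s, seed = 13,
                                              sources = src_s,
                                              dtdf = no_dtdf))
  expect_equal(fit_s$stats$mean, fit0$stats$mean, tolerance = 0.02)
})

test_that("identical seed and config reproduce the posterior exactly", {
  cons <- simulate_consumers(consumer_sim_spec(
    c(0.5, 0.5), sep_sources, no_dtdf, n = 20, seed = 17))
  cfg <- two_source_config(cons, seed = 17, sources = sep_sources,
                           dtdf = no_dtdf)
  f1 <- sample_posterior(cfg)
  f2 <- sample_posterior(cfg)
  expect_identical(f1$stats, f2$stats)
  expect_identical(f1$draws, f2$draws)
})

test_that("config validation enforces the n+1 source limit and the simplex", {
  cons <- data.frame(d13C = -17, d15N = 10)
  four <- list(source_spec("a", -20, 1, 6, 1), source_spec("b", -14, 1, 12, 1),
               source_spec("c", -18, 1, 8, 1), source_spec("d", -16, 1, 9, 1))
  expect_error(mixing_config(four, no_dtdf, cons), "3 sources")
  expect_error(mixing_config(four[1], no_dtdf, cons), "at least 2")
  expect_error(mixing_config(four[1:2], no_dtdf,
                             data.frame(d13C = numeric(), d15N = numeric())),
               "consumer")
})

test_that("the four-model suite crosses variants with DTDFs as labelled", {
  cons <- simulate_population(n = 30, seed = 19)
  fits <- run_model_suite(
    cons,
    surface_variants = list(normalized = study$sources$surface_ln,
                            bulk = study$sources$surface_bulk),
    mesopelagic = study$sources$mesopelagic,
    dtdfs = list(study$dtdfs$large_shark, study$dtdfs$leopard_shark),
    mcmc = quick_mcmc(19, iter = 2500, burn = 600))
  expect_named(fits, paste("Model", 1:4))
  expect_equal(fits[["Model 1"]]$stats$source[1], "surface zooplankton (LN)")
  expect_equal(fits[["Model 2"]]$stats$source[1], "surface zooplankton")
  # mesopelagic majority in every configuration
  meso <- vapply(fits, function(f) f$stats$mean[2], 0)
  expect_true(all(meso > 0.5))
  # surface contribution maximal under Model 3 (leopard DTDF, normalized)
  surf <- vapply(fits, function(f) f$stats$mean[1], 0)
  expect_equal(unname(which.max(surf)), 3L)
  expect_error(
    run_model_suite(cons, list(bulk = study$sources$surface_bulk),
                    study$sources$mesopelagic,
                    list(study$dtdfs$large_shark,
                         study$dtdfs$leopard_shark)),
    "normalized")
})

test_that("model averaging takes the mean and SD of per-model means", {
  fake <- function(m, label) {
    structure(list(label = label,
                   stats = data.frame(source = c("surface", "meso"),
                                      mean = c(m, 1 - m))),
              class = "mixing_fit")
  }
  fits <- Map(fake, c(0.21, 0.12, 0.43, 0.33), paste("Model", 1:4))
  avg <- average_models(fits)
  expect_equal(avg$mean, c(0.2725, 0.7275))
  expect_equal(avg$sd, c(0.135739, 0.135739), tolerance = 1e-5)
  same <- average_models(fits[c(1, 1, 1)])
  expect_equal(same$mean[1], 0.21)
  expect_equal(same$sd[1], 0)
  expect_error(average_models(list()), "non-empty")
})

test_that("effective-size estimate agrees with coda on iid-like chains", {
  skip_if_not_installed("coda")
  set.seed(23)
  draws <- matrix(rnorm(4000), 2000, 2)
  ours <- ess_multichain(draws)
  theirs <- sum(apply(draws, 2, function(x) {
    coda::effectiveSize(coda::mcmc(x))
  }))
  expect_equal(ours, theirs, tolerance = 0.25)
  expect_lt(abs(split_rhat(draws) - 1), 0.01)
})
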