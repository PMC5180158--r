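#' MCMC control settings for the mixing model
#'
#' Defaults: 4 chains of 10,000 iterations, 1,000 discarded as burn-in,
#' no thinning. Convergence is judged by split-chain potential scale
#' reduction < 1.1 and effective sample size > 400 on every reported
#' parameter.
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (including burn-in).
#' @param burn Burn-in iterations discarded per chain.
#' @param thin Thinning interval for stored draws.
#' @param seed Integer seed; each chain derives its own stream from it.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4L, iter = 10000L, burn = 1000L,
                         thin = 1L, seed = 1L) {
  stopifnot(chains >= 1, iter > burn, burn >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Specify one mass-balance mixing-model run
#'
#' Bundles sources, a DTDF, the consumer samples and sampler settings.
#' With two isotopes the model identifies at most three sources
#' (number of isotopes + 1).
#'
#' @param sources List of [source_spec()] objects (2 or 3 with two
#'   isotopes).
#' @param dtdf A [discrimination_factor()] applied to every source.
#' @param consumers Data frame with numeric columns `d13C` and `d15N`, one
#'   row per consumer sample (see [read_samples()] / [simulate_consumers()]).
#' @param mcmc An [mcmc_control()].
#' @param residual_sd_prior_upper Upper bound (per mil) of the uniform prior
#'   on each isotope's residual SD.
#' @param label Configuration label carried through to summaries.
#' @return An object of class `mixing_config`.
#' @export
mixing_config <- function(sources, dtdf, consumers, mcmc = mcmc_control(),
                          residual_sd_prior_upper = 10,
                          label = "model") {
  if (!is.list(sources) || length(sources) < 2L) {
    stop_input("need at least 2 sources")
  }
  if (!all(vapply(sources, inherits, TRUE, "source_spec"))) {
    stop_input("'sources' must be a list of source_spec objects")
  }
  if (length(sources) > 3L) {
    stop_input("with 2 isotopes at most 3 sources are identifiable ",
               "(number of isotopes + 1)")
  }
  stopifnot(inherits(dtdf, "discrimination_factor"),
            inherits(mcmc, "mcmc_control"))
  consumers <- as.data.frame(consumers)
  if (!all(c("d13C", "d15N") %in% names(consumers))) {
    stop_input("'consumers' needs columns d13C and d15N")
  }
  consumers <- consumers[, c("d13C", "d15N")]
  consumers <- consumers[complete.cases(consumers), , drop = FALSE]
  if (nrow(consumers) < 1L) stop_input("need at least one consumer sample")
  if (!is.finite(residual_sd_prior_upper) || residual_sd_prior_upper <= 0) {
    stop_input("'residual_sd_prior_upper' must be > 0")
  }
  structure(list(sources = sources, dtdf = dtdf, consumers = consumers,
                 mcmc = mcmc,
                 residual_sd_prior_upper = residual_sd_prior_upper,
                 label = label),
            class = "mixing_config")
}

# Corrected source means (K x 2) and variances (K x 2) for a config.
corrected_moments <- function(config) {
  cs <- lapply(config$sources, corrected_source, dtdf = config$dtdf)
  list(mean = do.call(rbind, lapply(cs, `[[`, "mean")),
       var = do.call(rbind, lapply(cs, `[[`, "var")),
       names = vapply(cs, `[[`, "", "name"))
}

#' Mixing-model log likelihood
#'
#' For each isotope j the consumer value is modelled as
#' Normal(sum_k p_k (mu_kj + c_kj), sum_k p_k^2 (omega_kj^2 + tau_kj^2) +
#' eps_j^2): a proportion-weighted mixture mean with source, DTDF and
#' residual variability propagated into the variance. The log likelihood
#' sums the normal log density over consumers and isotopes.
#'
#' @param p Diet-proportion vector on the simplex (non-negative, sums to 1).
#' @param residual_sds Length-2 non-negative vector (per-mil residual SD for
#'   d13C and d15N).
#' @param config A [mixing_config()].
#' @return Log density (scalar).
#' @export
mixing_loglik <- function(p, residual_sds, config) {
  stopifnot(inherits(config, "mixing_config"))
  K <- length(config$sources)
  if (length(p) != K || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
    stop_input("'p' must be a length-", K, " vector on the simplex")
  }
  if (length(residual_sds) != 2L || any(residual_sds < 0)) {
    stop_input("'residual_sds' must be two non-negative values")
  }
  cm <- corrected_moments(config)
  y <- as.matrix(config$consumers)
  mu <- colSums(p * cm$mean)
  v <- colSums(p^2 * cm$var) + residual_sds^2
  ll <- 0
  for (j in 1:2) {
    ll <- ll + sum(dnorm(y[, j], mu[j], sqrt(v[j]), log = TRUE))
  }
  ll
}

# One adaptive Metropolis-within-Gibbs chain on (theta, log eps).
# theta (length K-1) maps to the simplex by softmax with a fixed last
# coordinate; the Dirichlet(1) prior plus the transform Jacobian gives a
# log target contribution of sum(log p). Residual SDs get a uniform(0, U)
# prior, sampled on the log scale with its Jacobian.
run_chain <- function(cm, suff, U, iter, burn, thin, seed,
                      prior_only = FALSE) {
  set.seed(seed)
  K <- nrow(cm$mean)
  np <- (K - 1L) + 2L
  theta <- rnorm(K - 1L, 0, 0.5)
  lambda <- log(runif(2, 0.02 * U, 0.5 * U))

  log_post <- function(theta, lambda) {
    z <- c(theta, 0)
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    lp <- sum(log(p)) + sum(lambda)        # Dirichlet(1)+Jacobian; log-eps Jacobian
    eps2 <- exp(2 * lambda)
    if (any(exp(lambda) >= U)) return(-Inf)
    if (!prior_only) {
      mu <- colSums(p * cm$mean)
      v <- colSums(p^2 * cm$var) + eps2
      lp <- lp + sum(-0.5 * suff$n * log(2 * pi * v) -
                       (suff$ss - 2 * mu * suff$s + suff$n * mu^2) / (2 * v))
    }
    lp
  }

  scales <- rep(0.5, np)
  acc <- rep(0L, np)
  tries <- rep(0L, np)
  cur <- log_post(theta, lambda)
  keep <- floor((iter - burn) / thin)
  out_p <- matrix(NA_real_, keep, K)
  out_eps <- matrix(NA_real_, keep, 2)
  row <- 0L
  for (it in seq_len(iter)) {
    for (d in seq_len(np)) {
      th2 <- theta; la2 <- lambda
      if (d <= K - 1L) th2[d] <- th2[d] + rnorm(1, 0, scales[d])
      else la2[d - (K - 1L)] <- la2[d - (K - 1L)] + rnorm(1, 0, scales[d])
      prop <- log_post(th2, la2)
      tries[d] <- tries[d] + 1L
      if (is.finite(prop) && log(runif(1)) < prop - cur) {
        theta <- th2; lambda <- la2; cur <- prop
        acc[d] <- acc[d] + 1L
      }
    }
    # adapt proposal scales toward ~0.44 acceptance during burn-in only
    if (it <= burn && it %% 50L == 0L) {
      rate <- acc / pmax(tries, 1L)
      scales <- scales * exp(0.6 * (rate - 0.44))
      acc[] <- 0L; tries[] <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      row <- row + 1L
      z <- c(theta, 0); z <- z - max(z)
      out_p[row, ] <- exp(z) / sum(exp(z))
      out_eps[row, ] <- exp(lambda)
    }
  }
  list(p = out_p, eps = out_eps)
}

#' Sample the mixing-model posterior
#'
#' Draws diet proportions and per-isotope residual SDs from the posterior
#' under a symmetric Dirichlet(1) prior on the proportions and independent
#' uniform(0, upper) priors on the residual SDs, using adaptive random-walk
#' Metropolis-within-Gibbs on a softmax reparameterization of the simplex.
#' Runs are deterministic given the seed in `config$mcmc`.
#'
#' @param config A [mixing_config()].
#' @param prior_only If `TRUE` the likelihood is disabled and the sampler
#'   explores the prior alone (used for sampler validation).
#' @return An object of class `mixing_fit`: per-source posterior mean, SD
#'   and 2.5/25/50/75/97.5% quantiles; residual-SD posterior moments;
#'   split-chain potential scale reduction and effective sample sizes per
#'   parameter; pooled draws; the config label. Non-convergence (any
#'   potential scale reduction > 1.1) is flagged in `$diagnostics$converged`
#'   and raised as a warning, never silent.
#' @examples
#' \donttest{
#' inp <- manta_diet_inputs()
#' cons <- simulate_consumers(consumer_sim_spec(
#'   p = c(0.3, 0.7),
#'   sources = list(inp$sources$surface_ln, inp$sources$mesopelagic),
#'   dtdf = inp$dtdfs$large_shark, n = 30, seed = 1))
#' cfg <- mixing_config(list(inp$sources$surface_ln, inp$sources$mesopelagic),
#'                      inp$dtdfs$large_shark, cons,
#'                      mcmc = mcmc_control(chains = 2, iter = 2000,
#'                                          burn = 500, seed = 1))
#' fit <- sample_posterior(cfg)
#' fit
#' }
#' @export
sample_posterior <- function(config, prior_only = FALSE) {
  stopifnot(inherits(config, "mixing_config"))
  cm <- corrected_moments(config)
  y <- as.matrix(config$consumers)
  suff <- list(n = nrow(y), s = colSums(y), ss = colSums(y^2))
  mc <- config$mcmc
  chains <- lapply(seq_len(mc$chains), function(ch) {
    run_chain(cm, suff, config$residual_sd_prior_upper,
              mc$iter, mc$burn, mc$thin,
              seed = (mc$seed %% 1000003L) * 2011L + 7919L * ch,
              prior_only = prior_only)
  })
  K <- length(config$sources)
  par_names <- c(paste0("p[", cm$names, "]"),
                 "resid_sd[d13C]", "resid_sd[d15N]")
  # per parameter: iterations x chains matrix for diagnostics
  per_param <- lapply(seq_len(K + 2L), function(d) {
    if (d <= K) vapply(chains, function(ch) ch$p[, d], chains[[1]]$p[, 1])
    else vapply(chains, function(ch) ch$eps[, d - K], chains[[1]]$p[, 1])
  })
  rhat <- vapply(per_param, split_rhat, 0)
  ess <- vapply(per_param, ess_multichain, 0)
  names(rhat) <- names(ess) <- par_names
  converged <- all(is.finite(rhat)) && all(rhat < 1.1)
  if (!converged) {
    warning("mixing-model chains not converged (max Rhat = ",
            signif(max(rhat), 4), ") for ", config$label, call. = FALSE)
  }
  p_all <- do.call(rbind, lapply(chains, `[[`, "p"))
  colnames(p_all) <- cm$names
  eps_all <- do.call(rbind, lapply(chains, `[[`, "eps"))
  colnames(eps_all) <- c("d13C", "d15N")
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  stats <- data.frame(source = cm$names,
                      mean = colMeans(p_all),
                      sd = apply(p_all, 2, sd),
                      t(apply(p_all, 2, quantile, probs = qs)),
                      row.names = NULL, check.names = FALSE)
  names(stats)[4:8] <- paste0("q", c("2.5", "25", "50", "75", "97.5"))
  resid <- data.frame(isotope = c("d13C", "d15N"),
                      mean = colMeans(eps_all),
                      sd = apply(eps_all, 2, sd), row.names = NULL)
  structure(list(label = config$label, stats = stats, resid = resid,
                 diagnostics = list(rhat = rhat, ess = ess,
                                    converged = converged),
                 draws = list(p = p_all, resid_sd = eps_all),
                 seed = mc$seed),
            class = "mixing_fit")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf("Mixing-model posterior (%s)\n", x$label))
  st <- x$stats
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-28s %.2f +/- %.2f  [%.2f, %.2f]\n", st$source[i],
                st$mean[i], st$sd[i], st$`q2.5`[i], st$`q97.5`[i]))
  }
  cat(sprintf("  residual sd: d13C %.2f, d15N %.2f; max Rhat %.3f%s\n",
              x$resid$mean[1], x$resid$mean[2], max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "" else " (NOT CONVERGED)"))
  invisible(x)
}

#' Run the four-configuration mixing-model suite
#'
#' Crosses the two surface-zooplankton variants with the two DTDF sets,
#' exactly as the manta case study defines its models: Model 1 =
#' lipid-normalized zooplankton + first DTDF; Model 2 = bulk zooplankton +
#' first DTDF; Models 3 and 4 repeat 1 and 2 with the second DTDF.
#'
#' @param consumers Consumer sample data frame (columns `d13C`, `d15N`).
#' @param surface_variants Named list with elements `normalized` and `bulk`,
#'   each a [source_spec()] for surface zooplankton.
#' @param mesopelagic A [source_spec()] for the mesopelagic source, shared
#'   by all four models.
#' @param dtdfs List of two [discrimination_factor()]s; the first is used
#'   for Models 1-2, the second for Models 3-4.
#' @param mcmc An [mcmc_control()]; each model run offsets the seed so the
#'   four runs use distinct streams deterministically.
#' @param residual_sd_prior_upper Passed to [mixing_config()].
#' @return A list of four `mixing_fit` objects named `"Model 1"` ..
#'   `"Model 4"`.
#' @seealso [average_models()]
#' @export
run_model_suite <- function(consumers, surface_variants, mesopelagic, dtdfs,
                            mcmc = mcmc_control(),
                            residual_sd_prior_upper = 10) {
  if (!all(c("normalized", "bulk") %in% names(surface_variants))) {
    stop_input("'surface_variants' must contain elements ",
               "'normalized' and 'bulk'")
  }
  if (length(dtdfs) != 2L ||
      !all(vapply(dtdfs, inherits, TRUE, "discrimination_factor"))) {
    stop_input("'dtdfs' must be a list of two discrimination factors")
  }
  stopifnot(inherits(mesopelagic, "source_spec"))
  grid <- list(`Model 1` = list(surface_variants$normalized, dtdfs[[1]]),
               `Model 2` = list(surface_variants$bulk, dtdfs[[1]]),
               `Model 3` = list(surface_variants$normalized, dtdfs[[2]]),
               `Model 4` = list(surface_variants$bulk, dtdfs[[2]]))
  fits <- vector("list", 4L)
  names(fits) <- names(grid)
  for (i in seq_along(grid)) {
    m <- mcmc_control(mcmc$chains, mcmc$iter, mcmc$burn, mcmc$thin,
                      seed = (mcmc$seed + 101L * i) %% .Machine$integer.max)
    cfg <- mixing_config(list(grid[[i]][[1]], mesopelagic), grid[[i]][[2]],
                         consumers, mcmc = m,
                         residual_sd_prior_upper = residual_sd_prior_upper,
                         label = names(grid)[i])
    fits[[i]] <- sample_posterior(cfg)
  }
  fits
}

#' Average source contributions across mixing-model runs
#'
#' Arithmetic mean and SD, per source position, of the per-model posterior
#' mean contributions — the model-averaged diet estimate reported alongside
#' the individual configurations.
#'
#' @param fits List of `mixing_fit` objects sharing the source structure
#'   (same number of sources in the same roles; labels may differ across
#'   zooplankton variants).
#' @return Data frame with columns `source` (labels from the first fit),
#'   `mean` and `sd` of the per-model posterior means.
#' @export
average_models <- function(fits) {
  if (length(fits) < 1L ||
      !all(vapply(fits, inherits, TRUE, "mixing_fit"))) {
    stop_input("'fits' must be a non-empty list of mixing_fit objects")
  }
  ns <- vapply(fits, function(f) nrow(f$stats), 0L)
  if (length(unique(ns)) != 1L) {
    stop_input("all fits must share the same number of sources")
  }
  means <- vapply(fits, function(f) f$stats$mean, numeric(ns[1]))
  means <- matrix(means, nrow = ns[1])
  data.frame(source = fits[[1]]$stats$source,
             mean = rowMeans(means),
             sd = apply(means, 1, sd), row.names = NULL)
}

#' Exact mass-balance inversion for two sources
#'
#' Least-squares solution of the two-isotope, two-source linear mixing
#' system for a consumer mean; used as the analytic limit the Bayesian
#' posterior must approach as all variances shrink.
#'
#' @param consumer_mean Length-2 vector (d13C, d15N).
#' @param config A [mixing_config()] with exactly two sources.
#' @return Length-2 proportion vector (clamped to the simplex).
#' @export
mass_balance_solution <- function(consumer_mean, config) {
  stopifnot(inherits(config, "mixing_config"),
            length(config$sources) == 2L)
  cm <- corrected_moments(config)
  # c_j = p m1j + (1-p) m2j  ->  (c - m2) = p (m1 - m2); LS over j
  d <- cm$mean[1, ] - cm$mean[2, ]
  p1 <- sum((consumer_mean - cm$mean[2, ]) * d) / sum(d^2)
  p1 <- min(max(p1, 0), 1)
  setNames(c(p1, 1 - p1), cm$names)
}
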