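# Seeded generators for every input the pipeline consumes. All are pure
# functions of (spec, seed): the same arguments give bit-identical output.

# Standardize iid normal draws so the sample mean/SD equal the targets
# exactly. Published group moments are sample moments of the real animals;
# matching them reproduces the study's data configuration rather than a
# random population draw with drifting moments.
match_sample_moments <- function(x, mean_target, sd_target) {
  if (length(x) < 2L || sd(x) == 0) return(x * 0 + mean_target)
  (x - mean(x)) / sd(x) * sd_target + mean_target
}

new_sample_table <- function(sample_id, species, d13C, d15N,
                             c_to_n = NA_real_, sex = NA_character_,
                             year = NA_integer_) {
  data.frame(sample_id = sample_id, species = species, sex = sex,
             year = year, d13C = d13C, d15N = d15N, c_to_n = c_to_n,
             stringsAsFactors = FALSE)
}

#' Specification for forward-simulated consumers
#'
#' Defines the forward model of the mixing likelihood: consumers whose
#' isotope values are drawn around the proportion-weighted mixture of
#' discrimination-corrected sources, with source/DTDF variability and
#' residual error propagated into the variance. Used for parameter-recovery
#' tests of [sample_posterior()].
#'
#' @param p True diet proportions (simplex vector, one entry per source).
#' @param sources List of [source_spec()] objects.
#' @param dtdf A [discrimination_factor()].
#' @param residual_sds Length-2 per-isotope residual SD (per mil).
#' @param n Number of consumers.
#' @param seed Integer seed.
#' @param rho Within-consumer correlation between the two isotopes'
#'   deviations (defaults to 0, matching the mixing model's likelihood).
#' @return An object of class `consumer_sim_spec`.
#' @export
consumer_sim_spec <- function(p, sources, dtdf, residual_sds = c(0.5, 0.5),
                              n = 75L, seed = 20161130L, rho = 0) {
  if (length(p) != length(sources) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop_input("'p' must be a simplex vector, one entry per source")
  }
  stopifnot(all(vapply(sources, inherits, TRUE, "source_spec")),
            inherits(dtdf, "discrimination_factor"),
            length(residual_sds) == 2L, all(residual_sds >= 0),
            n >= 1L, abs(rho) < 1)
  structure(list(p = p, sources = sources, dtdf = dtdf,
                 residual_sds = residual_sds, n = as.integer(n),
                 seed = as.integer(seed), rho = rho),
            class = "consumer_sim_spec")
}

#' Forward-simulate consumers from known diet proportions
#'
#' Per isotope j, each consumer is drawn from
#' Normal(sum_k p_k (mu_kj + c_kj), sum_k p_k^2 (omega_kj^2 + tau_kj^2) +
#' eps_j^2) — exactly the mixing model's likelihood — so posterior
#' recovery of `spec$p` is a well-posed check.
#'
#' @param spec A [consumer_sim_spec()].
#' @param species Species label written to the sample table.
#' @return Sample-table data frame (columns `sample_id`, `species`, `sex`,
#'   `year`, `d13C`, `d15N`, `c_to_n`).
#' @export
simulate_consumers <- function(spec, species = "consumer") {
  stopifnot(inherits(spec, "consumer_sim_spec"))
  cs <- lapply(spec$sources, corrected_source, dtdf = spec$dtdf)
  m <- do.call(rbind, lapply(cs, `[[`, "mean"))
  v <- do.call(rbind, lapply(cs, `[[`, "var"))
  mu <- colSums(spec$p * m)
  sd_j <- sqrt(colSums(spec$p^2 * v) + spec$residual_sds^2)
  set.seed(spec$seed)
  z1 <- rnorm(spec$n)
  z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * rnorm(spec$n)
  new_sample_table(sprintf("sim%03d", seq_len(spec$n)), species,
                   mu[1] + sd_j[1] * z1, mu[2] + sd_j[2] * z2)
}

#' Simulate a consumer population from group moments
#'
#' Independent normal draws of delta13C and delta15N at stated group
#' moments — the route used when only published means and SDs, not
#' per-individual values, are available. Defaults are the giant manta ray
#' muscle moments (n = 75, delta13C -16.8 +/- 1.1, delta15N 10.6 +/- 1.5).
#'
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N Group moments (per mil).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param species Species label.
#' @param c_to_n Optional C:N value(s) recycled across rows.
#' @param match_moments If `TRUE` (default) the draws are standardized so
#'   the sample mean and SD equal the stated moments exactly. Published
#'   group moments are the sample moments of the real individuals, so this
#'   reproduces the study's data configuration; set `FALSE` for plain
#'   population draws whose sample moments fluctuate around the targets.
#' @return Sample-table data frame.
#' @export
simulate_population <- function(mean_d13C = -16.8, sd_d13C = 1.1,
                                mean_d15N = 10.6, sd_d15N = 1.5,
                                n = 75L, seed = 20161130L,
                                species = "Manta birostris",
                                c_to_n = NA_real_,
                                match_moments = TRUE) {
  stopifnot(sd_d13C >= 0, sd_d15N >= 0, n >= 1L)
  set.seed(as.integer(seed))
  c13 <- rnorm(n, mean_d13C, sd_d13C)
  n15 <- rnorm(n, mean_d15N, sd_d15N)
  if (match_moments) {
    c13 <- match_sample_moments(c13, mean_d13C, sd_d13C)
    n15 <- match_sample_moments(n15, mean_d15N, sd_d15N)
  }
  new_sample_table(sprintf("con%03d", seq_len(n)), species, c13, n15,
                   c_to_n = c_to_n)
}

#' Specification for simulated zooplankton tows
#'
#' Defaults are the surface-zooplankton study conditions: 35 net hauls with
#' bulk delta13C -20.5 +/- 0.6, delta15N 7.8 +/- 1.0 and C:N 4.3 +/- 0.5.
#'
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N,mean_cn,sd_cn Tow moments.
#' @param n Number of tows.
#' @param seed Integer seed.
#' @return An object of class `tow_sim_spec`.
#' @export
tow_sim_spec <- function(mean_d13C = -20.5, sd_d13C = 0.6,
                         mean_d15N = 7.8, sd_d15N = 1.0,
                         mean_cn = 4.3, sd_cn = 0.5,
                         n = 35L, seed = 20161130L) {
  stopifnot(sd_d13C >= 0, sd_d15N >= 0, sd_cn >= 0, n >= 1L)
  structure(list(mean_d13C = mean_d13C, sd_d13C = sd_d13C,
                 mean_d15N = mean_d15N, sd_d15N = sd_d15N,
                 mean_cn = mean_cn, sd_cn = sd_cn,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "tow_sim_spec")
}

#' Simulate zooplankton net tows
#'
#' Independent normals per field; C:N is truncated below at 1 to keep
#' ratios physical.
#'
#' @param spec A [tow_sim_spec()].
#' @param match_moments If `TRUE` (default) sample moments of each field
#'   are matched exactly to the stated tow moments (see
#'   [simulate_population()]).
#' @return Sample-table data frame with `species = "zooplankton"`.
#' @export
simulate_tows <- function(spec = tow_sim_spec(), match_moments = TRUE) {
  stopifnot(inherits(spec, "tow_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n
  c13 <- rnorm(n, spec$mean_d13C, spec$sd_d13C)
  n15 <- rnorm(n, spec$mean_d15N, spec$sd_d15N)
  cn <- rnorm(n, spec$mean_cn, spec$sd_cn)
  if (match_moments) {
    c13 <- match_sample_moments(c13, spec$mean_d13C, spec$sd_d13C)
    n15 <- match_sample_moments(n15, spec$mean_d15N, spec$sd_d15N)
    cn <- match_sample_moments(cn, spec$mean_cn, spec$sd_cn)
  }
  new_sample_table(sprintf("tow%03d", seq_len(n)), "zooplankton",
                   c13, n15, c_to_n = pmax(cn, 1))
}

#' Simulate a multi-species isotope community
#'
#' Bivariate normal point clouds per group, for niche-ellipse analyses of
#' co-occurring species.
#'
#' @param groups List of lists, each with `label`, `centroid` (length-2),
#'   `cov` (2x2 positive definite) and `n`.
#' @param seed Integer seed.
#' @return List of [group_observations()].
#' @export
simulate_community <- function(groups, seed = 20161130L) {
  stopifnot(length(groups) >= 1L)
  set.seed(as.integer(seed))
  lapply(groups, function(g) {
    stopifnot(length(g$centroid) == 2L, all(dim(g$cov) == c(2L, 2L)))
    ev <- eigen(g$cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop_input("covariance must be positive definite")
    z <- matrix(rnorm(2 * g$n), g$n, 2) %*% chol(g$cov)
    group_observations(g$label, g$centroid[1] + z[, 1],
                       g$centroid[2] + z[, 2])
  })
}
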