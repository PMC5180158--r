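#' siamix: stable-isotope diet analysis
#'
#' Deterministic delta-notation arithmetic, lipid normalization and
#' trophic-position estimation; a Bayesian mass-balance mixing model with
#' multi-configuration runs and model averaging; Bayesian standard-ellipse
#' isotopic-niche metrics; two-way ANOVA / Tukey HSD group comparisons;
#' and seeded synthetic-data generators.
#'
#' @section Worked system:
#' The package ships the inputs of a giant manta ray (\emph{Manta birostris})
#' case study — surface zooplankton and mesopelagic fishes as prey sources —
#' via [manta_diet_inputs()], and reproduces the whole analysis from those
#' group moments plus synthetic per-sample draws.
#'
#' @importFrom stats aov anova aggregate complete.cases cov dnorm pf ptukey
#'   qnorm quantile rWishart rbeta rgamma rnorm runif sd setNames var
#'   TukeyHSD median qtukey pt df.residual rchisq
#' @importFrom utils read.csv write.csv packageVersion
#' @keywords internal
"_PACKAGE"

stop_input <- function(...) stop(..., call. = FALSE)

#' Parameters for C:N-driven lipid normalization of delta13C
#'
#' Arithmetic lipid correction for bulk delta13C driven by the sample's
#' C:N ratio (a proxy for lipid content). The defaults are the standard
#' zooplankton correction: slope 7.95 per mil, protein reference C:N 3.8,
#' with normalization considered necessary only when the group mean C:N
#' exceeds 3.5.
#'
#' @param slope Correction slope in per mil.
#' @param cn_ref Reference C:N at which the correction vanishes.
#' @param trigger_threshold Group-mean C:N above which normalization is
#'   applied (strictly greater than; a mean of exactly 3.5 does not trigger).
#' @return An object of class `lipid_norm_params`.
#' @seealso [lipid_normalize()], [needs_lipid_normalization()]
#' @export
lipid_norm_params <- function(slope = 7.95, cn_ref = 3.8,
                              trigger_threshold = 3.5) {
  if (!is.finite(slope)) stop_input("'slope' must be finite")
  if (!is.finite(cn_ref) || cn_ref <= 0) stop_input("'cn_ref' must be > 0")
  if (!is.finite(trigger_threshold) || trigger_threshold <= 0) {
    stop_input("'trigger_threshold' must be > 0")
  }
  structure(list(slope = slope, cn_ref = cn_ref,
                 trigger_threshold = trigger_threshold),
            class = "lipid_norm_params")
}

#' Parameters for trophic-position estimation from delta15N
#'
#' @param d15N_primary Baseline delta15N (per mil) of the primary/low-trophic
#'   reference pool.
#' @param dtdf_n Diet-tissue discrimination factor for delta15N (per mil per
#'   trophic step); must be positive.
#' @param base_level Trophic level assigned to the baseline pool; half-levels
#'   are allowed when the baseline mixes primary and secondary consumers.
#' @return An object of class `trophic_position_params`.
#' @seealso [trophic_position()]
#' @export
trophic_position_params <- function(d15N_primary = 7, dtdf_n = 3.7,
                                    base_level = 2.5) {
  if (!is.finite(d15N_primary)) stop_input("'d15N_primary' must be finite")
  if (!is.finite(dtdf_n) || dtdf_n <= 0) stop_input("'dtdf_n' must be > 0")
  if (!is.finite(base_level)) stop_input("'base_level' must be finite")
  structure(list(d15N_primary = d15N_primary, dtdf_n = dtdf_n,
                 base_level = base_level),
            class = "trophic_position_params")
}

#' Delta notation from raw isotope ratios
#'
#' Converts a sample's heavy-to-light isotope ratio to delta notation in
#' per mil relative to a reference standard:
#' `(r_sample / r_standard - 1) * 1000`.
#'
#' @param r_sample Heavy-to-light isotope ratio of the sample; strictly
#'   positive. Vectorized.
#' @param r_standard Heavy-to-light ratio of the international standard.
#' @return Delta value(s) in per mil.
#' @examples
#' delta_value(0.0109000, 0.0112372)  # approx -30 per mil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (!all(is.finite(r_sample)) || !all(is.finite(r_standard))) {
    stop_input("isotope ratios must be finite")
  }
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    stop_input("isotope ratios must be strictly positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Lipid-normalize bulk delta13C values
#'
#' Applies the arithmetic C:N correction
#' `d13C_LN = d13C_bulk + slope * (c_to_n - cn_ref) / c_to_n`
#' sample by sample. Because the correction is a nonlinear function of C:N,
#' normalize per sample and then average; applying the correction once to a
#' group-mean C:N gives a different (biased) group value.
#'
#' @param d13C_bulk Bulk delta13C value(s), per mil.
#' @param c_to_n C:N ratio(s), strictly positive; recycled against
#'   `d13C_bulk`.
#' @param params A [lipid_norm_params()] object.
#' @return Lipid-normalized delta13C value(s), per mil.
#' @examples
#' lipid_normalize(-20.5, 4.3)  # -19.58
#' @export
lipid_normalize <- function(d13C_bulk, c_to_n, params = lipid_norm_params()) {
  stopifnot(inherits(params, "lipid_norm_params"))
  if (!all(is.finite(d13C_bulk))) stop_input("'d13C_bulk' must be finite")
  if (!all(is.finite(c_to_n)) || any(c_to_n <= 0)) {
    stop_input("'c_to_n' must be strictly positive")
  }
  d13C_bulk + params$slope * (c_to_n - params$cn_ref) / c_to_n
}

#' Should a group's delta13C values be lipid-normalized?
#'
#' Lipid stores are depleted in 13C, so lipid-rich tissue (high C:N) biases
#' bulk delta13C low. The conventional rule normalizes only lipid-rich
#' groups: this returns `TRUE` iff the mean C:N strictly exceeds the trigger
#' threshold (default 3.5). Muscle tissue at mean C:N 3.3 is left as is;
#' zooplankton at mean C:N 4.3 is normalized.
#'
#' @param c_to_n_values Non-empty numeric vector of per-sample C:N ratios
#'   (`NA`s dropped).
#' @param params A [lipid_norm_params()] object.
#' @return Logical scalar.
#' @export
needs_lipid_normalization <- function(c_to_n_values,
                                      params = lipid_norm_params()) {
  stopifnot(inherits(params, "lipid_norm_params"))
  c_to_n_values <- c_to_n_values[!is.na(c_to_n_values)]
  if (length(c_to_n_values) == 0L) {
    stop_input("'c_to_n_values' must contain at least one non-missing value")
  }
  if (any(c_to_n_values <= 0)) stop_input("C:N ratios must be positive")
  mean(c_to_n_values) > params$trigger_threshold
}

#' Trophic position from delta15N
#'
#' Relative trophic level inferred from enrichment of delta15N above a
#' baseline pool, scaled by the nitrogen diet-tissue discrimination factor:
#' `TL = (d15N_consumer - d15N_primary) / dtdf_n + base_level`.
#'
#' @param d15N_consumer Consumer delta15N value(s), per mil. Vectorized.
#' @param params A [trophic_position_params()] object.
#' @return Estimated trophic level(s).
#' @examples
#' trophic_position(10.6, trophic_position_params(7, 3.7, 2.5))
#' @export
trophic_position <- function(d15N_consumer,
                             params = trophic_position_params()) {
  stopifnot(inherits(params, "trophic_position_params"))
  if (!all(is.finite(d15N_consumer))) {
    stop_input("'d15N_consumer' must be finite")
  }
  (d15N_consumer - params$d15N_primary) / params$dtdf_n + params$base_level
}

#' Isotopic enrichment between a consumer and a source
#'
#' Plain difference `consumer_mean - source_mean` in per mil; the consumer's
#' enrichment relative to the putative diet.
#'
#' @param consumer_mean,source_mean Finite per-mil values (vectorized).
#' @return Per-mil difference(s).
#' @export
enrichment <- function(consumer_mean, source_mean) {
  if (!all(is.finite(consumer_mean)) || !all(is.finite(source_mean))) {
    stop_input("enrichment requires finite inputs")
  }
  consumer_mean - source_mean
}
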