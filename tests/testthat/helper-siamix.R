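# Shared fixtures: small MCMC settings for fast tests, and the case-study
# inputs used across modules.

quick_mcmc <- function(seed = 1L, chains = 2L, iter = 3000L, burn = 800L) {
  mcmc_control(chains = chains, iter = iter, burn = burn, seed = seed)
}

study <- manta_diet_inputs()

two_source_config <- function(consumers, seed = 1L, ...,
                              sources = list(study$sources$surface_ln,
                                             study$sources$mesopelagic),
                              dtdf = study$dtdfs$large_shark) {
  mixing_config(sources, dtdf, consumers, mcmc = quick_mcmc(seed), ...)
}

# Well-separated synthetic sources: identifiable on both isotopes.
sep_sources <- list(source_spec("inshore", -20, 0.5, 6, 0.5),
                    source_spec("offshore", -14, 0.5, 12, 0.5))
no_dtdf <- discrimination_factor(0, 0, 0, 0, label = "none")
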