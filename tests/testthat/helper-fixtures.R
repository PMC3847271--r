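# Shared builders for small, hand-checkable model inputs.

# Minimal valid profile: one or two causes per band, constant births.
tiny_profile <- function(births = 1e5, nmr = 30, child = 40, sbr = 20,
                         mmr = 500, years = 2013:2015) {
  country_profile(
    base_year = min(years),
    neonatal_mortality = nmr, child_1_59m_mortality = child,
    stillbirth_rate = sbr, maternal_mortality_ratio = mmr,
    cause_structures = list(
      STILLBIRTH = c(antepartum = 0.6, intrapartum = 0.4),
      MATERNAL = c(hemorrhage = 1),
      NEONATAL_0_1M = c(sepsis = 0.5, asphyxia = 0.5),
      M1_5 = c(diarrhea = 0.5, pneumonia = 0.5),
      M6_11 = c(diarrhea = 0.5, pneumonia = 0.5),
      M12_23 = c(diarrhea = 0.5, pneumonia = 0.5),
      M24_59 = c(diarrhea = 0.5, pneumonia = 0.5)),
    base_coverages = numeric(),
    live_births = stats::setNames(rep(births, length(years)),
                                  as.character(years)))
}

flat_traj <- function(cov, years) {
  stats::setNames(rep(cov, length(years)), as.character(years))
}

# One preventive intervention on a single (cause, band).
one_intervention <- function(id = "iv1", cause = "diarrhea", band = "M1_5",
                             efficacy = 0.5, category = "PREVENTIVE",
                             stage = 3) {
  intervention(id, category = category, stage_order = stage,
               effects = data.frame(cause = cause, band = band,
                                    efficacy = efficacy))
}

# Random impact terms in (0, 1]; seeded by caller.
random_impacts <- function(n) stats::runif(n, 0, 1)

# Independent oracle: apply impacts one at a time to the running residual,
# the way the narrative rule states it, instead of the closed-form product.
sequential_residual <- function(base, impacts) {
  d <- base
  for (v in impacts) d <- d - d * v
  max(0, d)
}
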