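#' Base-year-structured deaths by band and cause for one projection year
#'
#' Converts the profile's rates into death counts for a given year's birth
#' cohort, then splits each band total by the band's base-year cause
#' structure. The cause structure is frozen at the base year for every
#' projection year: only coverage changes move deaths.
#'
#' Denominators: neonatal deaths are `live_births * NMR / 1000`; the 1-59
#' month total `live_births * rate / 1000` is split across the four
#' sub-bands by the profile's `sub_band_weights`; stillbirths use total
#' births back-derived from live births,
#' `total = live / (1 - SBR/1000)`, times `SBR / 1000`; maternal deaths are
#' `live_births * MMR / 100000`.
#'
#' @param profile A [country_profile()].
#' @param year Projection year; must have a `live_births` entry.
#' @return Named list, band -> named numeric vector of cause -> deaths.
#' @examples
#' # 100,000 births at NMR 30 -> 3,000 neonatal deaths, split by cause
#' @export
base_band_deaths <- function(profile, year) {
  lb <- live_births_for(profile, year)
  totals <- band_totals_for(profile, lb)
  cs <- profile$cause_structures
  out <- lapply(stats::setNames(nm = all_bands()), function(b) {
    p <- cs[[b]]
    if (is.null(p))
      stop("profile has no cause structure for band ", b)
    totals[[b]] * p
  })
  out
}

live_births_for <- function(profile, year) {
  key <- as.character(year)
  if (!key %in% names(profile$live_births))
    stop("no live_births entry for year ", year)
  profile$live_births[[key]]
}

# Band death totals implied by the profile's rates for a live-birth cohort.
band_totals_for <- function(profile, live_births) {
  total_births <- live_births / (1 - profile$stillbirth_rate / 1000)
  child_total <- live_births * profile$child_1_59m_mortality / 1000
  c(list(
    STILLBIRTH = total_births * profile$stillbirth_rate / 1000,
    MATERNAL = live_births * profile$maternal_mortality_ratio / 1e5,
    NEONATAL_0_1M = live_births * profile$neonatal_mortality / 1000
  ), as.list(child_total * profile$sub_band_weights[sub_bands()]))
}

# Baseline (no coverage change) entrants per band for a live-birth cohort:
# the cascade resolved at base-year rates. These are the reference cohort
# sizes against which scenario entrants scale deaths.
baseline_entrants_for <- function(profile, live_births) {
  totals <- band_totals_for(profile, live_births)
  ent <- list(
    STILLBIRTH = live_births / (1 - profile$stillbirth_rate / 1000),
    MATERNAL = live_births,
    NEONATAL_0_1M = live_births
  )
  prev <- live_births
  for (b in child_bands()) {
    ent[[b]] <- prev
    prev <- prev - totals[[b]]
  }
  ent
}

#' Project one band's ledger under scenario coverages
#'
#' Scales the band's base-year-structured deaths to the actual entrant
#' cohort (deaths are proportional to entrants relative to the baseline
#' cohort size), then applies the residual-deaths rule per cause with the
#' impacts collected from the catalog. Survivors are entrants minus total
#' deaths.
#'
#' @param base_deaths_by_cause Named numeric, cause -> base-year-structured
#'   deaths for the baseline cohort (one element of [base_band_deaths()]).
#' @param entrants Cohort entering this band under the scenario.
#' @param base_entrants Baseline cohort size the base deaths refer to.
#' @param catalog List of [intervention()] objects.
#' @param base_coverages,scenario_coverages Named coverage maps (see
#'   [collect_impacts()]).
#' @param band Outcome-band token.
#' @return List with `band`, `entrants`, `deaths_by_cause` (named numeric),
#'   `survivors`.
#' @export
project_band <- function(base_deaths_by_cause, entrants, base_entrants,
                         catalog, base_coverages, scenario_coverages, band) {
  stopifnot(entrants >= 0)
  scale <- if (base_entrants > 0) entrants / base_entrants else 0
  deaths <- vapply(names(base_deaths_by_cause), function(cause) {
    imp <- collect_impacts(catalog, base_coverages, scenario_coverages,
                           cause, band)
    residual_deaths(base_deaths_by_cause[[cause]] * scale, imp)
  }, numeric(1))
  list(band = band, entrants = entrants, deaths_by_cause = deaths,
       survivors = entrants - sum(deaths))
}

#' Project a full multi-year scenario
#'
#' For each year from the profile's base year to `end_year`, resolves the
#' complete age-band cascade under that year's scenario coverages (the
#' period approximation: all bands experience year-t coverage and survivors
#' feed the next band within the same projection year, rather than tracking
#' lagged birth cohorts). The stillbirth band runs on total births; neonatal
#' entrants are the year's live births; each subsequent child band's
#' entrants are the previous band's survivors; the maternal band runs in
#' parallel on live births with no cascade descendant (maternal deaths do
#' not feed back into births).
#'
#' Because impacts multiply deaths while the cause structure and rates stay
#' frozen, a band's implied mortality probability (deaths / entrants) is
#' unaffected by upstream interventions -- but its absolute deaths rise when
#' upstream survival improves, since more children reach it.
#'
#' @param profile A [country_profile()].
#' @param catalog List of [intervention()] objects.
#' @param scenario A [coverage_scenario()]. Every intervention in the
#'   scenario must have a trajectory value for every projection year; use
#'   [expand_trajectory()] (plus constant extension) to build them.
#' @param end_year Last projection year (>= base year).
#' @return An object of class `projection_result`: list with
#'   `scenario_name`, `ledger` (tidy data.frame year x band x cause with
#'   entrants, deaths, survivors) and `band_totals` (data.frame year x band
#'   with entrants, deaths, survivors).
#' @seealso [lives_saved()], [baseline_scenario()], [as.data.frame.projection_result()]
#' @export
project_scenario <- function(profile, catalog, scenario, end_year) {
  if (end_year < profile$base_year)
    stop("end_year precedes base_year")
  # trajectory years beyond end_year are allowed and ignored, so a long
  # scenario can be projected over a shorter window
  probs <- validate_scenario(scenario, catalog, profile, end_year = NULL)
  if (length(probs))
    stop("invalid scenario '", scenario$name, "':\n  ",
         paste(probs, collapse = "\n  "))

  years <- seq.int(profile$base_year, end_year)
  rows <- vector("list", length(years) * length(all_bands()))
  k <- 0L
  for (yr in years) {
    lb <- live_births_for(profile, yr)
    base_d <- base_band_deaths(profile, yr)
    base_ent <- baseline_entrants_for(profile, lb)
    scen_cov <- scenario_coverages_at(scenario, yr)

    run <- function(band, entrants) {
      project_band(base_d[[band]], entrants, base_ent[[band]], catalog,
                   profile$base_coverages, scen_cov, band)
    }
    led <- list(run("STILLBIRTH", base_ent$STILLBIRTH),
                run("MATERNAL", lb))
    prev <- lb  # neonatal entrants are the live births
    for (b in child_bands()) {
      bl <- run(b, prev)
      led <- c(led, list(bl))
      prev <- bl$survivors
    }
    for (bl in led) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        year = yr, band = bl$band, cause = names(bl$deaths_by_cause),
        entrants = bl$entrants, deaths = unname(bl$deaths_by_cause),
        survivors = bl$survivors, stringsAsFactors = FALSE)
    }
  }
  ledger <- do.call(rbind, rows[seq_len(k)])
  rownames(ledger) <- NULL
  band_totals <- stats::aggregate(deaths ~ year + band, ledger, sum)
  per_band <- ledger[!duplicated(ledger[, c("year", "band")]),
                     c("year", "band", "entrants", "survivors")]
  band_totals <- merge(per_band, band_totals, by = c("year", "band"))
  band_totals <- band_totals[order(band_totals$year,
                                   match(band_totals$band, all_bands())),
                             c("year", "band", "entrants", "deaths",
                               "survivors")]
  rownames(band_totals) <- NULL
  structure(list(scenario_name = scenario$name, ledger = ledger,
                 band_totals = band_totals),
            class = "projection_result")
}

# Year-t coverages implied by a scenario: trajectory value for interventions
# in the scenario (required for every projection year), baseline otherwise.
scenario_coverages_at <- function(scenario, year) {
  key <- as.character(year)
  out <- vapply(names(scenario$trajectories), function(id) {
    tr <- scenario$trajectories[[id]]
    if (!key %in% names(tr))
      stop("scenario '", scenario$name, "': trajectory for '", id,
           "' has no value for year ", year)
    tr[[key]]
  }, numeric(1))
  stats::setNames(out, names(scenario$trajectories))
}

#' The constant-coverage counterfactual scenario
#'
#' @param profile A [country_profile()].
#' @param name Scenario name (default "baseline").
#' @return A [coverage_scenario()] with no trajectories: every intervention
#'   stays at baseline coverage, so projecting it reproduces base-year death
#'   rates in every year.
#' @export
baseline_scenario <- function(profile, name = "baseline") {
  coverage_scenario(name, list())
}

#' @export
print.projection_result <- function(x, ...) {
  yrs <- unique(x$ledger$year)
  cat("projection_result '", x$scenario_name, "': years ", min(yrs), "-",
      max(yrs), ", ", length(unique(x$ledger$band)), " bands, ",
      nrow(x$ledger), " ledger rows\n", sep = "")
  tot <- stats::aggregate(deaths ~ year, x$band_totals, sum)
  cat("  total deaths by year: ",
      paste(sprintf("%d: %.0f", tot$year, tot$deaths), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy export of a projection result
#'
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return data.frame with columns scenario, year, band, cause, entrants,
#'   deaths, survivors (entrants/survivors are band-level, repeated per
#'   cause row).
#' @export
as.data.frame.projection_result <- function(x, ...) {
  cbind(scenario = x$scenario_name, x$ledger, stringsAsFactors = FALSE)
}

#' Lives saved by a scenario relative to a counterfactual
#'
#' Cell-wise difference in deaths, baseline minus scenario, per (year, band,
#' cause). Downstream entries can legitimately be negative: when an upstream
#' intervention saves lives, more children survive into later bands and die
#' there at unchanged rates (the cascade effect). The net across all bands
#' stays positive when only beneficial interventions scale up.
#'
#' @param baseline,scenario `projection_result` objects from
#'   [project_scenario()] over the same profile, years, bands and causes.
#' @return data.frame with columns year, band, cause, lives_saved.
#' @export
lives_saved <- function(baseline, scenario) {
  b <- baseline$ledger
  s <- scenario$ledger
  if (!identical(sort(unique(b$year)), sort(unique(s$year))))
    stop("projection year ranges differ between baseline and scenario")
  m <- merge(b[, c("year", "band", "cause", "deaths")],
             s[, c("year", "band", "cause", "deaths")],
             by = c("year", "band", "cause"), suffixes = c("_base", "_scen"))
  if (nrow(m) != nrow(b))
    stop("baseline and scenario ledgers do not share bands/causes")
  m$lives_saved <- m$deaths_base - m$deaths_scen
  m <- m[order(m$year, match(m$band, all_bands()), m$cause),
         c("year", "band", "cause", "lives_saved")]
  rownames(m) <- NULL
  m
}
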