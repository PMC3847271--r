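#' Construct a country (or region) base-year health profile
#'
#' A profile pins down the base-year epidemiology that every projection is
#' anchored to: overall mortality rates per outcome band, the proportional
#' cause-of-death structure within each band (frozen at the base year), the
#' baseline intervention coverages, and the annual live-birth counts that
#' drive cohort sizes. All coverages and proportions are decimal fractions in
#' [0, 1], never percentage points.
#'
#' @param base_year Calendar base year of the profile.
#' @param neonatal_mortality Neonatal mortality rate, deaths per 1,000 live
#'   births.
#' @param child_1_59m_mortality Mortality over the whole 1-59 month window,
#'   deaths per 1,000 live births.
#' @param stillbirth_rate Stillbirths per 1,000 total births.
#' @param maternal_mortality_ratio Maternal deaths per 100,000 live births.
#' @param cause_structures Named list, one entry per outcome band, each a
#'   named numeric vector of cause -> fraction of that band's deaths
#'   (fractions sum to 1 within each band).
#' @param base_coverages Named numeric vector, intervention id -> baseline
#'   coverage fraction.
#' @param live_births Named numeric vector, year -> live-birth count.
#' @param sub_band_weights Named numeric vector splitting 1-59 month deaths
#'   across the four sub-bands `M1_5`, `M6_11`, `M12_23`, `M24_59`; must sum
#'   to 1. The default split is illustrative (front-loaded toward younger
#'   ages) and should be overridden with country-specific values when known.
#' @return An object of class `country_profile`.
#' @seealso [validate_profile()], [base_band_deaths()], [read_profile()]
#' @examples
#' pr <- country_profile(
#'   base_year = 2013, neonatal_mortality = 30, child_1_59m_mortality = 40,
#'   stillbirth_rate = 20, maternal_mortality_ratio = 500,
#'   cause_structures = list(
#'     STILLBIRTH    = c(antepartum = 0.6, intrapartum = 0.4),
#'     MATERNAL      = c(hemorrhage = 0.6, sepsis = 0.4),
#'     NEONATAL_0_1M = c(sepsis = 0.5, asphyxia = 0.5),
#'     M1_5   = c(diarrhea = 0.5, pneumonia = 0.5),
#'     M6_11  = c(diarrhea = 0.5, pneumonia = 0.5),
#'     M12_23 = c(diarrhea = 0.5, pneumonia = 0.5),
#'     M24_59 = c(diarrhea = 0.5, pneumonia = 0.5)),
#'   base_coverages = c(orsol = 0.3),
#'   live_births = c("2013" = 5e5, "2014" = 5e5))
#' pr
#' @export
country_profile <- function(base_year,
                            neonatal_mortality,
                            child_1_59m_mortality,
                            stillbirth_rate,
                            maternal_mortality_ratio,
                            cause_structures,
                            base_coverages = numeric(),
                            live_births,
                            sub_band_weights = default_sub_band_weights()) {
  structure(list(
    base_year = as.integer(base_year),
    neonatal_mortality = as.numeric(neonatal_mortality),
    child_1_59m_mortality = as.numeric(child_1_59m_mortality),
    stillbirth_rate = as.numeric(stillbirth_rate),
    maternal_mortality_ratio = as.numeric(maternal_mortality_ratio),
    sub_band_weights = unlist(sub_band_weights),
    cause_structures = lapply(cause_structures, unlist),
    base_coverages = unlist(base_coverages),
    live_births = stats::setNames(as.numeric(unlist(live_births)),
                                  names(unlist(live_births)))
  ), class = "country_profile")
}

#' Default split of 1-59 month mortality across sub-bands
#'
#' The 1-59 month mortality rate is a single input but deaths are modeled in
#' four sub-bands with higher risk at younger ages. This default split
#' (`M1_5` 0.45, `M6_11` 0.25, `M12_23` 0.18, `M24_59` 0.12) is an
#' illustrative fixture, not an empirical estimate; supply country-specific
#' weights in the profile whenever available.
#'
#' @return Named numeric vector over the four sub-bands, summing to 1.
#' @export
default_sub_band_weights <- function() {
  c(M1_5 = 0.45, M6_11 = 0.25, M12_23 = 0.18, M24_59 = 0.12)
}

#' @export
print.country_profile <- function(x, ...) {
  yrs <- names(x$live_births)
  cat("country_profile (base year ", x$base_year, ")\n", sep = "")
  cat("  NMR ", x$neonatal_mortality, "/1000, 1-59m ",
      x$child_1_59m_mortality, "/1000, SBR ", x$stillbirth_rate,
      "/1000, MMR ", x$maternal_mortality_ratio, "/100k\n", sep = "")
  cat("  live births: ", length(yrs), " year(s) ",
      if (length(yrs)) paste0("[", min(yrs), "-", max(yrs), "]") else "",
      "\n", sep = "")
  cat("  causes per band: ",
      paste(vapply(x$cause_structures, length, 1L), collapse = "/"),
      "; base coverages for ", length(x$base_coverages),
      " intervention(s)\n", sep = "")
  invisible(x)
}

#' Define an intervention and its cause-specific efficacies
#'
#' An intervention is either `PREVENTIVE` or `CURATIVE`, holds a
#' delivery-stage position (periconception = 0, pregnancy = 1, delivery = 2,
#' then the child age bands in cascade order) used to order attribution
#' blocks, and carries one efficacy entry per (cause, band) it acts on.
#' Efficacy is the proportional reduction in that cause's deaths achieved by
#' a 100-percentage-point coverage change.
#'
#' @param id Token identifying the intervention (used in coverage maps).
#' @param name Free-text label; defaults to `id`.
#' @param category `"PREVENTIVE"` or `"CURATIVE"`.
#' @param stage_order Non-negative integer delivery-stage position.
#' @param effects data.frame with columns `cause`, `band`, `efficacy`
#'   (fractions in [0, 1]); no duplicate (cause, band) pairs.
#' @return An object of class `intervention`.
#' @examples
#' intervention("ors", "oral rehydration solution", "CURATIVE", 3,
#'              effects = data.frame(cause = "diarrhea", band = "M1_5",
#'                                   efficacy = 0.69))
#' @export
intervention <- function(id, name = id, category, stage_order, effects) {
  category <- match.arg(category, c("PREVENTIVE", "CURATIVE"))
  stage_order <- as.integer(stage_order)
  if (is.na(stage_order) || stage_order < 0)
    stop("intervention '", id, "': stage_order must be a non-negative integer")
  effects <- as.data.frame(effects, stringsAsFactors = FALSE)
  need <- c("cause", "band", "efficacy")
  if (!all(need %in% names(effects)))
    stop("intervention '", id, "': effects needs columns cause, band, efficacy")
  effects <- effects[, need]
  if (anyDuplicated(effects[, c("cause", "band")]))
    stop("intervention '", id, "': duplicate (cause, band) efficacy entries")
  bad <- !is_band(effects$band)
  if (any(bad))
    stop("intervention '", id, "': unknown band(s) ",
         paste(unique(effects$band[bad]), collapse = ", "))
  if (any(effects$efficacy < 0 | effects$efficacy > 1))
    stop("intervention '", id, "': efficacy must be in [0, 1]")
  structure(list(id = as.character(id), name = as.character(name),
                 category = category, stage_order = stage_order,
                 effects = effects),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat("intervention ", x$id, " (", x$category, ", stage ", x$stage_order,
      "): ", nrow(x$effects), " efficacy entr",
      if (nrow(x$effects) == 1) "y" else "ies", "\n", sep = "")
  invisible(x)
}

catalog_ids <- function(catalog) vapply(catalog, `[[`, "", "id")

catalog_get <- function(catalog, id) {
  i <- match(id, catalog_ids(catalog))
  if (is.na(i)) stop("unknown intervention id '", id, "'")
  catalog[[i]]
}

#' Construct a coverage scale-up scenario
#'
#' A scenario names, per intervention, a coverage trajectory: a map from
#' projection year to coverage fraction. Interventions absent from the
#' scenario stay at their baseline coverage. Trajectories are typically
#' built with [expand_trajectory()] (linear interpolation between anchor
#' coverages, constant afterwards) but any explicit per-year values are
#' accepted.
#'
#' @param name Scenario name token.
#' @param trajectories Named list, intervention id -> named numeric vector of
#'   year -> coverage fraction in [0, 1].
#' @return An object of class `coverage_scenario`.
#' @examples
#' coverage_scenario("vita_scaleup",
#'   list(vita = expand_trajectory(0.50, 0.95, 2013, 2015)))
#' @export
coverage_scenario <- function(name, trajectories) {
  trajectories <- lapply(trajectories, function(tr) {
    tr <- unlist(tr)
    stats::setNames(as.numeric(tr), names(tr))
  })
  structure(list(name = as.character(name), trajectories = trajectories),
            class = "coverage_scenario")
}

#' @export
print.coverage_scenario <- function(x, ...) {
  yrs <- unique(unlist(lapply(x$trajectories, names)))
  cat("coverage_scenario '", x$name, "': ", length(x$trajectories),
      " intervention(s)",
      if (length(yrs)) paste0(", years ", min(yrs), "-", max(yrs)),
      "\n", sep = "")
  invisible(x)
}

#' Linearly interpolated coverage trajectory
#'
#' Expands a (start, target) coverage pair into per-year coverages, linear
#' and inclusive of both endpoints. For example, scaling from 50% in 2013 to
#' 95% in 2015 yields 0.50, 0.725, 0.95. After `end_year` the scenario
#' machinery holds coverage constant at the target.
#'
#' @param start_coverage,target_coverage Coverage fractions in [0, 1].
#' @param start_year,end_year First and last year of scale-up
#'   (`start_year <= end_year`).
#' @return Named numeric vector of year -> coverage.
#' @examples
#' expand_trajectory(0.50, 0.95, 2013, 2015)
#' @export
expand_trajectory <- function(start_coverage, target_coverage,
                              start_year, end_year) {
  if (end_year < start_year)
    stop("invalid scenario: end_year (", end_year,
         ") precedes start_year (", start_year, ")")
  if (any(c(start_coverage, target_coverage) < 0) ||
      any(c(start_coverage, target_coverage) > 1))
    stop("coverages must be fractions in [0, 1]")
  yrs <- seq.int(start_year, end_year)
  if (length(yrs) == 1L)
    return(stats::setNames(target_coverage, as.character(yrs)))
  cov <- start_coverage +
    (target_coverage - start_coverage) * (yrs - start_year) /
    (end_year - start_year)
  stats::setNames(cov, as.character(yrs))
}

#' Validate a profile against the model's structural rules
#'
#' Total check of every profile invariant: rates non-negative, sub-band
#' weights non-negative and summing to 1, cause proportions in [0, 1] and
#' summing to 1 per band (tolerance 1e-9), bands drawn from the closed band
#' set, coverages in [0, 1], live births non-negative, and (when a catalog
#' is given) every baseline-coverage key matching a catalog intervention id.
#' Findings are returned, never raised, so callers decide severity.
#'
#' @param profile A [country_profile()].
#' @param catalog Optional list of [intervention()] objects; when supplied,
#'   baseline coverage keys are checked against catalog ids.
#' @return Character vector of findings, empty iff the profile is valid.
#'   Each finding names the offending field and the violated rule.
#' @export
validate_profile <- function(profile, catalog = NULL) {
  f <- character()
  tol <- 1e-9
  rate_fields <- c("neonatal_mortality", "child_1_59m_mortality",
                   "stillbirth_rate", "maternal_mortality_ratio")
  for (fld in rate_fields) {
    v <- profile[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      f <- c(f, paste0(fld, ": must be a single number"))
    else if (v < 0)
      f <- c(f, paste0(fld, ": rate must be >= 0 (got ", v, ")"))
  }

  w <- profile$sub_band_weights
  if (!setequal(names(w), sub_bands()))
    f <- c(f, paste0("sub_band_weights: must name exactly ",
                     paste(sub_bands(), collapse = ", ")))
  if (any(w < 0))
    f <- c(f, "sub_band_weights: weights must be >= 0")
  if (abs(sum(w) - 1) > tol)
    f <- c(f, paste0("sub_band_weights: must sum to 1 (got ",
                     format(sum(w), digits = 12), ")"))

  cs <- profile$cause_structures
  unknown <- setdiff(names(cs), all_bands())
  if (length(unknown))
    f <- c(f, paste0("cause_structures: unknown band(s) ",
                     paste(unknown, collapse = ", "),
                     " (band set is closed)"))
  missing_b <- setdiff(all_bands(), names(cs))
  if (length(missing_b))
    f <- c(f, paste0("cause_structures: missing band(s) ",
                     paste(missing_b, collapse = ", ")))
  for (b in intersect(names(cs), all_bands())) {
    p <- cs[[b]]
    if (!length(p)) {
      f <- c(f, paste0("cause_structures[", b, "]: empty"))
      next
    }
    if (any(p < 0 | p > 1))
      f <- c(f, paste0("cause_structures[", b,
                       "]: proportions must be in [0, 1]"))
    if (abs(sum(p) - 1) > tol)
      f <- c(f, paste0("cause_structures[", b, "]: proportions sum to ",
                       format(sum(p), digits = 12), ", must sum to 1"))
  }

  cv <- profile$base_coverages
  bad <- cv < 0 | cv > 1
  if (any(bad))
    f <- c(f, paste0("base_coverages[", names(cv)[bad],
                     "]: coverage out of [0, 1] (got ", cv[bad], ")"))
  if (!is.null(catalog)) {
    ids <- catalog_ids(catalog)
    orphan <- setdiff(names(cv), ids)
    if (length(orphan))
      f <- c(f, paste0("base_coverages: id(s) not in catalog: ",
                       paste(orphan, collapse = ", ")))
  }

  lb <- profile$live_births
  if (!length(lb))
    f <- c(f, "live_births: at least one year required")
  if (any(lb < 0))
    f <- c(f, "live_births: counts must be >= 0")

  f
}

#' Validate a coverage scenario against a profile and catalog
#'
#' @param scenario A [coverage_scenario()].
#' @param catalog List of [intervention()] objects.
#' @param profile A [country_profile()] (for the base-year lower bound).
#' @param end_year Optional last projection year for the year-range check.
#' @return Character vector of findings, empty iff valid.
#' @export
validate_scenario <- function(scenario, catalog, profile, end_year = NULL) {
  f <- character()
  ids <- catalog_ids(catalog)
  orphan <- setdiff(names(scenario$trajectories), ids)
  if (length(orphan))
    f <- c(f, paste0("trajectories: unknown intervention id(s): ",
                     paste(orphan, collapse = ", ")))
  for (id in names(scenario$trajectories)) {
    tr <- scenario$trajectories[[id]]
    if (any(tr < 0 | tr > 1))
      f <- c(f, paste0("trajectories[", id, "]: coverage out of [0, 1]"))
    yrs <- suppressWarnings(as.integer(names(tr)))
    if (anyNA(yrs)) {
      f <- c(f, paste0("trajectories[", id, "]: non-numeric year key"))
      next
    }
    if (any(yrs < profile$base_year))
      f <- c(f, paste0("trajectories[", id, "]: year before base year ",
                       profile$base_year))
    if (!is.null(end_year) && any(yrs > end_year))
      f <- c(f, paste0("trajectories[", id, "]: year after end year ",
                       end_year))
  }
  f
}
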