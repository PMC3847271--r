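#' Coverage change between baseline and scenario
#'
#' @param base_coverage,scenario_coverage Coverage fractions in [0, 1].
#' @return Signed fraction `scenario_coverage - base_coverage`; negative
#'   when coverage declines.
#' @examples
#' delta_coverage(0.30, 0.50)  # 0.20
#' @export
delta_coverage <- function(base_coverage, scenario_coverage) {
  stopifnot(all(base_coverage >= 0 & base_coverage <= 1),
            all(scenario_coverage >= 0 & scenario_coverage <= 1))
  scenario_coverage - base_coverage
}

# Canonical empty impact table. `impact` is always delta_coverage * efficacy,
# derived at construction and never free.
empty_impacts <- function() {
  data.frame(intervention_id = character(), category = character(),
             stage_order = integer(), cause = character(),
             band = character(), delta_coverage = numeric(),
             efficacy = numeric(), impact = numeric(),
             stringsAsFactors = FALSE)
}

impact_values <- function(impacts) {
  if (is.data.frame(impacts)) {
    if (nrow(impacts) > 1L &&
        (length(unique(impacts$cause)) > 1L ||
         length(unique(impacts$band)) > 1L))
      stop("impacts mix causes/bands: residual application is per (cause, band)")
    impacts$impact
  } else {
    as.numeric(impacts)
  }
}

#' Residual deaths after sequentially applying intervention impacts
#'
#' The core no-double-counting rule. Each impact term (coverage change times
#' cause-specific efficacy) removes its share of the deaths *remaining*
#' after all previously applied interventions, so the combined effect is the
#' product `base_deaths * prod(1 - impact_i)`. With 10,000 base deaths and a
#' 50%-effective intervention at 50% coverage change, 7,500 deaths remain; a
#' second identical intervention acts on those 7,500 and leaves 5,625. The
#' product form is order-invariant: only attribution (see
#' [attribute_cell()]) is order-sensitive.
#'
#' Negative impact terms (coverage decline) give factors above 1, i.e.
#' deaths increase when coverage falls -- the natural extension of the same
#' formula.
#'
#' @param base_deaths Non-negative death count (carried as a real number;
#'   rounding happens only at report formatting).
#' @param impacts Impact table from [collect_impacts()] (all rows must share
#'   one cause and band), or a bare numeric vector of impact terms.
#' @return Residual death count, clamped below at 0.
#' @examples
#' residual_deaths(10000, 0.5 * 0.5)          # 7500
#' residual_deaths(10000, c(0.25, 0.25))      # 5625
#' @export
residual_deaths <- function(base_deaths, impacts) {
  stopifnot(base_deaths >= 0)
  v <- impact_values(impacts)
  if (any(abs(v) > 1))
    stop("impact terms must have magnitude <= 1")
  max(0, base_deaths * prod(1 - v))
}

#' Deaths averted by a set of impacts
#'
#' Complement of [residual_deaths()]: `base_deaths - residual`. Negative
#' only when net impacts are negative (coverage decline).
#'
#' @inheritParams residual_deaths
#' @return Signed death count averted.
#' @examples
#' deaths_averted(10000, 0.25)           # 2500
#' deaths_averted(10000, c(0.25, 0.25))  # 4375
#' @export
deaths_averted <- function(base_deaths, impacts) {
  base_deaths - residual_deaths(base_deaths, impacts)
}

#' Collect ordered impact terms for one (cause, band) cell
#'
#' Scans the catalog for interventions carrying an efficacy entry for the
#' given cause and band, computes each one's impact term (coverage change
#' times efficacy), drops zero-change terms, and orders the result: all
#' PREVENTIVE interventions by ascending delivery-stage order (ties broken
#' by id), then all CURATIVE likewise. The ordering matters only for
#' attribution; residual deaths are order-invariant.
#'
#' @param catalog List of [intervention()] objects.
#' @param base_coverages Named numeric, intervention id -> baseline coverage.
#'   Interventions missing from the map default to 0.
#' @param scenario_coverages Named numeric, intervention id -> coverage in
#'   the scenario year. Ids missing from the map stay at baseline. Every id
#'   present must exist in the catalog.
#' @param cause Cause-of-death token.
#' @param band Outcome-band token.
#' @return data.frame with columns `intervention_id`, `category`,
#'   `stage_order`, `cause`, `band`, `delta_coverage`, `efficacy`, `impact`.
#' @export
collect_impacts <- function(catalog, base_coverages, scenario_coverages,
                            cause, band) {
  base_coverages <- unlist(base_coverages)
  scenario_coverages <- unlist(scenario_coverages)
  ids <- catalog_ids(catalog)
  orphan <- setdiff(names(scenario_coverages), ids)
  if (length(orphan))
    stop("scenario coverage for unknown intervention id(s): ",
         paste(orphan, collapse = ", "))

  rows <- lapply(catalog, function(iv) {
    hit <- iv$effects$cause == cause & iv$effects$band == band
    if (!any(hit)) return(NULL)
    base <- if (iv$id %in% names(base_coverages))
      base_coverages[[iv$id]] else 0
    scen <- if (iv$id %in% names(scenario_coverages))
      scenario_coverages[[iv$id]] else base
    dc <- delta_coverage(base, scen)
    if (dc == 0) return(NULL)
    eff <- iv$effects$efficacy[hit][1L]
    data.frame(intervention_id = iv$id, category = iv$category,
               stage_order = iv$stage_order, cause = cause, band = band,
               delta_coverage = dc, efficacy = eff, impact = dc * eff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_impacts()), rows))
  block <- match(out$category, c("PREVENTIVE", "CURATIVE"))
  out <- out[order(block, out$stage_order, out$intervention_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
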