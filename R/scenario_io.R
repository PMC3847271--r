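#' @section Input file formats:
#' Profiles, catalogs and scenarios are plain YAML or JSON documents (the
#' extension decides the parser). All fractions are decimals in [0, 1],
#' never percentage points. See the package vignette for the full layout.
#' @name livesaved-io
NULL

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported input format '.", ext, "' for ", path,
         " (use .yaml, .yml or .json)")
  }
}

write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    stop("unsupported output format '.", ext, "' for ", path)
  }
  invisible(path)
}

as_named_num <- function(x, what) {
  v <- unlist(x)
  if (length(v) && is.null(names(v))) stop(what, ": entries must be named")
  stats::setNames(as.numeric(v), names(v))
}

#' Read and write country profiles
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_profile()` returns a [country_profile()];
#'   `write_profile()` returns `path` invisibly. Round-tripping a valid
#'   profile reproduces it field by field.
#' @export
read_profile <- function(path) {
  d <- read_structured(path)
  need <- c("base_year", "neonatal_mortality", "child_1_59m_mortality",
            "stillbirth_rate", "maternal_mortality_ratio",
            "cause_structures", "live_births")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("profile ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  country_profile(
    base_year = d$base_year,
    neonatal_mortality = d$neonatal_mortality,
    child_1_59m_mortality = d$child_1_59m_mortality,
    stillbirth_rate = d$stillbirth_rate,
    maternal_mortality_ratio = d$maternal_mortality_ratio,
    cause_structures = lapply(d$cause_structures, as_named_num,
                              what = "cause_structures"),
    base_coverages = as_named_num(d$base_coverages, "base_coverages"),
    live_births = as_named_num(d$live_births, "live_births"),
    sub_band_weights = if (is.null(d$sub_band_weights))
      default_sub_band_weights()
    else as_named_num(d$sub_band_weights, "sub_band_weights"))
}

#' @rdname read_profile
#' @param profile A [country_profile()].
#' @export
write_profile <- function(profile, path) {
  write_structured(list(
    base_year = profile$base_year,
    neonatal_mortality = profile$neonatal_mortality,
    child_1_59m_mortality = profile$child_1_59m_mortality,
    stillbirth_rate = profile$stillbirth_rate,
    maternal_mortality_ratio = profile$maternal_mortality_ratio,
    sub_band_weights = as.list(profile$sub_band_weights),
    cause_structures = lapply(profile$cause_structures, as.list),
    base_coverages = as.list(profile$base_coverages),
    live_births = as.list(profile$live_births)
  ), path)
}

#' Read and write intervention catalogs
#'
#' A catalog file is a list of interventions, each with `id`, optional
#' `name`, `category` (PREVENTIVE / CURATIVE), `stage_order`, and `effects`
#' entries of (`cause`, `band`, `efficacy`).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_catalog()` returns a list of [intervention()] objects.
#' @export
read_catalog <- function(path) {
  d <- read_structured(path)
  if (!length(d)) stop("catalog ", path, ": empty")
  lapply(d, function(e) {
    if (is.null(e$id) || is.null(e$category) || is.null(e$stage_order) ||
        is.null(e$effects))
      stop("catalog ", path,
           ": each entry needs id, category, stage_order, effects")
    eff <- do.call(rbind, lapply(e$effects, function(x)
      data.frame(cause = x$cause, band = x$band,
                 efficacy = as.numeric(x$efficacy),
                 stringsAsFactors = FALSE)))
    intervention(e$id, if (is.null(e$name)) e$id else e$name,
                 e$category, e$stage_order, eff)
  })
}

#' @rdname read_catalog
#' @param catalog List of [intervention()] objects.
#' @export
write_catalog <- function(catalog, path) {
  write_structured(lapply(catalog, function(iv) list(
    id = iv$id, name = iv$name, category = iv$category,
    stage_order = iv$stage_order,
    effects = lapply(seq_len(nrow(iv$effects)), function(i) list(
      cause = iv$effects$cause[i], band = iv$effects$band[i],
      efficacy = iv$effects$efficacy[i]))
  )), path)
}

#' Read and write coverage scenarios
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scenario()` returns a [coverage_scenario()].
#' @export
read_scenario <- function(path) {
  d <- read_structured(path)
  if (is.null(d$name) || is.null(d$trajectories))
    stop("scenario ", path, ": needs fields name and trajectories")
  coverage_scenario(d$name, lapply(d$trajectories, as_named_num,
                                   what = "trajectories"))
}

#' @rdname read_scenario
#' @param scenario A [coverage_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  write_structured(list(
    name = scenario$name,
    trajectories = lapply(scenario$trajectories, as.list)
  ), path)
}

#' Load and validate a full model input set
#'
#' Reads the profile, catalog and scenarios, runs [validate_profile()] and
#' [validate_scenario()], and aborts with a message listing every finding
#' if anything is invalid.
#'
#' @param profile_path,catalog_path Paths to the profile and catalog files.
#' @param scenario_paths Character vector of one or more scenario paths.
#' @param end_year Optional last projection year for scenario year checks.
#' @return List with elements `profile`, `catalog`, `scenarios`.
#' @export
load_inputs <- function(profile_path, catalog_path, scenario_paths,
                        end_year = NULL) {
  if (!length(scenario_paths)) stop("at least one scenario is required")
  profile <- read_profile(profile_path)
  catalog <- read_catalog(catalog_path)
  scenarios <- lapply(scenario_paths, read_scenario)
  findings <- validate_profile(profile, catalog)
  for (sc in scenarios) {
    sf <- validate_scenario(sc, catalog, profile, end_year)
    if (length(sf))
      findings <- c(findings, paste0("scenario '", sc$name, "': ", sf))
  }
  if (length(findings))
    stop("invalid inputs:\n  ", paste(findings, collapse = "\n  "))
  list(profile = profile, catalog = catalog, scenarios = scenarios)
}

# Deterministic CSV writer: fixed column order, fixed 6-decimal float
# formatting, so identical inputs give byte-identical files.
write_result_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write model result tables as tidy CSV
#'
#' Fixed column order and fixed 6-decimal float formatting make outputs
#' byte-reproducible; re-reading a file reproduces the table at the written
#' precision.
#'
#' @param result A `projection_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(result, path) {
  write_result_csv(as.data.frame(result), path)
}

#' @rdname write_projection_csv
#' @param saved A lives-saved table from [lives_saved()].
#' @param scenario_name Scenario name to stamp into the `scenario` column.
#' @export
write_lives_saved_csv <- function(saved, scenario_name, path) {
  write_result_csv(cbind(scenario = scenario_name, saved,
                         stringsAsFactors = FALSE), path)
}

#' @rdname write_projection_csv
#' @param attribution An `attribution_table` from [attribute_scenario()].
#' @export
write_attribution_csv <- function(attribution, path) {
  nm <- attr(attribution, "scenario_name")
  write_result_csv(cbind(scenario = if (is.null(nm)) "" else nm,
                         as.data.frame(attribution),
                         stringsAsFactors = FALSE), path)
}
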