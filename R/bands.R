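#' Outcome-band vocabulary
#'
#' The model tracks deaths in seven fixed outcome bands: stillbirths,
#' maternal deaths (pregnancy among women 15-49), and five child age bands
#' forming a strict survival cascade -- neonatal (0-1 month), 1-5, 6-11,
#' 12-23 and 24-59 months. Survivors of each child band are the entrants of
#' the next within a projection year. The band set is closed: no other band
#' token may appear in any profile, catalog or result table.
#'
#' @return A data.frame with columns `band` (token), `order_index` (cascade
#'   position; stillbirth = 0, neonatal = 1, ..., 24-59 months = 5; the
#'   maternal band sits parallel to the birth event) and `cascade` (logical;
#'   TRUE for the five child bands that chain survivors forward).
#' @examples
#' outcome_bands()
#' @export
outcome_bands <- function() {
  data.frame(
    band = c("STILLBIRTH", "MATERNAL", "NEONATAL_0_1M",
             "M1_5", "M6_11", "M12_23", "M24_59"),
    order_index = c(0L, 1L, 1L, 2L, 3L, 4L, 5L),
    cascade = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Child bands in cascade order (survivors of band i are entrants of band i+1).
child_bands <- function() c("NEONATAL_0_1M", "M1_5", "M6_11", "M12_23", "M24_59")

# The four sub-bands the 1-59 month mortality window is split across.
sub_bands <- function() c("M1_5", "M6_11", "M12_23", "M24_59")

all_bands <- function() outcome_bands()$band

is_band <- function(x) x %in% all_bands()

# Delivery-stage position of an age band in intervention ordering:
# periconception = 0, pregnancy = 1, delivery = 2, then the child bands.
band_stage_order <- function(band) {
  idx <- match(band, child_bands())
  ifelse(is.na(idx), NA_integer_, idx + 2L)
}
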