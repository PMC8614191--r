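#' Solar position at solar noon
#'
#' Solar declination from the Spencer Fourier expansion on day-of-year, and
#' the solar-noon geometry that follows: elevation = 90 - latitude +
#' declination, azimuth 180 degrees (due south) in the northern hemisphere.
#' Shade maps are computed at solar noon of each extreme date, when radiation
#' load on the water surface peaks.
#'
#' @param date A `Date`.
#' @param latitude_deg Site latitude in degrees; `|latitude| < 66.5` (polar
#'   latitudes, where the noon geometry degenerates, are rejected).
#' @return A list with `date`, `latitude`, `declination`, `elevation`,
#'   `azimuth` (degrees).
#' @export
#' @examples
#' solar_position(as.Date("2014-06-21"), 50)  # noon elevation ~ 63.4 deg
solar_position <- function(date, latitude_deg) {
  date <- as_date(date)
  if (!is_number(latitude_deg) || abs(latitude_deg) >= 66.5)
    stopf("solar_position: |latitude| must be < 66.5 degrees")
  doy <- as.integer(format(date, "%j"))
  g <- 2 * pi * (doy - 1) / 365
  decl_rad <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  decl <- decl_rad * 180 / pi
  elev <- 90 - latitude_deg + decl
  elev <- pmin(90, pmax(-90, elev))
  list(date = date, latitude = latitude_deg, declination = decl,
       elevation = elev, azimuth = if (latitude_deg >= 0) 180 else 0)
}
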