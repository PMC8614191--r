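#' Meteorological season of a date
#'
#' Fixed three-month blocks: winter = December-February, spring = March-May,
#' summer = June-August, autumn = September-November.
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return Character vector in `c("winter","spring","summer","autumn")`.
#' @export
#' @examples
#' assign_season(as.Date(c("2014-06-09", "2014-12-15")))
assign_season <- function(date) {
  m <- as.integer(format(as_date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer",
    "autumn", "autumn", "autumn", "winter")[m]
}

#' Regional summer extreme dates, 2012-2018
#'
#' The 17 region-wide summer (June-August) extreme dates of the 2012-2018
#' Walloon monitoring record, used as the default heat-wave schedule of the
#' synthetic generator and as the default event list of the summer analysis.
#'
#' @return A `Date` vector of length 17.
#' @export
summer_extreme_dates <- function() {
  as.Date(c(
    "2012-08-19", "2013-07-22", "2014-06-09", "2014-07-17", "2014-07-24",
    "2014-08-07", "2015-06-05", "2015-07-04", "2015-07-17", "2015-07-27",
    "2015-08-13", "2016-08-27", "2017-07-07", "2017-08-30", "2018-07-01",
    "2018-07-27", "2018-08-23"
  ))
}
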