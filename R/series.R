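#' Construct a tidy RSVI series table
#'
#' One row per (region, year) holding the relative search volume index
#' (RSVI), Google Trends' 0-100 popularity score for a topic within a query
#' window. A value of 0 means "insufficient search data" and is accepted in
#' the container but rejected by the prediction operations, which need a
#' positive denominator.
#'
#' @param region character vector of region codes (USPS two-letter codes for
#'   US states, ISO 3166-1 alpha-2 for countries; any stable key works).
#' @param year integer vector of calendar years.
#' @param rsvi numeric vector of index values in \[0, 100\].
#' @param topic optional topic label attached as an attribute (e.g. "cancer").
#' @return a tibble with columns `region`, `year`, `rsvi`, sorted by region
#'   then year.
#' @examples
#' rsvi_series(c("AL", "AL"), c(2016, 2017), c(89, 86))
#' @export
rsvi_series <- function(region, year, rsvi, topic = NULL) {
  x <- tibble::tibble(
    region = as.character(region),
    year = as.integer(year),
    rsvi = as.numeric(rsvi)
  )
  validate_rsvi(x)
  x <- dplyr::arrange(x, .data$region, .data$year)
  if (!is.null(topic)) attr(x, "topic") <- topic
  x
}

validate_rsvi <- function(x) {
  stopifnot(all(c("region", "year", "rsvi") %in% names(x)))
  if (anyNA(x$year)) stop_input("RSVI series has missing years")
  bad <- !is.na(x$rsvi) & (x$rsvi < 0 | x$rsvi > 100)
  if (any(bad)) {
    stop_input(
      "RSVI values outside [0, 100]: %s",
      paste(sprintf("%s/%d=%g", x$region[bad], x$year[bad], x$rsvi[bad]),
            collapse = ", ")
    )
  }
  dup <- duplicated(x[c("region", "year")])
  if (any(dup)) {
    stop_input(
      "duplicate (region, year) in RSVI series: %s",
      paste(unique(sprintf("%s/%d", x$region[dup], x$year[dup])), collapse = ", ")
    )
  }
  invisible(x)
}

#' Construct a tidy incidence series table
#'
#' One row per (region, year) holding a count of newly diagnosed cases and
#' its provenance: `"actual"` for registry-reported values, `"predicted"`
#' for model output. Provenance is carried through every operation so that a
#' chained projection can never masquerade as reported data.
#'
#' @param region character vector of region codes.
#' @param year integer vector of calendar years.
#' @param cases non-negative numeric vector of case counts.
#' @param provenance `"actual"` (default) or `"predicted"`, recycled.
#' @return a tibble with columns `region`, `year`, `cases`, `provenance`,
#'   sorted by region then year.
#' @examples
#' incidence_series("AL", 2016, 27550)
#' @export
incidence_series <- function(region, year, cases, provenance = "actual") {
  x <- tibble::tibble(
    region = as.character(region),
    year = as.integer(year),
    cases = as.numeric(cases),
    provenance = rep_len(as.character(provenance), length(region))
  )
  validate_incidence(x)
  dplyr::arrange(x, .data$region, .data$year)
}

validate_incidence <- function(x) {
  stopifnot(all(c("region", "year", "cases", "provenance") %in% names(x)))
  if (any(!is.na(x$cases) & x$cases < 0)) {
    bad <- which(!is.na(x$cases) & x$cases < 0)
    stop_input(
      "negative case counts: %s",
      paste(sprintf("%s/%d", x$region[bad], x$year[bad]), collapse = ", ")
    )
  }
  if (!all(x$provenance %in% c("actual", "predicted"))) {
    stop_input("provenance must be 'actual' or 'predicted'")
  }
  dup <- duplicated(x[c("region", "year")])
  if (any(dup)) {
    stop_input(
      "duplicate (region, year) in incidence series: %s",
      paste(unique(sprintf("%s/%d", x$region[dup], x$year[dup])), collapse = ", ")
    )
  }
  invisible(x)
}

# single-region year -> value lookup used by chain_forecast
rsvi_lookup <- function(rsvi, region = NULL) {
  if (is.numeric(rsvi) && !is.null(names(rsvi))) {
    return(stats::setNames(as.numeric(rsvi), names(rsvi)))
  }
  if (is.data.frame(rsvi)) {
    if (!is.null(region)) rsvi <- rsvi[rsvi$region == region, , drop = FALSE]
    regions <- unique(rsvi$region)
    if (length(regions) > 1L) {
      stop_input(
        "RSVI table covers %d regions; pass `region` to select one", length(regions)
      )
    }
    return(stats::setNames(as.numeric(rsvi$rsvi), as.character(rsvi$year)))
  }
  stop_config("`rsvi` must be an rsvi_series table or a year-named numeric vector")
}
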