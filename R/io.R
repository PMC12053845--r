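#' Normalise region display names to stable codes
#'
#' Maps US state names (plus District of Columbia and Puerto Rico) to USPS
#' two-letter codes and the country names appearing in the packaged world
#' tables to ISO 3166-1 alpha-2 codes. Unknown names are returned unchanged
#' so arbitrary keys still work as join keys.
#'
#' @param x character vector of region names or codes.
#' @return character vector of codes.
#' @examples
#' normalize_region(c("Alabama", "District of Columbia", "Viet Nam", "XX"))
#' @export
normalize_region <- function(x) {
  m <- region_code_map()
  hit <- unname(m[x])
  ifelse(is.na(hit), x, hit)
}

region_code_map <- function() {
  us <- stats::setNames(datasets::state.abb, datasets::state.name)
  extra <- c(
    "District of Columbia" = "DC",
    "Puerto Rico" = "PR",
    "United States" = "US",
    "United States of America" = "US",
    "Algeria" = "DZ", "Argentina" = "AR", "Australia" = "AU",
    "Bangladesh" = "BD", "Belgium" = "BE", "Bolivia" = "BO",
    "Brazil" = "BR", "Canada" = "CA", "Chile" = "CL", "Colombia" = "CO",
    "Costa Rica" = "CR", "Denmark" = "DK", "Dominican Republic" = "DO",
    "Ecuador" = "EC", "Egypt" = "EG", "France" = "FR", "Germany" = "DE",
    "Ghana" = "GH", "Guatemala" = "GT", "India" = "IN", "Indonesia" = "ID",
    "Ireland" = "IE", "Italy" = "IT", "Japan" = "JP", "Kenya" = "KE",
    "Malaysia" = "MY", "Mexico" = "MX", "Morocco" = "MA",
    "New Zealand" = "NZ", "Nigeria" = "NG", "Norway" = "NO",
    "Pakistan" = "PK", "Panama" = "PA", "Paraguay" = "PY", "Peru" = "PE",
    "Philippines" = "PH", "Poland" = "PL", "Portugal" = "PT",
    "Romania" = "RO", "Russian Federation" = "RU", "Saudi Arabia" = "SA",
    "Singapore" = "SG", "South Africa" = "ZA", "Spain" = "ES",
    "Sweden" = "SE", "Switzerland" = "CH", "Thailand" = "TH",
    "Turkey" = "TR", "United Arab Emirates" = "AE",
    "United Kingdom" = "GB", "Uruguay" = "UY", "Viet Nam" = "VN",
    "Vietnam" = "VN"
  )
  c(us, extra)
}

#' Read a tidy incidence CSV
#'
#' Expects a header row with region, year and cases columns (names
#' configurable). All rows are marked `provenance = "actual"`: files are
#' assumed to carry registry data, never model output.
#'
#' @param path file path (or connection) to a comma-separated file.
#' @param region_col,year_col,cases_col column names in the file.
#' @return an [incidence_series()] tibble.
#' @export
read_incidence_csv <- function(path, region_col = "region",
                               year_col = "year", cases_col = "cases") {
  raw <- read_csv_checked(path, c(region_col, year_col, cases_col))
  cases <- parse_numeric_col(raw[[cases_col]], cases_col, path)
  year <- parse_numeric_col(raw[[year_col]], year_col, path)
  incidence_series(raw[[region_col]], year, cases, provenance = "actual")
}

read_csv_checked <- function(path, required) {
  if (is.character(path) && !file.exists(path)) {
    stop_input("file not found: %s", path)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_input("missing column(s) %s in %s",
               paste(missing, collapse = ", "),
               if (is.character(path)) path else "input")
  }
  raw
}

parse_numeric_col <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_input("non-numeric `%s` value %s at data row %d of %s",
               name, x[bad[1L]], bad[1L],
               if (is.character(path)) path else "input")
  }
  out
}

#' Read RSVI values from a tidy CSV or a Google Trends multiTimeline export
#'
#' In `"tidy"` mode the file has (region, year, rsvi) columns, one yearly
#' value per row. In `"multitimeline"` mode the file is the CSV dialect
#' Google Trends exports for a time-series query: a title line, a blank
#' line, a `Month,<topic>: (<region>)` header, then `YYYY-MM,<value>` rows.
#' Cells printed as `"<1"` are parsed as 0.5 (the midpoint of the censored
#' interval). Monthly values are aggregated to a yearly arithmetic mean at
#' full precision; years with fewer than 12 months are excluded (with a
#' warning) unless `keep_partial_years = TRUE`.
#'
#' @param path file path.
#' @param mode `"tidy"` or `"multitimeline"`.
#' @param keep_partial_years keep years with < 12 exported months
#'   (multiTimeline mode only)? Default `FALSE`.
#' @return an [rsvi_series()] tibble; in multiTimeline mode the region is
#'   taken from the export header and normalised via [normalize_region()].
#' @export
read_trends_csv <- function(path, mode = c("tidy", "multitimeline"),
                            keep_partial_years = FALSE) {
  mode <- match.arg(mode)
  if (mode == "tidy") {
    raw <- read_csv_checked(path, c("region", "year", "rsvi"))
    return(rsvi_series(raw$region,
                       parse_numeric_col(raw$year, "year", path),
                       parse_numeric_col(raw$rsvi, "rsvi", path)))
  }
  read_multitimeline(path, keep_partial_years)
}

read_multitimeline <- function(path, keep_partial_years) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^Month,", lines)
  if (length(hdr) == 0L) {
    stop_input("no 'Month,...' header found in %s: not a multiTimeline export", path)
  }
  hdr <- hdr[1L]
  m <- regmatches(lines[hdr],
                  regexec("^Month,(.*?)(?::\\s*\\((.*)\\))?$", lines[hdr]))[[1L]]
  topic <- if (length(m) >= 2L) m[2L] else NA_character_
  region_name <- if (length(m) >= 3L && nzchar(m[3L])) m[3L] else "Unknown"
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  months <- integer(0); years <- integer(0); values <- numeric(0)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    tok <- trimws(parts[1L])
    if (!grepl("^\\d{4}-\\d{2}$", tok)) {
      stop_input("unparseable month token '%s' at line %d of %s",
                 tok, hdr + i, path)
    }
    val <- trimws(parts[2L])
    v <- if (val == "<1") 0.5 else suppressWarnings(as.numeric(val))
    if (is.na(v)) {
      stop_input("unparseable RSVI value '%s' at line %d of %s",
                 val, hdr + i, path)
    }
    years <- c(years, as.integer(substr(tok, 1, 4)))
    months <- c(months, as.integer(substr(tok, 6, 7)))
    values <- c(values, v)
  }
  if (any(values < 0 | values > 100)) {
    stop_input("RSVI outside [0, 100] in %s", path)
  }
  counts <- tapply(values, years, length)
  means <- tapply(values, years, mean)
  yrs <- as.integer(names(means))
  partial <- yrs[counts < 12L]
  if (length(partial) && !keep_partial_years) {
    warning(sprintf("excluding partial year(s) with fewer than 12 months: %s",
                    paste(partial, collapse = ", ")),
            call. = FALSE)
    keep <- counts == 12L
    yrs <- yrs[keep]; means <- means[keep]
  }
  if (length(yrs) == 0L) stop_input("no complete year in %s", path)
  rsvi_series(rep(normalize_region(region_name), length(yrs)),
              yrs, as.numeric(means), topic = topic)
}

fixture_names <- c("table1_2017", "table2_2018_2020",
                   "table3_us_projections", "table4_world_projections")

#' Load a packaged validation or projection table
#'
#' The package ships four plain-text tables transcribed from the published
#' state- and country-level validation study: `"table1_2017"` (50 US
#' regions: 2016 actual counts, 2016/2017 RSVI, displayed ratio, predicted
#' and actual 2017 counts, displayed percentage error), `"table2_2018_2020"`
#' (predicted/actual/%error per region and year 2018-2020),
#' `"table3_us_projections"` and `"table4_world_projections"` (chained
#' projections for 2021-2023; their RSVI inputs were not published, so these
#' are reference values only, not recomputable). Displayed ratio and %error
#' columns are stored exactly as printed (3 and 1 decimals respectively);
#' regions carry both the original display name and a normalised code.
#'
#' @param name one of `"table1_2017"`, `"table2_2018_2020"`,
#'   `"table3_us_projections"`, `"table4_world_projections"`.
#' @return a tibble; the fixture name is attached as attribute
#'   `fixture_name`.
#' @examples
#' load_fixture("table1_2017")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% fixture_names) {
    stop_config("unknown fixture '%s'; valid names: %s",
                paste(name, collapse = ","),
                paste(fixture_names, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "rsvicast",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(x, "fixture_name") <- name
  x
}

#' Rebuild model inputs from the one-step validation fixture
#'
#' Converts `"table1_2017"` into the (incidence, RSVI) series pair the model
#' consumes, so the packaged table can be reproduced end-to-end through
#' [validate_year()].
#'
#' @param name currently only `"table1_2017"` carries its own inputs.
#' @return list with elements `incidence` (actual counts for 2016 and 2017)
#'   and `rsvi` (2016 and 2017 index values).
#' @export
fixture_series <- function(name = "table1_2017") {
  if (!identical(name, "table1_2017")) {
    stop_config("only 'table1_2017' publishes its model inputs (RSVI values)")
  }
  t1 <- load_fixture("table1_2017")
  list(
    incidence = incidence_series(
      rep(t1$region, 2L),
      rep(c(2016L, 2017L), each = nrow(t1)),
      c(t1$actual_2016, t1$actual_2017)
    ),
    rsvi = rsvi_series(
      rep(t1$region, 2L),
      rep(c(2016L, 2017L), each = nrow(t1)),
      c(t1$rsvi_2016, t1$rsvi_2017)
    )
  )
}

#' Write a deterministic CSV or JSON report
#'
#' Serialises prediction records, validation tables, incidence/RSVI series
#' or any region-keyed mapping with a stable row order (region, then year if
#' present) and stable column order, so identical inputs always produce
#' byte-identical files -- suitable for regression diffing and for feeding
#' mapping tools.
#'
#' @param x a data frame, a [validate_year()] result, or a region-named
#'   numeric vector.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- report_frame(x)
  if (nrow(df) == 0L) stop_input("refusing to write an empty report")
  ord <- if ("year" %in% names(df)) order(df$region, df$year) else order(df$region)
  df <- df[ord, , drop = FALSE]
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_input("output directory does not exist: %s", dir)
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

report_frame <- function(x) {
  if (inherits(x, "validation_table")) return(as.data.frame(x$records))
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.frame(region = names(x), value = unname(x),
                      stringsAsFactors = FALSE))
  }
  stop_config("don't know how to report an object of class %s",
              paste(class(x), collapse = "/"))
}
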