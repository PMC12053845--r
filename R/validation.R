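#' One-year validation run
#'
#' For every region with an actual count in `target_year - 1`, an actual
#' count in `target_year`, and positive RSVI in both years, applies the
#' one-step predictor and computes the percentage error against the
#' reported actual. Regions missing any input are never silently dropped:
#' they are returned in a `skipped` table with a reason each.
#'
#' @param incidence an [incidence_series()] tibble (multi-region).
#' @param rsvi an [rsvi_series()] tibble (multi-region).
#' @param target_year the year to predict and validate.
#' @param threshold absolute %error threshold for the summary (default 6).
#' @return an object of class `validation_table`: list with `target_year`,
#'   `records` (prediction records sorted by region), `skipped` (tibble of
#'   region, reason), and `summary` (an [error_summary()]).
#' @export
validate_year <- function(incidence, rsvi, target_year, threshold = 6) {
  validate_incidence(incidence)
  validate_rsvi(rsvi)
  assert_scalar_number(target_year, "target_year")
  target_year <- as.integer(target_year)
  base_year <- target_year - 1L

  regions <- sort(unique(incidence$region))
  skipped <- list()
  rows <- list()
  for (r in regions) {
    inc <- incidence[incidence$region == r, ]
    rs <- rsvi[rsvi$region == r, ]
    base <- inc$cases[inc$year == base_year & inc$provenance == "actual"]
    act <- inc$cases[inc$year == target_year & inc$provenance == "actual"]
    v0 <- rs$rsvi[rs$year == base_year]
    v1 <- rs$rsvi[rs$year == target_year]
    reason <- NULL
    if (length(base) == 0L) {
      reason <- sprintf("no actual count for %d", base_year)
    } else if (length(act) == 0L) {
      reason <- sprintf("no actual count for %d", target_year)
    } else if (length(v0) == 0L) {
      reason <- sprintf("no RSVI for %d", base_year)
    } else if (length(v1) == 0L) {
      reason <- sprintf("no RSVI for %d", target_year)
    } else if (v0 == 0) {
      reason <- sprintf("RSVI 0 in %d (insufficient search data)", base_year)
    }
    if (!is.null(reason)) {
      skipped[[r]] <- tibble::tibble(region = r, reason = reason)
      next
    }
    rows[[r]] <- predict_one_step(base, v0, v1, region = r,
                                  base_year = base_year, actual = act)
  }
  if (length(rows) == 0L) {
    stop_input("no region qualifies for validation of year %d", target_year)
  }
  records <- dplyr::bind_rows(rows)
  structure(
    list(
      target_year = target_year,
      records = records,
      skipped = if (length(skipped)) dplyr::bind_rows(skipped)
                else tibble::tibble(region = character(), reason = character()),
      summary = error_summary(records$percent_error, threshold = threshold)
    ),
    class = "validation_table"
  )
}

#' @export
print.validation_table <- function(x, ...) {
  cat(sprintf("Validation of year %d: %d regions (%d skipped)\n",
              x$target_year, nrow(x$records), nrow(x$skipped)))
  print(x$summary)
  if (nrow(x$skipped)) {
    cat("Skipped:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat(sprintf("  %s: %s\n", x$skipped$region[i], x$skipped$reason[i]))
    }
  }
  invisible(x)
}

#' Multi-year validation runs
#'
#' Applies [validate_year()] to each requested year. Each year is predicted
#' from the *previous year's actual* count (not chained): this is the
#' construction under which every reported predicted/actual/%error triple
#' of the packaged 2018-2020 table is self-consistent.
#'
#' @inheritParams validate_year
#' @param years integer vector of target years (may be empty).
#' @return a named list of `validation_table`s, one per year.
#' @export
validate_multi_year <- function(incidence, rsvi, years, threshold = 6) {
  out <- lapply(as.integer(years), function(y) {
    validate_year(incidence, rsvi, y, threshold = threshold)
  })
  stats::setNames(out, as.character(years))
}

#' Project years without reported counts
#'
#' Chains the one-step predictor beyond the last year with reported data,
#' per region: step k's base is step k-1's unrounded prediction. Output
#' rows carry `provenance = "predicted"` and are appended to the input
#' series; an existing actual value is never overwritten. A note reminds
#' that the percentage error of chained projections is expected to grow
#' with horizon as deviations compound.
#'
#' @inheritParams validate_year
#' @param last_actual_year last year whose count is trusted as a base.
#' @param horizon number of years to project beyond `last_actual_year`.
#' @return the combined incidence tibble (actuals plus projected years,
#'   provenance-flagged); the full prediction records are attached as
#'   attribute `"records"` and the per-region skip table as `"skipped"`.
#' @export
project_unobserved <- function(incidence, rsvi, last_actual_year, horizon) {
  validate_incidence(incidence)
  validate_rsvi(rsvi)
  assert_scalar_number(last_actual_year, "last_actual_year")
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon < 1 || horizon != as.integer(horizon)) {
    stop_config("`horizon` must be a positive integer")
  }
  last_actual_year <- as.integer(last_actual_year)
  message(sprintf(
    paste0("projecting %d year(s) beyond %d from predicted bases: ",
           "expect the percentage error to increase with horizon as ",
           "deviations accumulate"),
    horizon, last_actual_year))

  regions <- sort(unique(incidence$region))
  recs <- list()
  skipped <- list()
  for (r in regions) {
    inc <- incidence[incidence$region == r, ]
    base <- inc$cases[inc$year == last_actual_year & inc$provenance == "actual"]
    if (length(base) == 0L) {
      skipped[[r]] <- tibble::tibble(
        region = r, reason = sprintf("no actual count for %d", last_actual_year))
      next
    }
    rec <- tryCatch(
      chain_forecast(base, last_actual_year, rsvi, horizon, region = r),
      rsvicast_input_error = function(e) e
    )
    if (inherits(rec, "error")) {
      skipped[[r]] <- tibble::tibble(region = r, reason = conditionMessage(rec))
      next
    }
    recs[[r]] <- rec
  }
  if (length(recs) == 0L) {
    stop_input("no region could be projected beyond %d", last_actual_year)
  }
  records <- dplyr::bind_rows(recs)
  new_rows <- incidence_series(records$region, records$target_year,
                               records$predicted, provenance = "predicted")
  clash <- paste(new_rows$region, new_rows$year) %in%
    paste(incidence$region, incidence$year)[incidence$provenance == "actual"]
  if (any(clash)) {
    warning("projected years overlapping existing actuals were dropped: ",
            paste(unique(sprintf("%s/%d", new_rows$region[clash],
                                 new_rows$year[clash])), collapse = ", "),
            call. = FALSE)
    new_rows <- new_rows[!clash, ]
  }
  out <- dplyr::arrange(dplyr::bind_rows(incidence, new_rows),
                        .data$region, .data$year)
  attr(out, "records") <- records
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped)
                          else tibble::tibble(region = character(), reason = character())
  out
}
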