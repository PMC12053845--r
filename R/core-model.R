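#' Year-over-year RSVI ratio
#'
#' The model's single parameter-free ingredient: the ratio of a region's
#' relative search volume index in the target year to the base year,
#' RSVI(t)/RSVI(t-1). The ratio is returned at full floating precision;
#' round to 3 decimals with [round_half_away()] only for display, never
#' before multiplying (the published predicted counts reproduce only under
#' the full-precision ratio).
#'
#' @param rsvi_target RSVI in the target year, in \[0, 100\].
#' @param rsvi_base RSVI in the base year, in (0, 100\]. Zero is rejected:
#'   Google Trends uses 0 to mean "insufficient search data", not zero
#'   interest, so there is no denominator to divide by.
#' @param region,year optional labels used in error messages.
#' @return the ratio, vectorised over its inputs.
#' @examples
#' rsvi_ratio(86, 89)                  # 0.9662921...
#' round_half_away(rsvi_ratio(98, 90), 3)  # 1.089
#' @export
rsvi_ratio <- function(rsvi_target, rsvi_base, region = NULL, year = NULL) {
  check_rsvi_value(rsvi_target, "rsvi_target")
  check_rsvi_value(rsvi_base, "rsvi_base")
  zero <- !is.na(rsvi_base) & rsvi_base == 0
  if (any(zero)) {
    lab <- label_at(which(zero)[1L], region, year)
    stop_input(
      "base RSVI is 0%s: an RSVI of 0 designates insufficient search data, so no ratio is defined",
      lab
    )
  }
  miss <- is.na(rsvi_base) | is.na(rsvi_target)
  if (any(miss)) {
    lab <- label_at(which(miss)[1L], region, year)
    stop_input("missing RSVI value%s", lab)
  }
  rsvi_target / rsvi_base
}

check_rsvi_value <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 100))) {
    stop_input("`%s` outside [0, 100]", name)
  }
  invisible(x)
}

label_at <- function(i, region, year) {
  parts <- c(
    if (!is.null(region)) as.character(region)[min(i, length(region))],
    if (!is.null(year)) as.character(year)[min(i, length(year))]
  )
  if (length(parts)) paste0(" (", paste(parts, collapse = "/"), ")") else ""
}

#' One-step incidence prediction
#'
#' Predicts a region's case count one year ahead by scaling the base-year
#' count with the RSVI ratio: predicted = base_count x RSVI(t)/RSVI(t-1).
#' The raw prediction is kept at full precision; `predicted` is the
#' half-away-from-zero integer rounding used for reporting. When `actual`
#' is supplied the record also carries the percentage error, computed from
#' the raw (unrounded) prediction, which is the convention under which the
#' packaged validation tables reproduce cell-for-cell.
#'
#' @param base_count case count in the base year (>= 0).
#' @param rsvi_base,rsvi_target RSVI values for base and target year.
#' @param region optional region code(s) for the record.
#' @param base_year optional base calendar year(s); `target_year` is always
#'   `base_year + 1`.
#' @param actual optional reported count for the target year; enables
#'   `percent_error`.
#' @param base_provenance `"actual"` (default) or `"predicted"`; records
#'   whether the base count is registry data or an earlier model output.
#' @return a tibble of prediction records with columns `region`,
#'   `base_year`, `target_year`, `base_count`, `rsvi_base`, `rsvi_target`,
#'   `ratio`, `predicted_raw`, `predicted`, `actual`, `percent_error`,
#'   `base_provenance`. Vectorised: one row per input element.
#' @examples
#' predict_one_step(27550, 89, 86)$predicted  # 26621
#' @export
predict_one_step <- function(base_count, rsvi_base, rsvi_target,
                             region = NA_character_, base_year = NA_integer_,
                             actual = NULL, base_provenance = "actual") {
  if (any(!is.na(base_count) & base_count < 0)) {
    stop_input("`base_count` must be non-negative")
  }
  n <- max(length(base_count), length(rsvi_base), length(rsvi_target))
  ratio <- rsvi_ratio(rsvi_target, rsvi_base, region = region, year = base_year)
  raw <- base_count * ratio
  actual <- if (is.null(actual)) NA_real_ else as.numeric(actual)
  pe <- ifelse(is.na(actual), NA_real_, percent_error_raw(raw, actual))
  tibble::tibble(
    region = rep_len(as.character(region), n),
    base_year = rep_len(as.integer(base_year), n),
    target_year = rep_len(as.integer(base_year), n) + 1L,
    base_count = rep_len(as.numeric(base_count), n),
    rsvi_base = rep_len(as.numeric(rsvi_base), n),
    rsvi_target = rep_len(as.numeric(rsvi_target), n),
    ratio = rep_len(ratio, n),
    predicted_raw = rep_len(raw, n),
    predicted = round_half_away(rep_len(raw, n)),
    actual = rep_len(actual, n),
    percent_error = rep_len(pe, n),
    base_provenance = rep_len(as.character(base_provenance), n)
  )
}

#' Percentage error of a prediction
#'
#' The validation statistic: (predicted - actual) / actual x 100. Returned
#' at full precision; the published tables display it at 1 decimal
#' ([round_half_away()]).
#'
#' @param predicted predicted count(s).
#' @param actual reported count(s), strictly positive.
#' @return percentage error, vectorised.
#' @examples
#' percent_error(26621, 27409)  # -2.875...
#' @export
percent_error <- function(predicted, actual) {
  if (any(!is.na(actual) & actual <= 0)) {
    stop_input("`actual` must be > 0: relative error is undefined at zero")
  }
  percent_error_raw(predicted, actual)
}

percent_error_raw <- function(predicted, actual) {
  (predicted - actual) / actual * 100
}

#' Chained multi-year forecast
#'
#' Projects `horizon` years beyond the last observed count by iterating the
#' one-step predictor, feeding each step's unrounded prediction in as the
#' next base (rounding happens only in the reported `predicted` column).
#' Because intermediate values are never rounded, the k-step raw forecast
#' telescopes exactly to `base_count x RSVI(base_year + k) / RSVI(base_year)`.
#' Every record after the first carries `base_provenance = "predicted"`;
#' expect the error of such projections to grow with horizon, since each
#' step compounds the deviation of the one before.
#'
#' @param base_count observed count at `base_year`.
#' @param base_year last year with an observed (or otherwise trusted) count.
#' @param rsvi RSVI values covering `base_year` through
#'   `base_year + horizon`: a single-region [rsvi_series()] table or a
#'   year-named numeric vector.
#' @param horizon number of years to project (positive integer).
#' @param region optional region code for records and error messages.
#' @param base_provenance provenance of the starting count (default
#'   `"actual"`).
#' @return a tibble of `horizon` prediction records (see
#'   [predict_one_step()]).
#' @examples
#' chain_forecast(10000, 2000, c(`2000` = 80, `2001` = 88, `2002` = 66), 2)
#' @export
chain_forecast <- function(base_count, base_year, rsvi, horizon,
                           region = NA_character_, base_provenance = "actual") {
  assert_scalar_number(base_count, "base_count")
  assert_scalar_number(base_year, "base_year")
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon < 1 || horizon != as.integer(horizon)) {
    stop_config("`horizon` must be a positive integer")
  }
  lut <- rsvi_lookup(rsvi, region = if (is.na(region)) NULL else region)
  years <- base_year + 0:horizon
  for (y in years) {
    v <- lut[as.character(y)]
    if (is.na(v)) {
      stop_input("no RSVI value for year %d%s (years are never interpolated)",
                 y, label_at(1L, region, NULL))
    }
    if (v == 0) {
      stop_input(
        "RSVI is 0 in year %d%s: 0 designates insufficient search data",
        y, label_at(1L, region, NULL)
      )
    }
  }
  out <- vector("list", horizon)
  base <- base_count
  prov <- base_provenance
  for (k in seq_len(horizon)) {
    y <- base_year + k - 1L
    rec <- predict_one_step(
      base, lut[as.character(y)], lut[as.character(y + 1L)],
      region = region, base_year = y, base_provenance = prov
    )
    out[[k]] <- rec
    base <- rec$predicted_raw   # unrounded carry-over between steps
    prov <- "predicted"
  }
  dplyr::bind_rows(out)
}

#' Summarise a vector of percentage errors
#'
#' Computes n, mean, median (midpoint of the two central order statistics
#' for even n), min, max, and the proportion of errors whose absolute value
#' is within a threshold (default 6 percentage points). Mean and median are
#' both always reported: for skewed error vectors they can differ
#' substantially, and summaries quoted in the literature do not always say
#' which one they are.
#'
#' @param errors non-empty numeric vector of percentage errors.
#' @param threshold absolute-error threshold in percentage points
#'   (default 6).
#' @return an object of class `error_summary`: a list with elements `n`,
#'   `mean`, `median`, `min`, `max`, `prop_within_threshold`, `threshold`.
#' @examples
#' error_summary(c(-2.9, 2.5, -4.4))
#' @export
error_summary <- function(errors, threshold = 6) {
  if (length(errors) == 0L) stop_input("`errors` must be non-empty")
  if (anyNA(errors)) stop_input("`errors` contains missing values")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_config("`threshold` must be a single positive number")
  }
  structure(
    list(
      n = length(errors),
      mean = mean(errors),
      median = stats::median(errors),
      min = min(errors),
      max = max(errors),
      prop_within_threshold = mean(abs(errors) <= threshold),
      threshold = threshold
    ),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Percentage-error summary (n = %d)\n", x$n))
  cat(sprintf("  mean:   %.2f%%\n", x$mean))
  cat(sprintf("  median: %.2f%%\n", x$median))
  cat(sprintf("  range:  [%.2f%%, %.2f%%]\n", x$min, x$max))
  cat(sprintf("  within +/-%g%%: %.0f%% of regions\n",
              x$threshold, 100 * x$prop_within_threshold))
  invisible(x)
}

#' Paired comparison of two per-region error vectors
#'
#' Compares the absolute percentage errors of two models region by region
#' (e.g. the RSVI-ratio model against an external projection). Regions
#' present in only one vector are dropped with a warning.
#'
#' @param errors_a,errors_b region-named numeric vectors of percentage
#'   errors.
#' @return an object of class `error_comparison`: list with a per-region
#'   tibble `by_region` (columns `region`, `error_a`, `error_b`,
#'   `abs_diff` = |a| - |b|), mean absolute errors `mae_a`/`mae_b`, and
#'   counts `n_a_better`, `n_b_better`, `n_tie`.
#' @examples
#' compare_error_vectors(c(r1 = -2, r2 = 4), c(r1 = 3, r2 = 4))
#' @export
compare_error_vectors <- function(errors_a, errors_b) {
  if (is.null(names(errors_a)) || is.null(names(errors_b))) {
    stop_config("both error vectors must be region-named")
  }
  common <- intersect(names(errors_a), names(errors_b))
  if (length(common) == 0L) stop_input("the two error vectors share no region")
  dropped <- setdiff(union(names(errors_a), names(errors_b)), common)
  if (length(dropped)) {
    warning(sprintf("dropping regions present in only one vector: %s",
                    paste(sort(dropped), collapse = ", ")),
            call. = FALSE)
  }
  common <- sort(common)
  a <- errors_a[common]
  b <- errors_b[common]
  abs_diff <- abs(a) - abs(b)
  structure(
    list(
      by_region = tibble::tibble(
        region = common,
        error_a = unname(a),
        error_b = unname(b),
        abs_diff = unname(abs_diff)
      ),
      mae_a = mean(abs(a)),
      mae_b = mean(abs(b)),
      n_a_better = sum(abs(a) < abs(b)),
      n_b_better = sum(abs(a) > abs(b)),
      n_tie = sum(abs(a) == abs(b))
    ),
    class = "error_comparison"
  )
}

#' @export
print.error_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired |%%error| comparison over %d regions\n", nrow(x$by_region)))
  cat(sprintf("  MAE a: %.2f%%   MAE b: %.2f%%\n", x$mae_a, x$mae_b))
  cat(sprintf("  a better: %d   b better: %d   ties: %d\n",
              x$n_a_better, x$n_b_better, x$n_tie))
  invisible(x)
}
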