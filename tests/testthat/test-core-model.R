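test_that("rsvi_ratio returns full precision with 3-decimal display rounding", {
  expect_equal(round_half_away(rsvi_ratio(86, 89), 3), 0.966)
  # 98/90 = 1.0889: display rounds half-to-nearest, not truncation
  expect_equal(round_half_away(rsvi_ratio(98, 90), 3), 1.089)
  expect_equal(rsvi_ratio(86, 89), 86 / 89)
  for (x in c(1, 37, 55.5, 100)) expect_equal(rsvi_ratio(x, x), 1)
})

test_that("rsvi_ratio rejects zero/missing denominators and out-of-range values", {
  expect_error(rsvi_ratio(50, 0, region = "AK", year = 2016),
               "insufficient search data.*AK|AK.*insufficient",
               class = "rsvicast_input_error")
  expect_error(rsvi_ratio(50, 0), "insufficient search data")
  expect_error(rsvi_ratio(101, 50), class = "rsvicast_input_error")
  expect_error(rsvi_ratio(50, -1), class = "rsvicast_input_error")
  expect_error(rsvi_ratio(NA, 50), class = "rsvicast_input_error")
})

test_that("predict_one_step uses the full-precision ratio, not the display ratio", {
  # 27550 x 86/89 = 26621.35 -> 26621; the 3-decimal ratio would give 26613
  rec <- predict_one_step(27550, 89, 86)
  expect_identical(rec$predicted, 26621)
  expect_false(rec$predicted == round_half_away(27550 * 0.966))
  expect_identical(predict_one_step(3008, 67, 70)$predicted, 3143)
  expect_identical(predict_one_step(1000, 80, 40)$predicted, 500)
  for (N in c(0, 17, 4811)) {
    expect_identical(predict_one_step(N, 63, 63)$predicted, N)
  }
  expect_error(predict_one_step(-1, 80, 80), class = "rsvicast_input_error")
})

test_that("one-step prediction is scale-equivariant and inverts exactly", {
  set.seed(11)
  for (i in 1:25) {
    N <- runif(1, 1, 2e5)
    a <- runif(1, 1, 100)
    b <- runif(1, 1, 100)
    k <- runif(1, 0.1, 10)
    expect_equal(predict_one_step(k * N, a, b)$predicted_raw,
                 k * predict_one_step(N, a, b)$predicted_raw)
    fwd <- predict_one_step(N, a, b)$predicted_raw
    back <- predict_one_step(fwd, b, a)$predicted_raw
    expect_equal(back, N, tolerance = 1e-12)
  }
})

test_that("percent_error matches the published convention and sign rule", {
  expect_equal(round_half_away(percent_error(26621, 27409), 1), -2.9)
  expect_equal(round_half_away(percent_error(30915, 27463), 1), 12.6)
  expect_identical(percent_error(123.4, 123.4), 0)
  expect_error(percent_error(10, 0), class = "rsvicast_input_error")
  expect_error(percent_error(10, -5), class = "rsvicast_input_error")
  set.seed(21)
  p <- runif(30, 1, 1000); a <- runif(30, 1, 1000)
  expect_identical(sign(percent_error(p, a)), sign(p - a))
})

test_that("chained forecasts carry unrounded bases and telescope", {
  cf <- chain_forecast(10000, 2000, c(`2000` = 80, `2001` = 88, `2002` = 66), 2)
  expect_equal(cf$predicted_raw, c(11000, 8250))
  expect_equal(cf$predicted_raw[2], 10000 * 66 / 80)   # telescoped form
  expect_identical(cf$base_provenance, c("actual", "predicted"))
  expect_identical(cf$target_year, c(2001L, 2002L))

  const <- chain_forecast(4321, 2010, c(`2010` = 70, `2011` = 70, `2012` = 70), 2)
  expect_equal(const$predicted_raw, c(4321, 4321))

  set.seed(31)
  for (i in 1:20) {
    h <- sample(2:6, 1)
    years <- 2000:(2000 + h)
    vals <- stats::setNames(runif(h + 1, 5, 100), years)
    cf <- chain_forecast(12345, 2000, vals, h)
    one <- 12345 * vals[as.character(2000 + h)] / vals["2000"]
    expect_equal(cf$predicted_raw[h], unname(one), tolerance = 1e-9)
  }
})

test_that("chain_forecast refuses missing or zero RSVI years, naming the year", {
  expect_error(chain_forecast(100, 2000, c(`2000` = 80, `2002` = 66), 2),
               "2001", class = "rsvicast_input_error")
  expect_error(chain_forecast(100, 2000, c(`2000` = 80, `2001` = 0, `2002` = 66), 2),
               "2001.*insufficient", class = "rsvicast_input_error")
  expect_error(chain_forecast(100, 2000, c(`2000` = 80, `2001` = 90), 0),
               class = "rsvicast_config_error")
})

test_that("error_summary agrees with a sort-based oracle and handles edge cases", {
  set.seed(41)
  for (i in 1:50) {
    e <- runif(sample(1:40, 1), -30, 30)
    s <- error_summary(e)
    o <- oracle_summary(e)
    expect_equal(s$mean, o$mean)
    expect_equal(s$median, o$median)
    expect_equal(s$min, o$min)
    expect_equal(s$max, o$max)
    expect_equal(s$prop_within_threshold, mean(abs(e) <= 6))
  }
  single <- error_summary(3.2)
  expect_equal(single$mean, 3.2)
  expect_equal(single$median, 3.2)
  expect_equal(single$min, single$max)
  expect_error(error_summary(numeric(0)), class = "rsvicast_input_error")
})

test_that("error_summary ordering invariants hold on random vectors", {
  set.seed(42)
  for (i in 1:20) {
    s <- error_summary(rnorm(sample(2:100, 1), 0, 10))
    expect_lte(s$min, s$median); expect_lte(s$median, s$max)
    expect_lte(s$min, s$mean); expect_lte(s$mean, s$max)
    expect_gte(s$prop_within_threshold, 0)
    expect_lte(s$prop_within_threshold, 1)
  }
})

test_that("compare_error_vectors counts wins and ties correctly", {
  idc <- compare_error_vectors(c(a = 1, b = -2), c(a = 1, b = -2))
  expect_equal(idc$by_region$abs_diff, c(0, 0))
  expect_equal(idc$n_tie, 2L)

  cmp <- compare_error_vectors(c(r1 = -2, r2 = 4), c(r1 = 3, r2 = 4))
  expect_equal(cmp$n_a_better, 1L)
  expect_equal(cmp$n_tie, 1L)
  expect_equal(cmp$mae_a, 3)
  expect_equal(cmp$mae_b, 3.5)

  set.seed(51)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    regions <- paste0("r", seq_len(n))
    a <- stats::setNames(round(runif(n, -10, 10)), regions)
    b <- stats::setNames(round(runif(n, -10, 10)), regions)
    got <- compare_error_vectors(a, b)
    want <- oracle_compare(a, b)
    expect_equal(got$n_a_better, want$wins_a)
    expect_equal(got$n_b_better, want$wins_b)
    expect_equal(got$n_tie, want$ties)
  }
})

test_that("compare_error_vectors inner-joins with a warning and rejects disjoint sets", {
  expect_warning(
    cmp <- compare_error_vectors(c(x = 1, y = 2), c(y = 3, z = 4)),
    "x.*z|z.*x")
  expect_identical(cmp$by_region$region, "y")
  expect_error(
    suppressWarnings(compare_error_vectors(c(x = 1), c(z = 2))),
    class = "rsvicast_input_error")
})
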