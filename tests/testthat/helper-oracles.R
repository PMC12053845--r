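# brute-force reference implementations kept deliberately naive and
# independent of the package's own code paths

oracle_summary <- function(e) {
  s <- sort(e)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(n = n, mean = sum(s) / n, median = med, min = s[1], max = s[n])
}

oracle_compare <- function(a, b) {
  regions <- sort(intersect(names(a), names(b)))
  wins_a <- 0L; wins_b <- 0L; ties <- 0L
  for (r in regions) {
    if (abs(a[[r]]) < abs(b[[r]])) wins_a <- wins_a + 1L
    else if (abs(a[[r]]) > abs(b[[r]])) wins_b <- wins_b + 1L
    else ties <- ties + 1L
  }
  list(wins_a = wins_a, wins_b = wins_b, ties = ties)
}

write_tmp_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "input.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_multitimeline <- function(values, months = seq_along(values),
                                years = 2016, topic = "cancer",
                                region = "United States",
                                dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "multiTimeline.csv")
  ym <- sprintf("%d-%02d", rep_len(years, length(values)), months)
  writeLines(c(
    "Category: All categories",
    "",
    sprintf("Month,%s: (%s)", topic, region),
    paste(ym, values, sep = ",")
  ), path)
  path
}

# model inputs reconstructed from the packaged one-step validation table
table1_inputs <- function() fixture_series("table1_2017")
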