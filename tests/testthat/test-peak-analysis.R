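china_health <- smeed_params(a = 273.42, b = 5.742)

traj_series <- function(years, x, population = 1e7) {
  country_series("Traj", data.frame(
    year = years, deaths = pmax(x, 0.01) * population / 1e5,
    vehicles = x * population, population = population))
}

test_that("peak-period labels cover before/exact/bracketing/after correctly", {
  s <- traj_series(2000:2004, c(0.2, 0.35, 0.5, 0.65, 0.8))
  expect_equal(locate_peak_year(s, 0.127), "Before 2000")
  expect_equal(locate_peak_year(s, 0.9), "After 2004")
  expect_equal(locate_peak_year(s, 0.35), "2001")
  expect_equal(locate_peak_year(s, 0.40), "2001-2002")

  # near-match within the 3-decimal reporting tolerance counts as exact
  s2 <- traj_series(2010:2012, c(0.1600, 0.17401, 0.1900))
  expect_equal(locate_peak_year(s2, 0.174), "2011")
})

test_that("exact-year matching reproduces the China-health style label", {
  s <- traj_series(2010:2013, c(0.150, 0.162, 0.1740, 0.185))
  expect_equal(locate_peak_year(s, 0.174), "2012")
})

test_that("gap years produce gap-spanning bracket labels", {
  s <- traj_series(c(1970, 1980, 1990, 1991, 1992), c(0.1, 0.2, 0.4, 0.45, 0.5))
  expect_equal(locate_peak_year(s, 0.25), "1980-1990")
})

test_that("non-monotone trajectories warn and use the first crossing", {
  s <- traj_series(2000:2004, c(0.1, 0.3, 0.2, 0.35, 0.5))
  expect_warning(lab <- locate_peak_year(s, 0.25), "non-monotone")
  expect_equal(lab, "2000-2001")
})

test_that("peak labels ignore the death counts entirely", {
  years <- 2000:2006
  x <- seq(0.05, 0.35, length.out = 7)
  pop <- 2e7
  s1 <- country_series("A", data.frame(year = years, deaths = 100,
                                       vehicles = x * pop, population = pop))
  s2 <- country_series("A", data.frame(year = years, deaths = 7000,
                                       vehicles = x * pop, population = pop))
  for (px in c(0.02, 0.1, 0.2, 0.5))
    expect_equal(locate_peak_year(s1, px), locate_peak_year(s2, px))
})

test_that("summarize_peak combines closed-form peaks with the trajectory", {
  s <- traj_series(2002:2013, seq(0.02, 0.20, length.out = 12))
  sum1 <- summarize_peak(s, china_health)
  expect_equal(round(sum1$pmm, 1), 17.5)
  expect_equal(round(sum1$peak_x, 3), 0.174)
  expect_equal(sum1$pmm, predict_mortality(china_health, sum1$peak_x))

  mono <- params_from_linear(5, 0.5)
  sum2 <- summarize_peak(s, mono)
  expect_true(is.na(sum2$pmm))
  expect_true(is.na(sum2$peak_x))
  expect_match(sum2$note, "no interior peak")
})

test_that("comparison table ranks, annotates ranges and flags early peaks", {
  fx <- table_fixtures()
  label <- ifelse(fx$source == "OECD online library", fx$country,
                  paste0(fx$country, "-", sub(" data", "", fx$source)))
  summaries <- lapply(seq_len(nrow(fx)), function(i) {
    s <- data.frame(country = label[i], source_note = fx$source[i],
                    pmm = fx$pmm[i], peak_x = fx$peak_x[i],
                    peak_period = fx$peak_period[i], note = "")
    class(s) <- c("peak_summary", "data.frame")
    s
  })
  others <- label[fx$source == "OECD online library"]
  tab <- comparison_table(summaries, reference = others)
  expect_equal(tab$peak_x, sort(tab$peak_x))
  expect_true(tab$below_reference_min[tab$country == "China-police"])
  expect_false(tab$below_reference_min[tab$country == "China-health"])
  expect_false(any(tab$below_reference_min[tab$country %in% others]))
  expect_equal(attr(tab, "pmm_range"), c(11.5, 38.7))
  expect_equal(attr(tab, "peak_x_range"), c(0.061, 0.369))
  # the 13-country reference band matches the published framing
  ref <- tab[tab$country %in% others, ]
  expect_equal(range(ref$pmm), c(13.9, 38.7))
  expect_equal(min(ref$peak_x), 0.127)
})

test_that("comparison table handles single rows and ties deterministically", {
  s <- traj_series(2000:2005, seq(0.05, 0.3, length.out = 6))
  one <- summarize_peak(s, china_health)
  tab1 <- comparison_table(list(one))
  expect_equal(nrow(tab1), 1)
  expect_false(any(tab1$below_reference_min))

  a <- one; a$country <- "Zeta"
  b <- one; b$country <- "Alpha"
  tab2 <- comparison_table(list(a, b))
  expect_equal(tab2$country, c("Alpha", "Zeta"))
})

test_that("peak report exports with display rounding", {
  s <- traj_series(2000:2005, seq(0.05, 0.3, length.out = 6))
  tab <- comparison_table(list(summarize_peak(s, china_health)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_report(tab, f)
  back <- utils::read.csv(f)
  expect_equal(back$pmm, 17.5)
  expect_equal(back$peak_x, 0.174)
})
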