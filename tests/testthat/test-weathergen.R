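# Stochastic weather generator: statistic recovery, physical bounds,
# hemisphere phase, seeding, and the weather file format.

test_that("built-in sites carry the published climate normals", {
  s <- builtin_sites()
  expect_length(s, 6)
  expect_equal(s[["RR"]]$mean_temp, 9.8)
  expect_equal(s[["RR"]]$annual_precip, 700)
  expect_equal(s[["RR"]]$mean_radiation, 9.8)
  expect_equal(s[["GO"]]$latitude, -46.12)
  expect_equal(s[["GO"]]$annual_precip, 976)
  expect_equal(sum(vapply(s, `[[`, "", "country") == "NZ"), 3L)
  expect_true(all(vapply(s, function(x)
    (x$country == "NZ") == (x$latitude < 0), TRUE)))
})

test_that("site_climate rejects inconsistent inputs", {
  expect_error(site_climate("XX", "NZ", 45, 170, 10, 600, 12), "latitude")
  expect_error(site_climate("XX", "UK", 52, 0, 10, 600, -1), "mean_radiation")
  expect_error(site_climate("XX", "UK", 52, 0, 10, 600, 12, wet_day_prob = 0),
               "wet_day_prob")
})

test_that("generation is seed-deterministic and input-validated", {
  a <- generate_weather("RR", 3, seed = 11)
  b <- generate_weather("RR", 3, seed = 11)
  expect_identical(a$days, b$days)
  c <- generate_weather("RR", 3, seed = 12)
  expect_false(identical(a$days, c$days))
  expect_error(generate_weather("RR", 0, seed = 1), "n_years")
  expect_error(generate_weather("XX", 3, seed = 1), "unknown site")
})

test_that("100-year series recover the site climate statistics", {
  for (sid in c("RR", "GO")) {
    site <- builtin_sites()[[sid]]
    s <- summarize_climate(generate_weather(sid, 100, seed = 404))
    expect_lt(abs(s$mean_temp - site$mean_temp), 0.3)
    expect_lt(abs(s$annual_precip / site$annual_precip - 1), 0.03)
    expect_lt(abs(s$mean_radiation / site$mean_radiation - 1), 0.03)
  }
})

test_that("generated weather respects physical bounds", {
  w <- generate_weather("PU", 20, seed = 5)
  d <- w$days
  expect_true(all(d$precip >= 0))
  expect_true(all(d$tmax >= d$tmin))
  expect_true(all(d$radiation >= 0))
  ra <- extraterrestrial_radiation(w$site$latitude, d$doy)
  expect_true(all(d$radiation <= ra))
})

test_that("seasonality is phase-shifted six months in the south", {
  nz <- generate_weather("PU", 10, seed = 3)$days
  uk <- generate_weather("RR", 10, seed = 3)$days
  summer_s <- nz$doy <= 59 | nz$doy >= 335   # Dec-Feb
  winter_s <- nz$doy >= 152 & nz$doy <= 243  # Jun-Aug
  expect_gt(mean(nz$tmax[summer_s]), mean(nz$tmax[winter_s]))
  expect_gt(mean(uk$tmax[winter_s]), mean(uk$tmax[summer_s]))
  month_mean <- function(d) vapply(1:12, function(m)
    mean(d$tmax[ceiling(d$doy / 30.44) == m]), 0)
  expect_equal((which.max(month_mean(uk)) - which.max(month_mean(nz))) %% 12, 6)
})

test_that("summarize_climate reproduces country means and constants", {
  s <- builtin_sites()
  cn <- vapply(s, `[[`, "", "country")
  uk <- summarize_climate(unname(s[cn == "UK"]))
  expect_equal(uk$mean_temp, 9.3, tolerance = 1e-9)
  expect_equal(uk$annual_precip, 681, tolerance = 1e-9)
  nz <- summarize_climate(unname(s[cn == "NZ"]))
  expect_equal(nz$annual_precip, 956, tolerance = 1e-9)
  cw <- constant_weather(365, tmin = 6, tmax = 14, precip = 2, radiation = 11)
  sm <- summarize_climate(cw)
  expect_equal(sm$mean_temp, 10)
  expect_equal(sm$annual_precip, 730)
  expect_equal(sm$mean_radiation, 11)
  expect_error(summarize_climate(list()), "non-empty")
})

test_that("weather files round-trip bit-exactly", {
  w <- generate_weather("GO", 3, seed = 21)
  path <- withr::local_tempfile(fileext = ".txt")
  write_weather(w, path)
  r <- read_weather(path)
  expect_equal(r$days, w$days)
  expect_equal(r$site, w$site)
  expect_identical(r$n_years, w$n_years)
  expect_identical(r$seed, w$seed)
})

test_that("malformed weather files are rejected with line numbers", {
  w <- generate_weather("RR", 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_weather(w, path)
  lines <- readLines(path)
  nhdr <- sum(startsWith(lines, "#"))

  bad <- lines
  f <- strsplit(bad[nhdr + 7], "\t")[[1]]; f[4] <- "-1.00"
  bad[nhdr + 7] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_error(read_weather(path), sprintf("precipitation at line %d", nhdr + 7))

  bad <- lines
  f <- strsplit(bad[nhdr + 3], "\t")[[1]]; f[2] <- "30"; f[3] <- "10"
  bad[nhdr + 3] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_error(read_weather(path), sprintf("tmax < tmin at line %d", nhdr + 3))

  bad <- lines
  bad[nhdr + 5] <- "1\t2\t3"
  writeLines(bad, path)
  expect_error(read_weather(path), sprintf("line %d", nhdr + 5))

  bad <- lines
  f <- strsplit(bad[nhdr + 10], "\t")[[1]]; f[1] <- "200"
  bad[nhdr + 10] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_error(read_weather(path), "non-monotone")
})

test_that("year bookkeeping survives a round trip", {
  w <- generate_weather("RR", 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_weather(w, path)
  r <- read_weather(path)
  expect_identical(r$n_years, 4L)
  expect_identical(nrow(r$days), 4L * 365L)
  expect_identical(max(r$days$year), 4L)
})
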