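test_that("canonical CSV round-trips byte-identically", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,treatment,plot,collar,flux,tsoil,swc",
    "2014-06-15T09:00:00,trench,p1,c1,1.52,21.3,0.11",
    "2014-06-15T09:00:00,trench,p1,c2,1.7,21.3,0.11",
    "2014-06-15T10:00:00,shrub,p2,c1,2.05,,"
  ), f)
  obs <- read_flux_csv(f)
  expect_equal(nrow(obs), 3)
  expect_s3_class(obs$timestamp, "POSIXct")
  expect_true(is.na(obs$tsoil[3]))

  g <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(obs, g)
  expect_identical(readLines(g), readLines(f))
  # and writing is a fixed point
  h <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(read_flux_csv(g), h)
  expect_identical(readLines(h), readLines(g))
})

test_that("malformed rows are rejected with a row-indexed report", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,treatment,plot,collar,flux,tsoil,swc",
    "2014-06-15T09:00:00,trench,p1,c1,1.52,,",
    "2014-06-15T10:00:00,trench,p1,c1,NA,,",
    "not-a-time,trench,p1,c1,1.0,,",
    "2014-06-15T12:00:00,trench,p1,c1,1.1,,1.7"
  ), f)
  obs <- suppressMessages(read_flux_csv(f))
  expect_equal(nrow(obs), 1)
  rej <- attr(obs, "rejected")
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_match(rej$reason[1], "flux")
  expect_match(rej$reason[2], "timestamp")
  expect_match(rej$reason[3], "moisture")
})

test_that("schema mapping resolves alternative column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,trt,ring,Rs", "2014-06-15T09:00:00,trench,c1,1.5"), f)
  obs <- read_flux_csv(f, schema = c(timestamp = "time", treatment = "trt",
                                     collar = "ring", flux = "Rs"))
  expect_equal(obs$flux, 1.5)
  expect_true(is.na(obs$plot))
  expect_error(read_flux_csv(f), class = "dielstab_error_config")
})

test_that("empty and missing inputs raise classed errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,treatment,plot,collar,flux,tsoil,swc", f)
  expect_error(read_flux_csv(f), class = "dielstab_error_empty")
  expect_error(read_flux_csv(file.path(tempdir(), "no-such.csv")),
               class = "dielstab_error_config")
})

test_that("simulator CSV of 2 treatments x 3 collars x 24 h reads back as 144 observations", {
  cfg <- sim_config(treatments = c("trench", "shrub"), collars = 3,
                    campaign_dates = "2014-06-15", seed = 4)
  sim <- simulate_campaigns(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(sim$observations, f)
  expect_equal(nrow(read_flux_csv(f)), 2 * 3 * 24)
})

test_that("assemble_campaigns bins, averages collars, and flags completeness", {
  obs <- make_obs(hours = 0:23, collars = 3)
  camp <- assemble_campaigns(obs)
  expect_equal(length(unique(camp$campaign_id)), 1)
  expect_equal(unique(camp$n), 24L)
  expect_true(all(camp$complete))
  expect_equal(sort(camp$hour), 0:23)

  # hour 13 missing: still one campaign, n = 23, incomplete
  camp2 <- assemble_campaigns(make_obs(hours = setdiff(0:23, 13)))
  expect_equal(length(unique(camp2$campaign_id)), 1)
  expect_equal(unique(camp2$n), 23L)
  expect_false(any(camp2$complete))

  # collar averaging is the unweighted mean
  obs3 <- make_obs(hours = 9, collars = 2,
                   flux_fun = function(h, c) ifelse(c == 1, 1.0, 3.0))
  expect_equal(assemble_campaigns(obs3)$flux, 2.0)
})

test_that("campaigns wrap midnight and split on the window length", {
  # 9:00 day T to 8:00 day T+1, as in a field campaign
  h1 <- make_obs(date = "2014-06-15", hours = 9:23, collars = 1)
  h2 <- make_obs(date = "2014-06-16", hours = 0:8, collars = 1)
  camp <- assemble_campaigns(dplyr::bind_rows(h1, h2))
  expect_equal(length(unique(camp$campaign_id)), 1)
  expect_equal(unique(camp$n), 24L)
  expect_true(all(camp$complete))

  # 48 consecutive hours -> two complete campaigns
  two_days <- dplyr::bind_rows(make_obs(date = "2014-06-15", collars = 1),
                               make_obs(date = "2014-06-16", collars = 1))
  camp48 <- assemble_campaigns(two_days)
  expect_equal(length(unique(camp48$campaign_id)), 2)
  expect_true(all(camp48$n == 24))
})

test_that("assemble_campaigns never invents hour slots", {
  obs <- make_obs(hours = c(0:5, 8:12), collars = 2)
  camp <- assemble_campaigns(obs)
  in_slots <- sort(unique(as.integer(format(obs$timestamp, "%H"))))
  expect_equal(sort(camp$hour), in_slots)
  expect_equal(assemble_campaigns(obs[0, ]), assemble_campaigns(obs)[0, ])
})

test_that("min_collars filters sparse hour bins", {
  full <- make_obs(hours = 0:23, collars = 3)
  drop <- full$collar == "c3" & format(full$timestamp, "%H") == "12"
  camp <- assemble_campaigns(full[!drop, ], min_collars = 3)
  expect_equal(unique(camp$n), 23L)  # hour 12 fell below the collar threshold
})

test_that("season classification follows the month map", {
  sp <- season_spec()
  expect_equal(classify_season(as.Date("2014-06-10"), sp), "dry")
  expect_equal(classify_season(as.Date("2014-01-10"), sp), "wet")
  all_wet <- season_spec(month_to_season = rep("wet", 12))
  dates <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "week")
  expect_true(all(classify_season(dates, all_wet) == "wet"))
  expect_error(season_spec(month_to_season = rep("x", 11)),
               class = "dielstab_error_config")
  expect_error(season_spec(month_to_season = c(rep("a", 10), "b", "c")),
               class = "dielstab_error_config")
})

test_that("hydrological-year labels follow the November convention", {
  expect_equal(assign_hydro_year(as.Date("2013-11-15"), 11), "HY2014")
  expect_equal(assign_hydro_year(as.Date("2014-10-15"), 11), "HY2014")
  expect_equal(assign_hydro_year(as.Date("2014-11-01"), 11), "HY2015")
  # degenerate start: hydro year equals calendar year
  dates <- seq(as.Date("2013-01-01"), as.Date("2015-12-01"), by = "month")
  expect_equal(assign_hydro_year(dates, 1),
               sprintf("HY%s", format(dates, "%Y")))
})

test_that("every date gets exactly one season and one hydro year", {
  sp <- season_spec()
  dates <- seq(as.Date("2012-01-01"), as.Date("2016-12-31"), by = "day")
  s <- classify_season(dates, sp)
  hy <- assign_hydro_year(dates, sp$hydro_year_start_month)
  expect_false(anyNA(s))
  expect_false(anyNA(hy))
  expect_setequal(unique(s), c("dry", "wet"))
  rec <- annotate_calendar(tibble::tibble(timestamp = as.POSIXct(dates, tz = "UTC")), sp)
  expect_identical(rec$season, s)
  expect_identical(rec$hydro_year, hy)
})
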