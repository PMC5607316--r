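#' @title Synthetic diel-cycle flux simulator
#' @name diel_simulator
#' @description Generates 24-hour campaigns and mid-day monitoring series
#'   with a known ground-truth diel structure: a sinusoidal soil-temperature
#'   cycle drives flux through a Q10 response with an optional
#'   Michaelis-type moisture modifier and mean-one multiplicative lognormal
#'   noise.
NULL

#' Simulation configuration
#'
#' Defaults emulate a semiarid Mediterranean shrubland monitoring design:
#' eight 24-hour campaigns (four per season under the default season map),
#' monthly mid-day (12:00-14:00) monitoring over one hydrological year,
#' three collars per treatment, soil temperature peaking at 14:00, Q10 = 2,
#' and 10% multiplicative noise.
#'
#' @param t_mean Mean diel soil temperature, degrees C.
#' @param t_amplitude Half-range of the diel temperature cycle, degrees C.
#' @param t_peak_hour Clock hour of the temperature maximum (fractional
#'   allowed).
#' @param q10 Factor by which flux multiplies per 10 degrees C warming.
#' @param r_base Flux at the 10 degrees C reference temperature (before the
#'   moisture modifier), umol CO2 m-2 s-1.
#' @param moisture_level Volumetric soil water content, m3 m-3; a scalar, or
#'   a named vector keyed by `"YYYY-MM-DD"` date for per-day values.
#' @param moisture_halfsat Half-saturation constant of the moisture
#'   modifier `theta / (theta + halfsat)`, m3 m-3; 0 disables the modifier's
#'   dependence on date only when `moisture_level` is constant.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 for noise-free data).
#' @param collars Collars per treatment.
#' @param treatments Treatment labels to simulate.
#' @param campaign_dates Dates (coercible by [as.Date()]) of the 24-hour
#'   campaigns.
#' @param monitoring_dates Dates of the routine monitoring visits.
#' @param monitoring_window Numeric `c(start, end)` clock-hour window for
#'   monitoring timestamps.
#' @param seed Integer seed driving all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_mean = 18, t_amplitude = 5, t_peak_hour = 14,
                       q10 = 2, r_base = 1.5,
                       moisture_level = 0.15, moisture_halfsat = 0.05,
                       noise_cv = 0.1, collars = 3, treatments = "trench",
                       campaign_dates = c("2014-06-15", "2014-10-15",
                                          "2015-06-15", "2015-10-15",
                                          "2014-11-15", "2015-01-15",
                                          "2015-04-15", "2015-11-15"),
                       monitoring_dates = NULL,
                       monitoring_window = c(12, 14), seed = 1L) {
  if (q10 <= 0) ds_abort("q10 must be positive", "config")
  if (r_base <= 0) ds_abort("r_base must be positive", "config")
  if (noise_cv < 0) ds_abort("noise_cv must be nonnegative", "config")
  if (collars < 1) ds_abort("collars must be >= 1", "config")
  if (length(monitoring_window) != 2 || monitoring_window[1] < 0 ||
      monitoring_window[2] > 24 || monitoring_window[1] >= monitoring_window[2]) {
    ds_abort("monitoring_window must be an increasing pair within [0, 24]", "config")
  }
  if (is.null(monitoring_dates)) {
    monitoring_dates <- seq(as.Date("2014-11-15"), as.Date("2015-10-15"), by = "month")
  }
  structure(list(
    t_mean = t_mean, t_amplitude = t_amplitude, t_peak_hour = t_peak_hour,
    q10 = q10, r_base = r_base, moisture_level = moisture_level,
    moisture_halfsat = moisture_halfsat, noise_cv = noise_cv,
    collars = as.integer(collars), treatments = treatments,
    campaign_dates = as.Date(campaign_dates),
    monitoring_dates = as.Date(monitoring_dates),
    monitoring_window = monitoring_window, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  T: %.1f +/- %.1f C, peak %.1f h; Q10 %.2f, r_base %.2f\n",
              x$t_mean, x$t_amplitude, x$t_peak_hour, x$q10, x$r_base))
  cat(sprintf("  noise CV %.2f, %d collar(s), %d treatment(s)\n",
              x$noise_cv, x$collars, length(x$treatments)))
  cat(sprintf("  %d campaign date(s), %d monitoring date(s), window %g-%g h, seed %d\n",
              length(x$campaign_dates), length(x$monitoring_dates),
              x$monitoring_window[1], x$monitoring_window[2], x$seed))
  invisible(x)
}

moisture_for_date <- function(cfg, date) {
  th <- cfg$moisture_level
  if (length(th) == 1) return(unname(th))
  if (is.null(date)) {
    ds_abort("per-day moisture_level requires a date", "config")
  }
  key <- format(as.Date(date), "%Y-%m-%d")
  if (!key %in% names(th)) {
    ds_abort(sprintf("no moisture_level entry for date %s", key), "config")
  }
  unname(th[[key]])
}

diel_temperature <- function(hour, cfg) {
  cfg$t_mean + cfg$t_amplitude * cos(2 * pi * (hour - cfg$t_peak_hour) / 24)
}

#' Noise-free diel flux
#'
#' Deterministic flux at a (fractional) clock hour:
#' `T(h) = t_mean + t_amplitude * cos(2*pi*(h - t_peak_hour)/24)`, then
#' `flux = r_base * q10^((T - 10)/10) * theta / (theta + moisture_halfsat)`.
#'
#' @param hour Fractional clock hour(s).
#' @param cfg A [sim_config()].
#' @param moisture Volumetric water content; defaults to the config's
#'   constant level.
#' @return Flux, umol CO2 m-2 s-1.
#' @export
diel_flux <- function(hour, cfg, moisture = NULL) {
  theta <- if (is.null(moisture)) moisture_for_date(cfg, NULL) else moisture
  temp <- diel_temperature(hour, cfg)
  cfg$r_base * cfg$q10^((temp - 10) / 10) * theta / (theta + cfg$moisture_halfsat)
}

#' Ground-truth diel profile for one day
#'
#' @param cfg A [sim_config()].
#' @param date Date (used to look up per-day moisture); `NULL` for the
#'   constant-moisture profile.
#' @return Tibble `hour` (0-23), `true_flux`, `true_relative` (the target of
#'   MRD estimation), with the true daily mean as attribute `"daily_mean"`.
#' @export
ground_truth <- function(cfg, date = NULL) {
  theta <- moisture_for_date(cfg, date)
  f <- diel_flux(0:23, cfg, moisture = theta)
  m <- mean(f)
  out <- tibble::tibble(hour = 0:23, true_flux = f, true_relative = f / m - 1)
  attr(out, "daily_mean") <- m
  out
}

# mean-one multiplicative lognormal noise: sigma chosen so CV matches
noise_sigma <- function(cv) sqrt(log(1 + cv^2))

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate 24-hour measurement campaigns
#'
#' For every campaign date, treatment, collar and hour 0-23, draws
#' `flux = diel_flux(h) * exp(eps)` with
#' `eps ~ Normal(-sigma^2/2, sigma)` so the noise multiplier has mean one.
#' All randomness is driven by the config seed; a fixed seed reproduces the
#' observations exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `observations` (flux-observation tibble, see
#'   [read_flux_csv()]) and `truth` (per-date [ground_truth()] rows plus
#'   `date` and `true_daily_mean`).
#' @export
simulate_campaigns <- function(cfg) {
  if (length(cfg$campaign_dates) == 0) ds_abort("no campaign dates", "config")
  sigma <- noise_sigma(cfg$noise_cv)
  grid <- expand.grid(hour = 0:23, collar = seq_len(cfg$collars),
                      treatment = cfg$treatments,
                      date = cfg$campaign_dates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  theta <- vapply(grid$date, function(d) moisture_for_date(cfg, d), double(1))
  base <- diel_flux(grid$hour, cfg, moisture = theta)
  eps <- with_sim_seed(cfg$seed, rnorm(nrow(grid), -sigma^2 / 2, sigma))
  obs <- tibble::tibble(
    timestamp = as.POSIXct(paste0(format(grid$date), "T",
                                  sprintf("%02d:00:00", grid$hour)),
                           tz = "UTC", format = "%Y-%m-%dT%H:%M:%S"),
    treatment = grid$treatment,
    plot = "p1",
    collar = sprintf("c%d", grid$collar),
    flux = base * exp(eps),
    tsoil = diel_temperature(grid$hour, cfg),
    swc = theta
  ) |>
    dplyr::arrange(.data$timestamp, .data$treatment, .data$collar)

  truth <- dplyr::bind_rows(lapply(cfg$campaign_dates, function(d) {
    gt <- ground_truth(cfg, d)
    gt$date <- d
    gt$true_daily_mean <- attr(gt, "daily_mean")
    gt
  }))
  list(observations = obs, truth = truth)
}

#' Simulate a routine monitoring series
#'
#' One record per date, treatment and collar, at a time drawn uniformly
#' within the monitoring window (truncated to the minute), with the same
#' noise model as [simulate_campaigns()].
#'
#' @param cfg A [sim_config()].
#' @return List with `records` (tibble `timestamp`, `treatment`, `collar`,
#'   `flux`) and `truth` (tibble `date`, `true_daily_mean`).
#' @export
simulate_monitoring <- function(cfg) {
  if (length(cfg$monitoring_dates) == 0) ds_abort("no monitoring dates", "config")
  sigma <- noise_sigma(cfg$noise_cv)
  grid <- expand.grid(collar = seq_len(cfg$collars), treatment = cfg$treatments,
                      date = cfg$monitoring_dates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  draws <- with_sim_seed(cfg$seed + 1L, {
    list(h = runif(nrow(grid), cfg$monitoring_window[1], cfg$monitoring_window[2]),
         eps = rnorm(nrow(grid), -sigma^2 / 2, sigma))
  })
  h <- floor(draws$h * 60) / 60  # minute resolution
  theta <- vapply(grid$date, function(d) moisture_for_date(cfg, d), double(1))
  records <- tibble::tibble(
    timestamp = as.POSIXct(format(grid$date), tz = "UTC") + round(h * 3600),
    treatment = grid$treatment,
    plot = "p1",
    collar = sprintf("c%d", grid$collar),
    flux = diel_flux(h, cfg, moisture = theta) * exp(draws$eps),
    tsoil = diel_temperature(h, cfg),
    swc = theta
  ) |>
    dplyr::arrange(.data$timestamp, .data$treatment, .data$collar)
  truth <- tibble::tibble(
    date = cfg$monitoring_dates,
    true_daily_mean = vapply(cfg$monitoring_dates, function(d) {
      attr(ground_truth(cfg, d), "daily_mean")
    }, double(1))
  )
  list(records = records, truth = truth)
}
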