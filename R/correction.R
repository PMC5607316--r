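#' @title Correction of non-optimally timed flux measurements
#' @name correction
#' @description Divides measured fluxes by (1 + MRD) for their sampling hour,
#'   using season- and treatment-specific correction tables, and aggregates
#'   corrected/uncorrected seasonal and annual budgets with percent
#'   differences.
NULL

#' Correct a flux for its sampling-time bias
#'
#' A measurement taken at an hour whose mean relative difference is `mrd`
#' systematically deviates from the daily mean by a factor `(1 + mrd)`;
#' dividing by that factor yields the daily-mean-equivalent flux.
#'
#' @param rs Measured flux (vectorised).
#' @param mrd Mean relative difference for the sampling hour (`> -1`).
#' @return Corrected flux `rs / (1 + mrd)`.
#' @examples
#' correct_flux(1.2, 0.2)  # 1.0
#' @export
correct_flux <- function(rs, mrd) {
  if (any(mrd <= -1)) {
    ds_abort("mrd <= -1 gives a nonpositive divisor; correction undefined", "domain")
  }
  rs / (1 + mrd)
}

#' Build a correction table from stability profiles
#'
#' Stacks per-(treatment, season) stability profiles into a lookup of MRD
#' offsets for hours 0-23. Hours absent from a profile are filled by circular
#' linear interpolation between the nearest observed hours and flagged
#' `interpolated`.
#'
#' @param profiles Tibble of row-bound [stability_profile()] outputs with a
#'   `season` column (use the profile's `scope`), i.e. columns `treatment`,
#'   `season`, `hour`, `mrd`.
#' @return Tibble `treatment`, `season`, `hour` (0-23), `mrd`,
#'   `interpolated`.
#' @export
build_correction_table <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    ds_abort("no stability profiles supplied", "empty")
  }
  if (!"season" %in% names(profiles) && "scope" %in% names(profiles)) {
    profiles <- dplyr::rename(profiles, season = "scope")
  }
  profiles |>
    dplyr::group_by(.data$treatment, .data$season) |>
    dplyr::reframe(fill_hours_circular(.data$hour, .data$mrd)) |>
    dplyr::ungroup()
}

# circular linear interpolation of per-hour values onto the full 0-23 grid
fill_hours_circular <- function(hour, mrd) {
  full <- tibble::tibble(hour = 0:23, mrd = NA_real_, interpolated = TRUE)
  full$mrd[hour + 1L] <- mrd
  full$interpolated[hour + 1L] <- FALSE
  miss <- which(is.na(full$mrd))
  if (length(miss) == 0) return(full)
  have <- which(!is.na(full$mrd)) - 1L
  if (length(have) == 1) {
    full$mrd[miss] <- full$mrd[have + 1L]
    return(full)
  }
  for (h in miss - 1L) {
    d_prev <- (h - have) %% 24L   # circular distance back to each known hour
    d_next <- (have - h) %% 24L
    i0 <- which.min(d_prev); i1 <- which.min(d_next)
    d0 <- d_prev[i0]; d1 <- d_next[i1]
    m0 <- full$mrd[have[i0] + 1L]; m1 <- full$mrd[have[i1] + 1L]
    full$mrd[h + 1L] <- (d1 * m0 + d0 * m1) / (d0 + d1)
  }
  full
}

#' Apply a correction table to a monitoring series
#'
#' Each record's flux is divided by `(1 + offset)`, where the offset is the
#' mean of the table's MRD values over the clock hours overlapped by the
#' record's measurement window (the single hour of the timestamp when no
#' window is given). Records whose (treatment, season) is absent from the
#' table pass through uncorrected and are flagged.
#'
#' @param records Monitoring tibble with `timestamp`, `treatment`, `flux` and
#'   `season` (see [annotate_calendar()]).
#' @param table Correction table from [build_correction_table()].
#' @param window Optional numeric `c(start_hour, end_hour)` measurement
#'   window applied to every record, e.g. `c(12, 14)` covers clock hours 12
#'   and 13.
#' @return `records` with added `flux_corrected`, `offset_used` and
#'   `flagged` columns.
#' @export
apply_correction_series <- function(records, table, window = NULL) {
  if (nrow(records) == 0) return(
    dplyr::mutate(records, flux_corrected = double(), offset_used = double(),
                  flagged = logical()))
  if (!"season" %in% names(records)) {
    ds_abort("records lack a season column; run annotate_calendar() first", "config")
  }
  hours_of <- function(ts) {
    if (is.null(window)) {
      as.integer(format(ts, "%H", tz = "UTC"))
    } else {
      rep(NA_integer_, length(ts))  # window hours handled below
    }
  }
  win_hours <- if (!is.null(window)) {
    seq.int(floor(window[1]), ceiling(window[2]) - 1L) %% 24L
  } else NULL

  offs <- vapply(seq_len(nrow(records)), function(i) {
    sub <- table[table$treatment == records$treatment[i] &
                 table$season == records$season[i], ]
    if (nrow(sub) == 0) return(NA_real_)
    hs <- if (is.null(win_hours)) hours_of(records$timestamp[i]) else win_hours
    mean(sub$mrd[match(hs, sub$hour)])
  }, double(1))

  flagged <- is.na(offs)
  if (any(flagged)) {
    ds_log("WARN", sprintf("%d record(s) had no correction-table entry; passed through",
                           sum(flagged)))
  }
  records |>
    dplyr::mutate(
      offset_used = ifelse(flagged, 0, offs),
      flux_corrected = correct_flux(.data$flux, .data$offset_used),
      flagged = flagged
    )
}

#' Seasonal and annual budget of corrected and uncorrected fluxes
#'
#' Computes, per treatment, the unweighted mean, sample SD and record count
#' of the uncorrected and corrected fluxes for each hydrological year
#' ("all-year" scope) and each season, plus the percent difference of the
#' corrected relative to the uncorrected mean.
#'
#' @param corrected Output of [apply_correction_series()] additionally
#'   carrying `hydro_year` (see [annotate_calendar()]).
#' @return Tidy tibble `treatment`, `scope`, `variant`
#'   (`"uncorrected"`/`"corrected"`), `mean`, `sd`, `n`, `diff_pct` (the
#'   group's percent difference, repeated on both variant rows).
#' @export
aggregate_budget <- function(corrected) {
  if (nrow(corrected) == 0) ds_abort("no records to aggregate", "empty")
  need <- c("hydro_year", "season", "flux", "flux_corrected")
  miss <- setdiff(need, names(corrected))
  if (length(miss)) {
    ds_abort(paste0("records lack column(s): ", paste(miss, collapse = ", ")), "config")
  }
  one_scope <- function(df, scope_label) {
    tibble::tibble(
      treatment = df$treatment[1],
      scope = scope_label,
      variant = c("uncorrected", "corrected"),
      mean = c(mean(df$flux), mean(df$flux_corrected)),
      sd = c(stats::sd(df$flux), stats::sd(df$flux_corrected)),
      n = nrow(df),
      diff_pct = percent_difference(mean(df$flux_corrected), mean(df$flux))
    )
  }
  by_year <- corrected |>
    dplyr::group_by(.data$treatment, .data$hydro_year) |>
    dplyr::group_map(~ one_scope(.x |> dplyr::mutate(treatment = .y$treatment),
                                 .y$hydro_year)) |>
    dplyr::bind_rows()
  by_season <- corrected |>
    dplyr::group_by(.data$treatment, .data$season) |>
    dplyr::group_map(~ one_scope(.x |> dplyr::mutate(treatment = .y$treatment),
                                 .y$season)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(by_year, by_season)
}

#' Percent difference of a corrected mean relative to the uncorrected mean
#'
#' @param corrected_mean,uncorrected_mean Mean fluxes (vectorised).
#' @return `100 * (corrected - uncorrected) / uncorrected`, full precision
#'   (round to one decimal for display).
#' @examples
#' round(percent_difference(0.95, 1.27), 1)  # -25.2
#' @export
percent_difference <- function(corrected_mean, uncorrected_mean) {
  if (any(uncorrected_mean == 0)) {
    ds_abort("uncorrected mean is zero; percent difference undefined", "domain")
  }
  100 * (corrected_mean - uncorrected_mean) / uncorrected_mean
}
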