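#' @title Temporal stability of the diel flux cycle
#' @name temporal_stability
#' @description Per-campaign relative differences against the 24-hour mean,
#'   multi-campaign MRD/SDMRD profiles, hour ranking, and selection of the
#'   most representative sampling interval.
NULL

#' Per-hour relative difference against the campaign mean
#'
#' For each campaign, computes the relative difference of every hourly flux
#' with respect to the campaign's mean flux: `rd = (x - m) / m` where `m` is
#' the mean over the campaign's slots. For a complete 24-hour campaign the
#' relative differences average to zero by construction.
#'
#' @param campaigns Campaign tibble from [assemble_campaigns()] (columns
#'   `campaign_id`, `treatment`, `hour`, `flux`; `season` carried through if
#'   present).
#' @return Tibble with one row per campaign slot: `campaign_id`, `treatment`,
#'   (`season`,) `hour`, `rd` and `campaign_mean`.
#' @export
relative_difference <- function(campaigns) {
  if (nrow(campaigns) == 0) ds_abort("no campaigns supplied", "empty")
  counts <- dplyr::count(campaigns, .data$campaign_id)
  if (any(counts$n < 2)) {
    ds_abort(paste0("campaign(s) with fewer than 2 hourly slots: ",
                    paste(counts$campaign_id[counts$n < 2], collapse = ", ")),
             "domain")
  }
  keep <- intersect(c("campaign_id", "treatment", "season", "hour", "flux"),
                    names(campaigns))
  out <- campaigns[, keep] |>
    dplyr::group_by(.data$campaign_id) |>
    dplyr::mutate(campaign_mean = mean(.data$flux)) |>
    dplyr::ungroup()
  if (any(out$campaign_mean == 0)) {
    ds_abort("campaign mean flux is zero; relative difference undefined", "domain")
  }
  if (any(out$campaign_mean < 0)) {
    ds_abort(paste0("campaign mean flux is negative; the sign semantics of the ",
                    "relative difference invert -- inspect the input data"),
             "domain")
  }
  out <- out |>
    dplyr::mutate(rd = .data$flux / .data$campaign_mean - 1) |>
    dplyr::select(-"flux")
  big <- abs(out$rd) > 1
  if (any(big)) {
    ds_log("WARN", sprintf("%d relative differences exceed 1 in magnitude", sum(big)))
  }
  out
}

#' Mean relative difference across campaigns
#'
#' Per clock hour, the arithmetic mean of the relative differences over the
#' campaigns that observed that hour. With a single campaign the MRD equals
#' the RD elementwise.
#'
#' @param rd RD tibble from [relative_difference()].
#' @return Tibble with `hour`, `mrd`, `n_campaigns`, sorted by hour.
#' @export
mean_relative_difference <- function(rd) {
  if (nrow(rd) == 0) ds_abort("no RD profiles supplied", "empty")
  if (length(unique(rd$treatment)) > 1) {
    ds_abort("RD profiles mix treatments; compute per treatment", "config")
  }
  rd |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mrd = mean(.data$rd), n_campaigns = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$hour)
}

#' Standard deviation of the mean relative difference
#'
#' Per clock hour, the sample standard deviation (denominator `N_h - 1`,
#' `N_h` = campaigns observing that hour) of the relative differences around
#' their per-hour mean. Hours observed by a single campaign get `NA` and are
#' flagged rather than raising an error.
#'
#' @param rd RD tibble from [relative_difference()].
#' @return Tibble with `hour`, `sdmrd` (`NA` where fewer than 2 campaigns).
#' @export
sd_mrd <- function(rd) {
  if (nrow(rd) == 0) ds_abort("no RD profiles supplied", "empty")
  out <- rd |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(
      sdmrd = if (dplyr::n() >= 2) stats::sd(.data$rd) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$hour)
  if (anyNA(out$sdmrd)) {
    ds_log("WARN", sprintf("%d hour(s) observed by a single campaign: SDMRD unset",
                           sum(is.na(out$sdmrd))))
  }
  out
}

#' Rank hours by mean relative difference
#'
#' Ranks are assigned in ascending order of MRD: rank 1 is the most negative
#' MRD, rank H the most positive. Ties are broken deterministically in favour
#' of the earlier clock hour, so the ranks are always a permutation of 1..H.
#'
#' @param mrd Numeric MRD values.
#' @param hour Integer clock hours aligned with `mrd` (defaults to the order
#'   of `mrd`).
#' @return Integer ranks aligned with the input.
#' @export
rank_hours <- function(mrd, hour = seq_along(mrd) - 1L) {
  if (length(mrd) == 0) ds_abort("no MRD values to rank", "empty")
  ord <- order(mrd, hour)
  rk <- integer(length(mrd))
  rk[ord] <- seq_along(mrd)
  rk
}

#' Full stability profile for one treatment/season scope
#'
#' Convenience wrapper combining [mean_relative_difference()], [sd_mrd()] and
#' [rank_hours()] into a per-hour profile.
#'
#' @param rd RD tibble from [relative_difference()] restricted to one
#'   treatment (and, typically, one season scope).
#' @param scope Label recorded in the output (`"all"`, `"dry"`, `"wet"`...).
#' @return Tibble `treatment`, `scope`, `hour`, `mrd`, `sdmrd`, `rank`,
#'   `n_campaigns`.
#' @export
stability_profile <- function(rd, scope = "all") {
  m <- mean_relative_difference(rd)
  s <- sd_mrd(rd)
  m |>
    dplyr::left_join(s, by = "hour") |>
    dplyr::mutate(rank = rank_hours(.data$mrd, .data$hour),
                  treatment = rd$treatment[1], scope = scope) |>
    dplyr::select("treatment", "scope", "hour", "mrd", "sdmrd", "rank",
                  "n_campaigns")
}

#' Most representative sampling interval
#'
#' Identifies (a) the hour whose MRD is closest to zero, with ties broken by
#' lower SDMRD then earlier hour; (b) the hours holding the middle ranks
#' (ranks H/2 and H/2 + 1 for even H, the single middle rank for odd H); and
#' (c) the longest circular run of consecutive clock hours whose |MRD| stays
#' at or below `run_threshold`, ties resolved to the earliest start hour.
#'
#' @param profile Stability profile from [stability_profile()].
#' @param run_threshold Absolute MRD below which an hour counts as
#'   near-optimal (default 0.05, i.e. 5% bias).
#' @return A list of class `optimal_window`: `best_hour_by_mrd`,
#'   `middle_rank_hours`, `best_run` (list with `start`, `length`), and
#'   `threshold`.
#' @export
optimal_interval <- function(profile, run_threshold = 0.05) {
  if (nrow(profile) == 0) ds_abort("empty stability profile", "empty")
  H <- nrow(profile)

  sd_key <- ifelse(is.na(profile$sdmrd), Inf, profile$sdmrd)
  ord <- order(abs(profile$mrd), sd_key, profile$hour)
  best_hour <- profile$hour[ord[1]]

  middle_ranks <- if (H %% 2 == 0) c(H %/% 2L, H %/% 2L + 1L) else (H + 1L) %/% 2L
  middle_hours <- sort(profile$hour[profile$rank %in% middle_ranks])

  ok <- rep(FALSE, 24)
  ok[profile$hour[abs(profile$mrd) <= run_threshold] + 1L] <- TRUE
  best <- list(start = NA_integer_, length = 0L)
  if (all(ok)) {
    best <- list(start = 0L, length = 24L)
  } else if (any(ok)) {
    for (s in 0:23) {
      len <- 0L
      while (len < 24L && ok[(s + len) %% 24L + 1L]) len <- len + 1L
      if (len > best$length) best <- list(start = s, length = len)
    }
  }

  structure(list(best_hour_by_mrd = best_hour,
                 middle_rank_hours = middle_hours,
                 best_run = best,
                 threshold = run_threshold),
            class = "optimal_window")
}

#' @export
print.optimal_window <- function(x, ...) {
  cat("<optimal_window>\n")
  cat("  hour with MRD closest to zero:", x$best_hour_by_mrd, "\n")
  cat("  middle-rank hour(s):", paste(x$middle_rank_hours, collapse = ", "), "\n")
  if (x$best_run$length > 0) {
    cat(sprintf("  longest run with |MRD| <= %g: start %02d:00, %d h\n",
                x$threshold, x$best_run$start, x$best_run$length))
  } else {
    cat(sprintf("  no hour has |MRD| <= %g\n", x$threshold))
  }
  invisible(x)
}
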