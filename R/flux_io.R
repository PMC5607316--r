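#' @title Flux data input/output and calendar logic
#' @name flux_io
#' @description Read and write chamber-flux observations in the canonical CSV
#'   dialect, assemble hourly observations into 24-hour campaigns, and label
#'   dates with seasons and hydrological years.
NULL

# canonical column order of the flux CSV dialect
FLUX_COLS <- c("timestamp", "treatment", "plot", "collar", "flux", "tsoil", "swc")
FLUX_REQUIRED <- c("timestamp", "treatment", "collar", "flux")

parse_timestamp <- function(x) {
  # local clock time, stored tz-naive (UTC container, no DST adjustment)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  for (fmt in c("%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = fmt)
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# shortest decimal representation that survives a read/write round-trip
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Read chamber-flux observations from CSV
#'
#' Reads a CSV of flux observations into a tibble with the canonical columns
#' `timestamp` (POSIXct, local clock time), `treatment`, `plot`, `collar`
#' (character), `flux`, `tsoil`, `swc` (double). Rows whose timestamp does not
#' parse, whose flux is missing or non-numeric, or whose volumetric water
#' content falls outside \[0, 1\] are rejected; the rejected rows and reasons
#' are attached as the `"rejected"` attribute (a tibble with `row`, `reason`)
#' and reported via a message.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(timestamp = "time", flux = "Rs")`. Unmapped canonical names are looked
#'   up verbatim.
#' @return A tibble of observations with attribute `"rejected"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,treatment,plot,collar,flux,tsoil,swc",
#'              "2014-06-15T12:00:00,trench,p1,c1,1.52,21.3,0.11"), f)
#' read_flux_csv(f)
#' @export
read_flux_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    ds_abort(sprintf("flux CSV not found: %s", path), "config")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    ds_abort(sprintf("flux CSV has no data rows: %s", path), "empty")
  }
  colmap <- stats::setNames(FLUX_COLS, FLUX_COLS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), FLUX_COLS)
    if (length(bad)) {
      ds_abort(paste0("unknown canonical column(s) in schema: ",
                      paste(bad, collapse = ", ")), "config")
    }
    colmap[names(schema)] <- unname(schema)
  }
  missing_req <- FLUX_REQUIRED[!colmap[FLUX_REQUIRED] %in% names(raw)]
  if (length(missing_req)) {
    ds_abort(paste0("required column(s) missing from ", path, ": ",
                    paste(colmap[missing_req], collapse = ", ")), "config")
  }

  get_col <- function(canon) {
    src <- colmap[[canon]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }
  ts_raw <- get_col("timestamp")
  flux_raw <- get_col("flux")
  obs <- tibble::tibble(
    timestamp = parse_timestamp(ts_raw),
    treatment = get_col("treatment"),
    plot      = get_col("plot"),
    collar    = get_col("collar"),
    flux      = suppressWarnings(as.numeric(flux_raw)),
    tsoil     = suppressWarnings(as.numeric(get_col("tsoil"))),
    swc       = suppressWarnings(as.numeric(get_col("swc")))
  )

  reason <- rep(NA_character_, nrow(obs))
  reason[is.na(obs$timestamp)] <- "unparseable timestamp"
  bad_flux <- is.na(obs$flux) | !is.finite(obs$flux)
  reason[is.na(reason) & bad_flux] <- "missing or non-numeric flux"
  bad_swc <- !is.na(obs$swc) & (obs$swc < 0 | obs$swc > 1)
  reason[is.na(reason) & bad_swc] <- "soil moisture outside [0, 1]"

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    ds_log("WARN", sprintf("rejected %d of %d rows", nrow(rejected), nrow(obs)),
           file = path,
           rows = paste(utils::head(rejected$row, 10), collapse = ","))
  }
  obs <- obs[is.na(reason), , drop = FALSE]
  attr(obs, "rejected") <- rejected
  obs
}

#' Write observations in the canonical flux CSV dialect
#'
#' Comma-separated, UTF-8, ISO-8601 timestamps, header
#' `timestamp,treatment,plot,collar,flux,tsoil,swc`, missing optional values
#' empty. Writing the result of [read_flux_csv()] on a canonical file
#' reproduces it byte-for-byte.
#'
#' @param obs Tibble of observations as returned by [read_flux_csv()].
#' @param path Output path.
#' @param header_line Optional comment line (e.g. provenance) written before
#'   the CSV header; [read_flux_csv()] skips `#` comments.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(obs, path, header_line = NULL) {
  out <- tibble::tibble(
    timestamp = format_timestamp(obs$timestamp),
    treatment = obs$treatment,
    plot = obs$plot,
    collar = obs$collar,
    flux = format_num(obs$flux),
    tsoil = format_num(obs$tsoil),
    swc = format_num(obs$swc)
  )
  if (!is.null(header_line)) {
    writeLines(header_line, path)
    readr::write_csv(out, path, na = "", append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Assemble hourly observations into 24-hour campaigns
#'
#' Observations are binned to the clock hour (floor of the timestamp, local
#' time). Within each treatment and hour bin the flux is averaged (unweighted)
#' across collars; bins with fewer than `min_collars` collars are dropped.
#' Per treatment, campaigns are formed greedily: the earliest unassigned bin
#' opens a campaign and every bin within the following `window_hours` hours
#' joins it, so a campaign may wrap midnight and may have interior gaps.
#' Campaigns with fewer than `window_hours` slots are kept but flagged
#' incomplete.
#'
#' @param obs Observation tibble (see [read_flux_csv()]).
#' @param window_hours Campaign length in hours (default 24).
#' @param min_collars Minimum collars per hour bin for the bin to be usable.
#' @return A tibble with one row per campaign slot: `campaign_id`,
#'   `treatment`, `start` (campaign start time), `time` (bin time), `hour`
#'   (0-23 clock hour), `flux` (mean across collars), `collar_count`, `n`
#'   (slots in the campaign) and `complete` (`n == window_hours`).
#' @export
assemble_campaigns <- function(obs, window_hours = 24, min_collars = 1) {
  if (nrow(obs) == 0) return(empty_campaigns())
  binned <- obs |>
    dplyr::mutate(time = as.POSIXct(floor(as.numeric(.data$timestamp) / 3600) * 3600,
                                    origin = "1970-01-01", tz = "UTC")) |>
    dplyr::group_by(.data$treatment, .data$time) |>
    dplyr::summarise(flux = mean(.data$flux),
                     collar_count = dplyr::n_distinct(.data$collar),
                     .groups = "drop") |>
    dplyr::filter(.data$collar_count >= min_collars) |>
    dplyr::arrange(.data$treatment, .data$time)
  if (nrow(binned) == 0) return(empty_campaigns())

  # greedy window assignment: earliest unassigned bin opens a campaign that
  # absorbs every bin starting within window_hours of it
  assign_windows <- function(times) {
    win <- integer(length(times))
    open_start <- -Inf
    k <- 0L
    for (i in seq_along(times)) {
      ti <- as.numeric(times[i])
      if (ti - open_start >= window_hours * 3600) {
        k <- k + 1L
        open_start <- ti
      }
      win[i] <- k
    }
    win
  }
  binned |>
    dplyr::group_by(.data$treatment) |>
    dplyr::mutate(window = assign_windows(.data$time)) |>
    dplyr::group_by(.data$treatment, .data$window) |>
    dplyr::mutate(
      start = min(.data$time),
      n = dplyr::n(),
      complete = dplyr::n() == window_hours,
      campaign_id = sprintf("%s_%s", .data$treatment[1],
                            format(min(.data$time), "%Y%m%dT%H", tz = "UTC"))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(hour = as.integer(format(.data$time, "%H", tz = "UTC"))) |>
    dplyr::select("campaign_id", "treatment", "start", "time", "hour",
                  "flux", "collar_count", "n", "complete")
}

empty_campaigns <- function() {
  tibble::tibble(campaign_id = character(), treatment = character(),
                 start = as.POSIXct(character(), tz = "UTC"),
                 time = as.POSIXct(character(), tz = "UTC"),
                 hour = integer(), flux = double(), collar_count = integer(),
                 n = integer(), complete = logical())
}

#' Season specification
#'
#' Maps calendar months to the two seasons of a Mediterranean-type climate
#' and fixes the start month of the hydrological year. The default assigns
#' May-October to the dry season and November-April to the wet season, with
#' the hydrological year starting in November; both are site conventions the
#' user can override.
#'
#' @param month_to_season Character vector of length 12 (one season label per
#'   month, January first) using exactly two distinct labels.
#' @param hydro_year_start_month Integer 1-12; first month of the
#'   hydrological year (default 11 = November).
#' @return An object of class `season_spec`.
#' @examples
#' sp <- season_spec()
#' classify_season(as.Date("2014-06-15"), sp)
#' @export
season_spec <- function(month_to_season = NULL, hydro_year_start_month = 11) {
  if (is.null(month_to_season)) {
    month_to_season <- c(rep("wet", 4), rep("dry", 6), rep("wet", 2))
  }
  if (length(month_to_season) != 12 || anyNA(month_to_season)) {
    ds_abort("month_to_season must map all 12 months", "config")
  }
  if (length(unique(month_to_season)) > 2) {
    ds_abort("month_to_season must use at most two season labels", "config")
  }
  if (!hydro_year_start_month %in% 1:12) {
    ds_abort("hydro_year_start_month must be in 1..12", "config")
  }
  structure(list(month_to_season = as.character(month_to_season),
                 hydro_year_start_month = as.integer(hydro_year_start_month)),
            class = "season_spec")
}

#' @export
print.season_spec <- function(x, ...) {
  cat("<season_spec>\n")
  cat("  months:", paste(x$month_to_season, collapse = " "), "\n")
  cat("  hydro year starts month", x$hydro_year_start_month, "\n")
  invisible(x)
}

#' Classify a date into a season
#'
#' @param d Date(s) or POSIXct.
#' @param spec A [season_spec()].
#' @return Character vector of season labels.
#' @export
classify_season <- function(d, spec = season_spec()) {
  m <- as.integer(format(as.Date(d, tz = "UTC"), "%m"))
  spec$month_to_season[m]
}

#' Assign a hydrological-year label to a date
#'
#' Months at or after `start_month` belong to the hydro-year labelled by the
#' following calendar year; earlier months to the one labelled by their own
#' year. With the default November start, Nov 2013 through Oct 2014 are all
#' `"HY2014"`.
#'
#' @param d Date(s) or POSIXct.
#' @param start_month Integer 1-12 (default 11).
#' @return Character vector of labels `"HY<year>"`.
#' @export
assign_hydro_year <- function(d, start_month = 11) {
  if (!start_month %in% 1:12) ds_abort("start_month must be in 1..12", "config")
  d <- as.Date(d, tz = "UTC")
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  sprintf("HY%d", y + as.integer(m >= start_month & start_month > 1))
}

#' Annotate records with season and hydrological year
#'
#' Adds `season` and `hydro_year` columns derived from `timestamp` under a
#' [season_spec()], turning raw observations into monitoring records.
#'
#' @param records Tibble with a `timestamp` column.
#' @param spec A [season_spec()].
#' @return `records` with `season` and `hydro_year` columns.
#' @export
annotate_calendar <- function(records, spec = season_spec()) {
  records |>
    dplyr::mutate(
      season = classify_season(.data$timestamp, spec),
      hydro_year = assign_hydro_year(.data$timestamp, spec$hydro_year_start_month)
    )
}
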