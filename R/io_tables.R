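# Tabular I/O for ship (GLODAP-style), float (snapshot-style) and gridded
# surface pCO2 data, with the quality-flag conventions enforced at read
# time: ship levels are retained only when every required secondary flag
# equals 1; float levels only when every required flag equals 0.
#
# Profiles are represented as flat data.frames, one row per retained level,
# carrying the profile metadata (profile_id, platform, lat, lon, date)
# alongside the level variables. Levels are ordered by increasing depth
# within each profile.

SHIP_FLAGGED_VARS <- c("oxygen", "nitrate", "ta", "dic", "ph_insitu")
FLOAT_FLAGGED_VARS <- c("temp", "sal", "oxygen", "nitrate", "ph_insitu")

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  d
}

.finalize_profiles <- function(d, platform) {
  if (nrow(d) == 0) {
    warning("no levels survived quality-flag filtering in ", platform, " table")
  }
  d <- d[order(d$profile_id, d$depth), , drop = FALSE]
  dup <- unlist(tapply(d$depth, d$profile_id,
                       function(z) c(FALSE, diff(z) <= 0)), use.names = FALSE)
  if (any(dup)) stop(platform, " profiles must have strictly increasing depth")
  if (any(d$sal < 20 | d$sal > 40, na.rm = TRUE) ||
      any(d$depth < 0, na.rm = TRUE) || any(d$oxygen < 0, na.rm = TRUE)) {
    stop(platform, " table violates level invariants (depth/sal/oxygen range)")
  }
  d$platform <- rep(platform, nrow(d))
  rownames(d) <- NULL
  d
}

#' Read ship bottle profiles
#'
#' Reads a ship profile table (CSV). Only levels whose secondary quality
#' flag (`f_<var>` column) equals 1 for every required variable (oxygen,
#' nitrate, TA, DIC, pH) are retained; profiles with no surviving levels
#' are dropped. Silicate and phosphate columns are optional and recorded as
#' missing, not zero, when absent.
#'
#' @param path path to CSV with columns profile_id, lat, lon, date, depth,
#'   pressure, temp, sal, oxygen, nitrate, ta, dic, ph_insitu (optionally
#'   ph_25c, silicate, phosphate) and f_<var> flag columns
#' @return data.frame of retained levels (one row per level), ordered by
#'   profile and depth, with a `platform = "ship"` column
#' @export
read_ship_table <- function(path) {
  req <- c("profile_id", "lat", "lon", "date", "depth", "pressure",
           "temp", "sal", SHIP_FLAGGED_VARS, paste0("f_", SHIP_FLAGGED_VARS))
  d <- .read_csv_checked(path, req)
  for (opt in c("silicate", "phosphate", "ph_25c")) {
    if (!opt %in% names(d)) d[[opt]] <- NA_real_
  }
  keep <- Reduce(`&`, lapply(paste0("f_", SHIP_FLAGGED_VARS),
                             function(f) !is.na(d[[f]]) & d[[f]] == 1))
  .finalize_profiles(d[keep, , drop = FALSE], "ship")
}

#' Read float profiles
#'
#' Reads a float profile table (CSV). Only levels whose quality flag
#' (`qc_<var>` column) equals 0 for every required variable (temperature,
#' salinity, oxygen, nitrate, pH) are retained. Floats carry
#' algorithm-estimated TA (`ta_estimated`) rather than measured TA, and no
#' DIC/silicate/phosphate.
#'
#' @param path path to CSV with columns profile_id, lat, lon, date, depth,
#'   pressure, temp, sal, oxygen, nitrate, ph_insitu, ta_estimated and
#'   qc_<var> flag columns
#' @return data.frame of retained levels with a `platform = "float"` column
#' @export
read_float_table <- function(path) {
  req <- c("profile_id", "lat", "lon", "date", "depth", "pressure",
           "temp", "sal", "oxygen", "nitrate", "ph_insitu", "ta_estimated",
           paste0("qc_", FLOAT_FLAGGED_VARS))
  d <- .read_csv_checked(path, req)
  keep <- Reduce(`&`, lapply(paste0("qc_", FLOAT_FLAGGED_VARS),
                             function(f) !is.na(d[[f]]) & d[[f]] == 0))
  .finalize_profiles(d[keep, , drop = FALSE], "float")
}

#' Read a gridded monthly surface pCO2 product
#'
#' @param path CSV with columns lat, lon, year, month, pco2 (cell centers,
#'   1 degree grid, pCO2 in uatm)
#' @return data.frame of cells; errors on months outside 1..12 or duplicate
#'   (lat, lon, year, month) keys
#' @export
read_gridded_surface <- function(path) {
  d <- .read_csv_checked(path, c("lat", "lon", "year", "month", "pco2"))
  if (any(d$month < 1 | d$month > 12)) {
    stop("gridded surface table: month outside 1..12")
  }
  key <- paste(d$lat, d$lon, d$year, d$month)
  if (anyDuplicated(key)) {
    stop("gridded surface table: duplicate (lat, lon, year, month) cell")
  }
  d
}

#' Write profile tables back to CSV
#'
#' Inverse of the readers: writes a level table (ship or float) to CSV so
#' that read -> write -> read is the identity on retained records.
#'
#' @param profiles level data.frame as returned by the readers or the
#'   synthetic generator
#' @param path output CSV path
#' @export
write_profile_table <- function(profiles, path) {
  p <- profiles
  p$platform <- NULL
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes each table in a named list to `<name>.tsv` under `dir`, plus a
#' `summary.json` with the scalar comparison metrics.
#'
#' @param tables named list of data.frames
#' @param metrics named list of scalar metrics for the JSON summary
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(tables, metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(metrics, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}
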