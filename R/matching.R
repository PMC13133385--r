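# Float-ship profile and level matching, float-grid surface matching, and
# austral-season filtering.
#
# Matching rules: a float profile matches the spatially closest ship cast
# within 25 km (time is deliberately ignored for subsurface work); float
# and ship levels are paired by the smallest absolute depth difference
# within a 10 m window for float depths shallower than 200 m and a 100 m
# window at 200 m and deeper. Floats and gridded surface cells match only
# in the same month and year within 25 km.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#' @return distance in km (vectorised)
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

.profile_meta <- function(levels) {
  u <- !duplicated(levels$profile_id)
  data.frame(profile_id = levels$profile_id[u], lat = levels$lat[u],
             lon = levels$lon[u], date = levels$date[u],
             stringsAsFactors = FALSE)
}

#' Match float profiles to ship casts
#'
#' For each float profile, selects the spatially closest ship cast within
#' `max_km`; floats with no cast in range are unmatched. Equidistant casts
#' are broken by the earlier ship timestamp (then by profile id) so results
#' are deterministic.
#'
#' @param floats,ships level data.frames (as from the readers)
#' @param max_km distance window, km (default 25)
#' @return data.frame with one row per matched float profile: float_id,
#'   ship_id, distance_km, year_diff (float minus ship), float_month,
#'   ship_month
#' @export
match_profiles <- function(floats, ships, max_km = 25) {
  if (nrow(floats) == 0 || nrow(ships) == 0) {
    stop("match_profiles: empty float or ship set")
  }
  fm <- .profile_meta(floats)
  sm <- .profile_meta(ships)
  sm <- sm[order(as.Date(sm$date), sm$profile_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(fm)), function(i) {
    d <- haversine_km(fm$lat[i], fm$lon[i], sm$lat, sm$lon)
    ok <- which(d <= max_km)
    if (!length(ok)) return(NULL)
    j <- ok[which.min(d[ok])]   # ties: earliest date wins via sort order
    data.frame(float_id = fm$profile_id[i], ship_id = sm$profile_id[j],
               distance_km = d[j],
               year_diff = as.integer(format(as.Date(fm$date[i]), "%Y")) -
                 as.integer(format(as.Date(sm$date[j]), "%Y")),
               float_month = as.integer(format(as.Date(fm$date[i]), "%m")),
               ship_month = as.integer(format(as.Date(sm$date[j]), "%m")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(float_id = character(0),
                                      ship_id = character(0),
                                      distance_km = numeric(0),
                                      year_diff = integer(0),
                                      float_month = integer(0),
                                      ship_month = integer(0))
  res
}

#' Match levels within a paired float-ship profile
#'
#' For each float level, selects the ship level with the smallest absolute
#' depth difference within the window implied by the float level's depth:
#' 10 m for float depths < 200 m, 100 m at >= 200 m. A ship level may serve
#' several float levels.
#'
#' @param flevels,slevels level rows of one float and one ship profile
#' @param shallow_window,deep_window depth windows in m
#' @return data.frame of index pairs with float_depth, ship_depth,
#'   depth_diff (float minus ship)
#' @export
match_levels <- function(flevels, slevels,
                         shallow_window = 10, deep_window = 100) {
  out <- lapply(seq_len(nrow(flevels)), function(i) {
    fd <- flevels$depth[i]
    win <- if (fd < 200) shallow_window else deep_window
    dd <- abs(slevels$depth - fd)
    j <- which.min(dd)
    if (!length(j) || dd[j] > win) return(NULL)
    data.frame(float_row = i, ship_row = j, float_depth = fd,
               ship_depth = slevels$depth[j], depth_diff = fd - slevels$depth[j])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(float_row = integer(0), ship_row = integer(0),
                      float_depth = numeric(0), ship_depth = numeric(0),
                      depth_diff = numeric(0))
  }
  res
}

#' Build the matched float-ship level table
#'
#' Combines profile matching and level matching and attaches per-variable
#' float/ship values and deltas (float minus ship) for every variable
#' present on both sides.
#'
#' @param floats,ships level data.frames; the float table may carry derived
#'   columns (ph_25c, pco2, dic) added by the adjustment step
#' @param max_km profile distance window (km)
#' @return data.frame with one row per matched level pair; columns
#'   `<var>_f`, `<var>_s`, `d_<var>` for each shared variable plus the pair
#'   metadata from [match_profiles()]
#' @export
match_float_ship <- function(floats, ships, max_km = 25) {
  pairs <- match_profiles(floats, ships, max_km = max_km)
  cand <- c("temp", "sal", "oxygen", "nitrate", "ta", "ph_insitu",
            "ph_25c", "pco2", "dic")
  vars <- cand[vapply(cand, function(v) {
    on_float <- v %in% names(floats) ||
      (v == "ta" && "ta_estimated" %in% names(floats))
    on_float && v %in% names(ships)
  }, logical(1))]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fl <- floats[floats$profile_id == pairs$float_id[i], , drop = FALSE]
    sl <- ships[ships$profile_id == pairs$ship_id[i], , drop = FALSE]
    lm <- match_levels(fl, sl)
    if (nrow(lm) == 0) return(NULL)
    base <- cbind(pairs[rep(i, nrow(lm)), , drop = FALSE],
                  lm[, c("float_depth", "ship_depth", "depth_diff")])
    for (v in vars) {
      fv <- fl[[v]][lm$float_row]
      # float "ta" is the algorithm-estimated TA channel
      if (v == "ta" && "ta_estimated" %in% names(fl)) {
        fv <- fl$ta_estimated[lm$float_row]
      }
      sv <- sl[[v]][lm$ship_row]
      base[[paste0(v, "_f")]] <- fv
      base[[paste0(v, "_s")]] <- sv
      base[[paste0("d_", v)]] <- fv - sv
    }
    # ship-side hydrography carried for water-mass work
    base$ship_pres <- sl$pressure[lm$ship_row]
    base$ship_sil <- if ("silicate" %in% names(sl)) sl$silicate[lm$ship_row] else NA_real_
    base$ship_pho <- if ("phosphate" %in% names(sl)) sl$phosphate[lm$ship_row] else NA_real_
    base$ship_dic <- if ("dic" %in% names(sl)) sl$dic[lm$ship_row] else NA_real_
    base$ship_ta <- sl$ta[lm$ship_row]
    base
  })
  res <- do.call(rbind, rows)
  if (!is.null(res)) {
    stopifnot(all(res$distance_km <= max_km),
              all(abs(res$depth_diff) <=
                    ifelse(res$float_depth < 200, 10, 100)))
    rownames(res) <- NULL
  }
  res
}

#' Austral season of a calendar month
#'
#' Summer: Dec-Feb; autumn: Mar-May; winter: Jun-Aug; spring: Sep-Nov.
#'
#' @param month integer month 1..12
#' @return character season
#' @export
austral_season <- function(month) {
  c("summer", "summer", "autumn", "autumn", "autumn", "winter",
    "winter", "winter", "spring", "spring", "spring", "summer")[month]
}

#' Retain only same-season float-ship pairs
#'
#' @param pairs matched pair table with float_month and ship_month columns
#' @return subset of `pairs` whose two months fall in the same austral season
#' @export
filter_same_season <- function(pairs) {
  pairs[austral_season(pairs$float_month) == austral_season(pairs$ship_month), ,
        drop = FALSE]
}

#' Match float surface values to gridded cells
#'
#' The float surface value is the shallowest level within the top 5 m;
#' profiles without such a level are excluded. A float matches a cell only
#' for the same year and month and a cell-center distance <= `max_km`
#' (nearest cell on ties).
#'
#' @param float_surface data.frame with one row per float surface record:
#'   profile_id, lat, lon, year, month and a value column (e.g. pco2)
#' @param cells gridded cell table from [read_gridded_surface()]
#' @param max_km distance window, km
#' @return data.frame of matches with float value, cell pco2 and distance
#' @export
match_float_grid <- function(float_surface, cells, max_km = 25) {
  rows <- lapply(seq_len(nrow(float_surface)), function(i) {
    f <- float_surface[i, ]
    sub <- cells[cells$year == f$year & cells$month == f$month, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    d <- haversine_km(f$lat, f$lon, sub$lat, sub$lon)
    j <- which.min(d)
    if (d[j] > max_km) return(NULL)
    data.frame(profile_id = f$profile_id, distance_km = d[j],
               year = f$year, month = f$month,
               pco2_float = f$pco2, pco2_grid = sub$pco2[j],
               d_pco2 = f$pco2 - sub$pco2[j], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(profile_id = character(0),
                                      distance_km = numeric(0),
                                      year = integer(0), month = integer(0),
                                      pco2_float = numeric(0),
                                      pco2_grid = numeric(0),
                                      d_pco2 = numeric(0))
  res
}

#' Extract float surface records (top 5 m)
#'
#' @param floats float level table carrying a `pco2` column
#' @param max_depth surface cutoff, m (default 5)
#' @return one row per profile with a level shallower than `max_depth`:
#'   shallowest such level's pco2 plus position and (year, month)
#' @export
float_surface_values <- function(floats, max_depth = 5) {
  ok <- floats[floats$depth < max_depth & is.finite(floats$pco2), , drop = FALSE]
  if (nrow(ok) == 0) {
    return(data.frame(profile_id = character(0), lat = numeric(0),
                      lon = numeric(0), year = integer(0), month = integer(0),
                      pco2 = numeric(0)))
  }
  ok <- ok[order(ok$profile_id, ok$depth), ]
  ok <- ok[!duplicated(ok$profile_id), ]
  data.frame(profile_id = ok$profile_id, lat = ok$lat, lon = ok$lon,
             year = as.integer(format(as.Date(ok$date), "%Y")),
             month = as.integer(format(as.Date(ok$date), "%m")),
             pco2 = ok$pco2, stringsAsFactors = FALSE)
}
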