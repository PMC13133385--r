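# Shared synthetic configurations for the test suite.

# small but fully structured dataset for fast unit tests
small_config <- function(seed = 7, ...) {
  synth_config(seed = seed, n_ship = 30, n_float = 40, ...)
}

# deterministic water column: all noise and mesoscale jitter off
quiet_config <- function(seed = 7, bias = c(surface = 0, mid = 0, deep = 0),
                         n_ship = 15, n_float = 20, ...) {
  synth_config(seed = seed, n_ship = n_ship, n_float = n_float,
               colocated_frac = 1, bias = bias,
               noise = c(ph = 0, oxygen = 0, nitrate = 0, temp = 0,
                         sal = 0, ta_estimated = 0),
               ship_noise = c(dic = 0, ta = 0, oxygen = 0, nitrate = 0,
                              temp = 0, sal = 0, silicate = 0, phosphate = 0),
               site_jitter = c(theta = 0, sal = 0, ta = 0, oxygen = 0,
                               nitrate = 0),
               grid_noise = 0, ...)
}

# cache expensive datasets across tests within one run
.synth_cache <- new.env(parent = emptyenv())
cached_dataset <- function(key, config) {
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <- generate_dataset(config)
  }
  .synth_cache[[key]]
}

# float processing + matching on a generated dataset (cached per dataset)
run_mini_pairs <- function(ds) {
  key <- paste0("pairs_", ds$config$seed, "_", ds$config$n_float, "_",
                sum(ds$config$noise))
  if (is.null(.synth_cache[[key]])) {
    ref <- generate_reference_ph_algorithm(ds$ship)
    fl <- float_pco2(crossover_adjust(ds$float, ref)$floats)
    .synth_cache[[key]] <- match_float_ship(fl, ship_carbonate_derivations(ds$ship))
  }
  .synth_cache[[key]]
}

# minimal hand-built profile tables for matching / io tests
toy_float_levels <- function(id = "F1", lat = -60, lon = 0,
                             date = "2020-01-15",
                             depth = c(4, 150, 500, 1500),
                             ph = 7.95) {
  n <- length(depth)
  data.frame(profile_id = id, lat = lat, lon = lon, date = date,
             depth = depth, pressure = depth * 1.008,
             temp = 2, sal = 34.5, oxygen = 250, nitrate = 30,
             ph_insitu = rep_len(ph, n), ta_estimated = 2330,
             platform = "float", stringsAsFactors = FALSE)
}

toy_ship_levels <- function(id = "S1", lat = -60, lon = 0,
                            date = "2010-01-15",
                            depth = c(4, 150, 500, 1500)) {
  n <- length(depth)
  data.frame(profile_id = id, lat = lat, lon = lon, date = date,
             depth = depth, pressure = depth * 1.008,
             temp = 2, sal = 34.5, oxygen = 250, nitrate = 30,
             silicate = 75, phosphate = 1.875, ta = 2330, dic = 2200,
             ph_insitu = 7.95, ph_25c = 7.6, pco2 = 400,
             platform = "ship", stringsAsFactors = FALSE)
}
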