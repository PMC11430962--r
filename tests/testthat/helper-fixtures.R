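# Small random instances built directly (not via the package generator), so
# property tests exercise the model against inputs it did not produce itself.
random_instance <- function(n_zones, n_providers, seed,
                            sentinel = 120, p_unreachable = 0.1,
                            p_zero_capacity = 0) {
  set.seed(seed)
  zones <- data.frame(
    zone_id = sprintf("z%03d", seq_len(n_zones)),
    population = round(runif(n_zones, 500, 5000)),
    x_km = runif(n_zones, 0, 50), y_km = runif(n_zones, 0, 50),
    imd_quintile = sample(1:5, n_zones, replace = TRUE),
    geo_parent = sprintf("parent%02d", sample(1:max(2, n_zones %/% 5),
                                              n_zones, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  uda <- rlnorm(n_providers, log(10000), 0.6)
  if (p_zero_capacity > 0)
    uda[runif(n_providers) < p_zero_capacity] <- 0
  providers <- data.frame(
    provider_id = sprintf("p%03d", seq_len(n_providers)),
    uda = uda,
    x_km = runif(n_providers, 0, 50), y_km = runif(n_providers, 0, 50),
    stringsAsFactors = FALSE
  )
  m <- matrix(round(runif(n_zones * n_providers, 0.5, 90), 1),
              n_zones, n_providers,
              dimnames = list(zones$zone_id, providers$provider_id))
  m[matrix(runif(length(m)) < p_unreachable, nrow(m))] <- sentinel
  list(zones = zones, providers = providers,
       travel = travel_matrix(m, sentinel_minutes = sentinel))
}

# one-zone/one-provider and other tiny hand instances
tiny_instance <- function(times, populations, udas, sentinel = 120) {
  n <- length(populations)
  m <- matrix(times, nrow = n, byrow = TRUE)
  zones <- data.frame(zone_id = sprintf("z%d", seq_len(n)),
                      population = populations,
                      stringsAsFactors = FALSE)
  providers <- data.frame(provider_id = sprintf("p%d", seq_len(ncol(m))),
                          uda = udas, stringsAsFactors = FALSE)
  rownames(m) <- zones$zone_id
  colnames(m) <- providers$provider_id
  list(zones = zones, providers = providers,
       travel = travel_matrix(m, sentinel_minutes = sentinel))
}

# brute-force catchment oracle: full sort per zone, no partial tricks
catchment_oracle <- function(tt, q) {
  m <- tt$minutes
  sent <- tt$sentinel_minutes
  mem <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    reach <- which(m[i, ] != sent)
    if (length(reach) == 0) next
    srt <- sort(m[i, reach])
    thr <- if (length(srt) <= q) srt[length(srt)] else srt[q]
    mem[i, reach[m[i, reach] <= thr]] <- TRUE
  }
  mem
}

# coordinate-consistent instance: travel times derive from the coordinates,
# so adding a provider back at the same location reproduces its column
coord_instance <- function(n_zones, n_providers, seed, extent = 40) {
  reg <- simulate_region(synth_config(n_zones, n_providers,
                                      region_extent_km = extent,
                                      seed = seed))
  list(zones = reg$zones, providers = reg$providers, travel = reg$travel)
}
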