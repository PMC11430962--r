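#' Configuration for a synthetic study region
#'
#' Bundles the parameters controlling the synthetic-region generator:
#' numbers of demand zones and providers, the side of the square region,
#' the zone population range, the provider capacity distribution targets,
#' and the travel-time conventions (car speed, crow-fly reachability cutoff
#' and the sentinel value marking unreachable pairs).
#'
#' Defaults emulate the statistical structure of English neighbourhood-level
#' dental provision data: zone populations uniform on 1000--3000 persons
#' (the LSOA range), right-skewed annual provider capacities with median
#' 10740 and mean 13277 Units of Dental Activity (UDA), and car travel
#' times with pairs beyond 32 km crow-fly distance marked unreachable at a
#' 120-minute sentinel.
#'
#' @param n_zones number of demand zones (positive integer).
#' @param n_providers number of providers (positive integer).
#' @param region_extent_km side of the square region in km.
#' @param pop_low,pop_high zone population range in persons.
#' @param capacity_median,capacity_mean target median and mean of the
#'   provider capacity distribution (UDA/year). The mean must exceed the
#'   median (right skew).
#' @param car_speed_kmh assumed straight-line car speed for travel times.
#' @param crowfly_threshold_km pairs at or beyond this crow-fly distance are
#'   treated as unreachable.
#' @param sentinel_minutes travel-time value recorded for unreachable pairs.
#' @param urban_k,urban_radius_km a zone is labelled "urban" when at least
#'   `urban_k` other zone centroids lie within `urban_radius_km` of it.
#' @param seed integer seed; `generate_zones()` seeds from `seed` and
#'   `generate_providers()` from `seed + 1`, so each call is reproducible.
#' @return an object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_zones = 50, n_providers = 10, seed = 1)
#' region <- simulate_region(cfg)
#' @export
synth_config <- function(n_zones, n_providers, region_extent_km = 100,
                         pop_low = 1000, pop_high = 3000,
                         capacity_median = 10740, capacity_mean = 13277,
                         car_speed_kmh = 40, crowfly_threshold_km = 32,
                         sentinel_minutes = 120,
                         urban_k = 10, urban_radius_km = 5,
                         seed = NULL) {
  stop_if_not_count(n_zones, "n_zones")
  stop_if_not_count(n_providers, "n_providers")
  for (nm in c("region_extent_km", "pop_low", "pop_high", "capacity_median",
               "capacity_mean", "car_speed_kmh", "crowfly_threshold_km",
               "sentinel_minutes", "urban_radius_km")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (pop_low > pop_high)
    stop("'pop_low' must not exceed 'pop_high'", call. = FALSE)
  if (capacity_mean <= capacity_median)
    stop("'capacity_mean' must exceed 'capacity_median' (right-skewed target)",
         call. = FALSE)
  stop_if_not_count(urban_k, "urban_k")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    n_zones = as.integer(n_zones), n_providers = as.integer(n_providers),
    region_extent_km = region_extent_km,
    pop_low = pop_low, pop_high = pop_high,
    capacity_median = capacity_median, capacity_mean = capacity_mean,
    car_speed_kmh = car_speed_kmh,
    crowfly_threshold_km = crowfly_threshold_km,
    sentinel_minutes = sentinel_minutes,
    urban_k = as.integer(urban_k), urban_radius_km = urban_radius_km,
    seed = seed
  ), class = "synth_config")
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  invisible(x)
}

#' Generate synthetic demand zones
#'
#' Draws `n_zones` zones with populations uniform on
#' `[pop_low, pop_high]` (rounded to whole persons), centroid coordinates
#' uniform over the square region, a deprivation quintile label uniform
#' over 1--5, and an urban/rural label from a local-density proxy: a zone
#' is "urban" when at least `urban_k` other zone centroids lie within
#' `urban_radius_km` km.
#'
#' @param cfg a [synth_config()].
#' @return a data frame with columns `zone_id`, `population`, `x_km`,
#'   `y_km`, `imd_quintile`, `urban_rural`.
#' @export
generate_zones <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_zones
  x <- stats::runif(n, 0, cfg$region_extent_km)
  y <- stats::runif(n, 0, cfg$region_extent_km)
  pop <- round(stats::runif(n, cfg$pop_low, cfg$pop_high))
  imd <- sample(1:5, n, replace = TRUE)
  data.frame(
    zone_id = sprintf("Z%04d", seq_len(n)),
    population = pop, x_km = x, y_km = y,
    imd_quintile = imd,
    urban_rural = urban_rural_label(x, y, cfg$urban_k, cfg$urban_radius_km),
    stringsAsFactors = FALSE
  )
}

# density proxy: "urban" iff >= k other centroids within r km; chunked so the
# full n x n distance matrix is never materialised
urban_rural_label <- function(x, y, k, r) {
  n <- length(x)
  counts <- integer(n)
  chunk <- max(1L, min(n, 512L))
  r2 <- r * r
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    counts[idx] <- rowSums(d2 <= r2) - 1L  # exclude self
  }
  ifelse(counts >= k, "urban", "rural")
}

#' Generate synthetic providers
#'
#' Provider capacities are drawn from a log-normal distribution whose
#' parameters are solved in closed form from the target median \eqn{m} and
#' mean \eqn{M}: \eqn{\mu = \log m}, \eqn{\sigma^2 = 2 \log(M/m)} (so the
#' distribution median \eqn{e^\mu} and mean \eqn{e^{\mu + \sigma^2/2}} hit
#' the targets exactly). Provider locations are biased toward zone-dense
#' areas: with probability 0.8 a provider is placed near a randomly chosen
#' zone centroid (Gaussian jitter, sd 1 km, clamped to the region), else
#' uniform over the region.
#'
#' @param cfg a [synth_config()].
#' @param zones optional zone table from [generate_zones()]; when `NULL`,
#'   all providers are placed uniformly.
#' @return a data frame with columns `provider_id`, `uda`, `x_km`, `y_km`.
#' @export
generate_providers <- function(cfg, zones = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  n <- cfg$n_providers
  mu <- log(cfg$capacity_median)
  sigma <- sqrt(2 * log(cfg$capacity_mean / cfg$capacity_median))
  uda <- stats::rlnorm(n, meanlog = mu, sdlog = sigma)
  ext <- cfg$region_extent_km
  if (is.null(zones) || nrow(zones) == 0L) {
    x <- stats::runif(n, 0, ext)
    y <- stats::runif(n, 0, ext)
  } else {
    near <- stats::runif(n) < 0.8
    pick <- sample.int(nrow(zones), n, replace = TRUE)
    x <- ifelse(near, zones$x_km[pick] + stats::rnorm(n, 0, 1),
                stats::runif(n, 0, ext))
    y <- ifelse(near, zones$y_km[pick] + stats::rnorm(n, 0, 1),
                stats::runif(n, 0, ext))
    x <- pmin(pmax(x, 0), ext)
    y <- pmin(pmax(y, 0), ext)
  }
  data.frame(
    provider_id = sprintf("P%04d", seq_len(n)),
    uda = uda, x_km = x, y_km = y,
    stringsAsFactors = FALSE
  )
}

#' Travel times from coordinates
#'
#' Straight-line car travel times in minutes:
#' `60 * distance_km / car_speed_kmh`, rounded to one decimal place. Pairs
#' whose crow-fly distance is at or beyond `crowfly_threshold_km` receive
#' exactly `sentinel_minutes`, marking them unreachable. Rounding to one
#' decimal is applied here, in the generator, so that ties at a zone's
#' Q-th nearest travel time arise naturally.
#'
#' @param zones,providers data frames with `x_km`, `y_km` columns (and
#'   `zone_id` / `provider_id`).
#' @param cfg a [synth_config()] supplying speed, threshold and sentinel.
#' @return a [travel_matrix()].
#' @export
travel_times_from_coords <- function(zones, providers, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!all(is.finite(zones$x_km)) || !all(is.finite(zones$y_km)) ||
      !all(is.finite(providers$x_km)) || !all(is.finite(providers$y_km)))
    stop("coordinates must be finite", call. = FALSE)
  d <- sqrt(outer(zones$x_km, providers$x_km, "-")^2 +
            outer(zones$y_km, providers$y_km, "-")^2)
  minutes <- round(60 * d / cfg$car_speed_kmh, 1)
  minutes[d >= cfg$crowfly_threshold_km] <- cfg$sentinel_minutes
  dimnames(minutes) <- list(zones$zone_id, providers$provider_id)
  travel_matrix(minutes, sentinel_minutes = cfg$sentinel_minutes)
}

#' Simulate a complete synthetic region
#'
#' Convenience wrapper chaining [generate_zones()], [generate_providers()]
#' and [travel_times_from_coords()].
#'
#' @param cfg a [synth_config()].
#' @return a list of class `fca_region` with elements `zones`, `providers`,
#'   `travel` and `config`.
#' @export
simulate_region <- function(cfg) {
  zones <- generate_zones(cfg)
  providers <- generate_providers(cfg, zones)
  travel <- travel_times_from_coords(zones, providers, cfg)
  structure(list(zones = zones, providers = providers, travel = travel,
                 config = cfg),
            class = "fca_region")
}

#' @export
print.fca_region <- function(x, ...) {
  cat("Synthetic study region:", nrow(x$zones), "zones,",
      nrow(x$providers), "providers\n")
  cat("  total population:", format(sum(x$zones$population), big.mark = ","),
      "| total capacity:",
      format(round(sum(x$providers$uda)), big.mark = ","), "UDA\n")
  cat("  unreachable pairs:",
      sum(x$travel$minutes == x$travel$sentinel_minutes), "of",
      length(x$travel$minutes), "\n")
  invisible(x)
}

#' Write a region to CSV files
#'
#' Writes `zones.csv` (`zone_id, population, x_km, y_km, imd_quintile,
#' urban_rural`), `providers.csv` (`provider_id, uda, x_km, y_km`) and
#' `travel.csv` in long format (`zone_id, provider_id, minutes`), UTF-8
#' with '.' decimal separator. Sentinel rows are included so the files are
#' self-contained.
#'
#' @param region an `fca_region` (or a list with `zones`, `providers`,
#'   `travel`).
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_region <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(region$zones, file.path(dir, "zones.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(region$providers, file.path(dir, "providers.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  tt <- region$travel
  long <- data.frame(
    zone_id = rep(tt$zone_ids, times = length(tt$provider_ids)),
    provider_id = rep(tt$provider_ids, each = length(tt$zone_ids)),
    minutes = as.vector(tt$minutes),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, file.path(dir, "travel.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
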