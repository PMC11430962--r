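#' Scenario edits
#'
#' Constructors for the edit records accepted by [apply_edits()] and
#' [run_scenario()]. Edits are applied in order, so e.g. a
#' `edit_set_capacity()` followed by `edit_remove_provider()` on the same
#' id ends with the provider removed.
#'
#' @param id zone or provider identifier.
#' @param uda capacity in UDA/year (>= 0).
#' @param x,y coordinates in km (for added providers; travel times to the
#'   new column are computed from coordinates with the straight-line
#'   convention).
#' @param persons population (> 0).
#' @return a list of class `fca_edit`.
#' @name scenario_edits
NULL

fca_edit <- function(op, ...) {
  structure(c(list(op = op), list(...)), class = "fca_edit")
}

#' @rdname scenario_edits
#' @export
edit_remove_provider <- function(id) fca_edit("remove_provider", id = id)

#' @rdname scenario_edits
#' @export
edit_add_provider <- function(id, uda, x, y) {
  if (!is.numeric(uda) || uda < 0) stop("'uda' must be >= 0", call. = FALSE)
  fca_edit("add_provider", id = id, uda = uda, x = x, y = y)
}

#' @rdname scenario_edits
#' @export
edit_set_capacity <- function(id, uda) {
  if (!is.numeric(uda) || uda < 0) stop("'uda' must be >= 0", call. = FALSE)
  fca_edit("set_capacity", id = id, uda = uda)
}

#' @rdname scenario_edits
#' @export
edit_remove_zone <- function(id) fca_edit("remove_zone", id = id)

#' @rdname scenario_edits
#' @export
edit_set_population <- function(id, persons) {
  if (!is.numeric(persons) || persons <= 0)
    stop("'persons' must be > 0", call. = FALSE)
  fca_edit("set_population", id = id, persons = persons)
}

#' Read scenario edits from a YAML or JSON file
#'
#' The file holds a list of records, each with an `op` field
#' (`remove_provider`, `add_provider`, `set_capacity`, `remove_zone`,
#' `set_population`) plus that edit's arguments. Requires the `yaml` or
#' `jsonlite` package according to the file extension.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a list of `fca_edit` records.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("scenario file must be .yaml/.yml or .json", call. = FALSE))
  lapply(raw, function(rec) {
    op <- rec$op
    args <- rec[setdiff(names(rec), "op")]
    ctor <- switch(op,
      remove_provider = edit_remove_provider,
      add_provider = edit_add_provider,
      set_capacity = edit_set_capacity,
      remove_zone = edit_remove_zone,
      set_population = edit_set_population,
      stop("unknown edit op: ", op, call. = FALSE))
    do.call(ctor, args)
  })
}

#' Apply scenario edits to baseline inputs
#'
#' Applies an ordered list of [scenario_edits] to the zone table, provider
#' table and travel matrix: removals drop the corresponding travel-matrix
#' column (provider) or row (zone); an added provider gets a fresh travel
#' column computed from coordinates with the same straight-line, rounded,
#' crow-fly-cutoff convention as [travel_times_from_coords()]; capacity
#' and population edits modify the tables in place.
#'
#' @param zones,providers,travel baseline inputs (zone/provider tables
#'   with coordinates, and a [travel_matrix()]).
#' @param edits list of `fca_edit` records (a single edit is also
#'   accepted).
#' @param car_speed_kmh,crowfly_threshold_km travel conventions used for
#'   added providers.
#' @return a list with edited `zones`, `providers`, `travel`.
#' @export
apply_edits <- function(zones, providers, travel, edits,
                        car_speed_kmh = 40, crowfly_threshold_km = 32) {
  stopifnot(inherits(travel, "travel_matrix"))
  if (inherits(edits, "fca_edit")) edits <- list(edits)
  zones <- as.data.frame(zones)
  providers <- as.data.frame(providers)
  m <- travel$minutes
  sent <- travel$sentinel_minutes
  for (e in edits) {
    if (!inherits(e, "fca_edit")) stop("edits must be fca_edit records",
                                       call. = FALSE)
    switch(e$op,
      remove_provider = {
        k <- match(e$id, providers$provider_id)
        if (is.na(k)) stop("unknown provider id: ", e$id, call. = FALSE)
        providers <- providers[-k, , drop = FALSE]
        m <- m[, colnames(m) != e$id, drop = FALSE]
      },
      add_provider = {
        if (e$id %in% providers$provider_id)
          stop("provider id already exists: ", e$id, call. = FALSE)
        providers <- rbind(providers,
          data.frame(provider_id = e$id, uda = e$uda,
                     x_km = e$x, y_km = e$y, stringsAsFactors = FALSE))
        zi <- match(rownames(m), zones$zone_id)
        d <- sqrt((zones$x_km[zi] - e$x)^2 + (zones$y_km[zi] - e$y)^2)
        col <- round(60 * d / car_speed_kmh, 1)
        col[d >= crowfly_threshold_km] <- sent
        m <- cbind(m, col)
        colnames(m)[ncol(m)] <- e$id
      },
      set_capacity = {
        k <- match(e$id, providers$provider_id)
        if (is.na(k)) stop("unknown provider id: ", e$id, call. = FALSE)
        providers$uda[k] <- e$uda
      },
      remove_zone = {
        k <- match(e$id, zones$zone_id)
        if (is.na(k)) stop("unknown zone id: ", e$id, call. = FALSE)
        zones <- zones[-k, , drop = FALSE]
        m <- m[rownames(m) != e$id, , drop = FALSE]
      },
      set_population = {
        k <- match(e$id, zones$zone_id)
        if (is.na(k)) stop("unknown zone id: ", e$id, call. = FALSE)
        zones$population[k] <- e$persons
      },
      stop("unknown edit op: ", e$op, call. = FALSE))
  }
  rownames(zones) <- NULL
  rownames(providers) <- NULL
  list(zones = zones, providers = providers,
       travel = travel_matrix(m, sentinel_minutes = sent))
}

#' Rank zones by an accessibility index
#'
#' Rank 1 is the highest value; ties share the average rank; zones with
#' undefined (missing) indices are unranked (`NA`).
#'
#' @param result an [mhv3sfca()] fit or its `$zones` data frame.
#' @param key `"sdi"` or `"spai"`.
#' @return numeric vector of ranks named by zone id.
#' @export
rank_table <- function(result, key = c("sdi", "spai")) {
  key <- match.arg(key)
  z <- if (inherits(result, "mhv3sfca")) result$zones else result
  v <- z[[key]]
  r <- rank(-v, ties.method = "average", na.last = "keep")
  stats::setNames(r, z$zone_id)
}

#' Run a what-if scenario
#'
#' Computes accessibility for the baseline inputs and again after applying
#' the edits (with full catchment recomputation), and reports per-zone
#' before/after indices and rank shifts. Ranks are computed separately on
#' SDI and SPAI with rank 1 = highest; `rank_change = rank_after -
#' rank_before`, so a positive change means the zone fell down the
#' ranking. Zones removed by the scenario get `NA` "after" values.
#'
#' @inheritParams apply_edits
#' @param q_target,decay,delta_mode model settings passed to [mhv3sfca()].
#' @return an object of class `scenario_delta`: a list with `$delta` (per
#'   baseline zone: `sdi_with`, `sdi_without`, `spai_with`,
#'   `spai_without`, `sdi_rank_change`, `spai_rank_change`),
#'   `$n_catchment_changed`, and the two fits (`$baseline`, `$scenario`).
#' @export
run_scenario <- function(zones, providers, travel, edits,
                         q_target = 10, decay = decay_function(),
                         delta_mode = c("absolute_difference", "raw"),
                         car_speed_kmh = 40, crowfly_threshold_km = 32) {
  delta_mode <- match.arg(delta_mode)
  before <- mhv3sfca(zones, providers, travel, q_target, decay, delta_mode)
  edited <- apply_edits(zones, providers, travel, edits,
                        car_speed_kmh, crowfly_threshold_km)
  after <- mhv3sfca(edited$zones, edited$providers, edited$travel,
                    q_target, decay, delta_mode)

  zb <- before$zones
  za <- after$zones
  ia <- match(zb$zone_id, za$zone_id)
  rb_sdi <- rank_table(before, "sdi")
  rb_spai <- rank_table(before, "spai")
  ra_sdi <- rank_table(after, "sdi")[ia]
  ra_spai <- rank_table(after, "spai")[ia]

  delta <- data.frame(
    zone_id = zb$zone_id,
    population = zb$population,
    sdi_with = zb$sdi, sdi_without = za$sdi[ia],
    spai_with = zb$spai, spai_without = za$spai[ia],
    sdi_rank_change = unname(ra_sdi - rb_sdi),
    spai_rank_change = unname(ra_spai - rb_spai),
    stringsAsFactors = FALSE
  )

  # zones whose catchment membership changed (over providers common to both
  # runs, plus any membership involving added/removed providers)
  mb <- before$catchment$membership
  ma <- after$catchment$membership
  common_p <- intersect(colnames(mb), colnames(ma))
  common_z <- intersect(rownames(mb), rownames(ma))
  changed <- rowSums(mb[common_z, common_p, drop = FALSE] !=
                       ma[common_z, common_p, drop = FALSE]) > 0
  extra_b <- setdiff(colnames(mb), common_p)
  extra_a <- setdiff(colnames(ma), common_p)
  if (length(extra_b))
    changed <- changed | rowSums(mb[common_z, extra_b, drop = FALSE]) > 0
  if (length(extra_a))
    changed <- changed | rowSums(ma[common_z, extra_a, drop = FALSE]) > 0

  structure(list(delta = delta,
                 n_catchment_changed = sum(changed),
                 baseline = before, scenario = after),
            class = "scenario_delta")
}

#' @export
print.scenario_delta <- function(x, n = 10, ...) {
  d <- x$delta
  cat("What-if scenario over", nrow(d), "baseline zones;",
      x$n_catchment_changed, "zones changed catchment membership\n")
  dd <- d$sdi_without - d$sdi_with
  aff <- which(!is.na(dd) & abs(dd) > 1e-9)
  cat("  zones with changed SDI:", length(aff), "\n")
  if (length(aff)) {
    ord <- aff[order(dd[aff])]
    cat("  largest impacts:\n")
    print(utils::head(d[ord, ], n), digits = 5, row.names = FALSE)
  }
  invisible(x)
}

#' Write a scenario delta table to CSV
#'
#' Columns: `zone_id, sdi_with, sdi_without, spai_with, spai_without,
#' sdi_rank_change, spai_rank_change`.
#'
#' @param x a [run_scenario()] result.
#' @param path output CSV path.
#' @export
write_scenario_delta <- function(x, path) {
  stopifnot(inherits(x, "scenario_delta"))
  cols <- c("zone_id", "sdi_with", "sdi_without", "spai_with",
            "spai_without", "sdi_rank_change", "spai_rank_change")
  utils::write.csv(x$delta[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
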