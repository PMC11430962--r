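# quartiles of sdi/spai per stratum label; linear-interpolation (type 7) rule
stratum_quartiles <- function(z, labels) {
  labels <- as.character(labels)
  labels[is.na(labels) | labels == ""] <- "unknown"
  ok <- !z$empty_catchment & !is.na(z$sdi)
  out <- lapply(sort(unique(labels)), function(lab) {
    sel <- ok & labels == lab
    q3 <- function(v) {
      if (!any(sel)) return(rep(NA_real_, 3))
      stats::quantile(v[sel], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    }
    qs <- q3(z$sdi)
    qa <- q3(z$spai)
    data.frame(stratum = lab, n_zones = sum(sel),
               sdi_q1 = qs[1], sdi_median = qs[2], sdi_q3 = qs[3],
               spai_q1 = qa[1], spai_median = qa[2], spai_q3 = qa[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stratified quartile summaries
#'
#' First quartile, median and third quartile of the SDI and SPAI per
#' stratum (e.g. deprivation quintile or urban/rural class), over zones
#' with defined indices. Uses the linear-interpolation quantile rule
#' (type 7). Zones without a label are grouped as `"unknown"`; an empty
#' stratum yields missing quartiles.
#'
#' @param result an [mhv3sfca()] fit.
#' @param labels either the name of a column of `result$zones` or a vector
#'   of labels, one per zone.
#' @return a data frame with one row per stratum: `stratum`, `n_zones`,
#'   `sdi_q1`, `sdi_median`, `sdi_q3`, `spai_q1`, `spai_median`,
#'   `spai_q3`.
#' @export
summarize_by_stratum <- function(result, labels) {
  stopifnot(inherits(result, "mhv3sfca"))
  z <- result$zones
  if (is.character(labels) && length(labels) == 1L) {
    if (!labels %in% names(z))
      stop("no column '", labels, "' in the fit's zone table", call. = FALSE)
    labels <- z[[labels]]
  }
  if (length(labels) != nrow(z))
    stop("'labels' must cover all zones", call. = FALSE)
  stratum_quartiles(z, labels)
}

#' Aggregate indices to a coarser geography
#'
#' Parent-level SDI and SPAI are population-weighted means of their member
#' zones' values; zones with missing indices are excluded from both the
#' numerator and the denominator. Population weighting (rather than simple
#' means) is what makes the national population-weighted mean SDI
#' invariant to the aggregation level.
#'
#' @param result an [mhv3sfca()] fit.
#' @param mapping either the name of a column of `result$zones` holding
#'   the parent id (default `"geo_parent"`), or a data frame with columns
#'   `zone_id` and `parent_id` covering every zone exactly once.
#' @return a data frame with one row per parent: `parent_id`,
#'   `population` (all member zones), `population_served` (members with
#'   defined indices — the weight actually used), `n_zones`, `sdi`,
#'   `spai`.
#' @export
aggregate_to_geography <- function(result, mapping = "geo_parent") {
  stopifnot(inherits(result, "mhv3sfca"))
  z <- result$zones
  if (is.character(mapping) && length(mapping) == 1L) {
    if (!mapping %in% names(z))
      stop("no column '", mapping, "' in the fit's zone table", call. = FALSE)
    parent <- z[[mapping]]
  } else {
    mapping <- as.data.frame(mapping)
    if (!all(c("zone_id", "parent_id") %in% names(mapping)))
      stop("mapping needs columns 'zone_id' and 'parent_id'", call. = FALSE)
    if (anyDuplicated(mapping$zone_id))
      stop("each zone must map to exactly one parent", call. = FALSE)
    parent <- mapping$parent_id[match(z$zone_id, mapping$zone_id)]
  }
  if (anyNA(parent))
    stop("every zone must map to a parent geography", call. = FALSE)
  ok <- !z$empty_catchment & !is.na(z$sdi)
  out <- lapply(sort(unique(as.character(parent))), function(p) {
    mem <- parent == p
    sel <- mem & ok
    w <- z$population[sel]
    data.frame(
      parent_id = p,
      population = sum(z$population[mem]),
      population_served = sum(w),
      n_zones = sum(mem),
      sdi = if (any(sel)) stats::weighted.mean(z$sdi[sel], w) else NA_real_,
      spai = if (any(sel)) stats::weighted.mean(z$spai[sel], w) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Write fit results to CSV
#'
#' Writes `result.csv` (`zone_id, population, sdi, spai, effective_q,
#' empty_catchment`) and `providers_out.csv` (`provider_id, uda,
#' allocated_demand, supply_ratio, zero_demand`).
#'
#' @param fit an [mhv3sfca()] fit.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "mhv3sfca"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zc <- c("zone_id", "population", "sdi", "spai", "effective_q",
          "empty_catchment")
  utils::write.csv(fit$zones[, zc], file.path(dir, "result.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  pc <- c("provider_id", "uda", "allocated_demand", "supply_ratio",
          "zero_demand")
  utils::write.csv(fit$providers[, pc], file.path(dir, "providers_out.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
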