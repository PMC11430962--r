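#' Zone-by-provider travel-time matrix
#'
#' A dense matrix of travel times in minutes with an explicit sentinel
#' value marking unreachable pairs. Entries exactly equal to
#' `sentinel_minutes` mean "not reachable"; all other entries are actual
#' travel times (conventionally stored to one decimal place).
#'
#' @param minutes numeric zone-by-provider matrix of non-negative minutes.
#' @param sentinel_minutes the unreachable marker value.
#' @param zone_ids,provider_ids identifiers; default to the dimnames of
#'   `minutes`.
#' @return an object of class `travel_matrix`: a list with `minutes`,
#'   `zone_ids`, `provider_ids`, `sentinel_minutes`.
#' @export
travel_matrix <- function(minutes, sentinel_minutes = 120,
                          zone_ids = rownames(minutes),
                          provider_ids = colnames(minutes)) {
  if (!is.matrix(minutes) || !is.numeric(minutes))
    stop("'minutes' must be a numeric matrix", call. = FALSE)
  if (anyNA(minutes) || any(minutes < 0))
    stop("travel times must be non-negative and non-missing", call. = FALSE)
  if (is.null(zone_ids)) zone_ids <- sprintf("Z%04d", seq_len(nrow(minutes)))
  if (is.null(provider_ids))
    provider_ids <- sprintf("P%04d", seq_len(ncol(minutes)))
  if (length(zone_ids) != nrow(minutes) ||
      length(provider_ids) != ncol(minutes))
    stop("id lengths must match matrix dimensions", call. = FALSE)
  if (anyDuplicated(zone_ids) || anyDuplicated(provider_ids))
    stop("zone and provider ids must be unique", call. = FALSE)
  dimnames(minutes) <- list(zone_ids, provider_ids)
  structure(list(minutes = minutes,
                 zone_ids = as.character(zone_ids),
                 provider_ids = as.character(provider_ids),
                 sentinel_minutes = sentinel_minutes),
            class = "travel_matrix")
}

#' @export
print.travel_matrix <- function(x, ...) {
  cat("Travel-time matrix:", length(x$zone_ids), "zones x",
      length(x$provider_ids), "providers (sentinel =",
      x$sentinel_minutes, "min)\n")
  n_sent <- sum(x$minutes == x$sentinel_minutes)
  cat("  unreachable pairs:", n_sent,
      sprintf("(%.1f%%)\n", 100 * n_sent / length(x$minutes)))
  invisible(x)
}

#' Read a travel-time matrix from CSV
#'
#' Accepts either long format (columns `zone_id, provider_id, minutes`;
#' pairs absent from the file are filled with `sentinel_minutes`) or dense
#' format (first column `zone_id`, remaining columns one per provider id).
#' The format is detected from the header.
#'
#' @param path CSV file path.
#' @param sentinel_minutes unreachable marker, also the fill value for
#'   missing long-format pairs.
#' @param zone_ids,provider_ids optional id universes for long format;
#'   defaults to the ids present in the file (sorted).
#' @return a [travel_matrix()].
#' @export
read_travel <- function(path, sentinel_minutes = 120,
                        zone_ids = NULL, provider_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (identical(names(df)[1:3][!is.na(names(df)[1:3])],
                c("zone_id", "provider_id", "minutes")) && ncol(df) == 3L) {
    if (is.null(zone_ids)) zone_ids <- sort(unique(df$zone_id))
    if (is.null(provider_ids)) provider_ids <- sort(unique(df$provider_id))
    m <- matrix(sentinel_minutes, length(zone_ids), length(provider_ids),
                dimnames = list(zone_ids, provider_ids))
    ri <- match(df$zone_id, zone_ids)
    ci <- match(df$provider_id, provider_ids)
    if (anyNA(ri) || anyNA(ci))
      stop("travel file contains ids outside the supplied universes",
           call. = FALSE)
    m[cbind(ri, ci)] <- df$minutes
    travel_matrix(m, sentinel_minutes)
  } else {
    zid <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- zid
    travel_matrix(m, sentinel_minutes)
  }
}

is_reachable <- function(tt) tt$minutes != tt$sentinel_minutes

#' Per-zone count of reachable providers
#'
#' @param tt a [travel_matrix()].
#' @return named integer vector, one count per zone.
#' @export
reachable_counts <- function(tt) {
  stopifnot(inherits(tt, "travel_matrix"))
  counts <- rowSums(is_reachable(tt))
  stats::setNames(as.integer(counts), tt$zone_ids)
}

#' Per-zone minimum travel time
#'
#' The smallest non-sentinel travel time per zone; `NA` for zones with no
#' reachable provider (deliberately not 0, so "no access" is
#' distinguishable from "zero travel time").
#'
#' @param tt a [travel_matrix()].
#' @return named numeric vector of minutes.
#' @export
minimum_time <- function(tt) {
  stopifnot(inherits(tt, "travel_matrix"))
  m <- tt$minutes
  m[!is_reachable(tt)] <- NA_real_
  res <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
  res[!is.finite(res)] <- NA_real_
  stats::setNames(res, tt$zone_ids)
}
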