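#' @keywords internal
"_PACKAGE"

# travel-cost argument fed to the decay function: either the raw time or the
# difference from the zone's own minimum reachable time (the default, so that
# zones are compared on absolute extra minutes, not relative ones)
delta_matrix <- function(tt, delta_mode) {
  if (delta_mode == "raw") return(tt$minutes)
  dmin <- minimum_time(tt)
  dmin[is.na(dmin)] <- 0  # empty rows: value irrelevant, masked out later
  sweep(tt$minutes, 1L, dmin, "-")
}

#' Huff provider-choice probabilities
#'
#' For each zone, members `j` of its catchment get weight proportional to
#' capacity times a decay on the travel cost,
#' \eqn{P_{ij} = S_j f(\Delta_{ij}) / \sum_{k \in B_i} S_k f(\Delta_{ik})},
#' where \eqn{\Delta_{ij}} is the raw time `d_ij` (`delta_mode = "raw"`) or
#' the excess over the zone's minimum reachable time,
#' \eqn{d_{ij} - d_i^{min}} (`"absolute_difference"`, the default).
#' Non-members get 0. Each non-empty row sums to 1; a row whose members all
#' have zero capacity cannot be normalised and is left all-zero (it is
#' treated as an empty catchment downstream).
#'
#' @param providers provider table with `uda` capacities.
#' @param tt a [travel_matrix()].
#' @param B a [build_catchments()] result computed from `tt`.
#' @param f a [decay_function()].
#' @param delta_mode `"absolute_difference"` or `"raw"`.
#' @return a zone-by-provider probability matrix.
#' @export
huff_probabilities <- function(providers, tt, B, f,
                               delta_mode = c("absolute_difference", "raw")) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(inherits(tt, "travel_matrix"), inherits(B, "catchment"))
  if (any(providers$uda < 0))
    stop("provider capacities must be non-negative", call. = FALSE)
  W <- B$membership * f(delta_matrix(tt, delta_mode))
  W <- sweep(W, 2L, providers$uda, "*")
  denom <- rowSums(W)
  P <- W
  ok <- denom > 0
  P[ok, ] <- W[ok, , drop = FALSE] / denom[ok]
  P[!ok, ] <- 0
  P
}

#' Allocate zone demand to providers
#'
#' Distributes each zone's population over its catchment providers in
#' proportion to the Huff probabilities: \eqn{D_j = \sum_i P_{ij} Pop_i}.
#' Because rows of `P` sum to 1 for served zones, total allocated demand
#' equals the total population of zones with non-empty catchments —
#' overall demand is independent of provision.
#'
#' @param P Huff probability matrix from [huff_probabilities()].
#' @param zones zone table with `population`.
#' @return named numeric vector of persons per provider.
#' @export
allocate_demand <- function(P, zones) {
  if (nrow(P) != nrow(zones))
    stop("dimension mismatch between P and zones", call. = FALSE)
  D <- as.vector(crossprod(P, zones$population))
  stats::setNames(D, colnames(P))
}

#' Provider supply-to-demand ratios
#'
#' \eqn{R_j = S_j / D_j} (capacity units per allocated person) where
#' demand is positive; providers attracting zero demand get
#' \eqn{R_j = 0} rather than an infinite ratio, and are flagged via the
#' `zero_demand` attribute.
#'
#' @param providers provider table with `uda`.
#' @param D allocated demand from [allocate_demand()].
#' @return numeric vector of ratios with a logical `zero_demand` attribute.
#' @export
supply_ratios <- function(providers, D) {
  if (any(providers$uda < 0) || any(D < 0))
    stop("capacities and demands must be non-negative", call. = FALSE)
  if (nrow(providers) != length(D))
    stop("dimension mismatch between providers and D", call. = FALSE)
  zero <- D == 0
  R <- ifelse(zero, 0, providers$uda / D)
  attr(R, "zero_demand") <- zero
  R
}

#' Spatial Density Index (availability)
#'
#' \eqn{SDI_i = 1000 \sum_j P_{ij} R_j}: the demand-weighted average
#' supply ratio over the zone's catchment, scaled to capacity units per
#' 1000 residents. `NA` for zones with empty catchments.
#'
#' @param P Huff probability matrix.
#' @param R supply ratios from [supply_ratios()].
#' @return named numeric vector, one value per zone.
#' @export
compute_sdi <- function(P, R) {
  if (ncol(P) != length(R))
    stop("dimension mismatch between P and R", call. = FALSE)
  sdi <- 1000 * as.vector(P %*% as.numeric(R))
  sdi[rowSums(P) == 0] <- NA_real_
  stats::setNames(sdi, rownames(P))
}

#' Spatial Accessibility Index
#'
#' \eqn{SPAI_i = \sum_j P_{ij} f(\Delta_{ij}) R_j}: like the SDI but with
#' each catchment provider's ratio discounted by the travel-time decay
#' weight, so availability at a distance counts for less. Uses the same
#' \eqn{\Delta} convention as [huff_probabilities()]. `NA` for empty
#' catchments. Since \eqn{f \le 1}, `spai <= sdi / 1000` elementwise.
#'
#' @param P Huff probability matrix.
#' @param R supply ratios.
#' @param f a [decay_function()].
#' @param tt the [travel_matrix()] the probabilities were built from.
#' @param delta_mode `"absolute_difference"` or `"raw"` (must match the
#'   mode used for `P`).
#' @return named numeric vector, one score per zone.
#' @export
compute_spai <- function(P, R, f, tt,
                         delta_mode = c("absolute_difference", "raw")) {
  delta_mode <- match.arg(delta_mode)
  if (ncol(P) != length(R))
    stop("dimension mismatch between P and R", call. = FALSE)
  fd <- f(delta_matrix(tt, delta_mode))
  spai <- as.vector((P * fd) %*% as.numeric(R))
  spai[rowSums(P) == 0] <- NA_real_
  stats::setNames(spai, rownames(P))
}

validate_fca_inputs <- function(zones, providers, tt) {
  problems <- character(0)
  req_z <- c("zone_id", "population")
  req_p <- c("provider_id", "uda")
  if (!all(req_z %in% names(zones)))
    problems <- c(problems, paste("zones must have columns:",
                                  paste(req_z, collapse = ", ")))
  if (!all(req_p %in% names(providers)))
    problems <- c(problems, paste("providers must have columns:",
                                  paste(req_p, collapse = ", ")))
  if (length(problems) == 0L) {
    dup_z <- unique(zones$zone_id[duplicated(zones$zone_id)])
    if (length(dup_z))
      problems <- c(problems, paste("duplicated zone_id:",
                                    paste(utils::head(dup_z, 5), collapse = ", ")))
    dup_p <- unique(providers$provider_id[duplicated(providers$provider_id)])
    if (length(dup_p))
      problems <- c(problems, paste("duplicated provider_id:",
                                    paste(utils::head(dup_p, 5), collapse = ", ")))
    bad_pop <- zones$zone_id[!is.finite(zones$population) |
                               zones$population <= 0]
    if (length(bad_pop))
      problems <- c(problems, paste("non-positive population for zones:",
                                    paste(utils::head(bad_pop, 5), collapse = ", ")))
    bad_uda <- providers$provider_id[!is.finite(providers$uda) |
                                       providers$uda < 0]
    if (length(bad_uda))
      problems <- c(problems, paste("negative capacity for providers:",
                                    paste(utils::head(bad_uda, 5), collapse = ", ")))
    if (length(tt$zone_ids) != nrow(zones) ||
        !setequal(tt$zone_ids, zones$zone_id))
      problems <- c(problems, "travel matrix zones do not match zone table")
    if (length(tt$provider_ids) != nrow(providers) ||
        !setequal(tt$provider_ids, providers$provider_id))
      problems <- c(problems, "travel matrix providers do not match provider table")
  }
  if (length(problems))
    stop(paste0("invalid inputs:\n  ", paste(problems, collapse = "\n  ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Fit the modified-Huff variable three-step floating catchment area model
#'
#' The end-to-end accessibility computation. Given demand zones,
#' capacitated providers and a zone-by-provider travel-time matrix, it
#' \enumerate{
#'   \item builds each zone's variable catchment — its `q_target` nearest
#'     reachable providers, including ties at the Q-th time
#'     ([build_catchments()]);
#'   \item splits each zone's population over its catchment by Huff
#'     probabilities (capacity times travel-time decay, normalised;
#'     [huff_probabilities()]), sums allocated demand per provider and
#'     forms supply-to-demand ratios ([supply_ratios()]);
#'   \item sums ratios back to zones as the Spatial Density Index
#'     (availability, capacity per 1000 residents; [compute_sdi()]) and
#'     the decay-weighted Spatial Accessibility Index ([compute_spai()]).
#' }
#' Zones with no reachable provider receive `NA` indices (flagged
#' `empty_catchment`) rather than zeros.
#'
#' @param zones data frame with `zone_id`, `population` (and optionally
#'   `imd_quintile`, `urban_rural`, `geo_parent`, coordinates).
#' @param providers data frame with `provider_id`, `uda` capacity.
#' @param travel a [travel_matrix()] covering exactly these zones and
#'   providers (any order; rows/columns are aligned by id).
#' @param q_target catchment size Q (default 10).
#' @param decay a [decay_function()] (default gaussian, `d_max` 30 min,
#'   `f_dmax` 0.05).
#' @param delta_mode travel-cost convention for the decay argument:
#'   `"absolute_difference"` (default; minutes beyond the zone's nearest
#'   provider) or `"raw"`.
#' @param verbose print exception counts (ties beyond Q, zones with fewer
#'   than Q reachable, empty catchments)?
#' @return an object of class `mhv3sfca`: a list with per-zone results
#'   (`$zones`: `sdi`, `spai`, `effective_q`, `empty_catchment`),
#'   per-provider results (`$providers`: `allocated_demand`,
#'   `supply_ratio`, `zero_demand`), the probability matrix (`$weights`),
#'   the catchment structure, the decay function and exception counts.
#' @examples
#' region <- simulate_region(synth_config(n_zones = 80, n_providers = 15,
#'                                        region_extent_km = 60, seed = 1))
#' fit <- mhv3sfca(region$zones, region$providers, region$travel)
#' fit
#' head(fit$zones)
#' @export
mhv3sfca <- function(zones, providers, travel, q_target = 10,
                     decay = decay_function(),
                     delta_mode = c("absolute_difference", "raw"),
                     verbose = FALSE) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(inherits(travel, "travel_matrix"), inherits(decay, "decay_fn"))
  zones <- as.data.frame(zones)
  providers <- as.data.frame(providers)
  validate_fca_inputs(zones, providers, travel)
  # align travel matrix to table order
  ri <- match(zones$zone_id, travel$zone_ids)
  ci <- match(providers$provider_id, travel$provider_ids)
  tt <- travel_matrix(travel$minutes[ri, ci, drop = FALSE],
                      sentinel_minutes = travel$sentinel_minutes,
                      zone_ids = zones$zone_id,
                      provider_ids = providers$provider_id)

  B <- build_catchments(tt, q_target)
  P <- huff_probabilities(providers, tt, B, decay, delta_mode)
  empty <- rowSums(P) == 0  # no reachable provider, or all-zero capacity
  D <- allocate_demand(P, zones)
  R <- supply_ratios(providers, D)
  sdi <- compute_sdi(P, R)
  spai <- compute_spai(P, R, decay, tt, delta_mode)

  exceptions <- list(
    ties_beyond_q = sum(B$effective_q > B$q_target),
    fewer_than_q_reachable = sum(B$n_reachable < B$q_target & !B$empty),
    empty_catchment = sum(empty)
  )
  if (verbose)
    message(sprintf(
      "catchment exceptions: %d zones with ties beyond Q (%.1f%%), %d with fewer than Q reachable (%.1f%%), %d empty",
      exceptions$ties_beyond_q,
      100 * exceptions$ties_beyond_q / nrow(zones),
      exceptions$fewer_than_q_reachable,
      100 * exceptions$fewer_than_q_reachable / nrow(zones),
      exceptions$empty_catchment))

  zone_out <- zones
  zone_out$sdi <- unname(sdi)
  zone_out$spai <- unname(spai)
  zone_out$effective_q <- B$effective_q
  zone_out$empty_catchment <- unname(empty)
  prov_out <- providers
  prov_out$allocated_demand <- unname(D)
  prov_out$supply_ratio <- as.numeric(R)
  prov_out$zero_demand <- unname(attr(R, "zero_demand"))

  structure(list(zones = zone_out, providers = prov_out,
                 weights = P, catchment = B, decay = decay,
                 delta_mode = delta_mode, q_target = as.integer(q_target),
                 exceptions = exceptions, call = match.call()),
            class = "mhv3sfca")
}

#' Reference implementation with explicit per-zone loops
#'
#' Computes the same model as [mhv3sfca()] with plain loops, per-zone
#' re-sorting and no shared intermediates, as an independent cross-check
#' for small instances. Slow by design; intended for verification, not
#' analysis.
#'
#' @inheritParams mhv3sfca
#' @return a list with `zones` and `providers` data frames shaped like the
#'   corresponding components of an [mhv3sfca()] fit.
#' @export
mhv3sfca_naive <- function(zones, providers, travel, q_target = 10,
                           decay = decay_function(),
                           delta_mode = c("absolute_difference", "raw")) {
  delta_mode <- match.arg(delta_mode)
  zones <- as.data.frame(zones)
  providers <- as.data.frame(providers)
  sent <- travel$sentinel_minutes
  n <- nrow(zones)
  np <- nrow(providers)
  m <- travel$minutes[match(zones$zone_id, travel$zone_ids),
                      match(providers$provider_id, travel$provider_ids),
                      drop = FALSE]

  members <- vector("list", n)
  probs <- vector("list", n)
  eff_q <- integer(n)
  for (i in seq_len(n)) {
    times <- m[i, ]
    reach <- which(times != sent)
    if (length(reach) == 0L) next
    ord <- reach[order(times[reach])]
    if (length(ord) <= q_target) {
      mem <- ord
    } else {
      thr <- times[ord[q_target]]
      mem <- reach[times[reach] <= thr]
    }
    eff_q[i] <- length(mem)
    dmin <- times[ord[1L]]
    w <- numeric(length(mem))
    for (k in seq_along(mem)) {
      j <- mem[k]
      dd <- if (delta_mode == "absolute_difference") times[j] - dmin
            else times[j]
      w[k] <- providers$uda[j] * decay(dd)
    }
    if (sum(w) > 0) {
      members[[i]] <- mem
      probs[[i]] <- w / sum(w)
    }
  }
  empty <- vapply(members, is.null, logical(1))

  D <- numeric(np)
  for (i in seq_len(n)) {
    if (empty[i]) next
    for (k in seq_along(members[[i]]))
      D[members[[i]][k]] <- D[members[[i]][k]] + probs[[i]][k] * zones$population[i]
  }
  R <- numeric(np)
  for (j in seq_len(np)) R[j] <- if (D[j] > 0) providers$uda[j] / D[j] else 0

  sdi <- rep(NA_real_, n)
  spai <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (empty[i]) next
    s <- 0; a <- 0
    times <- m[i, ]
    dmin <- min(times[times != sent])
    for (k in seq_along(members[[i]])) {
      j <- members[[i]][k]
      dd <- if (delta_mode == "absolute_difference") times[j] - dmin
            else times[j]
      s <- s + probs[[i]][k] * R[j]
      a <- a + probs[[i]][k] * decay(dd) * R[j]
    }
    sdi[i] <- 1000 * s
    spai[i] <- a
  }

  list(
    zones = data.frame(zone_id = zones$zone_id,
                       population = zones$population,
                       sdi = sdi, spai = spai, effective_q = eff_q,
                       empty_catchment = empty,
                       stringsAsFactors = FALSE),
    providers = data.frame(provider_id = providers$provider_id,
                           uda = providers$uda,
                           allocated_demand = D, supply_ratio = R,
                           zero_demand = D == 0,
                           stringsAsFactors = FALSE)
  )
}
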