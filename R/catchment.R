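#' Build variable catchments (the binary eligibility matrix)
#'
#' Restricts each zone's provider choice set to its `q_target` nearest
#' reachable providers, with two exceptions mirroring how one-decimal
#' travel times behave in practice:
#' \itemize{
#'   \item ties: every provider whose time equals the `q_target`-th
#'     smallest reachable time is included, so the effective Q can exceed
#'     `q_target`;
#'   \item sparse zones: when fewer than `q_target` providers are
#'     reachable, all reachable providers are members (effective Q below
#'     `q_target`). Zones with no reachable provider get an empty
#'     catchment and are flagged.
#' }
#' Sentinel (unreachable) entries are never members.
#'
#' @param tt a [travel_matrix()].
#' @param q_target number of nearest providers to retain (>= 1).
#' @return an object of class `catchment`: list with logical
#'   zone-by-provider `membership`, `q_target`, per-zone `effective_q`,
#'   `n_reachable` and logical `empty`.
#' @export
build_catchments <- function(tt, q_target = 10) {
  stopifnot(inherits(tt, "travel_matrix"))
  if (!is.numeric(q_target) || length(q_target) != 1L || q_target < 1 ||
      q_target != floor(q_target))
    stop("'q_target' must be an integer >= 1", call. = FALSE)
  q_target <- as.integer(q_target)
  m <- tt$minutes
  reach <- is_reachable(tt)
  n <- nrow(m)
  membership <- matrix(FALSE, n, ncol(m), dimnames = dimnames(m))
  for (i in seq_len(n)) {
    r <- reach[i, ]
    k <- sum(r)
    if (k == 0L) next
    if (k <= q_target) {
      membership[i, ] <- r
    } else {
      times <- m[i, r]
      thr <- sort(times, partial = q_target)[q_target]
      membership[i, ] <- r & (m[i, ] <= thr)
    }
  }
  n_reachable <- as.integer(rowSums(reach))
  empty <- n_reachable == 0L
  if (all(empty))
    warning("no zone has any reachable provider", call. = FALSE)
  structure(list(membership = membership, q_target = q_target,
                 effective_q = as.integer(rowSums(membership)),
                 n_reachable = n_reachable,
                 empty = empty),
            class = "catchment")
}

#' @export
print.catchment <- function(x, ...) {
  n <- nrow(x$membership)
  cat("Catchment structure:", n, "zones, Q target =", x$q_target, "\n")
  cat("  zones with ties beyond Q: ", sum(x$effective_q > x$q_target),
      sprintf(" (%.1f%%)\n", 100 * mean(x$effective_q > x$q_target)),
      sep = "")
  cat("  zones with fewer than Q reachable: ",
      sum(x$n_reachable < x$q_target & !x$empty),
      sprintf(" (%.1f%%)\n",
              100 * mean(x$n_reachable < x$q_target & !x$empty)), sep = "")
  cat("  zones with empty catchments: ", sum(x$empty), "\n", sep = "")
  invisible(x)
}
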