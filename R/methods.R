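#' @export
print.mhv3sfca <- function(x, ...) {
  nz <- nrow(x$zones)
  np <- nrow(x$providers)
  cat("Modified-Huff variable three-step floating catchment area model\n")
  cat("  ", nz, " zones, ", np, " providers, Q = ", x$q_target,
      ", delta mode = ", x$delta_mode, "\n", sep = "")
  cat("  decay: ", attr(x$decay, "family"), ", d_max = ",
      attr(x$decay, "d_max"), " min, f(d_max) = ",
      attr(x$decay, "f_dmax"), "\n", sep = "")
  ex <- x$exceptions
  cat(sprintf("  exceptions: %d ties beyond Q (%.1f%%), %d with < Q reachable (%.1f%%), %d empty\n",
              ex$ties_beyond_q, 100 * ex$ties_beyond_q / nz,
              ex$fewer_than_q_reachable,
              100 * ex$fewer_than_q_reachable / nz,
              ex$empty_catchment))
  ok <- !x$zones$empty_catchment
  if (any(ok)) {
    pw <- stats::weighted.mean(x$zones$sdi[ok], x$zones$population[ok])
    cat(sprintf("  SDI (per 1000): median %.0f, pop-weighted mean %.0f\n",
                stats::median(x$zones$sdi[ok]), pw))
    cat(sprintf("  SPAI: median %.3f\n", stats::median(x$zones$spai[ok])))
  }
  invisible(x)
}

#' Summarise an accessibility fit
#'
#' Overall and (when stratum labels are present) per-stratum quartile
#' summaries of the SDI and SPAI distributions, over zones with defined
#' indices.
#'
#' @param object an [mhv3sfca()] fit.
#' @param by optional character vector of stratum columns to summarise by;
#'   defaults to whichever of `imd_quintile` and `urban_rural` are present.
#' @param ... unused.
#' @return a list of class `summary.mhv3sfca` with an `overall` row and
#'   one quartile table per stratum variable.
#' @export
summary.mhv3sfca <- function(object, by = NULL, ...) {
  z <- object$zones
  if (is.null(by))
    by <- intersect(c("imd_quintile", "urban_rural"), names(z))
  overall <- stratum_quartiles(z, rep("all", nrow(z)))
  strata <- lapply(by, function(v) summarize_by_stratum(object, v))
  names(strata) <- by
  structure(list(overall = overall, strata = strata,
                 n_zones = nrow(z),
                 n_empty = sum(z$empty_catchment),
                 exceptions = object$exceptions),
            class = "summary.mhv3sfca")
}

#' @export
print.summary.mhv3sfca <- function(x, digits = 4, ...) {
  cat("Accessibility summary over", x$n_zones, "zones (",
      x$n_empty, "with empty catchments excluded )\n\n")
  cat("Overall quartiles:\n")
  print(x$overall, digits = digits, row.names = FALSE)
  for (nm in names(x$strata)) {
    cat("\nBy ", nm, ":\n", sep = "")
    print(x$strata[[nm]], digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Plot an accessibility fit
#'
#' Base-graphics diagnostic panel: histograms of the SDI and SPAI over
#' zones with defined indices, and SPAI against SDI (their ratio is the
#' effective decay discount each zone experiences).
#'
#' @param x an [mhv3sfca()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.mhv3sfca <- function(x, ...) {
  z <- x$zones[!x$zones$empty_catchment, ]
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  graphics::hist(z$sdi, main = "Availability (SDI)",
                 xlab = "capacity per 1000 residents", ...)
  graphics::hist(z$spai, main = "Accessibility (SPAI)",
                 xlab = "decay-weighted score", ...)
  graphics::plot(z$sdi, z$spai, xlab = "SDI", ylab = "SPAI",
                 main = "SPAI vs SDI", pch = 20,
                 col = grDevices::adjustcolor("steelblue", 0.5))
  graphics::abline(0, 1 / 1000, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.mhv3sfca <- function(x, ...) x$zones
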