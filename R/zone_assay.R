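#' Equal-area zone boundaries for the three-zone position assay
#'
#' A GFP-tagged locus is scored in the focal plane in which the spot is
#' brightest, so the relevant null geometry is the two-dimensional nuclear
#' cross-section: a disc of unit diameter. The disc is partitioned into three
#' concentric regions of equal area -- a peripheral ring (zone 1), a middle
#' ring (zone 2) and a central disc (zone 3). Positions are expressed as the
#' spot-to-envelope distance divided by the nuclear diameter, so boundaries
#' live on \code{[0, 0.5]} with 0 at the envelope and 0.5 at the centre.
#'
#' Solving \eqn{\pi(R^2 - r^2) = \pi R^2/3} with \eqn{R = 1/2} gives
#' \eqn{b_1 = (1 - \sqrt{2/3})/2 \approx 0.0918} and
#' \eqn{b_2 = (1 - \sqrt{1/3})/2 \approx 0.2113}.
#'
#' @return An object of class \code{"zone_boundaries"}: a list with elements
#'   \code{b1} and \code{b2}, the zone1|zone2 and zone2|zone3 cut points on
#'   the ratio-to-diameter scale.
#' @examples
#' b <- zone_boundaries()
#' b$b1 # 0.0918...
#' @export
zone_boundaries <- function() {
  structure(
    list(b1 = (1 - sqrt(2 / 3)) / 2, b2 = (1 - sqrt(1 / 3)) / 2),
    class = "zone_boundaries"
  )
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf("Equal-area zone boundaries (ratio to diameter): b1 = %.5f, b2 = %.5f\n",
              x$b1, x$b2))
  invisible(x)
}

#' Relative perinuclear position of a spot
#'
#' Distance from the nuclear envelope divided by the nuclear diameter. Valid
#' positions lie in \code{[0, 0.5]}; a distance exceeding the nuclear radius
#' places the spot outside the nucleus and is rejected.
#'
#' @param distance_um spot-to-envelope distance(s), micrometres, >= 0.
#' @param diameter_um nuclear diameter(s), micrometres, > 0.
#' @return Numeric vector of ratios in \code{[0, 0.5]}.
#' @examples
#' spot_ratio(0.2, 2.0) # 0.1
#' @export
spot_ratio <- function(distance_um, diameter_um) {
  if (any(diameter_um <= 0)) stop("nuclear diameter must be positive")
  if (any(distance_um < 0)) stop("spot-to-envelope distance must be >= 0")
  bad <- distance_um > diameter_um / 2
  if (any(bad)) {
    stop(sprintf("%d measurement(s) with distance exceeding the nuclear radius (spot outside nucleus)",
                 sum(bad)))
  }
  distance_um / diameter_um
}

#' Assign a relative position to one of three equal-area zones
#'
#' Bins are half-open toward the centre: zone 1 is \code{[0, b1)}, zone 2
#' \code{[b1, b2)}, zone 3 \code{[b2, 0.5]}, so a ratio landing exactly on a
#' boundary is assigned to the inner (more central) zone deterministically.
#'
#' @param ratio numeric vector of ratios in \code{[0, 0.5]}.
#' @param b a [zone_boundaries()] object.
#' @return Integer vector of zones in \code{{1, 2, 3}}.
#' @export
assign_zone <- function(ratio, b = zone_boundaries()) {
  if (any(ratio < 0 | ratio > 0.5)) {
    stop("ratio out of range [0, 0.5]")
  }
  ifelse(ratio < b$b1, 1L, ifelse(ratio < b$b2, 2L, 3L))
}

#' Tabulate spots per zone, by group
#'
#' Computes each spot's ratio-to-diameter position, bins it into the three
#' equal-area zones, and tallies counts per group. Records whose distance
#' exceeds the nuclear radius are dropped with a warning naming the offending
#' cells (measurement error should be visible, not silently clamped). Empty
#' groups are excluded with a warning.
#'
#' @param spots data.frame with columns \code{distance_um}, \code{diameter_um}
#'   and any grouping columns (e.g. \code{stage}, \code{condition}); a
#'   \code{cell_id} column is used in drop messages when present.
#' @param group_by character vector of column names to group by; \code{NULL}
#'   tallies the whole table as one group named \code{"all"}.
#' @param b a [zone_boundaries()] object.
#' @return data.frame of class \code{"zone_counts"} with columns
#'   \code{group}, \code{z1}, \code{z2}, \code{z3} (counts) and \code{n}.
#' @export
tabulate_zones <- function(spots, group_by = NULL, b = zone_boundaries()) {
  stopifnot(is.data.frame(spots),
            all(c("distance_um", "diameter_um") %in% names(spots)))
  bad <- spots$distance_um > spots$diameter_um / 2 |
    spots$distance_um < 0 | spots$diameter_um <= 0
  if (any(bad)) {
    ids <- if ("cell_id" %in% names(spots)) {
      paste(utils::head(spots$cell_id[bad], 5L), collapse = ", ")
    } else {
      paste(utils::head(which(bad), 5L), collapse = ", ")
    }
    warning(sprintf("dropping %d record(s) with spot outside the nucleus (e.g. %s)",
                    sum(bad), ids))
    spots <- spots[!bad, , drop = FALSE]
  }
  if (nrow(spots) == 0L) stop("no valid measurements to tabulate")
  zone <- assign_zone(spot_ratio(spots$distance_um, spots$diameter_um), b)
  grp <- if (is.null(group_by)) {
    rep("all", nrow(spots))
  } else {
    stopifnot(all(group_by %in% names(spots)))
    interaction(spots[group_by], drop = TRUE, sep = "/")
  }
  tab <- table(group = grp, zone = factor(zone, levels = 1:3))
  out <- data.frame(
    group = rownames(tab),
    z1 = as.integer(tab[, "1"]),
    z2 = as.integer(tab[, "2"]),
    z3 = as.integer(tab[, "3"]),
    stringsAsFactors = FALSE
  )
  out$n <- out$z1 + out$z2 + out$z3
  empty <- out$n == 0L
  if (any(empty)) {
    warning(sprintf("excluding empty group(s): %s",
                    paste(out$group[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("zone_counts", "data.frame")
  out
}

zone_pct <- function(counts, n) 100 * counts / n

new_zone_test <- function(chi2, df, p, percentages, comparison) {
  structure(
    list(chi2 = chi2, df = df, p = p, percentages = percentages,
         comparison = comparison),
    class = "zone_test"
  )
}

#' @export
print.zone_test <- function(x, ...) {
  cat(sprintf("Zone chi-squared test (%s)\n", x$comparison))
  cat(sprintf("  zone%%: %s\n",
              paste(sprintf("%.1f", x$percentages), collapse = " / ")))
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Chi-squared test of a zone distribution against the uniform (random) null
#'
#' Under random positioning, spot positions are uniform over the nuclear
#' cross-section, so each equal-area zone is expected to hold a third of the
#' spots. Pearson's chi-squared statistic is computed on raw counts against
#' expected counts \code{(n/3, n/3, n/3)} with 2 degrees of freedom; for
#' df = 2 the upper-tail p-value has the closed form \code{exp(-chi2/2)}.
#'
#' @param counts one row of a [tabulate_zones()] table, or any object with
#'   numeric \code{z1}, \code{z2}, \code{z3} entries, or a plain numeric
#'   vector of three zone counts.
#' @return A \code{"zone_test"} object: \code{chi2}, \code{df}, \code{p}, and
#'   the observed zone \code{percentages} (summing to 100).
#' @examples
#' zone_test_random(c(60, 20, 20)) # chi2 = 32, p ~ 1.1e-7
#' @export
zone_test_random <- function(counts) {
  obs <- zone_count_triple(counts)
  n <- sum(obs)
  if (n <= 0) stop("no spots scored (n = 0)")
  expected <- rep(n / 3, 3L)
  chi2 <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 2L, lower.tail = FALSE)
  new_zone_test(chi2, 2L, p, zone_pct(obs, n), "observed vs uniform random")
}

#' Chi-squared comparison of two zone distributions
#'
#' Pearson chi-squared test of homogeneity on the 2 x 3 contingency table of
#' zone counts (df = 2), without continuity correction. When any expected
#' cell count falls below 5 a warning is issued but the test is still the
#' plain chi-squared (no method switch).
#'
#' @param a,b zone count triples as accepted by [zone_test_random()].
#' @return A \code{"zone_test"} object; \code{percentages} are those of
#'   \code{a}.
#' @export
zone_test_between <- function(a, b) {
  oa <- zone_count_triple(a)
  ob <- zone_count_triple(b)
  if (sum(oa) == 0 || sum(ob) == 0) stop("both groups must have n > 0")
  m <- rbind(oa, ob)
  if (any(colSums(m) == 0)) stop("a zone with zero total count makes df ill-defined")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warning("expected count(s) below 5; chi-squared approximation may be coarse")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_zone_test(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                zone_pct(oa, sum(oa)), "group a vs group b")
}

# Accept a zone_counts row, a list with z1..z3, or a bare numeric triple.
zone_count_triple <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    v <- c(x$z1, x$z2, x$z3)
  } else if (is.list(x)) {
    v <- c(x$z1, x$z2, x$z3)
  } else {
    stopifnot(is.numeric(x), length(x) == 3L)
    v <- x
  }
  if (any(v < 0) || any(v != floor(v))) stop("zone counts must be non-negative integers")
  as.numeric(v)
}

#' Exact binomial test of pore colocalization
#'
#' Scores whether the observed fraction of cells with complete overlap of the
#' locus signal and the clustered nuclear-pore signal exceeds the expectation
#' for a randomly positioned locus (9\% by default, an empirical constant for
#' pore-cluster geometry). The test is the exact two-sided binomial test
#' (two-sidedness by the point-probability method, as in
#' \code{\link[stats]{binom.test}}).
#'
#' @param k number of cells with complete signal overlap.
#' @param n number of cells scored.
#' @param p0 expected random colocalization fraction (default 0.09).
#' @return A \code{"coloc_test"} object: \code{n}, \code{k}, \code{fraction},
#'   \code{percent}, \code{p0}, \code{p}.
#' @examples
#' coloc_test(72, 322) # 22.4%, p < 0.01
#' @export
coloc_test <- function(k, n, p0 = 0.09) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n,
            k == floor(k), n == floor(n))
  if (!(p0 > 0 && p0 < 1)) stop("'p0' must be in (0, 1)")
  ht <- stats::binom.test(k, n, p = p0)
  structure(
    list(n = as.integer(n), k = as.integer(k), fraction = k / n,
         percent = 100 * k / n, p0 = p0, p = ht$p.value),
    class = "coloc_test"
  )
}

#' @export
print.coloc_test <- function(x, ...) {
  cat(sprintf("Colocalization: %d/%d cells = %.1f%% (random expectation %.0f%%), exact binomial p = %.3g\n",
              x$k, x$n, x$percent, 100 * x$p0, x$p))
  invisible(x)
}
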