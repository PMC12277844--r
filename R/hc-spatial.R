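#' Tangent sampling circles around the optic disc
#'
#' Builds the regional sampling geometry for horizontal-cell counting:
#' along each of the four cardinal directions (up, down, left, right) from
#' the optic-disc center, a chain of three 500-um circles — proximal,
#' middle, distal — each tangent to the previous one, with the proximal
#' circle tangent to the disc circle. Center distances from the disc center
#' are therefore `disc_diameter/2 + 250`, `+ 750` and `+ 1250` um.
#'
#' @param disc_center optic-disc center `(x, y)`, um.
#' @param disc_diameter optic-disc circle diameter, um (conventional range
#'   100-200 um; values outside warn).
#' @param circle_diameter sampling-circle diameter, um (default 500).
#' @return data frame of class `sampling_circles`, 12 rows with columns
#'   `region` (`proximal`/`middle`/`distal`), `direction`
#'   (`up`/`down`/`left`/`right`), `center_x`, `center_y`, `diameter`,
#'   `excluded` (all `FALSE`; callers flag damaged circles).
#' @examples
#' place_sampling_circles(c(0, 0), 100)
#' @export
place_sampling_circles <- function(disc_center, disc_diameter,
                                   circle_diameter = 500) {
  check_number(disc_diameter, "disc_diameter", lower = 0, strict_lower = TRUE)
  if (disc_diameter < 100 || disc_diameter > 200)
    warning("disc_diameter outside the conventional 100-200 um range",
            call. = FALSE)
  check_number(circle_diameter, "circle_diameter", lower = 0,
               strict_lower = TRUE)
  r_c <- circle_diameter / 2
  dists <- disc_diameter / 2 + r_c + (0:2) * circle_diameter
  dirs <- rbind(up = c(0, 1), down = c(0, -1),
                left = c(-1, 0), right = c(1, 0))
  out <- do.call(rbind, lapply(rownames(dirs), function(d) {
    data.frame(region = c("proximal", "middle", "distal"),
               direction = d,
               center_x = disc_center[1] + dirs[d, 1] * dists,
               center_y = disc_center[2] + dirs[d, 2] * dists,
               diameter = circle_diameter,
               excluded = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("sampling_circles", "data.frame")
  out
}

#' Cell density inside a sampling circle
#'
#' Counts pattern points whose distance to the circle center is at most the
#' circle radius (boundary points count as inside) and divides by the circle
#' area in mm^2 (0.19635 mm^2 for a 500-um circle). Excluded circles yield
#' `NA` with a warning rather than a number.
#'
#' @param pattern a [point_pattern] (or data frame with `x_um`, `y_um`).
#' @param circle one row of a [place_sampling_circles] table (or any list
#'   with `center_x`, `center_y`, `diameter`, optionally `excluded`).
#' @return density in cells/mm^2, or `NA` for an excluded circle.
#' @export
circle_density <- function(pattern, circle) {
  pts <- if (inherits(pattern, "point_pattern")) pattern$points
         else as.data.frame(pattern)
  if (isTRUE(circle$excluded)) {
    warning("sampling circle is excluded; density not computed", call. = FALSE)
    return(NA_real_)
  }
  r <- circle$diameter / 2
  d2 <- (pts$x_um - circle$center_x)^2 + (pts$y_um - circle$center_y)^2
  count <- sum(d2 <= r^2)
  count / (pi * (r / 1000)^2)
}

#' Densities for a whole sampling-circle table
#'
#' @param pattern a [point_pattern].
#' @param circles a [place_sampling_circles] table.
#' @return the table with `count` and `density_mm2` columns added (`NA` for
#'   excluded circles).
#' @export
circle_densities <- function(pattern, circles) {
  circles <- as.data.frame(circles)
  dens <- counts <- rep(NA_real_, nrow(circles))
  for (i in seq_len(nrow(circles))) {
    ci <- as.list(circles[i, ])
    if (isTRUE(ci$excluded)) next
    dens[i] <- circle_density(pattern, ci)
    counts[i] <- dens[i] * pi * (ci$diameter / 2000)^2
  }
  circles$count <- round(counts)
  circles$density_mm2 <- dens
  circles
}

#' Nearest-neighbor distances of a point pattern
#'
#' Euclidean distance from each cell to its nearest other cell (the cell
#' itself excluded), plus a relative-frequency histogram. No edge
#' correction is applied.
#'
#' @param pattern a [point_pattern] or a two-column matrix/data frame of
#'   coordinates; at least 2 points.
#' @param bin_width histogram bin width, um (default 5).
#' @param range_max nominal histogram upper limit, um (default 100); the
#'   range is extended when larger distances occur, so relative frequencies
#'   always sum to 1.
#' @return object of class `nnd_result`: list with `distances` (um, one per
#'   point, input order) and `histogram` (data frame `bin_lo, bin_hi,
#'   count, rel_freq`).
#' @export
nnd <- function(pattern, bin_width = 5, range_max = 100) {
  pts <- if (inherits(pattern, "point_pattern")) pattern$points
         else as.data.frame(pattern)
  xy <- as.matrix(pts[, 1:2])
  n <- nrow(xy)
  if (n < 2L) stopf("nearest-neighbor distances need at least 2 points")
  # direct per-point scan: exact squared differences (no cross-product
  # expansion), O(n) memory, vectorized over the partner dimension
  x <- xy[, 1]; y <- xy[, 2]
  dist <- vapply(seq_len(n), function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf # exclude the cell itself
    sqrt(min(d2))
  }, 0)
  hi <- max(range_max, ceiling(max(dist) / bin_width) * bin_width)
  breaks <- seq(0, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  # bins [lo, hi), last bin closed at the top break, so counts sum to n
  counts <- tabulate(findInterval(dist, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(distances = dist,
                 histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                        bin_hi = breaks[-1],
                                        count = counts,
                                        rel_freq = counts / n)),
            class = "nnd_result")
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("NND: n = %d, min %.2f, median %.2f, max %.2f um\n",
              length(x$distances), min(x$distances),
              stats::median(x$distances), max(x$distances)))
  invisible(x)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test. The exact permutation
#' null is used when the groups are tie-free and the combined size is at
#' most 16; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U` (the U statistic of `a`), `p` (two-sided p-value)
#'   and `exact` (logical).
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  exact <- !anyDuplicated(c(a, b)) && (length(a) + length(b)) <= 16
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}
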