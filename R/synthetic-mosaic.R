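#' Specification of a simulated horizontal-cell mosaic field
#'
#' Describes a circular flat-mount field with an excluded optic-disc circle,
#' a target horizontal-cell density, a hard-core (minimum inter-cell)
#' distance, and optional "thinning patches" that emulate the spatially
#' patchy loss of horizontal cells in degenerating retinas: inside each
#' patch, cells are independently deleted with the patch's probability.
#'
#' @param field_radius radius of the circular field, um.
#' @param disc_center optic-disc center `(x, y)`, um.
#' @param disc_diameter optic-disc circle diameter, um; the conventional
#'   range is 100-200 um (values outside warn).
#' @param target_density cells per mm^2.
#' @param hardcore_radius minimum pairwise distance between cells, um.
#' @param thinning_patches list of patches, each
#'   `list(center = c(x, y), radius = , deletion_prob = )`.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(field_radius = 1600,
                       disc_center = c(0, 0),
                       disc_diameter = 150,
                       target_density = 1000,
                       hardcore_radius = 15,
                       thinning_patches = list()) {
  check_number(field_radius, "field_radius", lower = 0, strict_lower = TRUE)
  check_number(disc_diameter, "disc_diameter", lower = 0, strict_lower = TRUE)
  if (disc_diameter < 100 || disc_diameter > 200)
    warning("disc_diameter outside the conventional 100-200 um range",
            call. = FALSE)
  check_number(target_density, "target_density", lower = 0, strict_lower = TRUE)
  check_number(hardcore_radius, "hardcore_radius", lower = 0)
  for (p in thinning_patches) {
    if (!is.list(p) || is.null(p$center) || is.null(p$radius) ||
        is.null(p$deletion_prob))
      stopf("each thinning patch needs center, radius and deletion_prob")
    check_number(p$deletion_prob, "deletion_prob", lower = 0, upper = 1)
    check_number(p$radius, "patch radius", lower = 0, strict_lower = TRUE)
  }
  structure(list(field_radius = field_radius, disc_center = disc_center,
                 disc_diameter = disc_diameter,
                 target_density = target_density,
                 hardcore_radius = hardcore_radius,
                 thinning_patches = thinning_patches),
            class = "field_spec")
}

#' Point pattern of cell centroids
#'
#' @param points data frame (or matrix) with columns `x_um`, `y_um`.
#' @param field_radius,disc_center,disc_diameter field geometry as in
#'   [field_spec].
#' @return object of class `point_pattern`.
#' @export
point_pattern <- function(points, field_radius, disc_center = c(0, 0),
                          disc_diameter = 150) {
  points <- as.data.frame(points)
  if (nrow(points) && !all(c("x_um", "y_um") %in% names(points)))
    stopf("'points' needs columns 'x_um' and 'y_um'")
  if (!nrow(points))
    points <- data.frame(x_um = numeric(), y_um = numeric())
  structure(list(points = points[, c("x_um", "y_um"), drop = FALSE],
                 field_radius = field_radius,
                 disc_center = disc_center,
                 disc_diameter = disc_diameter),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d cells, field radius %g um, disc %g um at (%g, %g)\n",
              nrow(x$points), x$field_radius, x$disc_diameter,
              x$disc_center[1], x$disc_center[2]))
  invisible(x)
}

#' Simulate a hard-core horizontal-cell mosaic with patchy thinning
#'
#' Sequential dart throwing inside the circular field (optic-disc circle
#' excluded): candidate points are drawn uniformly and accepted only when at
#' least `hardcore_radius` from every accepted point, until the Poisson
#' target count `N ~ Pois(density x usable area)` is reached or the attempt
#' budget (10^4 x N darts) is exhausted, which raises an error (infeasible
#' packing). Points falling in a thinning patch are then independently
#' deleted with the patch's probability, which models the spatially uneven
#' cell loss of degeneration while leaving the minimum inter-cell distance
#' intact.
#'
#' @param field a [field_spec].
#' @param seed integer seed; same `(field, seed)` give an identical pattern.
#' @return a [point_pattern].
#' @export
gen_hc_pattern <- function(field, seed) {
  stopifnot(inherits(field, "field_spec"))
  local_rng(seed)
  r_f <- field$field_radius
  r_d <- field$disc_diameter / 2
  area_mm2 <- (pi * r_f^2 - pi * r_d^2) / 1e6
  if (area_mm2 <= 0) stopf("optic disc covers the whole field")
  n_target <- stats::rpois(1L, field$target_density * area_mm2)
  hc <- field$hardcore_radius

  # occupancy grid (cell size = hardcore radius) for O(1) neighbor checks
  use_grid <- hc > 0
  if (use_grid) {
    ng <- max(1L, ceiling(2 * r_f / hc))
    grid <- vector("list", ng * ng)
    cell_of <- function(x, y) {
      gx <- pmin(ng, pmax(1L, ceiling((x + r_f) / hc)))
      gy <- pmin(ng, pmax(1L, ceiling((y + r_f) / hc)))
      (gy - 1L) * ng + gx
    }
  }
  xs <- numeric(n_target); ys <- numeric(n_target)
  n_acc <- 0L
  budget <- 1e4 * max(1L, n_target)
  spent <- 0L
  chunk <- max(256L, n_target)
  while (n_acc < n_target) {
    if (spent >= budget)
      stopf("hard-core packing infeasible: %d of %d points placed after %g darts",
            n_acc, n_target, budget)
    m <- min(chunk, budget - spent)
    spent <- spent + m
    # uniform in the field disc by rejection from the bounding square
    cx <- stats::runif(m, -r_f, r_f)
    cy <- stats::runif(m, -r_f, r_f)
    rr <- cx^2 + cy^2
    dd <- (cx - field$disc_center[1])^2 + (cy - field$disc_center[2])^2
    ok <- rr <= r_f^2 & dd > r_d^2
    for (i in which(ok)) {
      if (n_acc >= n_target) break
      x <- cx[i]; y <- cy[i]
      if (use_grid && n_acc > 0L) {
        gx <- ceiling((x + r_f) / hc); gy <- ceiling((y + r_f) / hc)
        near <- unlist(lapply(max(1L, gy - 1L):min(ng, gy + 1L), function(g_y)
          unlist(grid[(g_y - 1L) * ng + max(1L, gx - 1L):min(ng, gx + 1L)])),
          use.names = FALSE)
        if (length(near) &&
            any((xs[near] - x)^2 + (ys[near] - y)^2 < hc^2)) next
      }
      n_acc <- n_acc + 1L
      xs[n_acc] <- x; ys[n_acc] <- y
      if (use_grid) {
        ci <- cell_of(x, y)
        grid[[ci]] <- c(grid[[ci]], n_acc)
      }
    }
  }
  xs <- xs[seq_len(n_acc)]; ys <- ys[seq_len(n_acc)]

  keep <- rep(TRUE, n_acc)
  for (p in field$thinning_patches) {
    inside <- (xs - p$center[1])^2 + (ys - p$center[2])^2 <= p$radius^2
    del <- inside & stats::runif(n_acc) < p$deletion_prob
    keep <- keep & !del
  }
  point_pattern(data.frame(x_um = xs[keep], y_um = ys[keep]),
                field_radius = r_f, disc_center = field$disc_center,
                disc_diameter = field$disc_diameter)
}
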