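#' Standard 60-electrode MEA layout
#'
#' 8 x 8 grid with the four corner positions absent (60 active electrodes),
#' 200-um inter-electrode pitch, 30-um electrode pads.
#'
#' @param pitch inter-electrode distance, um (default 200).
#' @param electrode_size pad side length, um (default 30).
#' @param origin `(x, y)` of the grid's first row/column position, um.
#' @return object of class `electrode_layout`: list with `positions`
#'   (data frame `electrode_id, row, col, x_um, y_um`), `pitch`,
#'   `electrode_size`.
#' @examples
#' nrow(electrode_layout()$positions) # 60
#' @export
electrode_layout <- function(pitch = 200, electrode_size = 30,
                             origin = c(0, 0)) {
  check_number(pitch, "pitch", lower = 0, strict_lower = TRUE)
  check_number(electrode_size, "electrode_size", lower = 0, strict_lower = TRUE)
  g <- expand.grid(row = 1:8, col = 1:8)
  corner <- (g$row %in% c(1, 8)) & (g$col %in% c(1, 8))
  g <- g[!corner, , drop = FALSE]
  pos <- data.frame(electrode_id = sprintf("el_%d%d", g$col, g$row),
                    row = g$row, col = g$col,
                    x_um = origin[1] + (g$col - 1) * pitch,
                    y_um = origin[2] + (g$row - 1) * pitch,
                    stringsAsFactors = FALSE)
  rownames(pos) <- NULL
  structure(list(positions = pos, pitch = pitch,
                 electrode_size = electrode_size),
            class = "electrode_layout")
}

#' Assign electrodes to graft-centric areas 1-5
#'
#' Labels each electrode by its position relative to the grafted region:
#' the graft mask is dilated by discs of radius `m * base_radius` for
#' magnifications `m = 1, 5, 10, 15`; area 1 is the 1x dilation (graft and
#' border), areas 2-4 are the successive 5x/10x/15x rings, and area 5 is
#' everything more peripheral than area 4. Dilation by a disc is evaluated
#' exactly through its distance characterization: a point lies in
#' `mask (+) disc(r)` iff its Euclidean distance to the mask is at most `r`,
#' so electrodes are binned by their distance to the nearest graft pixel.
#' The resulting electrode sets are nested by construction and every
#' electrode receives exactly one area.
#'
#' @param mask logical (or 0/1) matrix, the graft raster; `mask[i, j]` covers
#'   the pixel centered at `x = origin[1] + (j - 0.5) * pixel_size`,
#'   `y = origin[2] + (i - 0.5) * pixel_size`.
#' @param pixel_size pixel edge length, um.
#' @param layout an [electrode_layout].
#' @param base_radius dilation base radius, um; the default 200 um equals one
#'   electrode pitch.
#' @param magnifications increasing dilation magnifications (default
#'   `c(1, 5, 10, 15)`).
#' @param origin `(x, y)` of the raster's lower corner, um.
#' @return object of class `area_map`: list with `assignment` (data frame
#'   `electrode_id, area, dist_um` where `dist_um` is the distance to the
#'   graft mask), `base_radius`, `magnifications`.
#' @export
assign_electrode_areas <- function(mask, pixel_size, layout,
                                   base_radius = 200,
                                   magnifications = c(1, 5, 10, 15),
                                   origin = c(0, 0)) {
  stopifnot(inherits(layout, "electrode_layout"))
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(base_radius, "base_radius", lower = 0, strict_lower = TRUE)
  if (!is.matrix(mask)) stopf("'mask' must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stopf("'mask' is empty: no graft pixels")
  if (length(magnifications) != 4L || is.unsorted(magnifications, strictly = TRUE) ||
      any(magnifications <= 0))
    stopf("'magnifications' must be 4 strictly increasing positive values")

  idx <- which(mask, arr.ind = TRUE)
  px <- cbind(x = origin[1] + (idx[, "col"] - 0.5) * pixel_size,
              y = origin[2] + (idx[, "row"] - 0.5) * pixel_size)
  el <- layout$positions
  extent_x <- origin[1] + c(0, ncol(mask) * pixel_size)
  extent_y <- origin[2] + c(0, nrow(mask) * pixel_size)
  if (any(el$x_um < extent_x[1] | el$x_um > extent_x[2] |
          el$y_um < extent_y[1] | el$y_um > extent_y[2]))
    stopf("electrodes fall outside the raster extent")

  d <- sqrt(cross_dist2(cbind(el$x_um, el$y_um), px))
  dist_um <- apply(d, 1L, min)
  # electrode whose own pixel is graft counts as distance 0 (it is in the mask)
  row_i <- pmin(nrow(mask), pmax(1L, ceiling((el$y_um - origin[2]) / pixel_size)))
  col_i <- pmin(ncol(mask), pmax(1L, ceiling((el$x_um - origin[1]) / pixel_size)))
  dist_um[mask[cbind(row_i, col_i)]] <- 0

  # area 1 = within the 1x dilation; 2-4 = successive rings; 5 = beyond 15x
  thr <- magnifications * base_radius
  area <- vapply(dist_um, function(dd) {
    w <- which(dd <= thr)
    if (length(w)) w[1] else 5L
  }, 1L)

  structure(list(assignment = data.frame(electrode_id = el$electrode_id,
                                         area = as.integer(area),
                                         dist_um = dist_um,
                                         stringsAsFactors = FALSE),
                 base_radius = base_radius,
                 magnifications = magnifications),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  tab <- table(factor(x$assignment$area, levels = 1:5))
  cat("Electrode areas (1 = graft and border ... 5 = most peripheral):\n")
  print(tab)
  invisible(x)
}

#' Disc-shaped graft mask raster
#'
#' Convenience constructor of a circular graft mask: pixel centers within
#' `radius` of `center` are set. Useful for simulated recordings and for
#' closed-form checks of [assign_electrode_areas].
#'
#' @param nrow,ncol raster size in pixels.
#' @param pixel_size pixel edge length, um.
#' @param center disc center `(x, y)`, um.
#' @param radius disc radius, um.
#' @param origin raster lower-corner `(x, y)`, um.
#' @return logical matrix.
#' @export
disc_mask <- function(nrow, ncol, pixel_size, center, radius,
                      origin = c(0, 0)) {
  cx <- origin[1] + (seq_len(ncol) - 0.5) * pixel_size
  cy <- origin[2] + (seq_len(nrow) - 0.5) * pixel_size
  outer(cy, cx, function(y, x) (x - center[1])^2 + (y - center[2])^2 <= radius^2)
}
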