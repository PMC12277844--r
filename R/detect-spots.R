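# separable 1D Gaussian convolution along one dimension of a 3D array,
# symmetric-reflection padding at the borders
gauss_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

convolve_dim <- function(vol, k, dim_i) {
  if (length(k) == 1L) return(vol)
  half <- (length(k) - 1L) / 2L
  d <- dim(vol)
  # move the target dimension first, filter columns, move back
  perm <- c(dim_i, setdiff(1:3, dim_i))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  n <- nrow(m)
  pad_top <- m[pmin(n, (half + 1):2), , drop = FALSE]
  pad_bot <- m[pmax(1L, (n - 1):(n - half)), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  v <- array(out, dv)
  aperm(v, order(perm))
}

gaussian_smooth3d <- function(vol, sigma_vox) {
  for (i in 1:3) vol <- convolve_dim(vol, gauss_kernel1d(sigma_vox[i]), i)
  vol
}

# 26-neighborhood strict local maxima of a 3D array
local_maxima3d <- function(vol) {
  d <- dim(vol)
  if (any(d < 3L)) return(array(FALSE, d))
  core <- vol[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  is_max <- array(TRUE, dim(core))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- vol[(2:(d[1] - 1)) + dx, (2:(d[2] - 1)) + dy, (2:(d[3] - 1)) + dz]
    is_max <- is_max & (core > nb)
  }
  out <- array(FALSE, d)
  out[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- is_max
  out
}

#' Detect puncta in a 3D intensity volume (scale-normalized LoG)
#'
#' Blob detection standing in for interactive spot tracing: the volume is
#' smoothed with an isotropic (in physical units) Gaussian of width `sigma`,
#' the negated scale-normalized Laplacian `-sigma^2 * lap(G * I)` is
#' computed with finite differences on the physical grid, and strict
#' 26-neighborhood local maxima of the response above `min_intensity` are
#' returned as spot centroids in physical coordinates.
#'
#' @param volume 3D numeric array indexed `[x, y, z]`.
#' @param sigma blob scale, um; should match the expected punctum radius.
#' @param min_intensity detection threshold on the LoG response (a.u.).
#' @param voxel_size `(x, y, z)` voxel edge lengths, um; anisotropic voxels
#'   are supported (the z spacing must be given).
#' @param origin physical coordinates of the raster corner, um.
#' @return data frame `(id, x_um, y_um, z_um, response)`, strongest spots
#'   first. An all-zero volume yields no spots.
#' @export
detect_spots <- function(volume, sigma, min_intensity,
                         voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(volume)) != 3L) stopf("'volume' must be a 3D array")
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(min_intensity, "min_intensity")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stopf("'voxel_size' must give three positive spacings (z included)")

  sigma_vox <- sigma / voxel_size
  sm <- gaussian_smooth3d(volume, sigma_vox)

  # second differences along each axis, scaled by the physical spacing
  lap <- array(0, dim(volume))
  d <- dim(volume)
  for (i in 1:3) {
    if (d[i] < 3L) next
    perm <- c(i, setdiff(1:3, i))
    v <- aperm(sm, perm)
    dv <- dim(v)
    m <- matrix(v, nrow = dv[1])
    sec <- matrix(0, nrow = dv[1], ncol = ncol(m))
    sec[2:(dv[1] - 1), ] <- (m[1:(dv[1] - 2), ] + m[3:dv[1], ] -
                               2 * m[2:(dv[1] - 1), ]) / voxel_size[i]^2
    lap <- lap + aperm(array(sec, dv), order(perm))
  }
  resp <- -sigma^2 * lap

  peaks <- local_maxima3d(resp) & (resp > min_intensity)
  idx <- which(peaks, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(id = character(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), response = numeric()))
  r <- resp[peaks]
  ord <- order(-r)
  idx <- idx[ord, , drop = FALSE]
  rownames(idx) <- NULL
  data.frame(id = sprintf("spot_%03d", seq_len(nrow(idx))),
             x_um = origin[1] + (idx[, 1] - 0.5) * voxel_size[1],
             y_um = origin[2] + (idx[, 2] - 0.5) * voxel_size[2],
             z_um = origin[3] + (idx[, 3] - 0.5) * voxel_size[3],
             response = r[ord],
             stringsAsFactors = FALSE)
}
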