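#' Detect host-graft synapses by the triple-proximity rule
#'
#' A synapse is a CtBP2 spot lying within `radius` (default 1.5 um,
#' inclusive) of both an mGluR6 spot and an RBC dendrite. For each CtBP2
#' spot the nearest mGluR6 spot and the nearest point on any dendrite
#' polyline (exact point-to-segment distance) are found; a record is emitted
#' iff both distances are at most `radius`, so each CtBP2 spot yields at
#' most one synapse. Exact distance ties resolve to the lexicographically
#' smallest partner id. The dendrite realizing the shortest distance defines
#' the synapse's RBC.
#'
#' @param scene a [puncta_scene].
#' @param radius proximity radius, um (default 1.5).
#' @return data frame of class `synapse_records` with columns `ctbp2_id`,
#'   `mglur6_id`, `rbc_id`, `d_ctbp2_mglur6`, `d_ctbp2_dendrite` (um).
#'   Empty channels give an empty table.
#' @examples
#' sc <- gen_puncta_scene(scene_spec(n_true_synapses = 3,
#'                                   n_distractor_ctbp2 = 5,
#'                                   n_distractor_mglur6 = 5), seed = 1)
#' detect_synapses(sc$scene)
#' @export
detect_synapses <- function(scene, radius = 1.5) {
  stopifnot(inherits(scene, "puncta_scene"))
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  empty <- data.frame(ctbp2_id = character(), mglur6_id = character(),
                      rbc_id = character(), d_ctbp2_mglur6 = numeric(),
                      d_ctbp2_dendrite = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("synapse_records", "data.frame")
  if (!nrow(scene$ctbp2) || !nrow(scene$mglur6) || !nrow(scene$dendrites))
    return(empty)

  cx <- as.matrix(scene$ctbp2[, c("x_um", "y_um", "z_um")])
  mx <- as.matrix(scene$mglur6[, c("x_um", "y_um", "z_um")])
  # nearest mGluR6 per CtBP2; ties to the lexicographically smallest id
  m_ord <- order(scene$mglur6$id)
  d_m <- sqrt(cross_dist2(cx, mx[m_ord, , drop = FALSE]))
  j <- apply(d_m, 1L, which.min) # first minimum = smallest id after ordering
  d_mglur6 <- d_m[cbind(seq_len(nrow(cx)), j)]
  mglur6_id <- scene$mglur6$id[m_ord][j]

  dd <- dendrite_min_dist(cx, scene$dendrites)

  keep <- d_mglur6 <= radius & dd$dist <= radius
  out <- data.frame(ctbp2_id = scene$ctbp2$id[keep],
                    mglur6_id = mglur6_id[keep],
                    rbc_id = dd$cell_id[keep],
                    d_ctbp2_mglur6 = d_mglur6[keep],
                    d_ctbp2_dendrite = dd$dist[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("synapse_records", "data.frame")
  out
}

#' Rosette surface from a binary mask
#'
#' Wraps a 3D binary raster of the photoreceptor rosette (anisotropic voxels
#' supported) for distance queries: the distance from a point to the surface
#' is its Euclidean distance to the nearest mask voxel center in physical
#' coordinates (0 for points inside the rosette, up to voxel resolution).
#'
#' @param mask 3D logical (or 0/1) array indexed `[x, y, z]`.
#' @param voxel_size `(x, y, z)` voxel edge lengths, um.
#' @param origin physical coordinates of the raster corner, um.
#' @return object of class `rosette_surface`.
#' @export
rosette_surface <- function(mask, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stopf("'mask' must be a 3D array")
  mask <- mask != 0
  if (!any(mask)) stopf("rosette mask is empty")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("'voxel_size' must be three positive edge lengths")
  idx <- which(mask, arr.ind = TRUE)
  vox <- cbind(origin[1] + (idx[, 1] - 0.5) * voxel_size[1],
               origin[2] + (idx[, 2] - 0.5) * voxel_size[2],
               origin[3] + (idx[, 3] - 0.5) * voxel_size[3])
  structure(list(voxels = vox, voxel_size = voxel_size, origin = origin,
                 dim = dim(mask)),
            class = "rosette_surface")
}

#' Distance from points to a rosette surface
#'
#' @param surface a [rosette_surface].
#' @param points matrix/data frame of query points (x, y, z), um.
#' @return numeric vector of distances (um), one per point.
#' @export
surface_distance <- function(surface, points) {
  stopifnot(inherits(surface, "rosette_surface"))
  points <- as.matrix(points)
  # chunk queries so the cross-distance matrix stays small
  n <- nrow(points)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(surface$voxels)))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    d2 <- cross_dist2(points[s:e, , drop = FALSE], surface$voxels)
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Select RBCs extending dendrites near the rosette surface
#'
#' A cell is selected when any point of its skeleton — vertices and points
#' sampled densely along every segment — lies within `reach` (default 10 um,
#' inclusive) of the rosette surface.
#'
#' @param dendrites dendrite table as in [puncta_scene].
#' @param surface a [rosette_surface].
#' @param reach selection distance, um (default 10).
#' @param step sampling step along segments, um (default 0.5).
#' @return character vector of selected `cell_id`s (sorted, unique).
#' @export
select_rbcs_near_rosette <- function(dendrites, surface, reach = 10,
                                     step = 0.5) {
  stopifnot(inherits(surface, "rosette_surface"))
  dendrites <- as.data.frame(dendrites)
  if (!nrow(dendrites)) return(character())
  check_number(reach, "reach", lower = 0)
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  xyz <- as.matrix(dendrites[, c("x_um", "y_um", "z_um")])
  cells <- as.character(dendrites$cell_id)
  segs <- dendrite_segments(dendrites)
  pts <- list(xyz)
  owner <- list(cells)
  for (k in seq_len(nrow(segs))) {
    a <- xyz[segs$i[k], ]; b <- xyz[segs$j[k], ]
    len <- sqrt(sum((b - a)^2))
    if (len <= step) next
    t <- seq(0, 1, length.out = max(3L, ceiling(len / step) + 1L))
    t <- t[-c(1L, length(t))] # endpoints are already in the vertex set
    pts[[length(pts) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                     a[2] + t * (b[2] - a[2]),
                                     a[3] + t * (b[3] - a[3]))
    owner[[length(owner) + 1L]] <- rep(cells[segs$i[k]], length(t))
  }
  allp <- do.call(rbind, pts)
  allc <- unlist(owner, use.names = FALSE)
  d <- surface_distance(surface, allp)
  sort(unique(allc[d <= reach]))
}

#' Per-RBC synapse counts and the synapse-forming set
#'
#' Counts detected synapses per selected RBC; cells with at least one
#' synapse are labeled as "RBC with forming synapse". Records on cells
#' outside the selection are kept but flagged.
#'
#' @param records a [detect_synapses] table.
#' @param selected character vector of selected cell ids (e.g. from
#'   [select_rbcs_near_rosette]).
#' @return list with `counts` (named integer vector over `selected`),
#'   `forming` (cell ids with >= 1 synapse), `mean_count` (mean synapses
#'   per selected RBC) and `unselected_records` (rows whose RBC is outside
#'   the selection).
#' @export
synapses_per_rbc <- function(records, selected) {
  records <- as.data.frame(records)
  selected <- as.character(selected)
  counts <- stats::setNames(integer(length(selected)), selected)
  inside <- records$rbc_id %in% selected
  if (nrow(records) && any(inside)) {
    tab <- table(records$rbc_id[inside])
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts,
       forming = names(counts)[counts > 0],
       mean_count = if (length(counts)) mean(counts) else NA_real_,
       unselected_records = records[!inside, , drop = FALSE])
}

#' Density of synapse-forming RBCs per grafted area
#'
#' @param forming cell ids of RBCs with at least one synapse.
#' @param graft_area_mm2 grafted (projected) area, mm^2, > 0.
#' @return density in cells/mm^2.
#' @examples
#' forming_rbc_density(c("a", "b", "c", "d"), 0.2) # 20
#' @export
forming_rbc_density <- function(forming, graft_area_mm2) {
  check_number(graft_area_mm2, "graft_area_mm2", lower = 0,
               strict_lower = TRUE)
  length(unique(forming)) / graft_area_mm2
}
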