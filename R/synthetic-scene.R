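#' Specification of a simulated 3D puncta scene
#'
#' Describes a confocal-like volume containing planted host-graft synapses
#' — CtBP2 (presynaptic ribbon) / mGluR6 (postsynaptic) spot pairs with a
#' rod-bipolar-cell (RBC) dendrite routed past them — plus distractor spots
#' of both channels placed far from every planted structure. `min_separation`
#' must exceed twice the synapse radius used downstream (1.5 um), so that
#' distractors can never satisfy the proximity rule.
#'
#' @param volume_extent `(x, y, z)` extents of the volume, um.
#' @param n_true_synapses number of planted synaptic triplets.
#' @param n_distractor_ctbp2,n_distractor_mglur6 distractor spot counts.
#' @param n_rbc number of RBC dendritic skeletons.
#' @param min_separation minimum distance from any distractor to every other
#'   structure, um (default 4).
#' @param jitter_sd SD of the Gaussian CtBP2-mGluR6 offset, um; offsets are
#'   redrawn until their norm is below 1.4 um so planted pairs always satisfy
#'   the 1.5-um rule with margin.
#' @param synapse_radius downstream detection radius used for the
#'   `min_separation` feasibility check, um.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(volume_extent = c(60, 60, 30),
                       n_true_synapses = 20,
                       n_distractor_ctbp2 = 50,
                       n_distractor_mglur6 = 50,
                       n_rbc = 8,
                       min_separation = 4,
                       jitter_sd = 0.5,
                       synapse_radius = 1.5) {
  if (length(volume_extent) != 3L || any(volume_extent <= 0))
    stopf("'volume_extent' must be three positive extents (x, y, z)")
  for (nm in c("n_true_synapses", "n_distractor_ctbp2",
               "n_distractor_mglur6", "n_rbc"))
    check_number(get(nm), nm, lower = 0)
  check_number(min_separation, "min_separation", lower = 0, strict_lower = TRUE)
  check_number(jitter_sd, "jitter_sd", lower = 0, strict_lower = TRUE)
  if (min_separation <= 2 * synapse_radius)
    stopf("min_separation (%g) must exceed 2 x synapse radius (%g)",
          min_separation, 2 * synapse_radius)
  if (n_true_synapses > 0 && n_rbc < 1)
    stopf("planted synapses need at least one RBC")
  structure(list(volume_extent = volume_extent,
                 n_true_synapses = as.integer(n_true_synapses),
                 n_distractor_ctbp2 = as.integer(n_distractor_ctbp2),
                 n_distractor_mglur6 = as.integer(n_distractor_mglur6),
                 n_rbc = as.integer(n_rbc),
                 min_separation = min_separation,
                 jitter_sd = jitter_sd,
                 synapse_radius = synapse_radius),
            class = "scene_spec")
}

#' Assemble a puncta scene container
#'
#' @param ctbp2,mglur6 data frames `(id, x_um, y_um, z_um)`.
#' @param dendrites data frame
#'   `(cell_id, polyline_id, vertex, x_um, y_um, z_um)` with consecutive
#'   vertices of a polyline forming its segments.
#' @param voxel_size optional `(x, y, z)` voxel size for raster-derived
#'   scenes, um.
#' @return object of class `puncta_scene`.
#' @export
puncta_scene <- function(ctbp2, mglur6, dendrites, voxel_size = NULL) {
  empty_spots <- data.frame(id = character(), x_um = numeric(),
                            y_um = numeric(), z_um = numeric())
  empty_dend <- data.frame(cell_id = character(), polyline_id = integer(),
                           vertex = integer(), x_um = numeric(),
                           y_um = numeric(), z_um = numeric())
  norm_spots <- function(x, chan) {
    x <- as.data.frame(x)
    if (!nrow(x)) return(empty_spots)
    if (!all(c("id", "x_um", "y_um", "z_um") %in% names(x)))
      stopf("'%s' needs columns id, x_um, y_um, z_um", chan)
    if (anyDuplicated(x$id)) stopf("duplicate ids in channel '%s'", chan)
    if (!all(is.finite(as.matrix(x[, c("x_um", "y_um", "z_um")]))))
      stopf("non-finite coordinates in channel '%s'", chan)
    x[, c("id", "x_um", "y_um", "z_um")]
  }
  dendrites <- as.data.frame(dendrites)
  if (!nrow(dendrites)) dendrites <- empty_dend
  structure(list(ctbp2 = norm_spots(ctbp2, "ctbp2"),
                 mglur6 = norm_spots(mglur6, "mglur6"),
                 dendrites = dendrites,
                 voxel_size = voxel_size),
            class = "puncta_scene")
}

#' @export
print.puncta_scene <- function(x, ...) {
  cat(sprintf("puncta_scene: %d CtBP2, %d mGluR6 spots, %d dendrite vertices (%d cells)\n",
              nrow(x$ctbp2), nrow(x$mglur6), nrow(x$dendrites),
              length(unique(x$dendrites$cell_id))))
  invisible(x)
}

# minimum distance from points to every structure placed so far
min_dist_to_structures <- function(p, spots, dend_xyz, segs) {
  d <- Inf
  if (nrow(spots)) d <- min(d, sqrt(min(cross_dist2(p, spots))))
  if (!is.null(segs) && nrow(segs))
    for (k in seq_len(nrow(segs)))
      d <- min(d, point_segment_dist(p, dend_xyz[segs$i[k], ],
                                     dend_xyz[segs$j[k], ]))
  d
}

#' Simulate a 3D puncta scene with planted synapses
#'
#' For each planted synapse, one CtBP2 spot is placed uniformly in the
#' volume (with a margin), one mGluR6 spot is offset from it by a Gaussian
#' jitter rejected to stay within 1.4 um, and a short dendrite polyline of
#' the assigned RBC is routed so that it passes within about 0.5 um of the
#' CtBP2 spot. Planted structures keep `min_separation` from each other;
#' distractor spots of both channels are then placed at least
#' `min_separation` from every spot and every dendrite segment, so a
#' distractor can never satisfy the 1.5-um triple-proximity rule. Placement
#' failure after a bounded number of attempts raises an error.
#'
#' @param spec a [scene_spec].
#' @param seed integer seed; same `(spec, seed)` give an identical scene.
#' @return list with `scene` (a [puncta_scene]) and `ground_truth`
#'   (data frame `(ctbp2_id, mglur6_id, rbc_id)` of planted triplets).
#' @export
gen_puncta_scene <- function(spec, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  local_rng(seed)
  ext <- spec$volume_extent
  margin <- spec$min_separation
  if (any(ext <= 2 * margin + 1))
    stopf("volume too small for the requested min_separation")
  runifv <- function() vapply(ext, function(e) stats::runif(1, margin, e - margin), 0)

  n_syn <- spec$n_true_synapses
  rbc_ids <- if (spec$n_rbc > 0) sprintf("rbc_%02d", seq_len(spec$n_rbc)) else character()
  ctbp2 <- mglur6 <- matrix(numeric(0), ncol = 3)
  dend <- list()
  truth <- data.frame(ctbp2_id = character(), mglur6_id = character(),
                      rbc_id = character(), stringsAsFactors = FALSE)
  max_attempts <- 1e4

  all_spots <- function() rbind(ctbp2, mglur6)
  dend_table <- function() {
    if (!length(dend)) return(NULL)
    do.call(rbind, dend)
  }

  for (s in seq_len(n_syn)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- matrix(runifv(), ncol = 3)
      dtab <- dend_table()
      segs <- if (is.null(dtab)) NULL else dendrite_segments(dtab)
      dxyz <- if (is.null(dtab)) NULL else as.matrix(dtab[, c("x_um", "y_um", "z_um")])
      if (min_dist_to_structures(p, all_spots(), dxyz, segs) < spec$min_separation)
        next
      # mGluR6 within 1.4 um of CtBP2 (margin under the 1.5-um rule)
      repeat {
        off <- stats::rnorm(3, 0, spec$jitter_sd)
        if (sqrt(sum(off^2)) <= 1.4) break
      }
      q <- p + rbind(off)
      if (any(q < 0) || any(q > rbind(ext))) next
      # dendrite: straight 6-um segment whose closest point to the CtBP2
      # spot is a 0.5-um-offset anchor (distance to spot ~0.5 um <= 1.5)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      anchor <- p + 0.5 * rbind(v)
      a <- anchor - 3 * rbind(u); b <- anchor + 3 * rbind(u)
      ext2 <- matrix(ext, nrow = 2, ncol = 3, byrow = TRUE)
      if (any(rbind(a, b) < 0) || any(rbind(a, b) > ext2))
        next
      # the new dendrite must stay clear of every earlier spot, so each
      # planted CtBP2's nearest dendrite remains its own
      prev <- all_spots()
      if (nrow(prev) &&
          min(point_segment_dist(prev, as.numeric(a), as.numeric(b))) <
            spec$min_separation)
        next
      rbc <- rbc_ids[(s - 1L) %% length(rbc_ids) + 1L]
      ctbp2 <- rbind(ctbp2, p)
      mglur6 <- rbind(mglur6, q)
      dend[[length(dend) + 1L]] <- data.frame(
        cell_id = rbc, polyline_id = s, vertex = 1:3,
        x_um = c(a[1], anchor[1], b[1]),
        y_um = c(a[2], anchor[2], b[2]),
        z_um = c(a[3], anchor[3], b[3]),
        stringsAsFactors = FALSE)
      truth <- rbind(truth, data.frame(
        ctbp2_id = sprintf("ctbp2_%03d", s),
        mglur6_id = sprintf("mglur6_%03d", s),
        rbc_id = rbc, stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("failed to place planted synapse %d after %g attempts", s, max_attempts)
  }

  dtab <- dend_table()
  segs <- if (is.null(dtab)) NULL else dendrite_segments(dtab)
  dxyz <- if (is.null(dtab)) NULL else as.matrix(dtab[, c("x_um", "y_um", "z_um")])
  place_distractors <- function(n, existing_other) {
    out <- matrix(numeric(0), ncol = 3)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- matrix(runifv(), ncol = 3)
        existing <- rbind(ctbp2, mglur6, out, existing_other)
        if (min_dist_to_structures(p, existing, dxyz, segs) >= spec$min_separation) {
          out <- rbind(out, p); ok <- TRUE; break
        }
      }
      if (!ok) stopf("failed to place distractor after %g attempts", max_attempts)
    }
    out
  }
  d_ctbp2 <- place_distractors(spec$n_distractor_ctbp2,
                               matrix(numeric(0), ncol = 3))
  d_mglur6 <- place_distractors(spec$n_distractor_mglur6, d_ctbp2)

  mk_spots <- function(planted, distract, prefix) {
    xyz <- rbind(planted, distract)
    n_p <- nrow(planted)
    ids <- c(sprintf("%s_%03d", prefix, seq_len(n_p)),
             if (nrow(distract))
               sprintf("%s_d%03d", prefix, seq_len(nrow(distract))))
    if (!nrow(xyz))
      return(data.frame(id = character(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric()))
    data.frame(id = ids, x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  scene <- puncta_scene(mk_spots(ctbp2, d_ctbp2, "ctbp2"),
                        mk_spots(mglur6, d_mglur6, "mglur6"),
                        if (is.null(dtab)) data.frame() else dtab)
  list(scene = scene, ground_truth = truth)
}
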