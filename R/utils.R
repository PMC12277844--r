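# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the allowed range", name, x)
  invisible(x)
}

# squared euclidean distance between rows of a and rows of b (nxd, mxd)
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Distance from points to a line segment
#'
#' Exact Euclidean distance from each row of `p` to the segment with
#' endpoints `a` and `b`, in any dimension.
#'
#' @param p numeric matrix of query points (one per row).
#' @param a,b numeric vectors, the segment endpoints.
#' @return numeric vector of distances, one per row of `p`.
#' @keywords internal
#' @noRd
point_segment_dist <- function(p, a, b) {
  p <- as.matrix(p)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 <= 0) { # degenerate segment: a point
    return(sqrt(rowSums(sweep(p, 2L, a)^2)))
  }
  ap <- sweep(p, 2L, a)
  t <- pmin(1, pmax(0, as.vector(ap %*% ab) / len2))
  proj <- outer(t, ab) # closest point offsets from a
  sqrt(rowSums((ap - proj)^2))
}

# all segments of a dendrite table as endpoint index pairs; the table must be
# ordered (cell_id, polyline_id, vertex) with consecutive vertices forming
# segments within each polyline
dendrite_segments <- function(dendrites) {
  if (nrow(dendrites) == 0L)
    return(data.frame(i = integer(), j = integer()))
  key <- paste(dendrites$cell_id, dendrites$polyline_id)
  n <- nrow(dendrites)
  same <- key[-n] == key[-1L]
  i <- which(same)
  data.frame(i = i, j = i + 1L)
}

# minimum distance from each query point to any dendrite segment, plus the
# cell realizing it (ties broken by lexicographic cell_id order)
dendrite_min_dist <- function(points, dendrites) {
  points <- as.matrix(points)
  n <- nrow(points)
  best <- rep(Inf, n)
  best_cell <- rep(NA_character_, n)
  segs <- dendrite_segments(dendrites)
  if (nrow(segs) == 0L)
    return(list(dist = best, cell_id = best_cell))
  xyz <- as.matrix(dendrites[, c("x_um", "y_um", "z_um")])
  cells <- as.character(dendrites$cell_id)
  ord <- order(cells) # lexicographic tie-break: visit cells in id order
  segs <- segs[order(cells[segs$i]), , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    d <- point_segment_dist(points, xyz[segs$i[k], ], xyz[segs$j[k], ])
    upd <- d < best # strict: earlier (lexicographically smaller) cell wins ties
    best[upd] <- d[upd]
    best_cell[upd] <- cells[segs$i[k]]
  }
  list(dist = best, cell_id = best_cell)
}

# one pass: spike times grouped into per-trial vectors (empty trials kept)
split_trials <- function(t, trial, n_trials) {
  unname(split(t, factor(trial, levels = seq_len(n_trials))))
}

# seed all RNG locally for the duration of the caller
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}
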