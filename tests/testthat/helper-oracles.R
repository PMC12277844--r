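# Independent oracles and fixture builders. Everything here is deliberately
# written along different code paths than the package internals.

# fabricate a PSTH object from a bare rate vector
make_psth <- function(rates, bin_width = 0.02, n_trials = 1, smoothed = FALSE) {
  n <- length(rates)
  edges <- seq(0, by = bin_width, length.out = n + 1)
  structure(list(bin_width = bin_width, edges = edges,
                 centers = edges[-(n + 1)] + bin_width / 2,
                 rates = as.numeric(rates), n_trials = n_trials,
                 smoothed = smoothed),
            class = "psth")
}

make_baseline <- function(mean_rate, sd_rate, sd_multiplier = 4) {
  structure(list(mean_rate = mean_rate, sd_rate = sd_rate,
                 threshold = mean_rate + sd_multiplier * sd_rate,
                 n_bins = NA_integer_),
            class = "baseline_stats")
}

# constructed flash PSTH on the default protocol grid (800 bins of 20 ms):
# flat base rate, alternating 4/6 dark segment (bins 301:800, i.e. 6-16 s),
# single-bin bumps at 2.11 s (onset window) and 4.19 s (offset window)
flash_psth <- function(onset_amp = 0, offset_amp = 0, base = 5) {
  r <- rep(base, 800)
  r[301:800] <- rep(c(base - 1, base + 1), 250)
  if (onset_amp != 0) r[106] <- base + onset_amp
  if (offset_amp != 0) r[210] <- base + offset_amp
  make_psth(r, smoothed = TRUE)
}

# sample SD of the constructed dark segment (alternating base +/- 1)
dark_sd_alt <- function() stats::sd(rep(c(-1, 1), 250))

# O(n^2) nearest-neighbor scan, one point at a time
nnd_brute <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    min(d[-i])
  }, 0)
}

# scalar point-to-segment distance (independent formulation)
seg_dist1 <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

# all-pairs synapse scan: per CtBP2 spot, nearest mGluR6 and nearest dendrite
# segment by direct enumeration
brute_synapses <- function(scene, radius = 1.5) {
  cx <- as.matrix(scene$ctbp2[, c("x_um", "y_um", "z_um")])
  mx <- as.matrix(scene$mglur6[, c("x_um", "y_um", "z_um")])
  dd <- scene$dendrites
  out <- NULL
  for (i in seq_len(nrow(cx))) {
    dm <- sqrt((mx[, 1] - cx[i, 1])^2 + (mx[, 2] - cx[i, 2])^2 +
                 (mx[, 3] - cx[i, 3])^2)
    # nearest mGluR6, ties to smallest id
    best <- which(dm == min(dm))
    j <- best[order(scene$mglur6$id[best])][1]
    dbest <- Inf; cbest <- NA_character_
    if (nrow(dd)) {
      for (cell in sort(unique(as.character(dd$cell_id)))) {
        rows <- which(dd$cell_id == cell)
        for (pl in unique(dd$polyline_id[rows])) {
          vr <- rows[dd$polyline_id[rows] == pl]
          vr <- vr[order(dd$vertex[vr])]
          for (k in seq_len(length(vr) - 1)) {
            d <- seg_dist1(cx[i, ],
                           as.numeric(dd[vr[k], c("x_um", "y_um", "z_um")]),
                           as.numeric(dd[vr[k + 1], c("x_um", "y_um", "z_um")]))
            if (d < dbest) { dbest <- d; cbest <- cell }
          }
        }
      }
    }
    if (dm[j] <= radius && dbest <= radius)
      out <- rbind(out, data.frame(ctbp2_id = scene$ctbp2$id[i],
                                   mglur6_id = scene$mglur6$id[j],
                                   rbc_id = cbest,
                                   d_ctbp2_mglur6 = dm[j],
                                   d_ctbp2_dendrite = dbest,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(ctbp2_id = character(), mglur6_id = character(),
                      rbc_id = character(), d_ctbp2_mglur6 = numeric(),
                      d_ctbp2_dendrite = numeric())
  out
}

# full-enumeration Mann-Whitney two-sided p (tie-aware U with midranks)
mw_enum <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  u <- u_of(a, b)
  p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
  list(U = u, p = p)
}

# rank-based full enumeration of the U distribution (tie-free samples only):
# U = (rank sum of a) - na(na+1)/2 over every assignment of the pooled values
mw_enum_fast <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  pool <- c(a, b)
  na <- length(a)
  rk <- rank(pool)
  idx <- utils::combn(length(pool), na)
  us <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
  list(U = u, p = p)
}

# dense-grid Naka-Rushton SSE oracle with Rmin/Rmax fixed to observed extremes
ir_grid_oracle <- function(I, peak, n_i50 = 500, n_n = 500) {
  rmin <- min(peak); rmax <- max(peak)
  i50s <- exp(seq(log(min(I) / 10), log(max(I) * 10), length.out = n_i50))
  ns <- exp(seq(log(0.1), log(10), length.out = n_n))
  best <- Inf
  for (nn in ns) {
    pred <- outer(I^nn, i50s^nn, function(ip, jp) ip / (ip + jp))
    sse <- colSums((peak - (rmin + (rmax - rmin) * pred))^2)
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}

# per-electrode area by direct pixel-loop distance (independent of the
# package's vectorized route)
area_oracle <- function(mask, pixel_size, layout, base_radius,
                        magnifications = c(1, 5, 10, 15), origin = c(0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  px <- origin[1] + (idx[, "col"] - 0.5) * pixel_size
  py <- origin[2] + (idx[, "row"] - 0.5) * pixel_size
  el <- layout$positions
  vapply(seq_len(nrow(el)), function(i) {
    ri <- ceiling((el$y_um[i] - origin[2]) / pixel_size)
    ci <- ceiling((el$x_um[i] - origin[1]) / pixel_size)
    d <- if (ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask) &&
             mask[ri, ci] != 0) 0
         else min(sqrt((px - el$x_um[i])^2 + (py - el$y_um[i])^2))
    thr <- magnifications * base_radius
    w <- which(d <= thr)
    if (length(w)) min(w[1], 5L) else 5L
  }, 1L)
}
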