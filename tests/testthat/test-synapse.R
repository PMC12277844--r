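simple_scene <- function(ctbp2, mglur6, dendrites) {
  puncta_scene(ctbp2, mglur6, dendrites)
}

test_that("coincident spot on a dendrite vertex gives a zero-distance synapse", {
  dend <- data.frame(cell_id = "r1", polyline_id = 1L, vertex = 1:2,
                     x_um = c(5, 9), y_um = c(5, 5), z_um = c(5, 5))
  sc <- simple_scene(data.frame(id = "c1", x_um = 5, y_um = 5, z_um = 5),
                     data.frame(id = "m1", x_um = 5, y_um = 5, z_um = 5),
                     dend)
  rec <- detect_synapses(sc)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$d_ctbp2_mglur6, 0)
  expect_equal(rec$d_ctbp2_dendrite, 0)
  expect_identical(rec$rbc_id, "r1")
})

test_that("the 1.5-um rule is inclusive and binds both partners", {
  dend <- data.frame(cell_id = "r1", polyline_id = 1L, vertex = 1:2,
                     x_um = c(0, 10), y_um = c(1, 1), z_um = c(0, 0))
  ctbp2 <- data.frame(id = "c1", x_um = 5, y_um = 0, z_um = 0) # 1.0 to dendrite
  near <- simple_scene(ctbp2,
                       data.frame(id = "m1", x_um = 5, y_um = -1.4, z_um = 0),
                       dend)
  expect_identical(nrow(detect_synapses(near)), 1L)
  far <- simple_scene(ctbp2,
                      data.frame(id = "m1", x_um = 5, y_um = -2, z_um = 0),
                      dend)
  expect_identical(nrow(detect_synapses(far)), 0L)
  # distance exactly 1.5 um still counts (inclusive "within")
  edge <- simple_scene(ctbp2,
                       data.frame(id = "m1", x_um = 5, y_um = -1.5, z_um = 0),
                       dend)
  expect_identical(nrow(detect_synapses(edge)), 1L)
  # empty channels are fine
  expect_identical(nrow(detect_synapses(simple_scene(ctbp2[0, ],
                                                     ctbp2[0, ], dend))), 0L)
})

test_that("planted scenes are recovered with perfect precision and recall", {
  gen <- gen_puncta_scene(scene_spec(n_true_synapses = 20,
                                     n_distractor_ctbp2 = 50,
                                     n_distractor_mglur6 = 50,
                                     min_separation = 4), seed = 77)
  rec <- detect_synapses(gen$scene)
  gt <- gen$ground_truth
  expect_identical(nrow(rec), nrow(gt))
  m <- merge(rec, gt, by = "ctbp2_id")
  expect_identical(nrow(m), nrow(gt))
  expect_true(all(m$mglur6_id.x == m$mglur6_id.y))
  expect_true(all(m$rbc_id.x == m$rbc_id.y))
  # and the detection agrees with the all-pairs oracle exactly
  oracle <- brute_synapses(gen$scene)
  expect_equal(rec[order(rec$ctbp2_id), ], oracle[order(oracle$ctbp2_id), ],
               ignore_attr = TRUE)
})

test_that("record sets nest as the radius grows and move rigidly with the scene", {
  withr::with_seed(41, {
    sc <- simple_scene(
      data.frame(id = sprintf("c%02d", 1:40), x_um = runif(40, 0, 20),
                 y_um = runif(40, 0, 20), z_um = runif(40, 0, 10)),
      data.frame(id = sprintf("m%02d", 1:40), x_um = runif(40, 0, 20),
                 y_um = runif(40, 0, 20), z_um = runif(40, 0, 10)),
      data.frame(cell_id = rep(c("r1", "r2"), each = 3),
                 polyline_id = rep(1:2, each = 3), vertex = rep(1:3, 2),
                 x_um = runif(6, 0, 20), y_um = runif(6, 0, 20),
                 z_um = runif(6, 0, 10)))
  })
  radii <- c(0.5, 1, 1.5, 2.5, 4)
  recs <- lapply(radii, function(r) detect_synapses(sc, radius = r))
  for (i in seq_len(length(radii) - 1))
    expect_true(all(recs[[i]]$ctbp2_id %in% recs[[i + 1]]$ctbp2_id))
  # rigid motion: rotate about z and translate
  th <- 0.6; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mv <- function(df) {
    xyz <- as.matrix(df[, c("x_um", "y_um", "z_um")]) %*% t(R)
    df$x_um <- xyz[, 1] + 3; df$y_um <- xyz[, 2] - 2; df$z_um <- xyz[, 3] + 1
    df
  }
  sc2 <- simple_scene(mv(sc$ctbp2), mv(sc$mglur6), mv(sc$dendrites))
  r1 <- detect_synapses(sc, 1.5); r2 <- detect_synapses(sc2, 1.5)
  expect_identical(r1$ctbp2_id, r2$ctbp2_id)
  expect_equal(r1$d_ctbp2_mglur6, r2$d_ctbp2_mglur6, tolerance = 1e-9)
  expect_equal(r1$d_ctbp2_dendrite, r2$d_ctbp2_dendrite, tolerance = 1e-9)
})

test_that("RBC selection near the rosette includes segment interiors", {
  ball <- array(FALSE, c(21, 21, 21))
  for (k in 1:21)
    ball[, , k] <- outer((1:21 - 10.5)^2, (1:21 - 10.5)^2, "+") +
      (k - 10.5)^2 <= 4^2
  surf <- rosette_surface(ball, c(1, 1, 1))
  c0 <- c(10.5, 10.5, 10.5) # ball center, radius 4
  # vertex touching the surface / far skeleton / close-passing segment
  dend <- rbind(
    data.frame(cell_id = "touch", polyline_id = 1L, vertex = 1:2,
               x_um = c(14.5, 20), y_um = c(10.5, 10.5), z_um = c(10.5, 10.5)),
    data.frame(cell_id = "far", polyline_id = 1L, vertex = 1:2,
               x_um = c(45, 55), y_um = c(45, 45), z_um = c(45, 45)),
    # endpoints ~16.1 um from the center, midpoint at 12 um
    data.frame(cell_id = "midpass", polyline_id = 1L, vertex = 1:2,
               x_um = c0[1] + c(12, 12), y_um = c0[2] + c(-10.73, 10.73),
               z_um = c(10.5, 10.5)))
  sel <- select_rbcs_near_rosette(dend, surf, reach = 10)
  expect_true("touch" %in% sel)
  expect_true("midpass" %in% sel) # endpoints > reach, interior within reach
  expect_false("far" %in% sel)
})

test_that("per-RBC counts, the forming set and densities follow the rules", {
  rec <- data.frame(ctbp2_id = c("c1", "c2", "c3"),
                    mglur6_id = c("m1", "m2", "m3"),
                    rbc_id = c("cell1", "cell1", "cell1"),
                    d_ctbp2_mglur6 = 0.5, d_ctbp2_dendrite = 0.5)
  out <- synapses_per_rbc(rec, c("cell1", "cell2"))
  expect_identical(out$counts, c(cell1 = 3L, cell2 = 0L))
  expect_identical(out$forming, "cell1")
  expect_equal(out$mean_count, 1.5)
  expect_identical(nrow(out$unselected_records), 0L)

  none <- synapses_per_rbc(rec[0, ], c("a", "b"))
  expect_true(all(none$counts == 0))
  expect_identical(none$forming, character(0))

  expect_equal(forming_rbc_density(c("a", "b", "c", "d"), 0.2), 20)
  expect_equal(forming_rbc_density(character(0), 0.5), 0)
  expect_equal(forming_rbc_density(c("a", "b"), 0.4),
               forming_rbc_density(c("a", "b"), 0.2) / 2)
  expect_error(forming_rbc_density("a", 0), "graft_area")
})
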