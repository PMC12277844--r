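test_that("scene specifications enforce the separation feasibility rule", {
  expect_error(scene_spec(min_separation = 2.5), "min_separation")
  expect_error(scene_spec(n_true_synapses = 5, n_rbc = 0), "at least one RBC")
  expect_silent(scene_spec())
})

test_that("scenes are reproducible and empty specs give empty truth", {
  spec <- scene_spec(n_true_synapses = 5, n_distractor_ctbp2 = 10,
                     n_distractor_mglur6 = 10)
  s1 <- gen_puncta_scene(spec, seed = 8)
  s2 <- gen_puncta_scene(spec, seed = 8)
  expect_identical(s1$scene$ctbp2, s2$scene$ctbp2)
  expect_identical(s1$scene$dendrites, s2$scene$dendrites)
  expect_identical(s1$ground_truth, s2$ground_truth)

  s0 <- gen_puncta_scene(scene_spec(n_true_synapses = 0,
                                    n_distractor_ctbp2 = 5,
                                    n_distractor_mglur6 = 5), seed = 1)
  expect_identical(nrow(s0$ground_truth), 0L)
  expect_identical(nrow(s0$scene$ctbp2), 5L)
})

test_that("planted triplets satisfy both 1.5-um predicates with margin", {
  gen <- gen_puncta_scene(scene_spec(n_true_synapses = 12,
                                     n_distractor_ctbp2 = 20,
                                     n_distractor_mglur6 = 20), seed = 17)
  sc <- gen$scene
  gt <- gen$ground_truth
  for (i in seq_len(nrow(gt))) {
    p <- as.numeric(sc$ctbp2[sc$ctbp2$id == gt$ctbp2_id[i],
                             c("x_um", "y_um", "z_um")])
    q <- as.numeric(sc$mglur6[sc$mglur6$id == gt$mglur6_id[i],
                              c("x_um", "y_um", "z_um")])
    expect_lte(sqrt(sum((p - q)^2)), 1.5)
    # nearest point of the assigned cell's skeleton, by direct scan
    dd <- sc$dendrites[sc$dendrites$cell_id == gt$rbc_id[i], ]
    best <- Inf
    for (pl in unique(dd$polyline_id)) {
      v <- dd[dd$polyline_id == pl, ]
      v <- v[order(v$vertex), ]
      for (k in seq_len(nrow(v) - 1))
        best <- min(best, seg_dist1(p,
          as.numeric(v[k, c("x_um", "y_um", "z_um")]),
          as.numeric(v[k + 1, c("x_um", "y_um", "z_um")])))
    }
    expect_lte(best, 1.5)
  }
})

test_that("every distractor violates the proximity predicates", {
  gen <- gen_puncta_scene(scene_spec(n_true_synapses = 8,
                                     n_distractor_ctbp2 = 25,
                                     n_distractor_mglur6 = 25,
                                     min_separation = 4), seed = 23)
  sc <- gen$scene
  distract <- grepl("_d", sc$ctbp2$id)
  mx <- as.matrix(sc$mglur6[, c("x_um", "y_um", "z_um")])
  for (i in which(distract)) {
    p <- as.numeric(sc$ctbp2[i, c("x_um", "y_um", "z_um")])
    d_m <- min(sqrt((mx[, 1] - p[1])^2 + (mx[, 2] - p[2])^2 +
                      (mx[, 3] - p[3])^2))
    expect_gt(d_m, 1.5) # at least min_separation from every mGluR6
  }
  # and distractor mGluR6 spots sit far from every CtBP2 spot
  cxm <- as.matrix(sc$ctbp2[, c("x_um", "y_um", "z_um")])
  for (i in which(grepl("_d", sc$mglur6$id))) {
    q <- as.numeric(sc$mglur6[i, c("x_um", "y_um", "z_um")])
    expect_gt(min(sqrt((cxm[, 1] - q[1])^2 + (cxm[, 2] - q[2])^2 +
                         (cxm[, 3] - q[3])^2)), 1.5)
  }
})
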