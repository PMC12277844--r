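test_that("sampling circles sit on exact tangency chains", {
  for (dd in c(100, 200)) {
    circ <- place_sampling_circles(c(0, 0), dd)
    expect_identical(nrow(circ), 12L)
    expect_identical(as.vector(table(circ$region)[c("proximal", "middle", "distal")]),
                     c(4L, 4L, 4L))
    d <- sqrt(circ$center_x^2 + circ$center_y^2)
    expect_equal(sort(unique(d)), dd / 2 + c(250, 750, 1250))
    # regions map to the right chain position
    expect_true(all(d[circ$region == "proximal"] == dd / 2 + 250))
    expect_true(all(d[circ$region == "distal"] == dd / 2 + 1250))
  }
  # off-center disc translates the whole chain
  circ <- place_sampling_circles(c(300, -100), 150)
  d <- sqrt((circ$center_x - 300)^2 + (circ$center_y + 100)^2)
  expect_equal(sort(unique(d)), 75 + c(250, 750, 1250))
  expect_warning(place_sampling_circles(c(0, 0), 400), "100-200")
})

test_that("circle density divides inclusive counts by the circle area", {
  withr::with_seed(6, {
    pts <- data.frame(x_um = runif(10, -100, 100), y_um = runif(10, -100, 100))
  })
  pat <- point_pattern(pts, field_radius = 1000)
  circ <- list(center_x = 0, center_y = 0, diameter = 500, excluded = FALSE)
  expect_equal(circle_density(pat, circ), 10 / (pi * 0.25^2))
  # boundary point counts as inside; far points change nothing
  pat2 <- point_pattern(rbind(pts, data.frame(x_um = 250, y_um = 0),
                              data.frame(x_um = 5000, y_um = 0)),
                        field_radius = 10000)
  expect_equal(circle_density(pat2, circ), 11 / (pi * 0.25^2))
  # empty circle and excluded circle
  empty <- point_pattern(data.frame(x_um = 600, y_um = 600),
                         field_radius = 1000)
  expect_equal(circle_density(empty, circ), 0)
  circ$excluded <- TRUE
  expect_warning(dens <- circle_density(pat, circ), "excluded")
  expect_true(is.na(dens))
})

test_that("nearest-neighbor distances match brute force and simple geometry", {
  two <- data.frame(x_um = c(0, 5), y_um = c(0, 0))
  expect_equal(nnd(two)$distances, c(5, 5))
  # square grid: every nearest neighbor is an axis neighbor at the spacing
  g <- expand.grid(x_um = seq(0, 90, 15), y_um = seq(0, 90, 15))
  expect_true(all(nnd(g)$distances == 15))
  withr::with_seed(12, {
    pts <- data.frame(x_um = runif(200, 0, 500), y_um = runif(200, 0, 500))
  })
  res <- nnd(pts)
  expect_identical(res$distances, nnd_brute(pts))
  expect_equal(sum(res$histogram$rel_freq), 1, tolerance = 1e-12)
  expect_error(nnd(two[1, , drop = FALSE]), "at least 2")
})

test_that("NND is invariant under rigid motions and grows under thinning", {
  withr::with_seed(13, {
    pts <- cbind(runif(150, 0, 300), runif(150, 0, 300))
  })
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(rot, 2, c(40, -17), "+")
  expect_equal(nnd(moved)$distances, nnd(pts)$distances, tolerance = 1e-9)
  # removing points never shrinks a survivor's NND
  keep <- seq_len(150) %% 3 != 0
  d_all <- nnd(pts)$distances
  d_thin <- nnd(pts[keep, ])$distances
  expect_true(all(d_thin >= d_all[keep] - 1e-12))
})

test_that("Mann-Whitney comparisons match the exact and approximate regimes", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_true(r$exact)
  # identical samples: no evidence of a shift
  expect_gte(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # tie-free enumeration oracle across a few shapes
  withr::with_seed(14, {
    for (k in 1:5) {
      a <- sample(seq(0.1, 50, 0.1), sample(2:8, 1))
      b <- sample(setdiff(seq(0.1, 50, 0.1), a), sample(2:8, 1))
      ref <- mw_enum(a, b)
      got <- compare_groups(a, b)
      expect_equal(got$U, ref$U)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
    }
  })
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})
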