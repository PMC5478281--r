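make_grid_frame <- function(nx = 2, ny = 2, h = 10) {
  pl <- list()
  for (i in 0:nx) for (j in 0:(ny - 1)) {
    pl <- c(pl, list(rbind(c(i * h, j * h), c(i * h, (j + 1) * h))))
  }
  for (j in 0:ny) for (i in 0:(nx - 1)) {
    pl <- c(pl, list(rbind(c(i * h, j * h), c((i + 1) * h, j * h))))
  }
  network_frame(pl)
}

test_that("frames are built from polylines with snapped junctions", {
  # one 3-point polyline: two endpoints, one edge
  f1 <- network_frame(list(rbind(c(0, 0), c(3, 4), c(3, 9))))
  expect_equal(nrow(f1$nodes), 2)
  expect_equal(nrow(f1$edges), 1)
  expect_equal(total_length(f1), 10)
  expect_equal(count_junctions(f1), 0)

  # three polylines with endpoints within the snap tolerance merge into
  # one degree-3 junction
  f3 <- network_frame(list(rbind(c(0.2, 0), c(10, 0)),
                           rbind(c(-0.2, 0.1), c(-8, 6)),
                           rbind(c(0, -0.3), c(0, -12))), snap_tol = 1)
  expect_equal(count_junctions(f3), 1)
  expect_equal(sum(f3$nodes$kind == "endpoint"), 3)

  # crossings are drawn as overlapping polylines and create no node
  cr1 <- rbind(c(-5, 0), c(5, 0)); attr(cr1, "kind") <- "crossing"
  cr2 <- rbind(c(0, -5), c(0, 5)); attr(cr2, "kind") <- "crossing"
  fc <- network_frame(list(cr1, cr2))
  expect_equal(nrow(fc$nodes), 4)
  expect_equal(count_junctions(fc), 0)

  expect_error(network_frame(list(matrix(1:3, ncol = 1))), "2 columns")
})

test_that("total length and junction count are rigid-motion invariant", {
  f <- network_frame(list(rbind(c(0, 0), c(0, 5)), rbind(c(0, 0), c(5, 0)),
                          rbind(c(0, 0), c(-4, -3))))
  expect_equal(total_length(f), 15)
  expect_equal(count_junctions(f), 1)

  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f_rot <- network_frame(lapply(f$polylines, function(p)
    t(R %*% t(p)) + matrix(c(12, -7), nrow(p), 2, byrow = TRUE)))
  expect_close(total_length(f_rot), 15, tol = 1e-9)
  expect_equal(count_junctions(f_rot), 1)
})

test_that("chordless loops are the bounded faces with shoelace areas", {
  tri <- network_frame(list(rbind(c(0, 0), c(10, 0)), rbind(c(10, 0), c(5, 8)),
                            rbind(c(5, 8), c(0, 0))))
  loops <- chordless_loops(tri)
  expect_equal(nrow(loops), 1)
  expect_close(loops$area, 40, tol = 1e-9)

  # drawing direction of the polylines must not matter
  tri_rev <- network_frame(list(rbind(c(10, 0), c(0, 0)), rbind(c(10, 0), c(5, 8)),
                                rbind(c(0, 0), c(5, 8))))
  expect_close(chordless_loops(tri_rev)$area, 40, tol = 1e-9)

  g22 <- make_grid_frame(2, 2)
  loops22 <- chordless_loops(g22)
  expect_equal(nrow(loops22), 4) # brute-force enumeration: 4 unit faces
  expect_close(sort(loops22$area), rep(100, 4), tol = 1e-9)

  # Euler relation V - E + F_bounded = 1 for one connected component
  expect_equal(nrow(g22$nodes) - nrow(g22$edges) + nrow(loops22), 1)
  g33 <- make_grid_frame(3, 3)
  l33 <- chordless_loops(g33)
  expect_equal(nrow(l33), 9)
  expect_equal(nrow(g33$nodes) - nrow(g33$edges) + nrow(l33), 1)

  # a forest has no loops
  tree <- network_frame(list(rbind(c(0, 0), c(10, 0)), rbind(c(10, 0), c(20, 5))))
  expect_equal(nrow(chordless_loops(tree)), 0)
})

test_that("zipper angles use the sharpest-of-three rule on tangent windows", {
  # symmetric Y: 40 degrees between the distal arms
  half <- 20 * pi / 180
  y40 <- network_frame(list(
    rbind(c(0, 0), 8 * c(sin(half), cos(half))),
    rbind(c(0, 0), 8 * c(-sin(half), cos(half))),
    rbind(c(0, 0), c(0, -8))))
  expect_close(unname(zipper_angles(y40)), 40, tol = 1e-6)

  # arms at bearings 0, 50, 180: sharpest of 50, 130, 180
  b <- network_frame(list(rbind(c(0, 0), c(6, 0)),
                          rbind(c(0, 0), 6 * c(cos(50 * pi / 180), sin(50 * pi / 180))),
                          rbind(c(0, 0), c(-6, 0))))
  expect_close(unname(zipper_angles(b)), 50, tol = 1e-6)

  # a curved arm: tangent estimated over the 5 um window of a known circle
  th_seq <- seq(0, pi / 3, length.out = 60)
  Rr <- 20
  arc <- cbind(Rr * sin(th_seq), Rr * (1 - cos(th_seq))) # starts along +x
  curved <- network_frame(list(arc, rbind(c(0, 0), c(-8, 0)),
                               rbind(c(0, 0), c(3, -7))))
  ang <- zipper_angles(curved)
  # chord over a 5 um window of a radius-20 circle deviates from the true
  # tangent by ~7 degrees; the protractor reading of that chord is known
  chord_bearing <- atan2(Rr * (1 - cos(5 / Rr)), Rr * sin(5 / Rr)) * 180 / pi
  expect_close(min(ang), atan2(7, 3) * 180 / pi + chord_bearing, tol = 2)

  # degree-4 nodes are skipped and reported
  x4 <- network_frame(list(rbind(c(0, 0), c(5, 0)), rbind(c(0, 0), c(-5, 0)),
                           rbind(c(0, 0), c(0, 5)), rbind(c(0, 0), c(0, -5))))
  a4 <- zipper_angles(x4)
  expect_length(a4, 0)
  expect_equal(length(attr(a4, "skipped")), 1)

  # an override annotation selects a different edge pair
  ov <- zipper_angles(b, overrides = list("1" = c(1, 3)))
  expect_close(unname(ov), 180, tol = 1e-6)
})

test_that("time-series statistics correlate median angle with total length", {
  frames <- gen_network_sequence(generator_spec(seed = 2, scenario = "coarsening",
                                                cadence_min = 15))
  ts <- timeseries_stats(frames)
  expect_equal(nrow(ts$stats), length(frames))
  expect_true(all(diff(ts$stats$total_length) <= 1e-9))
  expect_gt(ts$r_angle_length, 0)

  # normalization by a reference frame
  ts_n <- timeseries_stats(frames, normalize_to = 1)
  expect_close(ts_n$stats$total_length_norm[1], 1, tol = 1e-12)

  # identical frames: constant series, undefined correlation flag
  same <- list(frames[[1]], frames[[1]], frames[[1]])
  expect_warning(ts_c <- timeseries_stats(same), "constant")
  expect_true(is.nan(ts_c$r_angle_length))
})

test_that("triangular loop collapse removes exactly two junctions", {
  frames <- gen_network_sequence(generator_spec(seed = 4, scenario = "coarsening",
                                                cadence_min = 1, n_motifs = 4L,
                                                n_triangles = 1L, n_crossings = 0L,
                                                duration_min = 60))
  juncs <- vapply(frames, count_junctions, numeric(1))
  man <- attr(frames, "manifest")
  sides <- man$triangle_sides[1, ]
  coll <- which(sides <= 0)[1]
  expect_false(is.na(coll))
  expect_equal(juncs[coll - 1] - juncs[coll], 2)
  loops_pre <- chordless_loops(frames[[coll - 2]])
  loops_post <- chordless_loops(frames[[coll]])
  expect_equal(nrow(loops_pre) - nrow(loops_post), 1)
})

test_that("segmentation files round-trip through the documented schema", {
  frames <- gen_network_sequence(generator_spec(seed = 5, scenario = "stable",
                                                duration_min = 10, cadence_min = 10,
                                                n_motifs = 5L, n_crossings = 1L))
  tmp <- tempfile(fileext = ".csv")
  write_segmentation(frames, tmp)
  back <- load_segmentation(tmp, snap_tol = 0.5)
  expect_length(back, length(frames))
  for (i in seq_along(back)) {
    expect_close(total_length(back[[i]]), total_length(frames[[i]]), tol = 1e-6)
    expect_equal(count_junctions(back[[i]]), count_junctions(frames[[i]]))
  }
  # pixel scaling applies to coordinates
  scaled <- load_segmentation(tmp, pixel_size = 2, snap_tol = 1)
  expect_close(total_length(scaled[[1]]), 2 * total_length(frames[[1]]), tol = 1e-6)

  # malformed rows are reported with their line number
  df <- utils::read.csv(tmp)
  df$x[3] <- NA
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(load_segmentation(bad), "line")

  # missing columns are named
  expect_error(load_segmentation({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "misses columns")
})

test_that("vertex type percentages are integer-rounded shares", {
  expect_equal(unname(vertex_type_fractions(c(134, 69, 44))), c(54, 28, 18))
  expect_equal(unname(vertex_type_fractions(c(1, 0, 0))), c(100, 0, 0))
  expect_equal(unname(vertex_type_fractions(c(10, 10, 20))), c(25, 25, 50))
  expect_error(vertex_type_fractions(c(0, 0, 0)), "zero")
})
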