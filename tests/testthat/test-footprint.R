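test_that("stadium geometry and immersion taper are as constructed", {
  fp <- wedge_footprint(U = -0.9)
  expect_equal(footprint_perimeter(fp), 2 * (3 - 1.2) + 2 * pi * 0.6)
  # constant U on the straight sides, zero at the tip centers, NA outside
  expect_equal(footprint_immersion(fp, cbind(0, 0.59)), -0.9)
  expect_equal(footprint_immersion(fp, cbind(-0.8, -0.5)), -0.9)
  expect_equal(footprint_immersion(fp, cbind(1.5, 0)), 0, tolerance = 1e-9)
  expect_true(is.na(footprint_immersion(fp, cbind(0, 0.7))))
  # linear in arc length halfway along the cap
  mid <- c(0.9, 0) + 0.6 * c(sin(pi / 4), cos(pi / 4))
  expect_equal(as.numeric(footprint_immersion(fp, rbind(mid))), -0.45,
               tolerance = 1e-9)
  # continuity: value just inside the cap near the junction is close to U
  expect_equal(footprint_immersion(fp, cbind(0.91, 0.55)), -0.9, tolerance = 0.02)
  expect_error(wedge_footprint(U = -0.9, L = 1, r0 = 0.6), "degenerate")
})

test_that("pose transforms carry the outline and immersion correctly", {
  fp <- wedge_footprint(U = -0.9, center = c(3, -2), theta = pi / 3)
  out <- footprint_outline(fp, n = 100)
  # outline points lie on the boundary: immersion defined and |distance to
  # core segment| == r0
  seg <- wedgelat:::.footprint_segment(fp)
  d <- apply(out, 1L, function(p)
    wedgelat:::.segment_distance(p, p, seg[1, ], seg[2, ]))
  expect_equal(max(abs(d - 0.6)), 0, tolerance = 1e-9)
  expect_true(all(footprint_contains(fp, out - 1e-6 * (out - matrix(fp$center,
    nrow(out), 2, byrow = TRUE)))))
})

test_that("overlap test is exact capsule distance", {
  a <- wedge_footprint(-0.9)
  expect_false(footprints_overlap(a, wedge_footprint(-0.9, center = c(0, 1.21))))
  expect_true(footprints_overlap(a, wedge_footprint(-0.9, center = c(0, 1.19))))
  # rotated near-tip contact
  b <- wedge_footprint(-0.9, center = c(1.9, 0.4), theta = pi / 2)
  expect_true(footprints_overlap(a, b))
  expect_false(footprints_overlap(a, wedge_footprint(-0.9, center = c(2.4, 0),
                                                     theta = pi / 2)))
})
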