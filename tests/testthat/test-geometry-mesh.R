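test_that("degenerate no-sac geometry is a plain channel", {
  g <- build_idealized_aneurysm(parent_width = 4e-3, parent_length = 40e-3,
                                curvature = 0, sac_neck_width = 0)
  expect_false(g$has_sac)
  expect_equal(sac_area(g), 0)
  expect_equal(domain_area(g), 4e-3 * 40e-3)
  expect_null(neck_segment(g))
})

test_that("circular-segment sac area matches the closed form", {
  r <- 3e-3; N <- 4e-3
  g <- build_idealized_aneurysm(dome_radius = r, sac_neck_width = N)
  # segment of height Hs = r + sqrt(r^2 - (N/2)^2) in a circle of radius r:
  # area above the chord = pi r^2 - minor segment below it
  d <- sqrt(r^2 - (N / 2)^2)
  minor <- r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
  expect_equal(sac_area(g), pi * r^2 - minor, tolerance = 1e-12)
  expect_equal(g$sac_depth, r + d, tolerance = 1e-12)
  # elliptical: half-ellipse area
  ge <- build_idealized_aneurysm(sac_shape = "elliptical", sac_depth = 5e-3)
  expect_equal(sac_area(ge), pi * 2e-3 * 5e-3 / 2, tolerance = 1e-12)
})

test_that("geometry constraint violations are rejected with named constraints", {
  expect_error(build_idealized_aneurysm(dome_radius = 1e-3, sac_neck_width = 4e-3),
               "dome_radius")
  expect_error(build_idealized_aneurysm(sac_center_arc = 1e-3), "neck")
  expect_error(build_idealized_aneurysm(parent_width = -1), ">")
  expect_error(build_idealized_aneurysm(sac_shape = "elliptical"), "sac_depth")
})

test_that("structured channel mesh: counts, tags, refinement ratio", {
  g <- chan_geom(L = 16e-3)
  m <- generate_mesh(g, 4e-4)
  expect_equal(sum(m$fluid), (16e-3 / 4e-4) * (4e-3 / 4e-4))
  expect_setequal(unique(m$boundary$tag), c("inlet", "outlet", "vessel_wall"))
  expect_equal(length(unique(m$boundary$group)), 4)  # 2 walls + inlet + outlet
  # every boundary face has exactly one tag by construction; partition check
  expect_false(any(duplicated(m$boundary[c("i", "j", "side")])))

  # halving h quadruples the cell count (2-D refinement)
  m2 <- generate_mesh(g, 2e-4)
  ratio <- sum(m2$fluid) / sum(m$fluid)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.5)
})

test_that("sac mesh: area convergence, coil mask, neck resolution guard", {
  g <- sac_geom()
  hs <- c(4e-4, 2e-4, 1e-4)
  errs <- vapply(hs, function(h) {
    m <- generate_mesh(g, h)
    abs(mesh_area(m) - domain_area(g)) / domain_area(g)
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  # at least first-order area convergence overall
  expect_lt(errs[3], errs[1])

  m <- generate_mesh(g, 2e-4)
  expect_equal(coil_area(m), g$coil_fill_fraction * sac_area(g),
               tolerance = 0.02)
  # coil area monotone non-decreasing in f_c
  fcs <- c(0, 0.25, 0.5, 0.75, 1)
  areas <- vapply(fcs, function(fc) {
    gf <- sac_geom(coil_fill_fraction = fc)
    coil_area(generate_mesh(gf, 2e-4))
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[1], 0)
  expect_equal(areas[5], sac_area(g), tolerance = 0.02)

  # unresolved neck: error names h and the neck width
  expect_error(generate_mesh(g, 9e-4), "neck")
  expect_error(generate_mesh(g, 2e-3), "parent_width")
})

test_that("sac-wall faces are tagged and ordered along the boundary walk", {
  m <- generate_mesh(sac_geom(), 4e-4)
  wf <- wall_faces(m)
  sac <- wf[wf$tag == "sac_wall", ]
  expect_gt(nrow(sac), 10)
  # all sac-wall faces bound cells above the wall line
  expect_true(all(sac$y >= m$geom$parent_width - 1e-12))
  # arc length strictly increasing along the walk within each loop
  expect_true(all(diff(m$boundary$arclength[m$boundary$loop == 1]) > 0))
})

test_that("bend mapping is isometric on the centerline and identity when straight", {
  g <- sac_geom()
  xy <- cbind(seq(0, 24e-3, length.out = 50), rep(2e-3, 50))
  bent <- bend_coordinates(g, xy)
  seg <- sqrt(rowSums(diff(bent)^2))
  # arc length preserved up to the polyline chord error (~theta^2/24)
  expect_equal(sum(seg), 24e-3, tolerance = 1e-4)
  g0 <- chan_geom()
  expect_equal(bend_coordinates(g0, xy), xy)
})
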