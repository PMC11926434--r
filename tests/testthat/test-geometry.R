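test_that("arrange_beams conventions", {
  expect_equal(sort(arrange_beams(5, span = 200, center = 0)),
               sort(c(-100, -50, 0, 50, 100) %% 360))
  expect_equal(sort(parallel_opposed(90)), c(90, 270))
  a15 <- arrange_beams(15, span = 360)
  expect_equal(diff(sort(a15)), rep(24, 14))
  expect_length(a15, 15)
  expect_equal(arrange_beams(1, span = 200, center = 30), 30)
  expect_equal(single_beam(370), 10)
  expect_error(arrange_beams(5, span = 400), "span")
  expect_error(arrange_beams(0, span = 360), "positive integer")
  ## centre shift rotates the set rigidly
  base <- arrange_beams(7, span = 200, center = 0)
  shifted <- arrange_beams(7, span = 200, center = 35)
  expect_equal(sort((shifted - 35) %% 360), sort(base))
})

test_that("field geometry basis is orthonormal and follows the convention", {
  f0 <- field_geometry(0, c(0, 0, 0))
  expect_equal(f0$beam_axis, c(0, 1, 0))  # enters anteriorly, travels +y
  f90 <- field_geometry(90, c(0, 0, 0))
  expect_equal(f90$beam_axis, c(-1, 0, 0), tolerance = 1e-12) # patient-left entry
  for (g in c(0, 37, 90, 123, 270)) {
    f <- field_geometry(g, c(1, 2, 3))
    expect_equal(sum(f$beam_axis^2), 1)
    expect_equal(sum(f$beam_axis * f$bev_u), 0)
    expect_equal(sum(f$beam_axis * f$bev_v), 0)
    expect_equal(sum(f$bev_u * f$bev_v), 0)
  }
})

test_that("WEPL equals geometric depth in uniform water", {
  grid <- tiny_water_grid(25, 4)  # 100 mm cube
  fld <- field_geometry(0, c(50, 50, 50))
  dm <- radiological_depth(grid, fld)
  ## voxel centres: depth along +y from the y=0 face
  expect_equal(dm[13, 25, 13], 98, tolerance = 1e-9)
  expect_equal(dm[1, 1, 1], 2, tolerance = 1e-9)
  ys <- (seq_len(25) - 0.5) * 4
  expect_equal(dm[7, , 19], ys, tolerance = 1e-9)
})

test_that("WEPL through a slab scales by relative density", {
  ## 50 mm slab of density 0.3 entered first, then water
  dens <- array(1, dim = c(20, 40, 20))
  dens[, 1:25, ] <- 0.3  # y in [0, 50] mm at 2 mm voxels
  grid <- image_grid(dens, spacing = c(2, 2, 2))
  fld <- field_geometry(0, c(20, 40, 20))
  dm <- radiological_depth(grid, fld)
  ## voxel centre 30 mm into the water: y = 80 mm -> j = 40
  expect_equal(dm[10, 40, 10], 0.3 * 50 + 29, tolerance = 1e-9)
})

test_that("WEPL agrees with dense ray-marching on random heterogeneity", {
  set.seed(11)
  dens <- array(runif(18^3, 0, 1.5), dim = c(18, 18, 18))
  grid <- image_grid(dens, spacing = c(2, 2, 2))
  for (g in c(0, 33, 90, 205)) {
    fld <- field_geometry(g, c(18, 18, 18))
    dm <- radiological_depth(grid, fld)
    picks <- cbind(sample(18, 20, TRUE), sample(18, 20, TRUE),
                   sample(18, 20, TRUE))
    for (r in seq_len(nrow(picks))) {
      ijk <- picks[r, ]
      expect_lt(abs(dm[ijk[1], ijk[2], ijk[3]] - oracle_wepl(grid, fld, ijk)),
                0.5)
    }
  }
})

test_that("BEV projection of simple solids", {
  grid <- tiny_water_grid(30, 2)  # 60 mm cube
  ctr <- c(30, 30, 30)
  xs <- grid_axis_centers(grid, 1)
  ## cuboid 20 x 12 x 28 mm
  m <- array(FALSE, grid$shape)
  m[abs(xs - 30) <= 10, abs(xs - 30) <= 6, abs(xs - 30) <= 14] <- TRUE
  cub <- structure_mask("ptv", m, "target")
  fld <- field_geometry(0, ctr)  # axis along y: footprint = x-z extent
  fp <- project_to_bev(cub, grid, fld, resolution = 2)
  expect_true(all(fp$mask))
  expect_equal(sum(fp$mask) * 4, 20 * 28, tolerance = 0.3)

  ## sphere -> disc of the same radius, any angle
  d2 <- outer(outer((xs - 30)^2, (xs - 30)^2, `+`), (xs - 30)^2, `+`)
  sph <- structure_mask("ptv", d2 <= 12^2, "target")
  for (g in c(0, 45)) {
    fp <- project_to_bev(sph, grid, field_geometry(g, ctr), resolution = 2)
    area <- sum(fp$mask) * 4
    expect_equal(area, pi * 144, tolerance = 0.15)
  }

  ## rotated cuboid: footprint area between face area and diagonal extent
  fp45 <- project_to_bev(cub, grid, field_geometry(45, ctr), resolution = 2)
  a45 <- sum(fp45$mask) * 4
  width45 <- (20 + 12) / sqrt(2)  # projected width of the x-y rectangle
  expect_gte(a45, 20 * 28 * 0.9)
  expect_lte(a45, width45 * 28 * 1.1)
  expect_error(project_to_bev(structure_mask("e", array(FALSE, grid$shape)),
                              grid, fld), "empty")
})

test_that("spot lattice matches the enumerate-and-filter count", {
  fld <- field_geometry(0, c(0, 0, 0))
  fp <- square_footprint(20, 2)    # 40 x 40 mm
  sg <- place_spots(fp, margin = 5, spacing = 6, field = fld, sigma0 = 4)
  expect_identical(nrow(sg$positions), 81L)  # 9 x 9, offsets |k*6| <= 25
  ## all positions on the lattice anchored at the (zero) centroid
  expect_true(all(abs(sg$positions %% 6) < 1e-9 |
                  abs(sg$positions %% 6 - 6) < 1e-9))
  sg4 <- place_spots(fp, margin = 5, spacing = 4, field = fld, sigma0 = 4)
  ## count ratio approximately (6/4)^2 = 2.25 up to lattice discretisation
  expect_equal(nrow(sg4$positions) / 81, 2.25, tolerance = 0.12)
  ## one-cell footprint with zero margin keeps exactly the centroid spot
  one <- structure(list(mask = matrix(TRUE, 1, 1), u_centers = 3,
                        v_centers = -1, resolution = 2),
                   class = "vhee_footprint")
  sg1 <- place_spots(one, margin = 0, spacing = 6, field = fld, sigma0 = 4)
  expect_identical(nrow(sg1$positions), 1L)
  expect_equal(as.numeric(sg1$positions), c(3, -1))
})

test_that("spot count monotone in spacing and margin; spots stay in bounds", {
  set.seed(3)
  fld <- field_geometry(0, c(0, 0, 0))
  for (rep in 1:5) {
    ## random blob footprint: union of a few discs
    ctr <- seq(-29, 29, by = 2)
    mm <- matrix(FALSE, length(ctr), length(ctr))
    for (b in 1:3) {
      cu <- runif(1, -12, 12); cv <- runif(1, -12, 12); r <- runif(1, 6, 16)
      mm <- mm | (outer((ctr - cu)^2, (ctr - cv)^2, `+`) <= r^2)
    }
    fp <- structure(list(mask = mm, u_centers = ctr, v_centers = ctr,
                         resolution = 2), class = "vhee_footprint")
    counts <- vapply(c(4, 6, 8, 12), function(sp)
      nrow(place_spots(fp, 5, sp, fld, 4)$positions), numeric(1))
    expect_true(all(diff(counts) <= 0))
    mcounts <- vapply(c(2, 5, 8), function(m)
      nrow(place_spots(fp, m, 6, fld, 4)$positions), numeric(1))
    expect_true(all(diff(mcounts) >= 0))

    ## containment within footprint (+) margin, and lattice coverage:
    ## guaranteed whenever spacing <= 2 * margin
    idx <- which(mm, arr.ind = TRUE)
    fu <- ctr[idx[, 1]]; fv <- ctr[idx[, 2]]
    for (sp in c(4, 6, 8, 10)) {
      pos <- place_spots(fp, 5, sp, fld, 4)$positions
      cheb <- function(i) min(pmax(abs(fu - pos[i, 1]), abs(fv - pos[i, 2])))
      expect_true(all(vapply(seq_len(nrow(pos)), cheb, numeric(1)) <= 5 + 1e-9))
      covered <- vapply(seq_along(fu), function(j)
        min(sqrt((pos[, 1] - fu[j])^2 + (pos[, 2] - fv[j])^2)), numeric(1))
      expect_true(all(covered <= sp * sqrt(2) / 2 + 1e-9))
    }
  }
})
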