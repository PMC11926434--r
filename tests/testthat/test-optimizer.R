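bd <- generate_analytic_base_data(beam_energy_spec(200, 4))

## small shared fixture: water cube, cubic target, three beams
toy_problem <- function(objectives, n = 16, sp = 4, angles = c(0, 120, 240)) {
  grid <- tiny_water_grid(n, sp)
  ctr <- rep(n * sp / 2, 3)
  m <- array(FALSE, grid$shape)
  hw <- round(n / 5)
  sel <- (n / 2 - hw):(n / 2 + hw)
  m[sel, sel, sel] <- TRUE
  ptv <- structure_mask("ptv", m, "target")
  body <- structure_mask("body", array(TRUE, grid$shape), "external")
  ss <- structure_set(grid, list(ptv, body))
  sgs <- lapply(angles, function(g) {
    fld <- field_geometry(g, ctr)
    place_spots(project_to_bev(ptv, grid, fld), 5, 8, fld, 4)
  })
  infl <- compute_influence(sgs, grid, bd)
  optimization_problem(infl, ss, objectives)
}

test_that("objective values match hand computation at zero weights", {
  prob <- toy_problem(list(
    dose_objective("ptv", "uniform_target", 1, 3),
    dose_objective("body", "max_dose", 5, 2),
    dose_objective("body", "mean_dose", 0.5, 4)))
  n <- ncol(prob$influence$matrix)
  ov <- objective_value(rep(0, n), prob)
  ## uniform: 3 * mean((0-1)^2) = 3; max_dose: 0; mean_dose: 4 * 0.25
  expect_equal(ov$value, 3 + 0 + 4 * 0.25)
  ## perfect uniform dose gives zero uniform objective
  prob2 <- toy_problem(list(dose_objective("ptv", "uniform_target", 1, 3)))
  res <- solve_fluence(prob2, max_iter = 300)
  expect_lt(objective_value(res$weights, prob2)$value, 1e-3)
})

test_that("gradient matches central finite differences", {
  prob <- toy_problem(list(
    dose_objective("ptv", "uniform_target", 2, 10),
    dose_objective("body", "max_dose", 1, 2),
    dose_objective("body", "mean_dose", 0.2, 1),
    dose_objective("body", "dvh_max", 0.5, 3, volume_fraction = 0.2)),
    n = 10, angles = c(0, 90))
  n <- ncol(prob$influence$matrix)
  set.seed(21)
  w <- runif(n, 0.5, 2) * 2 / max(prob$influence$matrix %*% rep(1, n))
  g <- objective_value(w, prob)$gradient
  h <- 1e-5 * max(abs(w))
  idx <- sample(n, min(10, n))
  for (i in idx) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    fd <- (objective_value(wp, prob)$value -
           objective_value(wm, prob)$value) / (2 * h)
    denom <- max(abs(fd), 1e-8)
    expect_lt(abs(g[i] - fd) / denom, 1e-4)
  }
})

test_that("single spot, single-voxel target recovers the closed form", {
  grid <- tiny_water_grid(12, 4)
  fld <- field_geometry(0, c(24, 24, 24))
  sg <- structure(list(field = fld,
                       positions = matrix(c(0, 0), 1, 2,
                                          dimnames = list(NULL, c("u", "v"))),
                       spacing = 4, margin = 5, sigma0 = 4),
                  class = "vhee_spot_grid")
  infl <- compute_influence(list(sg), grid, bd)
  m <- array(FALSE, grid$shape); m[6, 6, 6] <- TRUE
  ss <- structure_set(grid, list(structure_mask("ptv", m, "target")))
  prob <- optimization_problem(infl, ss,
                               list(dose_objective("ptv", "uniform_target", 2)))
  res <- solve_fluence(prob)
  dinf <- infl$matrix[which(m), 1]
  expect_equal(res$weights[1], 2 / dinf, tolerance = 1e-8)
})

test_that("optimisation converges, is monotone, bounded, deterministic", {
  prob <- toy_problem(list(dose_objective("ptv", "uniform_target", 60, 1)),
                      n = 20, angles = arrange_beams(5, 360))
  r1 <- solve_fluence(prob, seed = 1)
  r2 <- solve_fluence(prob, seed = 99)
  expect_identical(r1$weights, r2$weights)   # deterministic regardless of seed
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 0))
  expect_true(all(r1$weights >= 0))
  expect_lt(r1$value, 1e-3 * r1$trace[1])    # end-to-end convergence
  expect_lte(r1$value, r1$trace[1])
})

test_that("scale invariance of the optimised dose", {
  prob <- toy_problem(list(dose_objective("ptv", "uniform_target", 10, 1)),
                      n = 12, angles = c(0, 90, 180))
  res <- solve_fluence(prob)
  d1 <- as.numeric(prob$influence$matrix %*% res$weights)
  prob2 <- prob
  prob2$influence$matrix <- prob$influence$matrix * 8
  res2 <- solve_fluence(prob2)
  d2 <- as.numeric(prob2$influence$matrix %*% res2$weights)
  tmask <- prob$structure_set$structures$ptv$mask
  rms <- sqrt(mean((d1 - d2)[which(tmask)]^2)) / 10
  expect_lt(rms, 0.005)
})

test_that("dose recovery: known-weight target dose is reproduced", {
  ## three well-separated spots, target voxels on their axes: the uniform
  ## reference dose is exactly attainable by a known non-negative w*
  grid <- tiny_water_grid(24, 4)
  fld <- field_geometry(0, c(48, 48, 48))
  pos <- matrix(c(-24, 0, 24, 0, 0, 0), 3, 2,
                dimnames = list(NULL, c("u", "v")))
  sg <- structure(list(field = fld, positions = pos, spacing = 24,
                       margin = 5, sigma0 = 4),
                  class = "vhee_spot_grid")
  infl <- compute_influence(list(sg), grid, bd)
  m <- array(FALSE, grid$shape)
  m[cbind(c(6, 12, 18), 12, 12)] <- TRUE
  ss <- structure_set(grid, list(structure_mask("ptv", m, "target")))
  A <- as.matrix(infl$matrix[which(m), ])
  wstar <- solve(A, rep(2, 3))
  expect_true(all(wstar > 0))  # fixture sanity: w* is feasible
  prob <- optimization_problem(infl, ss,
                               list(dose_objective("ptv", "uniform_target", 2)))
  res <- solve_fluence(prob)
  dstar <- as.numeric(infl$matrix %*% wstar)
  dgot <- as.numeric(infl$matrix %*% res$weights)
  rms <- sqrt(mean((dgot - dstar)[which(m)]^2)) / 2
  expect_lt(rms, 0.005)
})

test_that("problem validation and infeasibility diagnostics", {
  prob <- toy_problem(list(dose_objective("ptv", "uniform_target", 1)))
  expect_error(optimization_problem(prob$influence, prob$structure_set,
                                    list(dose_objective("nope", "mean_dose", 1))),
               "unknown structure")
  expect_error(optimization_problem(prob$influence, prob$structure_set,
                                    list(dose_objective("body", "mean_dose", 1))),
               "uniform_target")
  expect_error(objective_value(rep(-1, ncol(prob$influence$matrix)), prob),
               ">= 0")
  ## target out of reach of all spots
  grid <- tiny_water_grid(12, 4)
  fld <- field_geometry(0, c(24, 24, 24))
  sg <- structure(list(field = fld,
                       positions = matrix(c(0, 0), 1, 2,
                                          dimnames = list(NULL, c("u", "v"))),
                       spacing = 4, margin = 5, sigma0 = 4),
                  class = "vhee_spot_grid")
  infl <- compute_influence(list(sg), grid, bd)
  far <- array(FALSE, grid$shape); far[1, 1, 12] <- TRUE
  ss <- structure_set(grid, list(structure_mask("ptv", far, "target")))
  p2 <- optimization_problem(infl, ss,
                             list(dose_objective("ptv", "uniform_target", 1)))
  expect_error(solve_fluence(p2), "no influence")
})

test_that("normalize_plan hits the prescription exactly", {
  prob <- toy_problem(list(dose_objective("ptv", "uniform_target", 60, 1)),
                      n = 12, angles = c(0, 180))
  res <- solve_fluence(prob, max_iter = 100)
  dose <- total_dose(prob$influence, res$weights)
  ptv <- prob$structure_set$structures$ptv
  for (pres in c(60, 55)) {
    norm <- normalize_plan(res$weights, dose, ptv, pres)
    expect_equal(mean(norm$dose$dose[ptv$mask]), pres, tolerance = 1e-12)
  }
  z <- normalize_plan(res$weights, dose, ptv, 0)
  expect_true(all(z$dose$dose == 0) && all(z$weights == 0))
  zero_dose <- dose; zero_dose$dose[] <- 0
  expect_error(normalize_plan(res$weights, zero_dose, ptv, 60), "zero")
})
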