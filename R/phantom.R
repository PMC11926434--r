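#' Voxel image grid
#'
#' A regular voxel grid of relative-to-water density. Coordinate
#' convention: x runs patient-right to patient-left, y anterior to
#' posterior, z inferior to superior; the origin is the grid corner and the
#' centre of voxel (i,j,k) (1-based) is `origin + (index - 0.5) * spacing`.
#'
#' @param density 3-D numeric array of relative density (>= 0).
#' @param spacing voxel size per axis, mm (default 2,2,2).
#' @param origin grid corner position, mm.
#' @return an object of class `vhee_grid`.
#' @export
image_grid <- function(density, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(density) || length(dim(density)) != 3L)
    stopf("`density` must be a 3-D array")
  if (any(!is.finite(density)) || any(density < 0))
    stopf("densities must be finite and >= 0")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stopf("spacing must be > 0")
  structure(list(shape = dim(density), spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L),
                 density = density),
            class = "vhee_grid")
}

#' Voxel-centre coordinates of a grid
#' @param grid a `vhee_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates along `axis`, mm.
#' @export
grid_axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

#' Structure (voxel mask)
#'
#' @param name structure name (unique within a set).
#' @param mask logical 3-D array aligned to the grid.
#' @param role one of `"target"`, `"oar"`, `"external"`.
#' @return an object of class `vhee_structure`.
#' @export
structure_mask <- function(name, mask, role = c("oar", "target", "external")) {
  role <- match.arg(role)
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("`mask` must be a logical 3-D array")
  if (role == "target" && !any(mask))
    stopf("target structure '%s' is empty", name)
  structure(list(name = name, mask = mask, role = role),
            class = "vhee_structure")
}

#' Structure set
#'
#' Bundles a grid with named structures. Target structures must be
#' non-empty and lie inside the external (body) structure when one exists.
#'
#' @param grid a `vhee_grid`.
#' @param structures list of `vhee_structure` objects.
#' @return an object of class `vhee_structure_set`.
#' @export
structure_set <- function(grid, structures) {
  nm <- vapply(structures, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate structure names")
  names(structures) <- nm
  for (s in structures)
    if (!identical(dim(s$mask), grid$shape))
      stopf("mask of '%s' is not aligned to the grid", s$name)
  ext <- Filter(function(s) s$role == "external", structures)
  if (length(ext)) {
    body <- ext[[1L]]$mask
    for (s in structures)
      if (s$role == "target" && any(s$mask & !body))
        stopf("target '%s' extends outside the body", s$name)
  }
  structure(list(grid = grid, structures = structures),
            class = "vhee_structure_set")
}

#' @export
print.vhee_structure_set <- function(x, ...) {
  cat(sprintf("<vhee_structure_set> grid %s @ %s mm\n",
              paste(x$grid$shape, collapse = "x"),
              paste(x$grid$spacing, collapse = "x")))
  for (s in x$structures)
    cat(sprintf("  %-12s %-8s %8.1f cm^3\n", s$name, s$role,
                structure_volume(s, x$grid)))
  invisible(x)
}

#' Structure volume
#'
#' @param s a `vhee_structure`.
#' @param grid the aligned `vhee_grid`.
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
structure_volume <- function(s, grid) {
  if (!identical(dim(s$mask), grid$shape))
    stopf("mask of '%s' is not aligned to the grid", s$name)
  sum(s$mask) * prod(grid$spacing) / 1000
}

#' Phantom specification
#'
#' Parameterises the synthetic phantom recipes. All geometry is
#' deterministic; `seed` is echoed into the output for provenance.
#' Recipes: `water_box` (uniform water with a centred cuboid PTV),
#' `pelvis` (elliptical body, ellipsoidal midline PTV at ~100 mm depth
#' with abutting posterior rectum and anterior bladder tubes),
#' `thorax_midline` / `thorax_chestwall` (elliptical body with two
#' low-density lungs, heart, oesophagus and spinal cord; spherical PTV
#' either midline overlapping the heart projection, calibrated to
#' 206.7 cm^3, or against the chest wall, calibrated to 271.5 cm^3).
#'
#' @param recipe one of `"water_box"`, `"pelvis"`, `"thorax_midline"`,
#'   `"thorax_chestwall"`.
#' @param spacing isotropic voxel size, mm (default 2).
#' @param seed integer echoed for provenance.
#' @param ... recipe parameter overrides (see Details in the vignette):
#'   `size_mm`, `ptv_size_mm` (water_box); `body_semiaxes`, `z_length_mm`,
#'   `ptv_semiaxes`, `ptv_depth_mm` (pelvis); `body_semiaxes`,
#'   `z_length_mm`, `lung_density`, `ptv_volume_cm3` (thorax);
#'   `air_density`, `air_margin_mm` (all).
#' @return an object of class `vhee_phantom_spec`.
#' @export
phantom_spec <- function(recipe = c("water_box", "pelvis", "thorax_midline",
                                    "thorax_chestwall"),
                         spacing = 2, seed = 1L, ...) {
  recipe <- match.arg(recipe)
  check_scalar(spacing, "spacing", positive = TRUE)
  defaults <- switch(recipe,
    water_box = list(size_mm = c(200, 200, 200), ptv_size_mm = c(40, 40, 40)),
    pelvis = list(body_semiaxes = c(150, 100), z_length_mm = 160,
                  ptv_semiaxes = c(30, 25, 25), ptv_depth_mm = 100,
                  rectum_radius_mm = 15, bladder_radius_mm = 25,
                  organ_gap_mm = 2, organ_length_mm = 100),
    thorax_midline = list(body_semiaxes = c(160, 95), z_length_mm = 160,
                          lung_density = 0.3, ptv_volume_cm3 = 206.7),
    thorax_chestwall = list(body_semiaxes = c(160, 95), z_length_mm = 160,
                            lung_density = 0.3, ptv_volume_cm3 = 271.5))
  defaults$air_density <- 0.001
  defaults$air_margin_mm <- 6
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown parameter(s) for recipe '%s': %s", recipe,
          paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, over)
  structure(list(recipe = recipe, spacing = spacing,
                 seed = as.integer(seed), params = params),
            class = "vhee_phantom_spec")
}

## digital ball: k nearest voxel centres to `center`, k chosen so the
## voxelised volume matches target_cm3 to within half a voxel
calibrated_ball <- function(xs, ys, zs, center, target_cm3, voxvol_mm3) {
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
              (zs - center[3])^2, `+`)
  k <- round(target_cm3 * 1000 / voxvol_mm3)
  thr <- sort(as.vector(d2), partial = k)[k]
  d2 <= thr
}

#' Generate a synthetic phantom
#'
#' Deterministic: identical specs produce voxel-identical phantoms.
#'
#' @param spec a [phantom_spec()].
#' @return a `vhee_structure_set`. The target structure is named `"ptv"`
#'   (`"itv"` for thorax recipes, as lung prescriptions are defined on the
#'   internal target volume); the body is `"body"` with role external.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "vhee_phantom_spec")) stopf("`spec` must be a vhee_phantom_spec")
  p <- spec$params
  sp <- spec$spacing
  out <- switch(spec$recipe,
    water_box = phantom_water_box(p, sp),
    pelvis = phantom_pelvis(p, sp),
    thorax_midline = phantom_thorax(p, sp, midline = TRUE),
    thorax_chestwall = phantom_thorax(p, sp, midline = FALSE))
  attr(out, "spec") <- spec
  out
}

phantom_water_box <- function(p, sp) {
  shape <- as.integer(round(p$size_mm / sp))
  dens <- array(1, dim = shape)
  grid <- image_grid(dens, spacing = rep(sp, 3))
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  zs <- grid_axis_centers(grid, 3)
  ctr <- p$size_mm / 2
  half <- p$ptv_size_mm / 2
  inx <- abs(xs - ctr[1]) <= half[1]
  iny <- abs(ys - ctr[2]) <= half[2]
  inz <- abs(zs - ctr[3]) <= half[3]
  ptv <- outer(outer(inx, iny, `&`), inz, `&`)
  body <- array(TRUE, dim = shape)
  structure_set(grid, list(
    structure_mask("ptv", ptv, "target"),
    structure_mask("body", body, "external")))
}

phantom_pelvis <- function(p, sp) {
  a <- p$body_semiaxes[1]; b <- p$body_semiaxes[2]
  m <- p$air_margin_mm
  ext <- c(2 * (a + m), 2 * (b + m), p$z_length_mm)
  shape <- as.integer(ceiling(ext / sp))
  grid <- image_grid(array(p$air_density, dim = shape), spacing = rep(sp, 3))
  xs <- grid_axis_centers(grid, 1); ys <- grid_axis_centers(grid, 2)
  zs <- grid_axis_centers(grid, 3)
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] / 2
  body2d <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`) <= 1
  body <- array(body2d, dim = shape)  # extruded along z (x fastest: ok)
  dens <- array(p$air_density, dim = shape)
  dens[body] <- 1

  ## PTV: ellipsoid centred at midline, ptv_depth_mm below the anterior
  ## body surface (y = cy - b)
  pc <- c(cx, cy - b + p$ptv_depth_mm, cz)
  e <- p$ptv_semiaxes
  ptv <- outer(outer(((xs - pc[1]) / e[1])^2, ((ys - pc[2]) / e[2])^2, `+`),
               ((zs - pc[3]) / e[3])^2, `+`) <= 1
  if (any(ptv & !body)) stopf("pelvis PTV extends outside the body")

  ## rectum: posterior tube abutting the PTV; bladder: anterior tube
  rr <- p$rectum_radius_mm; br <- p$bladder_radius_mm
  g <- p$organ_gap_mm; hl <- p$organ_length_mm / 2
  rc <- c(cx, pc[2] + e[2] + g + rr)
  bc <- c(cx, pc[2] - e[2] - g - br)
  inz <- abs(zs - cz) <= hl
  tube <- function(c2, r) {
    circ <- outer((xs - c2[1])^2, (ys - c2[2])^2, `+`) <= r^2
    outer(circ, inz, function(a, b) a & b)
  }
  rectum <- tube(rc, rr) & body
  bladder <- tube(bc, br) & body

  grid <- image_grid(dens, spacing = rep(sp, 3))
  structure_set(grid, list(
    structure_mask("ptv", ptv, "target"),
    structure_mask("rectum", rectum, "oar"),
    structure_mask("bladder", bladder, "oar"),
    structure_mask("body", body, "external")))
}

phantom_thorax <- function(p, sp, midline) {
  a <- p$body_semiaxes[1]; b <- p$body_semiaxes[2]
  m <- p$air_margin_mm
  ext <- c(2 * (a + m), 2 * (b + m), p$z_length_mm)
  shape <- as.integer(ceiling(ext / sp))
  xs <- (seq_len(shape[1]) - 0.5) * sp
  ys <- (seq_len(shape[2]) - 0.5) * sp
  zs <- (seq_len(shape[3]) - 0.5) * sp
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] / 2

  body2d <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`) <= 1
  body <- array(body2d, dim = shape)

  ## lungs: elliptic cylinders (patient-left = +x), z-extruded over the
  ## central lung_span
  lung_span <- p$z_length_mm - 20
  inz_lung <- abs(zs - cz) <= lung_span / 2
  lung_one <- function(x0) {
    circ <- outer(((xs - x0) / 58)^2, ((ys - (cy - 2)) / 58)^2, `+`) <= 1
    outer(circ, inz_lung, function(a, b) a & b) & body
  }
  lung_l <- lung_one(cx + 75)
  lung_r <- lung_one(cx - 75)
  lungs <- lung_l | lung_r

  zcyl <- function(c2, r, halflen = p$z_length_mm) {
    circ <- outer((xs - c2[1])^2, (ys - c2[2])^2, `+`) <= r^2
    inz <- abs(zs - cz) <= halflen / 2
    outer(circ, inz, function(a, b) a & b) & body
  }
  heart <- zcyl(c(cx + 12, cy - 28), 38, halflen = 90)
  oesophagus <- zcyl(c(cx, cy + 12), 8)
  cord <- zcyl(c(cx, cy + b - 22), 6)

  voxvol <- sp^3
  if (midline) {
    pc <- c(cx, cy - 30, cz)
  } else {
    pc <- c(cx + 85, cy - 5, cz)
  }
  target <- calibrated_ball(xs, ys, zs, pc, p$ptv_volume_cm3, voxvol)
  if (any(target & !body)) stopf("thorax PTV extends outside the body")

  dens <- array(p$air_density, dim = shape)
  dens[body] <- 1
  dens[lungs] <- p$lung_density
  dens[heart | oesophagus | cord] <- 1
  dens[target] <- 1  # tumour tissue displaces lung

  grid <- image_grid(dens, spacing = rep(sp, 3))
  structure_set(grid, list(
    structure_mask("itv", target, "target"),
    structure_mask("lungs", lungs & !target & !heart & !oesophagus & !cord,
                   "oar"),
    structure_mask("heart", heart, "oar"),
    structure_mask("oesophagus", oesophagus, "oar"),
    structure_mask("spinal_cord", cord, "oar"),
    structure_mask("body", body, "external")))
}

#' Name of the target structure of a structure set
#' @param ss a `vhee_structure_set`.
#' @return the name of the (first) structure with role `"target"`.
#' @export
target_name <- function(ss) {
  for (s in ss$structures) if (s$role == "target") return(s$name)
  stopf("structure set has no target")
}
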