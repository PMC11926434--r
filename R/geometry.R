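#' Beam angle arrangements
#'
#' Equidistant coplanar gantry angles. For `span < 360` the `n` angles are
#' endpoint-inclusive with pitch `span/(n-1)`, centred on `center` (the
#' IMRT-style partial arc); for `span == 360` the pitch is `360/n` with no
#' duplicate endpoint (full ring). All angles are reduced modulo 360.
#'
#' @param n number of beams (>= 1).
#' @param span arc span in degrees, 0 < span <= 360.
#' @param center arc centre angle, degrees.
#' @return numeric vector of gantry angles in [0, 360).
#' @examples
#' arrange_beams(5, span = 200, center = 0)  # pitch 50
#' arrange_beams(15, span = 360)             # pitch 24
#' @export
arrange_beams <- function(n, span = 360, center = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stopf("`n` must be a positive integer")
  check_scalar(span, "span")
  if (span <= 0 || span > 360) stopf("span must be in (0, 360]")
  if (n == 1) return(center %% 360)
  ang <- if (span == 360) center + 360 * (seq_len(n) - 1L) / n
         else center + span * ((seq_len(n) - 1L) / (n - 1L) - 0.5)
  ang %% 360
}

#' @rdname arrange_beams
#' @param gantry gantry angle, degrees.
#' @export
single_beam <- function(gantry = 0) gantry %% 360

#' @rdname arrange_beams
#' @export
parallel_opposed <- function(gantry = 0) c(gantry, gantry + 180) %% 360

#' Field geometry
#'
#' Parallel-beam (infinite SAD) pencil geometry, appropriate for
#' magnetically scanned beams. Gantry convention: 0 deg enters anteriorly
#' travelling +y; angles increase toward patient-left entry, so the beam
#' axis is `(-sin g, cos g, 0)`. The beam's-eye-view (BEV) basis is
#' `u = (cos g, sin g, 0)` (lateral) and `v = (0, 0, 1)` (superior).
#'
#' @param gantry_angle gantry angle, degrees.
#' @param isocenter isocentre position in grid coordinates, mm.
#' @return an object of class `vhee_field`.
#' @export
field_geometry <- function(gantry_angle, isocenter) {
  check_scalar(gantry_angle, "gantry_angle")
  if (length(isocenter) != 3L) stopf("isocenter must be length 3")
  g <- gantry_angle * pi / 180
  structure(list(gantry_angle = gantry_angle %% 360,
                 isocenter = as.numeric(isocenter),
                 beam_axis = c(-sin(g), cos(g), 0),
                 bev_u = c(cos(g), sin(g), 0),
                 bev_v = c(0, 0, 1)),
            class = "vhee_field")
}

## per-voxel BEV coordinates (u, v) relative to the isocentre, mm
bev_voxel_coords <- function(grid, field) {
  xs <- grid_axis_centers(grid, 1) - field$isocenter[1]
  ys <- grid_axis_centers(grid, 2) - field$isocenter[2]
  zs <- grid_axis_centers(grid, 3) - field$isocenter[3]
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  ux <- field$bev_u[1]; uy <- field$bev_u[2]
  u2d <- outer(xs * ux, ys * uy, `+`)     # bev_u has no z component
  u <- array(u2d, dim = grid$shape)
  v <- array(rep(zs, each = nx * ny), dim = grid$shape)
  list(u = u, v = v)
}

#' Water-equivalent (radiological) depth map
#'
#' For every voxel, the line integral of relative density along the beam
#' axis from the grid entry point to the voxel centre (Siddon-style exact
#' voxel traversal). With unit density everywhere this equals geometric
#' depth; surrounding air contributes its (near-zero) density.
#'
#' @param grid a `vhee_grid`.
#' @param field a `vhee_field`.
#' @return 3-D array of water-equivalent depths, mm.
#' @export
radiological_depth <- function(grid, field) {
  ax <- field$beam_axis
  if (abs(sqrt(sum(ax^2)) - 1) > 1e-9) stopf("beam axis must be unit length")
  d <- wepl_map_cpp(grid$density, grid$shape, grid$spacing, grid$origin, ax)
  array(d, dim = grid$shape)
}

#' Project a structure into the beam's-eye-view
#'
#' Orthographic projection of mask voxel centres onto the plane through the
#' isocentre perpendicular to the beam axis, rasterised at `resolution`.
#'
#' @param s a `vhee_structure` (non-empty).
#' @param grid the aligned `vhee_grid`.
#' @param field a `vhee_field`.
#' @param resolution raster cell size, mm (default: min grid spacing).
#' @return an object of class `vhee_footprint`: logical matrix `mask` with
#'   cell-centre coordinate vectors `u_centers`, `v_centers` (mm, relative
#'   to the isocentre) and `resolution`.
#' @export
project_to_bev <- function(s, grid, field, resolution = min(grid$spacing)) {
  if (!any(s$mask)) stopf("cannot project empty structure '%s'", s$name)
  check_scalar(resolution, "resolution", positive = TRUE)
  uv <- bev_voxel_coords(grid, field)
  u <- uv$u[s$mask]; v <- uv$v[s$mask]
  iu <- floor(u / resolution)
  iv <- floor(v / resolution)
  ru <- range(iu); rv <- range(iv)
  nu <- ru[2] - ru[1] + 1L; nv <- rv[2] - rv[1] + 1L
  mask <- matrix(FALSE, nu, nv)
  mask[cbind(iu - ru[1] + 1L, iv - rv[1] + 1L)] <- TRUE
  structure(list(mask = mask,
                 u_centers = (ru[1]:ru[2] + 0.5) * resolution,
                 v_centers = (rv[1]:rv[2] + 0.5) * resolution,
                 resolution = resolution),
            class = "vhee_footprint")
}

#' Place spots on a square lattice over a BEV footprint
#'
#' The lattice has pitch `spacing`, is anchored at the footprint centroid,
#' and a lattice point is kept iff it lies inside the footprint dilated by
#' `margin` — measured as Chebyshev (square-kernel) distance to the nearest
#' footprint raster-cell centre, points exactly on the dilated boundary
#' included. Spacing is conventionally a multiple k of the *initial* spot
#' sigma (k in 1.0-3.0).
#'
#' @param footprint a `vhee_footprint`.
#' @param margin dilation margin, mm (default 5).
#' @param spacing lattice pitch, mm (> 0).
#' @param field the `vhee_field` the spots belong to.
#' @param sigma0 initial spot sigma, mm (recorded on the grid).
#' @return an object of class `vhee_spot_grid` with a `positions` matrix
#'   (columns `u`, `v`, mm), ordered row-major (v, then u).
#' @export
place_spots <- function(footprint, margin = 5, spacing, field, sigma0 = 4) {
  check_scalar(margin, "margin", nonneg = TRUE)
  check_scalar(spacing, "spacing", positive = TRUE)
  fm <- footprint$mask
  if (!any(fm)) stopf("empty footprint")
  idx <- which(fm, arr.ind = TRUE)
  fu <- footprint$u_centers[idx[, 1L]]
  fv <- footprint$v_centers[idx[, 2L]]
  cu <- mean(fu); cv <- mean(fv)
  half_cell <- footprint$resolution / 2
  reach <- margin + half_cell + spacing
  ku <- seq(floor((min(fu) - reach - cu) / spacing),
            ceiling((max(fu) + reach - cu) / spacing))
  kv <- seq(floor((min(fv) - reach - cv) / spacing),
            ceiling((max(fv) + reach - cv) / spacing))
  cand <- expand.grid(u = cu + ku * spacing, v = cv + kv * spacing)
  ## Chebyshev distance from each candidate to the nearest footprint cell
  ## centre; boundary ties kept
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    min(pmax(abs(fu - cand$u[i]), abs(fv - cand$v[i]))) <= margin
  }, logical(1L))
  pos <- as.matrix(cand[keep, , drop = FALSE])
  if (nrow(pos) == 0L) stopf("no spots retained (footprint too small?)")
  pos <- pos[order(pos[, "v"], pos[, "u"]), , drop = FALSE]
  rownames(pos) <- NULL
  structure(list(field = field, positions = pos, spacing = spacing,
                 margin = margin, sigma0 = sigma0),
            class = "vhee_spot_grid")
}

#' @export
print.vhee_spot_grid <- function(x, ...) {
  cat(sprintf("<vhee_spot_grid> gantry %g deg: %d spots, pitch %g mm, margin %g mm\n",
              x$field$gantry_angle, nrow(x$positions), x$spacing, x$margin))
  invisible(x)
}
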