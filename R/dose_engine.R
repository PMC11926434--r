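#' Pencil-beam dose column for a single spot
#'
#' Dose per unit spot weight for every voxel: the product of the
#' longitudinal depth-dependent deposition (IDD at the voxel's
#' radiological depth) and a lateral Gaussian,
#' `IDD(d) * exp(-r^2/(2 sigma_tot(d)^2)) / (2 pi sigma_tot(d)^2)`,
#' where `r` is the lateral distance from the pencil axis in the BEV plane
#' and `sigma_tot^2 = sigma0^2 + sigma_scatter(d)^2`. The lateral Gaussian
#' is normalised to unit integral over the lateral plane (units 1/mm^2),
#' so the IDD carries all longitudinal information. Voxels beyond
#' `cutoff_sigmas * sigma_tot` receive exactly 0.
#'
#' @param spot_uv numeric length-2, spot (u, v) in the BEV plane, mm.
#' @param field a `vhee_field`.
#' @param grid a `vhee_grid`.
#' @param depth_map radiological depth array for this field
#'   (see [radiological_depth()]).
#' @param base a `vhee_base_data` for the field energy.
#' @param sigma0 initial spot sigma, mm.
#' @param cutoff_sigmas lateral cut-off in units of sigma_tot
#'   (default 3.5, keeping >= 99.8\% of the kernel mass).
#' @return a [Matrix::sparseVector] of length `prod(grid$shape)`.
#' @export
spot_dose <- function(spot_uv, field, grid, depth_map, base,
                      sigma0 = 4, cutoff_sigmas = 3.5) {
  if (!inherits(base, "vhee_base_data")) stopf("`base` must be vhee_base_data")
  check_scalar(sigma0, "sigma0", positive = TRUE)
  uv <- bev_voxel_coords(grid, field)
  tr <- influence_field_cpp(as.vector(uv$u), as.vector(uv$v),
                            as.vector(depth_map),
                            base$depth_dose$depths, base$depth_dose$idd,
                            base$lateral_spread$depths,
                            base$lateral_spread$sigma_scatter,
                            sigma0, spot_uv[1L], spot_uv[2L], cutoff_sigmas)
  Matrix::sparseVector(x = tr$x, i = tr$i, length = prod(grid$shape))
}

#' Assemble the sparse influence matrix
#'
#' One column per spot (dose per unit spot weight), all fields
#' concatenated in field order with each field's spots in their lattice
#' (row-major: v, then u) order.
#'
#' @param spot_grids list of `vhee_spot_grid` objects (one per field).
#' @param grid a `vhee_grid`.
#' @param bases either a single `vhee_base_data` shared by all fields or a
#'   list with one entry per field (single energy layer per field).
#' @param cutoff_sigmas lateral cut-off in sigma_tot units.
#' @return an object of class `vhee_influence`: sparse `matrix`
#'   (voxels x spots, dgCMatrix), `spots` data.frame
#'   (`field`, `gantry_deg`, `u_mm`, `v_mm`), `grid`, and per-field meta.
#' @export
compute_influence <- function(spot_grids, grid, bases, cutoff_sigmas = 3.5) {
  if (inherits(spot_grids, "vhee_spot_grid")) spot_grids <- list(spot_grids)
  nf <- length(spot_grids)
  if (inherits(bases, "vhee_base_data")) bases <- rep(list(bases), nf)
  if (length(bases) != nf) stopf("need one base data set per field")
  nvox <- prod(grid$shape)

  blocks <- vector("list", nf)
  meta <- vector("list", nf)
  for (f in seq_len(nf)) {
    sg <- spot_grids[[f]]
    pos <- sg$positions
    if (anyDuplicated(pos)) stopf("duplicate spot positions in field %d", f)
    dm <- radiological_depth(grid, sg$field)
    uv <- bev_voxel_coords(grid, sg$field)
    base <- bases[[f]]
    tr <- influence_field_cpp(as.vector(uv$u), as.vector(uv$v),
                              as.vector(dm),
                              base$depth_dose$depths, base$depth_dose$idd,
                              base$lateral_spread$depths,
                              base$lateral_spread$sigma_scatter,
                              sg$sigma0, pos[, "u"], pos[, "v"],
                              cutoff_sigmas)
    blocks[[f]] <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                        dims = c(nvox, nrow(pos)))
    meta[[f]] <- data.frame(field = f,
                            gantry_deg = sg$field$gantry_angle,
                            u_mm = pos[, "u"], v_mm = pos[, "v"])
  }
  structure(list(matrix = do.call(cbind, blocks),
                 spots = do.call(rbind, meta),
                 grid = grid,
                 spot_grids = spot_grids,
                 cutoff_sigmas = cutoff_sigmas),
            class = "vhee_influence")
}

#' @export
print.vhee_influence <- function(x, ...) {
  cat(sprintf("<vhee_influence> %d voxels x %d spots, %d fields, %.2f M nonzeros\n",
              nrow(x$matrix), ncol(x$matrix), length(x$spot_grids),
              length(x$matrix@x) / 1e6))
  invisible(x)
}

#' Total dose from spot weights
#'
#' Matrix-vector product of the influence matrix with the (non-negative)
#' spot weight vector; exactly linear in the weights.
#'
#' @param infl a `vhee_influence`.
#' @param weights numeric vector, one non-negative weight per spot.
#' @return an object of class `vhee_dose`: 3-D dose array plus grid
#'   reference. Units are arbitrary until prescription normalisation.
#' @export
total_dose <- function(infl, weights) {
  if (length(weights) != ncol(infl$matrix))
    stopf("expected %d weights, got %d", ncol(infl$matrix), length(weights))
  if (any(weights < 0)) stopf("spot weights must be >= 0")
  d <- as.numeric(infl$matrix %*% weights)
  structure(list(dose = array(d, dim = infl$grid$shape), grid = infl$grid),
            class = "vhee_dose")
}

#' Export / import an influence matrix (MatrixMarket + JSON sidecar)
#'
#' Plain-text sparse container: the matrix in MatrixMarket coordinate
#' format and the spot index map in a JSON sidecar `<path>.json`.
#'
#' @param infl a `vhee_influence`.
#' @param path `.mtx` output path.
#' @return `save_influence` returns `path` invisibly.
#' @export
save_influence <- function(infl, path) {
  Matrix::writeMM(infl$matrix, path)
  jsonlite::write_json(list(shape = infl$grid$shape,
                            spacing = infl$grid$spacing,
                            origin = infl$grid$origin,
                            spots = infl$spots,
                            cutoff_sigmas = infl$cutoff_sigmas),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
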