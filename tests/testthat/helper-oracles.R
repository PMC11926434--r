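# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, dense marching, full sorts) and share no code
# with the package internals beyond the public API.

## linear interpolation mirroring the documented table rules
oracle_interp <- function(x, y, q, zero_right) {
  n <- length(x)
  if (q <= x[1]) return(y[1])
  if (q >= x[n]) {
    if (q == x[n]) return(y[n])
    return(if (zero_right) 0 else y[n])
  }
  lo <- max(which(x <= q))
  t <- (q - x[lo]) / (x[lo + 1] - x[lo])
  y[lo] + t * (y[lo + 1] - y[lo])
}

## brute-force per-voxel pencil-beam dose (triple loop over the grid)
oracle_spot_dose <- function(grid, field, depth_map, base, spot_uv,
                             sigma0, cutoff = 3.5) {
  out <- array(0, dim = grid$shape)
  dd <- base$depth_dose
  ls <- base$lateral_spread
  for (k in seq_len(grid$shape[3])) for (j in seq_len(grid$shape[2]))
    for (i in seq_len(grid$shape[1])) {
      p <- grid$origin + (c(i, j, k) - 0.5) * grid$spacing
      rel <- p - field$isocenter
      u <- sum(rel * field$bev_u)
      v <- sum(rel * field$bev_v)
      d <- depth_map[i, j, k]
      idd <- oracle_interp(dd$depths, dd$idd, d, zero_right = TRUE)
      if (idd <= 0) next
      ss <- oracle_interp(ls$depths, ls$sigma_scatter, d, zero_right = FALSE)
      s2 <- sigma0 * sigma0 + ss * ss
      du <- u - spot_uv[1]
      dv <- v - spot_uv[2]
      r2 <- du * du + dv * dv
      if (r2 > cutoff * cutoff * s2) next
      out[i, j, k] <- idd * exp(-r2 / (2 * s2)) / (2 * pi * s2)
    }
  out
}

## dense ray-marching WEPL (0.1 mm nearest-neighbour sampling)
oracle_wepl <- function(grid, field, ijk, step = 0.1) {
  p <- grid$origin + (ijk - 0.5) * grid$spacing
  ax <- field$beam_axis
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$spacing
  tback <- Inf
  for (a in 1:3) {
    if (abs(ax[a]) > 1e-12) {
      t <- if (ax[a] > 0) (p[a] - lo[a]) / ax[a] else (p[a] - hi[a]) / ax[a]
      tback <- min(tback, t)
    }
  }
  if (!is.finite(tback) || tback <= 0) return(0)
  n <- floor(tback / step)
  acc <- 0
  ts <- if (n > 0) (seq_len(n) - 0.5) * step else numeric(0)
  for (t in ts) {
    q <- p - t * ax
    idx <- pmin(pmax(floor((q - lo) / grid$spacing) + 1, 1), grid$shape)
    acc <- acc + grid$density[idx[1], idx[2], idx[3]] * step
  }
  rem <- tback - n * step
  if (rem > 0) {
    q <- p - (n * step + rem / 2) * ax
    idx <- pmin(pmax(floor((q - lo) / grid$spacing) + 1, 1), grid$shape)
    acc <- acc + grid$density[idx[1], idx[2], idx[3]] * rem
  }
  acc
}

## Fermi-Eyges second moment by adaptive quadrature of the closed integrand
oracle_sigma_scatter <- function(energy_mev, z, params = analytic_model_params()) {
  if (z == 0) return(0)
  integrand <- function(t) {
    e <- pmax(energy_mev - params$collisional_stopping_power * t,
              params$min_energy)
    (params$highland_constant / e)^2 / params$radiation_length_water *
      (z - t)^2
  }
  sqrt(stats::integrate(integrand, 0, z, rel.tol = 1e-10)$value)
}

## full-sort DVH metric oracles
oracle_dx <- function(ds, x) {
  s <- sort(ds, decreasing = TRUE)
  s[ceiling(x / 100 * length(s))]
}
oracle_dabs <- function(ds, v_cm3, voxvol_cm3) {
  s <- sort(ds, decreasing = TRUE)
  s[ceiling(v_cm3 / voxvol_cm3)]
}
oracle_vx <- function(ds, x) 100 * sum(ds >= x) / length(ds)

## small uniform water grid
tiny_water_grid <- function(n = 20, spacing = 2) {
  image_grid(array(1, dim = rep(n, 3)), spacing = rep(spacing, 3))
}

## rectangular BEV footprint built directly (all cells inside)
square_footprint <- function(halfwidth = 20, resolution = 2) {
  ctr <- seq(-halfwidth + resolution / 2, halfwidth - resolution / 2,
             by = resolution)
  structure(list(mask = matrix(TRUE, length(ctr), length(ctr)),
                 u_centers = ctr, v_centers = ctr,
                 resolution = resolution),
            class = "vhee_footprint")
}

## random structure-and-dose fixture used by the DVH oracle suites
random_case_accept <- function(n = 8, sp = 2) {
  g <- image_grid(array(1, dim = rep(n, 3)), spacing = rep(sp, 3))
  m <- array(runif(n^3) < 0.4, dim = rep(n, 3))
  if (!any(m)) m[1] <- TRUE
  d <- array(rexp(n^3, 1 / 20), dim = rep(n, 3))
  list(grid = g, s = structure_mask("s", m), dose = d, ds = d[m])
}
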