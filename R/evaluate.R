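structure_doses <- function(dose, s) {
  d <- if (inherits(dose, "vhee_dose")) dose$dose else dose
  if (!identical(dim(d), dim(s$mask)))
    stopf("dose grid does not match mask of '%s'", s$name)
  if (!any(s$mask)) stopf("structure '%s' is empty", s$name)
  d[s$mask]
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level;
#' starts at 1 at dose 0 and is non-increasing.
#'
#' @param dose a `vhee_dose` (or dose array).
#' @param s a `vhee_structure`.
#' @param bin_width dose bin width, Gy.
#' @return an object of class `vhee_dvh`: `structure`, `dose` (bin
#'   edges, Gy), `volume_fraction`.
#' @export
compute_dvh <- function(dose, s, bin_width = 0.1) {
  check_scalar(bin_width, "bin_width", positive = TRUE)
  ds <- structure_doses(dose, s)
  edges <- seq(0, max(ds) + bin_width, by = bin_width)
  vf <- vapply(edges, function(e) mean(ds >= e), numeric(1L))
  structure(list(structure = s$name, dose = edges, volume_fraction = vf),
            class = "vhee_dvh")
}

#' Dose-volume metrics
#'
#' `dose_at_volume` (Dx\%): minimum dose received by the hottest x\% of the
#' structure — voxel doses sorted descending, value at rank
#' `ceiling(x/100 * n)` (no interpolation). `dose_at_absolute_volume`
#' (D_vcm3): the same at rank `ceiling(v / voxel volume)`.
#' `volume_at_dose` (V_xGy): percentage of the structure receiving at
#' least x Gy. `homogeneity_index`: `(D2% - D98%) / D50%` (ICRU-83 style;
#' lower is more homogeneous).
#'
#' @param dose a `vhee_dose` (or dose array).
#' @param s a `vhee_structure`.
#' @param x percentage volume (0 < x <= 100) for `dose_at_volume`; dose
#'   threshold in Gy for `volume_at_dose`.
#' @return Gy (dose metrics) or \% volume (`volume_at_dose`).
#' @export
dose_at_volume <- function(dose, s, x) {
  check_scalar(x, "x")
  if (x <= 0 || x > 100) stopf("x must be in (0, 100]")
  ds <- sort(structure_doses(dose, s), decreasing = TRUE)
  ds[ceiling(x / 100 * length(ds))]
}

#' @rdname dose_at_volume
#' @param v_cm3 absolute volume, cm^3 (<= structure volume).
#' @param grid the aligned `vhee_grid` (for the voxel volume).
#' @export
dose_at_absolute_volume <- function(dose, s, v_cm3, grid) {
  check_scalar(v_cm3, "v_cm3", positive = TRUE)
  voxvol <- prod(grid$spacing) / 1000
  ds <- sort(structure_doses(dose, s), decreasing = TRUE)
  k <- ceiling(v_cm3 / voxvol)
  if (k > length(ds))
    stopf("requested volume %g cm^3 exceeds structure volume %g cm^3",
          v_cm3, length(ds) * voxvol)
  ds[k]
}

#' @rdname dose_at_volume
#' @export
volume_at_dose <- function(dose, s, x) {
  check_scalar(x, "x", nonneg = TRUE)
  100 * mean(structure_doses(dose, s) >= x)
}

#' @rdname dose_at_volume
#' @export
homogeneity_index <- function(dose, s) {
  d50 <- dose_at_volume(dose, s, 50)
  if (d50 == 0) stopf("D50%% is zero; homogeneity index undefined")
  (dose_at_volume(dose, s, 2) - dose_at_volume(dose, s, 98)) / d50
}

#' Plan-quality metric set
#'
#' Tidy per-structure metrics: targets get D50\%, D98\%, D95\%, D2\%,
#' D_1cm3, Dmean and HI; other structures get Dmean, D2\%, D_1cm3 (when
#' the structure holds at least 1 cm^3), V20Gy and V5Gy.
#'
#' @param dose a `vhee_dose`.
#' @param ss a `vhee_structure_set`.
#' @return data.frame with columns `structure`, `metric`, `value`.
#' @export
plan_metrics <- function(dose, ss) {
  grid <- ss$grid
  rows <- list()
  add <- function(st, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(structure = st, metric = metric,
                                             value = value)
  for (s in ss$structures) {
    if (!any(s$mask)) next
    vol <- structure_volume(s, grid)
    if (s$role == "target") {
      add(s$name, "D50%", dose_at_volume(dose, s, 50))
      add(s$name, "D98%", dose_at_volume(dose, s, 98))
      add(s$name, "D95%", dose_at_volume(dose, s, 95))
      add(s$name, "D2%", dose_at_volume(dose, s, 2))
      add(s$name, "Dmean", mean(structure_doses(dose, s)))
      if (vol >= 1) add(s$name, "D1cm3",
                        dose_at_absolute_volume(dose, s, 1, grid))
      add(s$name, "HI", homogeneity_index(dose, s))
    } else {
      add(s$name, "Dmean", mean(structure_doses(dose, s)))
      add(s$name, "D2%", dose_at_volume(dose, s, 2))
      if (vol >= 1) add(s$name, "D1cm3",
                        dose_at_absolute_volume(dose, s, 1, grid))
      add(s$name, "V20Gy", volume_at_dose(dose, s, 20))
      add(s$name, "V5Gy", volume_at_dose(dose, s, 5))
    }
  }
  do.call(rbind, rows)
}
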