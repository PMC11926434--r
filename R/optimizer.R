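#' Dose objective specification
#'
#' Quadratic penalty objectives in the style of standard inverse planning:
#' \describe{
#'   \item{uniform_target}{`p * mean((D_i - d_ref)^2)` over the structure —
#'     exactly one per target structure.}
#'   \item{max_dose}{`p * mean(pmax(D_i - d_ref, 0)^2)` — overdose penalty.}
#'   \item{mean_dose}{`p * (mean(D) - d_ref)^2`.}
#'   \item{dvh_max}{overdose penalty applied only to the violating hottest
#'     fraction: the `volume_fraction * n` hottest voxels are exempt, any
#'     further voxel above `d_ref` is penalised quadratically (mean over
#'     the structure). Re-sorted each evaluation; non-convex.}
#' }
#'
#' @param structure structure name.
#' @param kind objective kind (see above).
#' @param dose_gy reference dose, Gy (>= 0).
#' @param weight penalty weight (>= 0).
#' @param volume_fraction for `dvh_max`: allowed hot volume fraction in
#'   (0, 1).
#' @return an object of class `vhee_objective`.
#' @export
dose_objective <- function(structure,
                           kind = c("uniform_target", "max_dose",
                                    "mean_dose", "dvh_max"),
                           dose_gy, weight = 1, volume_fraction = NULL) {
  kind <- match.arg(kind)
  check_scalar(dose_gy, "dose_gy", nonneg = TRUE)
  check_scalar(weight, "weight", nonneg = TRUE)
  if (kind == "dvh_max") {
    if (is.null(volume_fraction)) stopf("dvh_max needs a volume_fraction")
    check_scalar(volume_fraction, "volume_fraction", positive = TRUE)
    if (volume_fraction >= 1) stopf("volume_fraction must be < 1")
  }
  structure(list(structure = structure, kind = kind, dose_gy = dose_gy,
                 weight = weight, volume_fraction = volume_fraction),
            class = "vhee_objective")
}

#' Default protocol objective sets
#'
#' Editable starting points for the two cohorts: a uniform target
#' objective at prescription plus mean/max organ-at-risk penalties. The
#' numeric constraint values are pragmatic defaults in the spirit of
#' protocol-driven planning, not authoritative clinical constraints.
#'
#' @param protocol `"prostate"` (60 Gy to PTV mean) or `"lung"` (55 Gy to
#'   ITV mean).
#' @param prescription_gy prescription override, Gy.
#' @return list of `vhee_objective`.
#' @export
protocol_objectives <- function(protocol = c("prostate", "lung"),
                                prescription_gy = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "prostate") {
    pres <- prescription_gy %||% 60
    list(dose_objective("ptv", "uniform_target", pres, 100),
         dose_objective("rectum", "max_dose", 0.92 * pres, 5),
         dose_objective("rectum", "mean_dose", 0.4 * pres, 2),
         dose_objective("bladder", "max_dose", 0.92 * pres, 5),
         dose_objective("bladder", "mean_dose", 0.4 * pres, 1),
         dose_objective("body", "max_dose", 1.05 * pres, 1))
  } else {
    pres <- prescription_gy %||% 55
    list(dose_objective("itv", "uniform_target", pres, 100),
         dose_objective("lungs", "mean_dose", 0.2 * pres, 2),
         dose_objective("lungs", "max_dose", 0.9 * pres, 2),
         dose_objective("heart", "mean_dose", 0.2 * pres, 2),
         dose_objective("heart", "max_dose", 0.9 * pres, 2),
         dose_objective("oesophagus", "max_dose", 0.9 * pres, 2),
         dose_objective("spinal_cord", "max_dose", 0.7 * pres, 5),
         dose_objective("body", "max_dose", 1.05 * pres, 1))
  }
}

#' Fluence optimisation problem
#'
#' @param influence a `vhee_influence`.
#' @param structure_set the `vhee_structure_set` the masks come from.
#' @param objectives list of [dose_objective()] specs; structures absent
#'   from the set are rejected, and each target structure must carry
#'   exactly one `uniform_target` objective.
#' @return an object of class `vhee_problem`.
#' @export
optimization_problem <- function(influence, structure_set, objectives) {
  if (inherits(objectives, "vhee_objective")) objectives <- list(objectives)
  strs <- structure_set$structures
  for (ob in objectives) {
    if (is.null(strs[[ob$structure]]))
      stopf("objective references unknown structure '%s'", ob$structure)
    if (!any(strs[[ob$structure]]$mask))
      stopf("objective references empty structure '%s'", ob$structure)
  }
  tn <- target_name(structure_set)
  nut <- sum(vapply(objectives, function(o)
    o$kind == "uniform_target" && o$structure == tn, logical(1L)))
  if (nut != 1L)
    stopf("need exactly one uniform_target objective for target '%s' (got %d)",
          tn, nut)
  idx <- lapply(objectives, function(ob) which(strs[[ob$structure]]$mask))
  structure(list(influence = influence, structure_set = structure_set,
                 objectives = objectives, obj_index = idx,
                 target = tn),
            class = "vhee_problem")
}

#' Objective value and gradient
#'
#' Total penalised objective `F(w) = sum_obj p * f_obj(A w)` and its exact
#' gradient `A^T dF/dD` via the chain rule through the influence matrix.
#'
#' @param weights non-negative spot weights.
#' @param problem a `vhee_problem`.
#' @return list with `value` (scalar) and `gradient` (per spot).
#' @export
objective_value <- function(weights, problem) {
  if (any(weights < 0)) stopf("weights must be >= 0")
  A <- problem$influence$matrix
  D <- as.numeric(A %*% weights)
  g_vox <- numeric(length(D))
  val <- 0
  for (o in seq_along(problem$objectives)) {
    ob <- problem$objectives[[o]]
    ix <- problem$obj_index[[o]]
    ds <- D[ix]
    n <- length(ix)
    p <- ob$weight
    if (ob$kind == "uniform_target") {
      r <- ds - ob$dose_gy
      val <- val + p * mean(r^2)
      g_vox[ix] <- g_vox[ix] + p * 2 * r / n
    } else if (ob$kind == "max_dose") {
      r <- pmax(ds - ob$dose_gy, 0)
      val <- val + p * mean(r^2)
      g_vox[ix] <- g_vox[ix] + p * 2 * r / n
    } else if (ob$kind == "mean_dose") {
      r <- mean(ds) - ob$dose_gy
      val <- val + p * r^2
      g_vox[ix] <- g_vox[ix] + p * 2 * r / n
    } else { # dvh_max
      n_allow <- floor(ob$volume_fraction * n)
      ord <- order(ds, decreasing = TRUE)
      viol <- ord[-seq_len(n_allow)]
      viol <- viol[ds[viol] > ob$dose_gy]
      if (length(viol)) {
        r <- ds[viol] - ob$dose_gy
        val <- val + p * sum(r^2) / n
        gi <- ix[viol]
        g_vox[gi] <- g_vox[gi] + p * 2 * r / n
      }
    }
  }
  grad <- as.numeric(Matrix::crossprod(A, g_vox))
  list(value = val, gradient = grad)
}

#' Solve the fluence-map optimisation
#'
#' Bound-constrained quasi-Newton descent (L-BFGS-B, lower bound 0) from a
#' documented initial point: uniform positive weights (all 1, in the
#' arbitrary influence units). Fully deterministic;
#' `seed` is echoed for provenance only. The reported trace lists the
#' objective at each accepted (improving) function evaluation.
#'
#' @param problem a `vhee_problem`.
#' @param max_iter iteration cap (default 500).
#' @param tol projected-gradient tolerance (`pgtol`).
#' @param seed echoed into the result.
#' @return an object of class `vhee_result`: `weights`, `value`, `trace`,
#'   `converged`, `iterations`, `seed`.
#' @export
solve_fluence <- function(problem, max_iter = 500, tol = 1e-8, seed = NULL) {
  A <- problem$influence$matrix
  tmask <- problem$structure_set$structures[[problem$target]]$mask
  tix <- which(tmask)
  unit <- as.numeric(A %*% rep(1, ncol(A)))
  mtd <- mean(unit[tix])
  if (mtd <= 0)
    stopf("target '%s' receives no influence from any spot", problem$target)
  w0 <- rep(1, ncol(A))

  evals <- new.env(parent = emptyenv())
  evals$trace <- numeric(0)
  evals$w <- NULL
  eval_at <- function(w) {
    ## optim calls fn then gr at the same point: cache one evaluation
    if (is.null(evals$w) || !identical(w, evals$w)) {
      evals$w <- w
      evals$ov <- objective_value(pmax(w, 0), problem)
    }
    evals$ov
  }
  fn <- function(w) {
    v <- eval_at(w)$value
    if (!length(evals$trace) || v < min(evals$trace))
      evals$trace <- c(evals$trace, v)
    v
  }
  gr <- function(w) eval_at(w)$gradient
  res <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 10))
  structure(list(weights = pmax(res$par, 0), value = res$value,
                 trace = evals$trace,
                 converged = res$convergence == 0,
                 iterations = res$counts[["function"]],
                 message = res$message, seed = seed),
            class = "vhee_result")
}

#' Normalise a plan to prescription
#'
#' Rescales weights and dose by `s = prescription / mean(target dose)` so
#' the mean target dose equals the prescription exactly (all plans are
#' reported with target mean at 100\% of prescription).
#'
#' @param weights optimised spot weights.
#' @param dose a `vhee_dose`.
#' @param target the target `vhee_structure`.
#' @param prescription_gy prescription dose, Gy.
#' @return list with `weights`, `dose` (calibrated `vhee_dose`) and
#'   `scale`.
#' @export
normalize_plan <- function(weights, dose, target, prescription_gy) {
  check_scalar(prescription_gy, "prescription_gy", nonneg = TRUE)
  md <- mean(dose$dose[target$mask])
  if (prescription_gy == 0) {
    s <- 0
  } else {
    if (md <= 0) stopf("mean target dose is zero; cannot normalise")
    s <- prescription_gy / md
  }
  dose$dose <- dose$dose * s
  list(weights = weights * s, dose = dose, scale = s)
}
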