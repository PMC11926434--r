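#' Run one automated plan
#'
#' The three-stage automation: beam configuration (equidistant gantry
#' angles, isocentre at the target centroid, BEV spot placement with
#' margin), influence-matrix dose calculation, and fluence optimisation,
#' followed by prescription normalisation and metric scoring.
#'
#' @param phantom a `vhee_structure_set`.
#' @param n_beams number of beams (ignored when `angles` given).
#' @param span,center arc span and centre in degrees (see
#'   [arrange_beams()]).
#' @param angles explicit gantry angles, overriding `n_beams`/`span`.
#' @param energy_mev beam energy, MeV (single energy layer for all
#'   fields).
#' @param sigma0 initial spot sigma, mm.
#' @param spacing_k spot spacing as a multiple of `sigma0`.
#' @param objectives list of [dose_objective()]; default: the protocol
#'   matching the phantom's target name (`ptv` -> prostate,
#'   `itv` -> lung).
#' @param prescription_gy prescription dose, Gy.
#' @param margin BEV footprint margin, mm.
#' @param base optional `vhee_base_data` (generated analytically when
#'   omitted).
#' @param params [analytic_model_params()] for base-data generation.
#' @param max_iter,tol optimiser controls.
#' @param cutoff_sigmas lateral dose cut-off.
#' @param seed integer echoed for reproducibility (the pipeline itself is
#'   deterministic).
#' @param keep_dose keep the full dose array in the record (default TRUE).
#' @return an object of class `vhee_plan`: `config`, `metrics`
#'   (tidy data.frame), `spot_count`, `spots_per_100cm3`, `convergence`,
#'   and (optionally) `dose`, `weights`.
#' @export
run_plan <- function(phantom, n_beams = 5, span = 360, center = 0,
                     angles = NULL, energy_mev = 200, sigma0 = 4,
                     spacing_k = 1.5, objectives = NULL,
                     prescription_gy = 60, margin = 5,
                     base = NULL, params = analytic_model_params(),
                     max_iter = 500, tol = 1e-8, cutoff_sigmas = 3.5,
                     seed = 1L, keep_dose = TRUE) {
  stage <- "beam configuration"
  rec <- tryCatch({
    tn <- target_name(phantom)
    grid <- phantom$grid
    target <- phantom$structures[[tn]]
    if (is.null(angles)) angles <- arrange_beams(n_beams, span, center)
    if (is.null(objectives))
      objectives <- protocol_objectives(
        if (tn == "itv") "lung" else "prostate", prescription_gy)
    if (is.null(base))
      base <- generate_analytic_base_data(
        beam_energy_spec(energy_mev, sigma0), params)
    iso <- vapply(1:3, function(a)
      mean(grid_axis_centers(grid, a)[slice.index(target$mask, a)[target$mask]]),
      numeric(1L))
    spot_grids <- lapply(angles, function(g) {
      fld <- field_geometry(g, iso)
      fp <- project_to_bev(target, grid, fld)
      place_spots(fp, margin = margin, spacing = spacing_k * sigma0,
                  field = fld, sigma0 = sigma0)
    })

    stage <- "dose calculation"
    infl <- compute_influence(spot_grids, grid, base,
                              cutoff_sigmas = cutoff_sigmas)

    stage <- "plan optimisation"
    problem <- optimization_problem(infl, phantom, objectives)
    res <- solve_fluence(problem, max_iter = max_iter, tol = tol, seed = seed)
    dose <- total_dose(infl, res$weights)
    norm <- normalize_plan(res$weights, dose, target, prescription_gy)

    stage <- "evaluation"
    metrics <- plan_metrics(norm$dose, phantom)
    n_spots <- ncol(infl$matrix)
    tvol <- structure_volume(target, grid)
    spec <- attr(phantom, "spec")
    list(config = list(phantom = spec$recipe %||% "custom",
                       n_beams = length(angles), angles = angles,
                       span = span, center = center,
                       energy_mev = energy_mev, sigma0_mm = sigma0,
                       spacing_k = spacing_k,
                       prescription_gy = prescription_gy,
                       margin_mm = margin, cutoff_sigmas = cutoff_sigmas,
                       max_iter = max_iter, tol = tol, seed = seed),
         metrics = metrics,
         target = tn,
         spot_count = n_spots,
         spots_per_field = vapply(spot_grids, function(g)
           nrow(g$positions), integer(1L)),
         spots_per_100cm3 = n_spots / (tvol / 100),
         convergence = list(converged = res$converged,
                            iterations = res$iterations,
                            final_objective = res$value,
                            trace = res$trace),
         dose = if (keep_dose) norm$dose,
         weights = if (keep_dose) norm$weights)
  }, error = function(e) {
    stopf("plan failed during %s: %s", stage, conditionMessage(e))
  })
  structure(rec, class = "vhee_plan")
}

#' @export
print.vhee_plan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vhee_plan> %s: %d beams, %g MeV, %.1f sigma spacing, %d spots (%.0f / 100 cm^3)\n",
              cfg$phantom, cfg$n_beams, cfg$energy_mev, cfg$spacing_k,
              x$spot_count, x$spots_per_100cm3))
  cat(sprintf("  converged: %s after %d evaluations (objective %.4g)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$final_objective))
  invisible(x)
}

#' Study configuration
#'
#' Factor lists for an automated sweep; the Cartesian product of
#' `beam_counts` x `energies` x `spacings` is planned on each phantom.
#'
#' @param phantoms named list of `vhee_structure_set` (or
#'   `vhee_phantom_spec`, generated on demand).
#' @param beam_counts integer vector of beam numbers.
#' @param span,center arc span/centre, degrees.
#' @param energies energies, MeV.
#' @param sigma0 initial spot sigma, mm.
#' @param spacings spot-spacing multipliers of sigma0.
#' @param prescription_gy prescription, Gy.
#' @param fractions fraction count (bookkeeping only).
#' @param objectives optional objective list (default: per-phantom
#'   protocol).
#' @param margin BEV margin, mm.
#' @param max_iter optimiser iteration cap.
#' @param seed base seed; per-plan seeds are derived deterministically.
#' @return an object of class `vhee_study_config`.
#' @export
study_config <- function(phantoms, beam_counts, span = 360, center = 0,
                         energies = c(70, 110, 150, 200, 240), sigma0 = 4,
                         spacings = 1.5, prescription_gy = 60,
                         fractions = 20, objectives = NULL, margin = 5,
                         max_iter = 500, seed = 1L) {
  if (!length(phantoms)) stopf("`phantoms` must be non-empty")
  if (!length(beam_counts)) stopf("`beam_counts` must be non-empty")
  if (!length(energies)) stopf("`energies` must be non-empty")
  if (!length(spacings)) stopf("`spacings` must be non-empty")
  check_scalar(prescription_gy, "prescription_gy", positive = TRUE)
  if (is.null(names(phantoms)))
    names(phantoms) <- paste0("phantom", seq_along(phantoms))
  structure(list(phantoms = phantoms, beam_counts = as.integer(beam_counts),
                 span = span, center = center, energies = energies,
                 sigma0 = sigma0, spacings = spacings,
                 prescription_gy = prescription_gy, fractions = fractions,
                 objectives = objectives, margin = margin,
                 max_iter = max_iter, seed = as.integer(seed)),
            class = "vhee_study_config")
}

#' Read a study configuration from JSON
#'
#' Schema: `phantoms` (list of phantom-spec objects with `recipe`,
#' optional `spacing`, `seed` and parameter overrides), plus any of the
#' [study_config()] scalar/vector fields.
#'
#' @param path JSON file.
#' @return a `vhee_study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(cfg$phantoms)) stopf("config %s: missing `phantoms`", path)
  phantoms <- lapply(cfg$phantoms, function(p) {
    args <- p[setdiff(names(p), c("recipe", "spacing", "seed"))]
    do.call(phantom_spec, c(list(recipe = p$recipe,
                                 spacing = p$spacing %||% 2,
                                 seed = p$seed %||% 1L),
                            lapply(args, unlist)))
  })
  names(phantoms) <- vapply(cfg$phantoms, function(p)
    p$name %||% p$recipe, "")
  do.call(study_config, c(list(phantoms = phantoms),
    cfg[intersect(names(cfg),
                  c("beam_counts", "span", "center", "energies", "sigma0",
                    "spacings", "prescription_gy", "fractions", "margin",
                    "max_iter", "seed"))]))
}

#' Run a parameter sweep
#'
#' One plan per element of the configured factor product, in
#' deterministic order (phantom, beams, energy, spacing). Per-plan
#' failures are recorded and the sweep continues.
#'
#' @param cfg a [study_config()].
#' @param progress print one line per plan.
#' @return an object of class `vhee_summary`: `records` — long-format
#'   data.frame (`phantom`, `n_beams`, `arc_span`, `energy_mev`,
#'   `sigma0_mm`, `spacing_k`, `structure`, `metric`, `value`; plan-level
#'   quantities appear as metrics `spot_count`, `spots_per_100cm3` and
#'   `converged` under structure `"plan"`) — and `failures`.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  if (!inherits(cfg, "vhee_study_config")) stopf("`cfg` must be a vhee_study_config")
  phantoms <- lapply(cfg$phantoms, function(p)
    if (inherits(p, "vhee_phantom_spec")) make_phantom(p) else p)
  grid_df <- expand.grid(phantom = names(phantoms),
                         n_beams = cfg$beam_counts,
                         energy_mev = cfg$energies,
                         spacing_k = cfg$spacings,
                         stringsAsFactors = FALSE)
  records <- list(); failures <- list()
  for (r in seq_len(nrow(grid_df))) {
    row <- grid_df[r, ]
    plan_seed <- (cfg$seed + r) %% .Machine$integer.max
    if (progress)
      message(sprintf("[%d/%d] %s %d beams %g MeV %.1f sigma",
                      r, nrow(grid_df), row$phantom, row$n_beams,
                      row$energy_mev, row$spacing_k))
    rec <- tryCatch({
      pl <- run_plan(phantoms[[row$phantom]],
                     n_beams = row$n_beams, span = cfg$span,
                     center = cfg$center, energy_mev = row$energy_mev,
                     sigma0 = cfg$sigma0, spacing_k = row$spacing_k,
                     objectives = cfg$objectives,
                     prescription_gy = cfg$prescription_gy,
                     margin = cfg$margin, max_iter = cfg$max_iter,
                     seed = plan_seed, keep_dose = FALSE)
      m <- pl$metrics
      extra <- data.frame(structure = "plan",
                          metric = c("spot_count", "spots_per_100cm3",
                                     "converged", "final_objective"),
                          value = c(pl$spot_count, pl$spots_per_100cm3,
                                    as.numeric(pl$convergence$converged),
                                    pl$convergence$final_objective))
      m <- rbind(m, extra)
      cbind(data.frame(phantom = row$phantom, n_beams = row$n_beams,
                       arc_span = cfg$span, energy_mev = row$energy_mev,
                       sigma0_mm = cfg$sigma0, spacing_k = row$spacing_k),
            m)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        cbind(row, data.frame(error = conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  structure(list(records = if (length(records)) do.call(rbind, records)
                           else NULL,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = cfg),
            class = "vhee_summary")
}

#' Join plan metrics against a reference plan
#'
#' Adds reference values and differences to a long metric table:
#' `diff = value - ref` and `rel_diff_pct = 100 * (value - ref) / ref`.
#'
#' @param table long metric data.frame (from [run_sweep()] records or
#'   [plan_metrics()]); must have `structure`, `metric`, `value`.
#' @param reference reference metric data.frame with `structure`,
#'   `metric`, `value` (and optionally `phantom` to join per phantom).
#' @return the joined data.frame with `ref_value`, `diff`,
#'   `rel_diff_pct`; unmatched rows keep `NA` and are reported in the
#'   `"unmatched"` attribute.
#' @export
compare_to_reference <- function(table, reference) {
  need <- c("structure", "metric", "value")
  if (!all(need %in% names(table)) || !all(need %in% names(reference)))
    stopf("both tables need columns: %s", paste(need, collapse = ", "))
  keys <- intersect(c("phantom", "structure", "metric"), names(table))
  keys <- intersect(keys, names(reference))
  ref <- reference[, c(keys, "value")]
  names(ref)[names(ref) == "value"] <- "ref_value"
  out <- merge(table, ref, by = keys, all.x = TRUE, sort = FALSE)
  out$diff <- out$value - out$ref_value
  out$rel_diff_pct <- 100 * out$diff / out$ref_value
  un <- out[is.na(out$ref_value), keys, drop = FALSE]
  attr(out, "unmatched") <- un
  if (nrow(un))
    warning(sprintf("%d row(s) had no matching reference entry", nrow(un)),
            call. = FALSE)
  out
}

#' Build a pseudo-reference plan table
#'
#' A self-contained stand-in for an external reference: a 12-beam,
#' 360-degree VHEE plan (a pseudo arc). This is NOT a clinical VMAT
#' reference; it only enables self-contained difference tables.
#'
#' @param phantom a `vhee_structure_set`.
#' @param energy_mev,sigma0,spacing_k,prescription_gy plan parameters.
#' @param ... passed to [run_plan()].
#' @return metric data.frame.
#' @export
pseudo_reference <- function(phantom, energy_mev = 200, sigma0 = 4,
                             spacing_k = 1.5, prescription_gy = 60, ...) {
  pl <- run_plan(phantom, n_beams = 12, span = 360,
                 energy_mev = energy_mev, sigma0 = sigma0,
                 spacing_k = spacing_k, prescription_gy = prescription_gy,
                 keep_dose = FALSE, ...)
  pl$metrics
}
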