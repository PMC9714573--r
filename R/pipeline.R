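#' Define a brush study plan
#'
#' Experimental design for a sweep over tether spacings, system types,
#' tracer charges and radii, with a fixed number of realizations per cell
#' and counter-based seeding.
#'
#' @param d_grid Tether spacings (\eqn{\sigma}).
#' @param modes System types (subset of dynamic/static/straight/no_stiffness).
#' @param charges Tracer charges (e).
#' @param radii Tracer radii (\eqn{\sigma}).
#' @param n_realizations Realizations per cell.
#' @param base_seed Base seed; cell j, realization i uses
#'   `base_seed + (j - 1) * 100000 + i`.
#' @return An object of class `study_plan` with one row per cell.
#' @export
study_plan <- function(d_grid = c(2, 3, 4, 5, 7, 10, 15, 25, 50),
                       modes = "dynamic", charges = 0, radii = 0.5,
                       n_realizations = 100, base_seed = 1) {
  stopifnot(length(d_grid) >= 1, length(modes) >= 1, n_realizations >= 1)
  cells <- expand.grid(d = d_grid, mode = modes, charge = charges,
                       radius = radii, stringsAsFactors = FALSE)
  if (anyDuplicated(cells)) stop("duplicate (d, mode, charge, radius) cells")
  structure(list(cells = cells, n_realizations = n_realizations,
                 base_seed = base_seed), class = "study_plan")
}

#' Run a brush study
#'
#' Runs every cell of a [study_plan()]: builds and simulates the ensemble,
#' computes the dual MSD curves, the anisotropic diffusion estimate and the
#' structural observables (mean and sd of Rg over chains and realizations,
#' brush height, correlation length) and the tracer energy statistics.
#' When `output_dir` is given, each completed cell writes a one-row
#' `estimates.tsv` (plus a manifest line recording the seeds), and
#' re-running the same study resumes: cells whose estimates file already
#' exists are loaded instead of re-simulated.
#'
#' The bulk diffusion constant used for normalization is the model's
#' Stokes-Einstein value \eqn{D_\mathrm{bulk} = kT/\gamma_\mathrm{tracer}}
#' (which the free-particle ensembles of [run_bulk()] recover).
#'
#' @param plan A [study_plan()].
#' @param config Template [brush_config()]; d, mode, charge, radius and
#'   seeds are overridden per cell.
#' @param params A [forcefield_params()].
#' @param output_dir Optional directory for per-cell results and manifest.
#' @param n_groups Error groups for the diffusion fit.
#' @param progress Print one line per completed cell.
#' @return An object of class `brush_study`: a data frame `cells` of
#'   per-cell estimates plus the plan.
#' @export
run_study <- function(plan, config = brush_config(),
                      params = forcefield_params(), output_dir = NULL,
                      n_groups = 10, progress = FALSE) {
  stopifnot(inherits(plan, "study_plan"))
  cells <- plan$cells
  out <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    tag <- sprintf("d%g_%s_q%g_a%g", cells$d[j], cells$mode[j],
                   cells$charge[j], cells$radius[j])
    cell_dir <- if (!is.null(output_dir)) file.path(output_dir, tag) else NULL
    est_file <- if (!is.null(cell_dir)) file.path(cell_dir, "estimates.tsv")
    if (!is.null(est_file) && file.exists(est_file)) {
      out[[j]] <- read.table(est_file, header = TRUE, sep = "\t")
      if (progress) message("cell ", tag, ": loaded")
      next
    }
    cfg <- config
    cfg$d <- cells$d[j]
    cfg$mode <- cells$mode[j]
    cfg$tracer_charge <- cells$charge[j]
    cfg$tracer_radius <- cells$radius[j]
    seeds <- plan$base_seed + (j - 1L) * 100000L + seq_len(plan$n_realizations)
    trajs <- lapply(seeds, function(s) run_realization(cfg, params, seed = s))
    ng <- min(n_groups, length(trajs))
    est <- tryCatch(fit_diffusion(trajs, n_groups = ng),
                    error = function(e) NULL)
    d_bulk <- cfg$kT / (cfg$gamma * cfg$tracer_radius / 0.5)
    rg <- unlist(lapply(trajs, radius_of_gyration))
    en <- energy_stats(trajs)
    row <- data.frame(
      d = cfg$d, mode = cfg$mode, charge = cfg$tracer_charge,
      radius = cfg$tracer_radius, n = length(trajs),
      D_par = if (is.null(est)) NA else est$D_par,
      D_par_sd = if (is.null(est)) NA else est$D_par_sd,
      D_perp = if (is.null(est)) NA else est$D_perp,
      D_perp_sd = if (is.null(est)) NA else est$D_perp_sd,
      D_bulk = d_bulk,
      Rg_mean = mean(rg), Rg_sd = sd(rg),
      L_z = brush_height(trajs),
      xi = correlation_length(trajs),
      E_per_step = en$mean_energy_per_step,
      E_interacting = en$mean_energy_when_interacting,
      N_E = en$interacting_fraction,
      chain_E_per_bead = en$chain_mean_energy_per_bead,
      stringsAsFactors = FALSE)
    out[[j]] <- row
    if (!is.null(cell_dir)) {
      dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(row, est_file, comment = paste("cell", tag))
      cat(sprintf("%s\tseeds\t%d..%d\n", tag, seeds[1], seeds[length(seeds)]),
          file = file.path(output_dir, "manifest.tsv"), append = TRUE)
    }
    if (progress) message("cell ", tag, ": done")
  }
  structure(list(cells = do.call(rbind, out), plan = plan, config = config),
            class = "brush_study")
}

#' Summarize a brush study
#'
#' Pure reduction of a [run_study()] result into analysis-ready tables:
#' the normalized diffusion constants per direction with convergence and
#' anisotropy flags, the brush/mushroom phase table (brush when
#' \eqn{d < 2\langle R_g\rangle}) and the energy bookkeeping table.
#'
#' @param study A `brush_study`.
#' @return A list of data frames: `diffusion` (with `bulk_converged`
#'   flagging D/D_bulk near 1 at the largest spacing and `anisotropic`
#'   flagging \eqn{D_\parallel < D_\perp} for d in [2, 10]), `phase` and
#'   `energy`.
#' @export
report_study <- function(study) {
  stopifnot(inherits(study, "brush_study"))
  cc <- study$cells
  diff_tab <- data.frame(
    d = cc$d, mode = cc$mode, charge = cc$charge, radius = cc$radius,
    D_par_rel = cc$D_par / cc$D_bulk, D_perp_rel = cc$D_perp / cc$D_bulk,
    D_par_rel_sd = cc$D_par_sd / cc$D_bulk,
    D_perp_rel_sd = cc$D_perp_sd / cc$D_bulk)
  dmax <- max(cc$d)
  diff_tab$bulk_converged <- cc$d == dmax &
    abs(diff_tab$D_par_rel - 1) < 0.15 & abs(diff_tab$D_perp_rel - 1) < 0.15
  diff_tab$anisotropic <- cc$d >= 2 & cc$d <= 10 &
    diff_tab$D_par_rel < diff_tab$D_perp_rel
  phase <- data.frame(d = cc$d, mode = cc$mode, Rg_mean = cc$Rg_mean,
                      Rg_sd = cc$Rg_sd, L_z = cc$L_z, xi = cc$xi,
                      regime = ifelse(cc$d < 2 * cc$Rg_mean, "brush", "mushroom"))
  energy <- data.frame(d = cc$d, mode = cc$mode, charge = cc$charge,
                       E_per_step = cc$E_per_step,
                       E_interacting = cc$E_interacting, N_E = cc$N_E,
                       chain_E_per_bead = cc$chain_E_per_bead)
  list(diffusion = diff_tab, phase = phase, energy = energy)
}

#' @export
print.brush_study <- function(x, ...) {
  cat(sprintf("brush_study: %d cells, %d realizations each\n",
              nrow(x$cells), x$plan$n_realizations))
  print(x$cells[, c("d", "mode", "charge", "radius", "D_par", "D_perp",
                    "Rg_mean", "L_z")])
  invisible(x)
}
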