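# Single-trajectory MM-PBSA ensemble averaging with convergence monitoring.
#
# The binding free energy is assembled as
#   dG = <dE_gas(EL + vdW)> + <dG_solv(PB + SA)> - T dS,
# every term evaluated on receptor/ligand coordinates extracted from the
# complex frame (intramolecular contributions cancel).

select_frames <- function(ensemble, stride = NULL, from = NULL) {
  times <- ensemble$times
  if (is.null(stride)) stride <- ensemble$stride
  if (stride %% ensemble$stride != 0)
    stop(sprintf("analysis stride %g ps is not a multiple of the frame stride %g ps",
                 stride, ensemble$stride))
  sel <- which(abs((times - times[1]) %% stride) < 1e-9 |
               abs((times - times[1]) %% stride - stride) < 1e-9)
  if (!is.null(from)) sel <- sel[times[sel] >= from]
  sel
}

#' Per-snapshot energy decomposition of a complex ensemble
#'
#' For each selected frame: gas-phase EL and vdW cross-interaction terms,
#' the PB polar and SA nonpolar solvation differences
#' `G(complex) - G(receptor) - G(ligand)` on shared coordinates, and their
#' totals.
#'
#' @param ensemble a `conformer_ensemble` of a complex.
#' @param stride analysis stride, ps (multiple of the frame stride; default
#'   every frame).
#' @param from only frames at or after this time, ps.
#' @param settings [pb_settings()].
#' @param gamma,offset nonpolar parameters.
#' @return data.frame of class `energy_decomposition` with one row per
#'   selected frame and columns `frame_time`, `el`, `vdw`, `gas_total`,
#'   `polar_pb`, `nonpolar_sa`, `solv_total`, `enthalpic_total` (kcal/mol).
#' @export
snapshot_decomposition <- function(ensemble, stride = NULL, from = NULL,
                                   settings = pb_settings(),
                                   gamma = 0.00542, offset = 0.92) {
  complex <- ensemble$topology
  stopifnot(complex$role == "complex")
  sel <- select_frames(ensemble, stride, from)
  rows <- lapply(sel, function(i) {
    f <- ensemble$frames[[i]]
    gas <- gas_phase_binding(complex, f)
    solv <- binding_solvation(complex, f, settings, gamma, offset)
    data.frame(frame_time = ensemble$times[i], el = gas$el, vdw = gas$vdw,
               gas_total = gas$total, polar_pb = solv$polar,
               nonpolar_sa = solv$nonpolar, solv_total = solv$total,
               enthalpic_total = gas$total + solv$total)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("energy_decomposition", "data.frame")
  out
}

#' Ensemble-averaged binding free energy
#'
#' Means and block-corrected standard errors of the per-snapshot terms,
#' assembled with a normal-mode entropy term into the binding free energy.
#'
#' @param decomposition an `energy_decomposition` (from
#'   [snapshot_decomposition()]), >= 2 snapshots.
#' @param entropy an `entropy_result` (use [zero_entropy()] for
#'   enthalpy-only reporting).
#' @param n_blocks blocks for the standard errors (default ~ sqrt(n)).
#' @return list of class `binding_free_energy`: `mean` (named components),
#'   `se` (named), `minus_T_delta_S`, `delta_G`, `n_snapshots`.
#' @export
binding_free_energy <- function(decomposition, entropy = zero_entropy(),
                                n_blocks = NULL) {
  if (nrow(decomposition) < 1) stop("empty snapshot selection")
  comps <- c("el", "vdw", "gas_total", "polar_pb", "nonpolar_sa",
             "solv_total", "enthalpic_total")
  mu <- vapply(comps, function(k) mean(decomposition[[k]]), numeric(1))
  se <- vapply(comps, function(k) {
    x <- decomposition[[k]]
    if (length(x) < 2 || stats::sd(x) == 0) return(0)
    block_average(x, n_blocks)$se
  }, numeric(1))
  structure(list(mean = mu, se = se,
                 minus_T_delta_S = entropy$minus_T_delta_S,
                 delta_G = mu[["enthalpic_total"]] + entropy$minus_T_delta_S,
                 temperature = entropy$temperature,
                 n_snapshots = nrow(decomposition)),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf(paste0("<binding_free_energy over %d snapshots>\n",
                     "  EL %9.3f  vdW %9.3f  PB %9.3f  SA %9.3f  (kcal/mol)\n",
                     "  enthalpy %9.3f +/- %.3f   -T.dS %9.3f   dG %9.3f\n"),
              x$n_snapshots, x$mean[["el"]], x$mean[["vdw"]],
              x$mean[["polar_pb"]], x$mean[["nonpolar_sa"]],
              x$mean[["enthalpic_total"]], x$se[["enthalpic_total"]],
              x$minus_T_delta_S, x$delta_G))
  invisible(x)
}

#' Running-average convergence of a binding free-energy series
#'
#' The running average of the per-frame totals is converged when its
#' max-min excursion inside the trailing `window` is at most `tol`.
#'
#' @param times frame times, ps.
#' @param values per-frame totals, kcal/mol.
#' @param window trailing window, ps (must not exceed the series span).
#' @param tol kcal/mol.
#' @return list with `converged`, `excursion`, and the full `trace`
#'   data.frame (`time`, `running_average`).
#' @export
running_average_convergence <- function(times, values, window, tol = 1.0) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  span <- times[length(times)] - times[1]
  if (window > span)
    stop(sprintf("window %g ps exceeds the series span %g ps", window, span))
  ra <- cumsum(values) / seq_along(values)
  in_window <- times >= times[length(times)] - window
  excursion <- max(ra[in_window]) - min(ra[in_window])
  list(converged = excursion <= tol, excursion = excursion,
       trace = data.frame(time = times, running_average = ra))
}

#' Express a panel of binding free energies relative to a reference ligand
#'
#' @param panel named list of `binding_free_energy` objects (one per ligand).
#' @param reference name of the reference ligand.
#' @return data.frame with `ligand`, `delta_G`, `relative_delta_G`.
#' @export
relative_binding <- function(panel, reference) {
  if (!reference %in% names(panel))
    stop("reference ligand not in panel: ", reference)
  dg <- vapply(panel, function(b) b$delta_G, numeric(1))
  data.frame(ligand = names(panel), delta_G = unname(dg),
             relative_delta_G = unname(dg - dg[[reference]]))
}
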