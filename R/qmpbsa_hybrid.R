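# Hybrid free-energy assembly: externally supplied high-level gas-phase
# binding energies replace the MM gas term, the MM polar solvation term is
# weighted by a power-law dielectric fit, and snapshots are selected so the
# sampled subset reproduces the full-trajectory MM statistics.

#' Construct a set of high-level energy records
#'
#' @param frame_time ps, one per record.
#' @param gas_binding_energy kcal/mol, one per record.
#' @param forces optional named list (names = frame times) of lists with
#'   matrices `complex`, `receptor`, `ligand` of per-atom force 3-vectors,
#'   kcal/(mol A).
#' @return list of class `highlevel_records` with data.frame `table` and
#'   `forces`.
#' @export
highlevel_records <- function(frame_time, gas_binding_energy, forces = NULL) {
  stopifnot(length(frame_time) == length(gas_binding_energy))
  structure(list(table = data.frame(frame_time = frame_time,
                                    gas_binding_energy = gas_binding_energy),
                 forces = forces),
            class = "highlevel_records")
}

#' Read high-level records from whitespace-delimited text
#'
#' Energy file columns: `frame_time gas_binding_energy`.  An optional
#' companion force file has columns
#' `frame_time species atom_index fx fy fz`.
#'
#' @param path energy table path.
#' @param force_path optional force table path.
#' @return a `highlevel_records` object.
#' @export
read_highlevel_records <- function(path, force_path = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  forces <- NULL
  if (!is.null(force_path)) {
    ft <- utils::read.table(force_path, header = TRUE)
    forces <- lapply(split(ft, ft$frame_time), function(d) {
      lapply(split(d, d$species), function(s) {
        s <- s[order(s$atom_index), ]
        as.matrix(s[, c("fx", "fy", "fz")])
      })
    })
  }
  highlevel_records(tab$frame_time, tab$gas_binding_energy, forces)
}

#' Write high-level records to whitespace-delimited text
#' @param records a `highlevel_records`.
#' @param path energy table path.
#' @param force_path optional force table path.
#' @export
write_highlevel_records <- function(records, path, force_path = NULL) {
  utils::write.table(records$table, path, quote = FALSE, row.names = FALSE)
  if (!is.null(force_path) && !is.null(records$forces)) {
    rows <- list()
    for (t in names(records$forces)) {
      for (sp in names(records$forces[[t]])) {
        f <- records$forces[[t]][[sp]]
        rows[[length(rows) + 1]] <- data.frame(frame_time = as.numeric(t),
                                               species = sp,
                                               atom_index = seq_len(nrow(f)),
                                               fx = f[, 1], fy = f[, 2], fz = f[, 3])
      }
    }
    utils::write.table(do.call(rbind, rows), force_path, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Power-law fit of polar solvation against the solute dielectric
#'
#' Least-squares fit of `|G| = A * eps^b` in log-log space.  The scale
#' factor applied to the MM polar binding term is the fitted ratio
#' `(target_dielectric / reference_dielectric)^b`; with both defaults at 1
#' the weight is the identity, and the rule is a documented configuration
#' point.
#'
#' @param samples data.frame with columns `solute_dielectric` and `polar`
#'   (kcal/mol), >= 3 rows, distinct dielectrics, energies of one sign.
#' @param target_dielectric,reference_dielectric dielectrics at which the
#'   fitted curve is evaluated to form the weight.
#' @return list of class `power_law_fit`: `amplitude` (signed, kcal/mol),
#'   `exponent`, `rms_residual` (kcal/mol), `scale_factor`.
#' @export
fit_polar_scaling <- function(samples, target_dielectric = 1,
                              reference_dielectric = 1) {
  stopifnot(is.data.frame(samples),
            all(c("solute_dielectric", "polar") %in% names(samples)))
  if (nrow(samples) < 3) stop("need at least 3 (dielectric, polar) samples")
  eps <- samples$solute_dielectric
  g <- samples$polar
  if (any(eps <= 0) || anyDuplicated(eps)) stop("dielectrics must be distinct and > 0")
  sgn <- unique(sign(g[g != 0]))
  if (length(sgn) > 1) stop("polar energies must be of one sign")
  if (length(sgn) == 0) {               # all-zero degenerate input
    return(structure(list(amplitude = 0, exponent = 0, rms_residual = 0,
                          scale_factor = 1), class = "power_law_fit"))
  }
  if (any(g == 0)) stop("polar energies must be of one sign (zero present)")
  fit <- stats::lm(log(abs(g)) ~ log(eps))
  b <- unname(stats::coef(fit)[2])
  a <- sgn * exp(unname(stats::coef(fit)[1]))
  if (stats::sd(g) > 0 && stats::sd(log(abs(g))) > 0 &&
      abs(stats::sd(log(eps))) < 1e-14) stop("singular power-law fit")
  pred <- a * eps^b
  structure(list(amplitude = a, exponent = b,
                 rms_residual = sqrt(mean((g - pred)^2)),
                 scale_factor = (target_dielectric / reference_dielectric)^b),
            class = "power_law_fit")
}

#' Hybrid binding free energy (high-level gas term, weighted polar term)
#'
#' The per-snapshot MM gas-phase term is replaced by the supplied
#' high-level gas binding energy and the polar solvation binding term is
#' multiplied by the power-law scale factor; SA and entropy terms are
#' unchanged.  With identity records and scale factor 1, the result
#' reduces exactly to the classical assembly.
#'
#' @param decomposition an `energy_decomposition` of the sampled frames.
#' @param records a `highlevel_records`; every sampled frame time must have
#'   a record.
#' @param fit a `power_law_fit` (or NULL for scale factor 1).
#' @param entropy an `entropy_result`.
#' @param n_blocks blocks for standard errors.
#' @return a `binding_free_energy` with extra fields `scale_factor` and
#'   `half_vs_full` (first-half vs full-subset dG difference, kcal/mol).
#' @export
hybrid_binding_free_energy <- function(decomposition, records, fit = NULL,
                                       entropy = zero_entropy(), n_blocks = NULL) {
  scale <- if (is.null(fit)) 1 else fit$scale_factor
  idx <- match(decomposition$frame_time, records$table$frame_time)
  if (anyNA(idx))
    stop("no high-level record for frame time(s): ",
         paste(decomposition$frame_time[is.na(idx)], collapse = ", "))
  d <- decomposition
  d$el <- NA_real_; d$vdw <- NA_real_
  d$gas_total <- records$table$gas_binding_energy[idx]
  d$polar_pb <- scale * d$polar_pb
  d$solv_total <- d$polar_pb + d$nonpolar_sa
  d$enthalpic_total <- d$gas_total + d$solv_total
  comps <- c("gas_total", "polar_pb", "nonpolar_sa", "solv_total", "enthalpic_total")
  mu <- vapply(comps, function(k) mean(d[[k]]), numeric(1))
  se <- vapply(comps, function(k) {
    x <- d[[k]]
    if (length(x) < 2 || stats::sd(x) == 0) return(0)
    block_average(x, n_blocks)$se
  }, numeric(1))
  half <- d[seq_len(ceiling(nrow(d) / 2)), , drop = FALSE]
  half_dg <- mean(half$enthalpic_total) + entropy$minus_T_delta_S
  structure(list(mean = mu, se = se,
                 minus_T_delta_S = entropy$minus_T_delta_S,
                 delta_G = mu[["enthalpic_total"]] + entropy$minus_T_delta_S,
                 temperature = entropy$temperature,
                 n_snapshots = nrow(d), scale_factor = scale,
                 half_vs_full = half_dg - (mu[["enthalpic_total"]] +
                                           entropy$minus_T_delta_S)),
            class = "binding_free_energy")
}

subset_objective <- function(idx, enth, occ, full_stats, norms) {
  stats_sub <- c(mean(enth[idx]), stats::sd(enth[idx]),
                 if (!is.null(occ)) colMeans(occ[idx, , drop = FALSE]))
  dev <- ((stats_sub - full_stats) / norms)^2
  sum(dev[is.finite(dev)])     # sd undefined for size-1 interim subsets
}

#' Select representative snapshots for high-level analysis
#'
#' Returns the mandatory frames plus `k` additional frames chosen so the
#' subset's statistics (mean and standard deviation of the per-frame
#' enthalpic total, and the occupancy of each supplied hydrogen bond) best
#' match the full-trajectory values.  Each statistic's deviation is
#' z-scored by the full-trajectory standard deviation of the underlying
#' per-frame series, with equal weights.  The search is exhaustive when the
#' candidate pool admits at most `exhaustive_limit` subsets, otherwise
#' greedy with swap refinement.
#'
#' @param decomposition an `energy_decomposition` over the candidate pool.
#' @param k number of additional frames to select.
#' @param mandatory integer row indices always included (coarse-stride
#'   frames).
#' @param hbond_indicators optional logical matrix (frames x bonds) of
#'   per-frame hydrogen-bond indicators.
#' @param exhaustive_limit subset-count threshold for exhaustive search.
#' @return list with `selected` (sorted row indices incl. mandatory),
#'   `extra` (the k chosen rows), `objective`.
#' @export
select_representative_snapshots <- function(decomposition, k, mandatory = integer(0),
                                            hbond_indicators = NULL,
                                            exhaustive_limit = 5000) {
  n <- nrow(decomposition)
  enth <- decomposition$enthalpic_total
  occ <- if (!is.null(hbond_indicators)) {
    m <- as.matrix(hbond_indicators) * 1
    stopifnot(nrow(m) == n)
    m
  } else NULL
  candidates <- setdiff(seq_len(n), mandatory)
  if (k > length(candidates))
    stop(sprintf("k = %d exceeds the candidate pool (%d frames)", k, length(candidates)))
  sd_full <- stats::sd(enth)
  occ_sd <- if (!is.null(occ)) apply(occ, 2, stats::sd) else NULL
  norms <- c(sd_full, sd_full, occ_sd)
  norms[!is.finite(norms) | norms == 0] <- 1
  full_stats <- c(mean(enth), stats::sd(enth), if (!is.null(occ)) colMeans(occ))
  obj <- function(extra) subset_objective(sort(c(mandatory, extra)), enth, occ,
                                          full_stats, norms)
  if (choose(length(candidates), k) <= exhaustive_limit) {
    subsets <- utils::combn(candidates, k)
    vals <- apply(subsets, 2, obj)
    best <- subsets[, which.min(vals)]
    best_val <- min(vals)
  } else {
    chosen <- integer(0)
    for (step in seq_len(k)) {
      rest <- setdiff(candidates, chosen)
      vals <- vapply(rest, function(c0) obj(c(chosen, c0)), numeric(1))
      chosen <- c(chosen, rest[which.min(vals)])
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_along(chosen)) {
        rest <- setdiff(candidates, chosen)
        cur <- obj(chosen)
        vals <- vapply(rest, function(c0) { s <- chosen; s[i] <- c0; obj(s) },
                       numeric(1))
        if (length(vals) > 0 && min(vals) < cur - 1e-15) {
          chosen[i] <- rest[which.min(vals)]
          improved <- TRUE
        }
      }
    }
    best <- chosen
    best_val <- obj(chosen)
  }
  list(selected = sort(c(mandatory, best)), extra = sort(best),
       objective = best_val)
}

#' Per-atom MM force-error profile against high-level forces
#'
#' For each sampled frame with forces, the MM forces of the chosen species
#' are computed by analytic gradient of the configured energy model and the
#' per-atom magnitude of the force difference is averaged over frames.
#'
#' @param ensemble a `conformer_ensemble` of a complex.
#' @param records a `highlevel_records` carrying forces.
#' @param species `"complex"`, `"receptor"` or `"ligand"`.
#' @param ... passed to [energy_model()] (e.g. `gb`, `bond_k`).
#' @return data.frame of class `force_error_profile`: `serial`, `name`,
#'   `mean_abs_dF` (kcal/(mol A)), attribute `n_snapshots`.
#' @export
force_error_profile <- function(ensemble, records, species = "complex", ...) {
  if (is.null(records$forces)) stop("records carry no forces")
  complex <- ensemble$topology
  sys <- if (species == "complex") complex else extract_component(complex, species)
  rows <- if (species == "complex") seq_len(nrow(complex$atoms))
          else partition_rows(complex)[[species]]
  times <- as.numeric(names(records$forces))
  acc <- NULL
  n_used <- 0
  for (ti in seq_along(times)) {
    fi <- which(abs(ensemble$times - times[ti]) < 1e-9)
    if (length(fi) != 1) stop("force record at t = ", times[ti],
                              " ps does not match an ensemble frame")
    fh <- records$forces[[ti]][[species]]
    frame <- ensemble$frames[[fi]][rows, , drop = FALSE]
    if (is.null(fh) || nrow(fh) != nrow(frame))
      stop("force record shape mismatch for species ", species)
    fm <- mm_forces(sys, frame, ...)
    dmag <- sqrt(rowSums((fh - fm)^2))
    acc <- if (is.null(acc)) dmag else acc + dmag
    n_used <- n_used + 1
  }
  out <- data.frame(serial = sys$atoms$serial, name = sys$atoms$name,
                    mean_abs_dF = acc / n_used)
  attr(out, "n_snapshots") <- n_used
  class(out) <- c("force_error_profile", "data.frame")
  out
}
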