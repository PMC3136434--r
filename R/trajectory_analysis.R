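# Trajectory analytics: hydrogen-bond occupancy, block averaging, distance
# distributions, and backbone RMSD with optimal (Kabsch) superposition.

#' Hydrogen-bond geometric criterion
#'
#' @param donor,acceptor atom serials.
#' @param hydrogen optional hydrogen serial; when given, the
#'   donor-hydrogen-acceptor angle is also tested.
#' @param distance_cutoff donor-acceptor distance cutoff, A.
#' @param angle_cutoff minimum donor-H-acceptor angle, degrees.
#' @return list of class `hbond_spec`.
#' @export
hbond_spec <- function(donor, acceptor, hydrogen = NULL,
                       distance_cutoff = 3.5, angle_cutoff = 120) {
  stopifnot(distance_cutoff > 0, angle_cutoff >= 0, angle_cutoff <= 180)
  structure(list(donor = donor, acceptor = acceptor, hydrogen = hydrogen,
                 distance_cutoff = distance_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_spec")
}

serial_row <- function(topology, serial, what = "atom") {
  i <- match(serial, topology$atoms$serial)
  if (is.na(i)) stop(sprintf("unknown %s serial %s", what, serial))
  i
}

#' Per-frame hydrogen-bond indicator
#'
#' @param ensemble a `conformer_ensemble`.
#' @param spec an [hbond_spec()].
#' @return logical vector, one entry per frame.
#' @export
hbond_indicator <- function(ensemble, spec) {
  top <- ensemble$topology
  id <- serial_row(top, spec$donor, "donor")
  ia <- serial_row(top, spec$acceptor, "acceptor")
  ih <- if (!is.null(spec$hydrogen)) serial_row(top, spec$hydrogen, "hydrogen") else NA
  vapply(ensemble$frames, function(f) {
    d <- sqrt(sum((f[id, ] - f[ia, ])^2))
    if (d > spec$distance_cutoff) return(FALSE)
    if (is.na(ih)) return(TRUE)
    v1 <- f[id, ] - f[ih, ]; v2 <- f[ia, ] - f[ih, ]
    ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= spec$angle_cutoff
  }, logical(1))
}

#' Fractional occupancy of an intermittent hydrogen bond
#'
#' @inheritParams hbond_indicator
#' @param n_blocks blocks for the per-block fractions.
#' @return list of class `occupancy_result`: `fraction`, `per_block`,
#'   `n_frames`.
#' @export
hbond_occupancy <- function(ensemble, spec, n_blocks = 5) {
  ind <- hbond_indicator(ensemble, spec)
  per_block <- if (length(ind) >= n_blocks) {
    block_average(as.numeric(ind), n_blocks)$block_means
  } else mean(ind)
  structure(list(fraction = mean(ind), per_block = per_block,
                 n_frames = length(ind)),
            class = "occupancy_result")
}

#' Block averaging of an autocorrelated series
#'
#' Contiguous equal blocks (remainder folded into the last block); the
#' standard error of the mean is `sd(block means)/sqrt(n_blocks)`.
#'
#' @param series numeric vector.
#' @param n_blocks number of blocks (>= 2).
#' @return list with `block_means`, `mean`, `se`.
#' @export
block_average <- function(series, n_blocks = NULL) {
  n <- length(series)
  if (is.null(n_blocks)) n_blocks <- max(2, floor(sqrt(n)))
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (n < n_blocks) stop("series shorter than the number of blocks")
  size <- floor(n / n_blocks)
  starts <- (seq_len(n_blocks) - 1) * size + 1
  ends <- c(starts[-1] - 1, n)                     # remainder to last block
  bm <- vapply(seq_len(n_blocks), function(b) mean(series[starts[b]:ends[b]]),
               numeric(1))
  list(block_means = bm, mean = mean(series), se = stats::sd(bm) / sqrt(n_blocks))
}

#' Distance distribution of an atom pair over an ensemble
#'
#' @param ensemble a `conformer_ensemble`.
#' @param pair length-2 vector of atom serials.
#' @param bin_width histogram bin width, A.
#' @param log_counts also return log10 counts with empty bins masked (`NA`).
#' @return list with `breaks`, `mids`, `counts`, `distances`, and
#'   (optionally) `log_counts`.
#' @export
distance_distribution <- function(ensemble, pair, bin_width = 0.1, log_counts = FALSE) {
  top <- ensemble$topology
  i <- serial_row(top, pair[1]); j <- serial_row(top, pair[2])
  d <- vapply(ensemble$frames, function(f) sqrt(sum((f[i, ] - f[j, ])^2)), numeric(1))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  out <- list(breaks = h$breaks, mids = h$mids, counts = h$counts, distances = d)
  if (log_counts)
    out$log_counts <- ifelse(h$counts > 0, log10(h$counts), NA_real_)
  out
}

#' Backbone RMSD per frame after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch, via `bio3d::rmsd`) of the
#' selected atoms onto the reference, then coordinate RMSD.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param reference reference coordinates (matrix) or a frame index.
#' @param selection atom selection: serials, or atom names (e.g.
#'   `c("N","CA","C")`), or NULL for all atoms.
#' @return numeric vector of per-frame RMSD, A.
#' @export
backbone_rmsd <- function(ensemble, reference = 1, selection = c("N", "CA", "C")) {
  top <- ensemble$topology
  if (is.null(selection)) {
    rows <- seq_len(nrow(top$atoms))
  } else if (is.character(selection)) {
    rows <- which(top$atoms$name %in% selection)
  } else {
    rows <- match(selection, top$atoms$serial)
    if (anyNA(rows)) stop("selection contains unknown atom serials")
  }
  if (length(rows) == 0) stop("empty atom selection")
  ref <- if (is.matrix(reference)) reference else ensemble$frames[[reference]]
  if (nrow(ref) != nrow(top$atoms) && nrow(ref) != length(rows))
    stop("reference does not match the topology or the selection")
  refsel <- if (nrow(ref) == length(rows)) ref else ref[rows, , drop = FALSE]
  vapply(ensemble$frames, function(f) {
    bio3d::rmsd(as.vector(t(refsel)), as.vector(t(f[rows, , drop = FALSE])),
                fit = TRUE)
  }, numeric(1))
}

#' Flag ensembles whose backbone RMSD exceeds a bound
#'
#' Equilibration monitoring: an ensemble passes if its whole backbone RMSD
#' trace stays at or below `bound` relative to the reference.
#'
#' @inheritParams backbone_rmsd
#' @param bound RMSD bound, A (2.0 by default; e.g. 2.5 for a remodelled
#'   receptor vs. its source structure).
#' @return list with `ok`, `max_rmsd`, `trace`.
#' @export
rmsd_monitor <- function(ensemble, reference = 1, selection = c("N", "CA", "C"),
                         bound = 2.0) {
  trace <- backbone_rmsd(ensemble, reference, selection)
  list(ok = all(trace <= bound), max_rmsd = max(trace), trace = trace)
}
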