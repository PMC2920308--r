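# cells x record-times matrix of activated X3
x3a_matrix <- function(ensemble) {
  do.call(rbind, lapply(ensemble$trajectories, function(tr) tr$states$x3a))
}

#' Per-cell activation times
#'
#' First-passage time of activated X3 past a fractional threshold, per
#' cell: the earliest record time with `x3a >= theta * x3_total`. Cells
#' that never reach the threshold within the recorded horizon get `NA`.
#' Activation is irreversible, so the time is monotone in `theta`.
#'
#' @param ensemble An `ensemble` (SSA or CLE).
#' @param theta Activation threshold as a fraction of `x3_total`, in
#'   (0, 1); 0.5 defines the "activated cell" count used throughout.
#' @return A data.frame with columns `cell_id` and `time`.
#' @export
activation_times <- function(ensemble, theta = 0.5) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta >= 1) {
    stop("theta must be in (0, 1)", call. = FALSE)
  }
  cut <- theta * ensemble$params$x3_total
  times <- ensemble$record_times
  data.frame(
    cell_id = vapply(ensemble$trajectories, function(tr) tr$cell_id, numeric(1)),
    time = vapply(ensemble$trajectories, function(tr) {
      j <- which(tr$states$x3a >= cut)
      if (length(j) == 0) NA_real_ else times[j[1]]
    }, numeric(1)))
}

#' Population moments, Fano factor and activated fraction over time
#'
#' At each record time, computes across cells the mean and unbiased sample
#' variance of activated X3, the Fano factor (variance/mean, reported `NA`
#' where the mean is zero), and the fraction of cells past half-activation
#' (`x3a >= theta * x3_total`; the paper-style n/N).
#'
#' A Fano factor far above 1 signals super-Poissonian cell-to-cell
#' variability: in the all-or-none regime it approaches
#' `(1 - n/N) * x3_total` (see [fano_sharp_rising()]).
#'
#' @inheritParams activation_times
#' @return A data.frame of class `ensemble_summary` with columns `time`,
#'   `mean`, `variance`, `fano`, `fraction_activated`.
#' @export
ensemble_moments <- function(ensemble, theta = 0.5) {
  X <- x3a_matrix(ensemble)
  if (nrow(X) < 2) {
    stop("ensemble_moments needs at least 2 cells (variance undefined)",
         call. = FALSE)
  }
  m <- colMeans(X)
  v <- apply(X, 2, stats::var)
  fano <- ifelse(m > 0, v / m, NA_real_)
  frac <- colMeans(X >= theta * ensemble$params$x3_total)
  structure(data.frame(time = ensemble$record_times,
                       mean = m, variance = v, fano = fano,
                       fraction_activated = frac),
            class = c("ensemble_summary", "data.frame"))
}

#' Sharp-rising (all-or-none) moment estimates
#'
#' In the all-or-none limit each cell is either fully inactive or fully
#' activated, so with `n` of `N` cells activated the population moments of
#' activated X3 are `mean = (n/N) * x3_total`, second moment
#' `(n/N) * x3_total^2`, hence
#' `variance = (n/N) * (1 - n/N) * x3_total^2` and Fano factor
#' `(1 - n/N) * x3_total` — of order `x3_total` (far above 1) until the
#' whole population has activated, and scaling linearly with `x3_total`.
#'
#' @param n Number of activated cells (0..N).
#' @param N Population size (>= 1).
#' @param x3_total Copy-number total of the downstream species.
#' @return A list with `mean`, `variance`, `fano` (`NA` at `n = 0`, where
#'   the mean vanishes).
#' @examples
#' fano_sharp_rising(50, 100, 100)  # mean 50, variance 2500, Fano 50
#' @export
fano_sharp_rising <- function(n, N, x3_total) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (n < 0 || n > N) stop("n must be in 0..N", call. = FALSE)
  f <- n / N
  list(mean = f * x3_total,
       variance = f * (1 - f) * x3_total^2,
       fano = if (n == 0) NA_real_ else (1 - f) * x3_total)
}

#' Snapshot distribution of activated X3 across the population
#'
#' Histogram of per-cell activated X3 at one record time, with equal-width
#' bins spanning `[0, x3_total]`, plus the modality label assigned by
#' [classify_modality()] with its default cutoffs.
#'
#' @param ensemble An `ensemble`.
#' @param t A time on the ensemble's record grid (matched within 1e-8;
#'   anything else is an error naming the nearest grid times).
#' @param n_bins Number of bins (default 20).
#' @return A list of class `histogram_snapshot`: `time`, `breaks`
#'   (`n_bins + 1` edges), `counts`, `prob` (counts / N, sums to 1),
#'   `values` (the raw per-cell activated counts), `x3_total`, `n_cells`,
#'   `modality`.
#' @export
snapshot_distribution <- function(ensemble, t, n_bins = 20) {
  times <- ensemble$record_times
  j <- which(abs(times - t) <= 1e-8)
  if (length(j) == 0) {
    near <- times[order(abs(times - t))][seq_len(min(2, length(times)))]
    stop(sprintf("t = %g is not on the record grid; nearest grid times: %s",
                 t, paste(format(near), collapse = ", ")), call. = FALSE)
  }
  j <- j[1]
  vals <- vapply(ensemble$trajectories, function(tr) tr$states$x3a[j],
                 numeric(1))
  x3t <- ensemble$params$x3_total
  breaks <- seq(0, x3t, length.out = n_bins + 1)
  # left-closed bins, last bin closed on both sides
  idx <- pmin(findInterval(vals, breaks, rightmost.closed = TRUE), n_bins)
  idx <- pmax(idx, 1L)
  counts <- tabulate(idx, nbins = n_bins)
  snap <- structure(list(time = times[j], breaks = breaks, counts = counts,
                         prob = counts / length(vals), values = vals,
                         x3_total = x3t, n_cells = length(vals),
                         modality = NA_character_),
                    class = "histogram_snapshot")
  snap$modality <- classify_modality(snap)
  snap
}

#' @export
print.histogram_snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> t = %g, %d cells, %d bins over [0, %g], modality: %s\n",
              x$time, x$n_cells, length(x$counts), x$x3_total, x$modality))
  invisible(x)
}

#' Classify the modality of a snapshot distribution
#'
#' Threshold-mass classifier: with `p_low` the fraction of cells at or
#' below `low_cut * x3_total` and `p_high` the fraction at or above
#' `high_cut * x3_total`, the snapshot is
#'
#' * `bimodal` if both tails hold at least `min_mass` and together at
#'   least 0.8 of the population;
#' * `unimodal_low` / `unimodal_high` if a single tail alone holds at
#'   least 0.8;
#' * `transitional` otherwise (e.g. a peak traveling through the interior,
#'   as under a strong stimulus).
#'
#' @param snapshot A `histogram_snapshot`.
#' @param low_cut,high_cut Tail cut points as fractions of `x3_total`.
#' @param min_mass Minimum mass per tail for bimodality.
#' @return One of `"unimodal_low"`, `"unimodal_high"`, `"bimodal"`,
#'   `"transitional"`.
#' @export
classify_modality <- function(snapshot, low_cut = 0.1, high_cut = 0.9,
                              min_mass = 0.05) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < 1)) {
    stop("need 0 < low_cut < high_cut < 1", call. = FALSE)
  }
  x3t <- snapshot$x3_total
  p_low <- mean(snapshot$values <= low_cut * x3t)
  p_high <- mean(snapshot$values >= high_cut * x3t)
  if (p_low >= min_mass && p_high >= min_mass && p_low + p_high >= 0.8) {
    "bimodal"
  } else if (p_low >= 0.8) {
    "unimodal_low"
  } else if (p_high >= 0.8) {
    "unimodal_high"
  } else {
    "transitional"
  }
}

#' Pathway attribution of X3 activation events
#'
#' Fraction of all X3-activation firings that went through the one-step
#' type A channel rather than the type B completion channel, read from the
#' cumulative firing counters at the final record:
#' `fireA / (fireA + fireB3)`, pooled over cells and per cell. A fraction
#' near 1 means deterministic one-step signaling; near 0, stochastic
#' cascade signaling.
#'
#' @param ensemble An SSA `ensemble` (CLE paths carry no firing counters
#'   and yield `NA`).
#' @return A list with `pooled` (scalar in \[0, 1\], `NA` if no X3
#'   activation occurred anywhere) and `per_cell` (numeric vector, `NA`
#'   for cells without X3 events).
#' @export
channel_attribution <- function(ensemble) {
  fin <- function(tr, col) tr$states[[col]][nrow(tr$states)]
  fA <- vapply(ensemble$trajectories, fin, numeric(1), col = "fireA")
  fB3 <- vapply(ensemble$trajectories, fin, numeric(1), col = "fireB3")
  tot <- fA + fB3
  per_cell <- ifelse(is.na(tot) | tot == 0, NA_real_, fA / tot)
  pooled <- if (anyNA(tot) || sum(tot) == 0) NA_real_ else sum(fA) / sum(tot)
  list(pooled = pooled, per_cell = per_cell)
}

#' Phase-diagram scan over the slow rate constant and the stimulus
#'
#' For every grid point `(k_b2, x0)` the scan reports the analytic regime
#' label of [classify_regime_analytic()] and an empirical label obtained by
#' simulating an SSA ensemble and thresholding the pooled channel-A
#' attribution: `>= 0.9` is `TYPE_A`, `<= 0.1` is `TYPE_B`, in between
#' `MIXED`. Agreement between the two labelings is expected only for grid
#' points lying well beyond (about a factor of 10 in `x0`) the analytic
#' thresholds, which are order-of-magnitude estimates.
#'
#' @param k_b2_grid,x0_grid Strictly increasing grids.
#' @param base_params A [network_params()] object supplying all other
#'   fields.
#' @param n_cells Cells per grid point.
#' @param t_max Horizon per cell (must cover activation at the slowest
#'   grid point).
#' @param master_seed Integer seed; each grid point uses a seed derived
#'   from it and the grid indices.
#' @param n_records Records per cell.
#' @return A data.frame of class `phase_diagram` with columns `k_b2`,
#'   `x0`, `analytic`, `empirical`, `attribution`.
#' @export
phase_diagram_scan <- function(k_b2_grid, x0_grid, base_params,
                               n_cells = 50, t_max = 2000,
                               master_seed = 1L, n_records = 101) {
  if (length(k_b2_grid) == 0 || length(x0_grid) == 0) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (is.unsorted(k_b2_grid, strictly = TRUE) ||
      is.unsorted(x0_grid, strictly = TRUE)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  grid <- expand.grid(k_b2 = k_b2_grid, x0 = x0_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- base_params
    p$k_b2 <- grid$k_b2[g]
    p$x0 <- grid$x0[g]
    analytic <- classify_regime_analytic(p)$label
    ens <- simulate_population(p, n_cells = n_cells, t_max = t_max,
                               record_times = seq(0, t_max,
                                                  length.out = n_records),
                               master_seed = cell_seed(master_seed, 7919L * g))
    att <- channel_attribution(ens)$pooled
    empirical <- if (is.na(att)) NA_character_
                 else if (att >= 0.9) "TYPE_A"
                 else if (att <= 0.1) "TYPE_B"
                 else "MIXED"
    data.frame(k_b2 = p$k_b2, x0 = p$x0, analytic = analytic,
               empirical = empirical, attribution = att)
  })
  structure(do.call(rbind, res),
            class = c("phase_diagram", "data.frame"))
}
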